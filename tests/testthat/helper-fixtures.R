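# shared fixtures: everything is built in code at test time

example_reference <- function() {
  read_reference_tables(system.file("extdata", "example_reference.yaml",
                                    package = "eggrisk"))
}

# profile with EF x ED = AT, so THQ reduces to EDI/RfD
toy_profile <- function(group = "male", BW = 60, FIR = 30) {
  tibble::tibble(group = group, BW = BW, FIR = FIR,
                 EF = 365, ED = 70, AT = 25550)
}

toy_profiles <- function() {
  dplyr::bind_rows(
    toy_profile("male", BW = 60, FIR = 30),
    toy_profile("female", BW = 55, FIR = 30),
    tibble::tibble(group = "child", BW = 15, FIR = 25,
                   EF = 365, ED = 6, AT = 2190))
}

toy_toxicity <- function() {
  tibble::tibble(metal = c("Cr", "Cd", "Pb", "Zn"),
                 rfd = c(0.003, 0.001, 0.0035, 0.3),
                 sf = c(0.5, 6.1, 0.0085, NA))
}

# deterministic little dataset: each (area, metal) gets `n` values spread
# around a distinct level, all free-range/non-mining unless remapped
toy_records <- function(areas = c("A1", "A2", "A3"),
                        metals = c("Cr", "Cd"), n = 3) {
  grid <- expand.grid(area = areas, metal = metals, rep = seq_len(n),
                      stringsAsFactors = FALSE)
  base <- 0.02 * match(grid$area, areas) + 0.005 * match(grid$metal, metals)
  concentration_records(tibble::tibble(
    sample_id = sprintf("%s-%02d", grid$area, grid$rep),
    area = grid$area,
    production_system = "free_range",
    mining_class = "non_mining",
    metal = grid$metal,
    concentration = base * (1 + 0.1 * grid$rep),
    below_lod = FALSE))
}
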