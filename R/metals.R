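#' Metals covered by the egg risk workflow
#'
#' `egg_metals()` returns the ten trace elements routinely quantified in whole
#' egg (yolk plus albumen) surveys; `egg_carcinogens()` returns the subset
#' treated as probable oral carcinogens, i.e. the metals for which a cancer
#' slope factor may be supplied.
#'
#' @return Character vector of element symbols.
#' @export
#' @examples
#' egg_metals()
#' egg_carcinogens()
egg_metals <- function() {
  c("Cr", "Mn", "Co", "Ni", "Cu", "Zn", "As", "Se", "Cd", "Pb")
}

#' @rdname egg_metals
#' @export
egg_carcinogens <- function() {
  c("Cr", "Cd", "Pb")
}

# canonical factor levels for categorical record fields
.production_systems <- c("free_range", "commercial")
.mining_classes <- c("mining", "non_mining")
.population_groups <- c("male", "female", "child")
.limit_authorities <- c("GB2762", "FAO_WHO", "EC", "user")

# stable metal ordering: surveyed metals first (fixed panel order), then any
# extra symbols alphabetically; used everywhere a sum over metals happens so
# that deterministic and Monte Carlo summations accumulate in the same order
metal_levels <- function(x) {
  x <- unique(as.character(x))
  c(intersect(egg_metals(), x), sort(setdiff(x, egg_metals())))
}
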