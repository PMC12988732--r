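#' Distribution specifications for Monte Carlo inputs
#'
#' Small constructors for the input-uncertainty families understood by the
#' Monte Carlo engine. Normal and triangular specifications describing
#' non-negative physical quantities are truncated at zero at sampling time
#' (via the inverse-CDF, so no rejection loop is involved). An empirical
#' specification resamples the observed values with replacement.
#'
#' @param value,mean,sd,meanlog,sdlog,low,mode,high,values Family-specific
#'   parameters.
#' @return An object of class `dist_spec`.
#' @name dist_spec
NULL

new_dist_spec <- function(family, params) {
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, !is.na(value))
  new_dist_spec("point", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  if (!is.numeric(sd) || sd <= 0) abort("normal spec requires sd > 0")
  new_dist_spec("normal", list(mean = mean, sd = sd))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  if (!is.numeric(sdlog) || sdlog < 0) abort("lognormal spec requires sdlog >= 0")
  new_dist_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high) {
  if (low > high) abort("uniform spec requires low <= high")
  new_dist_spec("uniform", list(low = low, high = high))
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(low, mode, high) {
  if (!(low <= mode && mode <= high)) {
    abort("triangular spec requires low <= mode <= high")
  }
  if (low == high) {
    return(dist_point(low))
  }
  new_dist_spec("triangular", list(low = low, mode = mode, high = high))
}

#' @rdname dist_spec
#' @export
dist_empirical <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("empirical spec requires a non-empty sample")
  new_dist_spec("empirical", list(values = values))
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- x$params
  desc <- switch(x$family,
    point = sprintf("point(%g)", p$value),
    normal = sprintf("normal(mean=%g, sd=%g) truncated at 0", p$mean, p$sd),
    lognormal = sprintf("lognormal(meanlog=%g, sdlog=%g)", p$meanlog, p$sdlog),
    uniform = sprintf("uniform(%g, %g)", p$low, p$high),
    triangular = sprintf("triangular(%g, %g, %g) truncated at 0",
                         p$low, p$mode, p$high),
    empirical = sprintf("empirical(n=%d)", length(p$values)))
  cat("<dist_spec>", desc, "\n")
  invisible(x)
}

# triangular CDF / inverse CDF (a = low, c = mode, b = high)
ptri <- function(q, low, mode, high) {
  ifelse(q <= low, 0,
  ifelse(q >= high, 1,
  ifelse(q <= mode,
         (q - low)^2 / ((high - low) * (mode - low)),
         1 - (high - q)^2 / ((high - low) * (high - mode)))))
}

qtri <- function(p, low, mode, high) {
  fc <- (mode - low) / (high - low)
  ifelse(p <= fc,
         low + sqrt(p * (high - low) * (mode - low)),
         high - sqrt((1 - p) * (high - low) * (high - mode)))
}

#' Draw random variates from a distribution specification
#'
#' Uses the calling environment's RNG stream (seed management belongs to the
#' Monte Carlo engine, see [run_mcs()]).
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, n),
    normal = {
      # inverse-CDF sampling restricted to [0, Inf)
      lo <- pnorm(0, p$mean, p$sd)
      qnorm(runif(n, lo, 1), p$mean, p$sd)
    },
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    uniform = if (p$low == p$high) rep(p$low, n) else runif(n, p$low, p$high),
    triangular = {
      lo <- if (p$low < 0) ptri(0, p$low, p$mode, p$high) else 0
      qtri(runif(n, lo, 1), p$low, p$mode, p$high)
    },
    empirical = if (length(p$values) == 1) {
      rep(p$values, n)
    } else {
      sample(p$values, n, replace = TRUE)
    },
    abort(paste0("Unknown distribution family: ", spec$family))
  )
}

#' Quantile function of a distribution specification
#'
#' Closed-form where available; for the empirical family, the type-7
#' (linear-interpolation) sample quantile of the stored values.
#'
#' @inheritParams dist_draw
#' @param prob Probability in `[0, 1]`. Vectorised.
#' @return Numeric vector of quantiles.
#' @export
dist_quantile <- function(spec, prob) {
  stopifnot(inherits(spec, "dist_spec"), all(prob >= 0 & prob <= 1))
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, length(prob)),
    normal = {
      lo <- pnorm(0, p$mean, p$sd)
      qnorm(lo + prob * (1 - lo), p$mean, p$sd)
    },
    lognormal = qlnorm(prob, p$meanlog, p$sdlog),
    uniform = p$low + prob * (p$high - p$low),
    triangular = {
      lo <- if (p$low < 0) ptri(0, p$low, p$mode, p$high) else 0
      qtri(lo + prob * (1 - lo), p$low, p$mode, p$high)
    },
    empirical = unname(quantile(p$values, prob, type = 7)),
    abort(paste0("Unknown distribution family: ", spec$family))
  )
}

#' Moment-matched lognormal specification
#'
#' Two parameterisations:
#' * `fit_lognormal(values)` matches the sample log-moments: `meanlog` and
#'   `sdlog` are the mean and SD of `log(values)`.
#' * `lognormal_from_mean_cv(mean, cv)` converts an arithmetic mean and
#'   coefficient of variation into the equivalent lognormal parameters
#'   (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = log(mean) - sdlog^2/2`).
#'
#' @param values Strictly positive sample values.
#' @param mean,cv Arithmetic mean (> 0) and coefficient of variation (>= 0).
#' @return A lognormal [dist_spec].
#' @export
fit_lognormal <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("lognormal fit requires at least 2 values")
  if (any(values <= 0)) abort("lognormal fit requires strictly positive values")
  lv <- log(values)
  dist_lognormal(mean(lv), sd(lv))
}

#' @rdname fit_lognormal
#' @export
lognormal_from_mean_cv <- function(mean, cv) {
  if (mean <= 0) abort("`mean` must be > 0")
  if (cv < 0) abort("`cv` must be >= 0")
  if (cv == 0) return(dist_point(mean))
  sdlog <- sqrt(log(1 + cv^2))
  dist_lognormal(log(mean) - sdlog^2 / 2, sdlog)
}
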