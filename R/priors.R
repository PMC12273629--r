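#' Prior specifications for ABC
#'
#' A prior spec is a named list with one entry per model parameter. Four
#' entry types are supported: `prior_uniform(lo, hi)` (uniform on the
#' natural scale), `prior_loguniform(lo, hi)` (uniform on the log scale,
#' for scale parameters spanning orders of magnitude), `prior_discrete()`
#' (discrete uniform, used for the feedback exponents over `{0, 1, 2}`)
#' and `prior_fixed(value)` (pinned, not inferred).
#'
#' Continuous priors are uniform on a transformed scale (identity or log);
#' MCMC proposals are Gaussian on that same scale, so proposal symmetry
#' makes the Metropolis prior-ratio equal to 1 inside the support.
#'
#' @param lo,hi Support bounds, `lo < hi` (`0 < lo` for log-uniform).
#' @param values Support of a discrete prior.
#' @param value Pinned value of a fixed parameter.
#' @name priors
#' @return A prior entry (list with class `abc_prior`).
NULL

#' @rdname priors
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(lo < hi)
  structure(list(type = "uniform", lo = lo, hi = hi), class = "abc_prior")
}

#' @rdname priors
#' @export
prior_loguniform <- function(lo, hi) {
  stopifnot(0 < lo, lo < hi)
  structure(list(type = "loguniform", lo = lo, hi = hi),
            class = "abc_prior")
}

#' @rdname priors
#' @export
prior_discrete <- function(values = 0:2) {
  stopifnot(length(values) >= 1)
  structure(list(type = "discrete", values = sort(unique(values))),
            class = "abc_prior")
}

#' @rdname priors
#' @export
prior_fixed <- function(value) {
  structure(list(type = "fixed", value = value), class = "abc_prior")
}

#' Bundle named priors into a specification
#'
#' @param ... Named `abc_prior` entries, one per model parameter.
#' @return A `prior_spec` list.
#' @examples
#' prior_spec(alpha = prior_uniform(0.01, 0.15),
#'            l = prior_discrete(0:2), m = prior_fixed(2))
#' @export
prior_spec <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.list(ps[[1]]) &&
      !inherits(ps[[1]], "abc_prior")) ps <- ps[[1]]
  if (is.null(names(ps)) || any(names(ps) == ""))
    stop("every prior must be named after its parameter", call. = FALSE)
  ok <- vapply(ps, inherits, logical(1), "abc_prior")
  if (!all(ok)) stop("all entries must be abc_prior objects", call. = FALSE)
  structure(ps, class = "prior_spec")
}

#' Default priors for the base embryogenesis model
#'
#' Uniform priors on biologically sensible ranges: net growth
#' `alpha` in `[0.01, 0.15]` per hour (doubling times of roughly 5-70 h),
#' blastomere differentiation `beta` in `[0.01, 1]` per hour, ICM bias
#' `rho` in `[0, 1]`, and log-uniform priors over `[1e-6, 1]` for the
#' specification coefficients `zeta` and `eta`, whose natural magnitude
#' depends on the unknown feedback exponent. Exponents `l` and `m` are
#' discrete uniform over `{0, 1, 2}`.
#'
#' @param fixed Named list of parameters to pin (becomes [prior_fixed()]).
#' @return A [prior_spec()].
#' @export
default_base_priors <- function(fixed = list()) {
  ps <- list(alpha = prior_uniform(0.01, 0.15),
             beta = prior_uniform(0.01, 1),
             rho = prior_uniform(0, 1),
             zeta = prior_loguniform(1e-6, 1),
             l = prior_discrete(0:2),
             eta = prior_loguniform(1e-6, 1),
             m = prior_discrete(0:2))
  for (nm in names(fixed)) ps[[nm]] <- prior_fixed(fixed[[nm]])
  prior_spec(ps)
}

#' Default priors for the chimera-specific parameters
#'
#' Donor growth `alpha_D` uniform in `[0.005, 0.15]` per hour, crowding
#' factor `a` uniform in `[0, 10]`, crowding exponent `n` discrete uniform
#' over `{0, 1, 2}`. Variant pinning (see [chimera_params()]) is applied
#' on top: `F` and `FC` pin `alpha_D`, `F` and `GF` pin `a` and `n`.
#'
#' @param variant Chimera model variant.
#' @param alpha Host growth rate, used when the variant pins `alpha_D`.
#' @param fixed Named list of additional parameters to pin.
#' @return A [prior_spec()].
#' @export
default_chimera_priors <- function(variant = "GFC", alpha = 0.06,
                                   fixed = list()) {
  ps <- list(alpha_D = prior_uniform(0.005, 0.15),
             a = prior_uniform(0, 10),
             n = prior_discrete(0:2))
  if (variant %in% c("F", "FC")) ps$alpha_D <- prior_fixed(alpha)
  if (variant %in% c("F", "GF")) {
    ps$a <- prior_fixed(0)
    ps$n <- prior_fixed(1L)
  }
  for (nm in names(fixed)) ps[[nm]] <- prior_fixed(fixed[[nm]])
  prior_spec(ps)
}

prior_is_free <- function(pr) pr$type != "fixed"

free_params <- function(priors) names(priors)[vapply(priors, prior_is_free,
                                                     logical(1))]

prior_sample <- function(priors) {
  vals <- lapply(priors, function(pr) switch(pr$type,
    uniform = stats::runif(1, pr$lo, pr$hi),
    loguniform = exp(stats::runif(1, log(pr$lo), log(pr$hi))),
    discrete = sample(pr$values, 1),
    fixed = pr$value))
  stats::setNames(as.numeric(vals), names(priors))
}

prior_in_support <- function(priors, theta) {
  all(vapply(names(priors), function(nm) {
    pr <- priors[[nm]]; v <- theta[[nm]]
    switch(pr$type,
      uniform = v >= pr$lo && v <= pr$hi,
      loguniform = v >= pr$lo && v <= pr$hi,
      discrete = v %in% pr$values,
      fixed = isTRUE(all.equal(v, pr$value)))
  }, logical(1)))
}

propose_theta <- function(priors, theta, scales) {
  out <- theta
  for (nm in free_params(priors)) {
    pr <- priors[[nm]]
    out[[nm]] <- switch(pr$type,
      uniform = theta[[nm]] + stats::rnorm(1, 0, scales[[nm]]),
      loguniform = exp(log(theta[[nm]]) + stats::rnorm(1, 0, scales[[nm]])),
      discrete = {
        step <- sample(c(-1, 1), 1)
        cand <- theta[[nm]] + step
        # out-of-range steps keep the current value (symmetric kernel)
        if (cand %in% pr$values) cand else theta[[nm]]
      })
  }
  out
}

default_scales <- function(priors, frac = 0.05) {
  sc <- lapply(priors, function(pr) switch(pr$type,
    uniform = frac * (pr$hi - pr$lo),
    loguniform = frac * (log(pr$hi) - log(pr$lo)),
    0))
  stats::setNames(as.numeric(sc), names(priors))
}
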