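#' Rate parameters for the base embryogenesis model
#'
#' Bundles the rate constants and feedback exponents of the compartment
#' model of blastocyst formation. All host cells proliferate with a single
#' net per-capita rate `alpha` (division minus death). Blastomeres
#' differentiate at total per-capita rate `beta`, splitting between
#' unspecified inner cell mass (ICM) with bias `rho` and trophectoderm with
#' bias `1 - rho`. Unspecified ICM cells specify to epiblast at per-capita
#' rate `zeta * P^l` (positive feedback from primitive endoderm, PrE) and to
#' PrE at per-capita rate `eta * (C + E)^m` (FGF4 feedback from unspecified
#' ICM and epiblast).
#'
#' @param alpha Net per-capita growth rate (per hour), `>= 0`.
#' @param beta Blastomere differentiation rate (per hour), `>= 0`.
#' @param rho Blastomere bias toward unspecified ICM, in `[0, 1]`.
#' @param zeta Epiblast-specification rate coefficient (per hour per
#'   cells^`l`), `>= 0`.
#' @param l PrE-feedback exponent, integer in `{0, 1, 2}`.
#' @param eta PrE-specification rate coefficient (per hour per cells^`m`),
#'   `>= 0`.
#' @param m FGF4-feedback exponent, integer in `{0, 1, 2}`.
#'
#' @return An object of class `base_params`.
#' @seealso [chimera_params()], [base_rhs()], [solve_embryo()]
#' @examples
#' p <- base_params(alpha = 0.06, beta = 0.3, rho = 0.35,
#'                  zeta = 5e-4, l = 2, eta = 5e-4, m = 2)
#' @export
base_params <- function(alpha = 0.06, beta = 0.3, rho = 0.35,
                        zeta = 5e-4, l = 2, eta = 5e-4, m = 2) {
  p <- structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         rho = as.numeric(rho), zeta = as.numeric(zeta), l = as.integer(l),
         eta = as.numeric(eta), m = as.integer(m)),
    class = "base_params")
  validate_base_params(p)
  p
}

validate_base_params <- function(p) {
  stopifnot(inherits(p, "base_params"))
  with(p, {
    if (!all(is.finite(c(alpha, beta, rho, zeta, eta))))
      stop("base_params: all rates must be finite", call. = FALSE)
    if (alpha < 0 || beta < 0 || zeta < 0 || eta < 0)
      stop("base_params: rates alpha, beta, zeta, eta must be >= 0",
           call. = FALSE)
    if (rho < 0 || rho > 1)
      stop("base_params: rho must lie in [0, 1]", call. = FALSE)
    if (!(l %in% 0:2) || !(m %in% 0:2))
      stop("base_params: exponents l and m must be in {0, 1, 2}",
           call. = FALSE)
  })
  invisible(p)
}

#' Rate parameters for the chimera model
#'
#' Extends [base_params()] with donor-cell dynamics for embryonic stem cell
#' (ESC) chimeras. Donor cells grow at net per-capita rate `alpha_D` and may
#' crowd host blastomeres away from the inner cell mass: the ICM bias `rho`
#' of the base model is reinterpreted as an uncrowded bias `rho0` and
#' replaced by the decreasing function
#' `rho_eff = rho0 / (1 + a * (D_plus + D_minus)^n)`. Fgf4+/+ donor cells
#' additionally contribute to FGF4 induction of PrE: the PrE-specification
#' rate becomes `eta * (C + E + D_plus)^m`.
#'
#' Four nested variants are used for model comparison:
#' \describe{
#'   \item{`"F"`}{FGF4 induction only: `alpha_D = alpha`, `a = 0`.}
#'   \item{`"GF"`}{FGF4 induction plus differential donor growth: `a = 0`.}
#'   \item{`"FC"`}{FGF4 induction plus crowding, equal growth:
#'     `alpha_D = alpha`.}
#'   \item{`"GFC"`}{growth, FGF4 induction and crowding all free.}
#' }
#' The constructor enforces the variant's pinning constraints.
#'
#' @param base A [base_params()] object; its `rho` is read as `rho0`.
#' @param alpha_D Donor net per-capita growth rate (per hour), `>= 0`.
#' @param a Crowding factor (per cells^`n`), `>= 0`.
#' @param n Crowding feedback exponent, integer in `{0, 1, 2}`.
#' @param variant One of `"F"`, `"GF"`, `"FC"`, `"GFC"`.
#'
#' @return An object of class `chimera_params`.
#' @examples
#' cp <- chimera_params(base_params(), alpha_D = 0.02, a = 0.1, n = 1,
#'                      variant = "GFC")
#' @export
chimera_params <- function(base = base_params(), alpha_D = base$alpha,
                           a = 0, n = 1L, variant = c("GFC", "F", "GF", "FC")) {
  variant <- match.arg(variant)
  validate_base_params(base)
  p <- structure(
    list(base = base, alpha_D = as.numeric(alpha_D), a = as.numeric(a),
         n = as.integer(n), variant = variant),
    class = "chimera_params")
  validate_chimera_params(p)
  p
}

validate_chimera_params <- function(p) {
  stopifnot(inherits(p, "chimera_params"))
  if (!is.finite(p$alpha_D) || p$alpha_D < 0)
    stop("chimera_params: alpha_D must be finite and >= 0", call. = FALSE)
  if (!is.finite(p$a) || p$a < 0)
    stop("chimera_params: crowding factor a must be finite and >= 0",
         call. = FALSE)
  if (!(p$n %in% 0:2))
    stop("chimera_params: exponent n must be in {0, 1, 2}", call. = FALSE)
  eq <- function(x, y) isTRUE(all.equal(x, y, tolerance = 1e-12))
  if (p$variant == "F" && !(eq(p$alpha_D, p$base$alpha) && p$a == 0))
    stop("variant F requires alpha_D = alpha and a = 0", call. = FALSE)
  if (p$variant == "GF" && p$a != 0)
    stop("variant GF requires a = 0", call. = FALSE)
  if (p$variant == "FC" && !eq(p$alpha_D, p$base$alpha))
    stop("variant FC requires alpha_D = alpha", call. = FALSE)
  invisible(p)
}

#' @export
print.base_params <- function(x, ...) {
  cat("Base embryogenesis model parameters:\n")
  cat(sprintf("  alpha = %.4g /h, beta = %.4g /h, rho = %.4g\n",
              x$alpha, x$beta, x$rho))
  cat(sprintf("  EPI specification: zeta = %.4g, l = %d (PrE feedback)\n",
              x$zeta, x$l))
  cat(sprintf("  PrE specification: eta = %.4g, m = %d (FGF4 feedback)\n",
              x$eta, x$m))
  invisible(x)
}

#' @export
print.chimera_params <- function(x, ...) {
  cat(sprintf("Chimera model parameters (variant %s):\n", x$variant))
  cat(sprintf("  alpha_D = %.4g /h, a = %.4g, n = %d\n",
              x$alpha_D, x$a, x$n))
  print(x$base)
  invisible(x)
}

#' Cell-count state of one embryo at one time
#'
#' @param t Time in hours since the 8-cell stage.
#' @param B Blastomeres. @param T_ Trophectoderm. @param C Unspecified ICM.
#' @param P Primitive endoderm. @param E Epiblast.
#' @param D_plus Fgf4+/+ donor cells. @param D_minus Fgf4-/- donor cells.
#'
#' @return Named numeric vector of class `embryo_state` with attribute `t`.
#' @examples
#' embryo_state(B = 8) # 8-cell morula, the standard initial condition
#' @export
embryo_state <- function(t = 0, B = 0, T_ = 0, C = 0, P = 0, E = 0,
                         D_plus = 0, D_minus = 0) {
  x <- c(B = B, T = T_, C = C, P = P, E = E,
         D_plus = D_plus, D_minus = D_minus)
  if (any(!is.finite(x)) || any(x < 0))
    stop("embryo_state: all compartments must be finite and >= 0",
         call. = FALSE)
  structure(x, t = as.numeric(t), class = "embryo_state")
}

state_species <- c("B", "T", "C", "P", "E", "D_plus", "D_minus")
host_species  <- c("B", "T", "C", "P", "E")

#' Total cell number of a state
#' @param state An [embryo_state()] or named vector over the model species.
#' @return Sum of all compartments.
#' @export
state_total <- function(state) sum(unclass(state)[state_species], na.rm = TRUE)
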