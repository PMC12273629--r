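#' Right-hand side of the base embryogenesis ODE system
#'
#' Rates of change of the five host compartments. All compartments grow at
#' net rate `alpha`; blastomeres convert to trophectoderm and unspecified
#' ICM at per-capita rates `(1 - rho) * beta` and `rho * beta`; unspecified
#' ICM converts to PrE at per-capita rate `eta * (C + E)^m` and to epiblast
#' at `zeta * P^l`:
#' \deqn{dB/dt = \alpha B - \beta B}
#' \deqn{dT/dt = \alpha T + (1 - \rho)\beta B}
#' \deqn{dC/dt = \alpha C + \rho\beta B - \eta (C+E)^m C - \zeta P^l C}
#' \deqn{dP/dt = \alpha P + \eta (C+E)^m C}
#' \deqn{dE/dt = \alpha E + \zeta P^l C}
#' Transition terms cancel pairwise, so the total obeys
#' `d(total)/dt = alpha * total` exactly.
#'
#' @param state An [embryo_state()] (donor compartments must be zero) or a
#'   named vector with entries `B, T, C, P, E`.
#' @param params A [base_params()] object.
#' @return Named numeric vector of derivatives over `B, T, C, P, E`.
#' @export
base_rhs <- function(state, params) {
  validate_base_params(params)
  s <- as_state_vector(state)
  if (any(s < 0))
    stop("base_rhs: negative compartment", call. = FALSE)
  if (s[["D_plus"]] != 0 || s[["D_minus"]] != 0)
    stop("base_rhs: donor compartments must be zero in the base model; ",
         "use chimera_rhs()", call. = FALSE)
  with(params, {
    B <- s[["B"]]; T <- s[["T"]]; C <- s[["C"]]
    P <- s[["P"]]; E <- s[["E"]]
    pre_rate <- eta * (C + E)^m   # FGF4 feedback
    epi_rate <- zeta * P^l        # PrE feedback
    c(B = alpha * B - beta * B,
      T = alpha * T + (1 - rho) * beta * B,
      C = alpha * C + rho * beta * B - pre_rate * C - epi_rate * C,
      P = alpha * P + pre_rate * C,
      E = alpha * E + epi_rate * C)
  })
}

#' Right-hand side of the chimera ODE system
#'
#' As [base_rhs()], with two modifications and two donor equations. The ICM
#' bias becomes `rho_eff = rho0 / (1 + a * (D_plus + D_minus)^n)` (crowding
#' displacement), the PrE-induction term becomes
#' `eta * (C + E + D_plus)^m` (FGF4 production by Fgf4+/+ donors), and
#' donors grow exponentially: `dD/dt = alpha_D * D`. Only one donor
#' genotype may be present at a time.
#'
#' @param state An [embryo_state()] or named vector over the seven species.
#' @param params A [chimera_params()] object.
#' @return Named numeric vector of derivatives over all seven species.
#' @export
chimera_rhs <- function(state, params) {
  validate_chimera_params(params)
  s <- as_state_vector(state)
  if (any(s < 0))
    stop("chimera_rhs: negative compartment", call. = FALSE)
  if (s[["D_plus"]] > 0 && s[["D_minus"]] > 0)
    stop("chimera_rhs: at most one donor genotype may be present",
         call. = FALSE)
  b <- params$base
  B <- s[["B"]]; T <- s[["T"]]; C <- s[["C"]]
  P <- s[["P"]]; E <- s[["E"]]
  Dp <- s[["D_plus"]]; Dm <- s[["D_minus"]]
  rho_eff <- crowded_rho(b$rho, params$a, params$n, Dp + Dm)
  pre_rate <- b$eta * (C + E + Dp)^b$m
  epi_rate <- b$zeta * P^b$l
  c(B = b$alpha * B - b$beta * B,
    T = b$alpha * T + (1 - rho_eff) * b$beta * B,
    C = b$alpha * C + rho_eff * b$beta * B - pre_rate * C - epi_rate * C,
    P = b$alpha * P + pre_rate * C,
    E = b$alpha * E + epi_rate * C,
    D_plus = params$alpha_D * Dp,
    D_minus = params$alpha_D * Dm)
}

#' Crowded ICM bias
#'
#' `rho0 / (1 + a * D^n)`: the blastomere bias toward unspecified ICM as a
#' decreasing function of the number of donor cells `D` present.
#'
#' @param rho0 Uncrowded bias. @param a Crowding factor.
#' @param n Crowding exponent in `{0, 1, 2}`. @param D Donor cell number.
#' @return Effective bias in `[0, rho0]`.
#' @export
crowded_rho <- function(rho0, a, n, D) rho0 / (1 + a * D^n)

as_state_vector <- function(state) {
  x <- unclass(state)
  if (is.null(names(x)))
    stop("state must be a named vector or embryo_state", call. = FALSE)
  out <- stats::setNames(numeric(length(state_species)), state_species)
  out[intersect(names(x), state_species)] <-
    x[intersect(names(x), state_species)]
  out
}

#' Solve the embryogenesis or chimera model deterministically
#'
#' Integrates the compartment ODE system with an adaptive explicit
#' Runge-Kutta method (Dormand-Prince 4(5), via \pkg{deSolve}) at tight
#' tolerances, returning the trajectory on a fixed output grid. The default
#' setup is an 8-cell morula (`B(0) = 8`, all else 0) integrated over
#' `[0, 48]` hours at 0.1 h resolution; chimera injections add
#' `D_plus(0)` or `D_minus(0)` of 10 or 15 cells.
#'
#' Compartments are analytically non-negative; values within `-clip_tol` of
#' zero (integrator round-off) are clipped to 0 on output and anything more
#' negative raises an error.
#'
#' @param params A [base_params()] or [chimera_params()] object.
#' @param initial Initial [embryo_state()]. Defaults to the 8-cell morula.
#' @param t_max Final time (hours).
#' @param t_grid Output times. Defaults to `seq(0, t_max, by = 0.1)`.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param clip_tol Round-off clipping threshold for negative outputs.
#' @param method \pkg{deSolve} integration method. The default `"ode45"`
#'   (Dormand-Prince) is the reference choice; `"lsoda"` switches to an
#'   implicit scheme automatically and is preferred inside ABC, where
#'   prior draws can make specification rates stiff.
#' @param maxsteps Step budget per output interval.
#' @return A `trajectory` object: a data.frame with columns `t` and the
#'   model species, plus attributes `params` and `t_max`.
#' @examples
#' tr <- solve_embryo(base_params(alpha = log(2) / 12, beta = 0,
#'                                zeta = 0, eta = 0))
#' tail(tr, 1) # ~128 cells after four doublings
#' @export
solve_embryo <- function(params, initial = embryo_state(B = 8),
                         t_max = 48, t_grid = NULL,
                         rtol = 1e-10, atol = 1e-10, clip_tol = 1e-7,
                         method = "ode45", maxsteps = 50000) {
  is_chimera <- inherits(params, "chimera_params")
  if (!is_chimera) validate_base_params(params)
  y0 <- as_state_vector(initial)
  if (t_max < 0) stop("t_max must be >= 0", call. = FALSE)
  if (is.null(t_grid)) t_grid <- seq(0, t_max, by = 0.1)
  t_grid <- sort(unique(c(0, t_grid, t_max)))
  if (t_max == 0) {
    df <- as.data.frame(as.list(c(t = 0, y0)))
    return(new_trajectory(df, params, t_max))
  }
  # the RHS is integrated in compiled form (src/rhs.c, deSolve compiled-
  # function convention); base_rhs()/chimera_rhs() are the documented
  # reference forms and the test suite pins the two together
  if (is_chimera) {
    b <- params$base
    parms <- c(b$alpha, b$beta, b$rho, b$zeta, b$l, b$eta, b$m,
               params$alpha_D, params$a, params$n)
    func <- "chimera_derivs"; initfunc <- "chimera_initmod"
  } else {
    parms <- c(params$alpha, params$beta, params$rho, params$zeta,
               params$l, params$eta, params$m)
    func <- "base_derivs"; initfunc <- "base_initmod"
  }
  y0_used <- if (is_chimera) y0 else y0[host_species]
  if (!is_chimera && (y0[["D_plus"]] != 0 || y0[["D_minus"]] != 0))
    stop("base model cannot carry donor cells; use chimera_params",
         call. = FALSE)
  sol <- withCallingHandlers(
    deSolve::ode(y = y0_used, times = t_grid, func = func,
                 parms = parms, dllname = "blastoabc",
                 initfunc = initfunc, method = method,
                 rtol = rtol, atol = atol, maxsteps = maxsteps),
    warning = function(w) invokeRestart("muffleWarning"))
  diagn <- attr(sol, "istate")
  if ((!is.null(diagn) && diagn[1] < 0) || nrow(sol) < length(t_grid) ||
      anyNA(sol))
    stop("ODE integration failed (deSolve istate = ",
         if (is.null(diagn)) NA else diagn[1], ")", call. = FALSE)
  sol <- as.data.frame(sol)
  names(sol)[1] <- "t"
  if (!is_chimera) { sol$D_plus <- 0; sol$D_minus <- 0 }
  vals <- as.matrix(sol[state_species])
  if (any(vals < -clip_tol))
    stop("integrator produced negative compartment below -clip_tol (min ",
         format(min(vals)), "); tighten tolerances", call. = FALSE)
  sol[state_species] <- pmax(vals, 0)
  new_trajectory(sol, params, t_max)
}

new_trajectory <- function(df, params, t_max) {
  structure(df, params = params, t_max = t_max,
            class = c("trajectory", "data.frame"))
}

#' Extract the state of a trajectory at (or just before) a time
#' @param traj A `trajectory`. @param t Time in hours.
#' @return Named species vector at the last grid time `<= t`.
#' @export
trajectory_state <- function(traj, t) {
  idx <- findInterval(t, traj$t)
  if (idx < 1) stop("t precedes the trajectory start", call. = FALSE)
  unlist(traj[idx, state_species])
}

#' Asymptotic trophectoderm fraction of the base model
#'
#' Convenience wrapper: integrates the base model until the blastomere pool
#' is exhausted and returns the trophectoderm share of all cells. With
#' specification switched off (`zeta = eta = 0`) this converges to
#' `1 - rho`: the embryo settles into a fixed trophectoderm to ICM ratio
#' set solely by the blastomere lineage bias.
#'
#' @param params A [base_params()] with `beta > 0`.
#' @param t_max Integration horizon (hours); increase if blastomeres are
#'   not exhausted by then.
#' @param exhaustion_tol Required bound on `B / total` at `t_max`.
#' @return `T / total` at `t_max`.
#' @examples
#' asymptotic_te_fraction(base_params(rho = 0.35, zeta = 0, eta = 0)) # 0.65
#' @export
asymptotic_te_fraction <- function(params, t_max = 48,
                                   exhaustion_tol = 1e-3) {
  validate_base_params(params)
  if (params$beta <= 0)
    stop("beta must be > 0 for blastomeres to exhaust", call. = FALSE)
  tr <- solve_embryo(params, t_max = t_max)
  fin <- trajectory_state(tr, t_max)
  total <- sum(fin)
  if (fin[["B"]] / total >= exhaustion_tol)
    stop("blastomeres not exhausted at t_max = ", t_max,
         " (B/total = ", format(fin[["B"]] / total),
         "); increase t_max", call. = FALSE)
  unname(fin[["T"]] / total)
}
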