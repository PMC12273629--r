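# Independent oracles the implementation is checked against.

# Fixed-step classical RK4 built on the exported (reference) RHS
# functions; independent of the compiled integration path.
rk4_solve <- function(params, y0, t_max, h = 0.005) {
  is_chimera <- inherits(params, "chimera_params")
  f <- if (is_chimera) {
    function(y) chimera_rhs(y, params)
  } else {
    function(y) base_rhs(y[c("B", "T", "C", "P", "E")], params)
  }
  y <- y0
  nm <- names(f(y))
  steps <- ceiling(t_max / h)
  h <- t_max / steps
  yv <- y[nm]
  for (i in seq_len(steps)) {
    k1 <- f(yv)
    k2 <- f(pmax(yv + h / 2 * k1, 0))
    k3 <- f(pmax(yv + h / 2 * k2, 0))
    k4 <- f(pmax(yv + h * k3, 0))
    yv <- pmax(yv + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  yv
}

# Brute-force re-implementation of the three-term state-space statistic,
# written as explicit loops.
brute_force_S <- function(traj, data, weights = c(1, 1, 1)) {
  so <- attr(data, "species_order")
  df <- as.data.frame(data)
  s1 <- 0
  for (n in seq_len(nrow(df))) {
    best <- Inf
    for (ti in seq_len(nrow(traj))) {
      d2 <- 0
      for (j in seq_along(so))
        d2 <- d2 + (traj[[so[[j]]]][ti] - df[[names(so)[j]]][n])^2
      if (d2 < best) best <- d2
    }
    s1 <- s1 + best
  }
  s2 <- 0
  for (j in seq_along(so))
    s2 <- s2 + (max(traj[[so[[j]]]]) - max(df[[names(so)[j]]]))^2
  last <- nrow(traj)
  s3 <- traj$B[last]^2 + traj$C[last]^2
  sum(weights * c(s1, s2, s3))
}

# Hand-rolled trajectory object for summary-statistic unit tests.
toy_trajectory <- function(df, t_max = max(df$t)) {
  for (sp in c("B", "T", "C", "P", "E", "D_plus", "D_minus"))
    if (is.null(df[[sp]])) df[[sp]] <- 0
  structure(df, params = NULL, t_max = t_max,
            class = c("trajectory", "data.frame"))
}

# Standard small parameter sets reused across tests.
std_base <- function() base_params()
std_gfc <- function(alpha_D = 0.02, a = 0.1, n = 1L)
  chimera_params(base_params(), alpha_D = alpha_D, a = a, n = n,
                 variant = "GFC")

random_state <- function(max_cells = 50) {
  counts <- stats::runif(5, 0, max_cells)
  embryo_state(B = counts[1], T_ = counts[2], C = counts[3],
               P = counts[4], E = counts[5])
}

random_base_params <- function() {
  base_params(alpha = stats::runif(1, 0, 0.1),
              beta = stats::runif(1, 0, 0.5),
              rho = stats::runif(1),
              zeta = 10^stats::runif(1, -5, -2),
              l = sample(0:2, 1),
              eta = 10^stats::runif(1, -5, -2),
              m = sample(0:2, 1))
}
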