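#' Build the reaction network matching a compartment model
#'
#' Translates the deterministic model into a continuous-time Markov chain:
#' every ODE term becomes one reaction. Host species gain a birth reaction
#' `X -> 2X` at propensity `alpha * X` (net growth realised as pure birth;
#' see Details), donors at `alpha_D * D`; blastomeres convert to
#' trophectoderm and unspecified ICM at `(1 - rho_eff) * beta * B` and
#' `rho_eff * beta * B`; unspecified ICM converts to PrE at
#' `eta * (C + E + D_plus)^m * C` and to epiblast at `zeta * P^l * C`.
#' State-dependent propensities are recomputed after every event (exact
#' direct-method SSA, no tau-leaping).
#'
#' The deterministic model uses a net per-capita rate capturing both
#' division and death. A jump process needs the two separated; by default
#' the net rate is realised as pure birth (`birth_rate = alpha`,
#' `death_rate = 0`), the minimal-variance realisation with the same mean.
#' A birth/death split with `birth - death = alpha` can be requested via
#' `death_rate`.
#'
#' @param params A [base_params()] or [chimera_params()] object.
#' @param death_rate Optional per-capita death rate `d >= 0`; birth then
#'   runs at `alpha + d` so the net rate is unchanged.
#' @return A `reaction_network`: list with `species`, and `reactions`, each
#'   reaction a list with `name`, `change` (stoichiometry vector) and
#'   `propensity(state)`.
#' @export
build_network <- function(params, death_rate = 0) {
  if (death_rate < 0) stop("death_rate must be >= 0", call. = FALSE)
  is_chimera <- inherits(params, "chimera_params")
  b <- if (is_chimera) params$base else params
  validate_base_params(b)
  species <- if (is_chimera) state_species else host_species
  unit <- function(sp, v = 1) {
    x <- stats::setNames(numeric(length(species)), species); x[sp] <- v; x
  }
  birth <- b$alpha + death_rate
  reactions <- list()
  add <- function(name, change, propensity) {
    reactions[[length(reactions) + 1L]] <<-
      list(name = name, change = change, propensity = propensity)
  }
  for (sp in intersect(species, host_species)) {
    local({
      sp <- sp
      add(paste0("birth_", sp), unit(sp),
          function(s) birth * s[[sp]])
      if (death_rate > 0)
        add(paste0("death_", sp), unit(sp, -1),
            function(s) death_rate * s[[sp]])
    })
  }
  if (is_chimera) {
    for (sp in c("D_plus", "D_minus")) {
      local({
        sp <- sp
        add(paste0("birth_", sp), unit(sp),
            function(s) params$alpha_D * s[[sp]])
      })
    }
  }
  rho_fun <- if (is_chimera) {
    function(s) crowded_rho(b$rho, params$a, params$n,
                            s[["D_plus"]] + s[["D_minus"]])
  } else {
    function(s) b$rho
  }
  dplus <- function(s) if (is_chimera) s[["D_plus"]] else 0
  add("B_to_T", unit("B", -1) + unit("T"),
      function(s) (1 - rho_fun(s)) * b$beta * s[["B"]])
  add("B_to_C", unit("B", -1) + unit("C"),
      function(s) rho_fun(s) * b$beta * s[["B"]])
  add("C_to_P", unit("C", -1) + unit("P"),
      function(s) b$eta * (s[["C"]] + s[["E"]] + dplus(s))^b$m * s[["C"]])
  add("C_to_E", unit("C", -1) + unit("E"),
      function(s) b$zeta * s[["P"]]^b$l * s[["C"]])
  structure(list(species = species, reactions = reactions, params = params),
            class = "reaction_network")
}

#' Run one exact Gillespie (direct-method) realisation
#'
#' Simulates the jump process defined by a [build_network()] network from
#' an integer initial state. Event times are drawn from the exponential
#' waiting-time distribution with rate equal to the summed propensity; the
#' reaction is chosen proportionally to its propensity; the state changes
#' by exactly that reaction's stoichiometry. When all propensities vanish
#' the state is absorbed and held to `t_max`.
#'
#' @param network A `reaction_network`.
#' @param initial Initial [embryo_state()] with integer counts.
#' @param t_max Final time (hours).
#' @param seed Optional integer seed for reproducibility.
#' @return A `trajectory` whose rows are the initial state, every jump, and
#'   a final row holding the last state at `t_max`.
#' @export
gillespie_run <- function(network, initial = embryo_state(B = 8),
                          t_max = 48, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- network$species
  s <- as_state_vector(initial)[species]
  if (any(s != round(s)))
    stop("gillespie_run: initial state must be integer-valued",
         call. = FALSE)
  n_re <- length(network$reactions)
  changes <- do.call(rbind, lapply(network$reactions, `[[`, "change"))
  props <- lapply(network$reactions, `[[`, "propensity")
  # grow the record geometrically; typical runs have O(100) events
  cap <- 256L
  rec_t <- numeric(cap); rec_s <- matrix(0, cap, length(species))
  colnames(rec_s) <- species
  k <- 1L; t <- 0
  rec_t[1] <- 0; rec_s[1, ] <- s
  sl <- as.list(s)
  repeat {
    a <- vapply(props, function(f) f(sl), numeric(1))
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > t_max) break
    j <- sample.int(n_re, 1L, prob = a)
    s <- s + changes[j, ]
    sl <- as.list(s)
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      rec_t <- c(rec_t, numeric(cap / 2L))
      rec_s <- rbind(rec_s, matrix(0, cap / 2L, length(species)))
    }
    rec_t[k] <- t; rec_s[k, ] <- s
  }
  df <- data.frame(t = c(rec_t[seq_len(k)], t_max))
  mat <- rbind(rec_s[seq_len(k), , drop = FALSE], s)
  for (sp in state_species)
    df[[sp]] <- if (sp %in% species) mat[, sp] else 0
  new_trajectory(df, network$params, t_max)
}

#' Run an ensemble of independent Gillespie replicates
#'
#' @param network A `reaction_network`.
#' @param initial Initial integer [embryo_state()].
#' @param t_max Final time (hours).
#' @param n_reps Number of replicates (`>= 1`).
#' @param seed Integer seed; replicate `i` runs under sub-seed `seed + i`,
#'   so identical seeds reproduce the ensemble exactly.
#' @return A `stochastic_ensemble`: list with `replicates` (trajectories),
#'   `seed` and `n_reps`.
#' @export
gillespie_ensemble <- function(network, initial = embryo_state(B = 8),
                               t_max = 48, n_reps = 100, seed = 1L) {
  stopifnot(n_reps >= 1)
  reps <- lapply(seq_len(n_reps), function(i)
    gillespie_run(network, initial, t_max, seed = seed + i))
  structure(list(replicates = reps, seed = seed, n_reps = n_reps),
            class = "stochastic_ensemble")
}

#' Cross-replicate summary of a stochastic ensemble at one time
#'
#' Evaluates every replicate at the last event before (or at) time `t` and
#' summarises each compartment across replicates.
#'
#' @param ensemble A `stochastic_ensemble` with at least two replicates.
#' @param t Time (hours), within every replicate's horizon.
#' @return Data frame with one row per species: mean, sd and the
#'   2.5/25/50/75/97.5 percent quantiles.
#' @export
ensemble_summary <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "stochastic_ensemble"),
            ensemble$n_reps >= 2)
  if (any(vapply(ensemble$replicates, function(tr) t > attr(tr, "t_max"),
                 logical(1))))
    stop("t exceeds the ensemble horizon t_max", call. = FALSE)
  states <- t(vapply(ensemble$replicates,
                     function(tr) trajectory_state(tr, t),
                     numeric(length(state_species))))
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  out <- data.frame(
    species = colnames(states),
    mean = colMeans(states),
    sd = apply(states, 2, stats::sd),
    row.names = NULL)
  qm <- t(apply(states, 2, stats::quantile, probs = qs, type = 7))
  colnames(qm) <- paste0("q", c("2.5", "25", "50", "75", "97.5"))
  cbind(out, as.data.frame(qm, row.names = seq_len(nrow(out))))
}
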