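#' ABC run configuration
#'
#' @param epsilon Acceptance threshold on the summary statistic, `> 0`.
#' @param n_iterations Chain length (ABC-MCMC) , `>= 1`.
#' @param proposal_scales Optional named per-parameter Gaussian step
#'   standard deviations (on the prior's transformed scale); defaults to
#'   5 percent of each prior's range.
#' @param seed Integer RNG seed.
#' @param thinning Keep every `thinning`-th post-burn-in state.
#' @param burn_in Number of initial states to discard.
#' @param init_budget Prior draws allowed when searching for a starting
#'   state with `S <= epsilon`.
#' @return An `abc_config` list.
#' @export
abc_config <- function(epsilon, n_iterations = 10000,
                       proposal_scales = NULL, seed = 1L,
                       thinning = 1L, burn_in = 0L, init_budget = 1e5) {
  stopifnot(epsilon > 0, n_iterations >= 1, thinning >= 1, burn_in >= 0)
  structure(list(epsilon = epsilon, n_iterations = as.integer(n_iterations),
                 proposal_scales = proposal_scales, seed = as.integer(seed),
                 thinning = as.integer(thinning),
                 burn_in = as.integer(burn_in), init_budget = init_budget),
            class = "abc_config")
}

# Simulator failures (integrator breakdown at extreme prior draws) count
# as S = Inf, i.e. an ABC rejection.
safe_S <- function(model, data, weights) {
  function(theta) tryCatch(model_data_S(model(theta), data, weights),
                           error = function(e) Inf)
}

# Distance between one simulated model output and the data. `sim` is a
# trajectory (with `data` a count_dataset) or a named list of per-condition
# trajectories (with `data` a named list of count_datasets).
model_data_S <- function(sim, data, weights = c(1, 1, 1)) {
  if (inherits(sim, "trajectory")) return(as.numeric(summary_S(sim, data,
                                                               weights)))
  stopifnot(is.list(sim), is.list(data),
            all(names(data) %in% names(sim)))
  sum(vapply(names(data), function(cond)
    as.numeric(summary_S(sim[[cond]], data[[cond]], weights)),
    numeric(1)))
}

#' Simulator closure for the base embryogenesis model
#'
#' Returns a function mapping a named parameter vector to a trajectory,
#' for use with [abc_mcmc()] and [rejection_abc()] against a
#' cross-sectional dataset. The inference-time grid is 0.5 h.
#'
#' @param fixed Named list of parameters not present in the vector.
#' @param t_max Horizon (hours). @param dt Output grid step (hours).
#' @return `function(theta) -> trajectory`.
#' @export
base_model_simulator <- function(fixed = list(), t_max = 48, dt = 0.5) {
  grid <- seq(0, t_max, by = dt)
  function(theta) {
    args <- utils::modifyList(as.list(theta), fixed)
    p <- base_params(alpha = args$alpha, beta = args$beta, rho = args$rho,
                     zeta = args$zeta, l = args$l, eta = args$eta,
                     m = args$m)
    solve_embryo(p, t_max = t_max, t_grid = grid, method = "lsoda",
                 rtol = 1e-8, atol = 1e-8, clip_tol = 1e-4)
  }
}

#' Simulator closure for a chimera panel
#'
#' Maps a named parameter vector (chimera parameters `alpha_D`, `a`, `n`,
#' plus any free base parameters) to a named list of trajectories, one per
#' requested condition, for fitting against [split_chimera_panel()] output.
#'
#' @param base_fixed A [base_params()] object holding the (typically
#'   pinned) host parameters.
#' @param variant Chimera model variant label.
#' @param conditions Conditions to simulate.
#' @param t_max,dt Horizon and grid step (hours).
#' @return `function(theta) -> named list of trajectories`.
#' @export
chimera_panel_simulator <- function(base_fixed, variant = "GFC",
                                    conditions =
                                      chimera_conditions$condition,
                                    t_max = 48, dt = 0.5) {
  grid <- seq(0, t_max, by = dt)
  function(theta) {
    th <- as.list(theta)
    base <- base_fixed
    for (nm in intersect(names(th), names(base))) base[[nm]] <- th[[nm]]
    validate_base_params(base)
    p <- chimera_params(base,
                        alpha_D = if (!is.null(th$alpha_D)) th$alpha_D
                                  else base$alpha,
                        a = if (!is.null(th$a)) th$a else 0,
                        n = if (!is.null(th$n)) th$n else 1L,
                        variant = variant)
    sims <- lapply(conditions, function(cond)
      solve_embryo(p, initial = condition_initial(cond), t_max = t_max,
                   t_grid = grid, method = "lsoda", rtol = 1e-8,
                   atol = 1e-8, clip_tol = 1e-4))
    stats::setNames(sims, conditions)
  }
}

#' ABC-MCMC posterior sampling
#'
#' Likelihood-free Markov chain Monte Carlo: the chain is initialised at a
#' prior draw whose simulated summary statistic satisfies `S <= epsilon`
#' (rejection-sampled within `init_budget` draws); at each step a proposal
#' is drawn from a symmetric kernel (Gaussian on the prior's transformed
#' scale for continuous parameters, a +/-1 nearest-neighbour move for the
#' discrete exponents), the model is simulated at the proposal, and the
#' move is accepted if and only if the proposal is inside the prior
#' support and its summary statistic satisfies `S <= epsilon`. With
#' uniform priors and symmetric kernels the Metropolis prior-ratio is 1,
#' so no further randomisation is needed; the stationary distribution is
#' the prior truncated to the ABC acceptance region.
#'
#' @param model Simulator closure: named parameter vector to trajectory
#'   (or named list of per-condition trajectories).
#' @param data A [count_dataset()] (or named per-condition list matching
#'   the simulator, see [split_chimera_panel()]).
#' @param priors A [prior_spec()] covering every free parameter.
#' @param config An [abc_config()].
#' @param weights Summary-statistic term weights, see [summary_S()].
#' @return A `posterior_sample`: list with `accepted` (data frame of
#'   post-burn-in, thinned chain states and their `S`), `n_proposed`,
#'   `n_accepted_moves`, `acceptance_rate`, `epsilon`, `priors`, and
#'   `min_S` (smallest statistic seen).
#' @export
abc_mcmc <- function(model, data, priors, config, weights = c(1, 1, 1)) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "abc_config"))
  set.seed(config$seed)
  scales <- config$proposal_scales
  if (is.null(scales)) scales <- default_scales(priors)
  eps <- config$epsilon
  S_of <- safe_S(model, data, weights)
  # initialise inside the ABC-truncated support
  theta <- NULL; min_S <- Inf
  for (i in seq_len(config$init_budget)) {
    cand <- prior_sample(priors)
    S <- S_of(cand)
    min_S <- min(min_S, S)
    if (S <= eps) { theta <- cand; break }
  }
  if (is.null(theta))
    stop("abc_mcmc: no initial acceptance within ", config$init_budget,
         " prior draws; minimum S seen was ", format(min_S),
         " (epsilon = ", format(eps), " may be too small)", call. = FALSE)
  S_cur <- S
  n_iter <- config$n_iterations
  trace <- matrix(NA_real_, n_iter, length(theta),
                  dimnames = list(NULL, names(theta)))
  trace_S <- numeric(n_iter)
  n_acc <- 0L
  for (it in seq_len(n_iter)) {
    prop <- propose_theta(priors, theta, scales)
    if (prior_in_support(priors, prop)) {
      S_prop <- S_of(prop)
      min_S <- min(min_S, S_prop)
      if (S_prop <= eps) {
        theta <- prop; S_cur <- S_prop; n_acc <- n_acc + 1L
      }
    }
    trace[it, ] <- theta
    trace_S[it] <- S_cur
  }
  keep <- seq_len(n_iter) > config$burn_in &
    (seq_len(n_iter) - config$burn_in) %% config$thinning == 0
  accepted <- as.data.frame(trace[keep, , drop = FALSE])
  accepted$S <- trace_S[keep]
  structure(list(accepted = accepted, n_proposed = n_iter,
                 n_accepted_moves = n_acc,
                 acceptance_rate = n_acc / n_iter, epsilon = eps,
                 priors = priors, min_S = min_S,
                 method = "abc_mcmc"),
            class = "posterior_sample")
}

#' Rejection-ABC sampling
#'
#' Draws i.i.d. parameter vectors from the prior, simulates each, and
#' accepts those with `S <= epsilon`, stopping at `target_acceptances`.
#' The recorded acceptance rate is an unbiased estimate of the prior
#' predictive probability `P(S <= epsilon)`, the quantity whose ratio
#' between two models gives the ABC Bayes factor.
#'
#' @inheritParams abc_mcmc
#' @param epsilon Acceptance threshold.
#' @param target_acceptances Required number of accepted draws.
#' @param max_proposals Proposal budget before aborting.
#' @param seed Integer seed.
#' @return A `posterior_sample` with `accepted`, `n_proposed` and
#'   `acceptance_rate`.
#' @export
rejection_abc <- function(model, data, priors, epsilon,
                          target_acceptances = 500, max_proposals = 1e6,
                          seed = 1L, weights = c(1, 1, 1)) {
  stopifnot(inherits(priors, "prior_spec"), epsilon > 0,
            target_acceptances >= 1)
  set.seed(seed)
  S_of <- safe_S(model, data, weights)
  acc <- list(); n_prop <- 0L; min_S <- Inf
  while (length(acc) < target_acceptances) {
    if (n_prop >= max_proposals)
      stop("rejection_abc: proposal budget (", max_proposals,
           ") exhausted with ", length(acc), " acceptances; minimum S ",
           "seen was ", format(min_S), call. = FALSE)
    theta <- prior_sample(priors)
    S <- S_of(theta)
    n_prop <- n_prop + 1L
    min_S <- min(min_S, S)
    if (S <= epsilon) acc[[length(acc) + 1L]] <- c(theta, S = S)
  }
  accepted <- as.data.frame(do.call(rbind, acc))
  structure(list(accepted = accepted, n_proposed = n_prop,
                 n_accepted_moves = nrow(accepted),
                 acceptance_rate = nrow(accepted) / n_prop,
                 epsilon = epsilon, priors = priors, min_S = min_S,
                 method = "rejection_abc"),
            class = "posterior_sample")
}

#' Build a posterior_sample from acceptance bookkeeping alone
#'
#' For Bayes-factor arithmetic when only the counts are known (e.g.
#' reproducing a published comparison).
#'
#' @param n_accepted,n_proposed Acceptance bookkeeping counts.
#' @param epsilon Threshold the counts were produced at.
#' @return A `posterior_sample` with empty `accepted`.
#' @export
posterior_counts <- function(n_accepted, n_proposed, epsilon) {
  stopifnot(n_accepted >= 0, n_proposed >= n_accepted)
  structure(list(accepted = data.frame(), n_proposed = n_proposed,
                 n_accepted_moves = n_accepted,
                 acceptance_rate = n_accepted / n_proposed,
                 epsilon = epsilon, priors = NULL, min_S = NA_real_,
                 method = "counts"),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("posterior_sample (%s): %d kept states, %d proposals, ",
              x$method, nrow(x$accepted), x$n_proposed))
  cat(sprintf("acceptance rate %.4f at epsilon %.4g\n",
              x$acceptance_rate, x$epsilon))
  invisible(x)
}

#' Posterior point estimate: componentwise median / discrete mode
#'
#' Continuous parameters take the componentwise posterior median; discrete
#' exponents take the modal (majority) value, with ties broken toward the
#' larger exponent.
#'
#' @param sample A `posterior_sample` with a non-empty accepted set.
#' @return Named numeric vector of point estimates.
#' @export
posterior_median_params <- function(sample) {
  stopifnot(inherits(sample, "posterior_sample"))
  acc <- sample$accepted
  if (nrow(acc) == 0) stop("empty posterior sample", call. = FALSE)
  pars <- setdiff(names(acc), "S")
  out <- numeric(0)
  for (nm in pars) {
    pr <- sample$priors[[nm]]
    out[nm] <- if (!is.null(pr) && pr$type == "discrete")
      discrete_mode(acc[[nm]]) else stats::median(acc[[nm]])
  }
  out
}

discrete_mode <- function(x) {
  tab <- table(x)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  max(winners) # ties toward the larger exponent
}

#' Rejection-ABC Bayes factor between two models
#'
#' At a common threshold and dataset, the ratio of the two models' prior
#' predictive acceptance rates estimates the Bayes factor (equal prior
#' model odds). The result carries a qualitative Kass-Raftery evidence
#' label: 1-3 "barely worth mentioning", 3-20 "positive", 20-150 "strong",
#' above 150 "very strong" (labels applied to whichever direction the
#' evidence favours).
#'
#' @param sample_a,sample_b `posterior_sample`s for the two models,
#'   produced at the same epsilon against the same data and summary.
#' @param model_a,model_b Labels.
#' @return A `comparison_result` list with the bookkeeping, `bayes_factor`
#'   (model a over model b) and `evidence` label.
#' @examples
#' bayes_factor(posterior_counts(500, 6289, 17300),
#'              posterior_counts(500, 105027, 17300))
#' @export
bayes_factor <- function(sample_a, sample_b,
                         model_a = "model_a", model_b = "model_b") {
  stopifnot(inherits(sample_a, "posterior_sample"),
            inherits(sample_b, "posterior_sample"))
  if (!isTRUE(all.equal(sample_a$epsilon, sample_b$epsilon)))
    stop("Bayes factor requires a common epsilon", call. = FALSE)
  if (sample_b$n_accepted_moves == 0)
    stop("Bayes factor undefined: zero acceptances for ", model_b,
         call. = FALSE)
  bf <- sample_a$acceptance_rate / sample_b$acceptance_rate
  structure(list(model_a = model_a, model_b = model_b,
                 epsilon = sample_a$epsilon,
                 acceptances_a = sample_a$n_accepted_moves,
                 proposals_a = sample_a$n_proposed,
                 acceptances_b = sample_b$n_accepted_moves,
                 proposals_b = sample_b$n_proposed,
                 bayes_factor = bf,
                 evidence = kass_raftery_label(bf)),
            class = "comparison_result")
}

kass_raftery_label <- function(bf) {
  b <- max(bf, 1 / bf)
  lab <- if (b < 3) "barely worth mentioning"
         else if (b < 20) "positive"
         else if (b < 150) "strong"
         else "very strong"
  if (bf >= 1) lab else paste0(lab, " (favours model_b)")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("ABC model comparison at epsilon = %.4g\n", x$epsilon))
  cat(sprintf("  %s: %d / %d accepted\n", x$model_a, x$acceptances_a,
              x$proposals_a))
  cat(sprintf("  %s: %d / %d accepted\n", x$model_b, x$acceptances_b,
              x$proposals_b))
  cat(sprintf("  Bayes factor (a/b) = %.3g - %s evidence\n",
              x$bayes_factor, x$evidence))
  invisible(x)
}

#' Calibrate an ABC threshold from the prior predictive
#'
#' Draws `n_pilot` parameter vectors from the prior, simulates each, and
#' returns the requested quantile of the summary statistic, so that
#' rejection ABC at the returned threshold accepts roughly
#' `quantile * 100` percent of prior draws.
#'
#' @inheritParams rejection_abc
#' @param n_pilot Number of pilot draws.
#' @param quantile Target prior acceptance fraction (default 1 percent).
#' @return List with `epsilon`, and the pilot `S` values.
#' @export
calibrate_epsilon <- function(model, data, priors, n_pilot = 500,
                              quantile = 0.01, seed = 1L,
                              weights = c(1, 1, 1)) {
  set.seed(seed)
  S_of <- safe_S(model, data, weights)
  S <- vapply(seq_len(n_pilot), function(i) S_of(prior_sample(priors)),
              numeric(1))
  list(epsilon = as.numeric(stats::quantile(S, probs = quantile,
                                            type = 7)),
       pilot_S = S)
}
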