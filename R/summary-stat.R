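#' State-space summary statistic between a trajectory and count data
#'
#' Time is implicit in snapshot cell-count data: embryos are observed once,
#' at unknown developmental ages. The model is therefore fitted in state
#' space rather than as a time series, with the three-term statistic
#' \deqn{S = w_1 S_1 + w_2 S_2 + w_3 S_3}
#' \describe{
#'   \item{`S1`}{for each observation, the squared Euclidean distance (over
#'     observed species) to the nearest trajectory grid point, summed over
#'     observations - the solution should pass close to every data point at
#'     *some* time;}
#'   \item{`S2`}{the squared difference between each observed species'
#'     trajectory maximum and its maximum observed count, summed over
#'     species - pins down the timescale that `S1` alone leaves free;}
#'   \item{`S3`}{`B(t_max)^2 + C(t_max)^2` - blastomeres and unspecified
#'     ICM should be exhausted by the end of the period of interest.}
#' }
#' Only species present in the dataset's mapping enter `S1` and `S2`;
#' `S3` always reads the trajectory's `B` and `C` compartments. The
#' nearest-time minimisation in `S1` is over the trajectory's discrete
#' output grid, so the grid should be no coarser than 0.5 h.
#'
#' @param traj A `trajectory` from [solve_embryo()].
#' @param data A [count_dataset()].
#' @param weights Length-3 non-negative weights for the three terms.
#' @return Non-negative scalar with attribute `terms` (the three
#'   components, unweighted).
#' @examples
#' tr <- solve_embryo(base_params())
#' d <- count_dataset(data.frame(T = 80, C = 0, P = 25, E = 20))
#' summary_S(tr, d)
#' @export
summary_S <- function(traj, data, weights = c(1, 1, 1)) {
  stopifnot(inherits(traj, "trajectory"), inherits(data, "count_dataset"),
            length(weights) == 3, all(weights >= 0))
  so <- attr(data, "species_order")
  if (!all(so %in% names(traj)))
    stop("trajectory lacks species required by the dataset mapping: ",
         paste(setdiff(so, names(traj)), collapse = ", "), call. = FALSE)
  X <- as.matrix(traj[, so, drop = FALSE])      # grid times x species
  obs <- as.matrix(as.data.frame(data)[names(so)])  # embryos x species
  # S1: per-observation nearest-grid-point squared distance, summed
  s1 <- sum(vapply(seq_len(nrow(obs)), function(n) {
    d2 <- rowSums(sweep(X, 2, obs[n, ])^2)
    min(d2)
  }, numeric(1)))
  # S2: componentwise max mismatch
  s2 <- sum((apply(X, 2, max) - apply(obs, 2, max))^2)
  # S3: leftover blastomeres and unspecified ICM at the final time
  fin <- trajectory_state(traj, attr(traj, "t_max"))
  s3 <- fin[["B"]]^2 + fin[["C"]]^2
  structure(sum(weights * c(s1, s2, s3)),
            terms = c(S1 = s1, S2 = s2, S3 = s3))
}

#' ABC acceptance decision
#'
#' A parameter set is accepted when its simulated summary statistic is
#' sufficiently close to the data: `S <= epsilon` (closed threshold).
#'
#' @param S Summary-statistic value. @param epsilon Threshold, `> 0`.
#' @return Logical.
#' @export
distance_to_acceptance <- function(S, epsilon) {
  stopifnot(epsilon > 0)
  as.numeric(S) <= epsilon
}
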