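#' Specification for a synthetic count dataset
#'
#' Describes how to emulate the two kinds of calibration data the models
#' are fitted to: (a) a cross-sectional collection of embryos sampled at
#' unknown developmental ages across the 8- to ~128-cell window, with the
#' sampling times discarded (time-implicit snapshots), and (b) endpoint
#' datasets in which every embryo is observed at 48 h.
#'
#' @param true_params A [base_params()] or [chimera_params()] generating
#'   model.
#' @param n_embryos Number of embryos (`>= 1`).
#' @param sampling `"cross_sectional"` (ages uniform on `[0, 48]` h, then
#'   discarded) or `"endpoint"` (all at 48 h).
#' @param noise Observation model applied to the model state:
#'   `"multinomial"` (default; lineage identities re-drawn at the model's
#'   total cell number - classification noise between lineages that
#'   preserves each embryo's total), `"poisson"` (independent per-lineage
#'   counts with the model value as mean), or `"none"` (rounding only).
#' @param simulator `"deterministic"` (ODE state) or `"gillespie"` (one
#'   stochastic replicate per embryo).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(true_params = base_params(), n_embryos = 60,
                           sampling = c("cross_sectional", "endpoint"),
                           noise = c("multinomial", "poisson", "none"),
                           simulator = c("deterministic", "gillespie"),
                           seed = 1L) {
  stopifnot(n_embryos >= 1)
  structure(list(true_params = true_params, n_embryos = n_embryos,
                 sampling = match.arg(sampling), noise = match.arg(noise),
                 simulator = match.arg(simulator), seed = as.integer(seed)),
            class = "synthetic_spec")
}

apply_noise <- function(counts, noise) {
  counts <- pmax(counts, 0)
  switch(noise,
    none = round(counts),
    poisson = stats::rpois(length(counts), counts),
    multinomial = {
      n_total <- round(sum(counts))
      if (n_total == 0) return(counts * 0)
      probs <- if (sum(counts) > 0) counts / sum(counts)
               else rep(1 / length(counts), length(counts))
      as.numeric(stats::rmultinom(1, n_total, probs))
    })
}

#' Generate a synthetic per-embryo count dataset
#'
#' For each embryo: draw a sampling age (or use 48 h), evaluate the
#' generating model at that age, apply the observation-noise model and
#' emit integer lineage counts. Blastomeres are treated as unobservable,
#' matching real snapshot data in which only classified lineages are
#' counted: observed species are `T, C, P, E` (plus donor-derived epiblast
#' for chimera generators).
#'
#' @param spec A [synthetic_spec()].
#' @return A [count_dataset()].
#' @examples
#' d <- generate_dataset(synthetic_spec(n_embryos = 10, seed = 42))
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  is_chimera <- inherits(spec$true_params, "chimera_params")
  times <- if (spec$sampling == "cross_sectional")
    sort(stats::runif(spec$n_embryos, 0, 48)) else rep(48, spec$n_embryos)
  init <- embryo_state(B = 8)
  obs_species <- c(T = "T", C = "C", P = "P", E = "E")
  states <- if (spec$simulator == "deterministic") {
    tr <- solve_embryo(spec$true_params, initial = init, t_max = 48,
                       t_grid = times)
    lapply(times, function(tt) trajectory_state(tr, tt))
  } else {
    net <- build_network(spec$true_params)
    lapply(seq_along(times), function(i) {
      run <- gillespie_run(net, init, t_max = 48,
                           seed = spec$seed + 7919L * i)
      trajectory_state(run, times[i])
    })
  }
  rows <- lapply(seq_along(states), function(i) {
    counts <- apply_noise(states[[i]][obs_species], spec$noise)
    stats::setNames(as.list(counts), names(obs_species))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df <- cbind(embryo_id = seq_len(nrow(df)), condition = "non-injected", df)
  count_dataset(df, species_order = obs_species)
}

chimera_conditions <- data.frame(
  condition = c("non-injected", "10+/+", "15+/+", "10-/-", "15-/-"),
  D_plus0  = c(0, 10, 15, 0, 0),
  D_minus0 = c(0, 0, 0, 10, 15),
  stringsAsFactors = FALSE)

condition_initial <- function(condition) {
  row <- chimera_conditions[chimera_conditions$condition == condition, ]
  if (nrow(row) != 1) stop("unknown condition: ", condition, call. = FALSE)
  embryo_state(B = 8, D_plus = row$D_plus0, D_minus = row$D_minus0)
}

condition_donor_species <- function(condition) {
  if (grepl("\\+/\\+", condition)) "D_plus"
  else if (grepl("-/-", condition, fixed = TRUE)) "D_minus"
  else NA_character_
}

#' Generate a synthetic endpoint chimera panel
#'
#' Simulates all five experimental conditions - non-injected controls and
#' injections of 10 or 15 donor cells of either Fgf4 genotype - to 48 h
#' under a chimera model, applies the observation-noise model, and emits
#' one endpoint count row per embryo. Donor cells are reported as
#' donor-derived epiblast (`E_donor`); host epiblast is `E_host` and `E`
#' is their sum.
#'
#' @param params A [chimera_params()] generating model.
#' @param n_per_condition Embryos per condition (`>= 1`).
#' @param seed Integer seed.
#' @param noise Observation model, as in [synthetic_spec()].
#' @return A [count_dataset()] with columns
#'   `embryo_id, condition, T, C, P, E, E_host, E_donor`.
#' @export
generate_chimera_panel <- function(params, n_per_condition = 10, seed = 1L,
                                   noise = c("multinomial", "poisson",
                                             "none")) {
  stopifnot(inherits(params, "chimera_params"), n_per_condition >= 1)
  noise <- match.arg(noise)
  set.seed(seed)
  rows <- list()
  for (cond in chimera_conditions$condition) {
    tr <- solve_embryo(params, initial = condition_initial(cond),
                       t_max = 48)
    fin <- trajectory_state(tr, 48)
    donor_sp <- condition_donor_species(cond)
    donor_val <- if (is.na(donor_sp)) 0 else fin[[donor_sp]]
    mu <- c(T = fin[["T"]], C = fin[["C"]], P = fin[["P"]],
            E_host = fin[["E"]], E_donor = donor_val)
    for (i in seq_len(n_per_condition)) {
      counts <- apply_noise(mu, noise)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, T = counts[1], C = counts[2], P = counts[3],
        E = counts[4] + counts[5], E_host = counts[4],
        E_donor = counts[5])
    }
  }
  df <- do.call(rbind, rows)
  df <- cbind(embryo_id = seq_len(nrow(df)), df)
  count_dataset(df, species_order = c(T = "T", C = "C", P = "P",
                                      E_host = "E", E_donor = "D_minus"))
}

#' Split a chimera panel into per-condition datasets
#'
#' Returns one [count_dataset()] per condition present, each carrying the
#' species mapping appropriate to its donor genotype (`E_donor` maps to
#' `D_plus` in `+/+` conditions and `D_minus` in `-/-` conditions; the
#' non-injected condition keeps only host species).
#'
#' @param data A chimera-panel [count_dataset()].
#' @return Named list of `count_dataset`s keyed by condition.
#' @export
split_chimera_panel <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  out <- list()
  for (cond in unique(data$condition)) {
    sub <- as.data.frame(data)[data$condition == cond, , drop = FALSE]
    donor_sp <- condition_donor_species(cond)
    so <- c(T = "T", C = "C", P = "P")
    if ("E_host" %in% names(sub)) {
      so <- c(so, E_host = "E")
      if (!is.na(donor_sp) && "E_donor" %in% names(sub))
        so <- c(so, E_donor = donor_sp)
    } else {
      so <- c(so, E = "E")
    }
    out[[cond]] <- count_dataset(sub, species_order = so)
  }
  out
}
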