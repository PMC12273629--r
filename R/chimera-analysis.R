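#' Per-condition lineage composition summary
#'
#' For each condition and lineage present in an endpoint dataset, computes
#' the mean, standard deviation and standard error of the cell number, of
#' the ICM fraction (lineage over `E + P + C`) and of the whole-embryo
#' fraction (lineage over `T + C + P + E`). Embryos with zero ICM cells
#' have undefined ICM fractions; such rows are flagged and excluded from
#' the fraction means (not from count means).
#'
#' @param data A [count_dataset()] with condition labels.
#' @return A `composition_summary`: list with `summary` (long data frame:
#'   condition, lineage, measure, mean, sd, sem, n) and `flagged`
#'   (embryo_ids excluded from ICM-fraction averaging).
#' @export
summarise_composition <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  df <- as.data.frame(data)
  lineages <- intersect(c("T", "C", "P", "E", "E_host", "E_donor"),
                        names(df))
  icm <- df$C + df$P + df$E
  total <- df$T + df$C + df$P + df$E
  flagged <- df$embryo_id[icm == 0]
  rows <- list()
  stat_row <- function(condition, lineage, measure, x) {
    x <- x[is.finite(x)]
    data.frame(condition = condition, lineage = lineage,
               measure = measure, mean = mean(x), sd = stats::sd(x),
               sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  }
  for (cond in unique(df$condition)) {
    sel <- df$condition == cond
    for (ln in lineages) {
      counts <- df[[ln]][sel]
      rows[[length(rows) + 1L]] <- stat_row(cond, ln, "count", counts)
      icm_frac <- ifelse(icm[sel] > 0, df[[ln]][sel] / icm[sel], NA)
      if (ln != "T")
        rows[[length(rows) + 1L]] <-
          stat_row(cond, ln, "icm_fraction", icm_frac)
      rows[[length(rows) + 1L]] <-
        stat_row(cond, ln, "embryo_fraction",
                 ifelse(total[sel] > 0, df[[ln]][sel] / total[sel], NA))
    }
  }
  structure(list(summary = do.call(rbind, rows), flagged = flagged),
            class = "composition_summary")
}

#' Hi/Lo chimerism classification by k-means with silhouette selection
#'
#' Classifies injected embryos by the donor-cell contribution to the total
#' epiblast: the clustering feature is `E_donor / (E_donor + E_host)` per
#' embryo. k-means (with many random restarts under a fixed seed) is run
#' for every candidate cluster number; the k maximising the mean
#' silhouette width is selected. Hi/Lo labels always come from the k = 2
#' solution, the Hi cluster being the one with the higher mean donor
#' fraction.
#'
#' @param data A chimera [count_dataset()] with `E_host` and `E_donor`.
#' @param k_candidates Candidate cluster numbers (default `2:4`).
#' @param conditions Conditions to classify (default: all injected rows).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Random restarts per k.
#' @return A `chimerism_classification`: list with `k` (selected), mean
#'   `silhouette` at the selected k, `silhouettes` per candidate k,
#'   `labels` (data frame: embryo_id, condition, donor_fraction, cluster,
#'   chimerism Hi/Lo from k = 2) and `feature` name. If all feature values
#'   coincide the classification is degenerate: `k = 1` and the
#'   silhouette is `NA`.
#' @export
classify_chimerism <- function(data, k_candidates = 2:4,
                               conditions = NULL, seed = 1L,
                               nstart = 50) {
  stopifnot(inherits(data, "count_dataset"), length(k_candidates) >= 1)
  df <- as.data.frame(data)
  if (!all(c("E_host", "E_donor") %in% names(df)))
    stop("classify_chimerism needs E_host and E_donor columns",
         call. = FALSE)
  if (is.null(conditions)) conditions <-
    setdiff(unique(df$condition), "non-injected")
  df <- df[df$condition %in% conditions, , drop = FALSE]
  tot_epi <- df$E_host + df$E_donor
  df <- df[tot_epi > 0, , drop = FALSE]
  feat <- df$E_donor / (df$E_host + df$E_donor)
  if (nrow(df) < max(k_candidates))
    stop("fewer embryos (", nrow(df), ") than the largest candidate k",
         call. = FALSE)
  if (length(unique(feat)) == 1) {
    labels <- data.frame(embryo_id = df$embryo_id,
                         condition = df$condition,
                         donor_fraction = feat, cluster = 1L,
                         chimerism = NA_character_)
    return(structure(list(k = 1L, silhouette = NA_real_,
                          silhouettes = NULL, labels = labels,
                          feature = "donor fraction of total EPI"),
                     class = "chimerism_classification"))
  }
  x <- matrix(feat, ncol = 1)
  d <- stats::dist(x)
  fits <- list(); sil <- stats::setNames(numeric(0), character(0))
  set.seed(seed)
  for (k in sort(k_candidates)) {
    if (k < 2 || k > nrow(x) - 1) next
    fit <- stats::kmeans(x, centers = k, nstart = nstart)
    sw <- cluster::silhouette(fit$cluster, d)
    fits[[as.character(k)]] <- fit
    sil[as.character(k)] <- mean(sw[, "sil_width"])
  }
  best_k <- as.integer(names(sil)[which.max(sil)])
  fit2 <- if ("2" %in% names(fits)) fits[["2"]]
          else stats::kmeans(x, centers = 2, nstart = nstart)
  hi_cluster <- which.max(tapply(feat, fit2$cluster, mean))
  labels <- data.frame(embryo_id = df$embryo_id, condition = df$condition,
                       donor_fraction = feat,
                       cluster = fits[[as.character(best_k)]]$cluster,
                       chimerism = ifelse(fit2$cluster == hi_cluster,
                                          "Hi", "Lo"))
  structure(list(k = best_k, silhouette = unname(sil[as.character(best_k)]),
                 silhouettes = sil, labels = labels,
                 feature = "donor fraction of total EPI"),
            class = "chimerism_classification")
}

#' @export
print.chimerism_classification <- function(x, ...) {
  cat(sprintf("chimerism classification on %s\n", x$feature))
  cat(sprintf("  selected k = %d (mean silhouette %.4f)\n",
              x$k, x$silhouette))
  if (!is.null(x$labels$chimerism) && !all(is.na(x$labels$chimerism)))
    print(table(x$labels$condition, x$labels$chimerism))
  invisible(x)
}

#' Model-predicted versus observed composition per variant and condition
#'
#' Solves each chimera model variant for every condition to 48 h and
#' tabulates the predicted endpoint cell numbers and ICM fractions per
#' lineage, next to the observed condition means from the data (empty
#' where a condition is absent). Host epiblast is reported separately so
#' that held-out host-exclusion comparisons are possible.
#'
#' @param data An endpoint chimera [count_dataset()].
#' @param params_by_variant Named list of [chimera_params()], e.g.
#'   `list(F = ..., GF = ..., GFC = ...)`.
#' @param conditions Conditions to tabulate.
#' @return Long data frame: variant, condition, lineage, predicted count,
#'   predicted ICM fraction, observed mean count, observed mean ICM
#'   fraction.
#' @export
overlay_model_predictions <- function(data, params_by_variant,
                                      conditions =
                                        chimera_conditions$condition) {
  stopifnot(inherits(data, "count_dataset"), length(params_by_variant) >= 1)
  comp <- summarise_composition(data)$summary
  obs_val <- function(cond, lineage, measure) {
    v <- comp$mean[comp$condition == cond & comp$lineage == lineage &
                     comp$measure == measure]
    if (length(v)) v else NA_real_
  }
  lineages <- c("T", "C", "P", "E_host", "E_donor")
  rows <- list()
  for (variant in names(params_by_variant)) {
    p <- params_by_variant[[variant]]
    stopifnot(inherits(p, "chimera_params"))
    for (cond in conditions) {
      fin <- trajectory_state(
        solve_embryo(p, initial = condition_initial(cond), t_max = 48),
        48)
      donor_sp <- condition_donor_species(cond)
      pred <- c(T = fin[["T"]], C = fin[["C"]], P = fin[["P"]],
                E_host = fin[["E"]],
                E_donor = if (is.na(donor_sp)) 0 else fin[[donor_sp]])
      icm <- pred[["C"]] + pred[["P"]] + pred[["E_host"]] +
        pred[["E_donor"]]
      has_cond <- cond %in% data$condition
      for (ln in lineages) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = variant, condition = cond, lineage = ln,
          predicted_count = pred[[ln]],
          predicted_icm_fraction =
            if (ln == "T") NA_real_ else pred[[ln]] / icm,
          observed_mean_count =
            if (has_cond) obs_val(cond, ln, "count") else NA_real_,
          observed_mean_icm_fraction =
            if (has_cond && ln != "T")
              obs_val(cond, ln, "icm_fraction") else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
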