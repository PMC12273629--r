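#' Construct a per-embryo cell-count dataset
#'
#' A `count_dataset` holds time-implicit lineage-count observations: one
#' row per embryo with non-negative integer counts per observed lineage,
#' an `embryo_id` and a `condition` label (`"non-injected"`, `"10+/+"`,
#' `"15+/+"`, `"10-/-"`, `"15-/-"` for chimera panels). The
#' `species_order` attribute maps dataset columns onto model variables,
#' e.g. `c(T = "T", C = "C", P = "P", E = "E")` for host-only data or
#' `c(T = "T", C = "C", P = "P", E_host = "E", E_donor = "D_minus")` for a
#' chimera condition: donor cells contribute to the epiblast, so the donor
#' compartment is read as donor-derived epiblast at the endpoint.
#'
#' @param df Data frame with columns `embryo_id`, `condition`, and one
#'   column per observed lineage.
#' @param species_order Named character vector: names are dataset columns,
#'   values are model species (`B, T, C, P, E, D_plus, D_minus`).
#' @return A `count_dataset` (data frame subclass).
#' @export
count_dataset <- function(df, species_order = c(T = "T", C = "C",
                                                P = "P", E = "E")) {
  df <- as.data.frame(df)
  if (nrow(df) == 0) stop("count_dataset must be non-empty", call. = FALSE)
  if (is.null(df$embryo_id)) df$embryo_id <- seq_len(nrow(df))
  if (is.null(df$condition)) df$condition <- "non-injected"
  missing_cols <- setdiff(names(species_order), names(df))
  if (length(missing_cols))
    stop("count_dataset: missing lineage columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- setdiff(species_order, state_species)
  if (length(bad))
    stop("count_dataset: unknown model species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  counts <- as.matrix(df[names(species_order)])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("count_dataset: counts must be finite and >= 0", call. = FALSE)
  structure(df, species_order = species_order,
            class = c("count_dataset", "data.frame"))
}

#' Read / write the count-dataset CSV dialect
#'
#' One row per embryo; header `embryo_id,condition,T,C,P,E` with optional
#' `E_host,E_donor` columns for chimera panels. On reading, the species
#' mapping is inferred: `E_donor` maps to `D_plus` for `+/+` conditions and
#' `D_minus` for `-/-` conditions; mixed-genotype files use the per-row
#' condition at analysis time, and the stored mapping defaults `E_donor` to
#' `D_minus`.
#'
#' @param path CSV file path.
#' @param data A `count_dataset`.
#' @return `read_count_dataset()` returns a `count_dataset`;
#'   `write_count_dataset()` returns `path` invisibly.
#' @export
read_count_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  so <- c(T = "T", C = "C", P = "P")
  if ("E_host" %in% names(df)) {
    so <- c(so, E_host = "E")
    if ("E_donor" %in% names(df)) {
      donor_sp <- if (all(grepl("\\+/\\+", df$condition[df$E_donor > 0])))
        "D_plus" else "D_minus"
      so <- c(so, E_donor = donor_sp)
    }
  } else {
    so <- c(so, E = "E")
  }
  count_dataset(df, species_order = so)
}

#' @rdname read_count_dataset
#' @export
write_count_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.count_dataset <- function(x, ...) {
  so <- attr(x, "species_order")
  cat(sprintf("count_dataset: %d embryos, %d conditions\n",
              nrow(x), length(unique(x$condition))))
  cat("  species mapping:",
      paste(sprintf("%s->%s", names(so), so), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
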