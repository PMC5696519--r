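#' Multi-stand tree inventory
#'
#' A `forest_dataset` is a data frame of tree records grouped by sample
#' plot (stand), the data object consumed by the likelihoods. Required
#' columns: `plot_id`, `tree_id`, `age_years`, `dbh_cm`, `height_m`;
#' optional `volume_m3` and `trees_per_ha`. Column-name suffixes carry the
#' units (cm, m, years, m^3, trees/ha) to prevent silent mismatches.
#'
#' @param trees A data frame with the columns above.
#' @param true_effects Optional data frame `plot_id, phi_d, phi_h` recording
#'   simulation provenance (the true stand effects).
#' @return An object of class `forest_dataset` (a data frame).
#' @export
forest_dataset <- function(trees, true_effects = NULL) {
  need <- c("plot_id", "tree_id", "age_years", "dbh_cm", "height_m")
  miss <- setdiff(need, names(trees))
  if (length(miss))
    stop_data("tree table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(trees) == 0L) stop_data("tree table has no rows")
  for (col in intersect(c("age_years", "dbh_cm", "height_m", "volume_m3",
                          "trees_per_ha"), names(trees))) {
    v <- trees[[col]]
    if (!is.numeric(v))
      stop_data("column ", col, " is not numeric")
    bad <- which(!is.finite(v))
    if (col == "age_years" && length(bad))
      stop_data("non-finite age_years in row(s) ", paste(bad, collapse = ", "))
    if (col %in% c("dbh_cm", "height_m") && length(bad))
      stop_data("non-finite ", col, " in row(s) ", paste(bad, collapse = ", "))
  }
  if (any(trees$age_years <= 0))
    stop_data("age_years must be positive")
  out <- as.data.frame(trees, stringsAsFactors = FALSE)
  attr(out, "true_effects") <- true_effects
  class(out) <- c("forest_dataset", "data.frame")
  out
}

#' @export
print.forest_dataset <- function(x, ...) {
  M <- length(unique(x$plot_id))
  cat(sprintf("Forest inventory: %d trees in %d plots, ages %g-%g yr\n",
              nrow(x), M, min(x$age_years), max(x$age_years)))
  cat(sprintf("  dbh %.1f-%.1f cm (mean %.2f), height %.1f-%.1f m (mean %.2f)\n",
              min(x$dbh_cm), max(x$dbh_cm), mean(x$dbh_cm),
              min(x$height_m), max(x$height_m), mean(x$height_m)))
  if (!is.null(attr(x, "true_effects")))
    cat("  true stand effects recorded (simulated data)\n")
  invisible(x)
}

#' Read a tree inventory table from CSV
#'
#' Expects a header with at least `plot_id, tree_id, age_years, dbh_cm,
#' height_m`; `volume_m3` and `trees_per_ha` are carried through when
#' present. Missing columns and non-numeric cells are reported by name /
#' row number.
#'
#' @param path CSV file path.
#' @return A [forest_dataset].
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop_data("cannot parse CSV: ",
                                                conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop_data("empty tree table: ", path)
  for (col in intersect(c("age_years", "dbh_cm", "height_m", "volume_m3",
                          "trees_per_ha"), names(raw))) {
    if (is.character(raw[[col]])) {
      conv <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(conv) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
      if (length(bad))
        stop_data("non-numeric value in column ", col, ", row(s) ",
                  paste(bad, collapse = ", "))
      raw[[col]] <- conv
    }
  }
  forest_dataset(raw)
}

#' Write a tree inventory table to CSV
#'
#' Deterministic column order and plain-decimal formatting, so identical
#' datasets produce byte-identical files.
#'
#' @param dataset A [forest_dataset].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "forest_dataset"))
  cols <- c("plot_id", "tree_id", "age_years", "dbh_cm", "height_m",
            "volume_m3", "trees_per_ha")
  out <- as.data.frame(dataset)[, intersect(cols, names(dataset)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: stand index (1..M, in first-appearance order) for a dataset
stand_index <- function(dataset) {
  ids <- unique(dataset$plot_id)
  list(idx = match(dataset$plot_id, ids), ids = ids, M = length(ids))
}
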