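#' Read a long-form run table or probability map from CSV
#'
#' The pipeline's stages exchange plain headed CSV. These readers
#' validate the schema on ingest so externally produced tables (e.g.
#' archived study output in the same layout) can enter the pipeline at
#' any stage: run tables feed [classify_runs()] / [compute_pthrive()],
#' probability maps feed [fit_balance()] and the descriptive models.
#'
#' @param path CSV file path.
#' @return A tibble (`read_pthrive_map()` returns a `pthrive_map`).
#' @export
read_run_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("run_id", "seed", "n_initial", "spacing", "dKs_pct",
            "dmu_pct", "lineage_id", "final_fraction", "is_loser",
            "status")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste("run table lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "driftbalance_schema_error")
  }
  bad <- tab$final_fraction < 0 | tab$final_fraction > 1
  if (any(bad)) {
    abort("final_fraction values outside [0, 1]",
          class = "driftbalance_schema_error")
  }
  tab
}

#' @rdname read_run_table
#' @export
read_pthrive_map <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("n_initial", "spacing", "dKs_pct", "dmu_pct", "n_seeds",
            "n_thrive", "p_thrive")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste("probability map lacks columns:",
                paste(missing_cols, collapse = ", ")),
          class = "driftbalance_schema_error")
  }
  if (any(tab$p_thrive < 0 | tab$p_thrive > 1)) {
    abort("p_thrive values outside [0, 1]",
          class = "driftbalance_schema_error")
  }
  class(tab) <- c("pthrive_map", class(tab))
  tab
}
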