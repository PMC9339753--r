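#' Write result tables to tab-separated files
#'
#' Writes each table in a named list to `<out_dir>/<name>.tsv`. Floats
#' are serialised with 6 significant digits; rows are ordered by
#' `fish_id` then time-like columns where present, so output is
#' deterministic and re-readable with [read_results()]. An empty table
#' produces a header-only file.
#'
#' @param tables Named list of data frames (e.g. `slopes`, `summaries`,
#'   `anova`, `contrasts`).
#' @param out_dir Output directory; created if needed.
#' @return Character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir)
    }
  }
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    ord <- intersect(c("fish_id", "time_s", "t_mid", "loop_index"),
                     names(df))
    if (length(ord) && nrow(df) > 1) {
      df <- df[do.call(order, df[ord]), , drop = FALSE]
    }
    for (col in names(df)) {
      if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], 6)
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Flatten an ANOVA result into a tidy table
#'
#' One row per model term plus a `Model` row, in the layout of a
#' standard ANOVA report (`term`, `F`, `df1`, `df2`, `p`, `adj_r2`).
#'
#' @param fit An [fit_anova()] result.
#' @param label Optional label column value (e.g. the response name).
#' @return A data frame.
#' @export
anova_table <- function(fit, label = NA_character_) {
  stopifnot(inherits(fit, "anova_result"))
  tab <- fit$table
  tab <- rbind(tab, data.frame(term = "Model", F = fit$model_F,
                               df1 = fit$model_df1, df2 = fit$model_df2,
                               p = fit$model_p))
  tab$adj_r2 <- c(rep(NA_real_, nrow(tab) - 1), fit$adj_r2)
  if (!is.na(label)) tab <- cbind(response = label, tab)
  tab
}
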