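#' Read and validate a cohort table
#'
#' The cohort table holds one row per fish: identifier, habitat of
#' capture (`LITTORAL`/`PELAGIC`), sex (`M`/`F`/`UNKNOWN`), body mass
#' (g), length (mm), chamber volume (L), muscle stable-isotope values
#' (delta-13C in permil vs VPDB, delta-15N vs AIR), and optional C:N
#' ratio and morphology covariates `pc2`/`pc3`.
#'
#' Validation: mass, length and chamber volume must be finite and
#' positive; unknown sex is tolerated and flagged; delta-13C outside the
#' plausible freshwater-consumer range `[-35, -15]` permil triggers a
#' warning (the value is kept).
#'
#' @param path CSV or TSV file with a header. Required columns:
#'   `fish_id`, `habitat`, `sex`, `mass_g`, `length_mm`,
#'   `chamber_volume_l`, `d13c`, `d15n`. Optional: `cn_ratio`, `pc2`,
#'   `pc3`.
#' @param sep Field separator; guessed from the extension by default.
#' @return A data frame of class `cohort_table`.
#' @export
read_cohort_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_cohort(raw)
}

#' Validate a cohort data frame
#'
#' @param df A data frame with the columns documented in
#'   [read_cohort_table()].
#' @return The validated data frame, classed `cohort_table`.
#' @export
validate_cohort <- function(df) {
  need <- c("fish_id", "habitat", "sex", "mass_g", "length_mm",
            "chamber_volume_l", "d13c", "d15n")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$fish_id <- as.character(df$fish_id)
  if (anyDuplicated(df$fish_id)) stop("duplicate fish_id in cohort table")
  df$habitat <- toupper(df$habitat)
  bad_h <- setdiff(unique(df$habitat), c("LITTORAL", "PELAGIC"))
  if (length(bad_h)) stop("unknown habitat value(s): ", paste(bad_h, collapse = ", "))
  df$sex <- toupper(df$sex)
  df$sex[is.na(df$sex) | !df$sex %in% c("M", "F")] <- "UNKNOWN"
  for (col in c("mass_g", "length_mm", "chamber_volume_l")) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("cohort column '", col, "' must be finite and positive")
    }
  }
  out_of_range <- is.finite(df$d13c) & (df$d13c < -35 | df$d13c > -15)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " fish with d13c outside [-35, -15] permil: ",
            paste(df$fish_id[out_of_range], collapse = ", "))
  }
  if (!"cn_ratio" %in% names(df)) df$cn_ratio <- NA_real_
  if (any(is.finite(df$cn_ratio) & df$cn_ratio <= 0)) {
    stop("cn_ratio must be positive where present")
  }
  df <- df[order(df$fish_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
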