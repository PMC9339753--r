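#' Mass-independent metabolic measures via log-log residuals
#'
#' Whole-animal metabolic rates scale allometrically with body mass, so
#' raw SMR/MMR/AAS/FAS cannot be compared across fish of different
#' sizes. Both mass and each metabolic measure are log-transformed
#' (which also corrects the right skew typical of metabolic data) and a
#' single pooled OLS of log(measure) on log(mass) is fitted across the
#' whole cohort; the residuals are the mass-independent measures used by
#' the group comparisons. Pooling (one regression per measure, not per
#' group) is what makes residuals comparable across groups.
#'
#' Fish with a non-positive measure (e.g. AAS = 0 when SMR = MMR) cannot
#' be log-transformed; they are excluded from that measure's fit with a
#' warning.
#'
#' @param summaries Data frame with `fish_id` and the metric columns
#'   (default `smr`, `mmr`, `aas`, `fas`).
#' @param masses Data frame with `fish_id` and `mass_g`, or a numeric
#'   vector aligned with `summaries`.
#' @param metrics Character vector of metric columns to fit.
#' @param log_base Base of the log transform (default 10, conventional
#'   in metabolic scaling; residual magnitudes scale with the base but
#'   downstream F statistics and p-values do not depend on it).
#' @return A list of class `scaling_fits`: one element per metric, each
#'   with `metric`, `intercept`, `slope` (the scaling exponent), `r2`,
#'   `log_base`, and `residuals` (data frame `fish_id`,
#'   `resid_<metric>`); plus attribute `residual_table`, a wide data
#'   frame of all residuals keyed by `fish_id`.
#' @export
mass_residuals <- function(summaries, masses,
                           metrics = c("smr", "mmr", "aas", "fas"),
                           log_base = 10) {
  if (is.data.frame(masses)) {
    m <- masses$mass_g[match(summaries$fish_id, masses$fish_id)]
  } else {
    m <- rep_len(masses, nrow(summaries))
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("all masses must be known, finite and positive")
  }
  if (nrow(summaries) < 3L) stop("need at least 3 fish for a scaling fit")
  fits <- list()
  wide <- data.frame(fish_id = summaries$fish_id)
  for (met in metrics) {
    y <- summaries[[met]]
    if (is.null(y)) stop("metric column '", met, "' not found")
    ok <- is.finite(y) & y > 0
    if (any(!ok)) {
      warning(sum(!ok), " fish excluded from ", met,
              " scaling fit (non-positive value): ",
              paste(summaries$fish_id[!ok], collapse = ", "))
    }
    if (sum(ok) < 3L) stop("fewer than 3 usable fish for metric ", met)
    lx <- log(m[ok], base = log_base)
    ly <- log(y[ok], base = log_base)
    f <- stats::lm(ly ~ lx)
    res <- rep(NA_real_, nrow(summaries))
    res[ok] <- stats::residuals(f)
    fits[[met]] <- list(
      metric = met,
      intercept = unname(stats::coef(f)[1]),
      slope = unname(stats::coef(f)[2]),
      r2 = summary(f)$r.squared,
      log_base = log_base,
      residuals = data.frame(fish_id = summaries$fish_id,
                             residual = res)
    )
    wide[[paste0("resid_", met)]] <- res
  }
  structure(fits, class = "scaling_fits", residual_table = wide)
}

#' Extract the wide residual table from a scaling fit
#'
#' @param fits A [mass_residuals()] result.
#' @return Data frame `fish_id`, `resid_<metric>`...
#' @export
residual_table <- function(fits) {
  stopifnot(inherits(fits, "scaling_fits"))
  attr(fits, "residual_table")
}
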