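#' Extract the sealed measurement segments from a trace
#'
#' Splits a trace into its MEASURE-phase segments, one per loop, ordered
#' by time. FLUSH and WAIT points are discarded.
#'
#' @param trace A [resp_trace()].
#' @param protocol A [protocol_config()]; only used for sanity checks.
#' @return A list of data frames (`time_s`, `o2`, `loop_index`), one per
#'   measurement phase.
#' @export
segment_phases <- function(trace, protocol = protocol_config()) {
  stopifnot(inherits(trace, "resp_trace"))
  d <- trace$data[trace$data$phase == "MEASURE", , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("trace for fish ", trace$fish_id, " contains no MEASURE points")
  }
  segs <- split(d[c("time_s", "o2", "loop_index")], d$loop_index)
  segs <- segs[order(vapply(segs, function(s) s$time_s[1], numeric(1)))]
  unname(segs)
}

# Closed-form simple OLS of y on x; returns slope, intercept, r2 (squared
# Pearson correlation; NA when either variable is constant).
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy > 0 && sxx > 0) (sxy * sxy) / (sxx * syy) else NA_real_
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Fit the oxygen decline of one measurement phase
#'
#' Ordinary least squares of oxygen concentration on time over a sealed
#' measurement segment. R-squared is the squared Pearson correlation of
#' oxygen with time. Segments with fewer than 3 points are skipped with
#' a warning (returns `NULL`); a segment with zero oxygen variance gets
#' slope 0 and fails QC (R-squared undefined).
#'
#' @param segment Data frame with `time_s`, `o2` and optionally
#'   `loop_index`.
#' @return A one-row data frame (`loop_index`, `t_mid`, `slope`,
#'   `intercept`, `r2`, `n_points`), or `NULL`.
#' @export
fit_phase_slope <- function(segment) {
  n <- nrow(segment)
  if (n < 3L) {
    warning("measurement phase with ", n, " point(s) skipped (need >= 3)")
    return(NULL)
  }
  f <- ols_fit(segment$time_s, segment$o2)
  if (!is.finite(f$slope)) f$slope <- 0
  data.frame(
    loop_index = if ("loop_index" %in% names(segment))
      segment$loop_index[1] else NA_integer_,
    t_mid = (min(segment$time_s) + max(segment$time_s)) / 2,
    slope = f$slope, intercept = f$intercept, r2 = f$r2, n_points = n
  )
}

#' Convert an oxygen decline slope to a whole-animal uptake rate
#'
#' `MO2 = -slope * 3600 * V_eff` where
#' `V_eff = chamber_volume_l - mass_g / 1000` is the chamber water
#' volume corrected for the animal's body volume (density 1 g/ml).
#' Result in mg O2 per hour (non-mass-specific).
#'
#' @param slope Oxygen slope, mg O2/L/s (negative while the animal
#'   consumes oxygen).
#' @param chamber_volume_l Chamber volume (L).
#' @param mass_g Body mass (g); 0 for an empty chamber.
#' @return MO2 in mg O2/h.
#' @export
slope_to_mo2 <- function(slope, chamber_volume_l, mass_g = 0) {
  v_eff <- chamber_volume_l - mass_g / 1000
  if (any(v_eff <= 0)) stop("effective volume must be positive")
  -slope * 3600 * v_eff
}

#' Fit the background respiration model for one trial
#'
#' Each background measurement (sealed, empty chamber, taken immediately
#' before and after the trial) is fitted by OLS of oxygen on time; a
#' measurement is retained only if its own fit has R-squared above
#' `gate_r2` (default 0.1). With both retained the background rate is
#' interpolated linearly in time between the two; with one retained it
#' is held constant; with none the model is zero (with a warning).
#' Negative fitted rates are clamped to zero with a warning.
#'
#' @param pre,post [background_trace()] objects (either may be `NULL`).
#' @param chamber_volume_l Chamber volume (L) used to convert slopes to
#'   mg O2/h.
#' @param gate_r2 Retention gate on the background fit's R-squared.
#' @return An object of class `background_model`: fields `mode`
#'   (`"LINEAR"`, `"CONSTANT_PRE"`, `"CONSTANT_POST"`, `"ZERO"`),
#'   `bg_pre`/`bg_post` (mg O2/h, `NA` when not retained), and `bg_fun`,
#'   a vectorised function of trial time returning mg O2/h.
#' @export
fit_background <- function(pre, post, chamber_volume_l, gate_r2 = 0.1) {
  eval_bg <- function(bt) {
    if (is.null(bt)) return(NULL)
    stopifnot(inherits(bt, "background_trace"))
    f <- ols_fit(bt$data$time_s, bt$data$o2)
    if (!is.finite(f$r2) || f$r2 <= gate_r2) return(NULL)
    rate <- slope_to_mo2(f$slope, chamber_volume_l)
    if (rate < 0) {
      warning("negative fitted background rate clamped to 0")
      rate <- 0
    }
    list(rate = rate, t = mean(bt$data$time_s))
  }
  b_pre <- eval_bg(pre)
  b_post <- eval_bg(post)
  if (!is.null(b_pre) && !is.null(b_post)) {
    mode <- "LINEAR"
    slope_t <- (b_post$rate - b_pre$rate) / (b_post$t - b_pre$t)
    fun <- function(t) pmax(b_pre$rate + slope_t * (t - b_pre$t), 0)
  } else if (!is.null(b_pre)) {
    mode <- "CONSTANT_PRE"
    fun <- function(t) rep_len(b_pre$rate, length(t))
  } else if (!is.null(b_post)) {
    mode <- "CONSTANT_POST"
    fun <- function(t) rep_len(b_post$rate, length(t))
  } else {
    warning("no background measurement passed the R-squared gate; ",
            "assuming zero background respiration")
    mode <- "ZERO"
    fun <- function(t) rep_len(0, length(t))
  }
  structure(
    list(mode = mode,
         bg_pre = if (is.null(b_pre)) NA_real_ else b_pre$rate,
         bg_post = if (is.null(b_post)) NA_real_ else b_post$rate,
         bg_fun = fun),
    class = "background_model"
  )
}

#' Compute raw and background-corrected MO2 for every phase
#'
#' Converts each phase slope to a raw MO2 and subtracts the fitted
#' background respiration evaluated at the phase midpoint. Corrected
#' values below zero are floored at zero with a warning (dropping them
#' would bias the standard metabolic rate upward).
#'
#' @param slopes Data frame from [fit_phase_slope()] rows.
#' @param bg_model A [fit_background()] result, or `NULL` for no
#'   correction.
#' @param chamber_volume_l,mass_g Used for the slope-to-MO2 conversion.
#' @return `slopes` with columns `mo2_raw` and `mo2_corrected` added.
#' @export
correct_background <- function(slopes, bg_model, chamber_volume_l, mass_g) {
  slopes$mo2_raw <- slope_to_mo2(slopes$slope, chamber_volume_l, mass_g)
  bg <- if (is.null(bg_model)) 0 else bg_model$bg_fun(slopes$t_mid)
  corrected <- slopes$mo2_raw - bg
  n_neg <- sum(corrected < 0)
  if (n_neg > 0) {
    warning(n_neg, " background-corrected MO2 value(s) below zero ",
            "floored at 0")
    corrected <- pmax(corrected, 0)
  }
  slopes$mo2_corrected <- corrected
  slopes
}

#' Quality-filter phase estimates on fit linearity
#'
#' Phases whose oxygen-vs-time fit has R-squared below `qc_r2` (default
#' 0.90) are removed before SMR/MMR/scope estimation; phases with
#' undefined R-squared (zero oxygen variance) also fail.
#'
#' @param slopes Data frame of phase fits (needs column `r2`).
#' @param qc_r2 Minimum R-squared retained.
#' @return A list: `kept` and `removed` data frames, each with a
#'   `qc_pass` column.
#' @export
qc_filter <- function(slopes, qc_r2 = 0.90) {
  pass <- !is.na(slopes$r2) & slopes$r2 >= qc_r2
  slopes$qc_pass <- pass
  list(kept = slopes[pass, , drop = FALSE],
       removed = slopes[!pass, , drop = FALSE])
}

#' Summarise a trial into SMR, MMR and aerobic scope
#'
#' SMR (standard metabolic rate) is the mean of the lowest
#' `smr_quantile` fraction of the QC-passed, background-corrected MO2
#' values, with the count rounded half-up and floored at one value
#' (121 phases at the default 10% gives the 12 lowest). MMR (maximum
#' metabolic rate) is the global maximum; ties resolve to the earliest
#' phase. Absolute aerobic scope AAS = MMR - SMR and factorial scope
#' FAS = MMR / SMR hold exactly by construction.
#'
#' @param kept_slopes QC-passed phase data frame (needs `mo2_corrected`;
#'   `t_mid` used for tie-breaking).
#' @param smr_quantile Fraction of lowest values averaged for SMR.
#' @param min_phases Minimum number of usable phases; below this the
#'   fish is flagged (`NULL` returned with a warning) and should be
#'   excluded from downstream statistics.
#' @param fish_id Identifier copied into the summary.
#' @param n_total,n_removed Phase QC bookkeeping
#'   (`n_total = nrow(kept_slopes) + n_removed` must hold).
#' @return A one-row data frame: `fish_id`, `smr`, `mmr`, `aas`, `fas`,
#'   `mmr_t_mid`, `n_phases_total`, `n_phases_used`,
#'   `n_phases_qc_removed`; or `NULL` when under `min_phases`.
#' @export
summarize_metabolism <- function(kept_slopes, smr_quantile = 0.10,
                                 min_phases = 10, fish_id = NA_character_,
                                 n_total = nrow(kept_slopes),
                                 n_removed = n_total - nrow(kept_slopes)) {
  n_kept <- nrow(kept_slopes)
  stopifnot(n_total == n_kept + n_removed)
  if (n_kept < min_phases) {
    warning("fish ", fish_id, ": only ", n_kept,
            " usable phases (< ", min_phases, "); no summary produced")
    return(NULL)
  }
  mo2 <- kept_slopes$mo2_corrected
  n_low <- max(1L, floor(smr_quantile * n_kept + 0.5))
  smr <- mean(sort(mo2)[seq_len(n_low)])
  mmr <- max(mo2)
  mmr_t <- if ("t_mid" %in% names(kept_slopes)) {
    min(kept_slopes$t_mid[mo2 == mmr])
  } else NA_real_
  data.frame(
    fish_id = fish_id, smr = smr, mmr = mmr,
    aas = mmr - smr, fas = mmr / smr, mmr_t_mid = mmr_t,
    n_phases_total = n_total, n_phases_used = n_kept,
    n_phases_qc_removed = n_removed
  )
}

#' Process one trial end-to-end: trace to metabolic summary
#'
#' Runs the full per-fish chain: segment the measurement phases, fit
#' each phase's oxygen slope, fit and subtract background respiration,
#' apply the linearity QC gate, and summarise into SMR/MMR/AAS/FAS.
#'
#' @param trace A [resp_trace()].
#' @param bg_pre,bg_post Optional [background_trace()] objects.
#' @param chamber_volume_l,mass_g Chamber and animal size.
#' @param protocol A [protocol_config()].
#' @param bg_gate_r2 Background retention gate (default 0.1).
#' @param qc_r2 Phase linearity gate (default 0.90).
#' @param smr_quantile Lowest fraction averaged for SMR (default 0.10).
#' @param min_phases Minimum usable phases for a summary.
#' @param correct Set `FALSE` to skip background subtraction.
#' @return A list: `summary` (one-row data frame or `NULL`), `slopes`
#'   (all phases with QC flags), `bg_model`.
#' @export
process_trace <- function(trace, bg_pre = NULL, bg_post = NULL,
                          chamber_volume_l, mass_g,
                          protocol = protocol_config(),
                          bg_gate_r2 = 0.1, qc_r2 = 0.90,
                          smr_quantile = 0.10, min_phases = 10,
                          correct = TRUE) {
  segs <- segment_phases(trace, protocol)
  fits <- lapply(segs, fit_phase_slope)
  slopes <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(slopes) || nrow(slopes) == 0L) {
    stop("no fittable measurement phases for fish ", trace$fish_id)
  }
  bg_model <- if (correct && (!is.null(bg_pre) || !is.null(bg_post))) {
    fit_background(bg_pre, bg_post, chamber_volume_l, gate_r2 = bg_gate_r2)
  } else NULL
  slopes <- correct_background(slopes, bg_model, chamber_volume_l, mass_g)
  qc <- qc_filter(slopes, qc_r2 = qc_r2)
  summary <- summarize_metabolism(
    qc$kept, smr_quantile = smr_quantile, min_phases = min_phases,
    fish_id = trace$fish_id, n_total = nrow(slopes),
    n_removed = nrow(qc$removed)
  )
  list(summary = summary,
       slopes = rbind(qc$kept, qc$removed)[order(c(qc$kept$t_mid,
                                                   qc$removed$t_mid)), ,
                                           drop = FALSE],
       bg_model = bg_model)
}
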