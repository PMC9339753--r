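#' Process every trial of a study into per-fish summaries
#'
#' Maps [process_trace()] over a set of trials (e.g. from
#' [simulate_study()] or read from disk), returning the stacked phase
#' table and the per-fish metabolic summary table. Fish whose trials
#' yield too few usable phases are reported in `flagged` and omitted
#' from `summaries`.
#'
#' @param trials Named list; each element has `trace`, and optionally
#'   `bg_pre`, `bg_post`.
#' @param cohort Cohort data frame supplying `mass_g` and
#'   `chamber_volume_l` per fish.
#' @param protocol A [protocol_config()].
#' @param bg_gate_r2,qc_r2,smr_quantile,min_phases,correct Passed to
#'   [process_trace()].
#' @return A list: `summaries` (one row per fish), `slopes` (all phases,
#'   all fish), `flagged` (character vector of fish ids without a
#'   summary).
#' @export
process_study <- function(trials, cohort, protocol = protocol_config(),
                          bg_gate_r2 = 0.1, qc_r2 = 0.90,
                          smr_quantile = 0.10, min_phases = 10,
                          correct = TRUE) {
  summaries <- list(); slopes <- list(); flagged <- character()
  for (id in names(trials)) {
    tr <- trials[[id]]
    row <- cohort[cohort$fish_id == tr$trace$fish_id, , drop = FALSE]
    if (nrow(row) != 1L) stop("fish ", tr$trace$fish_id, " not in cohort")
    res <- process_trace(tr$trace, tr$bg_pre, tr$bg_post,
                         chamber_volume_l = row$chamber_volume_l,
                         mass_g = row$mass_g, protocol = protocol,
                         bg_gate_r2 = bg_gate_r2, qc_r2 = qc_r2,
                         smr_quantile = smr_quantile,
                         min_phases = min_phases, correct = correct)
    sl <- res$slopes
    sl$fish_id <- tr$trace$fish_id
    slopes[[id]] <- sl
    if (is.null(res$summary)) {
      flagged <- c(flagged, tr$trace$fish_id)
    } else {
      summaries[[id]] <- res$summary
    }
  }
  summ <- do.call(rbind, summaries)
  if (!is.null(summ)) {
    summ <- summ[order(summ$fish_id), , drop = FALSE]
    rownames(summ) <- NULL
  }
  list(summaries = summ, slopes = do.call(rbind, slopes),
       flagged = flagged)
}

#' Assemble the analysis table: residuals, groups, metadata
#'
#' Joins the mass-independent residuals with the cohort metadata and
#' the delta-13C group assignments into the single data frame the group
#' comparisons run on.
#'
#' @param summaries Per-fish summary table from [process_study()].
#' @param cohort Cohort data frame.
#' @param log_base Log base for [mass_residuals()].
#' @param nstart,seed Passed to the clustering.
#' @param min_group_n Minimum habitat-by-resource group size retained.
#' @return A list: `data` (analysis data frame with `resid_smr` ...
#'   `resid_fas`, `habitat`, `sex`, `resource_use`, `habitat_resource`,
#'   exclusion flags), `scaling` (the [mass_residuals()] fits),
#'   `groups_k3`, `groups_k2`, `groups_hr`.
#' @export
build_analysis_table <- function(summaries, cohort, log_base = 10,
                                 nstart = 25, seed = 1L,
                                 min_group_n = 2) {
  scaling <- mass_residuals(summaries, cohort, log_base = log_base)
  resid <- residual_table(scaling)
  sub <- cohort[cohort$fish_id %in% summaries$fish_id, , drop = FALSE]
  sub <- sub[order(sub$fish_id), , drop = FALSE]
  k3 <- assign_resource_groups(sub, k = 3, nstart = nstart, seed = seed)
  k2 <- assign_resource_groups(sub, k = 2, nstart = nstart, seed = seed)
  hr <- assign_habitat_resource_groups(sub, k2, min_group_n = min_group_n)
  d <- merge(resid, as.data.frame(sub), by = "fish_id")
  d$resource_use <- k3$resource_use[match(d$fish_id, k3$fish_id)]
  d$habitat_resource <- hr$habitat_resource[match(d$fish_id, hr$fish_id)]
  d$hr_excluded <- hr$excluded[match(d$fish_id, hr$fish_id)]
  d <- d[order(d$fish_id), , drop = FALSE]
  rownames(d) <- NULL
  list(data = d, scaling = scaling, groups_k3 = k3, groups_k2 = k2,
       groups_hr = hr)
}

#' Group-comparison models for one grouping condition
#'
#' For each mass-independent response, fits
#' `residual ~ sex + <condition>` (type-2 sums of squares; no
#' interaction) and computes Tukey-adjusted pairwise contrasts of the
#' condition's estimated marginal means. For the habitat-by-resource
#' condition, fish in excluded groups are dropped first.
#'
#' @param data Analysis data frame from [build_analysis_table()].
#' @param condition One of `"habitat"`, `"habitat_resource"`,
#'   `"resource_use"`.
#' @param responses Residual columns to model.
#' @return A named list per response: `anova` ([fit_anova()] result)
#'   and `contrasts` ([emm_pairwise()] data frame).
#' @export
compare_groups <- function(data, condition = c("habitat",
                                               "habitat_resource",
                                               "resource_use"),
                           responses = c("resid_smr", "resid_mmr",
                                         "resid_fas", "resid_aas")) {
  condition <- match.arg(condition)
  d <- data
  if (condition == "habitat_resource") {
    d <- d[!is.na(d$habitat_resource) & !d$hr_excluded, , drop = FALSE]
    d$habitat_resource <- droplevels(d$habitat_resource)
  }
  out <- list()
  for (resp in responses) {
    fit <- fit_anova(d, resp, c("sex", condition))
    out[[resp]] <- list(anova = fit,
                        contrasts = emm_pairwise(fit, condition))
  }
  out
}

#' Run the full analysis on a simulated or loaded study
#'
#' Chains [process_study()], [build_analysis_table()], and
#' [compare_groups()] for the three grouping conditions.
#'
#' @param study List with `trials` and `cohort` (e.g. from
#'   [simulate_study()]).
#' @param seed Seed for the clustering starts.
#' @param ... Passed to [process_study()].
#' @return A list: `processed`, `analysis`, `models` (per condition).
#' @export
run_pipeline <- function(study, seed = 1L, ...) {
  processed <- process_study(study$trials, study$cohort, ...)
  analysis <- build_analysis_table(processed$summaries, study$cohort,
                                   seed = seed)
  models <- lapply(
    c(habitat = "habitat", habitat_resource = "habitat_resource",
      resource_use = "resource_use"),
    function(cond) compare_groups(analysis$data, cond)
  )
  list(processed = processed, analysis = analysis, models = models)
}
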