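#' Typed-sums-of-squares ANOVA on a linear model
#'
#' Fits an OLS model with sum-to-zero factor coding and partitions
#' variance with type-2 sums of squares when the model has no
#' interaction and type-3 when it has one (type-3 tests are
#' contrast-dependent; sum-to-zero coding is the convention that makes
#' them marginal-mean tests). Rows with missing values in any model
#' variable are dropped as complete cases and counted.
#'
#' @param data Data frame.
#' @param response Name of the numeric response column.
#' @param terms Character vector of right-hand-side terms, e.g.
#'   `c("sex", "habitat")` or `c("sex", "habitat", "pc2", "pc2:habitat")`.
#' @param ss_type 2 or 3; by default 3 when any `terms` entry contains
#'   an interaction (`:"`), else 2.
#' @return An object of class `anova_result`: `table` (data frame
#'   `term`, `F`, `df1`, `df2`, `p`), `model_F`, `model_df1`,
#'   `model_df2`, `model_p`, `adj_r2`, `ss_type`, `n_used`,
#'   `n_dropped`, and `fit` (the underlying `lm`).
#' @export
fit_anova <- function(data, response, terms, ss_type = NULL) {
  has_interaction <- any(grepl(":", terms, fixed = TRUE))
  if (is.null(ss_type)) ss_type <- if (has_interaction) 3 else 2
  stopifnot(ss_type %in% c(2, 3))
  vars <- unique(c(response, unlist(strsplit(terms, ":", fixed = TRUE))))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("model variable(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }
  d <- data[vars]
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  ctr <- list()
  for (v in setdiff(vars, response)) {
    if (is.character(d[[v]]) || is.factor(d[[v]])) {
      d[[v]] <- droplevels(factor(d[[v]]))
      if (nlevels(d[[v]]) < 2) {
        stop("factor '", v, "' has fewer than 2 levels after exclusions")
      }
      ctr[[v]] <- "contr.sum"
    }
  }
  fml <- stats::reformulate(terms, response = response)
  fit <- stats::lm(fml, data = d,
                   contrasts = if (length(ctr)) ctr else NULL)
  if (stats::var(d[[response]]) == 0) {
    # zero-variance response: every term explains nothing
    p_model <- length(stats::coef(fit)) - 1
    tab <- data.frame(term = terms, F = 0, df1 = NA_integer_,
                      df2 = nrow(d) - p_model - 1, p = 1)
    return(structure(
      list(table = tab, model_F = 0, model_df1 = p_model,
           model_df2 = nrow(d) - p_model - 1, model_p = 1,
           adj_r2 = 0, ss_type = ss_type, n_used = nrow(d),
           n_dropped = n_dropped, fit = fit),
      class = "anova_result"
    ))
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient model; aliased coefficient(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  a <- car::Anova(fit, type = ss_type)
  at <- as.data.frame(a)
  keep <- !rownames(at) %in% c("(Intercept)", "Residuals")
  df_resid <- at["Residuals", "Df"]
  tab <- data.frame(
    term = rownames(at)[keep],
    F = at[keep, "F value"],
    df1 = at[keep, "Df"],
    df2 = df_resid,
    p = at[keep, "Pr(>F)"],
    row.names = NULL
  )
  s <- summary(fit)
  fstat <- s$fstatistic
  structure(
    list(table = tab,
         model_F = unname(fstat[1]), model_df1 = unname(fstat[2]),
         model_df2 = unname(fstat[3]),
         model_p = stats::pf(fstat[1], fstat[2], fstat[3],
                             lower.tail = FALSE),
         adj_r2 = s$adj.r.squared, ss_type = ss_type,
         n_used = nrow(d), n_dropped = n_dropped, fit = fit),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA (type ", x$ss_type, " SS), n = ", x$n_used, "\n", sep = "")
  print(x$table, digits = 4)
  cat(sprintf("Model: F(%d,%d) = %.2f, p = %.4g, adj R2 = %.2f\n",
              x$model_df1, x$model_df2, x$model_F, x$model_p, x$adj_r2))
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' Estimated marginal means average model predictions over the levels
#' of the other factors with equal weights; pairwise differences carry
#' standard errors from the coefficient covariance and p-values from
#' the studentized-range distribution on the residual degrees of
#' freedom (Tukey adjustment). With two levels the adjustment reduces
#' to the ordinary t-test p-value.
#'
#' @param fit An [fit_anova()] result (or an `lm`).
#' @param factor_name Factor whose levels are compared.
#' @return Data frame `contrast`, `estimate`, `se`, `df`, `p_adj`.
#' @export
emm_pairwise <- function(fit, factor_name) {
  model <- if (inherits(fit, "anova_result")) fit$fit else fit
  xl <- model$xlevels[[factor_name]]
  if (is.null(xl) || length(xl) < 2) {
    stop("'", factor_name, "' is not a multi-level factor in the model")
  }
  em <- emmeans::emmeans(model, specs = factor_name)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = as.character(pr$contrast),
             estimate = pr$estimate, se = pr$SE, df = pr$df,
             p_adj = pr$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. U for the first
#' sample is computed from midranks (ties allowed):
#' `U1 = R1 - n1 (n1 + 1) / 2`; `U1 + U2 = n1 n2` always. The p-value
#' is exact (distribution of the rank sum enumerated over all
#' assignments) when `n1 * n2 <= 400` and there are no ties, otherwise
#' a normal approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric samples.
#' @param alternative Passed to the test (default two-sided).
#' @return A list: `u` (first sample), `u_other`, `u_min`, `p`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && n1 * n2 <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(u = u1, u_other = n1 * n2 - u1, u_min = min(u1, n1 * n2 - u1),
       p = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n1 = n1, n2 = n2)
}

#' Screen morphology covariates and emit a reduced model
#'
#' Fits the base model plus each morphology covariate and its
#' interaction with the grouping factor (type-3 sums of squares, since
#' an interaction is present) and reports the covariate terms' F tests.
#' When every covariate-related term has p >= `alpha` the covariates
#' are dropped and the returned reduced term set equals the base model;
#' any covariate with a significant main effect or interaction is
#' retained.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param base_terms Character vector of base model terms
#'   (e.g. `c("sex", "habitat")`).
#' @param group_factor Factor interacting with the covariates
#'   (default `"habitat"`).
#' @param covariates Covariate column names; entries absent from `data`
#'   are ignored (pass-through when none present).
#' @param alpha Retention threshold (default 0.05).
#' @return A list: `report` (data frame `term`, `F`, `df1`, `df2`, `p`,
#'   `covariate`), `retained` (character), `reduced_terms` (character).
#' @export
screen_morphology_covariates <- function(data, response, base_terms,
                                         group_factor = "habitat",
                                         covariates = c("pc2", "pc3"),
                                         alpha = 0.05) {
  covariates <- intersect(covariates, names(data))
  covariates <- covariates[vapply(covariates, function(v)
    any(is.finite(data[[v]])), logical(1))]
  if (!length(covariates)) {
    return(list(report = data.frame(term = character(), F = numeric(),
                                    df1 = integer(), df2 = integer(),
                                    p = numeric(), covariate = character()),
                retained = character(), reduced_terms = base_terms))
  }
  cov_terms <- unlist(lapply(covariates, function(v)
    c(v, paste0(v, ":", group_factor))))
  full <- fit_anova(data, response, c(base_terms, cov_terms), ss_type = 3)
  tab <- full$table
  is_cov <- vapply(tab$term, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    any(parts %in% covariates)
  }, logical(1))
  report <- tab[is_cov, , drop = FALSE]
  report$covariate <- vapply(report$term, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    intersect(parts, covariates)[1]
  }, character(1))
  retained <- unique(report$covariate[report$p < alpha])
  reduced <- if (length(retained)) {
    c(base_terms, unlist(lapply(retained, function(v)
      c(v, paste0(v, ":", group_factor)))))
  } else {
    base_terms
  }
  list(report = report, retained = retained, reduced_terms = reduced)
}
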