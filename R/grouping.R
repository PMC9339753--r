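#' One-dimensional k-means clustering
#'
#' Partitions a numeric vector into `k` clusters by k-means with
#' `nstart` random starts, keeping the best solution by total
#' within-cluster sum of squares. Deterministic given `seed`. Centers
#' are reported in increasing order and assignments relabelled to match,
#' so the result does not depend on the input order or the arbitrary
#' labelling of a particular run.
#'
#' @param values Numeric vector (n >= k, at least k distinct values).
#' @param k Number of clusters.
#' @param nstart Random starts (default 25).
#' @param seed RNG seed.
#' @return A list: `assignments` (integer 1..k, 1 = lowest center),
#'   `centers` (increasing), `within_ss` (total within-cluster SS).
#' @export
kmeans_1d <- function(values, k, nstart = 25, seed = 1L) {
  stopifnot(is.numeric(values), k >= 1, nstart >= 1)
  n <- length(values)
  if (n < k) stop("need at least k = ", k, " values, got ", n)
  if (length(unique(values)) < k) {
    stop("fewer than k distinct values; clusters would be degenerate")
  }
  if (k == n) {
    # every point its own cluster
    return(list(assignments = as.integer(rank(values)),
                centers = sort(values), within_ss = 0))
  }
  set.seed(seed)
  km <- stats::kmeans(matrix(values, ncol = 1), centers = k,
                      nstart = nstart, iter.max = 100)
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  list(
    assignments = relabel[km$cluster],
    centers = unname(sort(km$centers[, 1])),
    within_ss = km$tot.withinss
  )
}

#' Assign pelagic resource-use groups from delta-13C
#'
#' In lakes, lower muscle delta-13C indicates greater reliance on
#' pelagic (open-water) carbon. Fish are clustered on delta-13C alone by
#' [kmeans_1d()]; with `k = 3` the clusters are labelled `HIGH`/`MID`/
#' `LOW` pelagic resource use in order of increasing delta-13C (the most
#' negative cluster center is the most pelagic-reliant), and with
#' `k = 2` analogously `HIGH`/`LOW`.
#'
#' @param cohort A cohort data frame with `fish_id` and `d13c`.
#' @param k 2 or 3 clusters.
#' @param nstart,seed Passed to [kmeans_1d()].
#' @return Data frame `fish_id`, `resource_use` (factor
#'   LOW/(MID)/HIGH), `d13c_center`, `excluded`, `exclude_reason`. Fish
#'   with missing delta-13C are excluded with a reason, not dropped.
#' @export
assign_resource_groups <- function(cohort, k = 3, nstart = 25, seed = 1L) {
  stopifnot(k %in% c(2, 3))
  ok <- is.finite(cohort$d13c)
  out <- data.frame(fish_id = cohort$fish_id,
                    resource_use = factor(NA, levels = if (k == 3)
                      c("LOW", "MID", "HIGH") else c("LOW", "HIGH")),
                    d13c_center = NA_real_,
                    excluded = !ok,
                    exclude_reason = ifelse(ok, "", "missing d13c"))
  if (sum(ok) < k) stop("fewer fish with d13c than clusters requested")
  km <- kmeans_1d(cohort$d13c[ok], k = k, nstart = nstart, seed = seed)
  # cluster 1 has the lowest (most negative) d13c center = most pelagic
  labels <- if (k == 3) c("HIGH", "MID", "LOW") else c("HIGH", "LOW")
  out$resource_use[ok] <- labels[km$assignments]
  out$d13c_center[ok] <- km$centers[km$assignments]
  out
}

#' Cross capture habitat with binary resource use
#'
#' Builds the four-way habitat-by-resource-use grouping
#' (`LITTORAL_LOW`, `LITTORAL_HIGH`, `PELAGIC_LOW`, `PELAGIC_HIGH`) from
#' the capture habitat and a `k = 2` resource-use assignment. Groups
#' with fewer than `min_group_n` fish are flagged excluded (a group of
#' one animal supports no comparison).
#'
#' @param cohort Cohort data frame with `fish_id` and `habitat`.
#' @param k2 Result of [assign_resource_groups()] with `k = 2`.
#' @param min_group_n Minimum group size retained (default 2).
#' @return Data frame `fish_id`, `habitat_resource` (factor), `excluded`,
#'   `exclude_reason`, plus attribute `group_sizes` (named integer).
#' @export
assign_habitat_resource_groups <- function(cohort, k2, min_group_n = 2) {
  stopifnot(all(cohort$fish_id == k2$fish_id))
  lvl <- c("LITTORAL_LOW", "LITTORAL_HIGH", "PELAGIC_LOW", "PELAGIC_HIGH")
  grp <- ifelse(k2$excluded, NA,
                paste(cohort$habitat, as.character(k2$resource_use),
                      sep = "_"))
  grp <- factor(grp, levels = lvl)
  sizes <- table(grp)
  small <- names(sizes)[sizes < min_group_n & sizes > 0]
  excluded <- k2$excluded | (!is.na(grp) & as.character(grp) %in% small)
  reason <- ifelse(k2$excluded, k2$exclude_reason,
                   ifelse(!is.na(grp) & as.character(grp) %in% small,
                          sprintf("group %s has n < %d", as.character(grp),
                                  min_group_n),
                          ""))
  structure(
    data.frame(fish_id = cohort$fish_id, habitat_resource = grp,
               excluded = excluded, exclude_reason = reason),
    group_sizes = sizes
  )
}
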