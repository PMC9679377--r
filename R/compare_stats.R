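# Comparative statistics: tie-corrected Kruskal-Wallis, Dunn's post hoc
# test with a pooled Bonferroni family, and effect summaries (medians and
# percent decrease).

#' Kruskal-Wallis test of a metric across groups
#'
#' Thin, surface-stable wrapper around [stats::kruskal.test()] (which
#' applies the tie correction). Groups with fewer than 2 observations are
#' dropped with a warning; fewer than 2 remaining groups is an error.
#'
#' @param values Numeric vector (NA dropped with a count).
#' @param groups Group labels, parallel to `values`.
#' @return List: `statistic` (H), `df`, `p_value`, `n`, `group_sizes`,
#'   `n_dropped_na`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  n_na <- sum(!ok)
  values <- values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2) stop("need at least 2 groups with >= 2 observations")
  kt <- stats::kruskal.test(values, factor(groups))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values),
       group_sizes = as.integer(sizes), n_dropped_na = n_na)
}

#' Dunn's post hoc test (tie-corrected)
#'
#' All pairwise comparisons on the ranks of the pooled sample:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' with two-sided unadjusted p-values `2 * pnorm(-|z|)`. Adjusted p-values
#' use Bonferroni with family size `m` — by default the number of pairs in
#' this test, but pass the pooled [bonferroni_family()] size to correct
#' across a batch of tests jointly.
#'
#' @param values Numeric vector.
#' @param groups Group labels, parallel to `values`.
#' @param m Bonferroni family size (default: pairs within this test).
#' @return Data frame: `group_i`, `group_j`, `z`, `p_unadjusted`,
#'   `p_adjusted`, `mean_rank_i`, `mean_rank_j`; attribute `m` records the
#'   family size used.
#' @export
dunn_posthoc <- function(values, groups, m = NULL) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  lev <- sort(unique(groups))
  k <- length(lev)
  if (k < 2) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)  # midranks for ties
  rbar <- tapply(r, factor(groups, levels = lev), mean)
  n <- tapply(r, factor(groups, levels = lev), length)
  t_sizes <- table(values)
  tie_term <- sum(t_sizes^3 - t_sizes) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(lev, 2)
  if (is.null(m)) m <- ncol(pairs)
  out <- data.frame(
    group_i = pairs[1, ], group_j = pairs[2, ],
    z = NA_real_, p_unadjusted = NA_real_, p_adjusted = NA_real_,
    mean_rank_i = unname(rbar[pairs[1, ]]),
    mean_rank_j = unname(rbar[pairs[2, ]]),
    stringsAsFactors = FALSE)
  se <- sqrt(var_base * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  out$z <- unname((rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se)
  out$p_unadjusted <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, out$p_unadjusted * m)
  attr(out, "m") <- m
  out
}

#' Pooled Bonferroni family size across a batch of tests
#'
#' The family is all pairwise comparisons pooled across every test in the
#' batch: `m = sum over tests of k_t * (k_t - 1) / 2`, where `k_t` is the
#' number of groups in test t.
#'
#' @param group_counts Integer vector: number of groups in each test.
#' @return Family size `m`.
#' @export
bonferroni_family <- function(group_counts) {
  if (any(group_counts < 2)) stop("each test needs at least 2 groups")
  sum(group_counts * (group_counts - 1) / 2)
}

#' Group medians and percent decrease of a two-group effect
#'
#' For a metric compared between an MHC and a non-MHC group, the effect is
#' reported as the percent decrease of the MHC median relative to the
#' non-MHC median: `100 * (median_ref - median_focal) / median_ref` (a
#' negative value is a percent increase). A zero reference median yields
#' `NA` with a warning.
#'
#' @param values Numeric vector.
#' @param groups Two-level labels, parallel to `values`.
#' @param focal,reference Group labels: focal (e.g. `"MHC"`) and reference
#'   (e.g. `"nonMHC"`).
#' @return List: `median_focal`, `median_reference`, `percent_decrease`,
#'   `n_focal`, `n_reference`.
#' @export
effect_and_decrease <- function(values, groups, focal = "MHC",
                                reference = "nonMHC") {
  vf <- values[groups == focal & !is.na(values)]
  vr <- values[groups == reference & !is.na(values)]
  if (!length(vf) || !length(vr))
    stop("both groups need at least one non-NA value")
  mf <- stats::median(vf); mr <- stats::median(vr)
  pd <- if (mr == 0) {
    warning("reference median is zero; percent decrease undefined")
    NA_real_
  } else 100 * (mr - mf) / mr
  list(median_focal = mf, median_reference = mr, percent_decrease = pd,
       n_focal = length(vf), n_reference = length(vr))
}
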