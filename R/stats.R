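# Exact-permutation two-sided p for the rank-sum (Mann-Whitney) statistic,
# with mid-ranks under ties; the reference distribution is enumerated on the
# observed (possibly tied) data. Two-sided p = min(1, 2 * min(P(W <= w),
# P(W >= w))).
.exact_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); N <- length(r)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(N, n1)
  w_all <- colSums(matrix(r[splits], nrow = n1))
  eps <- 1e-9
  p_lo <- mean(w_all <= w_obs + eps)
  p_hi <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact sign-flip two-sided p for the Wilcoxon signed-rank statistic (paired),
# zeros dropped, mid-ranks of |d| under ties.
.exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  eps <- 1e-9
  p_lo <- mean(v_all <= v_obs + eps)
  p_hi <- mean(v_all >= v_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

.test_result <- function(metric, test, n1, n2, statistic, p_raw,
                         adjust = "none", m = 1) {
  structure(
    list(metric = metric, test = test, n1 = n1, n2 = n2,
         statistic = statistic, p_raw = p_raw,
         p_adjusted = min(1, m * p_raw), adjust = adjust, m = m,
         alpha = 0.05),
    class = "cineflow_test"
  )
}

#' Two-group or paired nonparametric comparison of one metric
#'
#' Unpaired: Mann-Whitney rank-sum test; paired: Wilcoxon signed-rank test on
#' within-pair differences. For groups of up to `exact_max_n` subjects the
#' two-sided p-value is computed by exact permutation (all group relabellings
#' / all sign flips) on the observed data with mid-ranks under ties; larger
#' groups fall back to the normal approximation.
#'
#' @param table cohort table (see [cohort_table()]): data.frame with columns
#'   subject_id, age_group, metric, value
#' @param metric metric name to compare
#' @param paired logical; paired tests match subjects by order within group
#'   (requires equal group sizes)
#' @param group_col column defining the two groups (default "age_group")
#' @param exact_max_n exact-permutation limit per group (default 10)
#' @return a test-result object: metric, test, n1, n2, statistic, p_raw,
#'   p_adjusted (= p_raw here; see [bonferroni()]), alpha
#' @export
compare_groups <- function(table, metric, paired = FALSE,
                           group_col = "age_group", exact_max_n = 10) {
  rows <- table[table$metric == metric, ]
  g <- factor(rows[[group_col]])
  if (nlevels(g) != 2) stop("need exactly two groups")
  x <- rows$value[g == levels(g)[1]]
  y <- rows$value[g == levels(g)[2]]
  if (paired) {
    if (length(x) != length(y)) stop("paired comparison needs equal n")
    if (length(x) < 3) stop("need at least 3 pairs")
    d <- x - y
    if (all(d == 0)) warning("all paired differences are zero (tied data)")
    if (length(d) <= 12) {
      p <- .exact_signed_rank_p(d)
    } else {
      p <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
    }
    dd <- d[d != 0]
    stat <- if (length(dd)) sum(rank(abs(dd))[dd > 0]) else 0
    .test_result(metric, "wilcoxon_paired", length(x), length(y), stat, p)
  } else {
    if (length(x) < 3 || length(y) < 3) stop("need at least 3 per group")
    if (max(length(x), length(y)) <= exact_max_n) {
      p <- .exact_rank_sum_p(x, y)
    } else {
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    }
    if (length(unique(c(x, y))) == 1) warning("all values tied")
    stat <- sum(rank(c(x, y))[seq_along(x)])  # rank sum of group 1
    .test_result(metric, "mann_whitney", length(x), length(y), stat, p)
  }
}

#' Fisher's exact test of a 2x2 association (e.g. sex by age group)
#'
#' Two-sided exact p by summation of hypergeometric probabilities no larger
#' than that of the observed table (the standard two-sided convention).
#'
#' @param counts 2x2 matrix of nonnegative integer counts
#' @return a test-result object (statistic = odds ratio estimate)
#' @export
fisher_association <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("empty margin in 2x2 table")
  ft <- stats::fisher.test(counts)
  .test_result("association", "fisher_exact",
               sum(counts[1, ]), sum(counts[2, ]),
               unname(ft$estimate), ft$p.value)
}

#' Bonferroni adjustment over a declared family
#'
#' `p_adjusted = min(1, m * p_raw)` with the family size m declared
#' explicitly. Never lowers a p-value.
#'
#' @param results list of test-result objects (from [compare_groups()] etc.)
#' @param m family size; defaults to `length(results)`
#' @return the list with `p_adjusted`, `adjust` and `m` updated
#' @export
bonferroni <- function(results, m = length(results)) {
  lapply(results, function(r) {
    r$p_adjusted <- min(1, m * r$p_raw)
    r$adjust <- "bonferroni"
    r$m <- m
    r
  })
}

#' Tidy per-subject x per-metric cohort table
#'
#' One row per subject and metric, the long-format table feeding the group
#' statistics and summary tables.
#'
#' @param haemo list of [subject_haemodynamics()] objects
#' @param features optional named list (by subject_id) of per-vessel feature
#'   data.frames (rbind of [profile_features()] rows incl. composites)
#' @return data.frame with columns subject_id, age_group, sex, metric, value
#' @export
cohort_table <- function(haemo, features = NULL) {
  rows <- list()
  add <- function(sid, grp, sex, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = sid, age_group = grp, sex = sex,
      metric = metric, value = unname(value))
  }
  for (h in haemo) {
    sid <- h$subject_id; grp <- h$age_group; sex <- h$sex
    for (v in names(h$volumes_ul))
      add(sid, grp, sex, paste0("volume_", v), h$volumes_ul[[v]])
    for (t in names(h$totals_ul))
      add(sid, grp, sex, paste0("volume_", t), h$totals_ul[[t]])
    for (fr in names(h$fractions))
      add(sid, grp, sex, paste0("fraction_", fr), h$fractions[[fr]])
    add(sid, grp, sex, "perfusion_ml_min", h$perfusion_ml_min)
    add(sid, grp, sex, "drainage_ml_min", h$drainage_ml_min)
    add(sid, grp, sex, "cbf_ml_min_100g", h$cbf_ml_min_100g)
    add(sid, grp, sex, "CF", h$CF)
    add(sid, grp, sex, "oscillating_volume_ul", h$oscillating_volume_ul)
    add(sid, grp, sex, "osc_pct_csf", h$osc_pct_csf)
    add(sid, grp, sex, "hysteresis_area", h$hysteresis_area)
    if (!is.null(features) && sid %in% names(features)) {
      ft <- features[[sid]]
      for (i in seq_len(nrow(ft))) {
        v <- ft$vessel[i]
        add(sid, grp, sex, paste0("peak_pct_", v), ft$peak_pct_cc[i])
        if (is.finite(ft$upslope_ul_s2[i]))
          add(sid, grp, sex, paste0("upslope_", v), ft$upslope_ul_s2[i])
        if (is.finite(ft$PI[i])) add(sid, grp, sex, paste0("PI_", v), ft$PI[i])
        if (is.finite(ft$RI[i])) add(sid, grp, sex, paste0("RI_", v), ft$RI[i])
      }
    }
  }
  do.call(rbind, rows)
}

#' Group summary (mean +/- SD) of a cohort table
#'
#' @param table a [cohort_table()] data.frame
#' @return data.frame: metric, age_group, n, mean, sd (sd is NA with a
#'   degenerate-n flag when n = 1)
#' @export
summarize_cohort <- function(table) {
  stopifnot(nrow(table) > 0)
  agg <- split(table, list(table$metric, table$age_group), drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(d) {
    data.frame(metric = d$metric[1], age_group = d$age_group[1],
               n = nrow(d), mean = mean(d$value),
               sd = if (nrow(d) > 1) stats::sd(d$value) else NA_real_,
               degenerate_n = nrow(d) == 1)
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$age_group), ]
}
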