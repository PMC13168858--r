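#' Label deteriorated asthenopia from CVS-Q change
#'
#' A session is labelled deteriorated when the post-task CVS-Q score
#' increased by at least 3 points over baseline (threshold inclusive).
#'
#' @param cvsq_pre,cvsq_post non-negative questionnaire scores (vectorised).
#' @return character vector, `"deteriorated"` or `"nondeteriorated"`.
#' @examples
#' label_deterioration(6, 9)  # deteriorated
#' label_deterioration(6, 8)  # nondeteriorated
#' @export
label_deterioration <- function(cvsq_pre, cvsq_post) {
  if (any(cvsq_pre < 0) || any(cvsq_post < 0))
    stop("CVS-Q scores must be non-negative")
  ifelse(cvsq_post - cvsq_pre >= 3, "deteriorated", "nondeteriorated")
}

#' Flag baseline asthenopia
#'
#' Baseline asthenopia is defined as a CVS-Q score of at least 6.
#'
#' @param cvsq non-negative score(s).
#' @return logical.
#' @export
flag_baseline_asthenopia <- function(cvsq) {
  if (any(cvsq < 0)) stop("CVS-Q scores must be non-negative")
  cvsq >= 6
}

result_row <- function(feature, test, statistic, p, summaries = NULL) {
  structure(list(feature_name = feature, test = test, statistic = statistic,
                 p_value = p, group_summaries = summaries),
            class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
  cat(sprintf("<%s> %s: stat=%.4g, p=%.4g\n", x$test, x$feature_name,
              x$statistic, x$p_value))
  invisible(x)
}

#' Paired pre/post change test
#'
#' Shapiro-Wilk on the paired differences gates the test choice: paired t
#' when normality is not rejected (P >= .05), Wilcoxon signed-rank
#' otherwise. Two-tailed. All-zero differences return a degenerate sentinel
#' (`test = "degenerate"`, `p_value = NA`).
#'
#' @param pre_values,post_values equal-length paired samples, n >= 3.
#' @param feature feature name carried into the result.
#' @return a `group_comparison_result`.
#' @export
paired_change_test <- function(pre_values, post_values, feature = "feature") {
  stopifnot(length(pre_values) == length(post_values),
            length(pre_values) >= 3)
  d <- post_values - pre_values
  if (all(d == 0))
    return(result_row(feature, "degenerate", NA_real_, NA_real_))
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= 0.05) {
    tt <- stats::t.test(post_values, pre_values, paired = TRUE)
    result_row(feature, "paired_t", unname(tt$statistic), tt$p.value,
               summaries = list(mean_diff = mean(d),
                                ci95 = unname(tt$conf.int),
                                shapiro_p = sw$p.value))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(post_values, pre_values,
                                              paired = TRUE))
    result_row(feature, "wilcoxon_signed_rank", unname(wt$statistic),
               wt$p.value,
               summaries = list(median_diff = stats::median(d),
                                iqr = unname(stats::quantile(d, c(.25, .75))),
                                shapiro_p = sw$p.value))
  }
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-tailed Mann-Whitney U test. Exact enumeration of the U distribution
#' is used when both groups have at most `exact_max_n` observations and no
#' ties are present; otherwise the normal approximation with tie correction
#' and continuity correction. Group medians with IQR are attached.
#'
#' @param feature_values numeric vector.
#' @param labels two-level grouping vector of the same length.
#' @param feature feature name for the result.
#' @param exact_max_n exact-enumeration size limit per group.
#' @return a `group_comparison_result` with statistic U (first group).
#' @export
compare_groups <- function(feature_values, labels, feature = "feature",
                           exact_max_n = 20) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  x <- feature_values[labels == levels(labels)[1]]
  y <- feature_values[labels == levels(labels)[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && max(n1, n2) <= exact_max_n) {
    u <- round(u1)
    p_low <- stats::pwilcox(u, n1, n2)
    p_high <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "mann_whitney_u_exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "mann_whitney_u"
  }
  summ <- lapply(list(x, y), function(v)
    c(median = stats::median(v), q1 = unname(stats::quantile(v, .25)),
      q3 = unname(stats::quantile(v, .75)), n = length(v)))
  names(summ) <- levels(labels)
  result_row(feature, method, u1, p, summaries = summ)
}

#' McNemar's test for paired binary flags
#'
#' Continuity-corrected McNemar statistic `(|b - c| - 1)^2 / (b + c)` on the
#' discordant pair counts, with a two-tailed chi-squared P value, the net
#' change, and a Wald 95% CI for the paired proportion difference. With no
#' discordant pairs a degenerate sentinel is returned.
#'
#' @param pre_flags,post_flags equal-length logical vectors.
#' @param feature feature name.
#' @return a `group_comparison_result`.
#' @export
mcnemar_paired <- function(pre_flags, post_flags, feature = "feature") {
  stopifnot(length(pre_flags) == length(post_flags))
  b <- sum(!pre_flags & post_flags)   # gained the flag
  c_ <- sum(pre_flags & !post_flags)  # lost the flag
  n <- length(pre_flags)
  if (b + c_ == 0)
    return(result_row(feature, "degenerate", NA_real_, NA_real_))
  stat <- (abs(b - c_) - 1)^2 / (b + c_)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  d <- (b - c_) / n
  se <- sqrt(b + c_ - (b - c_)^2 / n) / n
  result_row(feature, "mcnemar", stat, p,
             summaries = list(discordant = c(b = b, c = c_),
                              net_change = d,
                              ci95 = d + c(-1, 1) * 1.96 * se))
}

#' Select classifier input features by significance
#'
#' Keeps features with P below `alpha`, ordered by ascending P. When
#' `append_cff = TRUE` the CFF feature is appended regardless of its own
#' significance, reflecting its established role as a fatigue index. This
#' filtering is performed once on the full dataset (not per CV fold); set
#' `warn_leakage = TRUE` to emit the documented selection-bias warning.
#'
#' @param results list of `group_comparison_result`s.
#' @param alpha significance threshold.
#' @param append_cff append `"cff"` unconditionally.
#' @param warn_leakage warn that full-dataset filtering can bias downstream
#'   performance estimates.
#' @return character vector of feature names (may be empty).
#' @export
select_features <- function(results, alpha = 0.05, append_cff = FALSE,
                            warn_leakage = FALSE) {
  stopifnot(length(results) >= 1)
  p <- vapply(results, function(r) r$p_value, numeric(1))
  nm <- vapply(results, function(r) r$feature_name, character(1))
  keep <- !is.na(p) & p < alpha
  sel <- nm[keep][order(p[keep])]
  if (append_cff && !("cff" %in% sel)) sel <- c(sel, "cff")
  if (warn_leakage)
    warning("feature filtering used the full dataset; downstream CV ",
            "estimates may be optimistic (selection bias)")
  sel
}

#' Group comparison table for a feature data frame
#'
#' Runs [compare_groups()] for every feature column against a label column
#' and returns a tidy table (feature, test, statistic, P value, per-group
#' median and IQR).
#'
#' @param features data frame of difference features plus a label column.
#' @param label_col name of the two-level label column.
#' @param feature_cols columns to test; defaults to all numeric columns
#'   except identifiers and the label.
#' @return list with `table` (data frame) and `results` (list of
#'   `group_comparison_result`).
#' @export
compare_feature_table <- function(features, label_col = "label",
                                  feature_cols = NULL) {
  if (is.null(feature_cols)) {
    drop <- c("participant_id", "eye", "truth_group", "cvsq_pre",
              "cvsq_post", label_col)
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))], drop)
  }
  labels <- features[[label_col]]
  results <- lapply(feature_cols, function(f) {
    v <- features[[f]]
    if (sum(!is.na(v)) < 2 || length(unique(stats::na.omit(v))) < 2)
      return(result_row(f, "degenerate", NA_real_, NA_real_))
    compare_groups(v, labels, feature = f)
  })
  tab <- do.call(rbind, lapply(results, function(r) {
    gs <- r$group_summaries
    fmt <- function(s) if (is.null(s)) NA_character_ else
      sprintf("%.2f (%.2f to %.2f)", s[["median"]], s[["q1"]], s[["q3"]])
    data.frame(feature = r$feature_name, test = r$test,
               statistic = r$statistic, p_value = r$p_value,
               group1 = fmt(gs[[1]]), group2 = fmt(gs[[2]]))
  }))
  list(table = tab, results = results)
}
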