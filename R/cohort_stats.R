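# Paired-cohort statistics for before/after treatment designs: percent
# change, Wilcoxon signed-rank and Friedman tests (via stats::), Bonferroni
# correction and Bland-Altman method agreement.

#' Percent change between two means
#'
#' `(post - pre) / pre * 100`, returned both raw and rounded at a stated
#' precision (report tables round at the precision of the quantity).
#'
#' @param pre,post baseline and follow-up means; `pre` must be nonzero.
#' @param digits decimal places for the rounded value (default 2).
#' @return list with `percent` (raw) and `rounded`.
#' @export
percent_change <- function(pre, post, digits = 2) {
  if (!is.finite(pre) || !is.finite(post))
    stop("pre and post must be finite")
  if (pre == 0) stop("percent change is undefined at a zero baseline")
  pc <- (post - pre) / pre * 100
  list(percent = pc, rounded = round(pc, digits))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on `post - pre`. Zero differences are dropped (Wilcoxon's
#' original convention); tied absolute differences get average ranks. The
#' exact null distribution is used when the effective n is below 13 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. A cohort with no nonzero differences returns
#' p = 1 with a warning.
#'
#' @param pre,post paired numeric vectors of equal length.
#' @return list with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n_effective`, `zeros_dropped`, `exact` and `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have the same length")
  if (length(pre) < 1) stop("need at least one pair")
  d <- post - pre
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n_effective = 0L,
                zeros_dropped = zeros, exact = TRUE,
                method = "degenerate (all differences zero)"))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n_eff < 13 && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_effective = n_eff, zeros_dropped = zeros, exact = exact,
       method = wt$method)
}

#' Friedman rank test for k matched samples
#'
#' Within-subject rank test with average-rank tie handling and the
#' tie-corrected statistic, referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param columns an n x k numeric matrix or data frame (subjects in rows,
#'   methods/timepoints in columns); no missing cells.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
friedman_test <- function(columns) {
  m <- as.matrix(columns)
  if (ncol(m) < 2 || nrow(m) < 2)
    stop("need at least 2 matched samples of at least 2 subjects")
  if (any(!is.finite(m)))
    stop("missing or non-finite cells are not allowed in a matched design")
  # every subject fully tied across all k samples carries no rank
  # information: the tie-corrected statistic is 0/0 there, by convention 0
  ranks <- t(apply(m, 1, rank))
  if (all(apply(ranks, 1, function(r) max(r) == min(r))))
    return(list(statistic = 0, p.value = 1, df = ncol(m) - 1))
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), p.value = ft$p.value,
       df = unname(ft$parameter))
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p_values)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, p_values * m)
}

#' Bland-Altman agreement between two methods
#'
#' Per-subject differences `a - b` (first method minus second, with method
#' names recorded); bias is their mean, limits of agreement are
#' bias +/- 1.96 x SD (sample SD, n - 1 denominator).
#'
#' @param method_a,method_b matched numeric vectors (length >= 2).
#' @param names length-2 character, names of the two methods.
#' @return an `agreement_report` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high` and the per-subject `(mean, diff)` pairs.
#' @export
bland_altman <- function(method_a, method_b,
                         names = c("method_a", "method_b")) {
  if (length(method_a) != length(method_b))
    stop("method vectors must have the same length (",
         length(method_a), " vs ", length(method_b), ")")
  if (length(method_a) < 2) stop("need at least 2 paired measurements")
  d <- method_a - method_b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(methods = names, bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 pairs = data.frame(mean = (method_a + method_b) / 2,
                                    diff = d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s - %s): bias %.4f, LoA [%.4f, %.4f]\n",
              x$methods[1], x$methods[2], x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
as_result_record.agreement_report <- function(x) {
  list(schema_version = SCHEMA_VERSION, record_type = "agreement_report",
       method_a = x$methods[1], method_b = x$methods[2],
       bias = x$bias, sd_diff = x$sd_diff,
       loa_low = x$loa_low, loa_high = x$loa_high)
}

#' Read a paired-cohort table from CSV
#'
#' One row per subject-timepoint: columns `subject_id`,
#' `timepoint` (`"pre"`/`"post"`), then numeric outcome columns.
#'
#' @param path CSV file.
#' @return a data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "timepoint") %in% names(df)))
    stop("cohort CSV needs columns subject_id and timepoint")
  if (!all(df$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  df
}

#' Descriptive summary of a paired cohort
#'
#' Per outcome column: mean, SD (n - 1), median, min and max at each
#' timepoint, plus the post - pre delta of means. SD is reported as `NA`
#' for a single subject.
#'
#' @param cohort data frame as returned by [read_cohort()].
#' @return data frame, one row per outcome variable.
#' @export
cohort_table <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  vars <- setdiff(names(cohort), c("subject_id", "timepoint"))
  vars <- vars[vapply(cohort[vars], is.numeric, logical(1))]
  one <- function(v, tp) {
    x <- cohort[[v]][cohort$timepoint == tp]
    x <- x[is.finite(x)]
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      median = stats::median(x), min = min(x), max = max(x))
  }
  rows <- lapply(vars, function(v) {
    pre <- one(v, "pre"); post <- one(v, "post")
    data.frame(variable = v,
               mean_pre = pre["mean"], sd_pre = pre["sd"],
               median_pre = pre["median"], min_pre = pre["min"],
               max_pre = pre["max"],
               mean_post = post["mean"], sd_post = post["sd"],
               median_post = post["median"], min_post = post["min"],
               max_post = post["max"],
               delta_mean = post["mean"] - pre["mean"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
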