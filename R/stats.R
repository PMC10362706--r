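#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measure
#'
#' Computes ICC(2,1) from the two-way ANOVA mean squares of a subjects x
#' raters table: `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with
#' MSR the between-subject, MSC the between-rater and MSE the residual mean
#' square. The confidence interval is the Shrout-Fleiss F-based interval.
#' Mean squares are taken from [stats::aov()].
#'
#' @param table numeric matrix, rows = subjects (n >= 2), columns = raters or
#'   occasions (k >= 2), no missing cells.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `n`, `k` and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
icc_2way_random_single <- function(table, conf = 0.95) {
  x <- as.matrix(table)
  if (any(!is.finite(x))) stop("rater table has missing cells")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  df <- data.frame(value = as.vector(x),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(value ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (msr <= mse && var(rowMeans(x)) < 1e-12 * (mean(x)^2 + 1))
    stop("zero between-subject variance: ICC undefined")
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse <= 0 && msc <= 0) {
    # perfect agreement: degenerate interval
    return(list(icc = 1, ci_low = 1, ci_high = 1, n = n, k = k,
                msr = msr, msc = msc, mse = mse))
  }
  alpha <- 1 - conf
  # Shrout & Fleiss F-based interval for ICC(2,1)
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2 /
    ((n - 1) * k^2 * icc^2 * fj^2 +
     (n * (1 + (k - 1) * icc) - k * icc)^2)
  fl <- qf(1 - alpha / 2, n - 1, vn)
  fu <- qf(1 - alpha / 2, vn, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

#' Pilot-study sample size for observing an event at least once
#'
#' `n = ln(1 - confidence) / ln(1 - pi)`: the number of subjects needed so
#' that an event of per-subject probability `pi` is seen at least once with
#' the given confidence. Returned unrounded together with the one-decimal
#' rounding (the conventional way the figure is reported) and the integer
#' ceiling.
#'
#' @param confidence required probability of observing the event at least
#'   once, in (0, 1).
#' @param pi per-subject event probability, in (0, 1).
#' @return list with `n` (unrounded), `n_1dp` (one decimal) and `n_ceiling`.
#' @export
pilot_sample_size <- function(confidence, pi) {
  if (!(confidence > 0 && confidence < 1))
    stop("confidence must be in (0, 1)")
  if (!(pi > 0 && pi < 1)) stop("pi must be in (0, 1)")
  n <- log(1 - confidence) / log(1 - pi)
  list(n = n, n_1dp = round(n, 1), n_ceiling = ceiling(n))
}

#' Paired side comparison of deviation metrics and STVC
#'
#' Assembles the per-period paired comparison between the two sides of the
#' face (e.g. extraction vs non-extraction): for every metric and period, the
#' paired differences (side a minus side b), a Shapiro-Wilk normality check,
#' and the paired t-test, or the Wilcoxon signed-rank test where normality
#' is rejected at `alpha`.
#'
#' @param data data.frame with columns `subject`, `side` (two levels),
#'   `period`, `metric`, `value`; every (subject, period, metric) must be
#'   present for both sides.
#' @param alpha normality rejection level routing to Wilcoxon (default 0.05).
#' @return data.frame, one row per metric x period: mean and SD of the paired
#'   differences, Shapiro-Wilk p, test used, statistic, p value and n.
#' @export
summarize_sides <- function(data, alpha = 0.05) {
  need <- c("subject", "side", "period", "metric", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  sides <- sort(unique(as.character(data$side)))
  if (length(sides) != 2L) stop("exactly two side levels are required")
  out <- list()
  for (m in unique(data$metric)) {
    for (p in unique(data$period[data$metric == m])) {
      d <- data[data$metric == m & data$period == p, ]
      a <- d[d$side == sides[1], ]
      b <- d[d$side == sides[2], ]
      a <- a[order(a$subject), ]
      b <- b[order(b$subject), ]
      if (nrow(a) != nrow(b) || !identical(as.character(a$subject),
                                           as.character(b$subject)))
        stop("unpaired records for metric ", m, ", period ", p)
      if (nrow(a) < 2L)
        stop("need at least 2 paired subjects (got ", nrow(a), ")")
      diffs <- a$value - b$value
      sw <- if (length(diffs) >= 3L && sd(diffs) > 0)
        shapiro.test(diffs)$p.value else NA_real_
      use_wilcox <- is.finite(sw) && sw < alpha
      tst <- if (use_wilcox)
        suppressWarnings(wilcox.test(a$value, b$value, paired = TRUE))
      else t.test(a$value, b$value, paired = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        metric = m, period = p, n = nrow(a),
        mean_diff = mean(diffs), sd_diff = sd(diffs),
        shapiro_p = sw,
        test = if (use_wilcox) "wilcoxon" else "paired-t",
        statistic = unname(tst$statistic), p_value = tst$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
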