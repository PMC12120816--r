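#' Normality-gated two-group comparison
#'
#' Both samples are tested for normality with the Shapiro-Wilk test; if both
#' pass at \code{alpha}, a two-sided two-sample Student's t-test is used,
#' otherwise a Mann-Whitney U (Wilcoxon rank-sum) test. Everything is
#' reported: per-group n/mean/SEM, the normality p-values, the gate
#' decision, the statistic and the p-value.
#'
#' @param a,b numeric samples, each with at least 3 values (the Shapiro-Wilk
#'   test is undefined below that).
#' @param alpha gate level for the normality test (default 0.05).
#' @param labels length-2 character vector of group labels.
#' @return object of class \code{group_comparison}.
#' @export
compare_groups <- function(a, b, alpha = 0.05, labels = c("A", "B")) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 non-missing values")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  # shapiro.test errors on zero-range samples; treat those as non-normal
  sw_p <- function(x) {
    if (diff(range(x)) == 0) return(0)
    stats::shapiro.test(x)$p.value
  }
  pa <- sw_p(a); pb <- sw_p(b)
  normal <- pa > alpha && pb > alpha
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t_test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    test <- "mann_whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(labels = labels,
                 n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)),
                 sem = c(sem(a), sem(b)),
                 shapiro_p = c(pa, pb),
                 chosen_test = test, statistic = statistic, p_value = p,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d, %.4g +/- %.3g) vs %s (n=%d, %.4g +/- %.3g)\n",
              x$labels[1], x$n[1], x$mean[1], x$sem[1],
              x$labels[2], x$n[2], x$mean[2], x$sem[2]))
  cat(sprintf("  Shapiro-Wilk p = %.3g / %.3g -> %s: statistic %.4g, p = %.4g\n",
              x$shapiro_p[1], x$shapiro_p[2], x$chosen_test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Flag potential outliers by median absolute deviation
#'
#' Optional convenience rule, off by default in the pipeline. This is a
#' plain |x - median| > k * MAD flag; it is NOT the ROUT procedure (robust
#' regression with a false-discovery threshold), which is intentionally not
#' implemented here.
#'
#' @param x numeric vector.
#' @param k MAD multiplier (default 3).
#' @return logical vector, TRUE where flagged.
#' @export
mad_outlier_flags <- function(x, k = 3) {
  m <- stats::mad(x, constant = 1.4826)
  if (m == 0) return(rep(FALSE, length(x)))
  abs(x - stats::median(x)) > k * m
}
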