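#' Exclude outliers beyond mean +/- 3 SD
#'
#' The mean and SD are computed once on the full input; values outside
#' `mean +/- 3 * sd` are removed.
#'
#' @param values numeric vector (length >= 3).
#' @param n_sd multiple of the standard deviation (default 3).
#' @return List: `retained` values, `excluded` values, `index` of retained
#'   positions, `log` data frame of removals.
#' @export
exclude_outliers <- function(values, n_sd = 3) {
  stopifnot(length(values) >= 3)
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  out <- !is.na(values) & (values < m - n_sd * s | values > m + n_sd * s)
  list(retained = values[!out], excluded = values[out],
       index = which(!out),
       log = data.frame(index = which(out), value = values[out],
                        bound_low = rep(m - n_sd * s, sum(out)),
                        bound_high = rep(m + n_sd * s, sum(out))))
}

new_test_result <- function(statistic, df, p, effect, effect_name,
                            method, n) {
  structure(list(statistic = statistic, df = df, p = p,
                 effect_size = effect, effect_name = effect_name,
                 method = method, n = n),
            class = "theta_test")
}

#' @export
print.theta_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g, %s = %.4g\n",
              x$method, x$statistic, x$df, x$p, x$effect_name,
              x$effect_size))
  invisible(x)
}

#' Paired t-test with d_z effect size
#'
#' t on the within-subject differences (`post - pre`), df = n - 1, and
#' `d_z = mean(diff) / sd(diff) = t / sqrt(n)`.
#'
#' @param x_pre,x_post paired numeric vectors of equal length (n >= 2).
#' @return A `theta_test` result.
#' @export
paired_t <- function(x_pre, x_post) {
  stopifnot(length(x_pre) == length(x_post), length(x_pre) >= 2)
  d <- x_post - x_pre
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (sd_d / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), n - 1)
  new_test_result(t, n - 1, p, t / sqrt(n), "d_z", "paired t", n)
}

#' Independent-samples t-test with standardized effect size
#'
#' Welch by default (the convention for group comparisons; fractional df);
#' `welch = FALSE` gives the pooled-variance test. The effect size is the
#' standardized mean difference using the pooled SD.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param welch use the Welch-Satterthwaite correction (default `TRUE`).
#' @return A `theta_test` result.
#' @export
independent_t <- function(a, b, welch = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      t <- if (md == 0) 0 else sign(md) * Inf
      df <- na + nb - 2
    } else {
      t <- md / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    method <- "Welch t"
  } else {
    se2 <- sp2 * (1 / na + 1 / nb)
    t <- if (se2 == 0) {
      if (md == 0) 0 else sign(md) * Inf
    } else md / sqrt(se2)
    df <- na + nb - 2
    method <- "pooled t"
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  d <- if (sp2 > 0) md / sqrt(sp2) else if (md == 0) 0 else sign(md) * Inf
  new_test_result(t, df, p, d, "d", method, c(na, nb))
}

#' Group x time interaction in a 2 (between) x 2 (within) design
#'
#' Mixed-design interaction F with df (1, nA + nB - 2) and generalized eta
#' squared. The F statistic equals the square of the pooled-variance
#' independent t on the per-subject difference scores (post - pre).
#'
#' @param group_labels factor-like vector, one entry per subject (two
#'   levels).
#' @param pre,post numeric vectors, one entry per subject.
#' @return A `theta_test` with `statistic` = F, `df` = error df, and
#'   `effect_size` = generalized eta squared.
#' @export
mixed_2x2_interaction <- function(group_labels, pre, post) {
  g <- as.factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  stopifnot(length(pre) == length(post), length(pre) == length(g))
  n <- length(pre)
  gi <- as.integer(g)
  d <- post - pre                          # per-subject difference scores
  m <- (post + pre) / 2                    # per-subject means
  n1 <- sum(gi == 1L); n2 <- sum(gi == 2L)
  d_bar <- tapply(d, gi, mean)
  m_bar <- tapply(m, gi, mean)
  # two time points: interaction and time-error SS live on d / 2,
  # subject-error SS on the subject means x 2
  ss_int <- unname((d_bar[1] - d_bar[2])^2 / (2 * (1 / n1 + 1 / n2)))
  ss_err_within <- sum((d - d_bar[gi])^2) / 2
  ss_subj <- 2 * sum((m - m_bar[gi])^2)
  df_err <- n - 2
  f <- ss_int / (ss_err_within / df_err)
  eta_g <- ss_int / (ss_int + ss_subj + ss_err_within)
  p <- stats::pf(f, 1, df_err, lower.tail = FALSE)
  res <- new_test_result(f, df_err, p, eta_g, "eta_G",
                         "group x time interaction F", n)
  res$df1 <- 1
  res
}

#' Correlation with t statistic
#'
#' Pearson or Spearman correlation, with `t = r * sqrt(df) / sqrt(1 -
#' r^2)`, `df = n - 2`, and a two-sided p. Spearman is Pearson on
#' midranks.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `t`, `df`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, t = NA_real_, df = n - 2, p = NA_real_,
                n = n, method = method, degenerate = TRUE))
  r <- stats::cor(x, y, method = method)
  df <- n - 2
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, t = t, df = df, p = p, n = n, method = method,
       degenerate = FALSE)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided p
#' from the standard normal.
#'
#' @param r1,r2 correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @param method label recorded in the result.
#' @return An object of class `corr_comparison`.
#' @export
compare_correlations <- function(r1, n1, r2, n2, method = "pearson") {
  if (n1 <= 3 || n2 <= 3) stop("both sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z = z, p = p,
                 method = method),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("correlation comparison (%s): r1 = %.3f (n = %d) vs r2 = %.3f (n = %d), z = %.3f, p = %.4g\n",
              x$method, x$r1, x$n1, x$r2, x$n2, x$z, x$p))
  invisible(x)
}
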