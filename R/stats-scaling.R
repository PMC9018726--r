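#' Fit a channel-length/area power law
#'
#' Fits sum(L) = a * Area^b by ordinary least squares on natural logs,
#' log y = log a + b log x. The regression F statistic is
#' (SSR/1) / (SSE/(n-2)) with df (1, n-2), satisfying
#' F = r^2 (n-2) / (1 - r^2).
#'
#' @param areas watershed areas in m^2 (> 0).
#' @param lengths total channel lengths in m (> 0).
#' @return object of class `power_law_fit`: a, b, n, F, df1, df2, r2,
#'   residual_log_sd, b_se, b_ci (95%).
#' @export
fit_power_law <- function(areas, lengths) {
  if (length(areas) != length(lengths))
    stop("areas and lengths must have equal length")
  bad <- which(!(areas > 0) | !(lengths > 0))
  if (length(bad)) stop("non-positive input at indices: ",
                        paste(bad, collapse = ", "))
  n <- length(areas)
  if (n < 3) stop("need at least 3 points")
  fit <- lm(log(lengths) ~ log(areas))
  sse <- sum(residuals(fit)^2)
  sst <- sum((log(lengths) - mean(log(lengths)))^2)
  ssr <- sst - sse
  df2 <- n - 2L
  Fstat <- (ssr / 1) / (sse / df2)
  b <- unname(coef(fit)[2])
  lx <- log(areas)
  b_se <- sqrt((sse / df2) / sum((lx - mean(lx))^2))
  structure(list(a = exp(unname(coef(fit)[1])), b = b, n = n,
                 F = Fstat, df1 = 1L, df2 = df2,
                 r2 = if (sst > 0) ssr / sst else NA_real_,
                 residual_log_sd = sqrt(sse / df2),
                 b_se = b_se,
                 b_ci = b + c(-1, 1) * qt(0.975, df2) * b_se,
                 p_value = pf(Fstat, 1, df2, lower.tail = FALSE)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit sum(L) = %.4g * Area^%.4f, n = %d, F = %.4g on 1 and %d DF, r^2 = %.4f>\n",
    x$a, x$b, x$n, x$F, x$df2, x$r2))
  invisible(x)
}

#' Compare power laws between two wetland types
#'
#' Nested-model F test on the log-log regression: the pooled single
#' line is compared against the full model with group-specific
#' intercept and slope (joint test, df = (2, n - 4)). A significant F
#' means the scaling relationships of the two groups differ.
#'
#' @param areas,lengths as in [fit_power_law()].
#' @param groups factor-like vector with exactly 2 levels.
#' @return list: F, df1, df2, p_value, rss_pooled, rss_full, and the
#'   per-group `power_law_fit`s.
#' @export
compare_power_laws <- function(areas, lengths, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 3)) stop("each group needs at least 3 points")
  bad <- which(!(areas > 0) | !(lengths > 0))
  if (length(bad)) stop("non-positive input at indices: ",
                        paste(bad, collapse = ", "))
  n <- length(areas)
  lx <- log(areas); ly <- log(lengths)
  pooled <- lm(ly ~ lx)
  full <- lm(ly ~ lx * g)
  rss0 <- sum(residuals(pooled)^2)
  rss1 <- sum(residuals(full)^2)
  df1 <- 2L; df2 <- n - 4L
  # a numerically zero RSS reduction (e.g. both groups on one noiseless
  # law) is an exact zero, not round-off ratio noise
  tol <- 1e-10 * max(rss0, sum(ly^2) * .Machine$double.eps, 1e-300)
  Fstat <- if (rss0 - rss1 <= tol) 0
           else if (rss1 > 0) ((rss0 - rss1) / df1) / (rss1 / df2)
           else Inf
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  fits <- lapply(split(seq_len(n), g), function(i)
    fit_power_law(areas[i], lengths[i]))
  list(F = Fstat, df1 = df1, df2 = df2, p_value = p,
       rss_pooled = rss0, rss_full = rss1, group_fits = fits)
}

#' Two-sided two-sample Wilcoxon rank-sum test
#'
#' Reports the rank-sum statistic W of `x`. For n1 + n2 <= 20 with no
#' ties the two-sided p value is exact, by enumeration of all
#' choose(n1+n2, n1) rank assignments
#' (p = 2 * min(P(W <= w), P(W >= w)), capped at 1); otherwise the
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y numeric samples.
#' @return list: test_name, statistic (rank sum of x), p_value, n1, n2,
#'   exact_flag.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (N <= 20 && !has_ties) {
    sums <- colSums(combn(N, n1))            # all possible rank sums of x
    p <- 2 * min(mean(sums <= W), mean(sums >= W))
    p <- min(p, 1)
    exact <- TRUE
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(W - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(2 * pnorm(z, lower.tail = FALSE), 1)
    }
    exact <- FALSE
  }
  list(test_name = "wilcoxon_rank_sum", statistic = W, p_value = p,
       n1 = n1, n2 = n2, exact_flag = exact)
}

#' Shapiro-Wilk normality test
#'
#' Gate used before reporting Wilcoxon comparisons; thin wrapper around
#' the standard algorithm. A constant vector is rejected with an error
#' (the statistic is undefined).
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list: test_name, statistic (W), p_value, n.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("sample size out of range [3, 5000]")
  if (length(unique(x)) == 1L)
    stop("constant vector: Shapiro-Wilk statistic undefined")
  sw <- shapiro.test(x)
  list(test_name = "shapiro_wilk", statistic = unname(sw$statistic),
       p_value = sw$p.value, n = n)
}
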