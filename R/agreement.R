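#' @importFrom stats cor.test lm coef ks.test pchisq pnorm qt sd var
NULL

assert_paired <- function(g, p, min_n = 1L) {
  if (length(g) != length(p)) rlang::abort("Series must have equal length.")
  if (anyNA(g) || anyNA(p)) rlang::abort("Series must not contain NA.")
  if (length(g) < min_n) {
    rlang::abort(sprintf("Need at least %d pairs, got %d.", min_n, length(g)))
  }
  invisible(NULL)
}

#' Rank correlations between two measurement series
#'
#' Spearman's rho (average ranks under ties) and Kendall's tau-b, with
#' two-sided p-values from the large-sample approximations. Rank
#' correlations are the right association measure here because pupil
#' diameter distributions over a recording are typically non-normal
#' (multimodal baseline/dilated mixtures), which the normality screen
#' confirms before these are reported.
#'
#' @param g,p Numeric series of equal length, n >= 3, neither constant.
#' @return A tibble with `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p`, `n`.
#' @export
rank_correlations <- function(g, p) {
  assert_paired(g, p, min_n = 3L)
  if (var(g) == 0 || var(p) == 0) {
    rlang::abort("Rank correlation undefined for a constant series.")
  }
  sp <- suppressWarnings(cor.test(g, p, method = "spearman", exact = FALSE))
  kd <- suppressWarnings(cor.test(g, p, method = "kendall", exact = FALSE))
  tibble::tibble(
    spearman_rho = unname(sp$estimate),
    spearman_p = sp$p.value,
    kendall_tau = unname(kd$estimate),
    kendall_p = kd$p.value,
    n = length(g)
  )
}

#' Regression of predicted on ground-truth diameters
#'
#' Ordinary least squares of `p` on `g` (prediction on the y axis, manual
#' ground truth on the x axis), with the coefficient of determination and
#' Pearson correlation.
#'
#' @param g,p Numeric series of equal length, n >= 3; `g` non-constant.
#' @return A tibble with `slope`, `intercept`, `r_squared`, `pearson_r`, `n`.
#' @export
fit_agreement_regression <- function(g, p) {
  assert_paired(g, p, min_n = 3L)
  if (var(g) == 0) rlang::abort("Regression undefined: zero variance in `g`.")
  fit <- lm(p ~ g)
  # a perfect fit (identical methods) is a legitimate input here, so the
  # "essentially perfect fit" warning from summary.lm is just noise
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    pearson_r = unname(stats::cor(g, p, method = "pearson")),
    n = length(g)
  )
}

#' Bland-Altman agreement between two measurement series
#'
#' Differences are relative: each pair contributes
#' \eqn{d_t = 100 (G_t - P_t) / ((G_t + P_t)/2)} percent of the pair mean,
#' the standard Bland-Altman variant when bias and limits are reported in
#' percent. The bias is `mean(d)`, the 95\% limits of agreement are
#' `bias +/- 1.96 sd(d)`, the CI of the bias uses
#' \eqn{t_{0.975, n-1} \cdot sd/\sqrt{n}} and the CI of each limit
#' \eqn{t_{0.975, n-1} \cdot sd \sqrt{3/n}}.
#'
#' @param g,p Numeric series of equal length, n >= 3; every pair mean must
#'   be strictly positive.
#' @return A tibble with `relative_bias_pct`, `sd_pct`, `loa_lower_pct`,
#'   `loa_upper_pct`, the three 95\% CIs (`ci_bias_lo/hi`, `ci_loa_lower_lo/hi`,
#'   `ci_loa_upper_lo/hi`), `n`, and the sign/denominator conventions as
#'   attributes `difference` (`"G - P"`) and `denominator` (`"pair mean"`).
#' @export
bland_altman <- function(g, p) {
  assert_paired(g, p, min_n = 3L)
  pm <- (g + p) / 2
  if (any(pm <= 0)) {
    rlang::abort("Bland-Altman relative differences need positive pair means.")
  }
  d <- 100 * (g - p) / pm
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, df = n - 1)
  out <- tibble::tibble(
    relative_bias_pct = bias,
    sd_pct = s,
    loa_lower_pct = bias - 1.96 * s,
    loa_upper_pct = bias + 1.96 * s,
    ci_bias_lo = bias - tq * s / sqrt(n),
    ci_bias_hi = bias + tq * s / sqrt(n),
    ci_loa_lower_lo = bias - 1.96 * s - tq * s * sqrt(3 / n),
    ci_loa_lower_hi = bias - 1.96 * s + tq * s * sqrt(3 / n),
    ci_loa_upper_lo = bias + 1.96 * s - tq * s * sqrt(3 / n),
    ci_loa_upper_hi = bias + 1.96 * s + tq * s * sqrt(3 / n),
    n = n
  )
  attr(out, "difference") <- "G - P"
  attr(out, "denominator") <- "pair mean"
  out
}

# D'Agostino skewness z (1970) and Anscombe-Glynn kurtosis z (1983);
# standard published small-sample corrections, combined into the
# D'Agostino-Pearson K^2 omnibus statistic.
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20L) {
    rlang::abort(sprintf(
      "D'Agostino-Pearson omnibus test needs n >= 20, got %d.", n))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) rlang::abort("Normality test undefined for a constant vector.")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness z
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Normality screen for measurement distributions
#'
#' Runs the D'Agostino-Pearson omnibus test (skewness and kurtosis z-scores
#' combined into a chi-squared K2 statistic) and a one-sample
#' Kolmogorov-Smirnov test against a normal with the sample's mean and
#' standard deviation. When either test rejects at `alpha`, downstream
#' association is reported with rank correlations rather than Pearson only.
#'
#' @param x Numeric vector, n >= 20 (required by the K2 small-sample
#'   corrections), non-constant.
#' @param alpha Significance level for the pass flags (default 0.05).
#' @return A tibble with `dagostino_k2`, `dagostino_p`, `ks_stat`, `ks_p`,
#'   `dagostino_pass`, `ks_pass`, `normal` (both passed), `n`.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  if (anyNA(x)) rlang::abort("`x` must not contain NA.")
  if (length(x) >= 1L && sd(x) == 0) {
    rlang::abort("Normality test undefined for a constant vector.")
  }
  dp <- dagostino_pearson(x)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  tibble::tibble(
    dagostino_k2 = dp$statistic,
    dagostino_p = dp$p_value,
    ks_stat = unname(ks$statistic),
    ks_p = ks$p.value,
    dagostino_pass = dp$p_value >= alpha,
    ks_pass = ks$p.value >= alpha,
    normal = dp$p_value >= alpha && ks$p.value >= alpha,
    n = length(x)
  )
}

#' Full method-agreement analysis between two diameter series
#'
#' Bundles the agreement workflow applied to paired pupil-diameter
#' measurements from two methods (e.g. manual annotation vs automatic
#' tracking): normality screening of both series, rank correlations,
#' ordinary least squares of predicted on ground truth, and Bland-Altman
#' bias with 95\% limits of agreement on relative differences.
#'
#' @param data Data frame with one row per frame/pair.
#' @param truth,pred Column names (tidy-eval) of the ground-truth and
#'   predicted series.
#' @return An object of class `pupil_agreement`. `tidy()` gives the per-pair
#'   table (`g`, `p`, `pair_mean`, `diff_pct`); `glance()` a one-row summary;
#'   `autoplot()` the Bland-Altman plot; [plot_agreement_scatter()] the
#'   regression scatter.
#' @export
#' @examples
#' d <- data.frame(manual = 40 + sin(1:50), auto = 40 + sin(1:50) + 0.1)
#' fit <- agreement_analysis(d, manual, auto)
#' glance(fit)
agreement_analysis <- function(data, truth, pred) {
  g <- dplyr::pull(data, {{ truth }})
  p <- dplyr::pull(data, {{ pred }})
  assert_paired(g, p, min_n = 3L)
  normality <- if (length(g) >= 20L && sd(g) > 0 && sd(p) > 0) {
    dplyr::bind_rows(
      dplyr::mutate(normality_screen(g), series = "truth", .before = 1),
      dplyr::mutate(normality_screen(p), series = "pred", .before = 1)
    )
  } else {
    NULL
  }
  structure(
    list(
      pairs = tibble::tibble(g = g, p = p, pair_mean = (g + p) / 2,
                             diff_pct = 100 * (g - p) / ((g + p) / 2)),
      normality = normality,
      correlations = rank_correlations(g, p),
      regression = fit_agreement_regression(g, p),
      bland_altman = bland_altman(g, p)
    ),
    class = "pupil_agreement"
  )
}

#' @export
print.pupil_agreement <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf(
    paste0("<pupil_agreement> n = %d pairs\n",
           "  Spearman rho %.3f, Kendall tau %.3f\n",
           "  fit: p = %.3f g %+.3f, R^2 = %.4f\n",
           "  relative bias %.3f%% (LoA %.2f%% .. %.2f%%)\n"),
    ba$n, x$correlations$spearman_rho, x$correlations$kendall_tau,
    x$regression$slope, x$regression$intercept, x$regression$r_squared,
    ba$relative_bias_pct, ba$loa_lower_pct, ba$loa_upper_pct))
  invisible(x)
}

#' @rdname agreement_analysis
#' @param x A `pupil_agreement` object.
#' @param ... Unused.
#' @export
tidy.pupil_agreement <- function(x, ...) x$pairs

#' @rdname agreement_analysis
#' @export
glance.pupil_agreement <- function(x, ...) {
  dplyr::bind_cols(
    x$correlations[, c("spearman_rho", "spearman_p", "kendall_tau", "kendall_p")],
    x$regression[, c("slope", "intercept", "r_squared", "pearson_r")],
    x$bland_altman
  )
}

#' Bland-Altman plot of a fitted agreement analysis
#'
#' @param object A `pupil_agreement` from [agreement_analysis()].
#' @param ... Unused.
#' @return A ggplot object: relative difference against pair mean with bias
#'   (solid) and 95\% limits of agreement (dashed).
#' @export
autoplot.pupil_agreement <- function(object, ...) {
  ba <- object$bland_altman
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pair_mean, y = .data$diff_pct)) +
    ggplot2::geom_point(alpha = 0.4, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = ba$relative_bias_pct, colour = "black") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower_pct, ba$loa_upper_pct),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "pair mean diameter (px)",
                  y = "relative difference (% of pair mean)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Scatter plot with the fitted agreement regression line
#'
#' @inheritParams autoplot.pupil_agreement
#' @return A ggplot object: predicted vs ground-truth diameters with the
#'   OLS line and the identity line.
#' @export
plot_agreement_scatter <- function(object, ...) {
  reg <- object$regression
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$g, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.4, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = "dotted") +
    ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept,
                         colour = "red") +
    ggplot2::labs(x = "ground-truth diameter (px)",
                  y = "predicted diameter (px)",
                  title = sprintf("p = %.3f g %+.3f, R^2 = %.4f",
                                  reg$slope, reg$intercept, reg$r_squared)) +
    ggplot2::theme_minimal()
}
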