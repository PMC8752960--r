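# Nonparametric statistics used in the virtual trial: one-sided Wilcoxon
# signed-rank tests of the paired reductions, Mann-Whitney comparisons of
# reduction distributions, and Bonferroni correction. Effect sizes (the
# reductions themselves) are always reported alongside p-values.

new_crt_test <- function(method, statistic, p_value, alternative, n, alpha) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), alternative = alternative,
                 n = n, alpha = alpha, significant = p_value < alpha),
            class = "crt_test")
}

#' @export
print.crt_test <- function(x, ...) {
  cat(sprintf("<crt_test> %s: statistic=%.4g, p=%.4g (%s), n=%s -> %s at alpha=%.3g\n",
              x$method, x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/"),
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' @export
tidy.crt_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         alternative = x$alternative, n = paste(x$n, collapse = "/"),
         alpha = x$alpha, significant = x$significant)
}

#' Wilcoxon signed-rank test of paced reductions
#'
#' One-sample signed-rank test of symmetry about `mu`, by default one-sided
#' with the alternative of a positive location shift (pacing helps). Exact
#' null distribution for n <= 25 without ties; tie-corrected normal
#' approximation otherwise. Zero differences are dropped by the classical
#' Wilcoxon convention (`zeros = "wilcox"`); `zeros = "pratt"` ranks them
#' first and then drops their ranks.
#'
#' @param values Numeric sample (e.g. percent reductions).
#' @param mu Hypothesized location, default 0.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param zeros Handling of zero differences.
#' @param alpha Significance level (0.01 in this package).
#' @return A `crt_test` object.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0,
                                 alternative = c("greater", "less", "two.sided"),
                                 zeros = c("wilcox", "pratt"), alpha = 0.01) {
  alternative <- match.arg(alternative)
  zeros <- match.arg(zeros)
  if (!length(values)) abort("empty sample", class = "quadlead_argument_error")
  d <- values - mu
  if (zeros == "wilcox") {
    d <- d[d != 0]
    if (!length(d)) {
      abort("all differences are zero: signed-rank test undefined",
            class = "quadlead_argument_error")
    }
    n <- length(d)
    exact <- n <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = alternative,
                                       exact = exact, correct = TRUE))
    return(new_crt_test("Wilcoxon signed-rank", wt$statistic, wt$p.value,
                        alternative, n, alpha))
  }
  # Pratt: rank |d| with zeros included, then drop the zero ranks
  if (all(d == 0)) {
    abort("all differences are zero: signed-rank test undefined",
          class = "quadlead_argument_error")
  }
  r <- rank(abs(d))
  nz <- d != 0
  W <- sum(r[d > 0])
  n <- length(d); n0 <- sum(!nz)
  e_w <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  ties <- table(r[nz])
  v_w <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  zstat <- (W - e_w) / sqrt(v_w)
  p <- switch(alternative,
              greater = stats::pnorm(zstat, lower.tail = FALSE),
              less = stats::pnorm(zstat),
              two.sided = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE))
  new_crt_test("Wilcoxon signed-rank (Pratt)", W, min(1, p), alternative,
               sum(nz), alpha)
}

#' Mann-Whitney rank-sum test between two reduction distributions
#'
#' Unpaired two-sample test; `alternative = "greater"` tests whether `x` is
#' stochastically larger than `y`. Exact for small samples
#' (`n_x * n_y <= 400`) without ties, tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param alpha Significance level.
#' @return A `crt_test` object.
#' @export
mann_whitney <- function(x, y, alternative = c("greater", "less", "two.sided"),
                         alpha = 0.01) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("empty sample", class = "quadlead_argument_error")
  exact <- length(x) * length(y) <= 400 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = exact, correct = TRUE))
  new_crt_test("Mann-Whitney", wt$statistic, wt$p.value, alternative,
               c(length(x), length(y)), alpha)
}

#' Bonferroni correction
#'
#' Adjusted p-values `min(1, m * p)` over a family of `m` comparisons.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "quadlead_argument_error")
  }
  p.adjust(p_values, method = "bonferroni")
}
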