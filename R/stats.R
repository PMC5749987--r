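#' Wilcoxon signed-rank test with Z statistic and effect size
#'
#' Paired two-sided Wilcoxon signed-rank test reporting the
#' normal-approximation Z (with the usual tie correction and no continuity
#' correction), as commonly reported alongside the effect size
#' r = Z / sqrt(N). Zero differences are dropped before ranking (the
#' classic treatment). When 15 or fewer non-zero pairs remain and there are
#' no ties in the absolute differences, the exact signed-rank distribution
#' is used for the p-value instead of the normal approximation.
#'
#' @param x first condition, or the paired differences when `y` is NULL
#' @param y optional second condition
#' @param convention effect-size denominator: `"r_sqrt_pairs"`
#'   (r = |Z|/sqrt(pairs), the default) or `"r_sqrt_obs"`
#'   (r = |Z|/sqrt(2 * pairs), i.e. total observations)
#' @return object of class `pam_test`: list with `test`, `statistic` (Z),
#'   `W` (sum of positive ranks), `p_value`, `n_pairs`, `effect_size`,
#'   `convention`, `degenerate`, `exact`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 convention = c("r_sqrt_pairs", "r_sqrt_obs")) {
  convention <- match.arg(convention)
  d <- if (is.null(y)) x else x - y
  n_in <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(test = "wilcoxon", statistic = 0, W = 0,
                          p_value = 1, n_pairs = n_in, effect_size = 0,
                          convention = convention, degenerate = TRUE,
                          exact = FALSE), class = "pam_test"))
  }
  if (n < 5) stop("need at least 5 non-zero paired differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- (W - mu) / sqrt(sigma2)
  no_ties <- !any(duplicated(abs(d)))
  exact <- n <= 15 && no_ties
  p <- if (exact) {
    min(1, 2 * min(stats::psignrank(W, n),
                   1 - stats::psignrank(W - 1, n)))
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  structure(list(test = "wilcoxon", statistic = Z, W = W, p_value = p,
                 n_pairs = n, effect_size = effect_size_r(Z, n, convention),
                 convention = convention, degenerate = FALSE, exact = exact),
            class = "pam_test")
}

#' Paired t-test with Cohen's d
#'
#' t = mean(diff) / (sd(diff)/sqrt(n)), df = n - 1, two-sided p, and
#' Cohen's d reported as the magnitude |t| / sqrt(n).
#'
#' @inheritParams wilcoxon_signed_rank
#' @return `pam_test` object with `statistic` (t), `df`, `p_value`,
#'   `effect_size` (d), `convention = "d_t_over_sqrt_n"`
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(structure(list(test = "paired_t", statistic = 0, df = n - 1,
                            p_value = 1, n_pairs = n, effect_size = 0,
                            convention = "d_t_over_sqrt_n",
                            degenerate = TRUE), class = "pam_test"))
    return(structure(list(test = "paired_t", statistic = Inf, df = n - 1,
                          p_value = 0, n_pairs = n, effect_size = Inf,
                          convention = "d_t_over_sqrt_n",
                          degenerate = TRUE), class = "pam_test"))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  structure(list(test = "paired_t", statistic = t_stat, df = n - 1,
                 p_value = 2 * stats::pt(-abs(t_stat), n - 1), n_pairs = n,
                 effect_size = cohens_d(t_stat, n),
                 convention = "d_t_over_sqrt_n", degenerate = FALSE),
            class = "pam_test")
}

#' Effect size r from a Z statistic
#'
#' Two conventions are in circulation and both are implemented and
#' labelled: `r_sqrt_pairs` divides |Z| by sqrt(number of pairs);
#' `r_sqrt_obs` divides by sqrt(total observations) = sqrt(2 * pairs), the
#' convention used for the paired 30-s whistle-count comparison.
#'
#' @param Z finite Z statistic
#' @param n_pairs number of pairs (>= 1)
#' @param convention see above
#' @return r in `[0, 1]` (unrounded; round to 2 d.p. for reporting)
#' @export
effect_size_r <- function(Z, n_pairs,
                          convention = c("r_sqrt_pairs", "r_sqrt_obs")) {
  convention <- match.arg(convention)
  denom <- switch(convention, r_sqrt_pairs = n_pairs, r_sqrt_obs = 2 * n_pairs)
  abs(Z) / sqrt(denom)
}

#' Cohen's d from a paired t statistic
#' @param t_stat t statistic
#' @param n number of pairs
#' @return d = |t| / sqrt(n)
#' @export
cohens_d <- function(t_stat, n) abs(t_stat) / sqrt(n)

#' Choose between the paired t-test and the Wilcoxon test
#'
#' Normality gate: Shapiro-Wilk on the paired differences at alpha = 0.05;
#' normal-looking differences get the parametric paired t-test, otherwise
#' the Wilcoxon signed-rank test. Constant differences short-circuit to the
#' Wilcoxon branch (flagged degenerate).
#'
#' @param differences paired differences, n >= 5
#' @param alpha gate level
#' @return list with `test` ("paired_t"/"wilcoxon") and `shapiro_p`
#' @export
choose_test <- function(differences, alpha = 0.05) {
  n <- length(differences)
  if (n < 5) stop("need at least 5 pairs for inference")
  if (stats::sd(differences) == 0)
    return(list(test = "wilcoxon", shapiro_p = NA_real_, degenerate = TRUE))
  sw <- stats::shapiro.test(differences)
  list(test = if (sw$p.value >= alpha) "paired_t" else "wilcoxon",
       shapiro_p = sw$p.value, degenerate = FALSE)
}

#' Paired comparison with automatic test choice
#'
#' @param before,value paired vectors (baseline, comparison)
#' @param test "auto" (normality-gated), "wilcoxon" or "paired_t"
#' @return `pam_test` object
#' @export
paired_comparison <- function(before, value, test = "auto") {
  d <- value - before
  if (test == "auto") test <- choose_test(d)$test
  switch(test,
         wilcoxon = wilcoxon_signed_rank(d),
         paired_t = paired_t(d),
         stop("unknown test: ", test))
}

#' 30-s whistle-count comparison around detonations
#'
#' Wilcoxon signed-rank test on paired whistle counts from the 30 s before
#' and after each detonation, with the effect size reported under the
#' total-observations convention (r = |Z| / sqrt(2N)) used for this
#' analysis.
#'
#' @param before,after paired whistle counts per detonation
#' @return `pam_test` object
#' @export
whistles_30s_comparison <- function(before, after) {
  wilcoxon_signed_rank(after, before, convention = "r_sqrt_obs")
}

#' @export
print.pam_test <- function(x, ...) {
  lab <- if (x$test == "wilcoxon") "Z" else "t"
  cat(sprintf("%s: %s = %.3f%s, p = %.4g, effect size = %.2f (%s), n = %d\n",
              x$test, lab, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value, x$effect_size, x$convention, x$n_pairs))
  invisible(x)
}

#' Day-scale response tests across events
#'
#' Runs the paired comparisons of each day label against the day before,
#' separately for the daytime and night blocks, over a stacked day-scale
#' series. Returns one row per comparison with the chosen test, statistic,
#' p-value and effect size.
#'
#' @param series stacked [day_scale_series()] output
#' @param test "auto", "wilcoxon" or "paired_t"
#' @return data.frame summary
#' @export
day_scale_tests <- function(series, test = "auto") {
  out <- list()
  for (block in c("day", "night")) {
    for (lab in c("day_of", "day_after", "second_day_after")) {
      p <- pair_with_baseline(series, lab, block)
      if (nrow(p) < 5) next
      res <- paired_comparison(p$before, p$value, test)
      out[[paste(block, lab)]] <- data.frame(
        comparison = paste0(lab, "_vs_day_before"), block = block,
        test = res$test, statistic = res$statistic,
        df = as.integer(res$df %||% NA_integer_),
        p = res$p_value, effect_size = res$effect_size,
        convention = res$convention, n = nrow(p))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
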