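# Screening statistics: correlation tests with Bonferroni correction and
# the R^2 > 0.5 retention rule; pooled two-sample t-test.

#' Screen optical parameters against a target variable
#'
#' Per-parameter Spearman (default) or Pearson correlation with a
#' two-sided p-value by the t approximation, Bonferroni-adjusted
#' significance threshold alpha/n_tests, and the retention rule:
#' a parameter is retained when it is significant AND its squared
#' correlation exceeds \code{r2_min}.
#'
#' @param data data.frame holding the target and parameter columns
#' @param target name of the target column (e.g. ultrasound SATT)
#' @param parameters character vector of parameter column names; default
#'   the seven optical parameters \code{c("thbmb", "sto2", "water",
#'   "fat", "a500", "b_power", "mus800")}
#' @param method \code{"spearman"} or \code{"pearson"}
#' @param n_tests Bonferroni family size; default
#'   \code{length(parameters)}
#' @param alpha family-wise significance level (default 0.05)
#' @param r2_min retention threshold on the squared correlation
#'   (default 0.5)
#' @param permutation_p use a permutation p-value (for small n) instead of
#'   the t approximation
#' @param n_perm number of permutations when \code{permutation_p}
#' @return data.frame, one row per parameter: \code{parameter},
#'   \code{method}, \code{r}, \code{r_squared}, \code{p_value}, \code{n},
#'   \code{alpha_adjusted}, \code{significant}, \code{retained}.
#'   Constant columns yield \code{NA} correlation, not significant, not
#'   retained.
#' @export
screen_parameters <- function(data, target,
                              parameters = c("thbmb", "sto2", "water",
                                             "fat", "a500", "b_power",
                                             "mus800"),
                              method = c("spearman", "pearson"),
                              n_tests = length(parameters),
                              alpha = 0.05, r2_min = 0.5,
                              permutation_p = FALSE, n_perm = 9999L) {
  method <- match.arg(method)
  miss <- setdiff(c(target, parameters), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  alpha_adj <- alpha / n_tests
  rows <- lapply(parameters, function(p) {
    ok <- stats::complete.cases(data[[p]], data[[target]])
    x <- data[[p]][ok]
    y <- data[[target]][ok]
    n <- length(x)
    if (n < 5L) stop("need >= 5 complete pairs for '", p, "'", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(parameter = p, method = method, r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_, n = n,
                        alpha_adjusted = alpha_adj, significant = FALSE,
                        retained = FALSE))
    }
    r <- stats::cor(x, y, method = method)
    pv <- if (permutation_p) {
      perm_r <- replicate(n_perm,
                          abs(stats::cor(x, sample(y), method = method)))
      (1 + sum(perm_r >= abs(r))) / (n_perm + 1)
    } else if (abs(r) >= 1) {
      0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    sig <- pv < alpha_adj
    data.frame(parameter = p, method = method, r = r, r_squared = r^2,
               p_value = pv, n = n, alpha_adjusted = alpha_adj,
               significant = sig, retained = sig && r^2 > r2_min)
  })
  do.call(rbind, rows)
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t statistic with a two-sided
#' p-value. Zero pooled variance with equal means yields t = 0, p = 1 by
#' convention.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2
#' @return list with \code{t}, \code{p_value}, \code{df}
#' @export
ttest_two_sample <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  df <- na + nb - 2
  dm <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, p_value = 1, df = df))
    return(list(t = sign(dm) * Inf, p_value = 0, df = df))
  }
  tt <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p_value = 2 * stats::pt(-abs(tt), df = df), df = df)
}
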