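#' Continuous ranked probability score of a predictive sample
#'
#' Exact pairwise sample estimator
#' `mean(|x_s - y|) - mean(|x_s - x_t|) / 2` over all ordered draw pairs.
#' Non-negative, zero when every draw equals the realised value, and
#' invariant to a common shift of draws and truth. Lower is better.
#'
#' @param draws Numeric vector of predictive draws (non-empty).
#' @param truth The realised value.
#' @return A single non-negative number.
#' @export
crps_sample <- function(draws, truth) {
  if (length(draws) == 0L) stopf("empty draws")
  assert_scalar_number(truth, "truth")
  # mean over ordered pairs |x_s - x_t| via the sorted-draw identity,
  # O(S log S) instead of the S^2 outer difference
  s <- sort(draws)
  n <- length(s)
  pair_mean <- if (n == 1L) 0 else
    2 * sum((2 * seq_len(n) - n - 1) * s) / n^2
  mean(abs(draws - truth)) - pair_mean / 2
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`: the Pearson
#' correlation (precision) scaled by a bias-correction factor (accuracy
#' against the identity line). Lies in \[-1, 1\] and never exceeds the
#' Pearson correlation in absolute value.
#'
#' @param x,y Numeric vectors of equal length (>= 2), not both constant.
#' @return A single number in \[-1, 1\].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stopf("x and y must have equal length >= 2")
  vx <- var_1n(x); vy <- var_1n(y)
  if (vx == 0 && vy == 0) stopf("both vectors are constant")
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

#' Signed estimation error
#'
#' Difference between the true and the estimated value (positive =
#' underestimation). Vectorised.
#'
#' @param true_value,estimate Numeric.
#' @return `true_value - estimate`.
#' @export
estimation_error <- function(true_value, estimate) true_value - estimate

#' Trait-specific effective population size from a genic-variance trend
#'
#' Fits `log(genic variance)` on year by least squares and inverts the
#' drift-decay model `V_t = V_0 (1 - 1/(2 Ne))^t`, giving
#' `Ne = 1 / (2 (1 - exp(slope)))`. A non-negative slope (no decay) returns
#' `Inf`.
#'
#' @param genic Strictly positive genic variances.
#' @param years Year of each value (defaults to `seq_along(genic)`).
#' @return Estimated effective population size (possibly `Inf`).
#' @export
effective_population_size <- function(genic, years = seq_along(genic)) {
  if (length(genic) < 2L) stopf("need at least two genic variances")
  if (any(genic <= 0)) stopf("genic variances must be strictly positive")
  slope <- unname(coef(lm(log(genic) ~ years))[2L])
  if (slope >= 0) return(Inf)
  1 / (2 * (1 - exp(slope)))
}

#' Score estimated variance partitions against the truth
#'
#' Joins a partition posterior with true component values and computes, per
#' group and component, the CRPS of the posterior draws against the truth
#' and the posterior-mean estimation error.
#'
#' @param posterior A `partition_posterior` (genome level).
#' @param truth Tibble with `group`, `component`, `true_value`.
#' @return Tibble with `group`, `component`, `true_value`, `post_mean`,
#'   `crps`, `error`.
#' @export
score_partitions <- function(posterior, truth) {
  draws <- dplyr::filter(tibble::as_tibble(posterior),
                         is.na(.data$chromosome))
  joined <- dplyr::inner_join(draws, truth, by = c("group", "component"))
  if (nrow(joined) == 0L) stopf("no overlapping group/component pairs")
  dplyr::summarise(
    dplyr::group_by(joined, .data$group, .data$component,
                    .data$true_value),
    post_mean = mean(.data$value),
    crps = crps_sample(.data$value, .data$true_value[1L]),
    .groups = "drop") |>
    dplyr::mutate(error = estimation_error(.data$true_value,
                                           .data$post_mean))
}
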