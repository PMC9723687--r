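#' Sloan neutral-model detection frequency
#'
#' Under neutral birth-death-immigration dynamics, the local relative
#' abundance of a taxon with metacommunity mean relative abundance `p`
#' follows a Beta(N*m*p, N*m*(1-p)) distribution; the probability of
#' detecting it at or above the detection limit `d` reads is
#' `1 - pbeta(d/N, N*m*p, N*m*(1-p))`. Monotone non-decreasing in `p` and
#' in `m`.
#'
#' @param p mean relative abundance, strictly inside (0, 1); vectorized.
#' @param m migration (immigration) probability.
#' @param N local community size in reads (the rarefaction depth).
#' @param d detection limit in reads (default 1).
#' @return predicted occurrence frequency in \[0, 1\].
#' @export
#' @examples
#' predict_frequency(0.01, m = 0.1, N = 1000) # (1 - 0.001)^99
predict_frequency <- function(p, m, N, d = 1) {
  if (any(p <= 0) || any(p >= 1))
    stop("p must lie strictly between 0 and 1")
  stopifnot(m > 0, N > 0, d >= 0)
  1 - pbeta(d / N, N * m * p, N * m * (1 - p))
}

# Wilson score interval for a proportion observed with n trials
wilson_interval <- function(p_hat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / den
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit Sloan's neutral community model
#'
#' Fits the migration parameter `m` by nonlinear least squares of observed
#' occurrence frequency against mean relative abundance across samples,
#' with the community size `N` fixed to the rarefaction depth. Each taxon
#' is then classed as `above`, `within` or `below` the neutral prediction
#' using a Wilson binomial confidence band (n = number of samples) around
#' the predicted frequency.
#'
#' The model describes whole-community species distributions; fitting it to
#' rare/common subsets is not meaningful, so pass the unpartitioned table.
#'
#' @param table rarefied `feature_table` or count matrix, >= 5 samples.
#' @param d detection limit in reads (default 1).
#' @param ci_level confidence level of the deviation band (default 0.95).
#' @param m_start starting value for the optimizer.
#' @param N local community size in reads; defaults to the (uniform)
#'   rarefaction depth of the table.
#' @return object of class `sloan_fit`: list with `m`, `Ntm` (= N*m), `N`,
#'   `d`, `r_squared`, `n_samples`, and `asv` (data.frame with `asv`, `p`,
#'   `freq_obs`, `freq_pred`, `lower`, `upper`, `deviation`).
#' @export
fit_sloan <- function(table, d = 1, ci_level = 0.95, m_start = 0.1,
                      N = NULL) {
  m0 <- ft_counts(table)
  S <- ncol(m0)
  if (S < 5) stop("Sloan fit needs at least 5 samples")
  if (is.null(N)) {
    depth <- unique(colSums(m0))
    if (length(depth) != 1)
      stop("table must be rarefied (uniform column sums), or supply `N`")
    N <- depth
  }
  relab <- relative_abundance(m0)
  p <- rowMeans(relab)
  freq <- rowSums(m0 >= d) / S
  keep <- p > 0 & p < 1
  p <- p[keep]; freq <- freq[keep]
  if (var(freq) == 0) {
    warning("observed frequencies have zero variance; R^2 undefined")
  }
  dat <- data.frame(p = p, freq = freq)
  fit <- minpack.lm::nlsLM(
    freq ~ 1 - pbeta(d / N, N * m * p, N * m * (1 - p)),
    data = dat, start = list(m = m_start),
    lower = 1e-8, upper = 1,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  m_hat <- unname(coef(fit)["m"])
  pred <- predict_frequency(p, m_hat, N, d)
  sse <- sum((freq - pred)^2)
  sst <- sum((freq - mean(freq))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  band <- wilson_interval(pred, S, ci_level)
  deviation <- ifelse(freq > band[, "upper"], "above",
               ifelse(freq < band[, "lower"], "below", "within"))
  structure(list(
    m = m_hat, Ntm = N * m_hat, N = N, d = d, r_squared = r2,
    n_samples = S,
    asv = data.frame(asv = names(p), p = unname(p),
                     freq_obs = unname(freq), freq_pred = unname(pred),
                     lower = unname(band[, "lower"]),
                     upper = unname(band[, "upper"]),
                     deviation = factor(deviation,
                                        levels = c("above", "within",
                                                   "below")),
                     stringsAsFactors = FALSE, row.names = NULL)
  ), class = "sloan_fit")
}

#' @export
print.sloan_fit <- function(x, ...) {
  cat(sprintf("sloan_fit: m = %.4g (N*m = %.1f), R^2 = %.3f over %d ASVs\n",
              x$m, x$Ntm, x$r_squared, nrow(x$asv)))
  print(table(x$asv$deviation))
  invisible(x)
}

#' Cross-tabulate neutral-model deviation against rarity types
#'
#' @param fit a `sloan_fit`.
#' @param types rarity-type assignment from [classify_rarity_types()].
#' @return contingency table (rarity type x deviation class) over the
#'   shared ASV universe; empty classes keep their zero rows/columns.
#' @export
crosstab_deviation_by_type <- function(fit, types) {
  shared <- intersect(fit$asv$asv, types$asv)
  if (!length(shared)) stop("fit and rarity types share no ASVs")
  dev <- fit$asv$deviation[match(shared, fit$asv$asv)]
  ty <- types$type[match(shared, types$asv)]
  table(type = ty, deviation = dev)
}
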