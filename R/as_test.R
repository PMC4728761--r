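## Allelic-imbalance scoring: exact two-sided binomial test of the G1 count
## against a 50:50 null, Benjamini-Hochberg FDR correction, and AS-SNP
## selection. The two-sided p-value uses the minimum-likelihood convention:
## the probabilities of all outcomes no more likely than the observed one are
## summed, with a small relative slack guarding against floating-point ties.

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' For each observed count `k` out of `n` trials, sums `P(X = i)` over all
#' outcomes `i` with `P(X = i) <= P(X = k) * (1 + 1e-7)` under
#' `X ~ Binomial(n, p0)`. When the observed outcome is the most likely one
#' the p-value is exactly 1. Vectorized over `k` (and `n`).
#'
#' @param k number of successes (G1-supporting reads), `0 <= k <= n`.
#' @param n number of trials (informative reads), `n >= 1`.
#' @param p0 null success probability, default 0.5 (equal G1:G2 coverage).
#' @return numeric vector of p-values in `[0, 1]`.
#' @examples
#' binom_two_sided(5, 10)   # 1
#' binom_two_sided(0, 10)   # 2 * 0.5^10 = 0.001953125
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  assert_scalar_number(p0, "p0", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  if (length(n) == 1L) n <- rep(n, length(k))
  if (length(k) != length(n)) stopf("k and n must have matching lengths")
  if (any(is.na(k)) || any(is.na(n)) || any(n < 1) || any(k < 0) || any(k > n))
    stopf("need 0 <= k <= n and n >= 1")
  rel <- 1 + 1e-7
  p <- numeric(length(k))
  for (nn in unique(n)) {
    idx <- which(n == nn)
    d <- dbinom(0:nn, nn, p0)
    o <- order(d)
    ds <- d[o]
    cs <- cumsum(ds)
    dk <- d[k[idx] + 1L]
    thr <- dk * rel
    pos <- findInterval(thr, ds)
    pv <- cs[pos]
    pv[thr >= max(d)] <- 1
    p[idx] <- pmin(1, pv)
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the BH-adjusted q-values in the input order:
#' `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped at 1. Backed by
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Score counted SNPs for allele-specific binding
#'
#' Computes the allelic ratio `n_g1 / (n_g1 + n_g2)`, the exact two-sided
#' binomial p-value under the equal-coverage null, the BH q-value across the
#' whole table, and a selection flag. Selection is on `q < alpha` by default
#' (the correction precedes selection); `select_on = "p"` switches to raw
#' p-values for sensitivity analyses.
#'
#' @param records an `allele_counts` table (after [discard_uncovered()]).
#' @param alpha selection threshold, in `(0, 1]`.
#' @param select_on `"q"` (default) or `"p"`.
#' @return data.frame with class `as_results`: the input columns plus
#'   `allelic_ratio, p_value, q_value, selected`.
#' @export
as_binomial_test <- function(records, alpha = 0.05, select_on = c("q", "p")) {
  select_on <- match.arg(select_on)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  res <- as.data.frame(records)
  if (nrow(res) == 0L) {
    res$allelic_ratio <- numeric(0)
    res$p_value <- numeric(0)
    res$q_value <- numeric(0)
    res$selected <- logical(0)
    class(res) <- c("as_results", "data.frame")
    return(res)
  }
  res$allelic_ratio <- res$n_g1 / res$n_total_informative
  res$p_value <- binom_two_sided(res$n_g1, res$n_total_informative)
  res$q_value <- bh_adjust(res$p_value)
  crit <- if (select_on == "q") res$q_value else res$p_value
  res$selected <- crit < alpha | alpha >= 1
  class(res) <- c("as_results", "data.frame")
  res
}

#' Select AS-SNPs from scored results
#'
#' Keeps the results flagged as selected (`q_value < alpha`, or raw
#' `p_value < alpha` when the results were scored with `select_on = "p"`),
#' sorted by q-value and then by decreasing distance of the allelic ratio
#' from 0.5 (strongest imbalance first).
#'
#' @param results an `as_results` table from [as_binomial_test()].
#' @param alpha selection threshold.
#' @param on `"q"` or `"p"`: which value `alpha` is compared against.
#' @return the selected rows, re-sorted, `selected` set to `TRUE`.
#' @export
select_as_snps <- function(results, alpha = 0.05, on = c("q", "p")) {
  on <- match.arg(on)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  crit <- if (on == "q") results$q_value else results$p_value
  ## alpha = 1 is a vacuous threshold (q <= 1 always), so it selects all
  sel <- results[crit < alpha | alpha >= 1, , drop = FALSE]
  if (nrow(sel)) {
    sel <- sel[order(sel$q_value, -abs(sel$allelic_ratio - 0.5)), , drop = FALSE]
    sel$selected <- TRUE
    rownames(sel) <- NULL
  }
  sel
}

#' Exact power of the two-sided binomial test by enumeration
#'
#' Probability that [binom_two_sided()] rejects at level `alpha` when the true
#' success probability is `p_alt`, for a fixed number of trials `n` — computed
#' by enumerating all `n + 1` outcomes. With `poisson_depth = TRUE`, `n` is
#' instead the mean of a Poisson depth distribution and the power is averaged
#' over depths (sites with zero reads never reach the test and are excluded,
#' matching the pipeline's discard rule).
#'
#' @param n trials, or Poisson mean depth.
#' @param p_alt true success probability.
#' @param alpha rejection level on the raw p-value.
#' @param p0 null probability.
#' @param poisson_depth average over a Poisson depth distribution.
#' @return scalar power.
#' @export
binomial_power <- function(n, p_alt, alpha = 0.05, p0 = 0.5,
                           poisson_depth = FALSE) {
  power_at <- function(nn) {
    pv <- binom_two_sided(0:nn, nn, p0)
    sum(dbinom(0:nn, nn, p_alt)[pv < alpha])
  }
  if (!poisson_depth) return(power_at(n))
  dmax <- max(10L, ceiling(n + 10 * sqrt(n)))
  w <- dpois(1:dmax, n)
  sum(w * vapply(1:dmax, power_at, numeric(1L))) / sum(w)
}

#' Write / read scored result tables
#'
#' @param results an `as_results` table.
#' @param path TSV path.
#' @export
write_results <- function(results, path) write_tsv_file(results, path)

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read_tsv_file(path)
  class(df) <- c("as_results", "data.frame")
  df
}
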