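# Paired nonparametric statistics: Wilcoxon signed-rank with exact
# enumeration for small samples, rank-biserial effect size, and the
# Bonferroni-style family-wise error threshold.

#' Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Zero differences are dropped (drop-zeros convention). Ranks of
#' absolute differences use mid-ranks for ties. For `n <= exact_max`
#' non-zero differences the two-sided p-value is exact, computed by
#' enumerating all `2^n` sign assignments of the observed ranks (which
#' also handles ties exactly); otherwise a normal approximation with tie
#' correction and a 0.5 continuity correction is used. The rank-biserial
#' correlation is `(R+ - R-) / (R+ + R-)` over the signed-rank sums.
#'
#' @param x,y paired numeric vectors; at least 5 non-zero differences.
#' @param alternative `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @param exact_max largest n for which the exact enumeration is used.
#' @return list `(W, p, rbc, n, method)` where `W` is the positive-rank
#'   sum.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("two.sided", "greater", "less"),
                                 exact_max = 12L) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_mosr("all paired differences are zero")
  if (n < 5) stop_mosr("need at least 5 non-zero differences, got %d", n)
  rk <- rank(abs(d))
  Wpos <- sum(rk[d > 0])
  Wneg <- sum(rk[d < 0])
  rbc <- (Wpos - Wneg) / (Wpos + Wneg)
  if (n <= exact_max) {
    # full enumeration of sign assignments over the observed ranks
    dist <- signrank_distribution(rk)
    p_ge <- sum(dist$prob[dist$w >= Wpos - 1e-9])
    p_le <- sum(dist$prob[dist$w <= Wpos + 1e-9])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z_ge <- (Wpos - mu - cc) / sqrt(sigma2)
    z_le <- (Wpos - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = pnorm(z_ge, lower.tail = FALSE),
                less = pnorm(z_le),
                two.sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE),
                                           pnorm(z_le))))
    method <- "normal_approx"
  }
  list(W = Wpos, p = p, rbc = rbc, n = n, method = method)
}

# Exact null distribution of the positive-rank sum for a given rank
# vector (handles tied mid-ranks), by enumerating all 2^n sign vectors.
signrank_distribution <- function(rk) {
  n <- length(rk)
  # subset-sum doubling: each rank either contributes or not
  sums <- 0
  for (i in seq_len(n)) sums <- c(sums, sums + rk[i])
  tab <- table(sums)
  list(w = as.numeric(names(tab)), prob = as.numeric(tab) / 2^n)
}

#' Family-wise error threshold (Bonferroni division)
#'
#' @param alpha nominal significance level.
#' @param m number of comparisons in the family.
#' @return per-comparison threshold `alpha / m` (e.g. 0.05 / 8 = 0.00625
#'   for four tissue types by two model contrasts).
#' @export
fwer_threshold <- function(alpha, m) {
  if (m < 1) stop_mosr("m must be >= 1")
  alpha / m
}
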