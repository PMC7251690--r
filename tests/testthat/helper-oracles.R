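# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the implementation it checks.

# Hypergeometric tail by exhaustive enumeration of all C(N, n) draws.
enum_hyper_tail <- function(N, k, n, x) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= k)        # items 1..k are the "successes"
  mean(hits >= x)
}

enum_hyper_point <- function(N, k, n, x) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= k) == x)
}

# Brute-force grid-search maximisation of the two-group NB likelihood for a
# single gene with equal library sizes; the coarse log-spaced grid is zoomed
# around its argmax until the resolution no longer limits the comparison.
grid_nb_lrt <- function(y1, y2, disp, grid_n = 4000) {
  r <- 1 / disp
  ll <- function(y, mu) sum(dnbinom(y, size = r, mu = mu, log = TRUE))
  rng <- range(c(y1, y2, 1))
  best <- function(y) {
    mus <- exp(seq(log(max(rng[1], 0.05) / 4), log(rng[2] * 4),
                   length.out = grid_n))
    for (pass in 1:4) {
      lls <- vapply(mus, function(m) ll(y, m), 0)
      i <- which.max(lls)
      lo <- mus[max(1L, i - 1L)]; hi <- mus[min(length(mus), i + 1L)]
      if (pass < 4) mus <- seq(lo, hi, length.out = grid_n)
    }
    c(mu = mus[i], ll = lls[i])
  }
  f1 <- best(y1); f2 <- best(y2); f0 <- best(c(y1, y2))
  stat <- max(0, 2 * (f1["ll"] + f2["ll"] - f0["ll"]))
  list(p = pchisq(stat, 1, lower.tail = FALSE),
       log2fc = log2(f2["mu"] / f1["mu"]))
}

# Textbook pooled-variance two-sample t-test.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Literal transcription of the control-study decision rule using an explicit
# range (max - min) of the two fold changes.
decision_rule_literal <- function(lfc_sf, lfc_control) {
  rng <- max(lfc_sf, lfc_control) - min(lfc_sf, lfc_control)
  (abs(rng) > abs(lfc_control)) || (abs(lfc_sf) > abs(lfc_control))
}
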