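## Negative-binomial two-group differential expression.
##
## The model: y_gj ~ NB(mu_gj, alpha) with log link and library-size offsets,
## mu_gj = N_j * exp(beta_g[condition_j]); variance = mu + alpha mu^2.  The
## group log-mean beta is the only free parameter per gene x group, so the
## score equation U(beta) = sum_j r (y_j - mu_j) / (mu_j + r), r = 1/alpha, is
## strictly decreasing in beta and Newton iteration converges globally with a
## mild step cap.

# Vectorised Newton fit of one log-mean per gene.
# Y: genes x samples counts; offset: per-sample library sizes; disp: scalar or
# per-gene dispersion. Returns beta (log rate per unit library), the NB
# log-likelihood per gene, and the Fisher information at the optimum.
.nb_fit_one_group <- function(Y, offset, disp, max_iter = 60L, tol = 1e-12) {
  G <- nrow(Y)
  r <- 1 / disp
  if (length(r) == 1L) r <- rep(r, G)
  tot <- rowSums(Y)
  zero <- tot == 0
  beta <- log((tot + 0.5) / sum(offset))
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% offset
    U <- rowSums(r * (Y - mu) / (mu + r))
    I <- rowSums(r * mu * (r + Y) / (mu + r)^2)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    beta <- beta + step
    if (all(zero) || max(abs(step[!zero])) < tol) break
  }
  beta[zero] <- -Inf
  mu <- exp(beta) %o% offset
  ll <- rowSums(stats::dnbinom(Y, size = r, mu = pmax(mu, 1e-300), log = TRUE))
  ll[zero] <- 0   # all-zero rows: P(y = 0 | mu -> 0) = 1
  info <- rowSums(r * mu * (r + Y) / (mu + r)^2)
  list(beta = beta, loglik = ll, info = info)
}

# Per-gene profile log-likelihood at a given dispersion, with optional
# Cox-Reid adjustment (-0.5 log I per fitted group mean).
.nb_profile_ll <- function(Y, offset, condition, disp, adjust = TRUE) {
  ll <- numeric(nrow(Y))
  for (lev in levels(condition)) {
    j <- condition == lev
    fit <- .nb_fit_one_group(Y[, j, drop = FALSE], offset[j], disp)
    adj <- if (adjust) -0.5 * log(pmax(fit$info, 1e-12)) else 0
    adj[rowSums(Y[, j, drop = FALSE]) == 0] <- 0
    ll <- ll + fit$loglik + adj
  }
  ll
}

#' Estimate NB dispersion from a two-condition count matrix
#'
#' Maximises the summed per-gene Cox-Reid adjusted profile log-likelihood
#' (group means profiled out) over a log-spaced dispersion grid, then refines
#' the optimum locally with [stats::optimize()]. Optional tagwise estimates
#' shrink each gene's profile likelihood toward the common curve with a prior
#' weight expressed in pseudo-genes.
#'
#' @param cm a [count_matrix()]. Genes with zero total count are excluded from
#'   estimation.
#' @param tagwise also return per-gene shrunken estimates.
#' @param prior_n shrinkage weight (pseudo-genes) for tagwise estimates.
#' @param grid dispersion grid searched before local refinement.
#' @return list with `common` (scalar) and, if requested, `tagwise`
#'   (per retained gene, named).
#' @export
estimate_dispersion <- function(cm, tagwise = FALSE, prior_n = 10,
                                grid = 10^seq(-4, log10(4), length.out = 25)) {
  stopifnot(inherits(cm, "count_matrix"))
  Y <- cm$counts[rowSums(cm$counts) > 0, , drop = FALSE]
  if (nrow(Y) == 0) stop("all-zero count matrix: nothing to estimate")
  offset <- cm$library_size
  cond <- cm$condition

  ll_grid <- matrix(vapply(grid, function(a)
    .nb_profile_ll(Y, offset, cond, a), numeric(nrow(Y))), nrow = nrow(Y))
  tot <- colSums(ll_grid)
  i <- which.max(tot)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(a)
    sum(.nb_profile_ll(Y, offset, cond, a)), c(lo, hi), maximum = TRUE,
    tol = 1e-6)
  common <- if (opt$objective >= tot[i]) opt$maximum else grid[i]
  out <- list(common = common)
  if (tagwise) {
    shrunk <- ll_grid + prior_n * matrix(tot / nrow(Y), nrow(Y),
                                         length(grid), byrow = TRUE)
    out$tagwise <- stats::setNames(grid[max.col(shrunk)], rownames(Y))
  }
  out
}

#' Negative-binomial likelihood-ratio test for two-group count data
#'
#' Per gene, fits the NB model with a separate mean per condition (full) and a
#' single mean (null), both with log link and library-size offsets, and refers
#' `2 (l_full - l_null)` to chi-square with 1 df. The log2 fold change is the
#' difference of fitted group log-means (offset-normalised), second condition
#' level minus the first. Genes with zero counts everywhere get `p = 1`,
#' `log2fc = 0`.
#'
#' @param cm a [count_matrix()].
#' @param dispersion scalar common dispersion or a per-gene vector named by
#'   feature (e.g. from [estimate_dispersion()]).
#' @return a data frame of differential records: `feature_id`, `layer`
#'   (`"rna"`), `log2fc`, `p`, `fdr` (NA; fill with [adjust_bh()]), `passes`
#'   (NA; fill with [call_rna_degs()]).
#' @export
nb_lrt <- function(cm, dispersion) {
  stopifnot(inherits(cm, "count_matrix"))
  Y <- cm$counts
  offset <- cm$library_size
  cond <- cm$condition
  if (is.list(dispersion)) dispersion <- dispersion$common
  disp <- if (length(dispersion) == 1L) dispersion
          else dispersion[rownames(Y)]
  if (anyNA(disp)) stop("per-gene dispersion missing for some features")

  j1 <- cond == levels(cond)[1]
  f0 <- .nb_fit_one_group(Y, offset, disp)
  f1 <- .nb_fit_one_group(Y[, j1, drop = FALSE], offset[j1], disp)
  f2 <- .nb_fit_one_group(Y[, !j1, drop = FALSE], offset[!j1], disp)

  lrt <- pmax(0, 2 * (f1$loglik + f2$loglik - f0$loglik))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  log2fc <- (f2$beta - f1$beta) / log(2)
  zero <- rowSums(Y) == 0
  p[zero] <- 1; log2fc[zero] <- 0
  # one group all-zero, the other not: lfc is +/-Inf; keep the sign but cap
  log2fc[is.infinite(log2fc)] <- sign(log2fc[is.infinite(log2fc)]) * 30
  log2fc[is.nan(log2fc)] <- 0
  .diff_record(rownames(Y), "rna", log2fc, p)
}

#' Benjamini-Hochberg adjustment with NaN passthrough
#'
#' Step-up adjusted values over the non-missing p-values (`m` = number of
#' finite entries); NA/NaN inputs are returned as NA.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call transcript-level differential expression
#'
#' Retains records with `|log2fc| >=` the transcript fold-change threshold and
#' BH FDR at or below the FDR threshold (boundaries inclusive), and partitions
#' them by sign.
#'
#' @param records differential records carrying `fdr` (see [nb_lrt()] +
#'   [adjust_bh()]).
#' @param thresholds a [de_thresholds()].
#' @return `records` with `passes` filled; attributes `up` and `down` hold the
#'   passing feature ids by sign.
#' @export
call_rna_degs <- function(records, thresholds = de_thresholds()) {
  if (anyNA(records$fdr) && all(is.na(records$fdr)))
    stop("records carry no FDR; run adjust_bh() first")
  pass <- !is.na(records$fdr) &
    abs(records$log2fc) >= thresholds$rna_lfc &
    records$fdr <= thresholds$rna_fdr
  records$passes <- pass
  structure(records,
            up = records$feature_id[pass & records$log2fc > 0],
            down = records$feature_id[pass & records$log2fc < 0])
}
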