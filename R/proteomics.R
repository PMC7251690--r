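#' Protein inference filter parameters
#'
#' A protein is reportable when it has at least `min_peptides` distinct
#' peptides with ion score strictly greater than `min_score` — the standard
#' two-peptide rule used for iTRAQ discovery runs.
#'
#' @param min_peptides minimum distinct qualifying peptides (default 2).
#' @param min_score ion-score bar, strict `>` (default 20).
#' @return a `protein_inference_params` list.
#' @export
protein_inference_params <- function(min_peptides = 2, min_score = 20) {
  if (min_peptides < 1) stop("'min_peptides' must be >= 1")
  structure(list(min_peptides = min_peptides, min_score = min_score),
            class = "protein_inference_params")
}

#' Reportable proteins under the two-peptide rule
#'
#' @param qt a [quant_table()] of peptide rows.
#' @param params a [protein_inference_params()].
#' @return character vector of reportable protein ids (sorted).
#' @export
infer_reportable_proteins <- function(qt, params = protein_inference_params()) {
  stopifnot(inherits(qt, "quant_table"))
  if (nrow(qt) == 0) return(character(0))
  ok <- !is.na(qt$ion_score) & qt$ion_score > params$min_score
  # distinct peptides: unique (protein, sequence) pairs among qualifying rows
  hits <- unique(data.frame(protein = qt$protein_id[ok],
                            pep = qt$peptide_seq[ok]))
  n <- table(hits$protein)
  sort(names(n)[n >= params$min_peptides])
}

# Two-sample pooled-variance (classic Student) t-test on two numeric vectors.
# Degenerate zero-variance groups are handled explicitly: p = 1 when the means
# agree, an epsilon above zero (flagged) when they differ.
.pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  d <- mean(x) - mean(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 < .Machine$double.eps) {
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else .Machine$double.xmin,
                df = df, degenerate = TRUE))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

.split_channels <- function(qt) {
  cond <- attr(qt, "condition")
  ch <- attr(qt, "channels")
  lev <- levels(cond)
  list(ref = ch[cond == lev[1]], trt = ch[cond == lev[2]])
}

#' Differential protein abundance by Student's t-test
#'
#' Rolls peptide rows up to the protein level (per channel, the unweighted
#' mean — or median — of the protein's unmodified peptide intensities), then
#' applies a two-sample equal-variance t-test per protein. `log2fc` is
#' treatment mean minus reference mean (flight minus ground).
#'
#' @param qt a [quant_table()].
#' @param params a [protein_inference_params()]; only reportable proteins are
#'   tested.
#' @param rollup `"mean"` (default) or `"median"` peptide-to-protein summary.
#' @return differential records with `layer` set to the fraction tag.
#' @export
protein_ttest <- function(qt, params = protein_inference_params(),
                          rollup = c("mean", "median")) {
  stopifnot(inherits(qt, "quant_table"))
  rollup <- match.arg(rollup)
  agg <- if (rollup == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  keep <- infer_reportable_proteins(qt, params)
  ch <- .split_channels(qt)
  if (length(ch$ref) < 2 || length(ch$trt) < 2)
    stop("at least 2 channels per condition are required")
  unmod <- qt[qt$modification == "none" & qt$protein_id %in% keep, ]
  if (nrow(unmod) == 0)
    return(.diff_record(character(0), attr(qt, "fraction"),
                        numeric(0), numeric(0)))
  res <- lapply(split(seq_len(nrow(unmod)), unmod$protein_id), function(i) {
    prof <- agg(as.matrix(unmod[i, c(ch$ref, ch$trt), drop = FALSE]))
    tt <- .pooled_t(prof[ch$trt], prof[ch$ref])
    c(lfc = mean(prof[ch$trt]) - mean(prof[ch$ref]), p = tt$p)
  })
  ids <- names(res)
  res <- do.call(rbind, res)
  .diff_record(ids, attr(qt, "fraction"), res[, "lfc"], res[, "p"])
}

#' Call differentially abundant proteins
#'
#' Retains records with `|log2fc| >= 0.2` and `p <= 0.05` (defaults,
#' boundaries inclusive), partitioned by fraction and sign.
#'
#' @param records output of [protein_ttest()] (one or more fractions bound
#'   together).
#' @param thresholds a [de_thresholds()].
#' @return `records` with `passes` filled; attributes `up`/`down` list passing
#'   feature ids by sign.
#' @export
call_daps <- function(records, thresholds = de_thresholds()) {
  pass <- !is.na(records$p) &
    abs(records$log2fc) >= thresholds$protein_lfc &
    records$p <= thresholds$protein_p
  records$passes <- pass
  structure(records,
            up = records$feature_id[pass & records$log2fc > 0],
            down = records$feature_id[pass & records$log2fc < 0])
}

#' Peptide-level differential testing of post-translational modifications
#'
#' Applies the same pooled-variance t machinery to each modified peptide row
#' individually, at the relaxed threshold `p <= alpha` (default 0.1, chosen to
#' permit PTM detection without phosphoenrichment). Rows with fewer than two
#' channels per condition are skipped with a message.
#'
#' @param qt a [quant_table()].
#' @param alpha decision threshold on the peptide p-value.
#' @param modifications which modification labels to test.
#' @return data frame with one row per tested peptide: `protein_id`,
#'   `peptide_seq`, `modification`, `site`, `fraction`, `log2fc`, `p`,
#'   `passes`.
#' @export
ptm_differential <- function(qt, alpha = 0.1,
                             modifications = c("phospho", "oxidation",
                                               "deamidation")) {
  stopifnot(inherits(qt, "quant_table"))
  ch <- .split_channels(qt)
  rows <- which(qt$modification %in% modifications)
  if (length(ch$ref) < 2 || length(ch$trt) < 2) {
    message("ptm_differential: <2 channels per condition; no rows tested")
    rows <- integer(0)
  }
  out <- lapply(rows, function(i) {
    x <- as.numeric(unlist(qt[i, ch$trt]))
    y <- as.numeric(unlist(qt[i, ch$ref]))
    tt <- .pooled_t(x, y)
    data.frame(protein_id = qt$protein_id[i], peptide_seq = qt$peptide_seq[i],
               modification = qt$modification[i], site = qt$site[i],
               fraction = attr(qt, "fraction"),
               log2fc = mean(x) - mean(y), p = tt$p,
               passes = tt$p <= alpha, stringsAsFactors = FALSE)
  })
  if (length(out) == 0)
    return(data.frame(protein_id = character(0), peptide_seq = character(0),
                      modification = character(0), site = character(0),
                      fraction = character(0), log2fc = numeric(0),
                      p = numeric(0), passes = logical(0)))
  do.call(rbind, out)
}

#' Oxidation-prevalence summary for one fraction
#'
#' Tests every oxidized peptide's channel intensities (flight vs ground,
#' pooled t) and reports how many were tested, how many reached `p <= 0.05`,
#' and — among the significant ones — the fraction more prevalent in flight.
#' By default the oxidized peptide's own abundance is tested; `ratio = TRUE`
#' instead tests its log2 ratio to the mean of the protein's unmodified
#' peptides (when available), normalising out protein-level shifts.
#'
#' @param qt a [quant_table()].
#' @param alpha significance threshold (default 0.05).
#' @param ratio test oxidized/unmodified log2 ratios instead of raw abundance.
#' @return list: `fraction`, `n_oxidized_tested`, `n_significant`,
#'   `fraction_increased` (NaN when nothing is significant).
#' @export
oxidation_prevalence_summary <- function(qt, alpha = 0.05, ratio = FALSE) {
  stopifnot(inherits(qt, "quant_table"))
  ch <- .split_channels(qt)
  ox <- which(qt$modification == "oxidation")
  if (length(ox) == 0)
    return(list(fraction = attr(qt, "fraction"), n_oxidized_tested = 0L,
                n_significant = 0L, fraction_increased = NaN))
  chans <- c(ch$ref, ch$trt)
  base <- NULL
  if (ratio) {
    unmod <- qt[qt$modification == "none", ]
    base <- rowsum(as.matrix(unmod[, chans]), unmod$protein_id) /
      as.vector(table(unmod$protein_id)[sort(unique(unmod$protein_id))])
  }
  res <- vapply(ox, function(i) {
    v <- as.numeric(unlist(qt[i, chans]))
    if (ratio && qt$protein_id[i] %in% rownames(base))
      v <- v - as.numeric(base[qt$protein_id[i], ])
    names(v) <- chans
    tt <- .pooled_t(v[ch$trt], v[ch$ref])
    c(lfc = mean(v[ch$trt]) - mean(v[ch$ref]), p = tt$p)
  }, c(lfc = 0, p = 0))
  sig <- res["p", ] <= alpha
  list(fraction = attr(qt, "fraction"),
       n_oxidized_tested = length(ox),
       n_significant = sum(sig),
       fraction_increased = if (any(sig)) mean(res["lfc", sig] > 0) else NaN)
}
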