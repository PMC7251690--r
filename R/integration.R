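#' Specification of a two-list overlap against a finite genome
#'
#' @param N genome size (default 27000, the working estimate for the
#'   Arabidopsis gene universe).
#' @param k number of candidates in the first list (transcripts).
#' @param n number of candidates in the second list (proteins).
#' @param x observed overlap.
#' @return validated `overlap_spec` list.
#' @export
overlap_spec <- function(N = 27000, k, n, x) {
  v <- c(N = N, k = k, n = n, x = x)
  if (any(v != round(v)) || any(v < 0)) stop("N, k, n, x must be non-negative integers")
  if (x > min(k, n) || max(k, n) > N)
    stop("infeasible overlap: need 0 <= x <= min(k, n) <= N")
  structure(as.list(v), class = "overlap_spec")
}

#' Intersection of transcript and protein candidate lists
#'
#' Protein ids may be supplied per fraction; duplicates are collapsed before
#' the exact set intersection.
#'
#' @param rna_ids character vector of transcript-passing loci.
#' @param protein_ids character vector (or list of vectors, one per fraction)
#'   of protein-passing loci.
#' @return sorted character vector of overlapping loci.
#' @export
intersect_layers <- function(rna_ids, protein_ids) {
  if (is.list(protein_ids)) protein_ids <- unlist(protein_ids)
  sort(intersect(unique(rna_ids), unique(protein_ids)))
}

#' Sign-concordance classification of cross-layer candidates
#'
#' Each overlapping locus is classified `concordant` when its transcript and
#' protein log2FCs share a sign and `discordant` otherwise. The protein value
#' comes from whichever fraction quantified the locus; when both fractions did,
#' the one with the smaller p-value is used.
#'
#' @param records data frame with columns `feature_id`, `rna_log2fc`, and
#'   per-fraction pairs `membrane_log2fc`/`membrane_p`,
#'   `soluble_log2fc`/`soluble_p` (NA where not quantified).
#' @return `records` with added `protein_log2fc`, `fraction_used`, `class`.
#' @export
classify_concordance <- function(records) {
  pick <- function(i) {
    mp <- records$membrane_p[i]; sp <- records$soluble_p[i]
    if (!is.na(mp) && (is.na(sp) || mp <= sp)) {
      c(records$membrane_log2fc[i], "membrane")
    } else if (!is.na(sp)) {
      c(records$soluble_log2fc[i], "soluble")
    } else stop("locus ", records$feature_id[i],
                " has no protein quantification")
  }
  sel <- t(vapply(seq_len(nrow(records)), pick, character(2)))
  records$protein_log2fc <- as.numeric(sel[, 1])
  records$fraction_used <- sel[, 2]
  if (any(records$rna_log2fc == 0 | records$protein_log2fc == 0))
    stop("zero log2FC cannot be sign-classified")
  records$class <- ifelse(sign(records$rna_log2fc) ==
                            sign(records$protein_log2fc),
                          "concordant", "discordant")
  records
}

.lhyper_point <- function(N, k, n, x) {
  lchoose(k, x) + lchoose(N - k, n - x) - lchoose(N, n)
}

#' Hypergeometric point probability of an observed overlap
#'
#' Exact point mass `P(X = x) = C(k, x) C(N - k, n - x) / C(N, n)`, computed
#' in log-gamma space. This is the statistic used to score the
#' transcript/protein overlap; see [hypergeometric_upper_tail()] for the
#' conventional enrichment tail.
#'
#' @param spec an [overlap_spec()].
#' @return the point probability.
#' @export
hypergeometric_point_probability <- function(spec) {
  stopifnot(inherits(spec, "overlap_spec"))
  if (spec$x < max(0, spec$n + spec$k - spec$N)) return(0)
  exp(.lhyper_point(spec$N, spec$k, spec$n, spec$x))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= x)` by summation of point masses over the feasible support;
#' equals 1 at `x <= max(0, n + k - N)`. This is the conventional
#' over-representation statistic and the kernel shared with the GO enrichment
#' stage.
#'
#' @param spec an [overlap_spec()].
#' @return the upper-tail probability.
#' @export
hypergeometric_upper_tail <- function(spec) {
  stopifnot(inherits(spec, "overlap_spec"))
  support <- seq(max(spec$x, spec$n + spec$k - spec$N, 0), min(spec$n, spec$k))
  min(1, sum(exp(.lhyper_point(spec$N, spec$k, spec$n, support))))
}

#' Cross-layer overlap report
#'
#' Convenience wrapper: intersects the candidate lists, classifies
#' concordance, and scores the overlap with both hypergeometric modes.
#'
#' @param rna_records transcript records with `passes` filled.
#' @param protein_records protein records (all fractions bound) with `passes`
#'   filled.
#' @param N genome size for the overlap test.
#' @param mode `"point"` (the reported statistic) or `"tail"`.
#' @return list with `overlap` (classified records), and a `summary` list
#'   (k, n, x, x_concordant, p_point, p_tail, p_point_concordant,
#'   p_tail_concordant).
#' @export
overlap_report <- function(rna_records, protein_records, N = 27000,
                           mode = c("point", "tail")) {
  mode <- match.arg(mode)
  rna_pass <- rna_records[rna_records$passes, ]
  prot_pass <- protein_records[protein_records$passes, ]
  ids <- intersect_layers(rna_pass$feature_id, prot_pass$feature_id)
  rec <- data.frame(feature_id = ids,
                    rna_log2fc = rna_pass$log2fc[match(ids, rna_pass$feature_id)],
                    stringsAsFactors = FALSE)
  for (fr in c("membrane", "soluble")) {
    sub <- prot_pass[prot_pass$layer == fr, ]
    m <- match(ids, sub$feature_id)
    rec[[paste0(fr, "_log2fc")]] <- sub$log2fc[m]
    rec[[paste0(fr, "_p")]] <- sub$p[m]
  }
  k <- length(unique(rna_pass$feature_id))
  n <- length(unique(prot_pass$feature_id))
  x <- length(ids)
  if (x > 0) rec <- classify_concordance(rec)
  xc <- if (x > 0) sum(rec$class == "concordant") else 0L
  pfun <- function(xx) list(
    point = hypergeometric_point_probability(overlap_spec(N, k, n, xx)),
    tail = hypergeometric_upper_tail(overlap_spec(N, k, n, xx)))
  p_all <- pfun(x); p_con <- pfun(xc)
  list(overlap = rec,
       summary = list(N = N, k = k, n = n, x = x, x_concordant = xc,
                      mode = mode,
                      p_point = p_all$point, p_tail = p_all$tail,
                      p_point_concordant = p_con$point,
                      p_tail_concordant = p_con$tail))
}
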