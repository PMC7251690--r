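#' Curated summary tables from the BRIC-20 spaceflight experiment
#'
#' Small tables transcribed from the published summary of the BRIC-20
#' Arabidopsis experiment (deposited as GeneLab Data Set GLDS-38): the 17 loci
#' significant in both the transcript and protein layers (with per-fraction
#' protein p and log2FC, transcript log2FC and FDR), the 16 differentially
#' phosphorylated peptides, and the 8 extracellular-localized soluble proteins
#' downregulated in flight. They serve as worked examples and regression
#' fixtures; the full per-gene data require the GLDS-38 deposit and do not
#' ship with the package.
#'
#' @return a data frame.
#' @export
bric20_cross_omics <- function() {
  .read_tsv(system.file("extdata", "bric20_cross_omics.tsv",
                        package = "bricomics"))
}

#' @rdname bric20_cross_omics
#' @export
bric20_phosphopeptides <- function() {
  .read_tsv(system.file("extdata", "bric20_phosphopeptides.tsv",
                        package = "bricomics"))
}

#' @rdname bric20_cross_omics
#' @export
bric20_extracellular <- function() {
  .read_tsv(system.file("extdata", "bric20_extracellular_soluble_down.tsv",
                        package = "bricomics"))
}

#' Differential records from the curated cross-omics table
#'
#' Reshapes [bric20_cross_omics()] into the standard differential-record
#' layout: one transcript record per locus (log2fc + FDR) and one protein
#' record per quantified fraction (log2fc + p), ready for [call_rna_degs()],
#' [call_daps()] and [overlap_report()].
#'
#' @param tab the cross-omics table (defaults to the packaged fixture).
#' @return list with `rna` and `protein` record data frames.
#' @export
cross_omics_records <- function(tab = bric20_cross_omics()) {
  rna <- .diff_record(tab$tair_id, "rna", tab$gene_log2fc, NA_real_,
                      fdr = tab$gene_fdr)
  prot <- do.call(rbind, lapply(c("membrane", "soluble"), function(fr) {
    p <- tab[[paste0(fr, "_p")]]
    keep <- !is.na(p)
    .diff_record(tab$tair_id[keep], fr, tab[[paste0(fr, "_log2fc")]][keep],
                 p[keep])
  }))
  list(rna = rna, protein = prot)
}

#' Recompute the headline cross-omics results from the curated tables
#'
#' Runs the package's own decision rules and statistics over the packaged
#' fixtures: transcript calls (`|log2FC| >= 1`, FDR <= 0.05), protein calls
#' (`|log2FC| >= 0.2`, p <= 0.05), the layer intersection, sign-concordance
#' classification, the hypergeometric point probabilities of the concordant
#' and total overlaps at the published list sizes, the phosphopeptide count,
#' and the extracellular soluble-down localization tally.
#'
#' @param N genome size; `k`, `n` transcript/protein candidate list sizes for
#'   the overlap test (defaults: 27000, 968 transcripts, 210 proteins = 107
#'   soluble + 103 membrane).
#' @param thresholds a [de_thresholds()].
#' @return named list of the recomputed quantities.
#' @export
published_tables_summary <- function(N = 27000, k = 968, n = 210,
                                     thresholds = de_thresholds()) {
  recs <- cross_omics_records()
  rna <- call_rna_degs(recs$rna, thresholds)
  prot <- call_daps(recs$protein, thresholds)
  report <- overlap_report(rna, prot, N = N)
  ov <- report$overlap
  x <- nrow(ov)
  xc <- sum(ov$class == "concordant")
  phos <- bric20_phosphopeptides()
  extra <- bric20_extracellular()
  loc <- assign_localizations(extra$tair_id,
                              data.frame(feature_id = extra$tair_id,
                                         location = extra$location))
  list(
    overlap_loci = x,
    concordant = xc,
    discordant = x - xc,
    p_point_concordant =
      hypergeometric_point_probability(overlap_spec(N, k, n, xc)),
    p_point_all =
      hypergeometric_point_probability(overlap_spec(N, k, n, x)),
    phosphopeptide_count = nrow(phos),
    extracellular_soluble_down =
      sum(loc$assignments$location == "extracellular")
  )
}
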