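#' Transcript count matrix with a two-condition design
#'
#' A light container for gene-level read counts: an integer matrix
#' (features x samples), a condition label per sample (exactly two levels),
#' and per-sample library sizes (column sums unless overridden).
#'
#' @param counts non-negative integer matrix, features in rows. Row names are
#'   feature ids; generated when absent.
#' @param condition character/factor of length `ncol(counts)` with exactly two
#'   levels. The FIRST level (alphabetical unless a factor is supplied) is the
#'   reference; log2 fold changes downstream are second level minus reference.
#' @param library_size optional positive per-sample totals.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, library_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(condition) != ncol(counts))
    stop("one condition label per sample is required")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("exactly two condition levels are required")
  if (any(table(condition) < 2L))
    stop("at least 2 samples per condition are required")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts, condition = condition,
                 library_size = as.numeric(library_size)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$condition),
                            tabulate(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Drop features below a counts-per-million floor
#'
#' Removes features whose CPM is below `min_cpm` in every sample — the
#' standard low-count guard applied before dispersion estimation.
#'
#' @param cm a [count_matrix()].
#' @param min_cpm CPM floor (default 1).
#' @return a filtered `count_matrix`.
#' @export
filter_low_counts <- function(cm, min_cpm = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  cpm <- t(t(cm$counts) / cm$library_size) * 1e6
  keep <- apply(cpm, 1, max) >= min_cpm
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition, cm$library_size)
}

#' Peptide/protein quantification table (iTRAQ-style)
#'
#' Rows are peptide (or protein-level) observations with identification
#' metadata and one log2 intensity column per channel; a channel-to-condition
#' map and a fraction tag ride along as attributes.
#'
#' @param data data frame with columns `protein_id`, `peptide_seq`,
#'   `modification` (one of none/phospho/oxidation/deamidation), `site`,
#'   `ion_score`, followed by one numeric log2-intensity column per channel.
#' @param condition condition label per channel (two levels; first level is
#'   the reference).
#' @param fraction `"membrane"` or `"soluble"`.
#' @return an object of class `quant_table` (a data frame).
#' @export
quant_table <- function(data, condition, fraction = c("membrane", "soluble")) {
  fraction <- match.arg(fraction)
  meta <- c("protein_id", "peptide_seq", "modification", "site", "ion_score")
  if (!all(meta %in% names(data)))
    stop("missing required columns: ",
         paste(setdiff(meta, names(data)), collapse = ", "))
  channels <- setdiff(names(data), meta)
  if (length(condition) != length(channels))
    stop("every channel must be mapped to exactly one condition")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two condition levels required")
  if (any(!is.na(data$ion_score) & data$ion_score < 0))
    stop("ion scores must be >= 0")
  bad <- !data$modification %in% c("none", "phospho", "oxidation", "deamidation")
  if (any(bad)) stop("unknown modification label: ",
                     paste(unique(data$modification[bad]), collapse = ", "))
  structure(data, class = c("quant_table", "data.frame"),
            channels = channels, condition = condition, fraction = fraction)
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table (%s fraction): %d rows, %d proteins, %d channels\n",
              attr(x, "fraction"), nrow(x), length(unique(x$protein_id)),
              length(attr(x, "channels"))))
  invisible(x)
}

#' Default decision thresholds for each omics layer
#'
#' Transcripts: `|log2FC| >= 1` and BH FDR `<= 0.05`. Proteins:
#' `|log2FC| >= 0.2` and `p <= 0.05`. Modified peptides: `p <= 0.1` (relaxed
#' to permit PTM detection without phosphoenrichment). All boundaries
#' inclusive.
#'
#' @param rna_lfc,rna_fdr,protein_lfc,protein_p,ptm_p threshold overrides.
#' @return a `de_thresholds` list.
#' @export
de_thresholds <- function(rna_lfc = 1, rna_fdr = 0.05,
                          protein_lfc = 0.2, protein_p = 0.05, ptm_p = 0.1) {
  th <- list(rna_lfc = rna_lfc, rna_fdr = rna_fdr, protein_lfc = protein_lfc,
             protein_p = protein_p, ptm_p = ptm_p)
  if (any(unlist(th) <= 0)) stop("thresholds must be strictly positive")
  class(th) <- "de_thresholds"
  th
}

.diff_record <- function(feature_id, layer, log2fc, p, fdr = NA_real_,
                         passes = NA) {
  data.frame(feature_id = feature_id, layer = layer, log2fc = log2fc,
             p = p, fdr = fdr, passes = passes, stringsAsFactors = FALSE)
}

## --- TSV dialects -----------------------------------------------------------

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a count matrix as TSV
#'
#' The counts go to `<path>` (feature_id column + one column per sample) and
#' the condition map to `<path>.conditions.tsv` (sample_id, condition).
#'
#' @param cm a [count_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  .write_tsv(data.frame(feature_id = rownames(cm$counts), cm$counts,
                        check.names = FALSE), path)
  .write_tsv(data.frame(sample_id = colnames(cm$counts),
                        condition = as.character(cm$condition),
                        is_reference = cm$condition == levels(cm$condition)[1]),
             paste0(path, ".conditions.tsv"))
  invisible(path)
}

.condition_factor <- function(condition, is_reference) {
  ref <- unique(condition[as.logical(is_reference)])
  factor(condition, levels = c(ref, setdiff(unique(condition), ref)))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  tab <- .read_tsv(path)
  cond <- .read_tsv(paste0(path, ".conditions.tsv"))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$feature_id
  ord <- match(colnames(m), cond$sample_id)
  count_matrix(m, .condition_factor(cond$condition, cond$is_reference)[ord])
}

#' Write / read a quantification table as TSV
#'
#' Columns: protein_id, peptide_seq, modification, site, ion_score, then one
#' log2-intensity column per channel. The channel map goes to
#' `<path>.channels.tsv` (channel, condition, fraction).
#'
#' @param qt a [quant_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qt, path) {
  stopifnot(inherits(qt, "quant_table"))
  .write_tsv(as.data.frame(qt), path)
  cond <- attr(qt, "condition")
  .write_tsv(data.frame(channel = attr(qt, "channels"),
                        condition = as.character(cond),
                        is_reference = cond == levels(cond)[1],
                        fraction = attr(qt, "fraction")),
             paste0(path, ".channels.tsv"))
  invisible(path)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  tab <- .read_tsv(path)
  ch <- .read_tsv(paste0(path, ".channels.tsv"))
  quant_table(tab, condition = .condition_factor(ch$condition, ch$is_reference),
              fraction = ch$fraction[1])
}

#' Read a control-study differential table
#'
#' Expected columns: feature_id, log2fc, significant (logical).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_control_study <- function(path) {
  tab <- .read_tsv(path)
  need <- c("feature_id", "log2fc", "significant")
  if (!all(need %in% names(tab)))
    stop("control study table must have columns: ",
         paste(need, collapse = ", "))
  tab$significant <- as.logical(tab$significant)
  tab
}
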