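#' Control-study decision rule for spaceflight candidates
#'
#' A candidate that was also significant in a hardware or preservative control
#' study is retained only when its spaceflight perturbation is different from,
#' or larger than, its perturbation in that control:
#'
#' `(|lfc_sf - lfc_control| > |lfc_control|)  OR  (|lfc_sf| > |lfc_control|)`
#'
#' The first disjunct is the absolute range of the two fold changes
#' (`max - min`); both inequalities are strict, so a gene perturbed
#' identically by the control is excluded. The rule is scale invariant:
#' multiplying both arguments by a positive constant never changes the
#' decision.
#'
#' @param lfc_sf log2FC in the spaceflight/ground comparison (vectorised).
#' @param lfc_control log2FC in the control study where the feature was
#'   significant.
#' @return logical: retain the candidate?
#' @export
passes_decision_rule <- function(lfc_sf, lfc_control) {
  if (any(!is.finite(lfc_sf)) || any(!is.finite(lfc_control)))
    stop("log2 fold changes must be finite")
  (abs(lfc_sf - lfc_control) > abs(lfc_control)) |
    (abs(lfc_sf) > abs(lfc_control))
}

#' Screen candidates against one or more control studies
#'
#' A candidate significant in one or several control studies is retained iff
#' [passes_decision_rule()] holds for EVERY control study in which it was
#' significant (conjunction); candidates absent from all control significance
#' lists pass unconditionally. Every evaluation is recorded in an audit table.
#'
#' @param sf_records differential records of the spaceflight comparison
#'   (`feature_id`, `log2fc`, ...); typically the passing subset of a layer.
#' @param controls named list of control-study data frames with columns
#'   `feature_id`, `log2fc`, `significant` (see [read_control_study()]).
#' @return list with `retained` (subset of `sf_records`), `excluded`, and
#'   `audit` (feature_id, control, lfc_sf, lfc_control, passes).
#' @export
filter_candidates <- function(sf_records, controls) {
  if (is.null(names(controls)) || any(names(controls) == ""))
    stop("'controls' must be a named list of control studies")
  evals <- lapply(names(controls), function(nm) {
    ctl <- controls[[nm]]
    sig <- ctl[ctl$significant, c("feature_id", "log2fc")]
    if (anyDuplicated(sig$feature_id))
      stop(sprintf("duplicate feature rows in control study '%s'", nm))
    hit <- merge(sf_records[, c("feature_id", "log2fc")], sig,
                 by = "feature_id", suffixes = c("_sf", "_control"))
    if (nrow(hit) == 0) return(NULL)
    data.frame(feature_id = hit$feature_id, control = nm,
               lfc_sf = hit$log2fc_sf, lfc_control = hit$log2fc_control,
               passes = passes_decision_rule(hit$log2fc_sf,
                                             hit$log2fc_control),
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, evals)
  if (is.null(audit))
    audit <- data.frame(feature_id = character(0), control = character(0),
                        lfc_sf = numeric(0), lfc_control = numeric(0),
                        passes = logical(0))
  failed <- unique(audit$feature_id[!audit$passes])
  keep <- !sf_records$feature_id %in% failed
  list(retained = sf_records[keep, , drop = FALSE],
       excluded = sf_records[!keep, , drop = FALSE],
       audit = audit[order(audit$feature_id, audit$control), , drop = FALSE])
}
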