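#' Synthetic ontology and annotation scaffolding
#'
#' A small randomly shaped but seed-deterministic biological_process DAG plus
#' random gene-to-term annotations, used when a pipeline run has no real OBO /
#' annotation inputs. Purely synthetic test scaffolding: term names are
#' placeholders and annotations carry no biology.
#'
#' @param n_terms number of non-root terms.
#' @param n_branches direct children of the root.
#' @param seed RNG seed.
#' @return list with `ontology` (as from [load_obo()]) and `obo_path` (the
#'   generated file).
#' @export
synthetic_ontology <- function(n_terms = 30, n_branches = 3, seed = 1L) {
  set.seed(seed)
  ids <- c("GO:0000000", sprintf("GO:%07d", seq_len(n_terms)))
  parents <- vector("list", length(ids))
  for (i in seq_along(ids)[-1]) {
    pool <- if (i <= n_branches + 1) 1L else sample(2:(i - 1), 1)
    parents[[i]] <- unique(c(pool,
      if (i > n_branches + 2 && stats::runif(1) < 0.2) sample(2:(i - 1), 1)))
  }
  path <- tempfile(fileext = ".obo")
  con <- file(path, "w")
  writeLines("format-version: 1.2", con)
  for (i in seq_along(ids)) {
    writeLines(c("", "[Term]", paste0("id: ", ids[i]),
                 paste0("name: synthetic term ", i - 1),
                 "namespace: biological_process",
                 sprintf("is_a: %s ! parent", ids[parents[[i]]])), con)
  }
  close(con)
  list(ontology = load_obo(path), obo_path = path)
}

#' @rdname synthetic_ontology
#' @param feature_ids genes to annotate.
#' @param ontology the ontology to annotate against.
#' @param terms_per_gene mean annotations per gene.
#' @export
synthetic_annotations <- function(feature_ids, ontology, terms_per_gene = 2,
                                  seed = 1L) {
  set.seed(seed)
  terms <- setdiff(igraph::V(ontology$graph)$name, ontology$root)
  n <- pmax(1L, stats::rpois(length(feature_ids), terms_per_gene))
  data.frame(gene = rep(feature_ids, n),
             term = sample(terms, sum(n), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_ontology
#' @param locations label vocabulary for synthetic localization tables.
#' @export
synthetic_localizations <- function(feature_ids,
                                    locations = c("plastid", "nucleus",
                                                  "cytosol", "mitochondrion",
                                                  "plasma membrane",
                                                  "extracellular", "vacuole"),
                                    seed = 1L) {
  set.seed(seed)
  data.frame(feature_id = feature_ids,
             location = sample(locations, length(feature_ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param sim a [simulation_config()]; drives every synthetic input layer.
#' @param thresholds a [de_thresholds()].
#' @param inference a [protein_inference_params()].
#' @param overlap_N genome size for the overlap test; `NULL` (default) uses
#'   the simulated gene universe.
#' @param overlap_mode `"point"` (reported statistic) or `"tail"`.
#' @param rollup peptide-to-protein rollup, `"mean"` or `"median"`.
#' @param enrich_alpha,enrich_size Bonferroni level and term-size bounds for
#'   GO thinning.
#' @param obo,annotations,localizations optional paths to an OBO file, a
#'   gene-to-term TSV (columns gene, term) and a localization TSV (columns
#'   feature_id, location); synthetic stand-ins are generated when `NULL`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            thresholds = de_thresholds(),
                            inference = protein_inference_params(),
                            overlap_N = NULL,
                            overlap_mode = c("point", "tail"),
                            rollup = c("mean", "median"),
                            enrich_alpha = 0.05,
                            enrich_size = c(4, 750),
                            obo = NULL, annotations = NULL,
                            localizations = NULL) {
  structure(list(sim = sim, thresholds = thresholds, inference = inference,
                 overlap_N = overlap_N,
                 overlap_mode = match.arg(overlap_mode),
                 rollup = match.arg(rollup),
                 enrich_alpha = enrich_alpha, enrich_size = enrich_size,
                 obo = obo, annotations = annotations,
                 localizations = localizations),
            class = "pipeline_config")
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full multi-omics pipeline on synthetic data
#'
#' simulate -> transcript NB-LRT -> protein/PTM t-tests -> control-study
#' decision rule -> cross-layer overlap and concordance -> GO enrichment with
#' thinning -> localization tabulation. All result tables are written as TSV
#' under `out_dir` together with a machine-readable `run_summary.json`
#' (counts per stage, parameters, seed). Re-running with an identical config
#' reproduces identical outputs. Progress is logged to stderr; any stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the run summary, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  th <- config$thresholds

  sim <- stage("simulate", {
    s <- simulate_counts(config$sim)
    write_count_matrix(s$counts, file.path(out_dir, "counts.tsv"))
    s
  })
  .log_stage("simulate", "%d genes x %d samples", nrow(sim$counts$counts),
             ncol(sim$counts$counts))

  rna <- stage("de-rna", {
    cm <- filter_low_counts(sim$counts)
    disp <- estimate_dispersion(cm)
    rec <- nb_lrt(cm, disp)
    rec$fdr <- adjust_bh(rec$p)
    rec <- call_rna_degs(rec, th)
    .write_tsv(rec, file.path(out_dir, "de_rna.tsv"))
    list(records = rec, dispersion = disp$common)
  })
  .log_stage("de-rna", "%d / %d transcripts pass (dispersion %.3f)",
             sum(rna$records$passes), nrow(rna$records), rna$dispersion)

  prot <- stage("de-protein", {
    layers <- simulate_protein_layers(config$sim, sim$truth)
    peps <- simulate_peptides(config$sim, layers$truth)
    recs <- list(); ptm <- list(); ox <- list()
    for (fr in c("membrane", "soluble")) {
      qt <- peps[[fr]]
      write_quant_table(qt, file.path(out_dir, paste0("peptides_", fr, ".tsv")))
      recs[[fr]] <- protein_ttest(qt, config$inference, config$rollup)
      ptm[[fr]] <- ptm_differential(qt, alpha = th$ptm_p)
      ox[[fr]] <- oxidation_prevalence_summary(qt)
    }
    rec <- call_daps(do.call(rbind, recs), th)
    ptm <- do.call(rbind, ptm)
    .write_tsv(rec, file.path(out_dir, "de_protein.tsv"))
    .write_tsv(ptm, file.path(out_dir, "ptm.tsv"))
    list(records = rec, ptm = ptm, oxidation = ox, truth = peps$truth)
  })
  .log_stage("de-protein", "%d / %d proteins pass; %d PTM peptides pass",
             sum(prot$records$passes), nrow(prot$records),
             sum(prot$ptm$passes))

  ctl <- stage("filter-controls", {
    cs <- simulate_control_studies(config$sim, prot$truth)
    .write_tsv(cs$hardware, file.path(out_dir, "control_hardware.tsv"))
    .write_tsv(cs$preservative, file.path(out_dir, "control_preservative.tsv"))
    controls <- list(hardware = cs$hardware, preservative = cs$preservative)
    rna_pass <- rna$records[rna$records$passes, ]
    prot_pass <- prot$records[prot$records$passes, ]
    frna <- filter_candidates(rna_pass, controls)
    fprot <- filter_candidates(prot_pass, controls)
    .write_tsv(rbind(frna$audit, fprot$audit),
               file.path(out_dir, "control_audit.tsv"))
    .write_tsv(frna$retained, file.path(out_dir, "retained_rna.tsv"))
    .write_tsv(fprot$retained, file.path(out_dir, "retained_protein.tsv"))
    list(rna = frna, protein = fprot)
  })
  .log_stage("filter-controls", "retained %d / %d transcripts, %d / %d proteins",
             nrow(ctl$rna$retained),
             nrow(ctl$rna$retained) + nrow(ctl$rna$excluded),
             nrow(ctl$protein$retained),
             nrow(ctl$protein$retained) + nrow(ctl$protein$excluded))

  integ <- stage("integrate", {
    N <- if (is.null(config$overlap_N)) config$sim$n_genes else config$overlap_N
    report <- overlap_report(ctl$rna$retained, ctl$protein$retained, N = N,
                             mode = config$overlap_mode)
    .write_tsv(report$overlap, file.path(out_dir, "overlap.tsv"))
    report
  })
  .log_stage("integrate", "overlap %d (concordant %d), p_point = %.3g",
             integ$summary$x, integ$summary$x_concordant,
             integ$summary$p_point)

  enr <- stage("enrich", {
    ont <- if (is.null(config$obo))
      synthetic_ontology(seed = .stream_seed(config$sim, "annotation"))$ontology
    else load_obo(config$obo)
    ann <- if (is.null(config$annotations))
      synthetic_annotations(sim$truth$rna$feature_id, ont,
                            seed = .stream_seed(config$sim, "annotation"))
    else .read_tsv(config$annotations)
    background <- sim$truth$rna$feature_id
    out <- list()
    for (dir in c("up", "down")) {
      de <- ctl$rna$retained$feature_id[
        if (dir == "up") ctl$rna$retained$log2fc > 0
        else ctl$rna$retained$log2fc < 0]
      rec <- enrich(de, background, ann, ont)
      rec <- thin_terms(rec, ont, alpha = config$enrich_alpha,
                        size_range = config$enrich_size)
      rec$direction <- rep(dir, nrow(rec))
      out[[dir]] <- rec
    }
    tab <- do.call(rbind, out)
    .write_tsv(tab, file.path(out_dir, "enrichment.tsv"))
    tab
  })
  .log_stage("enrich", "%d terms tested, %d retained", nrow(enr),
             sum(enr$status == "retained"))

  localization <- stage("localize", {
    loc_tab <- if (is.null(config$localizations))
      synthetic_localizations(sim$truth$rna$feature_id,
                              seed = .stream_seed(config$sim, "annotation"))
    else .read_tsv(config$localizations)
    subsets <- list(
      rna_up = ctl$rna$retained$feature_id[ctl$rna$retained$log2fc > 0],
      rna_down = ctl$rna$retained$feature_id[ctl$rna$retained$log2fc < 0],
      protein_up = ctl$protein$retained$feature_id[
        ctl$protein$retained$log2fc > 0],
      protein_down = ctl$protein$retained$feature_id[
        ctl$protein$retained$log2fc < 0])
    dist <- do.call(rbind, lapply(names(subsets), function(nm) {
      d <- assign_localizations(subsets[[nm]], loc_tab)$distribution
      if (nrow(d)) d$subset <- nm
      d
    }))
    .write_tsv(dist, file.path(out_dir, "localization.tsv"))
    dist
  })

  summary <- list(
    seed = config$sim$seed,
    n_genes = config$sim$n_genes,
    dispersion_estimate = rna$dispersion,
    n_rna_pass = sum(rna$records$passes),
    n_protein_pass = sum(prot$records$passes),
    n_ptm_pass = sum(prot$ptm$passes),
    oxidation = prot$oxidation,
    n_rna_retained = nrow(ctl$rna$retained),
    n_protein_retained = nrow(ctl$protein$retained),
    overlap = integ$summary,
    n_terms_retained = sum(enr$status == "retained"),
    thresholds = unclass(config$thresholds)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Validate pipeline input files
#'
#' Schema checks over the TSV dialects consumed by the pipeline: counts are
#' non-negative integers with a complete two-level condition map, quant-table
#' channels are all mapped, control studies carry the required columns.
#' Reports every violation instead of stopping at the first.
#'
#' @param counts,quant_tables,controls optional paths: a count-matrix TSV, a
#'   character vector of quant-table TSVs, a character vector of
#'   control-study TSVs.
#' @return data frame of violations (`input`, `message`); zero rows when all
#'   inputs are well formed.
#' @export
validate_inputs <- function(counts = NULL, quant_tables = NULL,
                            controls = NULL) {
  bad <- list()
  note <- function(input, msg)
    bad[[length(bad) + 1L]] <<- data.frame(input = input, message = msg,
                                           stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    if (!file.exists(counts)) note(counts, "file does not exist")
    else {
      tab <- .read_tsv(counts)
      m <- as.matrix(tab[, -1, drop = FALSE])
      neg <- which(m < 0 | m != round(m), arr.ind = TRUE)
      for (i in seq_len(min(nrow(neg), 20)))
        note(counts, sprintf("non-count entry at row %d ('%s'), column '%s'",
                             neg[i, 1], tab$feature_id[neg[i, 1]],
                             colnames(m)[neg[i, 2]]))
      cpath <- paste0(counts, ".conditions.tsv")
      if (!file.exists(cpath)) note(cpath, "condition map missing")
      else {
        cond <- .read_tsv(cpath)
        missing <- setdiff(colnames(m), cond$sample_id)
        for (s in missing)
          note(cpath, sprintf("sample '%s' missing from condition map", s))
        if (length(unique(cond$condition)) != 2)
          note(cpath, "condition map must have exactly two levels")
      }
    }
  }
  for (q in quant_tables) {
    if (!file.exists(q)) { note(q, "file does not exist"); next }
    tab <- .read_tsv(q)
    meta <- c("protein_id", "peptide_seq", "modification", "site", "ion_score")
    for (col in setdiff(meta, names(tab)))
      note(q, sprintf("required column '%s' missing", col))
    chpath <- paste0(q, ".channels.tsv")
    if (!file.exists(chpath)) { note(chpath, "channel map missing"); next }
    ch <- .read_tsv(chpath)
    for (c0 in setdiff(setdiff(names(tab), meta), ch$channel))
      note(chpath, sprintf("channel '%s' is not mapped to a condition", c0))
  }
  for (ct in controls) {
    if (!file.exists(ct)) { note(ct, "file does not exist"); next }
    tab <- .read_tsv(ct)
    for (col in setdiff(c("feature_id", "log2fc", "significant"), names(tab)))
      note(ct, sprintf("required column '%s' missing", col))
  }
  if (length(bad) == 0)
    return(data.frame(input = character(0), message = character(0)))
  do.call(rbind, bad)
}
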