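#' Parse a Gene Ontology OBO file
#'
#' Minimal reader for `[Term]` stanzas: `id`, `name`, `namespace`, and `is_a`
#' edges (child to parent). Obsolete terms are dropped and all other relation
#' types are ignored. The graph must be acyclic and, within the
#' biological_process namespace, every term must reach the namespace root
#' (the unique BP term without parents).
#'
#' @param path path to an OBO file.
#' @return an `ontology` object: list with `terms` (data frame: id, name,
#'   namespace), `edges` (data frame: child, parent), `root` (BP root id),
#'   and `graph` (an igraph DAG over the BP terms, edges child -> parent).
#' @export
load_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  ends <- c(starts[-1] - 1L, length(lines))
  take <- function(block, key) {
    v <- sub(paste0("^", key, ": "), "",
             grep(paste0("^", key, ": "), block, value = TRUE))
    if (length(v)) v else NA_character_
  }
  recs <- lapply(term_starts, function(s) {
    block <- lines[s:ends[match(s, starts)]]
    list(id = take(block, "id")[1],
         name = take(block, "name")[1],
         namespace = take(block, "namespace")[1],
         obsolete = identical(take(block, "is_obsolete")[1], "true"),
         parents = sub(" !.*$", "", take(block, "is_a")))
  })
  recs <- Filter(function(r) !r$obsolete && !is.na(r$id), recs)
  if (length(recs) == 0) stop("no usable [Term] stanzas in ", path)
  terms <- data.frame(id = vapply(recs, `[[`, "", "id"),
                      name = vapply(recs, `[[`, "", "name"),
                      namespace = vapply(recs, `[[`, "", "namespace"),
                      stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(recs, function(r) {
    p <- r$parents[!is.na(r$parents) & r$parents %in% terms$id]
    if (length(p)) data.frame(child = r$id, parent = p,
                              stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0))
  bp <- terms$id[is.na(terms$namespace) | terms$namespace == "biological_process"]
  g <- igraph::graph_from_data_frame(
    edges[edges$child %in% bp & edges$parent %in% bp, ],
    directed = TRUE, vertices = data.frame(name = bp))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop("ontology contains a cycle among: ", paste(cyc, collapse = ", "))
  }
  roots <- bp[igraph::degree(g, bp, mode = "out") == 0]
  if (length(roots) != 1L)
    stop("expected exactly one biological_process root, found: ",
         paste(roots, collapse = ", "))
  unreachable <- !is.finite(igraph::distances(g, v = bp, to = roots,
                                              mode = "out"))
  if (any(unreachable))
    stop("term(s) cannot reach the namespace root: ",
         paste(bp[unreachable], collapse = ", "))
  structure(list(terms = terms, edges = edges, root = roots, graph = g),
            class = "ontology")
}

#' Shortest is_a distance of each term from the namespace root
#'
#' @param ontology an [load_obo()] object.
#' @return named integer vector of depths (root = 0).
#' @export
term_depths <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  d <- igraph::distances(ontology$graph, to = ontology$root, mode = "out")
  stats::setNames(as.integer(d), rownames(d))
}

#' Propagate gene annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is annotated to all of the term's ancestors.
#' Idempotent; annotations to unknown terms are skipped with a warning.
#'
#' @param annotations data frame with columns `gene`, `term`.
#' @param ontology an [load_obo()] object.
#' @return expanded (and de-duplicated) annotation data frame.
#' @export
propagate_annotations <- function(annotations, ontology) {
  stopifnot(inherits(ontology, "ontology"))
  known <- annotations$term %in% igraph::V(ontology$graph)$name
  if (any(!known)) {
    warning("skipping annotations to unknown term(s): ",
            paste(unique(annotations$term[!known]), collapse = ", "))
    annotations <- annotations[known, , drop = FALSE]
  }
  anc <- lapply(unique(annotations$term), function(t)
    igraph::subcomponent(ontology$graph, t, mode = "out")$name)
  names(anc) <- unique(annotations$term)
  out <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i)
    data.frame(gene = annotations$gene[i], term = anc[[annotations$term[i]]],
               stringsAsFactors = FALSE)))
  out <- unique(out[order(out$gene, out$term), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' GO over-representation of a candidate gene list
#'
#' Per term, an upper-tail hypergeometric test of the candidate hits against
#' the background annotation counts (the same kernel as the cross-omics
#' overlap statistic), Bonferroni-corrected over the number of terms with at
#' least one candidate annotation. Up- and down-regulated lists are meant to
#' be run in separate invocations.
#'
#' @param de_genes candidate gene ids (must be a subset of `background`).
#' @param background all assayed gene ids.
#' @param annotations gene-to-term data frame (columns `gene`, `term`).
#' @param ontology an [load_obo()] object.
#' @param propagate apply the true-path rule before counting (default TRUE).
#' @return data frame of enrichment records: `term`, `name`, `n_de_in_term`,
#'   `n_background_in_term`, `p_raw`, `p_bonferroni`, `depth`, `status`
#'   (`"tested"`); attribute `de_hits` holds the candidate gene set per term.
#' @export
enrich <- function(de_genes, background, annotations, ontology,
                   propagate = TRUE) {
  stopifnot(inherits(ontology, "ontology"))
  if (length(background) == 0) stop("empty background")
  if (!all(de_genes %in% background))
    stop("candidate genes must be a subset of the background")
  if (propagate) annotations <- propagate_annotations(annotations, ontology)
  annotations <- annotations[annotations$gene %in% background, , drop = FALSE]
  bg_by_term <- split(annotations$gene, annotations$term)
  de_by_term <- lapply(bg_by_term, function(g) unique(g[g %in% de_genes]))
  tested <- names(de_by_term)[vapply(de_by_term, length, 0L) > 0]
  m <- length(tested)
  N <- length(unique(background)); n <- length(unique(de_genes))
  depth <- term_depths(ontology)
  recs <- do.call(rbind, lapply(tested, function(t) {
    K <- length(unique(bg_by_term[[t]]))
    x <- length(de_by_term[[t]])
    p <- hypergeometric_upper_tail(overlap_spec(N = N, k = K, n = n, x = x))
    data.frame(term = t,
               name = ontology$terms$name[match(t, ontology$terms$id)],
               n_de_in_term = x, n_background_in_term = K,
               p_raw = p, p_bonferroni = min(1, p * m),
               depth = depth[[t]], status = "tested",
               stringsAsFactors = FALSE)
  }))
  if (is.null(recs))
    recs <- data.frame(term = character(0), name = character(0),
                       n_de_in_term = integer(0),
                       n_background_in_term = integer(0),
                       p_raw = numeric(0), p_bonferroni = numeric(0),
                       depth = integer(0), status = character(0))
  structure(recs[order(recs$p_raw, recs$term), , drop = FALSE],
            de_hits = de_by_term[tested], m_tested = m)
}

#' Thin enrichment results to a concise representative set
#'
#' Applies, in order: (1) Bonferroni `p <= alpha`; (2) background term size
#' within `size_range`; (3) more than one candidate gene in the term;
#' (4) within each branch (the subtree of each direct child of the
#' biological_process root) keep only the two surviving terms of minimal
#' depth, ties broken by smaller p then lexicographic id; (5) among terms with
#' identical candidate gene sets keep only the deepest (most specific). The
#' `status` column records the first rule that dropped each term.
#'
#' @param records output of [enrich()] (carries the per-term candidate sets).
#' @param ontology an [load_obo()] object.
#' @param alpha Bonferroni significance level (default 0.05).
#' @param size_range allowed background term size (default `c(4, 750)`).
#' @param per_branch terms kept per branch (default 2).
#' @return `records` with final `status`: `retained`, `dropped_alpha`,
#'   `dropped_size`, `dropped_hits`, `dropped_depth`, or `dropped_redundant`.
#' @export
thin_terms <- function(records, ontology, alpha = 0.05,
                       size_range = c(4, 750), per_branch = 2) {
  stopifnot(inherits(ontology, "ontology"))
  if (nrow(records) == 0) return(records)
  de_hits <- attr(records, "de_hits")
  status <- rep("retained", nrow(records))

  status[records$p_bonferroni > alpha] <- "dropped_alpha"
  live <- status == "retained"
  bad_size <- records$n_background_in_term < size_range[1] |
    records$n_background_in_term > size_range[2]
  status[live & bad_size] <- "dropped_size"
  live <- status == "retained"
  status[live & records$n_de_in_term < 2] <- "dropped_hits"
  live <- status == "retained"

  # branch membership: which direct children of the root each term descends
  # from (a DAG term can belong to several branches)
  g <- ontology$graph
  branch_roots <- igraph::neighbors(g, ontology$root, mode = "in")$name
  in_branch <- function(term) {
    anc <- igraph::subcomponent(g, term, mode = "out")$name
    branch_roots[branch_roots %in% anc | branch_roots == term]
  }
  if (any(live)) {
    keep_depth <- rep(FALSE, nrow(records))
    membership <- lapply(records$term[live], in_branch)
    for (br in branch_roots) {
      idx <- which(live)[vapply(membership, function(b) br %in% b, TRUE)]
      if (length(idx) == 0) next
      ord <- idx[order(records$depth[idx], records$p_raw[idx],
                       records$term[idx])]
      keep_depth[utils::head(ord, per_branch)] <- TRUE
    }
    # terms in no branch (the root itself) are never retained here
    status[live & !keep_depth] <- "dropped_depth"
    live <- status == "retained"
  }

  if (any(live)) {
    sets <- vapply(records$term[live],
                   function(t) paste(sort(de_hits[[t]]), collapse = "|"), "")
    for (s in unique(sets)) {
      idx <- which(live)[sets == s]
      if (length(idx) < 2) next
      ord <- idx[order(-records$depth[idx], records$p_raw[idx],
                       records$term[idx])]
      status[ord[-1]] <- "dropped_redundant"
    }
  }
  records$status <- status
  records
}

#' Subcellular localization assignment and distribution
#'
#' Labels each feature with its consensus location from a SUBA-style
#' annotation table (features absent from the table become `"unknown"`) and
#' tabulates the distribution per candidate subset for multi-level pie-style
#' reporting.
#'
#' @param feature_ids character vector of candidate loci.
#' @param annotation data frame with columns `feature_id`, `location`
#'   (one consensus label per feature; conflicting duplicates are an error).
#' @return list with `assignments` (feature_id, location) and `distribution`
#'   (location, n, fraction).
#' @export
assign_localizations <- function(feature_ids, annotation) {
  ann <- unique(annotation[, c("feature_id", "location")])
  if (anyDuplicated(ann$feature_id))
    stop("conflicting location labels for: ",
         paste(unique(ann$feature_id[duplicated(ann$feature_id)]),
               collapse = ", "))
  loc <- ann$location[match(feature_ids, ann$feature_id)]
  loc[is.na(loc)] <- "unknown"
  assignments <- data.frame(feature_id = feature_ids, location = loc,
                            stringsAsFactors = FALSE)
  if (length(feature_ids) == 0) {
    dist <- data.frame(location = character(0), n = integer(0),
                       fraction = numeric(0))
  } else {
    tab <- sort(table(loc), decreasing = TRUE)
    dist <- data.frame(location = names(tab), n = as.integer(tab),
                       fraction = as.numeric(tab) / length(loc),
                       stringsAsFactors = FALSE)
  }
  list(assignments = assignments, distribution = dist)
}
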