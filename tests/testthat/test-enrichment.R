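test_that("the OBO reader parses terms, multiple parents, and depths", {
  ont <- load_obo(write_toy_obo())
  expect_equal(nrow(ont$terms), 5)
  expect_equal(nrow(ont$edges), 5)   # 4 single + 1 extra parent on the leaf
  expect_identical(ont$root, "GO:0000001")
  d <- term_depths(ont)
  ids <- c("GO:0000001", "GO:0000002", "GO:0000004", "GO:0000005")
  expect_identical(d[ids], setNames(c(0L, 1L, 2L, 2L), ids))

  obsolete <- write_toy_obo(c("", "[Term]", "id: GO:0000006",
                              "name: gone", "namespace: biological_process",
                              "is_a: GO:0000001 ! root", "is_obsolete: true"))
  expect_equal(nrow(load_obo(obsolete)$terms), 5)

  cyclic <- write_toy_obo(c("", "[Term]", "id: GO:0000007",
                            "name: c1", "namespace: biological_process",
                            "is_a: GO:0000008 ! other",
                            "", "[Term]", "id: GO:0000008",
                            "name: c2", "namespace: biological_process",
                            "is_a: GO:0000007 ! other"))
  expect_error(load_obo(cyclic), "cycle")
})

test_that("annotation propagation implements the true-path rule idempotently", {
  ont <- load_obo(write_toy_obo())
  ann <- data.frame(gene = "g1", term = "GO:0000005")
  out <- propagate_annotations(ann, ont)
  expect_setequal(out$term[out$gene == "g1"],
                  c("GO:0000005", "GO:0000002", "GO:0000003", "GO:0000001"))
  expect_identical(propagate_annotations(out, ont), out)
  expect_warning(propagate_annotations(
    data.frame(gene = "g1", term = c("GO:0000004", "GO:9999999")), ont),
    "unknown")

  # random annotations equal a transitive-closure oracle
  set.seed(51)
  genes <- sprintf("g%02d", 1:30)
  terms <- c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000005")
  ann <- data.frame(gene = sample(genes, 60, replace = TRUE),
                    term = sample(terms, 60, replace = TRUE))
  out <- propagate_annotations(ann, ont)
  parents <- list("GO:0000001" = character(0),
                  "GO:0000002" = "GO:0000001", "GO:0000003" = "GO:0000001",
                  "GO:0000004" = "GO:0000002",
                  "GO:0000005" = c("GO:0000002", "GO:0000003"))
  closure <- function(t) {
    seen <- t
    repeat {
      more <- setdiff(unlist(parents[seen]), seen)
      if (!length(more)) return(seen)
      seen <- c(seen, more)
    }
  }
  oracle <- unique(do.call(rbind, lapply(seq_len(nrow(ann)), function(i)
    data.frame(gene = ann$gene[i], term = closure(ann$term[i])))))
  expect_equal(nrow(out), nrow(oracle))
  expect_setequal(paste(out$gene, out$term), paste(oracle$gene, oracle$term))
})

test_that("enrichment p-values match combinatorial enumeration", {
  ont <- load_obo(write_toy_obo())
  background <- sprintf("g%02d", 1:20)
  # term GO:0000004 annotates 5 background genes; candidate list of 5 hits 3
  ann <- data.frame(gene = background[1:5], term = "GO:0000004")
  de <- c(background[1:3], background[11:12])
  rec <- enrich(de, background, ann, ont)
  r4 <- rec[rec$term == "GO:0000004", ]
  expect_equal(r4$n_de_in_term, 3)
  expect_equal(r4$n_background_in_term, 5)
  expect_equal(r4$p_raw, enum_hyper_tail(20, 5, 5, 3), tolerance = 1e-10)
  # Bonferroni multiplicity counts only terms with >= 1 candidate hit
  expect_equal(attr(rec, "m_tested"), nrow(rec))
  expect_equal(r4$p_bonferroni, min(1, r4$p_raw * attr(rec, "m_tested")))
  expect_true(all(rec$p_bonferroni >= rec$p_raw))

  # a fully covered exclusive term is the strongest hit
  ann2 <- rbind(ann, data.frame(gene = background[6:10], term = "GO:0000005"))
  rec2 <- enrich(background[6:10], background, ann2, ont)
  expect_identical(rec2$term[which.min(rec2$p_raw)][1] %in%
                     c("GO:0000005", "GO:0000003"), TRUE)
  expect_error(enrich("zz", background, ann, ont), "subset")
  expect_error(enrich(de, character(0), ann, ont), "background")
})

test_that("null candidate lists are calibrated", {
  set.seed(53)
  res <- synthetic_ontology(n_terms = 40, seed = 7)
  ont <- res$ontology
  background <- sprintf("g%03d", 1:300)
  ann <- synthetic_annotations(background, ont, terms_per_gene = 3, seed = 7)
  rates <- replicate(30, {
    de <- sample(background, 30)
    rec <- enrich(de, background, ann, ont)
    mean(rec$p_raw <= 0.05)
  })
  # hypergeometric p is discrete and conservative; the rejection rate under
  # the null must not exceed the nominal level by more than noise
  expect_lt(mean(rates), 0.05 + 3 * sd(rates) / sqrt(length(rates)) + 0.02)
})

test_that("thinning applies its five rules in order with recorded statuses", {
  # two branches, three significant terms each, plus size/hit casualties
  lines <- character(0)
  add_term <- function(id, parent)
    c("", "[Term]", paste0("id: ", id), paste0("name: term ", id),
      "namespace: biological_process", paste0("is_a: ", parent, " ! p"))
  for (spec in list(c("GO:0000010", "GO:0000002"),
                    c("GO:0000011", "GO:0000010"),
                    c("GO:0000012", "GO:0000003"),
                    c("GO:0000013", "GO:0000012")))
    lines <- c(lines, add_term(spec[1], spec[2]))
  ont <- load_obo(write_toy_obo(lines))

  background <- sprintf("g%02d", 1:40)
  de <- background[1:6]
  ann <- rbind(
    data.frame(gene = background[1:6], term = "GO:0000004"),   # branch A d2
    data.frame(gene = background[c(1:5, 20)], term = "GO:0000010"), # A d2
    data.frame(gene = background[c(1:4, 21:22)], term = "GO:0000011"), # A d3
    data.frame(gene = background[c(1:4, 6, 23)], term = "GO:0000012"), # B d2
    data.frame(gene = background[c(1:2, 24:25)], term = "GO:0000013"), # B d3
    data.frame(gene = background[1:3], term = "GO:0000005"))  # tiny term
  rec <- enrich(de, background, ann, ont, propagate = FALSE)
  out <- thin_terms(rec, ont, alpha = 0.05, size_range = c(4, 750))
  status <- setNames(out$status, out$term)
  # GO:0000004 (6/6 hits, depth 2) and GO:0000010 (5 hits) survive branch A;
  # GO:0000011 is deeper -> dropped_depth; branch B keeps GO:0000012
  expect_identical(unname(status["GO:0000004"]), "retained")
  expect_identical(unname(status["GO:0000010"]), "retained")
  expect_identical(unname(status["GO:0000011"]), "dropped_depth")
  expect_identical(unname(status["GO:0000012"]), "retained")
  # GO:0000005 is strongly enriched (3/3 hits) but has only 3 background
  # genes, below the size floor of 4
  expect_identical(unname(status["GO:0000005"]), "dropped_size")

  # hit rule: a term with exactly 1 candidate gene is dropped_hits
  ann_hits <- rbind(data.frame(gene = background[1:6], term = "GO:0000004"),
                    data.frame(gene = background[c(1, 30:33)],
                               term = "GO:0000010"))
  rec2 <- enrich(de, background, ann_hits, ont, propagate = FALSE)
  out2 <- thin_terms(rec2, ont, alpha = 1, size_range = c(1, 750))
  st2 <- setNames(out2$status, out2$term)
  expect_identical(unname(st2["GO:0000010"]), "dropped_hits")

  # redundancy: identical candidate sets collapse to the deepest term
  ann_red <- rbind(data.frame(gene = background[c(1:4, 34)],
                              term = "GO:0000010"),
                   data.frame(gene = background[c(1:4, 35)],
                              term = "GO:0000011"))
  rec3 <- enrich(background[1:4], background, ann_red, ont,
                 propagate = FALSE)
  out3 <- thin_terms(rec3, ont, alpha = 1, size_range = c(1, 750),
                     per_branch = 10)
  st3 <- setNames(out3$status, out3$term)
  expect_identical(unname(st3["GO:0000011"]), "retained")   # deeper
  expect_identical(unname(st3["GO:0000010"]), "dropped_redundant")

  # retained set shrinks monotonically through the pipeline
  expect_true(all(out$status %in% c("retained", "dropped_alpha",
                                    "dropped_size", "dropped_hits",
                                    "dropped_depth", "dropped_redundant")))
})

test_that("localization assignment counts and labels correctly", {
  extra <- bric20_extracellular()
  res <- assign_localizations(
    extra$tair_id, data.frame(feature_id = extra$tair_id,
                              location = extra$location))
  expect_equal(nrow(res$assignments), 8)
  expect_true(all(res$assignments$location == "extracellular"))

  empty <- assign_localizations(character(0),
                                data.frame(feature_id = "x",
                                           location = "plastid"))
  expect_equal(nrow(empty$distribution), 0)

  mix <- assign_localizations(c("a", "b", "c", "d"),
                              data.frame(feature_id = c("a", "b", "c"),
                                         location = c("plastid", "plastid",
                                                      "nucleus")))
  d <- mix$distribution
  expect_equal(d$fraction[d$location == "plastid"], 0.5)
  expect_equal(d$n[d$location == "unknown"], 1L)
  expect_error(assign_localizations(
    "a", data.frame(feature_id = c("a", "a"),
                    location = c("plastid", "nucleus"))), "conflicting")
})
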