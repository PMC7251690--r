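# Small in-code fixtures shared across tests.

# A quant_table built directly from a matrix of log2 intensities.
make_quant <- function(protein_id, intensities,
                       peptide_seq = NULL, modification = "none",
                       site = NA_character_, ion_score = 30,
                       fraction = "membrane", n_per_group = 3) {
  m <- matrix(intensities, nrow = length(protein_id))
  colnames(m) <- sprintf("ch%02d", seq_len(ncol(m)))
  if (is.null(peptide_seq))
    peptide_seq <- sprintf("PEP%03d", seq_along(protein_id))
  quant_table(
    data.frame(protein_id = protein_id, peptide_seq = peptide_seq,
               modification = modification, site = site,
               ion_score = ion_score, m, stringsAsFactors = FALSE,
               check.names = FALSE),
    condition = factor(rep(c("ground", "flight"), each = n_per_group),
                       levels = c("ground", "flight")),
    fraction = fraction)
}

# A five-term toy ontology: BP root, two branch roots, two grandchildren
# (one with two parents), written as OBO text.
write_toy_obo <- function(extra = character(0)) {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: biological_process",
    "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: branch A",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000003", "name: branch B",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000004", "name: leaf A1",
    "namespace: biological_process", "is_a: GO:0000002 ! branch A",
    "",
    "[Term]", "id: GO:0000005", "name: leaf shared",
    "namespace: biological_process", "is_a: GO:0000002 ! branch A",
    "is_a: GO:0000003 ! branch B",
    extra), path)
  path
}
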