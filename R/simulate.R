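#' Simulation configuration for a BRIC-style two-condition multi-omics design
#'
#' Bundles every tunable of the synthetic-data generators: negative-binomial
#' transcript counts (3 flight vs 3 ground replicates), iTRAQ-style log2
#' channel intensities for a membrane and a soluble protein fraction, peptide
#' tables with ion scores and phospho/oxidation annotations, and two control
#' studies (hardware-like and preservative-like) whose perturbations partially
#' overlap the treatment effects.
#'
#' Counts are NB with `variance = mu + dispersion * mu^2` (a single shared
#' dispersion). Per-sample library-size factors are log-normal with
#' `libsize_sdlog` (default ~ +/-20%) so downstream offset handling is
#' exercised. Spiked genes receive `|log2FC|` drawn uniformly from
#' `effect_size` (minimum at least the downstream calling threshold of 1).
#'
#' @param n_genes number of transcript features.
#' @param n_replicates biological replicates per condition (>= 2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for per-gene
#'   baseline NB means.
#' @param dispersion NB dispersion alpha (> 0); `variance = mu + alpha mu^2`.
#' @param frac_de fraction of genes truly differentially expressed at the
#'   transcript level.
#' @param effect_size length-2 numeric, range of true `|log2FC|` for spiked
#'   genes; signs are random.
#' @param libsize_sdlog sdlog of the log-normal library-size factors.
#' @param n_proteins proteins quantified per fraction (drawn from the gene
#'   universe; the two fractions are disjoint).
#' @param rna_protein_coupling probability that an RNA-DE gene present in a
#'   fraction is also protein-DE.
#' @param discordant_frac among coupled protein effects, fraction with sign
#'   opposite to the transcript (default 5/17, the discordance rate observed
#'   in the BRIC-20 overlap set).
#' @param frac_de_protein fraction of proteins with RNA-independent abundance
#'   effects.
#' @param protein_effect range of `|log2FC|` for protein effects.
#' @param protein_baseline_mean,protein_baseline_sd normal parameters of the
#'   per-protein baseline log2 intensity.
#' @param protein_noise_sd per-channel log2 noise SD.
#' @param peptides_per_protein mean number of peptides per protein (>= 1;
#'   counts are 1 + Poisson(mean - 1)).
#' @param score_fail_frac fraction of peptide ion scores falling at or below
#'   the score-20 reporting bar.
#' @param frac_ptm fraction of peptide rows carrying a phosphorylation.
#' @param frac_oxidized fraction of peptide rows carrying a methionine
#'   oxidation.
#' @param frac_ptm_de fraction of phosphopeptides with a true differential
#'   phosphorylation effect.
#' @param ptm_effect range of `|log2FC|` for differential PTM effects.
#' @param ox_de_frac fraction of oxidized peptides with a true prevalence
#'   shift.
#' @param ox_positive_frac among shifted oxidized peptides, fraction shifted
#'   upward in flight (default 0.79 for the membrane-fraction asymmetry).
#' @param control_frac fraction of genes perturbed in each control study.
#' @param control_effect range of `|log2FC|` for control-study effects.
#' @param control_overlap_frac fraction of the treatment-DE genes that each
#'   control study also perturbs (default 0.27).
#' @param control_scale range of the multiplicative factor applied to the
#'   treatment log2FC for overlapping control effects (attenuated through
#'   inflated).
#' @param seed master RNG seed; each generator derives its own stream by a
#'   fixed offset so adding one generator never perturbs another.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 5000,
                              n_replicates = 3,
                              baseline_meanlog = log(150),
                              baseline_sdlog = 1.2,
                              dispersion = 0.2,
                              frac_de = 0.05,
                              effect_size = c(1, 3),
                              libsize_sdlog = 0.2,
                              n_proteins = 400,
                              rna_protein_coupling = 0.1,
                              discordant_frac = 5 / 17,
                              frac_de_protein = 0.1,
                              protein_effect = c(0.2, 1),
                              protein_baseline_mean = 15,
                              protein_baseline_sd = 2,
                              protein_noise_sd = 0.2,
                              peptides_per_protein = 3,
                              score_fail_frac = 0.25,
                              frac_ptm = 0.05,
                              frac_oxidized = 0.2,
                              frac_ptm_de = 0.3,
                              ptm_effect = c(0.2, 1.2),
                              ox_de_frac = 0.05,
                              ox_positive_frac = 0.79,
                              control_frac = 0.05,
                              control_effect = c(1, 3),
                              control_overlap_frac = 0.27,
                              control_scale = c(0.5, 1.5),
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, frac_de = frac_de,
    effect_size = effect_size, libsize_sdlog = libsize_sdlog,
    n_proteins = as.integer(n_proteins),
    rna_protein_coupling = rna_protein_coupling,
    discordant_frac = discordant_frac, frac_de_protein = frac_de_protein,
    protein_effect = protein_effect,
    protein_baseline_mean = protein_baseline_mean,
    protein_baseline_sd = protein_baseline_sd,
    protein_noise_sd = protein_noise_sd,
    peptides_per_protein = peptides_per_protein,
    score_fail_frac = score_fail_frac,
    frac_ptm = frac_ptm, frac_oxidized = frac_oxidized,
    frac_ptm_de = frac_ptm_de, ptm_effect = ptm_effect,
    ox_de_frac = ox_de_frac, ox_positive_frac = ox_positive_frac,
    control_frac = control_frac, control_effect = control_effect,
    control_overlap_frac = control_overlap_frac,
    control_scale = control_scale,
    seed = as.integer(seed)
  )
  fracs <- c("frac_de", "rna_protein_coupling", "discordant_frac",
             "frac_de_protein", "score_fail_frac", "frac_ptm",
             "frac_oxidized", "frac_ptm_de", "ox_de_frac",
             "ox_positive_frac", "control_frac", "control_overlap_frac")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  }
  if (cfg$n_genes < 1L) stop("'n_genes' must be positive")
  if (cfg$n_replicates < 2L) stop("'n_replicates' must be >= 2")
  if (cfg$dispersion <= 0) stop("'dispersion' must be > 0")
  if (cfg$effect_size[1] < 1)
    stop("spiked |log2FC| must be >= 1, the transcript calling threshold")
  if (cfg$n_proteins * 2L > cfg$n_genes)
    stop("'n_proteins' per fraction cannot exceed half the gene universe")
  if (cfg$peptides_per_protein < 1) stop("'peptides_per_protein' must be >= 1")
  if (cfg$frac_ptm + cfg$frac_oxidized > 0.98)
    stop("'frac_ptm' + 'frac_oxidized' must leave room for unmodified peptides")
  class(cfg) <- "sim_config"
  cfg
}

# Fixed per-generator seed offsets; keeps streams independent of each other.
.stream_seed <- function(config, stream) {
  offs <- c(counts = 0L, protein = 1L, peptides = 2L, controls = 3L,
            annotation = 4L)
  (config$seed + offs[[stream]]) %% .Machine$integer.max
}

.runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Simulate an NB transcript count matrix with known ground truth
#'
#' Counts for gene g in sample j are NB with mean
#' `libsize_factor_j * baseline_g * 2^(log2fc_g)` in the flight condition and
#' `libsize_factor_j * baseline_g` on the ground, so the two condition means
#' differ by exactly the true log2FC on the log2 scale.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`, a ground-truth
#'   container whose `$rna` data frame has `feature_id`, `is_de`, `log2fc`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, "counts"))
  G <- config$n_genes
  n <- config$n_replicates
  ids <- sprintf("G%05d", seq_len(G))

  baseline <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  n_de <- round(config$frac_de * G)
  is_de <- rep(FALSE, G)
  lfc <- rep(0, G)
  if (n_de > 0) {
    de_idx <- sample.int(G, n_de)
    is_de[de_idx] <- TRUE
    lfc[de_idx] <- .runif_range(n_de, config$effect_size) *
      sample(c(-1, 1), n_de, replace = TRUE)
  }

  sf <- stats::rlnorm(2 * n, 0, config$libsize_sdlog)
  sf <- sf / exp(mean(log(sf)))                  # geometric mean 1
  cond <- rep(c("ground", "flight"), each = n)
  mu <- outer(baseline, sf)
  mu[, cond == "flight"] <- mu[, cond == "flight"] * 2^lfc
  size <- 1 / config$dispersion
  counts <- matrix(stats::rnbinom(G * 2 * n, mu = mu, size = size),
                   nrow = G, ncol = 2 * n,
                   dimnames = list(ids, sprintf("%s_%d", cond,
                                                rep(seq_len(n), 2))))
  cm <- count_matrix(counts,
                     condition = factor(cond, levels = c("ground", "flight")))
  truth <- list(rna = data.frame(feature_id = ids, is_de = is_de,
                                 log2fc = lfc, stringsAsFactors = FALSE),
                config = config)
  class(truth) <- "sim_truth"
  list(counts = cm, truth = truth)
}

#' Simulate protein-level iTRAQ log2 intensity tables for two fractions
#'
#' Each fraction quantifies `n_proteins` genes (fractions disjoint). Observed
#' log2 intensity = baseline + condition effect (flight only) + N(0, sd)
#' channel noise. An RNA-DE gene that is quantified becomes protein-DE with
#' probability `rna_protein_coupling`; a fraction `discordant_frac` of those
#' coupled effects flips sign relative to the transcript. Additional proteins
#' receive RNA-independent effects at rate `frac_de_protein`.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [simulate_counts()] (shared feature
#'   universe).
#' @return list with `membrane` and `soluble` protein-level [quant_table()]s
#'   and the `truth` object extended with a `$protein` data frame
#'   (`feature_id`, `fraction`, `is_de`, `log2fc`, `baseline`).
#' @export
simulate_protein_layers <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (is.null(truth$rna)) stop("truth lacks an RNA layer; run simulate_counts first")
  set.seed(.stream_seed(config, "protein"))
  ids <- truth$rna$feature_id
  P <- config$n_proteins
  picked <- sample(ids, 2 * P)
  frac_ids <- list(membrane = picked[seq_len(P)],
                   soluble = picked[P + seq_len(P)])

  prot <- do.call(rbind, lapply(names(frac_ids), function(fr) {
    fid <- frac_ids[[fr]]
    rna <- truth$rna[match(fid, truth$rna$feature_id), ]
    coupled <- rna$is_de & stats::runif(P) < config$rna_protein_coupling
    indep <- !coupled & stats::runif(P) < config$frac_de_protein
    lfc <- numeric(P)
    mag <- .runif_range(P, config$protein_effect)
    sgn <- ifelse(stats::runif(P) < config$discordant_frac, -1, 1)
    lfc[coupled] <- (mag * sgn * sign(rna$log2fc))[coupled]
    lfc[indep] <- (mag * sample(c(-1, 1), P, replace = TRUE))[indep]
    data.frame(feature_id = fid, fraction = fr, is_de = coupled | indep,
               log2fc = lfc,
               baseline = stats::rnorm(P, config$protein_baseline_mean,
                                       config$protein_baseline_sd),
               stringsAsFactors = FALSE)
  }))

  n <- config$n_replicates
  make_table <- function(fr) {
    pr <- prot[prot$fraction == fr, ]
    eff <- outer(pr$log2fc, c(rep(0, n), rep(1, n)))  # ground then flight
    m <- pr$baseline + eff +
      matrix(stats::rnorm(nrow(pr) * 2 * n, 0, config$protein_noise_sd),
             nrow(pr), 2 * n)
    quant_table(
      data.frame(protein_id = pr$feature_id, peptide_seq = NA_character_,
                 modification = "none", site = NA_character_,
                 ion_score = NA_real_, m, stringsAsFactors = FALSE,
                 check.names = FALSE),
      condition = factor(rep(c("ground", "flight"), each = n),
                         levels = c("ground", "flight")),
      fraction = fr)
  }
  truth$protein <- prot
  list(membrane = make_table("membrane"), soluble = make_table("soluble"),
       truth = truth)
}

.random_peptide <- function(n, len_range = c(8L, 20L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Simulate peptide-level quantification tables with scores and modifications
#'
#' Expands each simulated protein into one or more peptide rows. Ion scores
#' fall at or below the score-20 reporting bar with probability
#' `score_fail_frac` (and strictly above it otherwise), so the expected
#' reportable fraction has a closed binomial form. Peptide intensities are the
#' protein baseline + condition effect + a peptide offset + channel noise;
#' phosphopeptides and oxidized peptides carry modification labels, site
#' strings, and (for a configured fraction) their own differential effects.
#'
#' @param config a [simulation_config()].
#' @param truth truth extended by [simulate_protein_layers()].
#' @return list with `membrane` and `soluble` peptide-level [quant_table()]s
#'   and `truth` extended with a `$ptm` data frame (per modified peptide row:
#'   `protein_id`, `fraction`, `modification`, `is_de`, `log2fc`).
#' @export
simulate_peptides <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (is.null(truth$protein))
    stop("truth lacks a protein layer; run simulate_protein_layers first")
  set.seed(.stream_seed(config, "peptides"))
  n <- config$n_replicates
  cond <- factor(rep(c("ground", "flight"), each = n),
                 levels = c("ground", "flight"))

  build <- function(fr) {
    pr <- truth$protein[truth$protein$fraction == fr, ]
    npep <- 1L + stats::rpois(nrow(pr), config$peptides_per_protein - 1)
    idx <- rep(seq_len(nrow(pr)), npep)
    N <- length(idx)
    fail <- stats::runif(N) < config$score_fail_frac
    score <- ifelse(fail, stats::runif(N, 0, 20), 20 + stats::rexp(N, 1 / 15))
    modification <- sample(c("none", "phospho", "oxidation", "deamidation"), N,
                           replace = TRUE,
                           prob = c(1 - config$frac_ptm - config$frac_oxidized - 0.02,
                                    config$frac_ptm, config$frac_oxidized, 0.02))
    seqs <- .random_peptide(N)
    site <- rep(NA_character_, N)
    site[modification == "phospho"] <-
      paste0(sample(c("S", "T", "Y"), sum(modification == "phospho"), TRUE),
             sample(20:400, sum(modification == "phospho"), TRUE))
    site[modification == "oxidation"] <-
      paste0("M", sample(20:400, sum(modification == "oxidation"), TRUE))
    site[modification == "deamidation"] <-
      paste0(sample(c("N", "Q"), sum(modification == "deamidation"), TRUE),
             sample(20:400, sum(modification == "deamidation"), TRUE))

    # modification-specific differential effects, on top of the protein effect
    mod_lfc <- numeric(N)
    is_ptm_de <- modification == "phospho" & stats::runif(N) < config$frac_ptm_de
    mod_lfc[is_ptm_de] <- .runif_range(sum(is_ptm_de), config$ptm_effect) *
      sample(c(-1, 1), sum(is_ptm_de), TRUE)
    is_ox_de <- modification == "oxidation" & stats::runif(N) < config$ox_de_frac
    mod_lfc[is_ox_de] <- .runif_range(sum(is_ox_de), config$ptm_effect) *
      ifelse(stats::runif(sum(is_ox_de)) < config$ox_positive_frac, 1, -1)

    pep_off <- stats::rnorm(N, 0, 1)
    eff <- outer(pr$log2fc[idx] + mod_lfc, c(rep(0, n), rep(1, n)))
    m <- pr$baseline[idx] + pep_off + eff +
      matrix(stats::rnorm(N * 2 * n, 0, config$protein_noise_sd), N, 2 * n)
    tab <- quant_table(
      data.frame(protein_id = pr$feature_id[idx], peptide_seq = seqs,
                 modification = modification, site = site, ion_score = score,
                 m, stringsAsFactors = FALSE, check.names = FALSE),
      condition = cond, fraction = fr)
    tr <- data.frame(protein_id = pr$feature_id[idx], fraction = fr,
                     modification = modification,
                     is_de = is_ptm_de | is_ox_de, log2fc = mod_lfc,
                     stringsAsFactors = FALSE)[modification != "none", ]
    list(tab = tab, tr = tr)
  }
  mem <- build("membrane"); sol <- build("soluble")
  truth$ptm <- rbind(mem$tr, sol$tr)
  list(membrane = mem$tab, soluble = sol$tab, truth = truth)
}

#' Simulate hardware-like and preservative-like control studies
#'
#' Each control study reports per-feature log2FCs with a `significant` flag.
#' A fraction `control_overlap_frac` of the treatment-DE genes is perturbed in
#' each control with a log2FC equal to the treatment log2FC times a factor
#' drawn from `control_scale` (identical, attenuated or inflated); a further
#' `control_frac` of random genes is perturbed independently, so the
#' control-study decision rule has non-trivial work.
#'
#' @param config a [simulation_config()].
#' @param truth truth from [simulate_counts()] (RNA layer required).
#' @return list with `hardware` and `preservative` data frames (`feature_id`,
#'   `log2fc`, `significant`) and `truth` extended with `$control`.
#' @export
simulate_control_studies <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(.stream_seed(config, "controls"))
  rna <- truth$rna
  G <- nrow(rna)
  one_control <- function(name) {
    lfc <- numeric(G)
    affected <- rep(FALSE, G)
    de_idx <- which(rna$is_de)
    n_ov <- round(config$control_overlap_frac * length(de_idx))
    if (n_ov > 0) {
      ov <- sample(de_idx, n_ov)
      affected[ov] <- TRUE
      lfc[ov] <- rna$log2fc[ov] * .runif_range(n_ov, config$control_scale)
    }
    n_bg <- round(config$control_frac * G)
    if (n_bg > 0) {
      bg <- sample(setdiff(seq_len(G), which(affected)), n_bg)
      affected[bg] <- TRUE
      lfc[bg] <- .runif_range(n_bg, config$control_effect) *
        sample(c(-1, 1), n_bg, TRUE)
    }
    data.frame(feature_id = rna$feature_id, log2fc = lfc,
               significant = affected, control = name,
               stringsAsFactors = FALSE)
  }
  hardware <- one_control("hardware")
  preservative <- one_control("preservative")
  truth$control <- rbind(hardware, preservative)
  list(hardware = hardware[, c("feature_id", "log2fc", "significant")],
       preservative = preservative[, c("feature_id", "log2fc", "significant")],
       truth = truth)
}
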