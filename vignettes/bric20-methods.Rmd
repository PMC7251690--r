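---
title: "Statistical methods behind bricomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind bricomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bricomics)
```

# Scope

`bricomics` implements the analysis skeleton of a multi-omics spaceflight
experiment of the BRIC-20 type (transcriptome + two-fraction iTRAQ proteome
+ PTM survey, 3 flight vs 3 ground replicates), together with a synthetic
data generator that produces inputs with known ground truth. This vignette
documents the statistical models, the numerical choices, and the places where
an underdetermined methodological description forced an explicit decision.

# The count model and the likelihood-ratio test

Transcript counts are modeled as negative binomial,
$y_{gij} \sim \mathrm{NB}(\mu_{gi}, \alpha)$ with
$\mathrm{Var}(y) = \mu + \alpha\mu^2$, a log link, and per-sample library-size
offsets, the standard model for RNA-seq with biological replicates. The
differential test for gene $g$ compares the two-mean model (one mean per
condition) to the pooled single-mean model via the likelihood-ratio statistic
$2(\ell_\text{full} - \ell_\text{null}) \sim \chi^2_1$.

Numerical choices:

* **Group-mean fitting.** With a single factor and equal offsets within a
  group, the per-group score equation
  $U(\beta) = \sum_j r\,(y_j - \mu_j)/(\mu_j + r)$ (with $r = 1/\alpha$,
  $\mu_j = e^{\beta} s_j$) is strictly decreasing in $\beta$, so a vectorized
  Newton iteration converges globally. Steps are capped at $\pm 3$ on the log
  scale for safety; all-zero rows get $\hat\beta = -\infty$ and a
  log-likelihood of 0, which makes the LRT statistic exactly 0 (p = 1).
* **Dispersion estimation.** A common dispersion maximizes the Cox–Reid
  adjusted profile likelihood (subtracting $\tfrac12 \log I(\hat\beta)$ per
  fitted group mean), evaluated on a log-spaced grid
  `10^seq(-4, log10(4), length = 25)` and refined with `stats::optimize`
  around the grid optimum. The adjustment removes most of the downward bias
  of plain profile ML at $n = 3 + 3$; on shared data the estimate agrees with
  edgeR's common-dispersion estimate to four decimals. An optional tagwise
  estimate shrinks each gene's grid likelihood toward the common curve with a
  prior weight of 10 pseudo-genes.
* **Fold changes.** `log2fc` is the MLE contrast
  $(\hat\beta_2 - \hat\beta_1)/\log 2$ with *no* shrinkage prior; infinite
  contrasts (a group with all zeros) are capped at $\pm 30$ for
  serializability.

Multiplicity is handled by Benjamini–Hochberg; transcripts are called at
$|\mathrm{log2FC}| \ge 1$ and FDR $\le 0.05$ (both boundaries inclusive).

# Proteomics

Peptide-to-protein inference uses the classical reporting rule: a protein is
reportable when it has at least two distinct peptides with ion score strictly
greater than 20. Reportable proteins are quantified by rolling up unmodified
peptide channels (mean by default, median available) and tested with a
pooled-variance two-sample t-test on the log2 intensities; proteins are called
at $|\mathrm{log2FC}| \ge 0.2$ and $p \le 0.05$. Zero-variance degenerate
input returns $p = 1$ when the means agree and the smallest representable
double otherwise, so downstream ranking never sees `NaN`.

Modified peptides are tested individually (per peptide-site record) with the
same t-test; phosphopeptides use the deliberately relaxed $p \le 0.1$
threshold, reflecting the absence of phosphoenrichment and the resulting low
coverage. Methionine-oxidation prevalence is *operationalized* as the fraction
of oxidized peptides whose abundance changes significantly, together with the
fraction of those changes that are increases — the underlying description
("increased oxidation") does not fix a statistic, so this definition is a
package decision and is reported as two numbers rather than one.

# The control-study decision rule

Candidates are screened against ground-control perturbation studies (hardware
and preservative controls) with the rule

$$\text{pass} \iff |L_\text{SF} - L_\text{ctl}| > |L_\text{ctl}|
\;\lor\; |L_\text{SF}| > |L_\text{ctl}|,$$

with strict inequalities, applied as a conjunction over every control in
which the feature was significant (features absent from all control lists
pass vacuously). Note the rule's range interpretation: the first disjunct is
the *range* between the two fold changes, so a sign-flipped response of equal
magnitude passes. Non-finite fold changes are rejected rather than coerced.

# Cross-layer integration

The transcript and protein candidate lists are intersected on the shared
locus namespace, and each overlapping locus is classified as sign-concordant
or discordant; when both protein fractions are quantified, the fraction with
the smaller p-value speaks for the protein layer. The overlap statistic is
hypergeometric with genome size $N = 27000$ by default. The kernel is
computed in log space via `lchoose` and exposes **both** the point probability
$P(X = x)$ and the conventional upper tail $P(X \ge x)$. The headline
published probabilities (0.036 at $x = 12$, $9.7\times10^{-4}$ at $x = 17$)
are *point* probabilities — verified by independent computation before the
kernel was written — so the point mass is the default reproduction mode while
the tail is recommended for new analyses.

# GO enrichment and thinning

The package ships a minimal OBO reader (`[Term]` stanzas, `is_a` edges,
biological_process namespace only), validates acyclicity and a unique root,
and applies the true-path rule before counting. Enrichment per term is the
same upper-tail hypergeometric kernel, Bonferroni-corrected over the number
of terms with at least one candidate annotation (terms with zero hits are
untestable and do not inflate $m$).

Because "representative term selection" is underdetermined, the thinning
pipeline is an explicit, deterministic rule sequence, each recorded in a
`status` column: (1) Bonferroni $p \le 0.05$; (2) background term size within
[4, 750]; (3) at least two candidate genes; (4) within each *branch* — defined
here as the subtree of each direct child of the BP root — keep the two terms
of minimal *depth* — defined as shortest `is_a` distance from the root — with
ties broken by smaller p then lexicographic id; (5) among terms with
identical candidate gene sets keep only the deepest. Branch and depth are
interpretations, not published definitions, and are configurable.

# The synthetic generator

The generator emulates: NB counts with lognormal baseline means
(`meanlog = log(150)`, `sdlog = 1.2`) and lognormal library-size factors
(`sdlog = 0.2`, normalized to geometric mean 1); spiked effects on 5% of
genes with $|\mathrm{log2FC}| \sim U(1, 3)$; two disjoint protein fractions
coupled to the transcript effects with tunable correlation and a discordant
sign-flip fraction (default 5/17, matching the observed discordance rate);
peptide tables with ion scores drawn so that a peptide passes the score
filter with probability exactly 0.6; PTM and oxidation effects; and two
control studies overlapping the DE set. Each sub-generator draws from its own
seed stream (fixed offsets from the master seed) so layers can be regenerated
independently and deterministically.

The generator does **not** emulate: mapping/quantification error, batch or
run effects, missing channels, isotopic impurity, shared peptides between
proteins, or gene-length effects. Problem sizes used in tests (e.g. 5000
genes, 500 proteins) are the package's own choices for desk-scale runtimes.

# Known limitations

* With 3 vs 3 replicates, dispersion 0.2, and effects uniform on [1, 3]
  against a lognormal mean distribution, the spiked-gene recall of the NB-LRT
  at FDR $\le 0.05$ plateaus near 60%. This is a power ceiling of the design,
  not an implementation artifact: edgeR's GLM-LRT on identical counts yields
  the same recall and an essentially identical dispersion estimate.
* The hypergeometric reproduction mode reports a point probability because
  that is what the published numbers are; it is not a recommended test
  statistic.
* The OBO reader handles the subset of the format needed here; it is not a
  general ontology parser.

# Reproducing the headline numbers

```{r headline}
published_tables_summary()
```
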