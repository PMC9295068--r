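---
title: "Models and methods behind poolscreen"
author: "poolscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The screening problem

A pooled CRISPR knockout screen transduces a cell population with a
genome-scale guide library at low multiplicity of infection (MOI), so that
most infected cells carry a single knockout, then applies a selective
pressure — here, a multikinase inhibitor in vitro, followed by orthotopic
tumor growth and lung metastasis in mice — and reads out the surviving
composition by sequencing the integrated guide spacers. Guides targeting
genes whose loss confers resistance enrich; the analysis problem is to turn
raw reads into a ranked, error-controlled gene list.

`poolscreen` implements the complete path: guide library handling, spacer
counting from FASTQ, per-guide negative-binomial (NB) differential
abundance, gene-level aggregation, hit calling across screen arms, QC, and
a mechanistic simulator that generates screens with known ground truth.

## Spacer counting

Guide quantification is an exact-lookup problem: the 20-nt spacer is a
designed barcode, and reads either contain it verbatim or with rare
sequencing errors. `quantify_sample()` therefore hashes the extracted
spacer window against the library and, optionally, retries all $3k$
single-substitution neighbours (`max_mismatch = 1`). A read is *assigned*
when exactly one guide matches, *ambiguous* when several do (spacers shared
by more than one guide are treated the same way), and *unassigned*
otherwise; ambiguous reads are discarded rather than fractionally split,
matching the multi-mapping discard convention of alignment-based pipelines.
The three bins always sum to the input read count, and the suite fuzz-tests
that conservation. Because amplicon designs differ, the spacer position in
the read (offset or 5' anchor) is a required configuration input, never
guessed.

## Normalization and the NB test

Sequencing depth is removed by median-of-ratios size factors: for sample
$s$, $\hat{f}_s = \mathrm{median}_g \, c_{gs} / (\prod_t c_{gt})^{1/m}$
over guides with nonzero counts everywhere, rescaled to geometric mean 1.
A `pseudo_reference` flag computes the per-guide reference over positive
counts only, for severely bottlenecked samples in which no guide is
positive everywhere; total-count normalization is available for
comparison.

Counts are modelled as NB with $\mathrm{Var} = \mu + \alpha\mu^2$.
Dispersion is estimated in three steps:

1. **Per-guide moments.** With normalized counts $q_{gs}$, pooled
   within-group variance $s_g^2$ and mean $\bar{q}_g$,
   $\hat\alpha_g = (s_g^2 - c\,\bar{q}_g) / (\bar{q}_g^2 - s_g^2/n)$,
   truncated at 0. The shot-noise term $c\,\bar q_g$ uses
   $c = \overline{1/f_s}$, and the $s_g^2/n$ correction in the denominator
   removes the upward bias of $\bar{q}_g^2$ as an estimate of $\mu_g^2$ —
   without it the dispersion is systematically underestimated and null
   p-values become anticonservative.
2. **Trend.** $\alpha(\mu) = a_1/\mu + a_0$ fitted by ordinary least
   squares over guides with $\bar q_g \ge 1$. Plain OLS is used
   deliberately: the per-guide estimates have strongly right-skewed
   sampling noise, and robust/median-type fits track the mode rather than
   the mean, biasing the trend low.
3. **Blend.** The final dispersion is
   $0.25\,\hat\alpha_g + 0.75\,\alpha(\bar q_g)$ by default. With the two
   replicates per arm typical of screens the per-guide estimate carries
   very little information (2 residual degrees of freedom per group), so
   most weight goes to the trend; the residual raw weight keeps some
   adaptivity for guides whose dispersion genuinely departs from the
   trend. Heavier raw weights were rejected during development because
   they visibly broke the uniformity of null p-values at the 2-vs-2
   design; weight 0.25 keeps the Kolmogorov–Smirnov distance of null
   p-values from $U(0,1)$ below the $\alpha = 0.01$ critical value across
   seeds while retaining per-guide signal. This weighted blend is a
   deliberately simple stand-in for full empirical-Bayes MAP shrinkage.

Testing uses a per-guide two-group NB GLM with log link and
$\log \hat f_s$ offsets, fitted at fixed dispersion by iteratively
reweighted least squares (vectorized across all guides, since the design
matrix is shared), and a Wald statistic $\hat\beta_1 / \mathrm{SE}$
against the standard normal. The *reported* `log2fc` is the descriptive
$\log_2$ ratio of group mean normalized counts with a 0.5 pseudo-count,
which is always finite; the test statistic comes from the GLM coefficient.
P-values are floored at $10^{-300}$. Guides with all-zero counts are
reported with `log2fc = 0`, `p = 1`, and flagged. Fold changes are
reported unshrunk.

One subtlety worth stating: uniform depth rescaling of a sample leaves the
pseudo-count-free normalized mean ratios exactly invariant, but the
pseudo-counted `log2fc` moves by $O(0.5/\mu)$; the tests assert both the
exact invariance of the underlying ratio and the boundedness of that
wiggle.

## Gene-level aggregation

Guide statistics collapse to targets (genes and miRNAs alike; non-targeting
controls are excluded) as the arithmetic mean of member `log2fc` — a flag
switches to the mean of linear fold changes, since "mean fold change" is
genuinely ambiguous — plus Fisher's combination
$X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$ and Benjamini–Hochberg
correction across targets. BH is delegated to `stats::p.adjust` and
cross-checked in the tests against a literal implementation of the step-up
rule. Because the NB test is two-sided, a gene driven by depleted guides
can combine to a small p with a negative mean fold change; the `direction`
column carries the sign, and `alternative = "greater"` converts guide
p-values to one-sided enrichment form, which is the recommended mode for
positive-selection resistance screens. Note that BH-adjusted p-values are
not idempotent under re-adjustment (a short counterexample:
$p = (0.1, 0.9)$ adjusts to $(0.2, 0.9)$, which re-adjusts to
$(0.4, 0.9)$); the suite asserts the properties the step-up rule actually
has — monotonicity and order preservation.

## Hit calling

Hit identification follows the screen's published decision rules: a guide
passes thresholds when its treated-arm count strictly exceeds 100 *and*
its $\log_2$ fold change strictly exceeds 3; the top 600/400/200 enriched
guides per arm (drug-treated cells / primary tumors / lung metastases) are
intersected to give the core resistance genes; and the *trend group*
collects guides whose counts are strictly ordered
metastasis > primary tumor > drug-treated cells. Two decisions were open
and are configurable: "count" means replicate-averaged *normalized* counts
by default (depth artifacts otherwise dominate cross-arm ordering;
`use_normalized = FALSE` restores raw treated maxima), and the top-N
ranking key defaults to `log2fc` among guides passing the count filter
(`rank_key = "count"` is available). Ties break by smaller p-value, then
lexicographic guide id, making the selection deterministic.

## The simulator

`simulate_screen()` is a mechanistic generative model, not a count
shuffler, and every stage reports its ground truth:

* **Library**: random unique spacers; per-guide plasmid abundance is
  log-normal with $\sigma = 0.5$ (`library_skew`), the community default
  for the unequal representation real libraries show; the *same* plasmid
  pool seeds all infection replicates.
* **Infection**: each exposed cell receives Poisson(`moi` = 0.3)
  integrations; each integration founds one lineage drawn from the plasmid
  frequencies. The default number of exposed cells is
  `coverage * n_guides / (1 - e^{-moi})`, so that the *infected* population
  carries `coverage` (400) lineages per guide — protocols state coverage
  after transduction/selection, and modelling it otherwise quietly starves
  the screen of representation.
* **Selection**: each round multiplies expected lineage abundance by the
  gene's fitness multiplier and multinomially resamples to constant
  population size; a multiplier $m$ over $r$ rounds gives $m^r$ expected
  relative enrichment. The vehicle arm is passaged the same number of
  rounds with neutral fitness.
* **Bottlenecks**: engraftment and metastatic seeding subsample without
  replacement (multivariate hypergeometric), by default to 20% and 2% of
  the incoming population — severe enough to produce the stochastic guide
  loss and replicate heterogeneity real in vivo arms show. Two further
  drug-selection rounds follow each bottleneck (`in_vivo_rounds`).
* **Sequencing**: NB with mean proportional to lineage frequency times
  `seq_depth` (500 reads/guide) and technical overdispersion
  `nb_dispersion = 0.01`, the extra-Poisson noise of PCR and
  resequencing. Biological replicate divergence is *not* folded into this
  dispersion — it emerges mechanistically from independent infections and
  selections, which is why replicate log-count correlations sit near 0.92
  rather than being dialled in directly.

What the simulator does not model: guide efficiency differences within a
gene (a hook exists but is off by default), off-target effects, copy-number
artifacts, PCR jackpotting beyond the NB noise, and any pharmacokinetics —
drug dose and schedule are labels, not model inputs. Passing tests on
simulated screens therefore demonstrate statistical correctness of the
pipeline under its stated model, not robustness to every artifact of real
data.

## Numerical and degenerate-input choices

* IRLS runs at most 30 damped iterations (steps clipped to ±3 on the log
  scale) with a $10^{-10}$ convergence tolerance; means are capped at
  $10^{12}$ to keep weights finite.
* Raw dispersion estimates are capped at 20; trend dispersions floored at
  $10^{-8}$; size-factor estimation refuses matrices with no
  everywhere-positive guide unless `pseudo_reference = TRUE`.
* Fisher inputs are clipped to $[10^{-300}, 1]$; with $k = 1$ the
  combination is the identity, which the tests exploit as a closed form.
* Zero-variance samples yield `NA` correlations with a warning rather than
  an error; empty FASTQ files quantify to all-zero counts; all-zero count
  columns are retained.
* KS p-values use the asymptotic Kolmogorov distribution — adequate at
  library scale (thousands of guides), inaccurate below a few dozen
  observations.

## Problem sizes used by the test-suite and acceptance script

Simulated screens in the tests use 100 genes × 3 guides + 1000 controls at
400× coverage and 500 reads/guide — large enough that moment estimators are
in their working regime and small enough to keep the whole suite in tens of
seconds. Null-calibration and FDR checks use 2000 guides × 4 samples over
20 seeds. These sizes are the package's own choice of a regime where the
asymptotics the methods rely on are already valid; behaviour at
genome-scale (123k guides) differs only in runtime.

## Known limitations

* The Wald test with a normal reference is approximate at 2-vs-2; the
  suite verifies calibration empirically rather than assuming it.
* Dispersion shrinkage is a fixed-weight blend, not empirical Bayes; very
  heterogeneous dispersions will be over-smoothed.
* No multi-factor designs, no outlier refitting, no independent filtering.
* The quantifier handles substitutions only (no indels) — a deliberate
  trade, since designed barcodes fail mostly by substitution and indel
  reads are a small unassigned fraction.
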