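---
title: "Methods: simulation and analysis of pooled shRNA dropout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of pooled shRNA dropout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

## The problem

Pooled shRNA dropout (synthetic-lethality) screens ask which genes a cell
population needs to survive a selective pressure — here, maintained
resistance to a targeted drug. A lentiviral library of barcoded short
hairpin RNAs (typically several thousand genes, each covered by eight or
more independent hairpins) is transduced into resistant cells; after weeks
of culture under drug, hairpins whose barcodes have dropped out of the
sequenced pool mark genes required to maintain resistance. Two confounders
must be handled before a gene list is credible:

* **General drug essentiality.** A hairpin can drop out simply because its
  target is needed to survive the drug at all, resistant or not. Screening
  drug-naive parental cells under acute treatment and *subtracting* those
  dropouts isolates resistance-specific genes.
* **Inert hairpins and count noise.** Real libraries contain hairpins with
  little or no knockdown activity, and sequencing counts are overdispersed.
  Calling a gene only when several independent hairpins deplete guards
  against both.

`dropscreen` implements this computation end to end, together with a
negative-binomial differential-expression stage, set-overlay candidate
integration, and over-representation / GSEA-style enrichment, plus a
synthetic-data generator that plants known drivers so every stage can be
verified against recorded truth.

## The generative model

`simulate_screen()` draws, per hairpin $i$ targeting gene $g$:

$$w_i^{(a)} = b_i \, 2^{\, s_g \, e_i \, t_a}, \qquad
  y_i^{(a,r)} \sim \mathrm{NB}\!\left(\mu = D \frac{w_i^{(a)}}{\sum_j w_j^{(a)}},\ \phi\right)$$

where $b_i$ is a log-normal baseline abundance (sdlog 1, reproducing the
skew of real pooled libraries), $s_g \le 0$ the per-week log2 selection
coefficient, $e_i \in [0,1]$ the hairpin's knockdown efficacy, $t_a$ the
weeks of selection in arm $a$, $D$ the sequencing depth and $\phi$ the
negative-binomial dispersion (variance $\mu + \phi\mu^2$). The selection
term applies in the resistant arm for resistance drivers, in both the
resistant and the parental-acute arm for acute-essential genes, and nowhere
for neutral genes. The closed-form arm-wise mean depletion
$2^{s_g e_i t_a}$ is what the Monte-Carlo tests check convergence against.

Efficacies follow the library model of `random_screen_truth()`: a fraction
(default 0.8) of each gene's hairpins are active with $e_i \sim
\mathrm{Beta}(5, 2)$ (mean $\approx 0.71$), the rest inert ($e_i = 0$).
Inert hairpins are the reason a multi-hairpin gene filter carries
information.

Default study conditions mirror a genome-wide screen at desk scale: 4 weeks
of selection, two million reads per sample, $\phi = 0.05$, three replicates
per arm, drivers at $s = -0.75$/week. The acute arm uses the same selection
window as the resistant arm — the design intent is that any shared
essentiality expresses comparably in both arms, which is what makes the
subtraction sound; an acute arm much shorter than the resistant arm would
under-call shared essentials and weaken the filter.

What the generator deliberately does **not** model: PCR amplification bias,
UMIs, infection multiplicity and puromycin bottlenecks (only their net
effect — baseline composition plus stochastic counts — matters to the
analysis), and the physical kinetics of drug selection. Passing recovery
tests therefore show that the *analysis* inverts the *stated* generative
model; they do not certify performance under amplification artifacts or
batch structure absent from that model.

## Depletion scoring and candidate tiers

Counts are CPM-normalized; per hairpin,

$$\mathrm{lfc}_i = \log_2 \frac{\bar{x}^{\mathrm{trt}}_i + \epsilon}
  {\bar{x}^{\mathrm{ref}}_i + \epsilon}, \qquad \epsilon = 0.5\ \mathrm{CPM},$$

and a hairpin is *depleted* when $\mathrm{lfc}_i$ is strictly below the
threshold (default $-1$, at least two-fold loss) **and** its mean reference
abundance is at least the floor (default 5 CPM; a hairpin that was never
well represented cannot credibly drop out). The mean-of-replicates CPM log
ratio was chosen as the default statistic because it is simple, closed-form
and independently recomputable in tests; rank-aggregation scores are a
documented extension, not the default.

`subtract_acute()` clears the depleted flag of every hairpin also depleted
in the acute arm (hairpin-level by default; a gene-level variant clears all
hairpins of any acute-hit gene). `aggregate_genes()` then tiers genes:
**candidate** at $\ge 2$ surviving depleted hairpins, **stringent** at
$\ge 4$ — i.e. *more than three* independent hairpins, the conventional
high-confidence cut in this assay family; exactly three hairpins is
candidate, not stringent. Published screens of this design do not always
state the quantitative rule behind their headline gene counts; the
candidate tier ($\ge 2$) is this package's explicit, configurable stand-in
for such unstated permissive criteria. Both thresholds, the lfc cut and the
abundance floor are `run_config()` fields.

## The negative-binomial test

The differential-expression stage is written in-house so that every number
it produces is checkable against an oracle:

* **Size factors** — median-of-ratios: a pseudo-reference per gene
  (geometric mean over genes positive in all samples), per-sample median of
  natural-scale ratios to it, centered to geometric mean 1.
* **Dispersion** — pooled within-group method of moments per gene,
  $\hat\phi^{raw}_g = (\sum_k SS_k - \sum_k (n_k{-}1)\bar x_k) / \sum_k
  (n_k{-}1)\bar x_k^2$, floored at 0, then shrunk to the across-gene mean:
  $\hat\phi_g = (1-w)\hat\phi^{raw}_g + w\bar\phi$. The default weight is
  $w = 0.7$: with three replicates per group the raw moment carries ~4
  residual degrees of freedom, and a precision-based weighting (prior
  strength of order 10 df, as moderated-dispersion estimators use) puts
  most weight on the stable common value. At $w = 0.3$ the likelihood-ratio
  test measurably over-rejects under the null (empirical type-I error
  $\approx 0.085$ at nominal 0.05, 3 vs 3, $\phi = 0.1$); at $w = 0.7$ it
  is calibrated ($\approx 0.06$). The weight is an exposed argument.
* **Test** — per gene, counts $y_{ij} \sim \mathrm{NB}(s_j q_i, \hat\phi_i)$
  with size factors $s_j$ fixed; the common-abundance MLE solves the score
  equation $\sum_j (y_j - s_j q)/(1 + \phi s_j q) = 0$ (monotone in $q$,
  solved by damped Newton, vectorized over genes; at $\phi = 0$ it reduces
  in one step to the Poisson MLE $\sum y / \sum s$). The likelihood ratio
  of free-per-group vs equal means is referred to $\chi^2_1$. The LRT was
  preferred over a Wald test for stability at low counts; $\phi$ is held
  fixed during the fit.
* **Reporting** — log2 fold change from normalized group means with
  pseudocount 0.5 (so it is finite and antisymmetric under label swap);
  group order is the sorted label order (or factor levels), making the
  contrast orientation deterministic. BH-adjusted p-values are reported
  alongside, but the significance filter defaults to the *unadjusted* p,
  matching the convention this pipeline reproduces: `filter_de()` takes
  genes with $p < 0.05$ strictly and $|\mathrm{lfc}| \ge 0.58$ inclusively
  (about 1.5-fold; "minimum" fold change is read as inclusive, "smaller
  than" as strict). `use_fdr = TRUE` switches the filter to `padj`.
  All-zero genes are dropped before testing and reported via a message.

## Integration and enrichment

Candidate integration is set algebra with hygiene: symbols are upper-cased
and whitespace-trimmed (no alias mapping — symbol synonymy is out of
scope and must be resolved upstream), intersections record provenance, and
`venn_summary()` returns all 3 or 7 disjoint region counts, which always
sum to the union's size. The screen-vs-DE overlay defaults to the union of
up- and down-regulated genes, since loss of a maintenance driver may be
marked by deregulation in either direction; direction is an argument. When
comparing against published Venn panels, note that text and figure legends
of published studies occasionally disagree by a few genes; `venn_summary()`
simply reports the exact counts of its inputs.

Enrichment offers both families: `hypergeom_test()` gives the exact
upper-tail $P[X \ge k]$ (identical to one-sided Fisher, verified
exhaustively in tests), with the measured universe — not the genome — as
default background; `gsea_es()` implements the classic weighted running-sum
statistic (weight exponent default $p = 1$; increments
$|r|^p / \sum_{hits} |r|^p$, decrements $1/(N-m)$, ES the signed extremum,
always in $[-1, 1]$) and `gsea_perm_p()` a gene-permutation null with the
add-one estimator $(1 + \#\{|ES_\pi| \ge |ES|\})/(1 + B)$. Gene
permutation (not phenotype permutation) is the only null available to a
consumer of a single ranked list; normalized enrichment scores are out of
scope. ORA significance defaults to $P \le 0.05$ inclusive.

## Numerical and degenerate-input choices

* Newton iterations stop at relative change $10^{-10}$ with step damping
  (never below a tenth of the current value); p-values are clipped into
  $(0, 1]$.
* `dnbinom` is evaluated with `size = 1/max(phi, 1e-12)`, so $\phi = 0$
  follows the Poisson limit smoothly (verified against a directly coded
  Poisson LRT).
* Barcode matching: exact match always wins; at `max_mismatch = 1` a
  one-error neighbor index is consulted, and any neighbor reachable from
  two library barcodes is marked ambiguous and discarded — a read is never
  double-counted. Reads containing `N` are discarded under either policy.
  Matching is case-insensitive.
* Empty FASTQ files yield all-zero columns with zero discards; short reads
  are no-calls tallied as discards, not errors.
* `aggregate_genes()` on an empty call table returns an empty summary;
  ties in GSEA extrema resolve to the earliest position (`which.max`).
* Every generator is a pure function of its arguments including `seed`
  (RNG state is restored afterwards), and the pipeline derives all stage
  seeds from the single config seed, which is what makes `report.json`
  byte-identical across reruns.

## Scale of the verification experiments

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to make the statistical properties measurable while staying
desk-scale: screens of 100 genes x 8 hairpins at depth $2 \times 10^6$
over 20 seeds for recovery; 5,000-gene, 3 vs 3 null simulations over 10
seeds for calibration; 20 seeds at $n = 8$ for power; exhaustive
hypergeometric checks for all universes up to $N = 30$. A genome-scale run
(~6,000 genes, ~50,000 hairpins) is the same code path and completes in
minutes, but recovery claims verified here are claims about the stated
generative model at the stated sizes.

## Known limitations

* The depletion call has no p-value model; it is a thresholded effect
  size. A rank-based or beta-binomial dropout model is the natural
  extension point.
* The DE stage handles exactly two groups; multi-factor designs are out of
  scope.
* Gene symbols are matched textually; no alias resolution.
* The FASTQ emitter models substitution errors only (no indels, no quality
  gradients), matching what the Hamming-distance matcher can absorb.
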