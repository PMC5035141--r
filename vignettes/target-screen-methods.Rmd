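---
title: "Methods: screening for direct Six1/Eya1 targets in expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for direct Six1/Eya1 targets in expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppescreen)
```

# The screen and its assumptions

The experimental paradigm behind this package identifies *direct*
transcriptional targets of Six1 and Eya1 in pre-placodal ectoderm: GR-fusion
constructs are overexpressed, protein synthesis is blocked with
cycloheximide (CHX), and nuclear translocation of the fusion protein is then
induced with dexamethasone (DEX). Because no new protein can be made, any
transcriptional response to DEX is attributed to the induced factor acting
directly. The design is factorial: four injection groups (Six1, Eya1,
Six1+Eya1, un-injected) × two treatments (CHX, CHX+DEX) × two biological
replicates, quantified as FPKM.

The package assumes its inputs are expression tables of this shape. It does
not model read counts or FPKM estimation; statistical statements are made on
the log2(FPKM+1) scale throughout, which linearises fold changes and keeps
zero-expression genes finite.

# The filter cascade

Per injection group, the induction contrast is

\[
\mathrm{log_2FC} = \log_2\frac{\overline{\mathrm{FPKM}}_{\mathrm{DEX}} + c}
                              {\overline{\mathrm{FPKM}}_{\mathrm{CHX}} + c},
\qquad c = 1 \text{ (pseudocount)},
\]

with replicate FPKMs averaged arithmetically before the ratio — matching the
pooling behaviour of the FPKM-based upstream tool family, and stated here
explicitly so results are reproducible from the tables alone. A gene is
called differentially expressed (up) when:

1. mean FPKM in the CHX+DEX condition ≥ `fpkm_min` (default 1);
2. log2FC ≥ `fc_min_log2` (default 1, i.e. two-fold);
3. the un-injected control comparison holds.

The down direction mirrors the fold-change clauses; the expression floor
stays on the CHX+DEX condition in both directions, as the cascade is
defined. All boundaries are inclusive (≥), uniformly with the
transcriptome-level floor; inclusive-vs-strict matters only for genes
sitting exactly on a threshold and is documented rather than consequential.

**Control rule.** Two formulations of criterion 3 are implemented because
both are defensible readings of the screen's design. The default `delta`
rule requires the experimental fold change to exceed the control fold change
by at least `control_delta_min_log2` (default 1 log2 unit); it is symmetric
between directions and excludes DEX artifacts by *relative* response. The
alternative `absolute` rule caps the control's own fold change at
`control_abs_max_log2` (default 0.5 log2 units). On real data the two rules
can produce different gene lists; the choice is a config switch
(`control_rule`), and the per-group screen tables always carry the control
fold change so the decision is auditable.

Individual treatment groups have two replicates and receive no p-value: the
cascade is deliberately fold-change based, and formal significance lives in
the merged re-analysis.

# Co-regulation classification

DE sets from the three treatment groups (S = Six1 alone, E = Eya1 alone,
C = combined) are partitioned into the seven disjoint Venn regions per
direction. Classes:

| region(s)      | class                       |
|----------------|-----------------------------|
| SEC            | `coregulated_all_three`     |
| C only         | `coregulated_combined_only` |
| S only, S∩C    | `six1_independent`          |
| E only, E∩C    | `eya1_independent`          |
| S∩E only       | `ambiguous_pair_only`       |

The co-regulated aggregate is defined as `coregulated_all_three` ∪
`coregulated_combined_only`. Genes DE in both single-factor groups but *not*
the combined group (`ambiguous_pair_only`) are deliberately kept out of that
aggregate: a gene responding to each factor alone but not to both together
does not fit the co-regulation model, and folding it into either aggregate
would silently change the class arithmetic. The class is flagged prominently
in outputs instead.

The top-fraction overlap test ranks two groups' genes by descending fold
change over the same universe, takes the top `ceiling(fraction × n)` of each
(default fraction 0.1), and applies a Fisher exact test to the 2×2
membership table. Two-sided is the default (one-sided enrichment is an
argument); ranking ties are broken lexicographically by gene id so the top
set is deterministic.

# Merged re-analysis

Pooling schemes treat replicates as exchangeable across the groups sharing a
factor: `six1_m` = {Six1, Six1+Eya1}, `eya1_m` = {Eya1, Six1+Eya1},
`six1_eya1_m` = all three injected groups. The un-injected group is never
pooled. At the default design this gives 4, 4 and 6 replicates per pooled
condition.

Per gene the package computes a Welch (unequal-variance) two-sample *t*
statistic on log2(FPKM+1) replicate values with Welch–Satterthwaite degrees
of freedom and a two-sided p-value, then Benjamini–Hochberg q-values. This
is a deliberate, transparent substitute for the negative-binomial machinery
of count-based DE tools: the package starts from FPKM tables (no counts, no
dispersion estimation is possible), and a Welch test on the log scale is the
standard defensible choice at that point. Significance additionally requires
the filter cascade, so a tiny q-value on a sub-two-fold change never
produces a call on its own.

Degenerate inputs are contracted explicitly rather than left to error: zero
variance in both conditions with equal means gives p = 1; zero variance with
unequal means gives the minimum representable positive p and a `degenerate`
flag. This keeps the pipeline total on noise-free simulations.

# Enrichment

`fisher_enrichment()` is the upper-tail hypergeometric probability
P(X ≥ k) at fixed margins; `ease_score()` is the same quantity with the
observed overlap reduced by one (floored at zero), a conservative variant
that penalises terms supported by a single gene. The cluster score is
E = −log10 of the geometric mean of member EASE p-values, computed in log
space with p-values floored at 1e-300 to avoid underflow. The phrase
"geometric mean of the scores" is interpreted on the p-value scale before
the −log10 transform — the only reading under which strongly enriched
clusters get large E (e.g. member p-values 1e-40 and 1e-46 give E = 43)
rather than values near zero. Term-to-cluster assignment is user input; no
fuzzy clustering of terms is performed, since any such grouping is a
curatorial choice that should be visible, not baked in.

# Prioritisation

The well-supported list requires log2FC ≥ 1 in at least two of the three
individual groups, with missing entries failing the threshold (the screen's
own tables print values only down to 0.5, so absence is information). When a
control column is present, every *passing* group must additionally beat the
control fold change by at least 1 log2 unit. Transcription-factor status is
an explicit input list and rescues are explicit gene ids — both curatorial
decisions that the package records (`is_tf`, `rescue`) but never infers.
Known-target recovery is presence-with-fold-change reporting, deliberately
looser than the DE criteria: recovering an established target at 1.9-fold is
evidence about the screen even though it misses the cutoff.

# The synthetic-data generator

`simulate_experiment()` emulates the screen's design with planted structure:

- **Baseline** expression is Gaussian on the log2(FPKM+1) scale
  (`baseline_log2_mean = 5`, `baseline_log2_sd = 2` by default, i.e. median
  FPKM ≈ 31 with a heavy right tail — typical of expressed genes after a
  FPKM ≥ 1 floor). Parameterising baseline on the same +1-shifted scale the
  contrast uses is a deliberate choice: it makes the noise-free contrast of
  an affected group recover the planted effect *exactly*, so truth-table
  tests can assert equality instead of approximation.
- **Classes**: co-regulated targets come in high-response-threshold
  (respond in all three injected groups) and low-response-threshold
  (respond only to combined injection) variants, alongside Six1-only,
  Eya1-only, DEX-artifact (respond in every group including un-injected)
  and null genes; each non-null class has up- and down-regulated variants
  via the sign of its planted effect. The default mix is 84% null, 10%
  up-regulated targets/artifacts and 6% down-regulated — a DE fraction and
  up/down imbalance of the same order as the screen reports.
- **Effects** are additive in log2 space on DEX samples of the responding
  groups only; CHX samples are effect-free, mirroring the blocked-protein
  baseline. Default effect size ±3 log2 units (sd 0.5) sits in the middle
  of the screen's reported fold-change range (1–7.5). No magnitude
  difference between high- and low-threshold classes is asserted — the
  distinction the screen supports is *which groups respond*, not by how
  much — but per-class means and sds are config-exposed.
- **Noise** is i.i.d. Gaussian per sample in log2 units (default sd 0.2,
  consistent with the high between-replicate correlation the screen
  design expects). No mean–variance trend is modelled; that is a real
  feature of RNA-seq data this generator does not emulate, so passing
  sensitivity/FDR tests here demonstrate correct mechanics, not
  performance on count-level noise. Neither are gene–gene correlation,
  batch effects, or library-size artifacts.
- **Determinism**: one integer seed drives a single random stream with a
  fixed draw order (class assignment is a deterministic largest-remainder
  apportionment, then baseline, effects and noise are drawn in that
  order), so identical configs are bit-reproducible.

FPKM values are reconstructed as `2^x − 1`, clamped at zero; with the
default baseline the clamp touches well under 1% of genes and shifts the
realised baseline mean by far less than its standard error.

# Problem sizes and numerical checks

The test suite validates each operation against an independent oracle:
enrichment p-values against explicit enumeration with `choose()` for
backgrounds up to 60 (and conservativeness of EASE on 1,000 random tables),
BH q-values against the step-up formula written out, the Welch statistic
against its textbook formula and `stats::t.test`, and filter outcomes on
noise-free simulations against direct evaluation of the generative
equations. Stochastic properties use fixed seeds at moderate sizes chosen to
make the expected margins wide: FDR control under a 2,000-gene global null
(noise sd 0.3), ≥ 95% per-group sensitivity for planted |effect| = 3 at
noise sd 0.2 over 1,000 planted genes, and ≥ 90% detection at q < 0.05 in
the six-replicate merged scheme over 500 planted genes. End-to-end pipeline
determinism is asserted by byte-comparing all outputs across two runs.

# Known limitations

- FPKM-scale inference ignores count-level uncertainty; genes with very low
  expression have noisier fold changes than the Welch model assumes.
- The published merged-analysis gene counts depend on the original
  count-based tool's internal test and the raw sequencing data, and are not
  reproducible from expression tables; this package's merged statistics are
  its own, defined above.
- Annotation condensing keeps the highest-mean-FPKM transcript per
  annotation by default (summing FPKM across transcript models would
  double-count length-normalised signal); `method = "sum"` is available
  where summation is wanted. How duplicate annotations were condensed in
  the original screen is not recoverable, so the rule here is declared, not
  inferred.
- qPCR quantification assumes amplification efficiency 2 per cycle;
  efficiency is an argument but no standard-curve estimation is provided.
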