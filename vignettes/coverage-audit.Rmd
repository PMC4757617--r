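---
title: "Coverage completeness auditing: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage completeness auditing: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mean depth of coverage is a poor summary of whether a sequencing assay can
support clinical variant calling: what matters is the *guarantee* that every
base of every assessable exon clears a minimum read depth. This package
audits that guarantee. Its statistics are organised around one definition —
an interval is **complete at cutoff t** iff every base of the half-open
interval has depth ≥ t — and everything else (stratum percentages,
confidence intervals, near-miss reports, the maximum complete threshold, the
cv decomposition) is built on top of it.

All internal coordinates are 0-based half-open; 1-based inputs (per-base
depth TSVs, variant positions) are converted at the reader boundary. Bases
absent from a depth file are depth 0, never skipped: a gap that a depth
extractor chose not to emit is exactly the kind of gap a completeness audit
exists to find.

# The synthetic study

The simulator generates the data the audit consumes, with the statistical
structure the analysis assumes. Expected depth at a base of exon $e$ in
sample $s$ is

$$\lambda_{es} = \mu \cdot g(\mathrm{GC}_e) \cdot b_e \cdot a_s,$$

where $\mu$ is the platform mean depth, $g$ a GC-efficiency curve, $b_e$ a
per-exon capture efficiency shared across samples (lognormal, mean 1,
$\sigma_b$ = `exon_bias_sd`), and $a_s$ a per-sample library factor
(lognormal, mean 1, $\sigma_a$ = `sample_effect_sd`). Per-base counts are
Poisson by default (negative binomial behind `noise = "nb"`, deterministic
rounding behind `"none"`). Because the lognormals are mean-1 parameterized,
their coefficients of variation are $\sqrt{e^{\sigma^2} - 1}$, which is what
the cv decomposition recovers on simulated data — the key property linking
the generator to the variability statistics.

The GC curve is log-quadratic, peaked at `gc_opt` (default 0.45) and
floor-clamped at 0.01:
$g(x) = \max(0.01,\, e^{-k (x - \mathrm{gc\_opt})^2})$ with $k$ =
`gc_strength`. $k = 0$ gives a flat curve. The bundled profiles encode the
three study conditions:

| profile | $\mu$ | $k$ | $\sigma_b$ | $\sigma_a$ | targets only |
|---|---|---|---|---|---|
| `wes_profile()` | 154 | 24 | 0.5 | 0.1 | yes |
| `wgs_wpcr_profile()` | 65 | 2 | 0.1 | 0.1 | no |
| `wgs_pcrfree_profile()` | 65 | 0 | 0.1 | 0.1 | no |

The capture strength $k = 24$ was set so that efficiency at GC 0.8 is a few
percent of peak, matching the steep unimodal decline capture platforms show
in GC-rich sequence; it makes GC-rich first exons — simulated ~8 GC
percentage points above the exon body, i.e. ~59% vs ~51% — measurably harder
to complete at 154× mean depth, while ordinary exons mostly pass. The
PCR-free profile keeps a small residual $\sigma_b = 0.1$: real PCR-free
libraries retain some exon-level variability, and a strictly zero value
would make the intra-individual cv purely a noise artifact. $\sigma_b = 0.5$
for capture reproduces an intra-individual cv near 0.6, several-fold above
genome sequencing, with an inter-individual cv near 0.1 on both — the
"reproducible bias, comparable noise" signature.

Two mean-depth conventions exist in the wild: $\mu$ as the pre-bias per-base
expectation, and $\mu$ as the realized on-target mean. The profile exposes
both (`mean_convention`); the default `"on_target"` rescales $\lambda$ so
the expected mean over exon bases equals $\mu$, which is how platform mean
depths are usually quoted.

Annotation geometry: one synthetic chromosome per gene (coordinates can
never collide), exons non-overlapping with exact-count GC targets (a
sequence of length $L$ gets exactly $\mathrm{round}(g L)$ G/C bases, so the
realized GC is always within 0.05 of target), exactly one first exon per
transcript at the 5′ end of its strand. Confounder resources (mappability
gaps, CNV overlaps, identity mismatches) knock out configurable exon
fractions and ship with a ground-truth sidecar so tests compare filter
output against emitted labels, never against generator internals.

What the generator does **not** emulate: read-level artifacts (mapping
quality, duplicates, strand), realistic sequence composition beyond GC
fraction, overlapping transcripts or shared exons across genes, real capture
kit target design, and length-biased mappability structure. Passing tests
therefore demonstrate that the statistics are computed correctly and that
the platform contrast follows from the modelled biases — not that any real
kit achieves these exact percentages.

# Statistical conventions

- **Across-sample 95% CI** on stratum percentages uses the t distribution on
  the per-sample values (n = 5 samples is the study condition; the normal
  approximation is available via `ci_method = "normal"`). A single sample
  yields no CI, with a logged note — never a fabricated interval.
- **Display rounding** is two decimals ("100.00%" implies a deviation of at
  most 0.005%); exact per-sample fractions are retained in the
  machine-readable output, and the formatted table is always derived from
  them.
- **cv convention**: sample SD (n − 1 denominator) in both directions, since
  five samples are few; switchable to the population SD (`sd_denom = "n"`)
  and recorded in every summary. Exons are unweighted (length-weighted GC
  profiles are available behind `weight = "length"`).
- **Inter-individual cv** averages per-exon cv over exons; exons with zero
  mean depth carry no cv and are excluded with a count. Pooling across exons
  instead of averaging would weight deep exons differently; the mean-over-
  exons convention is symmetric with the intra direction.
- **Variant coverage** assesses the full reference span by default
  (`mode = "span"`); a span-0 insertion requires both bases flanking the
  insertion point. Assessing only the first position (`"start_only"`) is
  exposed because variant catalogs differ in how they anchor indels.
- **Exon deduplication**: exons shared by transcripts are counted once per
  coordinate triple; first-exon sets are the union over transcripts,
  deduplicated the same way.
- **Eligibility**: "uniquely mappable" means 100% containment in the
  mappability intervals by default (`containment_fraction` exposes laxer
  thresholds); CNV exclusion triggers on ≥ 1 bp overlap (the strictest
  reading of "not overlapping"); assembly identity is consumed as a
  precomputed exon-level table — recomputing it via liftover is deliberately
  out of scope, but `sequence_identity_table()` derives the flag by exact
  string equality when both assemblies' exon sequences are at hand. An exon
  missing from the identity table is a mismatch under the lenient default
  and an error under `strict_identity = TRUE`; the choice is the caller's
  because identity of *sequence* and identity of *coordinates* are different
  claims and upstream tables conflate them differently.

# The 13× boundary and calibration

The completeness cutoff of 13 reads is not arbitrary: it is the kind of
cutoff one *derives* from data, as the largest t at which a platform's
coverage is still everywhere complete — `max_complete_threshold()`, the
global minimum depth over assessed bases. `calibrate_min_depth()` shifts
simulated tracks by a constant so that this global minimum equals a chosen
target, which lets tests and the acceptance script place a simulated genome
platform exactly at its completeness boundary: 100.00% everywhere at t = 13
and below 100% at t = 14. The linear scaling rule
`required_mean_depth(65, 13, 20) = 100` then answers what mean depth the
same performance implies for a stricter per-base guarantee.

# Problem sizes

The bundled analysis and the acceptance script audit 200 genes (~1,100–1,200
exons after eligibility) with five samples per platform; cv-recovery checks
use ~2,000 exons for the intra direction and 150 samples for the inter
direction, sizes at which the sample cv of a lognormal is stable to a few
percent. These are the package's chosen study sizes; all of them are plain
`sim_config()` parameters.

# Known limitations

Depth tracks are taken as ground truth — no mapping-quality or base-quality
filtering is applied before counting, because depth extraction is an
upstream step users run with standard tools. The whole-genome profiles apply
the exon's GC efficiency only within exons and a background efficiency
elsewhere, so off-target GC structure is flat by construction. Gene panels
(ACMG-like, variant-hosting exon sets) are user-supplied ID lists; no
licensed catalog content is bundled, and the synthetic variant catalog
stands in for tests. CNV/SV detection, capture normalization algorithms, and
cost considerations are outside the package's scope.
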