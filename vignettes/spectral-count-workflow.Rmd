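---
title: "Spectral-count quantification in two-organism cultures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count quantification in two-organism cultures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NSAFquant)
```

# The measurement model

Bottom-up shotgun proteomics with spectral counting treats the number of
MS/MS spectra assigned to a protein's peptides in one run (SpC) as a
semi-quantitative proxy for its abundance. Conditional on a run's total
number of assigned spectra, the per-protein counts behave approximately
multinomially, with allocation probabilities proportional to molar
abundance × protein length (longer proteins yield more tryptic peptides)
modulated by peptide-level detectability effects — most prominently a
roughly three-fold depression for proteins with transmembrane domains,
whose tryptic peptides are fewer and less MS-compatible. Everything in
this package follows from that model: the normalization chain removes the
known multiplicative nuisances; the synthetic generator samples from
exactly this model so recovery can be tested.

The package targets a specific experimental design: a host organism grown
alone (`pure_host`), the host carrying its obligate ectosymbiont
(`coculture`), and a symbiont fraction purified from a co-culture
(`purified_symbiont`), each measured in technical triplicate.

# Identification layer

PSMs are score-filtered with per-charge XCorr minima
(`{1: 1.8, 2: 2.5, 3: 3.5}`, charges above 3 reusing the charge-3 value as
a conservative extension) and ΔCn ≥ 0.08 — the conventional SEQUEST/
DTASelect operating point for LTQ/Orbitrap data. Protein assembly applies
the two-peptide rule (≥ 2 distinct peptides, ≥ 1 unique, ≥ 2 spectra).
Peptide uniqueness is defined against the *retained* protein set, which is
circular; we resolve it with one re-pass: uniqueness is first evaluated
against all matched proteins, the rule applied, and assembly repeated once
against the survivors. A single re-pass is deterministic, order-independent
and in practice at the fixed point (a peptide shared only with a discarded
protein correctly becomes unique). PSMs whose accession set mixes target
and decoy entries are counted as target matches, the usual convention for
concatenated searches; the decoy FDR estimator is 2·D/(T+D) capped at 1,
with D/T available by flag. Both PSM-level and protein-level estimates are
exposed, since published summary FDRs rarely state their level.

In-silico tryptic digestion cleaves C-terminally to K/R except before P,
with up to 2 missed cleavages and a 6–50 residue detectability window by
default. The window stands in for "detection criteria" (mass range,
chromatographic behavior) without modeling them; all three knobs are
arguments. Peptides are compared as written — no I/L folding — the
simplest convention that keeps uniqueness logic testable.

# Quantification chain

**Balancing (aSpC).** A unique peptide keeps its full SpC. A shared
peptide's SpC is apportioned among its sharing proteins proportionally to
their unique-peptide SpC totals in the same run. When no sharer has unique
spectra in a run the count is split equally — a deterministic fallback
that keeps the per-run sum of aSpC equal to the number of assigned
spectra (each spectrum counted once). Note the raw SpC layer deliberately
keeps the inflated convention (shared spectra counted fully for every
sharer), because that is the bias balancing corrects; conservation is
therefore a statement about aSpC versus the spectrum total, not versus the
SpC layer's column sum.

**NSAF.** `NSAF_i = (aSpC_i / L_i) / Σ_j (aSpC_j / L_j)` per run over
detected proteins (aSpC > 0); columns sum to 1. The formula is the
standard length-normalized spectral abundance factor from the spectral
counting literature.

**nSpC.** NSAF × a single scale constant, default 46,541 — the average
per-run spectra total of the emulated study — so values read like
spectral counts. When unset the constant is computed as the mean of the
observed per-run totals. Downstream fold ratios are provably invariant to
this choice (and a property test asserts it).

**RSpC.** The host's nSpC values in the co-culture are multiplied by one
global factor so the host's co-culture total equals its pure-culture
total. This corrects the systematic depression of host spectra caused by
the symbiont's share of the co-culture's sampling capacity. We use
condition totals (summed over replicates) for the factor because the
correction models a composition effect, which is a property of the sample,
not of an individual run; a per-replicate variant is available by flag.
The purified-symbiont sample passes through unchanged — the transfer
screen's φ is a ratio of within-sample proportions and is invariant to any
per-sample rescaling anyway.

# Differential abundance

Condition summaries are per-protein sums of RSpC over the three
replicates. Fold ratios are computed at full precision; display rounding
is a separate, caller-chosen precision because published tables of this
kind use different typography for different ratio ranges (one decimal for
moderate ratios, integers for large up-regulation ratios, two decimals
below 1). Censoring: denominator zero prints as ">50" (detected in one
condition only); numerator zero keeps the exact value 0 — small values
are data, only the display is coarse. Classification into <1.5 / 1.5–2 /
2–3 / ≥3-fold bands is symmetric (r and 1/r share a band with opposite
direction), with band edges belonging to the upper band.

Significance uses Student's pooled-variance t-test on log2 RSpC — the
named test of the emulated workflow — restricted to proteins detected in
every replicate of both conditions; anything else returns `NA` (a
not-testable marker, not an error). Welch's variant and Benjamini–Hochberg
correction are available by flag, but the default follows the original
procedure (raw p ≤ 0.05): fidelity first, rigor optional. The zero-variance
corner (all replicates identical after log2) returns p = 1 for equal means,
so degenerate fixtures behave sensibly.

# Transfer enrichment

For each host protein detected in the purified symbiont fraction,
`φ = (P_N/T_N)/(P_IN/T_IN)` with totals T taken over *all* detected host
proteins in the respective sample (the screen compares proteins against
the whole carried-over host proteome, not against other candidates).
Under pure carry-over, a host protein's share of the host total is the
same in both samples up to counting noise, so φ ≈ 1; genuine transfer
shows up as φ > 2. Proteins with purified-sample RSpC below 20 are kept in
the table but fail the screen: at such counts the φ numerator has
double-digit relative noise, exactly the instability the floor excludes.
The abundance floor is applied to the purified-sample value (the sample
under scrutiny); requiring both samples is a flag. A protein absent from
the co-culture has infinite φ; it is flagged and appended unranked rather
than sorted, since its magnitude is meaningless.

# Gene-set enrichment

Proteins are ranked by the signal-to-noise statistic
`(μ_a − μ_b)/(σ_a + σ_b)` on NSAF replicate values, each σ floored at
0.2·|μ| (and at 0.2 when μ = 0) — the standard guard against
near-constant profiles; `sd_floor = 0` gives the unguarded statistic. The
enrichment score is the weighted Kolmogorov–Smirnov running sum (hits
weighted by |score|^w normalized over hits, misses by −1/(N−N_h); w = 1
default, w = 0 the classic KS statistic), and NES/p-values come from
gene-set permutation: random same-size sets drawn from the ranked list.
With three replicates per condition only 20 distinct phenotype
relabellings exist, far too few for a permutation null, so tag permutation
is a statistical necessity at this design size, not a shortcut. The null
distribution of the permuted ES depends only on set size, so collections
share one null per distinct size — numerically equivalent to per-set
permutation and what makes genome-wide operon collections affordable.
p-values use a +1 pseudocount over same-sign permutations; a set with no
same-sign permutations gets p = 1/(n+1) and an undefined NES, flagged.
Positive ES means enrichment in the condition given first to the ranking
(the co-culture, in the pipeline's default orientation).

Gene sets come from arCOG single-letter functional classes, from operon
identifiers (operon tables are consumed as given — operon prediction is
out of scope), from GMT files, or from two-column TSVs. Singleton sets are
dropped with a message: a one-gene set cannot be distinguished from its
gene.

# The synthetic benchmark

The generator's defaults are the emulated study conditions and are not
tuning knobs: 1444 host and 556 symbiont proteins; log-normal lengths
(median ≈ 280 aa, σ_log = 0.45, clamped to 60–3000) and molar abundances
(σ_log = 1.5, spanning the ~3 decades seen in deep archaeal proteomes);
25% of proteins flagged TMD with spectral yield depressed 3-fold; 46,541
spectra per run, three replicates per condition; co-culture spectra split
68.5/31.5 between host and symbiont; purified-symbiont runs drawing 10%
of spectra from host proteins in proportion to their co-culture weights
(pure carry-over null); ~10% of host proteins given co-culture fold
effects drawn log-uniformly from 2–5×, half down; twenty cross-species
homolog pairs sharing tryptic peptides (exact block copies of consecutive
fully-cleaved peptides, so uniqueness logic is exercised unambiguously);
reversed decoys with filter-passing decoy PSMs at 1.5% of the spectra
budget, reproducing a ~3% PSM-level FDR.

Two deliberate simplifications matter when interpreting green tests.
First, sequences are uniform-random over the 20 residues, so peptide
detectability has no physicochemical structure; spectra are spread
uniformly over a protein's fully-cleaved detectable peptides. Second, the
desk-scale decoy peptide space is tiny compared with a real search, so
decoy *proteins* assemble far more often than in practice: the generator
calibrates PSM-level FDR, and protein-level decoy rates should not be read
as realistic. Passing recovery tests shows the analysis chain is correct
under the stated counting model; it does not certify behavior under
ionization suppression, retention-time effects or biological replicate
variance, none of which are modeled.

The ten designated "transferred" proteins default to 5× enrichment and are
drawn from the top abundance-weight quartile of the host proteome. That
choice mirrors the screen's own RSpC ≥ 20 floor: a transfer planted below
the detection limit is unrecoverable by any spectral-count method, so
benchmarking sensitivity on such proteins would measure the detector, not
the method.

All generator randomness flows from a single integer seed; identical
configurations produce byte-identical FASTA, annotation, ground-truth and
PSM files, which is what makes the end-to-end determinism test meaningful.

# Recovery behavior and known limitations

Two attenuation effects are worth understanding because they shape what
"recovery" means on this kind of data.

*Detection truncation of the TMD ratio.* The TMD bias summary averages
over detected proteins. Low-abundance TMD proteins drop out of detection
more often, which raises the detected TMD mean and pulls the
non-TMD/TMD ratio below the planted 3× — mildly in the deep
single-organism sample (≈ 2.6 at default depth), more strongly in mixed
samples where per-protein depth is diluted (≈ 2.2 in the co-culture, less
in the purified fraction, whose composition is further distorted by
contamination and transfer up-weighting). Recovery of the planted factor
is therefore asserted on the pure-culture sample, where the estimator is
well-posed; the attenuated mixed-sample values are expected behavior, not
failures. This mirrors real data, where average TMD depression is
reported as "2–3 fold".

*Compositional closure of fold ratios.* Relative-abundance ratios are not
independent across proteins: planting fold effects changes the host
weight total, so every ratio carries a shared closure factor (typically
5–15%), on top of Poisson noise (~18% CV at the 20-count quantification
floor). Per-protein fold recovery is therefore evaluated as a median-level
statement (median relative error ≤ 25%, most proteins within 25%), not a
uniform bound — a uniform bound at this depth would be violated by
counting noise alone with high probability.

Other limitations: intensity-based quantification (iBAQ/LFQ), isobaric
labeling, match-between-runs, PTM localization and empirical-Bayes count
models (negative-binomial shrinkage) are out of scope; the inference layer
is intentionally the plain t-test of the emulated workflow. Replicate
correlations are computed on untransformed values including zeros by
default (log2 by flag) — published correlation figures of this kind rarely
state their transform, so they are surfaced as QC, not asserted against.

# Problem sizes used by the test suite

Unit tests run on hand-built fixtures and a small synthetic dataset
(80 + 30 proteins, 5,000 spectra/run). The acceptance-style tests run the
generator at its full default scale (1444 + 556 proteins, 46,541
spectra/run, nine runs, ~425k PSMs), which the implementation processes in
well under a minute; the end-to-end determinism check runs the whole
pipeline twice on that dataset. Monte-Carlo calibrations use 1000 random
balancing instances, 2000 null proteins for t-test type-I error, and 200
random gene sets against 400 permutations for p-value uniformity — sizes
chosen so each check has enough resolution to fail informatively while the
whole suite stays interactive.
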