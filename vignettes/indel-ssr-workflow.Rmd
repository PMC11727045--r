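---
title: "InDel-SSR marker development and association analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{InDel-SSR marker development and association analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelssr)
```

# The marker system

An *InDel-SSR* is a composite molecular marker: an insertion/deletion
polymorphism that lies within 500 bp of a microsatellite (SSR) tract. A
PCR primer pair spanning the InDel amplifies a product whose length shifts
with the InDel allele, so the marker can be scored on a gel as
presence/absence of discrete bands, while the nearby repeat tract makes
the region mutation-rich and the product length-variable. `indelssr`
implements the full desk side of developing such markers from a reference
genome and InDel calls, and the downstream population-genetic and
marker-trait analyses that a germplasm study runs on the resulting band
data.

The pipeline is: **discover** (SSR detection near InDels) → **screen**
(primer design and product-level filtering) → **pcr** (in-silico banding
of a genotyped cohort) → **stats** (per-marker allele statistics) →
**diversity** (distances, UPGMA tree, PCA, ΔK, kinship) → **assoc**
(GLM/MLM marker-trait models) → **genes** (candidate windows). A
synthetic-data module generates every input with known ground truth.

# SSR detection

A perfect SSR is a maximal tandem run of a 1–6 bp motif meeting a
per-motif-length copy threshold. The defaults follow the standard MISA
configuration used for marker development:

| motif length | 1 | 2 | 3 | 4 | 5 | 6 |
|---|---|---|---|---|---|---|
| min. copies | 10 | 5 | 4 | 4 | 4 | 4 |

Detection contracts, stated precisely because every downstream count
depends on them:

* a tract is reported **once**, at the smallest motif length at which it
  qualifies. Operationally, only *primitive* motifs (not a power of a
  shorter string) are emitted, so a poly-A run is mono, never di `"AA"`;
* among equal tracts the **leftmost phase** wins: a tract starts where
  its match run starts, so `CAATAATAAT…` yields motif `AAT` anchored at
  the first `A`;
* trailing partial copies are trimmed: `end − start + 1 = motif_len ×
  n_repeats` always holds;
* `N` never matches anything, so tracts cannot cross ambiguous bases and
  motifs never contain them.

Two tracts separated by strictly fewer than 100 bp merge into a
*compound* locus; compounds keep their member tracts, count once in all
totals, and form their own repeat class. The implementation is a
vectorized lag-match/run-length scan; the test suite holds it equal to an
independent brute-force enumerator on hundreds of random sequences with
planted repeats straddling every threshold.

InDel co-localization extracts the window `anchor ± 500 bp` (anchor = the
VCF `POS`, the first reference base of the variant), clipped at
chromosome bounds, and runs the same detection inside it. *Overlap* with
the window suffices — full containment is not required — because the
marker is anchored on the InDel: one InDel with several in-window SSRs is
one marker locus. The locus' repeat class comes from the member tract
nearest the anchor.

## Coordinates

All coordinates in the package are 1-based inclusive — the native
convention of VCF, GFF3 and R itself. Converting between an "internal"
and an "external" convention is exactly where flank and window off-by-one
errors breed, so the package refuses to have two conventions at all.
Window arithmetic (`anchor ± flank`), product intervals and gene windows
are all closed intervals on the same scale.

# Primer design and screening

Candidate enumeration is exhaustive within the constraint box rather than
heuristic: primer length 16–24 nt, reference product length 100–300 bp,
product containing the anchor, melting temperature 50–60 °C, pair ΔTm ≤
3 °C. Tm uses the Wallace rule `2(A+T) + 4(G+C)` below 14 nt and the
GC-count formula `64.9 + 41(n_GC − 16.4)/L` otherwise — deterministic and
monotone in GC content, which is all the constraint logic requires; full
nearest-neighbor thermodynamics (and hairpin/dimer checks) is out of
scope. Candidates are ranked by `|Tm − 55|` summed over the pair, then
`|product − 200|`, then leftmost start — an explicit, documented
tie-break so runs are bit-reproducible. A per-side candidate cap (default
400, ordered by Tm closeness) bounds the pairing enumeration.

Screening then applies the marker-development filter: a pair passes when
its product contains at least 18 bp of SSR tract, those tract bases are
at least 50% A/T ("AT-abundant", operationalized as a configurable
fraction), and the product contains the InDel anchor. Failures list every
violated criterion.

In-silico PCR turns screened pairs plus per-sample genotypes into a band
matrix: an individual's band set is the set of distinct product lengths
implied by its two allele copies (reference length shifted by each
allele's length difference), so homozygotes show one band, heterozygotes
two, and missing genotypes propagate as NA for all of the marker's bands.

# Band statistics

Band patterns are read codominantly: one present band = homozygote, two =
heterozygote, zero or more than two = missing (the cohort may contain
polyploids, but the statistics reported are diploid-style; this is a
documented limitation, not a polyploid model). From allele frequencies
$p_i$ per marker:

* $N_a$ = observed alleles; $N_e = 1/\sum p_i^2$;
* $H_e = 1 - \sum p_i^2$ (uncorrected; a $2N/(2N-1)$ small-sample
  variant is available but off by default);
* $H_o$ = fraction of heterozygous scorable individuals;
* $\mathrm{PIC} = 1 - \sum p_i^2 - \sum_i\sum_{j>i} 2 p_i^2 p_j^2$;
* Shannon $I = -\sum p_i \ln p_i$.

The closed forms are tested against definitional double-sum enumeration
on 10⁴ random frequency vectors, with the order constraints
$\mathrm{PIC} < H_e < 1$ and $N_e \le N_a$ (equality iff equifrequent).
Panel summaries report unweighted means across markers plus the fractions
of markers with PIC > 0.5 and > 0.25, the two conventional polymorphism
cutoffs.

# Diversity toolchain

**Nei's (1972) distance** between units $x, y$ (populations, or
individuals treated as two-allele samples): $D = -\ln(J_{xy} /
\sqrt{J_x J_y})$ with $J$'s averaged over loci. Cauchy–Schwarz guarantees
$D \ge 0$ with equality iff the frequency vectors coincide; pairs sharing
no alleles get a configurable cap (default 10) rather than infinity. A
binary Dice distance on raw band vectors is offered as an alternative.

**UPGMA** is average-linkage agglomeration returned as a rooted
ultrametric tree (branch length = half the merge-height difference). On
any ultrametric input the generating tree is recovered exactly; the suite
verifies this on 50 random trees.

**PCA** of centered band vectors (NA imputed by band mean) fixes each
component's sign so its largest-magnitude loading is positive — PCA is
otherwise sign-ambiguous and runs would not be comparable.

**Evanno ΔK** consumes any table of replicate log-likelihoods by K:
$\Delta K = |L(K+1) - 2L(K) + L(K-1)| / \mathrm{sd}(L(K))$, maximized
over interior K. Bayesian clustering itself (STRUCTURE/ADMIXTURE) is
deliberately not implemented; the tests feed ΔK both constructed tables
with known kinks and synthetic likelihood tables (Gaussian-mixture
log-likelihoods on PCA coordinates with marker-bootstrap replicates) from
structured cohorts.

**Kinship** defaults to allele sharing: the mean over co-scored markers
of the shared-allele fraction (1, ½, 0), rescaled so the minimum
off-diagonal is 0 and identity is 1. A frequency-weighted
(centered-dosage covariance) estimator is available for model-based
contexts.

# Association models

Traits are analyzed per year, never pooled. Marker genotypes enter as
band-dosage columns (0/1/2 copies per band allele) with the last column
dropped for identifiability; the Q matrix likewise drops one group.

* **GLM**: least squares of trait on dosage (+ Q), partial F-test of the
  marker block, complete cases per marker. The marker $R^2$ is the
  incremental variance explained.
* **MLM(K)** and **MLM(K+Q)**: $y = X\beta + u + e$, $u \sim (0,
  \sigma_u^2 K)$. K is eigendecomposed once per trait/year; REML profiles
  the variance ratio $\delta = \sigma_e^2/\sigma_u^2$ by golden-section
  search over $\log\delta \in [\log 10^{-5}, \log 10^{5}]$; each marker
  is tested by a generalized least-squares partial F-test in the rotated,
  whitened basis. The default follows the P3D approximation (variance
  components fixed at the null model, one REML fit per trait/year);
  `p3d = FALSE` refits per marker. Slightly negative kinship eigenvalues
  are clipped to zero; substantially negative ones are an error. With
  K = I the model collapses to the GLM exactly, which the tests assert
  to 10⁻⁶. Missing genotypes are mean-imputed in the MLM (so the
  spectral transform is shared), complete-cased in the GLM.

Significance uses the raw p < 0.05 convention of marker-trait screens; no
multiple-testing correction is applied by default (Benjamini–Hochberg via
`stats::p.adjust` is one line away for users who want it). "Stable"
markers are those significant in at least two models, the usual guard
against single-model artifacts. Candidate genes are looked up in a 1 Mb
window around each stable marker's anchor; "a 1 Mb region surrounding"
is read as a *total* 1 Mb (± 500 kb), with `mode = "flank"` giving ± 1 Mb
for the other reading. Windows clip at chromosome ends and results sort
by distance to the anchor.

# The synthetic-data generator

The generator's defaults are the study conditions the package validates
against: 121 individuals from 3 subpopulations, 219 multi-allelic
markers, 10 traits over 2 years. Its model, stage by stage:

* **Genome**: i.i.d. uniform ACGT background, scrubbed of accidental
  near-threshold repeats so that the planted truth tables are exhaustive;
  planted tracts use random primitive AT-biased motifs with copy numbers
  *below, at and well above* each threshold; a configured fraction of
  InDels is placed adjacent to (or inside) an above-threshold tract, the
  rest far from any. Because the background is sanitized, discovery
  recall and precision against truth are exact properties, not
  approximate ones.
* **Cohort**: per-marker subpopulation frequencies are Dirichlet draws
  around shared base frequencies (divergence controlled by a
  concentration divisor, default 0.3); individual admixture is a
  symmetric Dirichlet (default α = 0.2, i.e. mostly near-pure
  individuals); genotypes are two allele draws from admixture-weighted
  frequencies, with an inbreeding probability (default 0.1) of copying
  the first draw — producing the expected $H_o < H_e$ deficit of a
  partially selfing, structured germplasm panel.
* **Traits**: planted QTL effects (in sd units on standardized dosage) +
  a polygenic term $\sim N(0, h^2 K)$ + independent Gaussian year noise
  around the shared genetic value, matching a two-year trial with stable
  genetic values. If no noise sd is given it is derived so total variance
  is ≈ 1, and an infeasible variance budget is an error.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps, triploid genotypes, genotyping error, null alleles,
and gel-scoring artifacts. Passing tests therefore demonstrate
correctness of the algorithms under a clean admixture model, not
robustness to those real-data complications.

One integer seed drives every stage (per-stage seeds are derived from
it), and the pipeline writes artifacts atomically plus a manifest of
checksums; two runs from one seed are byte-identical, which the tests
assert end to end.

# Problem sizes and numerical choices

The validation suite runs the oracle comparison on 200 random 2 kb
sequences, the statistics identities on 10⁴ frequency vectors, UPGMA
recovery on 50 trees (n ≤ 12), GLM null calibration on 2 000
marker-trait pairs (n = 200), REML recovery on 20 replicates at n = 200,
and QTL power on 50 replicates at the 121-individual cohort scale;
cohort-level clustering properties use 75 × 60 panels. These sizes are
the package's own choice of a thorough-but-quick validation set. Key
tolerances: symmetry and frequency identities at 10⁻¹²; GLM/MLM(K=I)
equivalence at 10⁻⁶; UPGMA recovery at 10⁻⁹; REML convergence via
`stats::optimize` (golden section) on the log-δ interval above.

# Known limitations

* The Tm model is intentionally simple; rankings agree with
  thermodynamic calculators only in broad strokes.
* The codominant band reading discards >2-band patterns instead of
  modeling polyploidy.
* ΔK is post-processing only; the package neither runs nor replaces
  Bayesian clustering.
* The MLM's P3D approximation trades a small loss in per-marker accuracy
  for a large speedup, as is standard in marker-trait screens; exact
  per-marker REML is available where it matters.
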