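---
title: "panicleBSA: models, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panicleBSA: models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicleBSA)
```

## The scientific setting

Sorghum inflorescence branches carry paired spikelets: a fertile
sessile spikelet (SS) and one or two pedicellate spikelets (PS) that
normally abort before setting grain. A recessive mutant class in which
the PS also becomes fertile roughly doubles grain number per panicle;
the underlying gene is a class II TCP transcription factor acting as a
PS suppressor at a specific developmental stage (stage 4), in part
through the jasmonic acid pathway. This package implements the two
computational arms of that discovery as reusable, testable machinery:

1. **Variant arm** — from per-sample VCFs of EMS mutant lines and a
   phenotype-selected F2 bulk to a causal gene with an allelic series.
2. **Expression arm** — from staged PS/SS expression matrices to a set
   of candidate regulatory targets and their GO enrichment.

Both arms run on simulated inputs with known truth. Nothing in the
analysis code knows the truth; recovery is the test.

## Variant arm

### Filter model and assumptions

Each VCF record is reduced to (chrom, pos, ref, alt, genotype, depth,
quality); only biallelic SNVs are admitted (indels and multi-allelic
records are dropped at parse time with a logged count, since the
screen is SNV-based). The chain keeps a record iff QUAL > 20
(strictly), the call is homozygous-alternate, the substitution is a
canonical EMS transition (`G>A` or `C>T` written on the reference
strand), depth lies in the closed window 3–50 for the parent and
individual mutants or 5–100 for the bulk, and the (chrom, pos, ref,
alt) key is absent from the parental line.

Choices worth making explicit:

* **Depth windows are closed intervals** ("from 3 to 50" read
  literally); boundary tests pin both ends. The quality gate is
  strict.
* **Quality gate applies to the variant QUAL field.** The original
  protocol gated read-level mapping/base quality upstream of calling;
  this pipeline starts from VCF records, so QUAL is the single
  available gate. It is a config default, not a claim about the
  upstream protocol.
* **Homozygosity is the called genotype only**; no allele-fraction
  rescue is attempted.
* **Parental subtraction matches the full key**, not position alone:
  a true EMS hit coinciding positionally with a different parental
  allele must survive.
* **Strand convention:** EMS chemistry alkylates G; on the reference
  strand the two canonical records are G>A and C>T. A minus-strand
  gene therefore sees a coding-strand C>T arising from a reference
  G>A; the consequence classifier, not the filter, handles strand.

### Consequence annotation

A deliberately small stand-in for a full effect predictor: regions are
`cds`, `exon_noncoding`, `intron`, `splice_2bp` (the two intronic
bases flanking each exon, i.e. the canonical donor/acceptor
dinucleotides — no wider window is assumed) and `intergenic`. For CDS
hits the affected codon is rebuilt on the coding strand
(reverse-complementing minus-strand genes) and both codons are
translated with the standard nuclear code: `stop_gained`,
`start_lost` (first codon loses ATG), `synonymous`, else `missense`.
Gene models are single-transcript; overlapping models resolve to the
gene whose CDS contains the position, then lexicographically.
"Large effect" is {stop_gained, missense, start_lost, splice_site}:
missense must be included because most real allelic-series lesions in
the TCP domain are single-residue changes; a missense-excluding
definition could not recover that design.

### Mapping by intersection

Intersection is at the **gene** level (allelic mutants hit different
positions in the same gene), restricted by default to large-effect
hits; both modes are exposed because the original analysis does not
state whether pre-rollup variants were restricted. Candidate reports
are ranked by the number of independent alleles (distinct (pos, alt)
pairs), ties broken lexicographically and all tied reports returned.
The allelic series over additional lines counts distinct (pos, alt)
pairs not already attributed to the defining lines.

### Co-segregation statistics

The 2×3 genotype × phenotype table is collapsed to 2×2 (hom-alt vs
het + hom-ref) for the Fisher test because the trait is recessive; the
full table is still reported. The two-sided p uses probability
ordering (sum of all tables with point probability ≤ observed, the
dominant convention; doubling conventions exist and would differ).
The 3:1 fit is a plain Pearson χ² with 1 df. Both are cross-checked
in the tests against `stats::fisher.test` and hand arithmetic.

## Expression arm

### Replicate QC and expressed filter

Pearson correlations between replicate pairs are computed on
log2(value + 1) — log scale chosen (and recorded as a choice) because
correlation on raw FPKM is dominated by a handful of extreme genes. A
replicate is discarded when its best r² against its siblings is
strictly below 0.9. A gene is "expressed" when its count reaches 5 in
at least one sample (the inclusive reading of the protocol's
truncated phrasing).

### Differential expression stand-in

The original quantification/DE engine is out of scope; the declared
stand-in is a Welch two-sample t test on log2(value + 1) across
replicates with Benjamini–Hochberg adjustment per condition pair, and
significance = (FDR < 0.05) AND (|log2FC| ≥ 1). The simulator's
lognormal noise matches this test's assumptions by construction —
which is precisely why passing tests validate the pipeline logic, not
the stand-in's fitness for real count data (see Limitations). A gene
with zero variance in both groups gets p = 1 when means agree, p = 0
otherwise.

### The three-rule classifier

On condition means of log2(value + 1):

* **R1 (peak):** WT S4-PS is the *strict* maximum over the six WT
  conditions {S1, S3, S4-PS, S4-SS, S5-PS, S5-SS}. A pattern
  statement, not a test; strictness makes ties fail rather than
  producing ambiguous candidates.
* **R2 (contrast + loss):** WT S4-PS vs WT S4-SS significant with
  positive log2FC, and mutant S4-PS vs WT S4-PS significant with
  negative log2FC. "Greatly reduced" is operationalised with both the
  FDR and fold-change knobs since no threshold is stated; both are
  exposed in `pattern_thresholds()`.
* **R3 (similarity):** |mean log2 difference| between mutant S4-PS and
  S4-SS below 1 AND that pair not significant — "similar levels" has
  no stated threshold, so it is the mirror of the "different" knob.

Rules are applied uniformly to every gene; the suppressor's own
profile is excluded only if it fails R3, never by special-casing.
BH is used within each DE pair; the Benjamini–Yekutieli correction is
reserved for GO enrichment, where the original analysis names it.

### GO enrichment

Only terms represented in the candidate set (k ≥ 1) are tested and
counted in m, matching singular-enrichment behaviour. The upper tail
includes the observed k (P(X ≥ k)). The background universe defaults
to the expressed-gene set and N is always reported, because published
enrichment tables rarely print their universe: with N = 26,654 the
headline oxylipin term (k = 9, K = 66, n = 167) gives p = 3.27e-10,
the same order as the printed 6.6e-10; the residual factor ~2 is
consistent with an unprinted, somewhat larger effective universe.
BY adjustment inflates BH by c(m) = Σ 1/i and is therefore always ≥
BH; both properties are tested.

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions: a 50-plant selected
F2 bulk at mean depth 27; 17 independent mutant lines of which 7 are
allelic at the causal gene; a planted bulk pass set of 14; staged
PS/SS profiles with 3 replicates and 167 planted pattern genes among
4,900 expressed (5,000 total) — at desk scale (2 × 500 kb genome, 120
genes) rather than genome scale.

Design choices a maintainer should know:

* **Linkage is a fixed window** (100 kb) around the causal allele
  treated as homozygous in the bulk, not a recombination map: it is
  the minimal structure producing the causal-region homozygosity
  signal. Unlinked founder mutations segregate with pooled alternate
  fraction ~ Binomial(2·50, 1/2)/100, and a pooled site is emitted
  "homozygous" when that fraction reaches 0.9 — the desk-scale
  stand-in for a diploid caller on a pool.
* **Non-causal bulk window mutations are placed intergenic**, so the
  bulk's large-effect gene set is exactly the causal gene — mirroring
  the observed outcome that a single gene was homozygously mutated in
  the bulk. Background mutations are never placed in the causal gene
  (allelic lines carry *exactly one* lesion there; non-allelic lines
  none), which is what makes "5 additional unique alleles" a
  deterministic recovery target.
* **Decoys are single-violation probes:** each planted decoy fails
  exactly one predicate (non-EMS change, heterozygous call,
  out-of-window depth, parental-shared key) so the manifest can be
  verified predicate-by-predicate. Parental sites that are themselves
  non-EMS fail two predicates and are tagged `multiple`, outside the
  single-violation contract.
* **Per-line mutation load is a free parameter** (Poisson mean 25
  here): genome-wide EMS load is not a recovery target, and real
  per-line counts scale with genome size and dose.
* **Expression values are lognormal around class means; counts are
  round(value × library factor)** — the simplest monotone pair
  satisfying the classifier's assumptions. Planted targets get a
  +4 log2 peak at WT S4-PS over a per-gene baseline; every non-target
  class violates at least one rule by construction (flat, peak
  elsewhere, no WT contrast, no mutant loss, mutant PS/SS
  divergence).
* **Noise calibration.** The scenario noise is log2 sd 0.08 per
  replicate (each replicate emulates a 10-plant pool, so low
  replicate noise is the realistic reading). The binding constraint
  is not the condition-mean margin (which is ~60 sd at this noise)
  but the Welch denominator at n = 3: its variance estimate
  occasionally lands at effective df ≈ 2, where even enormous t
  statistics leave p above a BH cut of ~2e-3. Monte Carlo of the
  per-gene escape probability gives ~9e-2 at sd 0.25, 5e-5 at 0.10
  and 5e-7 at 0.08; at 0.08 planted-truth recovery is effectively
  certain at any seed.
* **Not modelled:** read-level data (FASTQ), sequencing error,
  recombination maps, indels and multi-allelic sites, isoforms,
  GO-graph ancestor propagation.

Because the simulator and the DE stand-in share a noise model, green
recovery tests demonstrate correctness of the pipeline's logic and
arithmetic, not robustness to overdispersed real count data — on real
data one would substitute a count-model DE engine behind the same
`differential_expression()` contract.

## Numerical and degenerate-input choices

* Hypergeometric tails are log-space `lchoose` sums (exact against
  `phyper` to ≥ 6 significant digits across exhaustive small sweeps);
  k = 0 returns 1 by convention.
* Fisher p sums point probabilities with a 1e-7 relative tie
  tolerance, as is conventional for floating-point probability
  ordering; an all-zero table is an explicit error.
* BY uses the running-minimum form and caps at 1; an empty p-vector
  returns an empty vector.
* Seeded runs are byte-reproducible: every generator derives all
  randomness from `sim_config$seed` (with small fixed offsets per
  stage) and emitted files are compared byte-for-byte in the tests.
* Sizing errors are explicit: too many genes for a chromosome, a
  causal gene too short to host the requested distinct alleles, a
  condition left with fewer than two replicates after QC, a missing
  design condition, candidate genes absent from the enrichment
  background.

## Problem sizes used by the test-suite and acceptance runs

Module tests run a 1 × 150 kb, 40-gene configuration (seconds); the
shipped `msd1_bulk` scenario is 2 × 500 kb with 120 genes, 17 lines
and ~340 bulk records; `panicle_rnaseq` is 5,000 genes × 36 samples.
The full suite completes in well under a minute on one CPU.
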