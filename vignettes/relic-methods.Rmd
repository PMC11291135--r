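---
title: "Methods: how relic analyzes RNA-linked CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how relic analyzes RNA-linked CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relic)
```

## The assay and the analysis problem

In an RNA-linked CRISPR screen, each perturbed cell carries a dual-sgRNA
knockout cassette and a reporter mRNA with a random 20-nt barcode in its
3' UTR. Because the barcode travels with the reporter RNA, counting barcodes
in any RNA pool — total mRNA, polysome fractions, isoform-selective
amplicons, or relative to a co-integrated control reporter — converts a bulk
biochemical readout into a pooled genetic screen. The analysis problem is a
chain of deconvolutions:

1. which barcode belongs to which sgRNA pair (linkage);
2. how many reporter molecules carried each barcode in each sample
   (UMI counting);
3. how a perturbation shifted the readout (ratio statistics);
4. which genes did so reproducibly across their sgRNAs (hit calling).

`relic` implements this chain, plus the two bespoke downstream analyses
that the screening platform motivates — splice-junction metrics for exon
skipping and intron retention, and ribosome-profiling P-site metagenes —
and a ground-truth simulator that exercises every stage.

## Linkage: assigning barcodes to sgRNA inserts

Linkage sequencing reads pair an observed sgRNA insert with a barcode.
Insert matching is exact against the designed library: an insert one
substitution away from every designed cassette is treated as absent and the
read is dropped. Rescuing mismatched inserts would trade a small gain in
yield for a real risk of mis-assignment, which is the one error this stage
must not make.

Barcode filtering applies two rules, strictly in this order:

* **Ambiguity exclusion.** A barcode observed with more than one distinct
  insert is removed entirely. It cannot be attributed to one perturbation,
  and its counts would contaminate two genes.
* **Error collapse.** Among barcodes linked to the same insert, any pair
  within a small edit distance is presumed to differ only by sequencing
  error; the lower-count member is discarded, and the survivor keeps its own
  count (no merging, since the discarded reads were never unambiguously the
  survivor's). Pairs are resolved greedily from the highest-count barcode
  down, with count ties broken against the lexicographically larger barcode,
  so the procedure is deterministic and the surviving set contains no pair
  within the threshold.

Similarity is global Levenshtein distance with a default threshold of 2.
A seeded aligner run in all-hits mode over 20-nt barcodes detects
essentially 1-mismatch relatives plus single-indel variants; edit distance
2 covers both without an aligner dependency. The threshold is a parameter
(`edit_threshold`), and the test suite checks the whole stage against an
exhaustive pairwise oracle, so the surrogate's behavior is pinned down
rather than assumed. Barcode-insert pairs finally need `min_reads = 5`
supporting reads; reads whose barcode contains N or has the wrong length
are discarded up front, since a 20-nt exact-match whitelist is meaningless
for malformed barcodes.

## Counting molecules: distinct UMIs

Screen reads carry the barcode, a 7-nt UMI added at reverse transcription,
and a 6-nt constant reporter identifier. Within each (sample, reporter,
barcode), duplicate (barcode, UMI) combinations collapse to one molecule.
Three exact-matching decisions are deliberate:

* **No UMI error correction.** Distinct literal 7-mers count separately.
  With 16,384 possible UMIs and tens of molecules per barcode, merging
  near-identical UMIs would remove more true molecules than errors.
* **Exact barcode matching against the linkage whitelist.** The linkage
  stage already discarded 1–2-edit barcode relatives, so an errored barcode
  simply fails the whitelist instead of being rescued into the wrong gene.
* **Exact reporter identifiers.** The 6-mers are designed to be mutually
  distinguishable; a mismatched identifier is a discarded read, not a guess.

A barcode needs `min_umis = 20` distinct UMIs in a sample to count as
detected. The floor is applied symmetrically per sample (each sample's
records are flagged), while contrast-level flooring (below) handles the
asymmetric case where a unit is well measured on one side only.

## Ratio statistics and hit calling

Every screen modality reduces to a per-barcode ratio between two count
sets: day-13 versus day-1 abundance (fitness), heavy or light polysomes
versus monosomes (ribosome occupancy), isoform amplicon versus total
(splicing), treatment versus control (modifier screens), or reporter versus
co-integrated control within one sample (dual barcode). The pipeline is:

1. **Contrast flooring.** Units below 20 UMIs in both samples are
   undetected and excluded; a count below 20 in one sample is raised to 20.
   This caps the magnitude a poorly sampled denominator can produce, at the
   cost of compressing very large true effects (a 64-fold depletion with a
   depth of ~100 UMIs per barcode reports as roughly 3–4-fold after
   flooring — rank order, which drives hit calling, is preserved).
2. **Library-size scaling** to equal totals over the analysis set; any
   residual global factor is irrelevant after centering.
3. **log2 ratio, median-centered** across all units in the library, so
   "the typical perturbation does nothing" is the definition of zero. After
   centering the library median is 0 to within 1e-9, which the tests assert
   as an invariant.
4. **Aggregation by medians**: barcodes to sgRNAs, then sgRNAs to genes.
   Medians are robust to a single aberrant barcode (integration artifacts,
   residual collisions). Barcode-level testing is available via
   `aggregate = "none"` since the counting unit is genuinely the barcode;
   sgRNA-level aggregation is the default because sgRNA values are what the
   screen design replicates (4 independent sgRNA pairs per gene).

**Gene test.** Gene significance uses a modified robust rank aggregation
(alpha-RRA) score: with a gene's sgRNAs at normalized ranks
$r_{(1)} \le \dots \le r_{(k)}$ among all $n$ sgRNAs, the score is
$\rho = \min_{i : r_{(i)} \le \alpha} P\big(\mathrm{Beta}(i, k-i+1) \le r_{(i)}\big)$,
i.e. the most improbable prefix of the gene's rank list, restricted to the
"good" tail fraction $\alpha$ (`alpha_frac`, default 0.25). The null
distribution of $\rho$ comes from permuting gene labels over the observed
ranks (`n_perm` draws per gene size, default 1000), giving
$p = (1 + \#\{\rho_{null} \le \rho\})/(n_{perm}+1)$. Both directions are
scored; each gene reports the direction with the smaller p-value.
Benjamini–Hochberg FDR is computed per direction. A hit requires strict
FDR < 0.05 **and** at least `min_good = 3` sgRNAs inside the directional
tail — the "consistent effects in at least 3 sgRNAs" rule, operationalized
as tail membership.

Two calibration facts matter for interpretation:

* With $\alpha < 1$, a gene with *no* sgRNA in the tail scores exactly 1,
  so null p-values have a point mass at 1 (probability $0.75^4 \approx 0.32$
  for 4 sgRNAs at $\alpha = 0.25$). The p-values are conservative
  (sub-uniform), never anti-conservative; the acceptance suite verifies
  exact uniformity at $\alpha = 1$, where the score is continuous, and
  validity ($P(p \le x) \le x + \varepsilon$) at the default $\alpha$.
* The permutation seed is an explicit argument; all stochastic outputs are
  reproducible from (data, seed).

**Dual-barcode normalization** divides reporter counts by the
co-integrated control reporter's counts for the same barcode within the
same sample, canceling abundance and integration effects. Barcodes whose
control count is below the floor are excluded (the ratio would be
unstable); reporter counts below the floor are raised to it, mirroring
contrast flooring.

## Splicing metrics

Coordinates are 1-based inclusive throughout, and a junction is keyed by
the first and last base of its spliced-out intron.

* **Junction extraction** enumerates the gap between each pair of
  consecutive exons per transcript and collapses duplicates across
  transcripts. Transcripts with overlapping exons are malformed and dropped
  with a warning.
* **Cassette exons.** A junction is a skip junction when it contains
  exactly one annotated exon strictly inside its open interval and exactly
  two annotated introns as proper subintervals, one sharing the skip
  junction's 5' boundary and one its 3' boundary. The boundary-sharing
  introns are necessarily the skipped exon's flanking inclusion junctions;
  requiring one on each side is what distinguishes a genuine cassette from
  nested or alternative-splice-site geometries. (Enclosed *introns* may
  touch the skip junction's boundaries — they must, to share an end — while
  enclosed *exons* may not; an exon touching the boundary would abut the
  junction rather than sit inside it.)
* **Percent spliced out**: $100 \cdot s/(s + i_5 + i_3)$ for skip reads $s$
  and flanking inclusion reads $i_5, i_3$; undefined below 2 skip reads or
  below 100 summed flanking reads. The skipped isoform is usually the rare
  one, so the evidence thresholds are asymmetric by design.
* **Intron retention**: reads overlapping the intron by at least 10 nt are
  counted (at least 100 required), then length-normalized by
  $L_{read}/(L_{intron} + L_{read})$ — a read can start anywhere in
  $L_{intron} + L_{read}$ nt and still overlap the intron, so the factor
  converts an interval count into a junction-equivalent crossing count —
  and compared against the splice-out junction:
  $\psi = 100 \cdot n/(n + j)$. `read_length` is a single nominal scalar
  (e.g. 50), not a per-read value, because the normalization is a global
  correction, not a per-alignment weight.
* Only uniquely mapping junction reads are used; only annotation-derived
  events are quantified. Downstream effect-size filters (e.g. "changes of
  10% or more") are presentation choices left to the caller.

## Ribosome P-site metagenes

Footprints of 27–33 nt place their P-site 13 nt downstream of the read's
5' end; `psite_pos` is the P-site's first nucleotide in 0-based transcript
coordinates. P-site counts are summed per position relative to each
transcript's start codon (offset 0 = first base of the AUG) over a window
(default −100 to +500 nt) and divided by the window maximum, so profiles
are comparable across libraries. An all-zero profile skips normalization
rather than dividing by zero. Length-stratified offset calibration is out
of scope: the fixed 13-nt offset is part of the method being implemented.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults mirror the screen design this workflow targets:
2,190 targeted genes, 4 dual-sgRNA pairs per gene, barcodes per sgRNA from
a truncated negative binomial (size 5) targeting a median of ~8, 20-nt
barcodes, 7-nt UMIs, plus non-targeting sgRNA pairs grouped into
pseudo-genes. Where the emulated study prescribes no value, defaults were
chosen once as field-realistic and are not tuned: per-base substitution
error 1e-3 (Illumina-scale), PCR duplication averaging 1.5 reads per
molecule, sequencing depth ~100 molecules per barcode per sample, lognormal
(sdlog 0.5) baseline barcode abundances, monosome/light/heavy baseline
fractions 0.20/0.35/0.45 for a well-translated reporter (over 75% in
polysomes), and a 0.97/0.01/0.01/0.01 canonical/aberrant isoform baseline.

Growth is modeled as deterministic exponential depletion
($a_0 \cdot 2^{f \cdot d}$ for fitness $f$ in log2/day over $d$ days) with
multinomial sampling at sequencing; fraction and isoform effects
redistribute a gene's molecules across samples; dual-barcode stabilization
multiplies reporter weights. An optional `mrna_amplification` factor lets
mRNA depletion exceed genomic DNA depletion for slow-growing knockouts
(default 1: no amplification, since the underlying functional form is not
established). Junction-read simulation is per molecule: an included
molecule contributes its read to one of its two flanking junctions with
equal probability, which makes percent spliced out an estimator of the
molecular skip fraction.

Every simulated dataset is a pure function of (config, seed) and is
emitted alongside a truth object sufficient to compute any expected
statistic in closed form. What the simulator does **not** emulate — and
therefore what passing tests do not certify about real data — includes
platform-specific error profiles (errors are uniform substitutions),
quality-score information (FASTQ qualities are constant), chimeric PCR
artifacts, barcode-abundance dependence of PCR duplication, nonuniform
ribosome elongation, and alignment ambiguity (the pipeline consumes exact
reads and precomputed junction tables rather than running an aligner).

## Numerical and degenerate-input choices

* Centering tolerance 1e-9 (floating-point median subtraction).
* Permutation p-values use the add-one estimator, never 0.
* Null-score comparisons use a 1e-12 tie slack so exact rho ties count.
* Empty linkage read streams warn and return empty tables; an empty
  detected-unit intersection in a contrast is an error (the contrast is
  unanalyzable, not merely sparse).
* Equal-count barcode pairs in the error collapse discard the
  lexicographically larger member: arbitrary, but deterministic.
* `floor_counts` excludes units below the floor on both sides *before*
  flooring, so wholly undetected units never acquire fake counts.

## Problem sizes used by the tests

The test and acceptance suites run at desk scale, chosen as the smallest
sizes at which each property is informative: linkage oracle equivalence on
20 instances of 80–500 barcodes; null calibration on 250 pseudo-genes with
2,000 permutations; empirical FDR pooled over 20 replicate 100-gene
screens; effect recovery on a 200-gene screen with 20 essential genes
(~6,400 barcodes, ~2.5 million molecules); splicing convergence at 1e5
molecules. The full-scale defaults (2,190 genes) run the same code paths.

## Known limitations

* The edit-distance-2 similarity surrogate is a documented approximation
  of seeded self-alignment, not a bit-for-bit reproduction of it.
* Gene-level FDR relies on permutation exchangeability across sgRNAs;
  strong library-wide covariates (e.g. GC-dependent capture) would violate
  it and are not modeled.
* Contrast flooring compresses effect magnitudes beyond the detection
  range; reported `median_lfc` is a floor-censored estimate for very strong
  effects.
* With two-level simulated truth (essential versus neutral), rank
  correlations between truth and estimate are bounded well below 1 by
  ties in the truth vector regardless of recovery quality; linear
  correlation and hit recall are the informative recovery measures there.
* Splicing significance testing, time-course depletion modeling and
  alignment itself are out of scope by design.
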