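---
title: "Methods: allele-specific cis-regulatory divergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific cis-regulatory divergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisdiverge)
library(dplyr)
```

## The analytical setting

An allodiploid cell line carries one complete haploid genome from each of
two species in a single nucleus. Because both alleles see the same
trans-regulatory environment (the same TF concentrations, chromatin
machinery and signalling state), any reproducible difference between the
two alleles — in TF binding or in the transcriptional response to inducing
a TF — must be attributable to *cis*: to sequence differences at or near
the locus itself. `cisdiverge` implements the sequence of computational
steps that turns raw allele-mixed data into that readout, together with a
synthetic data generator that makes each step testable by parameter
recovery.

## Competitive read assignment

Reads from an allodiploid library are a mixture from two genomes that are
(at mouse–rat scale) roughly 5% diverged at aligned positions. A read is
assigned by aligning it to both genomes and comparing the best edit
distances (Levenshtein: substitutions plus indels):

* Candidate loci are found by exact k-mer seeds (default `k = 12`, taken
  at non-overlapping offsets so that a read with `e` edits still has an
  intact seed unless `e` is large) against a hash index of each genome,
  on both strands.
* Each candidate is verified by a full dynamic-programming alignment of
  the whole read against the candidate window with free end gaps on the
  genome side; the minimum edit distance wins. The default edit budget is
  10% of the read length, matching typical aligner sensitivity at the
  simulated divergence.
* The allele with the strictly smaller distance gets the read. Equal
  distances give `ambiguous`; the tie policy is deliberately conservative
  — ambiguous reads are excluded from all per-allele counts — because a
  tied read carries no allele information at the chosen resolution.
* Ties between loci *within* one genome go to the lowest chromosome name,
  then the leftmost start, making assignment deterministic.

Feature counting uses the midpoint rule: a read increments a feature
exactly when the midpoint of its aligned interval lies inside the feature
(0-based, half-open). This gives every read at most one feature and makes
the partition identity (`A + B + ambiguous + unmapped = total`) exact.

Real pipelines additionally filter on mapping quality and remove PCR
duplicates before assignment; the simulator emits neither multi-mapping
artefacts at that scale nor duplicates, so those filters are intentionally
absent here.

## Peak projection and orthology classes

Each peak is represented by the 400 bp window `[summit − 200,
summit + 200)`. We fix the window at 400 bp half-open (the summit base is
the 201st of 400) rather than a 401 bp closed window; at 400 bp the
distinction never changes a classification in practice, but fixing it
makes coordinates reproducible.

Projection to the other genome uses a blat-style seeded aligner:

* 11-mer exact seeds on both strands, with occurrence masking (seeds
  occurring more than `max_occ` times in the target are skipped, playing
  the role of blat's `.ooc` files). At least two seeds on nearby
  diagonals (`diag_tol = 50` bp of drift) are required before alignment
  is attempted, which suppresses spurious single-seed clusters.
* Each seed cluster's diagonal-implied span is aligned to the query by
  Smith–Waterman with +1/match, −2/mismatch and −2 per gapped column.
  The −2 penalties are chosen so that random sequence sits in the
  logarithmic score regime (no percolating alignments) while homology at
  70% identity still has positive expected score per column
  (0.7 − 0.6 > 0) and extends. The reported score is
  `matches − mismatches − gap_opens`, an explicit approximation to blat's
  tiling score, with the conventional cutoffs retained
  (`min_identity = 70`, `min_score = 100`).
* Best-hit filtering drops hits covering < 70% of the query
  (`min_aligned_fraction = 0.7`) and discards peaks whose second-best hit
  scores ≥ 95% of the best (`single_hit_ratio = 0.95`): near-ties are
  genuinely ambiguous placements, and multi-mapped peaks are excluded
  from classification rather than guessed.

Classification is then an existence test: `no_hit` → **unaligned**; a hit
whose target interval covers strictly more than 50% of the length of any
target-genome peak → **conserved**; otherwise **loss**. The denominator is
the *target peak's* length and the inequality is strict, so a hit covering
exactly 50.0% is loss. Classification is direction-specific; both
directions are always computed.

Proximal/distal stratification (window midpoint within 3 kb of a TSS) is
exposed as an option; the 3 kb threshold is a declared convention, not a
derived quantity.

## Motif scanning

Scanning is FIMO-like: every window of the PWM's width, on both strands,
is scored by the log2 odds of the position probabilities (pseudocount
regularised) against a 0-order background (uniform by default,
configurable). Scores are discretised at 1/100 bit and the exact tail
distribution of the window score under the background model is computed by
dynamic programming (a convolution across motif positions); a window is a
hit when its exact p-value is ≤ 1e-4. Because the scanner and the p-value
DP use the same discretised scores, the DP is exactly equal to exhaustive
enumeration of all 4^w windows — the test suite asserts this for a width-6
matrix. `N` bases contribute zero log-odds.

The shipped motif (`cdx2_demo_pwm()`) is a synthetic A/T-rich
homeodomain-like matrix used by the simulator and the examples; any
MEME-format matrix (e.g. from JASPAR) can be supplied instead.

## Differential-signal rules

The thresholds are deliberately simple, declared rules rather than fitted
models:

* High-confidence peaks: −log10 q strictly greater than 4.
* Accessibility: UP iff log2 FC > 1 (pseudocount 1 on normalised counts)
  and the *summed* normalised pair is ≥ 40; DOWN symmetrically; everything
  else COMMON. The total threshold is applied to the summed pair after
  any replicate averaging — the alternative (per-replicate) reading would
  make the rule depend on replicate count.
* Allele-stronger binding: one allele at least 2× the other after
  pseudocount, else `similar`.
* Library scaling for these count tables is total-count scaling to the
  mean library size, preserving within-sample ratios exactly; dispersion
  modelling and shrinkage estimators are out of scope here.

## Expression typing

Per-allele responses to induction are called from normalised counts:
log2 FC (induced over control, pseudocount 1) with a call requiring
|log2 FC| > 1 and the allele to pass an expression floor (normalised
count > 3 in at least one condition). Candidate pairs are those where
*both* alleles pass the floor; this declared candidate rule is
configurable. Replicate libraries are averaged after normalisation.

For typing, the default library normalisation is **median-of-ratios**
(each library scaled by the median ratio of its counts to a
geometric-mean reference profile). Total-count scaling is biased here: a
strong induction response is asymmetric on the count scale (a gene moving
±3 log2 contributes 8× or 0.125× its baseline, averaging ≈ 4×), which
inflates the induced library total and drags every non-responding gene's
fold change downward — in simulations at overdispersion 0.05 this false
response pushed a fifth of null genes over the threshold. Median-based
factors are robust to a responding minority; the implementation is
validated against an established independent estimator in the test suite.
Total-count and no-op normalisation remain available as options.

Types are then a total function of the two calls: (none, none) → 0;
A-only → 1; opposite directions → 2; B-only → 3; same direction → 4.
Swapping the allele labels provably maps 1 ↔ 3 and fixes 0, 2, 4.
Response magnitudes (|log2 FC|, type 4 versus 1 on allele A and 4 versus 3
on allele B) are compared by a natively computed Welch t test
(Welch–Satterthwaite df, two-sided p); the native computation is asserted
against `stats::t.test` to 1e-6.

## Peak-to-gene linking

A peak is linked to a gene when its summit lies in the half-open 60 kb
window centred on the strand-aware TSS. Summit containment (rather than
any-overlap) avoids double-edge artefacts and makes the window-monotonicity
property exact; any-overlap is a configuration away. Composition tables
report, per regulation type in {0, 1, 3, 4}, the proportion of linked
peaks per orthology class; type 2 is excluded because a single-gene
category supports no proportion, and an empty type row is reported as `NA`
rather than zero.

## The synthetic generator: what it does and does not emulate

The generator is the package's study design. Genome B is genome A mutated
at `subst_rate` (default 0.05, rodent-like aligned divergence) with indel
events at `indel_rate` (default 0.002) of geometric length (mean 3 bp —
a single-parameter length model); each genome additionally receives
lineage-specific insertions of i.i.d. uniform-ACGT sequence, 3× the peak
window long, which cannot align at 70% identity and make the `unaligned`
truth class unambiguous. The truth coordinate map of aligned blocks is
strictly increasing and round-trips exactly.

Peaks are planted non-overlapping: conserved peaks embed the motif
consensus at homologous positions in both genomes; loss peaks in one
genome only (the homologous region exists, alignable, unbound); unaligned
peaks inside lineage-specific blocks. Loss and unaligned peaks are planted
per genome so both projection directions carry all classes. Reads are
drawn uniformly within half a fragment (default fragment 250 bp, within
the 100–500 bp range typical of sonicated ChIP libraries) of each summit
from the carrying allele, plus Poisson background; they are untrimmed and
error-free by default since read QC is upstream of this package's scope.
Expression counts are negative binomial around `mean_expression` with the
induced mean shifted ±`effect_size_log2` per the planted type
(proportions default to 0.7585/0.0673/0.0001/0.0577/0.1164, echoing the
observed rarity of opposite-direction responses).

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real data: mappability structure and
repeats, PCR duplicates and base-quality error profiles, fragment-length
biases, replicate-level biological variability beyond a single NB draw,
splicing, and trans effects of any kind. Recovery results should be read
as validation of the algorithms, not as performance estimates on
sequencing data.

All randomness flows from one seed: each stage derives a deterministic
sub-stream (`stage_seed`), so identical configurations produce
byte-identical outputs and partial reruns reproduce the full run.

## Numerical choices and degenerate inputs

* Rounding of reported percentages is half-away-from-zero to one decimal,
  two decimals under 1%, and every percentage is stored next to its raw
  counts so it can be re-derived exactly.
* Score discretisation for motif p-values is 1/100 bit; the DP equals
  enumeration at that resolution by construction.
* Degenerate inputs are explicit: reads shorter than the seed length are
  unmapped with a warning; summits outside chromosomes, negative counts,
  unknown chromosomes and malformed PWMs raise errors naming the
  offender; empty groups propagate `NA`, never silent zeros.
* Problem sizes used by the validation runs (chosen to exercise every
  class boundary at comfortable statistical resolution): 100 planted
  peaks per class over ~1 Mb per genome for projection recovery; ~10,000
  100 bp reads for assignment recovery; 2,000 homolog pairs at
  overdispersion 0.005 for type recovery; 200 homologous pairs up to 1 kb
  for the aligner-versus-DP oracle suite.

## Known limitations

* The aligner approximates blat's scoring; agreement is asserted against
  a full Needleman–Wunsch oracle to ±2 identity points, not bit-exactly.
* Spliced (RNA) alignment is not modelled; simulated RNA reads are
  unspliced.
* The allele-stronger call compares two normalised counts at a fold
  threshold with no variance model, exactly as declared — it is a
  screening rule, not a test.
* `find_exclusive_substitutions` consumes pre-aligned (equal-length)
  protein sets; alignment itself is upstream.
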