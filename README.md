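# cisdiverge

Allele-specific analysis of cis-regulatory divergence in allodiploid cells.

When two diverged genomes share a single nucleus — as in rat–mouse
allodiploid embryonic stem (RMES) cells, where one haploid mouse and one
haploid rat genome experience the same trans-regulatory environment —
allele-specific differences in transcription-factor (TF) binding and in the
transcriptional response to TF induction read out *cis*-regulatory
divergence directly. `cisdiverge` implements the computational core of that
analysis for researchers in comparative regulatory genomics:

- **Competitive read assignment.** Each read is aligned to both parental
  genomes (k-mer seeded, verified by full edit-distance dynamic
  programming) and assigned to the allele with the smaller Levenshtein
  distance; ties are `ambiguous`, and ambiguous/unmapped reads never enter
  per-allele counts.
- **Cross-genome peak orthology.** Each binding peak is reduced to the
  400 bp window `[summit − 200, summit + 200)`, aligned to the other genome
  with a blat-style seeded Smith–Waterman aligner (11-mer seeds with
  occurrence masking, `minIdentity = 70`, `minScore = 100`, best-hit
  filtering at aligned fraction ≥ 0.7 with multi-mapper exclusion), and
  classified: **conserved** if the aligned locus covers > 50% of a peak in
  the target genome, **loss** if alignable but unbound, **unaligned**
  otherwise.
- **Motif scanning.** FIMO-style PWM scanning of peak windows on both
  strands, with *exact* p-values from a dynamic program over the
  discretised log-odds score distribution under the background model, and
  per-class motif-occurrence fractions.
- **Differential signal rules.** High-confidence peak filtering
  (−log10 q > 4, strict), UP/DOWN/COMMON accessibility calls
  (|log2 FC| > 1 and total normalised count ≥ 40), and allele-stronger
  binding calls at a fold-change threshold of 2.
- **Regulation typing.** Homologous gene pairs are typed 0–4 by their
  per-allele response to TF induction: no change / mouse-allele only /
  opposite / rat-allele only / concordant. Magnitudes are compared by a
  natively computed Welch t test; type × peak-class composition is
  tabulated through 60 kb TSS-centred windows.
- **DBD screen kernel.** Lineage-exclusive amino-acid substitutions in
  aligned TF DNA-binding-domain orthologue sets.
- **Synthetic allodiploid generator.** Two genomes at a stated
  substitution/indel divergence with lineage-specific insertions, planted
  peaks in all three orthology classes, ChIP-style reads with known allele
  of origin, and expression responses drawn from the five regulation types
  — so every stage is validated by parameter recovery against planted
  truth.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; results plot via `autoplot()` / `plot_*()` and
tidy via `tidy()` / `glance()`.

## Worked example

```r
library(cisdiverge)
library(dplyr)

cfg  <- sim_config(seed = 3, n_chrom_per_genome = 2, chrom_length = 100000,
                   n_peaks_conserved = 20, n_peaks_loss = 20,
                   n_peaks_unaligned = 5, n_unalignable_blocks = 6)
pair  <- simulate_genome_pair(cfg) |> plant_peaks()
reads <- simulate_reads(pair)

# competitive allele assignment
asg <- assign_reads(reads, pair)
count(asg, label)
#> # A tibble: 3 × 2
#>   label         n
#>   <chr>     <int>
#> 1 A          2245
#> 2 B          2252
#> 3 ambiguous    20

# peak projection and orthology classification, A -> B
proj <- project_peaks(filter(pair$peaks, genome == "A"),
                      pair$genomes$A, pair$genomes$B,
                      filter(pair$peaks, genome == "B"))
peak_class_summary(proj)
#> # A tibble: 3 × 3
#>   klass         n percent
#>   <chr>     <dbl>   <dbl>
#> 1 conserved    20    44.4
#> 2 loss         20    44.4
#> 3 unaligned     5    11.1
```

Every planted class is recovered exactly here: 20 conserved, 20 loss and 5
unaligned peaks, i.e. 44.4/44.4/11.1% of the 45 classified peaks. Against
the shipped demo motif, `motif_fraction_by_class()` reports fraction 1.0 in
every class because the generator embeds the consensus at each planted
summit.

The whole pipeline — simulation, assignment, counting, projection in both
directions, motif scanning, expression typing, peak-to-gene linking, and
truth-versus-recovered confusion tables — runs as one call:

```r
report <- run_pipeline(sim_config(seed = 5))
report$assignment_accuracy   # 1.0 at the default 5% divergence
report$type_summary
autoplot(report)
```

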