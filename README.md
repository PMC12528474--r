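# ighrepsel

Simulation and analysis of immunoglobulin heavy-chain (IgH) repertoire
selection over the pre-B transition, and detection of VH-replacement
excision circles.

## The problem

Only about a quarter of VDJ rearrangements are *productive* (in frame and
stop-free), and of those, a large fraction encode mu-chains that cannot
pair with the surrogate light chain (SLC) to form a signalling pre-BCR.
Developing B cells therefore pass through several selection filters:
D-mu-mediated arrest of cells with a reading-frame-2 DJ join, SLC-pairing
selection on the V gene, the JH, and individual CDR3 residues (numbered
from position 97, after the invariant Cys96), and rescue of stalled cells
by **VH replacement (VHR)** - invasion of an existing VDJ by a more distal
V gene at the cryptic RSS heptamer `TACTGTG`, which excises a signal-joint
circle carrying back-to-back cryptic/conventional heptamers
(`TACTGTG` + 0-4 nt + `CACA[GAT]TG`).

This package is for anyone who wants these mechanisms as runnable,
testable code: it provides

* a **toy germline locus** generator with the landmarks that matter
  (cryptic RSSs, TA-terminal V genes, D reading-frame structure, long and
  short JH), serialisable as FASTA + metadata;
* a **generative simulator** of VDJ recombination (geometric trimming,
  Poisson N additions, P nucleotides) and developmental selection (D-mu
  arrest, SLC pairing, stalling, VHR with circle emission, allelic
  exclusion, muMT mode for the unselected reference);
* **read-level emitters** for a J-anchored capture library with UMIs
  (VDJseq-like) and a framework-3 run-off library (RCseq-like);
* a **simplified annotator**: pair merging, UMI deduplication, V/D/J
  assignment, productivity, CDR3 extraction, Ichihara D reading frames
  (with the IMGT transposition 1→2, 2→3, 3→1);
* **repertoire statistics**: frequency tables with the 0.1% retention
  threshold, selection folds, family-by-JH matrices, positional residue
  deltas, reading-frame and stop-codon summaries, usage-weighted D
  logos, CDR3 biophysics (net charge, Kyte-Doolittle GRAVY, aliphatic
  index), simple-regression R^2 and Welch tests;
* an **excision-circle detector**: the 60-nt anchored main search, the
  grep-style fallback for short reads, and automated curation (junction
  confirmed, anchors sufficient, donor distinct and distal).

## Worked example

```r
library(ighrepsel)

locus <- build_toy_locus(n_v = 12, n_d = 3, n_j = 4, crss_fraction = 0.75,
                         seed = 1)
pop <- simulate_cohort(locus, junction_params(),
                       default_selection_params(locus),
                       n_cells = 50000, seed = 7)
print(pop)
#> bcell_population: 50000 cells (seed 7)
#>   arrested     13938
#>   dead         22004
#>   large pre-B  2011
#>   pro-B        8287
#>   small pre-B  3760
#>   VH-replacement circles: 5258
```

The pro-B compartment (pro-B plus arrested cells) is the "before"
repertoire; small pre-B cells are the "after". The most D-proximal V
gene, which `default_selection_params()` endows with a strong
SLC-pairing deficit, collapses over the transition:

```r
pro <- repertoire(pop)                        # pro-B VDJ alleles
pre <- repertoire(pop, stages = "small pre-B")
sf <- selection_fold(vh_frequency(as_rows(pro), productive = TRUE),
                     vh_frequency(as_rows(pre), productive = TRUE))
head(sf[order(sf$fold), ], 1)
#>     key freq_a freq_b   fold    diff fold_undefined
#> 1 VH5-1 0.3787 0.0157 0.0414 -0.3630          FALSE
```

(`as_rows` stands for the small data-frame adapter shown in the methods
vignette; annotated reads from `annotate_molecules()` feed the same
statistics directly.) The proximal gene falls from 37.9% to 1.6% of
productive VDJ - a 0.04-fold change, the same order as the published
collapse of VH5-2/81X. Detecting the excision circles that VHR left
behind:

```r
panel <- locus$v$name[!is.na(locus$v$crss_offset)]
reads <- emit_rcseq_reads(pop$circles, locus, panel,
                          germline_background = 20000, err_rate = 0.001,
                          seed = 11)
mg <- merge_pairs(reads$r1, reads$r2)
dd <- dedup_by_umi(mg$merged)
calls <- detect_circles(dd$molecules, locus)
summarize_circles(calls, locus)$n_curated
#> [1] 15549
```

Every curated call names a recipient V, a distal donor V and the
insertion between the heptamers; `summarize_circles()` returns donor and
recipient maps by locus rank, the insertion-length histogram and, given
library labels, the reference-to-mean count ratio.

An end-to-end run (simulate → annotate → statistics → circles) with a
manifest and ground-truth tables:

```r
cli_run_all(config = NULL, seed = 42, outdir = "run1")
```

or from a shell via the thin wrapper `inst/cli/ighrepsel.R`.

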