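---
title: "Simulating and measuring heavy-chain repertoire selection and VH replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring heavy-chain repertoire selection and VH replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighrepsel)
```

## The biology being modelled

During B-cell development, the heavy-chain variable exon is assembled by
VDJ recombination: D-to-J joining first (usually on both alleles), then
V-to-DJ. Joins are imprecise - exonucleolytic trimming, non-templated (N)
and palindromic (P) additions diversify the junctions - so only about a
third of assemblies are in frame, and some in-frame assemblies carry stop
codons. A rearrangement that translates into a mu-chain is *productive*;
a productive mu-chain that also pairs with the surrogate light chain (SLC)
to form a signalling pre-BCR is *functional*. Signalling triggers allelic
exclusion and drives the cell through the large pre-B and small pre-B
stages. Three further selection layers shape which rearrangements survive
this pre-B transition:

* **D-mu arrest.** A DJ join in D reading frame 2 (Ichihara convention)
  expresses the truncated D-mu protein and arrests the cell once D-mu has
  accumulated - so early, D-proximal V recombination escapes this filter.
* **SLC pairing.** Up to half of new mu-chains fail to pair, and the
  failure rate depends on the V gene, on JH length (the short JH2/JH3 cost
  two CDR3 residues, penalising certain V families), and on individual
  CDR3 residues near the V-D junction (positions numbered from 97, after
  the invariant Cys96).
* **VH replacement (VHR).** A stalled cell - productive but non-pairing -
  can invade its own VDJ at the cryptic RSS heptamer `TACTGTG` found a few
  base pairs from the 3' end of many V genes. A more distal donor V
  replaces the original V, and the intervening DNA is excised as a circle
  whose signal joint carries the back-to-back cryptic/conventional
  heptamers (`TACTGTG` ... `CACA[GAT]TG`), possibly separated by a short
  insertion. Detecting these circles in framework-3 run-off libraries is
  direct physical evidence of VHR.

The package implements this entire arc as testable code: a toy germline
locus, a generative simulator of recombination and selection, read-level
emitters for the two library chemistries, a simplified annotator, the
repertoire statistics, and the excision-circle detector. In muMT mode the
membrane mu-chain cannot signal, which switches off every
signalling-dependent transition and turns the simulated pro-B compartment
into an unselected reference - the same role muMT mice play in the wet
lab.

## The toy locus

`build_toy_locus()` generates V segments whose 3' ends spell the
framework-3 landmark Tyr-Tyr-Cys-Ala-Arg followed by two bases of a
partial codon. In the cryptic-RSS variant the Tyr-Cys codons spell
`TACTGTG`, exactly as in real V genes; in the plain variant a synonymous
codon choice (`TAT TGC`) removes the motif while keeping the protein
landmark. A configurable fraction of V genes ends in `TA`, the first two
bases of a potential stop codon completed by the junction. D segments are
forward-orientation only; the first two encode the canonical frame
structure explicitly (an ATG in RF2, the D-mu frame; a stop in RF3; RF1
glycine/tyrosine-rich) and additional D segments are random but
constrained to be stop-free in RF1/RF2. J segments carry a conserved
in-frame Trp with 5' overhangs of 0-2 nt to exercise the frame
arithmetic, and alternate between 4-codon and 2-codon CDR3 contributions
so that JH2/JH3 are two residues shorter than JH1/JH4. Random cores are
rejection-sampled so that neither heptamer pattern can occur by accident,
which is what guarantees a motif-free background for the detector tests.

Clan assignments are looked up in a packaged family-to-clan table
(`inst/extdata/clan_table.tsv`) rather than hard-coded, since real
references differ. Coordinates are 0-based half-open internally.

## Junction model

`junction_params()` defaults: trimming per end is geometric(0.25) capped
at 10 nt; N additions are Poisson(3) capped at 15 nt per junction; P
additions of up to 2 nt (the palindrome of the terminal bases) occur only
on untrimmed ends. These values give a net CDR3 gain of roughly 0-3 amino
acids per junction and an in-frame fraction near 1/3. J 5' trimming is
capped at the Trp offset so the frame anchor always survives; trims that
would consume a whole D segment are redrawn. All caps are parameters.

A V-to-DJ join is evaluated by direct translation: the frame shift is the
read position of the J frame anchor modulo 3, the stop scan runs from the
V start through the conserved Trp codon (over the whole read-through for
frame-shifted alleles), and `productive` is exactly `in-frame and
stop-free`. The same evaluation code serves the simulator and is
re-derived independently in the test suite, where a test-local junction
sampler reproduces the productive fraction within three percentage
points.

## Selection model

`selection_params()` composes the pairing probability of a productive
allele multiplicatively and clips to [0, 1]:

    p = clip( base_pair_p
              * vh_pair_mult[v]
              * jh_short_mult   (families VH2/VH3/VH5 with JH2/JH3)
              * prod residue_mults over observed (position, residue) )

Defaults and rationale:

* `base_pair_p = 0.5` - about half of new mu-chains fail to pair.
* `default_selection_params()` gives the most D-proximal V a pairing
  multiplier of 0.05 (the VH5-2/81X analogue, which collapses over the
  pre-B transition); all other V are neutral.
* `jh_short_mult = 0.3` plants the short-JH penalty on the designated
  families.
* `residue_mults` plants G97 (x0.3), S98/K98 (x0.5) counter-selection,
  H99 (x1.8) and Y101 (x1.6) selection, and T101 (x0.4)
  counter-selection. Because RF1 of the canonical D is G/Y-rich and RF2
  is T/V-rich, the position-101 multipliers also generate the RF2 purge
  over the pre-B transition without a dedicated reading-frame parameter -
  the same route the biology takes.
* `dmu_arrest_p = 0.9` in wave 2, zero in wave 1 (D-mu has not
  accumulated), never in muMT mode.
* `vhr_rate = 0.15` per stall step, with `vhr_rate_nonproductive_mult =
  0.25`: non-productive alleles exit quickly via nonsense-mediated-decay
  signalling to the second allele, so their replacement window is brief;
  productive non-pairing alleles stall for `n_steps` (default 3) attempts.
  The absolute rate and the stall duration are not quantified in the
  underlying biology; they are order-of-magnitude choices exposed as
  parameters, and the suite verifies that circle counts scale linearly
  with the rate rather than pinning an absolute number.
* muMT mode multiplies the rate by 0.4 and grants a single replacement
  window (the repeated windows *are* the signalling-dependent stall).
  This is an explicit calibration, not a measured mechanism.
* Signal-joint insertions are uniform on {0,...,4} nt; replaced alleles
  keep the recipient's V-D insert and D-J junction exactly, prefixed by
  the donor coding sequence plus the recipient remnant 3' of the cryptic
  heptamer (the footprint; the literature is silent on its exact extent,
  so it is simply what survives 3' of the cut). Donors are uniform over
  strictly distal V genes. Second replacements of an already replaced
  allele are supported but off by default.

Two discrete recombination waves stand in for continuous developmental
time: wave-1 V choice is proximal-biased with weights `exp(-rank/tau1)`
(`tau1 = 2` ranks), wave 2 is flat, modelling locus contraction. The
pro-B "snapshot" consists of the cells whose final stage is pro-B or
arrested - cells that paired have moved on, cells that exhausted both
alleles have died. Because death is instantaneous in the model, the
wild-type pro-B compartment is more enriched for productive alleles than
a real sorted pro-B pool, where failed cells linger; the muMT compartment
has no such distortion and is the reference for generation-rate
statistics. This is the main known gap between the generator and real
data: passing tests demonstrate internal consistency of the selection
machinery, not that real pro-B pools have these exact compositions.

## Sequencing emulation and annotation

`emit_vdjseq_reads()` samples each allele with the assay's molecular
sampling probability (5-10% in the real chemistry; 5% in the acceptance
run), attaches a random 12-nt UMI, amplifies into `1 + Poisson(0.6)` PCR
duplicates and emits read pairs with uniform substitution errors (default
0.001/base; indels are out of scope). `emit_rcseq_reads()` emits the
run-off library: dominant germline background (framework-3 through the
conventional RSS into the 3' intergenic region) plus molecules traversing
each excision circle whose recipient is in the primer panel.

The annotator assumes molecules oriented V-to-J and spanning the segment
boundaries (as merged run-off molecules are): V and J are assigned by
30-nt ungapped anchors tolerating 2 mismatches (ties take the lower locus
rank and set an ambiguity flag), D by the longest exact match of at least
6 nt inside the junction window, and the Ichihara D reading frame follows
from the match offset relative to the translation frame (anchored on V,
or propagated back from J for DJ-only rows). UMI deduplication keys on
(UMI, sequence length), keeping the highest-mean-quality read, ties by
lexicographic sequence. Short D remnants are genuinely ambiguous -
repeated substrings can map to two offsets - which bounds attainable
D-call agreement below the V/J level; the suite holds V/J at 99% and
D/d_rf at 95%.

## Circle detection

`find_circles_main()` is the anchored search: 60 nt of framework-3 of any
V, a 10-120 nt gap that must contain `TACTGTG` then 0-4 nt then
`CACA[GAT]TG`, then 60 nt of the 3' intergenic sequence of a *different*
V, each anchor tolerating 2 mismatches (a tolerance chosen to absorb
sequencing error without enabling cross-V matches on this locus; the
published search tolerates "imprecise joining" without quantifying it).
`find_circles_fallback()` is the grep-style junction search with up to
3 nt insertions, for reads too short to reach the donor anchor, with
20-nt reduced anchors for partner identification. `curate_calls()` makes
the published manual curation explicit and automatic: junction confirmed,
anchors long enough, donor distinct from recipient, donor distal to
recipient; every rejection carries a reason code. One call is emitted per
molecule; multi-junction molecules (possible serial replacements) are not
resolved.

## Numerical and interface choices

* Single RNG stream per simulation; the seed is mandatory in the CLI and
  the only entropy source, which makes whole-pipeline runs
  byte-deterministic per (config, seed).
* Net CDR3 charge ignores histidine by default (pKa near 7), configurable
  via `his_charge`; GRAVY uses the Kyte-Doolittle table; the aliphatic
  index is `100 (fA + 2.9 fV + 3.9 (fI + fL))`. These are the standard
  definitions, stated here because the source analyses do not spell
  theirs out.
* Frequency folds with a zero baseline are reported as undefined (flagged)
  rather than infinite; V genes below the 0.1% retention threshold stay
  in every denominator.
* Positional statistics use only rows with a resolved CDR3 (both the
  Cys96 and Trp landmarks intact); unresolved rows are excluded from
  numerator and denominator alike.
* Welch tests across V groups can carry Benjamini-Hochberg q-values via
  `p.adjust` if desired; single tests are the default, matching the
  source analyses.

## Problem sizes

The test suite simulates cohorts of 5 x 10^4 cells for the selection
statistics (its planted effects are detected at p < 0.01 there), 10^5
background molecules for the detector's false-positive bound, and ten
seeds at substitution rate 0.001 for detector robustness. The acceptance
script simulates 4 x 10^5 cells so that the pro-B compartment holds at
least 2 x 10^5 VDJ alleles over a 32-V locus, then draws five pairs of
independent 5% molecular samples and reports the median per-V frequency
R^2. These sizes were chosen so every stochastic check sits far from its
threshold while a full run stays comfortably on a laptop.

## Known limitations

Light-chain editing, somatic hypermutation, cell-cycle timing, indel
errors, cryptic RSSs other than the 3'-most one, and the real 195-gene
locus with IMGT nomenclature are all out of scope. The annotator is a
simplified stand-in tuned to the synthetic regime (ungapped anchors, no
novel-allele inference). Absolute circle counts depend on the
unquantified VHR rate and stall duration; only relative statements
(linear scaling, wild-type versus muMT direction) are meaningful.
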