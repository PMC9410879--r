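---
title: "Detecting NMD decay intermediates in ribosome profiling data"
author: "nmdtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting NMD decay intermediates in ribosome profiling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdtrace)
library(data.table)
```

## The biological model

Nonsense-mediated decay (NMD) recognises mRNAs with premature termination
codons (PTCs) and destroys them. The degradation leaves physical
intermediates that ribosome profiling (Ribo-seq) and 3′ RACE can capture,
provided downstream clearance (the SKI/PELO rescue machinery) is disabled:
mRNA fragments cleaved near the stop codon, and ribosomes stalled on the
truncated 3′ ends of those fragments.

Two mechanisms could place a stalled ribosome over a cleaved stop codon:

1. **Direct A-site cleavage** — the endonuclease cuts inside the ribosomal
   A-site while the ribosome occupies the stop codon. The stalled
   footprint's 3′ end falls within the stop codon, and there is nothing
   between cleavage and stalling to observe.
2. **Cleavage, trimming and run-on** — the endonuclease cuts downstream of
   or near the stop codon; the 3′→5′ exosome trims the fragment back until
   it is blocked (at a guanosine it fails to processively degrade, or at
   the boundary protected by a trailing ribosome); the trailing ribosome
   then elongates to the truncated end and stalls.

Mechanism 2, and only mechanism 2, predicts a transient **approach
series**. A ribosome protects a full footprint of about 28 nt, of which
about 10 nt lie between the A-site first nt and the mRNA entry tunnel.
When the mRNA ends inside the entry tunnel, the protected length is

$$L(d) = \min(L_\mathrm{full},\; L_\mathrm{stall}^{\max} + d),$$

where $d$ is the distance from the A-site first nt to the fragment 3′ end,
$L_\mathrm{full} = 28$ and $L_\mathrm{stall}^{\max} = 18$. Codon-by-codon
translocation steps $d$ by 3, so the series of protected lengths is 28,
25, 22, 19, and finally the stalled 15–18 nt range — all sharing one 3′
end and shrinking at the 5′ end:

```{r geometry}
cfg <- sim_config()
data.frame(a_site_to_end = c(10, 7, 4, 1, 0),
           protected = footprint_length(c(10, 7, 4, 1, 0), cfg))
```

`sim_config_human()` provides a preset with a 31-nt full footprint (and a
13-nt entry-tunnel span), which shifts the intermediate 5′ ends 3 nt
upstream — the mammalian-geometry variant of the same series.

## Coordinate and data conventions

* Transcript-space positions are 0-based; reads occupy `[end5, end3]`
  inclusive with `length = end3 - end5 + 1`.
* Relative position 0 is the **first** nt of the annotated stop codon (the
  stop occupies 0, 1, 2). The literature rarely states this convention;
  fixing it here makes every table and test unambiguous.
* CDS features in GFF3 are assumed to include the stop codon (Ensembl
  convention); the stop codon is the last 3 nt of the spliced CDS.
* Size classes follow the gel size selections: 15–18 ("short"), 19–26
  ("mid"), 28–30 ("long"); 27 nt falls in no class.
* PCR duplicates are collapsed by exact match on (gene, 5′ end, length,
  UMI). One-mismatch UMI merging is deliberately not attempted: at the N6/N8
  randomer lengths used here the collision cost of merging exceeds the
  duplicate-leakage cost of exact matching. The 3′ end is implied by the
  other key fields because the UMI-bearing adapter ligates to the fragment
  3′ end in both protocols.
* Reads are analysed through one representative isoform per gene
  (`canonical_transcripts()`: longest CDS, lexicographic tie-break), while
  `n_annotated_stops` is counted across all isoforms so multi-stop genes
  can be excluded from gene-level positional analyses.

## The permutation significance map

`build_tallies()` restricts to genes with at least 5 reads (the count is
taken over all the gene's reads, before windowing) and tallies reads by 5′
end and length. `average_density()` is the per-cell mean count over
included genes. `permutation_significance()` then shuffles, within each
(gene, length) stratum, the observed multiset of counts onto uniformly
random **distinct** positions of the analysis window, recomputes the
average density, and repeats (30 shuffles by default). Each cell gets

$$z = \frac{\mathrm{obs} - \overline{\mathrm{perm}}}{s_\mathrm{perm}},
\qquad p = 1 - \Phi(z),$$

with the sample standard deviation ($n-1$) over permutations and a
one-sided upper tail, no multiple-testing correction — the map is read as
a significance heat-plot, not as a discovery list.

Numerical choices:

* **Shuffle target.** "Shuffling (position, count) pairs" admits two
  readings: reassignment over the *full window* (default, `mode =
  "window"`) or permutation among the stratum's *occupied* positions only
  (`mode = "occupied"`, provided for sensitivity analysis). The full-window
  mode is the default because it breaks positional structure while
  conserving counts; the occupied-only mode cannot move a single-position
  stratum at all.
* **Degenerate cells.** Cells with zero permutation variance and observed
  equal to the permutation mean get z = 0, p = 1. p-values are clamped
  into (0, 1]; extreme signals underflow to the smallest positive double.
* **Window.** Default −40..+20 for 5′-end coordinates, so the stop-proximal
  3′ ends of 15–28-nt reads place their 5′ ends inside the window.
* **Determinism.** The permutation RNG is seeded explicitly; identical
  inputs and seed give identical matrices.

The test suite checks this machinery three ways: Monte-Carlo moments
against an exhaustively enumerated placement distribution on a tiny
instance; type-I calibration on null data (the fraction of p < 0.05 cells
is ~5%); and model discrimination on simulated data (the 25/22/19
diagonal reaches p < 0.01 under the run-on model and stays silent under
direct A-site cleavage).

## Metagene normalisation

`gene_density()` divides a gene's per-position counts by its
length-normalised CDS read count (`cds_total / cds_length`), so uniform
coverage has density 1.0 and expression differences cancel;
`metagene()` averages gene densities position-wise. Choices:

* The denominator counts reads anchored **inside the CDS** only, even when
  the window extends into the UTRs; by default it uses all supplied reads
  (any size class), and a separate `norm_reads` table can be passed when a
  library is a single size class.
* Genes whose transcript does not span the full window contribute only at
  covered positions; each position's mean is over genes covering it. This
  avoids deflating window edges with artificial zeros.
* Default window −50..+50; the published metagenes use windows of roughly
  this span without stating bounds.

## Gene-level stop-codon maps

The CDF heatmap uses a 100-nt window fixed as relative positions −50..+49
(100 positions, anchor 0 = stop first nt; stated in output metadata since
"centered on the stop codon" is ambiguous for an even window). Genes need
at least 50 read 3′ ends in the window and a single annotated stop
across isoforms. `half_point` uses "at or upstream" semantics exactly: the
smallest position with cdf ≥ 0.5. Ordering ties break lexicographically so
output is deterministic. Raw CDFs are emitted without further per-gene
normalisation.

`frame_fractions()` classifies reads with 3′ ends strictly downstream of
the stop (relative position > 2) by their 5′-end offset modulo 3 against
the CDS frame — actively elongating (readthrough) ribosomes are
frame-locked, post-termination or rescue intermediates are not.

## 3′-end chemistry

`compare_libraries()` normalises each library by its total deduplicated
read count and calls a site OH-dominant at a −PNK/+PNK ratio ≥ 0.5 and
P-dominant at ≤ 0.25. These thresholds are heuristics chosen to separate
the simulated pure-OH and pure-P regimes with margin; they are exposed as
arguments and are not measured constants. Sites with fewer than 10
combined reads are always indeterminate. `end_base_composition()` tabulates
the transcript base under each read 3′ end within 10 nt of a stop codon,
against `background_base_composition()` over the same positions.

## What the simulator emulates — and what it does not

`simulate_transcriptome()` generates single-isoform genes (5′UTR 30 nt,
CDS 300–900 nt at 43% GC with a canonical stop, 3′UTR 150 nt), log-normal
expression weights, and one designated IRE-1-like gene with a fixed
mid-CDS cleavage site leaving 3′-phosphate ends (the metal-independent
control locus). `simulate_reads()` emits, per molecule:

* elongating 28–30-nt footprints uniform over the CDS;
* 21-nt empty-A-site termination footprints at the stop (5% of intact
  molecules, emitted regardless of model — termination pausing does not
  depend on the endonuclease), anchored with their 3′ end on the stop's
  last nt;
* under **model 1**, stalled 15–18-nt footprints with 3′ ends uniform over
  the stop codon;
* under **model 2**, a cut site from the cleavage-offset law (default:
  mass 0.5 on the stop's first nt with a geometric tail downstream, so
  cleavage concentrates over the stop while allowing the downstream cuts
  the run-on model requires), exosome trimming halting at guanosines with
  probability 0.3 and unconditionally at the trailing ribosome's boundary
  (the stop's last nt), stalled footprints whose 3′ end is the truncated
  end, and — with probability 0.02 — a pre-stall snapshot of length
  `footprint_length(d)` for a codon-stepped distance d ∈ {1, 4, 7}. The
  capture probability is a free parameter: the relative abundance of
  approach-series versus stalled footprints has no measured value, and
  0.02 encodes "rare but detectable at realistic depth";
* optional readthrough (frame 0 or −1) emitting frame-locked downstream
  footprints with 5% digestion frame-noise;
* 3′ RACE fragments mirroring the fragment ends with their nuclease's
  chemistry (OH for the endonuclease and exosome, P for the IRE-1-like
  site); intact molecules contribute their mature 3′ end. The −PNK library
  drops phosphate ends; the +PNK library keeps everything.

Stalled-footprint lengths are drawn uniformly from 15–18 to mimic RNase1
digestion heterogeneity (the range is attributed to digestion; no
distribution has been reported). PCR duplicates are appended at 15% with
reused UMIs so the collapse step has real work to do.

Not emulated: ligation and circularisation biases, sequencing errors,
multi-mapping, untemplated tailing, and multi-isoform genes. Passing
tests therefore demonstrate correctness of the statistics under the
mechanistic model, not robustness to library-prep artefacts in real data.

## Problem sizes and determinism

The packaged checks use 300-gene transcriptomes at 2×10⁵ Ribo-seq reads
for model discrimination (10 seeds per model), 500 genes × 200 reads for
null calibration with 200 permutations, 10⁴ permutations for the
enumeration oracle, and 20–100 genes for dose-response, chemistry and
frame checks — sizes chosen so each property is measured with comfortable
statistical margin while the whole suite runs in a few minutes on one
core. Every stochastic step takes an explicit integer seed, and fixing the
seed fixes outputs byte-for-byte (the pipeline determinism test asserts
md5 equality across reruns).

## Known limitations

* The permutation p-value relies on a normal approximation to a 30-draw
  permutation distribution; it is calibrated in aggregate (see the type-I
  test) but individual extreme cells should be read qualitatively.
* Exact-match UMI collapse slightly overcounts molecules under sequencer
  UMI errors and undercounts at saturation; neither regime occurs in the
  simulator.
* The heatmap window convention (−50..+49) shifts half-points by at most
  1 nt relative to any other centring of a 100-nt window.
* The trimming automaton models guanosine stalling as a per-base Bernoulli
  event; real exoribonuclease stalling depends on run length and structure.
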