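---
title: "Quantifying ssDNA and dsDNA viral communities by mass apportioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ssDNA and dsDNA viral communities by mass apportioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromass)
```

## The problem

Fluorescence-based direct counting of SYBR-stained virus particles is the
standard way to enumerate viruses in sediment, but it systematically
undercounts viruses with small genomes: an ssDNA virus of ~2 kb carries so
little DNA that its stained particle is often invisible. `viromass`
implements an orthogonal, mass-based estimator: extract and quantify the
viral ssDNA and dsDNA fractions separately, then convert each measured mass
concentration into genome copies by dividing by the DNA mass of a single
virion under an assumed genome size.

## The mass-apportioning model

The DNA mass of one virion with genome size $L$ (kb) is

$$ m(L) = \frac{L \cdot 10^3 \cdot w}{N_A}, $$

where $w$ is the average monomer molecular weight (331.2 g/mol per
nucleotide of ssDNA; structurally $2w = 662.4$ g/mol per base pair of
dsDNA) and $N_A$ is Avogadro's number. These defaults give
$m(1.8\,\mathrm{kb}, \mathrm{ss}) = 9.90\times10^{-19}$ g,
$m(24.9\,\mathrm{kb}, \mathrm{ss}) = 1.37\times10^{-17}$ g and
$m(50\,\mathrm{kb}, \mathrm{ds}) = 5.5\times10^{-17}$ g.

A measured mass concentration $C$ (ng per cm$^3$ sediment) and an assumed
genome-size range $[L_{\min}, L_{\max}]$ yield an abundance *interval*
(copies per cm$^3$):

$$ V \in \left[\frac{C \cdot 10^{-9}}{m(L_{\max})},\;
               \frac{C \cdot 10^{-9}}{m(L_{\min})}\right]. $$

The ssDNA envelope defaults to 1.8–24.9 kb, the span of known ssDNA viral
family genome sizes; dsDNA uses a 50 kb point assumption (a literature
average for tailed phages), though the interface accepts a range. The
relative ssDNA share $R = 100\,V_{ss}/(V_{ss}+V_{ds})$ is evaluated with a
conservative pairing — the ssDNA lower bound against the dsDNA upper bound
and vice versa — which reduces to the plain ratio when dsDNA is a point.
The report also derives the virus-to-cell ratio (direct viral count /
direct cell count) and the fold-difference between the mass-derived ssDNA
estimate and the direct viral count, the quantity that exposes the
undercounting of ssDNA virions.

Display rounding follows the reporting conventions of the field: two
significant figures for counts and copies, two decimals for VCR, one
decimal for percentages, one significant figure for contamination ratios.
Unrounded values are always retained; only the display table is rounded.
With the bundled sediment measurements, recomputation reproduces every
derived column at printed precision except four cells that differ by one
unit in the last printed digit (a VCR of 0.48 vs recomputed 0.47; two
dsDNA copy numbers; one relative-abundance lower bound) — consistent with
the original table having been derived from unrounded intermediates that
were not printed.

## Read profiling

Virome reads searched against a protein database arrive as 12-column BLAST
tabular hits. Profiling proceeds as: strict E-value filter
($E < 10^{-5}$); per-read MEGAN-style lowest-common-ancestor assignment
(retain hits with bitscore $\ge$ 50 and within 10% of the best retained
bitscore, then take the deepest taxonomy node shared by all retained
taxa); category binning at family rank, nucleic-acid type, or
superkingdom; and collapsing of families below 2% of viral reads into
"other ssDNA/dsDNA viruses" bins. The LCA parameters are conventional
defaults, exposed as arguments, since the original analysis names the tool
but not its settings. Both threshold rules are strict less-than: a hit at
exactly $10^{-5}$ is removed, a family at exactly 2% is retained.

The taxonomy is a small explicit registry (TSV: name, rank, parent,
nucleic-acid type, genome-size range) rather than an NCBI dump: lookups
(genome size, nucleic-acid type) walk up the ancestor chain to the nearest
annotated node, so annotating families suffices. The bundled registry
covers the ssDNA families typical of sediment viromes (Circoviridae,
Microviridae, Inoviridae) and the common dsDNA families (Caudovirales
families, Phycodnaviridae); the 1.8–24.9 kb envelope is attached to the
internal "ssDNA viruses" node as a community-level assumption, with
per-family ranges as refinements, because no published family list pins
down which families define the envelope's endpoints.

## Library QC

Library summaries (read count, mean length, total Mb, GC over unambiguous
bases only) come from FASTA/FASTQ via Biostrings. The contamination
criterion is the published virome standard: a library passes when rRNA
gene-associated reads are strictly below 0.02% of total reads. rRNA read
identification itself is upstream of this package; counts arrive as input.

## Ordination

Community comparison uses PCA on family-level relative-abundance
proportions (each library's viral category counts divided by its viral
read total; unassigned reads excluded). Proportions enter untransformed by
default — the original analysis states no transform — with a Hellinger
option available. The fit is `stats::prcomp` on the column-centered
matrix; explained-variance fractions are taken against total variance so a
full-rank fit sums to 1; eigenvector signs follow a deterministic
convention (largest-magnitude loading positive) so scores are reproducible
across runs. Projection of new samples centers with the training means;
categories unknown to the model are dropped with a warning, missing ones
zero-filled. The choice of rank (family) and scale (proportions) is a
documented assumption: the original figure does not state either.

## The synthetic community generator

Because the study's raw reads live in an external archive, every stage is
exercised against a seeded simulator that emulates the statistical
structure the analysis assumes:

* **Community** — `nSsFamilies = 5` ssDNA and `nDsFamilies = 3` dsDNA
  families with log-normal particle abundances
  (`lognormalMuSs = 17.6`, `lognormalMuDs = 14.0`, `lognormalSigma = 1`,
  log copies/cm$^3$) and ssDNA genome sizes uniform on 1.8–24.9 kb, dsDNA
  fixed at 50 kb. These defaults reproduce the measured magnitudes of
  bathyal surface sediment: ssDNA masses of roughly 1.5–3 ng/cm$^3$, dsDNA
  0.2–0.5 ng/cm$^3$, direct counts of $10^5$–$10^7$/cm$^3$.
* **Masses** — each channel's true mass is the abundance-weighted sum of
  per-virion masses; a fraction `s1CarryoverF = 0.05` of ssDNA mass
  escapes S1 nuclease digestion into the dsDNA channel; measurement noise
  is multiplicative mean-preserving lognormal with `massNoiseCv = 0.1`.
* **Reads** — multinomial with weights abundance × genome size, ssDNA
  weights multiplied by `mdaSsBias = 10` in the ssDNA library (multiple
  displacement amplification preferentially amplifies circular ssDNA);
  the dsDNA library sees ssDNA families only through the carryover
  fraction.
* **Direct counts** — Poisson with expectation
  $e_{ss}\sum V_{ss} + e_{ds}\sum V_{ds}$, with stain efficiencies
  `stainEfficiencySs = 0.002` and `stainEfficiencyDs = 0.8` chosen so the
  simulated ssDNA fold-underestimation spans the tens-to-hundreds regime
  observed in real sediment. The true MDA bias and S1 carryover magnitudes
  are unknown in the field; these values are placeholders for sensitivity
  analysis, not estimates.
* **Hit tables** — per read, a best hit on the true family (bitscore
  80–200) plus, with probability `decoyFraction = 0.3`, 1–4 decoy hits at
  40–88% of the best bitscore; `noHitFraction = 0.2` of reads get no hits.
  Decoys deliberately sit below the default top-10% LCA retention window,
  so recovery at default parameters is exact; the generator does not model
  within-window conflicting hits.

All randomness flows from one root seed through fixed named sub-streams
(community, masses, profiles, counts, hits, reads), drawn up front so
adding a new stream never perturbs existing output.

## Numerical and design notes

* Intervals are closed; a zero mass gives the degenerate interval [0, 0],
  and the relative share is undefined (a classed error) only when both
  abundances are zero.
* A genome-size range may be degenerate (`min = max`), turning the
  interval into a point estimate — this is what makes noise-free simulated
  masses invert exactly.
* Direct-count standard deviations are carried through reports as
  annotations only; no error propagation is applied, matching how such
  tables are reported.
* Containment of the truth by the abundance interval is *not* guaranteed
  under mass noise: it holds exactly when the realized noise factor lies
  within the interval's structural slack (the ratio between the envelope
  bounds and the community's abundance-weighted mean genome size). At a
  CV of 0.1 the slack is typically many noise SDs wide, and measured
  coverage over 200 replicates is 99.5–100% depending on the seed; the
  rare failures are communities that happen to draw all their genome
  sizes near the envelope's upper end. The test suite asserts the exact
  characterization rather than pretending coverage is structurally 100%.
* Test and simulation problem sizes (3,000-read libraries, 200-replicate
  coverage runs, 1,000-case LCA randomization) are chosen so the whole
  suite completes in well under a minute while keeping multinomial and
  Poisson sampling error far below the asserted tolerances.

## What the synthetic tests do and do not show

Passing recovery tests show the estimator chain is self-consistent: masses
generated from a known community invert to intervals containing the truth,
simulated hit tables profile back to the generating composition within 1%,
and held-out samples project into their generating cluster. They do not
validate the biological assumptions against real data — the true genome
size distribution of an environmental community, the actual MDA bias, S1
digestion completeness, extraction efficiency (no correction is applied),
or database completeness for LCA assignment. Real composition percentages
and ordination coordinates depend on external sequence archives and
reference databases and are deliberately out of scope.
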