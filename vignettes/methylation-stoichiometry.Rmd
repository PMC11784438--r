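---
title: "Quantifying per-residue lysine methylation stoichiometry in repetitive proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying per-residue lysine methylation stoichiometry in repetitive proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylstoich)
```

## The problem

Large bacterial cell-surface adhesins of the trimeric autotransporter
family carry hundreds of lysines, many of which can be mono-, di- or
trimethylated on the side-chain ε-amino group by dedicated outer-membrane
protein lysine methyltransferases. Label-free LC–MS proteomics identifies
and quantifies tryptic peptides, not residues, so estimating the
*stoichiometry* of methylation at each lysine — the fraction of the
residue's population in each of the four states (unmethylated, mono, di,
tri) — requires aggregating peptide-level evidence back onto protein
coordinates. Two features of these proteins make that non-trivial:

1. **Repetitiveness.** Domain repeats mean that a peptide sequence can
   occur at several positions of one protein. Label-free quantification
   reports peptide *species* (sequence + modification set), summing peak
   areas over all copies; the positional origin of the signal is lost.
2. **Localization ambiguity.** A methyl group seen on a peptide may not be
   confidently assignable to a specific residue within it; such peptides
   cannot contribute to site-level quantification.

## The estimator

For a target protein with sequence $S$ and lysine positions
$\{p_1,\dots,p_m\}$, and a table of peptide observations
$(q_i, M_i, a_i, c_i)$ — sequence, modification set, peak-area abundance,
localization confidence — the per-residue abundance of state
$s \in \{\mathrm{un}, \mathrm{me1}, \mathrm{me2}, \mathrm{me3}\}$ at
position $p$ is

$$
A_s(p) \;=\; \sum_{i \,:\, \text{confident}} \;
\sum_{o \in \mathrm{occ}(q_i, S)}
\frac{a_i}{|\mathrm{occ}(q_i, S)|}\;
\mathbf{1}\!\left[\, o \le p \le o + |q_i| - 1 \;\wedge\;
\mathrm{state}(M_i,\, p - o + 1) = s \,\right],
$$

where $\mathrm{occ}(q, S)$ is the set of exact-substring start positions
of $q$ in $S$ (overlaps allowed) and $\mathrm{state}(M, j)$ reads the
methylation state annotated at within-peptide offset $j$ (no methyl
annotation, or a non-methyl modification such as oxidation, gives
"unmethylated"). The occupancy percentages are
$100 \cdot A_s(p) / \sum_{s'} A_{s'}(p)$ for residues with positive total
abundance ("detected"); undetected residues are reported as missing, never
zero-filled. The protein-level *mean methylation percentage* is the
unweighted mean over detected residues of $(100 - \%\mathrm{un})$, so all
three methyl states count as methylated.

Three processing rules precede the sum:

* rows reporting the same peptide species are merged by summing abundance
  (peptide abundance is a peak-area sum);
* observations carrying a modification with
  `localization_confident = FALSE` are excluded entirely; unmodified
  peptides are always retained, whatever their flag, since they have
  nothing to localize;
* peptides mapping to zero positions of the target are excluded and
  counted in the diagnostics — they may simply belong to other proteins.

Equal apportionment across occurrences is the only assignment available
without positional information. Its cost is characterized exactly below.

### Digestion

In-silico digestion uses the standard trypsin rule: cleave C-terminal to K
or R, suppressed when the next residue is proline, with a configurable
number of allowed missed cleavages (default 2, the common search-engine
setting). Digestion is modification-blind: quantification happens
downstream of identification and never re-digests, so any interplay
between methylation and cleavage efficiency belongs to the simulator, not
the estimator. Coordinates are 1-based inclusive throughout, matching the
field's residue naming (e.g. "Lys616"). Peptide length filters exist but
default to off.

### Arginine methylation and other modifications

Methylation annotations on arginine are parsed and carried, but
per-arginine stoichiometry is not computed; at the lysine positions such a
peptide covers it contributes to the unmethylated state, exactly as any
peptide without a methyl group on that lysine does. Oxidation and
N-terminal acetylation are likewise carried but never alter a lysine's
state.

## The synthetic-data generator

Because the real deposited datasets require a proprietary search upstream,
every stage here is validated against simulated data with known truth. The
generator emulates an adhesin-like repeat protein and the statistical
structure of a label-free peptide table:

* **Architecture** — head (18 residues) + $n$ copies of a 30-residue unit
  + tail (12 residues). The unit carries two cleavage lysines (mid-unit
  and unit-terminal), giving a lysine fraction of ~7%, typical of large
  repetitive adhesins, and tryptic fragments of ~15 residues. Copies
  diverge by independent point substitutions at a configurable per-position
  rate. The proteolytic skeleton is deliberately held fixed across copies
  — cleavage lysines are never mutated, and the residue after a cleavage
  site is never proline — so repeats stay aligned at fragment resolution
  while their sequences diverge; with divergence 0.2 the chance that two
  15-mer fragments from different copies remain identical is below 0.2%,
  which is what makes exact noiseless recovery testable.
* **Truth** — per-lysine occupancy vectors drawn from a Dirichlet with
  concentration (8, 3, 0.3, 0.1) over (un, mono, di, tri): mono-dominant
  methylation averaging ~30%, with only trace di/tri, mirroring the
  wild-type-like regime where monomethylation dominates and trimethylation
  is essentially absent. A `fixed` scheme plants one vector at every
  lysine (default (0.74, 0.26, 0, 0), i.e. 26% methylation), and an
  `all-unmethylated` scheme gives negative controls.
* **Observation model** — for each tryptic peptide and each combination of
  methylation states over its lysines, the expected species abundance is
  `abundance_base` × the product of the per-lysine state occupancies.
  Species arising identically from several repeat copies are merged by
  summing expectations *before* anything else: this is the step that makes
  multi-mapping a real inference problem, since the table then reports
  peptide species with no positional information, exactly as label-free
  quantification does. Each merged species receives one multiplicative
  log-normal noise factor $e^{\mathcal N(0,\sigma)}$ (the standard model
  for peak-area error; $\sigma$ on the natural-log scale), is observed
  with probability `detection_probability`, and modified species are
  flagged localization-ambiguous with probability `ambiguous_fraction`.
  Noise and detection act on the merged species rather than per copy
  because the instrument sees one chromatographic species, not one signal
  per genomic occurrence; for the noiseless identifiability results the
  two orderings are equivalent.
* **Cleavage blocking** — optionally, a cleavage site at a lysine is
  suppressed with probability `p_block × (methylated fraction)` before
  enumeration, emulating trypsin's reluctance to cut after methylated
  lysine. The default is 0 (modification-blind digestion), which keeps
  noiseless recovery exact; blocking is for robustness experiments only.

All randomness flows from a single integer seed (sequence, truth and
table use separated sub-streams so changing one scheme never perturbs the
others), and the provenance record carries the full configuration.

## What the tests establish

* **Digestion** equals a brute-force enumeration of all substrings
  bounded by termini/cleavage sites with bounded internal site count, on
  hundreds of random sequences.
* **Noiseless identifiability.** With no noise, full detection, no
  ambiguity and diverged repeats (divergence 0.2, at which peptides map
  uniquely), the pipeline recovers every planted occupancy vector to
  machine precision. This is the end-to-end correctness statement.
* **The apportionment law.** With *identical* repeats and heterogeneous
  planted occupancies, each repeat position's estimate equals the
  across-repeat mean occupancy exactly. The tested configuration uses a
  fragment-aligned array (no flanks, boundary-terminated units, fully
  tryptic species) so that every lysine-bearing species occurs exactly
  once per repeat; peptides with missed cleavages that straddle repeat
  junctions additionally average over the $n-1$ interior junctions, a
  second-order edge effect outside the exact law. This quantifies
  precisely what equal splitting can and cannot tell you: repeats are
  estimated at their family mean, and within-family differences are
  invisible to a shared peptide.
* **Conservation.** Detected residues' percentages sum to 100 within
  1e-9, and the total assigned abundance equals an independent
  per-occurrence re-count, on stochastic simulations with noise, missing
  species and ambiguity.
* **Stochastic consistency.** Mean absolute recovery error increases
  monotonically with the noise scale over $\sigma \in \{0.05, 0.2, 0.5\}$
  (20 seeds each).
* **Motif discrimination.** The flanking-window analysis (±10 residues
  around methylated lysines, position frequency matrix, per-column
  information content $\log_2 20 - H$) flags a planted 3-letter motif at
  100 windows and stays silent on uniform flanks at the default 1-bit
  threshold. Pads at the termini are excluded from column denominators;
  the center column, conditioned to be lysine, is excluded from the
  verdict. No small-sample correction is applied by default: at $n=100$
  windows the uniform-flank bias is ~0.14 bits, far from the threshold,
  and the option stays available for small window sets.

What the simulation does *not* emulate: chimeric/mis-identified spectra,
intensity-dependent detection (a species' detection odds do not depend on
its abundance), retention-time or charge-state effects, and
between-protein interference. Passing these tests therefore demonstrates
the correctness of the quantification arithmetic and its documented bias
under multi-mapping — not the upstream identification quality of any real
search.

## Numerical and design choices

* Percentages are computed in double precision; tests compare at 1e-9
  absolute tolerance.
* "Detected" means total abundance strictly above a threshold that
  defaults to 0; no minimum-abundance filter is imposed beyond that, and
  the threshold is an explicit argument.
* The "average percentage of lysine methylation" is the *unweighted* mean
  over detected residues; an abundance-weighted mean would over-represent
  well-ionizing regions of the protein.
* A lysine at a peptide's C-terminus (a cleaved, hence typically
  unmodified site) is treated identically to internal lysines; the
  estimator takes the annotations at face value.
* The consensus threshold of 1 bit per column is this package's
  operationalization of "a clear consensus": one bit corresponds to a
  column whose composition is about as constrained as a 50/50 choice
  between two letters, comfortably above sampling noise at realistic
  window counts yet far below single-letter conservation (~4.3 bits).
* Problem sizes in the shipped tests (units of 30 residues, 2–5 repeats,
  20 seeds per noise level) are chosen so the full property suite
  exercises every code path in well under a coffee break while keeping
  every claim exact rather than approximate.

## Limitations

Equal apportionment is an assumption, not an inference: when repeat
copies genuinely differ, shared peptides pull every copy toward the family
mean (the bias quantified above), and only copy-unique peptides restore
identifiability. Stoichiometry from peak areas also assumes equal
ionization efficiency of a peptide's methylated and unmethylated forms —
standard practice for label-free site occupancy, but a methyl group can
shift charge and hydrophobicity, so absolute occupancies carry that
caveat. Finally, protein inference is out of scope: peptides are mapped to
the one target protein, and anything that maps nowhere is merely reported.
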