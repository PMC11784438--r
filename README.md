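# methylstoich

Per-residue lysine methylation stoichiometry from label-free proteomics,
for repetitive proteins.

Large bacterial surface adhesins (trimeric autotransporter adhesins and
relatives) can carry methylation on over a hundred lysines. LC–MS
identifies and quantifies tryptic *peptides*; turning those into
site-level occupancy estimates requires mapping peptides back onto
protein coordinates, excluding modifications that could not be confidently
localized, and — because these proteins are built from sequence repeats —
dealing with peptides whose sequence occurs at several positions at once.
`methylstoich` implements that quantification procedure as a tested,
reusable pipeline, together with a synthetic-data generator with known
ground truth so every stage is verifiable without any external download.

For a target protein $S$ and confident peptide observations
$(q_i, M_i, a_i)$, the abundance of methylation state
$s \in \{\mathrm{un}, \mathrm{me1}, \mathrm{me2}, \mathrm{me3}\}$ at lysine
position $p$ is

$$A_s(p) = \sum_i \sum_{o \in \mathrm{occ}(q_i,S)}
\frac{a_i}{|\mathrm{occ}(q_i,S)|}\,
\mathbf 1[\text{occurrence } o \text{ covers } p \text{ with state } s],$$

i.e. a peptide occurring at $k$ positions contributes $a_i/k$ to each, and
the occupancy percentage of each state is $100\,A_s(p)/\sum_{s'}A_{s'}(p)$
for residues with positive total abundance. Protein-level summaries report
how many lysines were detected and methylated and the unweighted mean
methylation percentage over detected residues. A flanking-window module
(±10 residues, position frequency matrix, per-column information content)
asks whether methylated sites share a consensus motif.

## What's in the box

| area | functions |
|---|---|
| sequences & digestion | `read_fasta`, `write_fasta`, `protein_record`, `tryptic_digest`, `map_peptide_occurrences` |
| peptide tables | `psm_dialect`, `read_psm_table`, `write_psm_table`, `parse_modification_string`, `filter_ambiguous` |
| stoichiometry | `residue_stoichiometry`, `methylation_summary`, `assign_state_at_position`, `apportion_abundance` |
| motif analysis | `extract_windows`, `build_pfm`, `consensus_verdict`, `methylated_positions` |
| simulation | `simulation_config`, `simulate_methylation_dataset`, `generate_repeat_protein`, `assign_truth`, `simulate_psm_table`, `evaluate_recovery` |
| pipeline & phenotype | `run_quantify_pipeline`, `render_state_profile`, `autoagglutination_ratio`, `replicate_summary` |

## Worked example

Simulate a 3-repeat adhesin-like protein in which every lysine is planted
at 26% monomethylation, with realistic abundance noise and incomplete
detection, then quantify it:

```r
library(methylstoich)

cfg <- simulation_config(n_repeats = 3, inter_repeat_mutation_rate = 0.3,
                         noise_sigma = 0.2, detection_probability = 0.9,
                         ambiguous_fraction = 0.05,
                         occupancy_scheme = "fixed", seed = 29)
ds <- simulate_methylation_dataset(cfg)
st <- residue_stoichiometry(ds$psms$observations, ds$protein)
head(st[, c("position", "pct_un", "pct_mono", "pct_di", "pct_tri", "detected")], 4)
#>   position   pct_un pct_mono pct_di pct_tri detected
#> 1       33 80.98149 19.01851      0       0     TRUE
#> 2       48 74.17040 25.82960      0       0     TRUE
#> 3       63 72.35214 27.64786      0       0     TRUE
#> 4       78 71.96363 28.03637      0       0     TRUE

methylation_summary(st)
#> <methylation_summary> SYNREP_n3_seed29
#>   lysines: 6 total, 6 detected, 6 methylated
#>   sites: 6 mono, 0 di, 0 tri
#>   mean methylation of detected residues: 25.9%

evaluate_recovery(st, ds$truth)
#> <recovery_report> 6/6 lysines detected (coverage 100.0%)
#>   absolute error (percentage points): max 6.98, mean 1.12
```

Each row is one lysine: under multiplicative peak-area noise the
estimated monomethyl occupancies scatter around the planted 26%, and the
protein-level mean lands at 25.9%. With `noise_sigma = 0`,
`detection_probability = 1` and `ambiguous_fraction = 0` the recovery is
exact to machine precision — that property, and the exact
across-repeat-mean behaviour of equal apportionment on identical repeats,
are part of the test suite.

File-based use mirrors the same steps: `run_quantify_pipeline(fasta,
psm_table, protein_id, out_prefix)` reads a FASTA and a delimited peptide
table (column layout adapted via `psm_dialect`), and writes a per-lysine
TSV, a JSON summary and a diagnostics log naming every excluded peptide
and its reason.

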