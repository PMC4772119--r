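---
title: "Detecting and comparing single-span transmembrane domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing single-span transmembrane domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdscan)
```

## Background

Bitopic (single-span) membrane proteins cross the lipid bilayer with one
hydrophobic helix, the transmembrane domain (TMD). Because bilayer
thickness differs between cellular membranes, the *length* of that helix
carries information: TMD-length distributions differ systematically
between proteins resident in the plasma membrane, the early secretory
pathway, and various organelles, and the same logic extends to viral
membrane proteins, whose TMD lengths track the compartment in which the
virus enters or replicates. `tmdscan` implements the three ingredients
needed to study such signatures from sequence alone:

1. **Detection** — locate the TMD of each protein from a hydropathy
   profile and refine its boundaries to residue precision.
2. **Redundancy reduction** — collapse near-identical TMD regions so each
   distribution counts independent observations.
3. **Comparison** — summarise and contrast integer TMD-length
   distributions between groups.

## Detection

Detection operates on a residue hydropathy scale. Two scales are bundled
as versioned data files: `GES` (Goldman–Engelman–Steitz, water–oil
transfer free energies in kcal/mol, hydrophobic residues positive) and
`KD` (Kyte–Doolittle). A residue is *hydrophobic* when its score is
strictly greater than the threshold (default 0); the unknown residue `X`
scores exactly 0 and is therefore never hydrophobic.

The procedure has four deterministic stages, all exposed individually:

1. **Rough scan** (`rough_scan()`): sum the scores over every
   `window = 18`-residue window and keep the window with the largest sum.
   Ties (within a fixed 1e-9 numerical tolerance, to neutralise
   floating-point summation noise) resolve to the smallest start
   position.
2. **Flank attachment** (`attach_flanks()`): extend the window by up to
   `max_flank = 8` residues on each side, truncated at the sequence ends.
   The resulting *candidate* region is therefore 18–34 residues long, and
   at least 26 residues whenever 8 residues exist on either side.
3. **Edge refinement** (`refine_edges()`): starting from the core window,
   first *expand* each edge outward through the candidate while the next
   residue is admissible, then *contract* inward while an edge residue is
   inadmissible. A residue is admissible when it is hydrophobic, or when
   it is *buried*: an uncharged hydrophilic residue with at least
   `burial = 3` contiguous hydrophobic residues on both sides within the
   candidate. Charged residues (D, E, K, R, H) are never
   buried-admissible. A candidate with no hydrophobic residue at all
   yields a `no_tmd` flag rather than an error.
4. **Orientation** (`orient_span()`): the refined span is reported with
   position 1 at its cytosolic end, using the record's topology
   (`N_CYTO` keeps sequence order, `C_CYTO` reverses it). The oriented
   *context* additionally extends towards the exoplasmic side, which is
   what the profile machinery consumes.

All stage parameters live in one `tmd_config()` object, so sensitivity
analyses are a one-liner.

### A known geometric limitation

The candidate region reaches at most 8 residues beyond one edge of the
best-scoring 18-residue window. A hydrophobic stretch longer than 26
residues is therefore only recovered exactly when the argmax window
happens to land within 8 residues of a run edge; for runs of 27–34
residues the true boundary can fall outside the candidate, and refinement
cannot reach it. This is a property of the stated constants (window 18,
flank 8), not of the implementation; the package documents it rather than
silently widening the constants. Unconditional exact recovery holds for
planted runs of up to 26 residues, and the test suite exercises that
regime explicitly.

## Redundancy reduction

Two TMD regions are compared by global alignment with match score 1,
mismatch 0, and unit gap penalty. Per cent identity is defined as
`2*(S + G) / (nA + nB + G)` where `S` is the optimal alignment score and
`G` the number of gap columns. Because co-optimal alignments can differ
in `G`, and the identity is monotone increasing in `G` at fixed score,
the implementation tracks the *maximum* number of gap columns among all
optimal alignments; this makes the identity well defined and symmetric
without a traceback. Sequences with identity above
`identity_threshold = 0.30` are joined by single linkage
(`cluster_tmds()`, connected components via igraph), and each cluster is
represented by its longest member (ties to the lexicographically smallest
id).

## Statistics

TMD lengths are small positive integers, so distributions are exact
integer histograms (`length_distribution()`). Group location is compared
with Welch's unequal-variance two-tailed t-test (`welch_ttest()`, a thin
wrapper around `stats::t.test`); the degenerate case of two constant
samples with equal means reports t = 0, p = 1 with a flag.

Distribution shape is compared with the Kullback–Leibler divergence of
the length histograms (`kldm()`), using the natural logarithm by default.
Zeros make the divergence infinite, so both histograms are first
restricted to their common nonzero support and renormalised
(`trim_zero_support()`); two distributions with no common support have no
finite divergence — `kldm()` errors, while the bundled group comparison
(`compare_groups()`) reports `NA` with a
`"non-overlapping distributions"` flag. `kldm_symmetric()` averages the
two directed divergences. No multiple-testing correction is applied; the
package reports raw two-tailed p-values.

Aligned profiles complement the scalar summaries:
`mean_hydropathy_profile()` averages per-position scores across records
anchored at the cytosolic end (window 1 by default — averaging across
records already smooths, and a left-anchored multi-residue window would
shift the apparent membrane boundary inward and bias the mode reading),
and `profile_mode_length()` reads the dominant span length as the first
zero crossing of the mean curve. `abundance_profile()` gives
per-position residue frequencies.

## Synthetic data

`plant_tmd()` and `generate_group()` build sequences of the form
*hydrophilic flank + hydrophobic run + hydrophilic flank* with known
ground truth. The hydrophobic alphabet is {L, I, V, F, M, A} and the
hydrophilic one {D, E, K, R, N, Q}; serine is deliberately excluded from
the flanks because it scores positively on the GES scale and would break
the invariant that the planted run is the unique maximal hydrophobic
stretch. Flanks must be at least 9 residues (half the scan window) so
the scan cannot latch onto a sequence end. `generate_group()` draws
lengths from a rounded normal clipped to [8, 34], varies flanks over
10–14 residues, and alternates topologies; everything is deterministic
per seed, and the caller's RNG stream is restored afterwards. These
generators model isolated single-span proteins with strong hydropathy
contrast — they are validation fixtures, not a model of real membrane
proteomes.

## Worked example

```{r example}
sim_er <- generate_group(30, 19, 2, seed = 11, group = "ER_like")
sim_pm <- generate_group(30, 24, 2, seed = 12, group = "PM_like")
tab <- detect_tmds(rbind(sim_er$records, sim_pm$records))
summary(tab)

run_compare(tab, "ER_like", "PM_like")
```

And the bundled viral TMD-length table:

```{r viral}
viral <- viral_tmd_lengths()
cmp <- run_compare(data.frame(group = viral$group,
                              length = viral$tmd_length), "PM", "CME")
cmp
```

## Problem sizes

The package targets desk-scale analyses: hundreds to a few thousand
records, sequences up to a few thousand residues. The test suite uses
groups of up to 200 generated records, alignment oracles on sequences of
10–25 residues, and recovery sweeps of 500 planted sequences; all of it
runs in well under a minute on one CPU.
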