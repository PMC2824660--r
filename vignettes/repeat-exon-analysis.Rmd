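---
title: "Characterizing tandem-repeat exons in alternatively spliced regions"
author: "plastex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tandem-repeat exons in alternatively spliced regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastex)
```

## The scientific problem

Some vertebrate genes carry a C-terminal coding region that evolves far
faster than the rest of the gene: exon counts and lengths vary between
lineages, most exons are alternatively spliced cassettes, and in teleost
fish the region collapses into one long exon built from tandem copies of a
~13-amino-acid / 39-nucleotide unit. Periostin is the canonical example:
its C-terminal region (exons 16–23 in mammals) is homologous, exon by
exon, to the teleost repeat array, and every analysis the package
implements exists to establish or exploit that homology:

1. **Repeat characterization** — find the repeat period, cut the array
   into units, align them, and call a consensus with per-column
   information content (sequence-logo matrices).
2. **Dot-matrix similarity** — windowed self- and cross-comparisons that
   surface the repeat as off-diagonal lines, including similarity of the
   repeat to its own reverse complement.
3. **Profile homology search** — position-specific scoring matrices built
   from repeat-unit alignments, scanned against protein databases with
   calibrated E-values and iterative refinement. The headline behaviour is
   the *duplet rule*: one repeat unit is too little context and matches
   generic repetitive proteins; two consecutive units already retrieve the
   true homologs specifically.
4. **Exon reconstruction** — translated local alignment of a protein
   query against genomic DNA, chaining of the resulting HSPs, and
   refinement of exon boundaries to canonical GT-AG splice sites, with the
   three hallmarks of a functional cassette exon (frame preservation,
   stop-freedom, canonical flanks) checked explicitly.
5. **Region-wise phylogenetics** — progressive alignment, p-distances
   with gapped columns excluded, neighbor-joining trees with bootstrap
   support, and the branch-length contrast between a conserved and a
   plastic region of the same alignment.

Everything is validated against a synthetic-locus generator, so every
pipeline stage has a ground truth.

## Repeat period, segmentation, and consensus

`estimate_period()` scores every lag `p` by the fraction of positions
`i` with `s[i] == s[i+p]`. Significance comes from a shuffle null: the
input's residues are permuted (100 times by default) and the 99th
percentile of the per-shuffle maximum lag score is the detection
threshold. Multiples of the fundamental period score as well as the
period itself, so the smallest lag within tolerance of the maximum wins;
the tolerance is 5% of the maximum or twice the binomial standard error
of the best lag's identity estimate, whichever is larger, so short
diverged arrays do not lose the fundamental to sampling noise at a
multiple. The
sequence must be longer than `max_period`; lags are scored over whatever
overlap they have, which lets a six-unit array of a 13-mer (78 residues)
be scanned up to lag 40.

`segment_units()` phases unit starts on an anchor residue (proline by
default — a preference mirroring how repeat alignments are conventionally
phased, not a requirement) and then cuts greedily, allowing per-unit
length deviations of up to ±2 residues (±3, in steps of 3, for DNA so the
reading frame stays intact). Each candidate cut is scored by the unit's
own identity to the reference unit combined with a look-ahead at the
following window; ties prefer the nominal period. When the anchor is
absent the phase with the most self-consistent greedy segmentation is
used. Note that for arrays containing an insertion-bearing unit, an
alternative phasing that shifts all unit starts can be equally
self-consistent; unit *counts* are stable under such re-phasings but unit
boundaries need not match a manual segmentation exactly — which is why
census-style checks compare unit totals with a small tolerance.

`align_units()` is an iterated star alignment: units are globally aligned
to the current consensus, merged into a rectangular alignment, and the
consensus is re-called (two rounds). A unit carrying a single-residue
insertion that no other unit shares may instead have that residue
deleted. The decision is a two-way comparison of summed column agreement
with gap characters penalized: keeping the insertion adds a column with
one supporting residue and `n - 1` gaps (net change `2 - n`), deleting
costs nothing (net 0), so with three or more units the deletion wins
whenever it restores agreement. Every such edit is recorded in the
array's `edits` table; at most one deletion per unit is permitted.

`build_consensus()` takes per-column majorities over non-gap residues
(lexicographic tie-break, flagged), drops insertion columns (gap fraction
above 50%) from the consensus string, and — when units carry locus
labels — flags columns whose modal residue is modal in *every*
locus-specific sub-alignment. `logo_matrix()` reports per-column residue
frequencies and information content `log2(A) + sum(f log2 f)` in bits,
deliberately **without** small-sample correction, with gap fractions
tracked separately; letter heights are `f × IC`.

Percent identity (`percent_identity()`) counts identical non-gap column
pairs over columns with at least one residue and rounds half-up, so a
10/13 match prints as 77%.

## Dot plots

`compute_dot_matrix()` sums raw per-position scores over a sliding window
(+5/−4 for DNA with window 50 by default; BLOSUM62 with window 5 for
proteins), computed only where the window fits both sequences — no
padding, which keeps diagonal detection free of edge artifacts.
`detect_diagonals()` reports maximal runs of cells meeting a per-window
score threshold (default 60% of the window maximum) spanning at least
twice the window; reverse-complement runs are found by scanning the first
sequence against the reverse complement of the second and mapping
coordinates back. Requesting reverse detection on proteins is an error
rather than a no-op. Rendering follows the grey-map convention of
classic dot-plot viewers: scores at or below the top bound map to black,
at or above the bottom bound to white (white = highest similarity), with
an optional white–yellow–orange–red–black continuum; the conventional
display settings are 0/35 for DNA repeat plots and 0/245 for protein
plots at full dynamic range.

## Profile search and the duplet rule

`build_profile()` converts a repeat-unit alignment into per-column
log-odds scores in bits against a UniProt-style background. The default
pseudocounts are substitution-matrix based (each observed residue spreads
pseudocount mass onto its BLOSUM62 neighbours, as in PSI-BLAST): profiles
built from two to four rows otherwise over-penalize conservative
substitutions, and a diverged tandem array then matches only one unit at
a time — precisely the failure the duplet search exists to overcome.
Plain background pseudocounts remain available
(`pseudocount_model = "background"`), and the two models agree in the
vanishing-pseudocount limit. Columns that are mostly gaps are dropped and
recorded. Scanning (`scan_profile()`) is local affine-gap alignment
(open 11, extend 1, in half-bit units) against each target, implemented
in compiled code and checked against a quadratic brute-force DP in the
tests. Calibration fits a Gumbel location/scale by moments to the maximum
scores over at least 50 null sequences (length- and composition-preserving
shuffles when templates are given, background draws otherwise);
`E = db_size × P(S ≥ s)`. `iterate_search()` scans, includes hits at or
below the E-value threshold (1.8 by default), realigns included regions
to the profile consensus, rebuilds, and stops at convergence or
`max_iter`, returning all per-iteration hit tables for audit.

`duplet_rule_experiment()` operationalizes the duplet rule at desk scale.
Per replicate: a profile is built from four units at 20% divergence from
the consensus; the true target is a distant homolog whose repeat array
descends from an ancestor unit with exactly 6 of 13 positions substituted
(about 54% identity — the divergence range where single units become
marginal) expanded into eight nearly identical copies, embedded in random
flanks; the database adds ten generic-repeat decoys — tandem
low-complexity proteins and myosin-like heptad textures — of 2000
residues, myosin-scale. The ancestor is placed at a *fixed* distance
rather than by i.i.d. coin flips so that replicates probe ranking
behaviour, not the lottery of whether the homolog retained any repeat
signal at all. Under these conditions the two-unit profile ranks the true
homolog first in every replicate while the single-unit profile is
overtaken by decoys in some — the qualitative claim the module makes.

## Exon reconstruction

`translated_hsp_search()` aligns the protein query locally against all
six translated frames (BLOSUM62, gap open 11 / extend 1), with no
low-complexity masking and a deliberately permissive score floor so
repetitive queries report all their overlapping matches. Alignments are
decomposed into HSPs by splitting at gap runs longer than five columns
(intron-scale jumps) and each segment is trimmed to its maximal-scoring
sub-block — segments from masked re-searches are not otherwise
guaranteed to be locally maximal and can carry net-negative junk flanks.

`chain_exons()` runs a weighted DP over HSPs collinear in query and
genome on one strand. Because local alignments overrun true exon ends by
chance matches in intronic translation, consecutive HSPs may overlap in
the query; the overlap is penalized at the lower score density of the
two HSPs (the overrun causing it is low-density junk), each link must
contribute at least one fresh query residue, and the apparent genomic
gap may undershoot the minimum intron length by three nucleotides per
overlapping residue. The exhaustive-subset oracle in the tests applies
the same rules.

`refine_boundaries()` then commits to canonical splice sites only: for
each junction, donor positions (intron starting `GT`) and acceptor
positions (intron ending `AG`) are enumerated within ±15 nt of the HSP
ends — widened by 3 nt per residue of query overlap, the measured
overrun — and the pair maximizing the local alignment score of the
translated junction against the query wins, with reading-frame phase
carried across exons. GC-AG and AT-AC junctions are rejected: a junction
with no GT-AG pair in the window is flagged unresolved and keeps its
HSP-derived boundaries. `validate_exon()` reports the three hallmarks of
a functional cassette exon — length divisible by 3, no stop codon in the
phase-consistent reading, GT-AG flanks — and `reconstruct_protein()`
splices and translates a model, failing loudly on frameshifts or internal
stops. `conservation_profile()` provides the windowed percent-identity
track over a global pairwise genomic alignment with intervals classified
against a 75% threshold; inputs are ordered canonically internally so the
track is symmetric in its arguments.

## Phylogenetics

`progressive_msa()` implements the classic progressive contract:
pairwise global alignments give p-distances, a neighbor-joining guide
tree orders profile–profile merges (affine-gap DP over frequency-vector
cross-scores). It is deterministic and its rows ungap to the inputs;
bit-compatibility with any particular aligner is not promised, which is
also why gapped-column counts of published alignments are treated as
alignment-dependent observations rather than targets.

`pdistance_matrix()` uses complete deletion by default — a column with a
gap in any row is excluded globally, matching the convention of building
trees with gapped positions excluded — with pairwise deletion behind a
flag. `nj_tree()` is the canonical agglomeration (via ape), with negative
branch-length estimates clamped to zero (flagged and warned) and
zero-length internal edges collapsed. `bootstrap_support()` resamples
columns with replacement; supports are the percentage of replicate trees
containing each bipartition of the point-estimate tree, and depend only
on the seed and the column count, not on taxon order.
`region_branch_compare()` builds one tree per disjoint column region and
reports per-leaf terminal branch lengths and midpoint-rooted root-to-tip
distances with B:A ratios plus the Robinson–Foulds distance: equal rates
give ratios near 1; a region evolving three times faster gives terminal
ratios concentrated in roughly 2–4, the package's quantitative handle on
"markedly longer branches" for a plastic region.

## The synthetic-data generator

`simulate_locus()` emulates the features the analyses assume and nothing
more: a multi-exon coding locus (default eight exons, 60–195 nt, all
divisible by 3 so every exon is a skippable cassette), one repeat exon of
five 13-residue units at 10% divergence from the canonical consensus,
introns of 60–200 nt that always start `GT` and end `AG`, and optional
duplication clusters of diverged template-exon copies (the
eight-extra-copies configuration is one call away). The protein is
generated first and reverse-translated with uniformly sampled synonymous
codons, so every exon is stop-free by construction and frame-breaking
exon lengths split codons across introns exactly as in real genes.
`simulate_transcripts()` samples cassette exons independently per
transcript, flags frame-breaking exclusion combinations, and applies
EST-style end truncation last. `evolve_two_rate()` applies
Poisson-distributed substitution counts per branch and region along a
known tree. `synthetic_teleost_repeat_set()` reproduces the six-locus
repeat census configuration — per-locus unit counts 6, 13, 7, 5, 8, 6
(45 units in total) at 15% divergence, a well-conserved repeat — as a
synthetic stand-in used where the curated sequence listing is not
redistributed.

Deliberate simplifications: substitutions are uniform over alternative
residues (no rate matrix, no transition/transversion bias), introns are
uniform random with forced flanks (no branch points or splice-site
motifs beyond GT-AG), there is no indel evolution, and codon usage is
uniform over synonymous codons. Passing the recovery tests therefore
shows that the algorithms invert the generative process they were
designed for; it does not certify performance on real genomes, where
splice-site context, repeat-length mutation, and alignment ambiguity are
all harder.

Problem sizes used by the test suite — chosen to exercise every code
path at desk scale — are: 20 simulated loci (about 2 kb each) for
boundary-recovery statistics, 45 units for consensus recovery, 10
replicates for the duplet experiment, 20 seeds × 8 taxa × 300 residues
for the two-rate contrast, and 100-replicate bootstraps where the
conventional choice is 1000.

## Numerical and policy choices

- Coordinates are 0-based half-open internally everywhere; 1-based
  conventions appear only in GFF3 output and in reported alignment
  coordinates.
- Splice flanks are always read on the coding strand, so the GT-AG rule
  is strand-agnostic by construction (the minus-strand case is computed
  via the reverse-complement identity and tested against it).
- Ambiguity characters (`N`, `X`) never count as matches and score zero
  in profile and dot-plot scoring.
- Consensus ties break lexicographically and are flagged rather than
  hidden.
- Percent identity rounds half-up to an integer.
- Gumbel calibration refuses fewer than 50 null sequences (unstable
  moment fits).
- The period-estimator null threshold is the 99th percentile of shuffle
  maxima; the seed is an explicit argument everywhere randomness occurs,
  and generator seeds are required, never defaulted.

## Known limitations

- The exon finder assumes the query protein is (close to) the locus's
  true product; paralogous repeat arrays can attract chains, and all
  candidate chains are exposed rather than adjudicated.
- Boundary refinement commits to GT-AG; true non-canonical junctions are
  reported unresolved by design.
- The progressive aligner targets contract-level correctness, not parity
  with any published aligner's output.
- E-values are calibrated per profile against a configurable null and are
  not comparable across databases or software.
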