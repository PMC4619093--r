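---
title: "Methods: defense-island enrichment, motif conservation and coevolution in the GmrSD family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defense-island enrichment, motif conservation and coevolution in the GmrSD family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmrsdkit)
```

## The biological problem

GmrSD is a modification-dependent (Type IV) restriction enzyme that attacks
phage DNA carrying glucosylated hydroxymethylcytosine. Its two halves — the
GmrS domain (PFAM DUF262, a ParB/Srx-fold module with a conserved DGQQR
motif) and the GmrD domain (DUF1524, a putative HNH endonuclease) — occur
in two genomic configurations: fused in one double-domain protein, or as two
separately encoded single-domain proteins that can form a heterodimeric
system. This dual organisation raises three questions that `gmrsdkit`
operationalises as testable computations:

1. **Architecture and inventory.** Which proteins of a genome are GmrS-only,
   GmrD-only, or double-domain, and which genomes carry a candidate
   heterodimeric pair?
2. **Genomic neighborhood.** Are GmrSD-like genes embedded in *defense
   islands* — regions statistically enriched in restriction–modification,
   mobility and DNA-metabolism domains?
3. **Coevolution.** Do the GmrS and GmrD halves share their evolutionary
   history, as a tanglegram of the two domain trees would suggest?

Because the original analyses depended on database snapshots and external
search servers, the package ships a first-class synthetic-data module: every
statistical claim the package makes is exercised against generated data with
*planted*, known truth.

## Architecture classification and pairing

Domain hits (hmmscan-style rows with envelope coordinates, E-value and model
coverage) are filtered by `accept_domain_hits()` with **strict** thresholds:
E-value `< 0.001` and coverage `> 0.8`. Boundary values are rejected — the
acceptance rule is worded as "below"/"above", and we implement the strict
reading so that a hit exactly at a threshold never drifts in or out of the
family between runs.

`classify_architectures()` maps accepted hits to four classes: `GMRS_ONLY`
(DUF262 without DUF1524), `GMRD_ONLY`, `DOUBLE` (both, canonically DUF262
N-terminal), `OTHER`. Decisions where the design was genuinely open:

* **Multiple hits of one family domain** collapse to a single union-span
  region: an architecture is a set of domain types, not a hit count.
* **Overlapping DUF262/DUF1524 regions** cannot be a genuine fusion; the
  protein is classified by the better-scoring domain and flagged
  (`overlap_flag`) rather than silently resolved.
* **Pairing** (`pair_single_domains()`) emits a merged, double-domain-like
  sequence (S residues then D residues) for exactly the genomes with one
  GmrS-only and one GmrD-only protein. The rule as stated constrains only
  the single-domain counts, so pairing proceeds even when the genome also
  carries double-domain proteins; such pairs carry a `double_present` flag
  so downstream analyses can audit or exclude them. We flag rather than
  guess because the source procedure is silent on this case.

## Alignment merging, conservation, motifs

`merge_alignments()` implements the bookkeeping for combining two family
alignments that share a backbone of identically aligned double-domain
sequences — one extended with GmrS-only members, the other with GmrD-only
members. Columns of each input are classified as *anchor* columns (carrying
at least one backbone residue) or *insertion* columns; the merge interleaves
both inputs' insertion columns around the shared anchors. The result is that
stretches of gaps of equal length are inserted identically into every
backbone sequence — the minimal padding that satisfies the construction.
Two invariants are enforced and property-tested over random merges:
restricting the output to the backbone and deleting all-gap columns
reproduces the backbone portion of *either* input column-for-column, and no
sequence gains or loses a residue. Inputs whose backbone sub-alignments
disagree are rejected with an error naming the problem, not repaired.

`conservation_profile()` reports, per column, the modal non-gap residue and
its frequency **over all sequences** — a gapped row counts against
conservation, because "conserved in more than 95 % of sequences" counts
sequences, not residues present. The `+` mark requires frequency strictly
above the threshold (default 0.95): a column at exactly 19/20 = 0.95 is not
marked. `X` (unknown residue) is never a modal candidate and never matches a
motif element — an unknown residue is not evidence.

The motif engine (`compile_motif()` / `scan_motif()`) uses the field's
compact notation: fixed residues, `(I/L/V)`-style alternative sets, and a
lower-case `x` wildcard over the 20 standard amino acids. The five family
signature motifs are built in (`gmrsd_motifs()`): the GmrS DGQQR-core motif
`(I/V)(I/V)DGQQRLTT(I/L/V)xLL` and the GmrD motifs `(I/L/V)(E/D)H(I/L/V)xPQ`,
`L(G/A)NLxLLxxxN`, `NxxFxxKK`, plus the weakly conserved 21-residue
tryptophan-flanked motif, scanned by the same engine with no special-casing.
All overlapping matches are reported; the scanner is tested for exact
agreement with a brute-force matcher on random strings, and
`expected_motif_matches()` supplies the closed-form chance-match expectation
used to bound false positives on shuffled controls.

## Neighborhood (defense-island) enrichment

The neighborhood of a focal gene is the `k` ORFs upstream and `k`
downstream on the same contig (`window_k = 10` by default, the conventional
defense-island window); the focal ORF itself is excluded, and windows cut by
a contig end are flagged as truncated. Domain annotation of neighborhood and
background proteins keeps only **top-scoring, non-overlapping** hits below
the neighborhood E-value cut (default `1e-3`): hits are sorted by ascending
E-value and accepted greedily unless they overlap an already accepted hit,
so every rejected hit demonstrably lost to a better or equal hit.

The statistic is a difference of proportions per domain: `x1/n1 - x2/n2`,
where the denominators are total accepted **domain instances** (not
proteins) in the neighborhood set and in the background. The confidence
interval is the continuity-corrected Wald interval of the standard
equal-proportions test (numerically identical to `stats::prop.test` with
`correct = TRUE`; verified to `1e-9` against it). With `M` domains tested
simultaneously, each interval is computed at the Bonferroni-adjusted
individual level `1 - alpha/M`, and a domain is called **enriched** iff its
interval lies entirely above zero. Results are ranked by the lower
confidence bound, most enriched first by default (`rank_direction =
"ascending"` gives the literal ascending order).

Further choices, each configurable:

* Neighbor proteins shared by overlapping windows are counted once
  (de-duplicated by protein id) — identical evidence should not be counted
  twice.
* The background is every protein of the genomes that contain at least one
  focal gene, neighborhoods included (`background = "exclude_neighborhood"`
  excludes them).
* Domains absent from the background (`x2 = 0`) are retained and their CI
  computed normally.

### Numerical behavior of the interval

The continuity correction makes the interval deliberately conservative. At
`p1 = p2 = 0.1` and `n1 = n2 = 500` its exact coverage (computable by
enumerating the binomial grid) is 0.9608 rather than 0.95; the uncorrected
Wald interval would sit at 0.9495. We keep the corrected interval because it
is the reference behavior of the standard test and it errs on the safe side
for enrichment calls; the cost is a familywise error rate well *below* the
nominal `alpha` (measured ≈ 0 at `M = 200` in the acceptance script) and
slightly reduced power, which the planted-signal study shows is ample at
realistic effect sizes.

## Coevolution pipeline

Trees arrive as Newick with SH-like split supports in the internal node
labels; if any support exceeds 1 the whole tree is treated as using the
percentage dialect and rescaled by 1/100. `collapse_low_support()` contracts
every internal split with support strictly below the threshold (default 0.8:
0.79 collapses, 0.80 survives) into a polytomy; splits with missing support
are collapsed conservatively and logged. Collapsed edges donate their length
to their child edges, preserving root-to-tip distances, and the operation is
idempotent. `prune_unpaired()` removes leaves without a counterpart in the
GmrS↔GmrD association and suppresses the unary nodes left behind.

`congruence()` compares the two trees as unrooted split sets after
relabeling leaves through the association: the Robinson–Foulds distance is
the number of non-trivial bipartitions present in exactly one tree, and the
normalized form divides by the total split count of both trees (defined as 0
for two stars). Polytomies are compared as-is — collapsing is part of the
procedure, and resolving polytomies would inject information the data do not
contain. The split extraction is implemented directly on the edge matrix and
cross-checked in the tests against an independent RF implementation
(`phangorn::RF.dist`).

## What the simulators emulate — and what they do not

`simulate_genomes()` produces ordered-ORF annotations in which every
non-focal protein draws its domain from a background frequency vector,
except within `±window_k` ORFs of a planted focal (double-domain) gene,
where the *odds* of each enriched domain are multiplied by its multiplier —
multiplying the weight and renormalizing is exactly an odds multiplication
for the enriched domain against the rest. Focal genes are placed uniformly
with minimum separation `2k + 1`, so windows never overlap and calibration
replicates are independent. One domain hit per protein is the default
(denominators stay interpretable); a 0–3 hit mode exercises multi-domain
counting.

`simulate_family()` draws the S- and D-region lengths and the motif offsets
**once per family**, so members of one architecture class are
length-identical and planted coordinates are homologous by construction —
the family aligns trivially (`family_msa()`), and truth coordinates double
as alignment columns. At each motif column a consensus residue is kept with
probability `conservation_level`, otherwise the residue is redrawn uniformly
from all 20 amino acids; the expected consensus frequency is therefore
`c + (1 - c)/20`, the closed form the tests check at `c = 0.5`, and at
`c = 1` every motif is exact by construction. Default region lengths
(220–320 residues) match the scale of the real DUF262/DUF1524 conserved
regions.

`simulate_tree_pair()` derives the GmrD topology from the GmrS topology by
`n_spr` subtree-prune-regraft moves, each drawn uniformly over the valid
(prune-edge, regraft-edge) pairs — the standard discordance model. The move
is implemented as explicit edge surgery in the package (uniformity over
pairs and robustness on rooted binary trees are contract requirements) and
validated on hundreds of random trees. Supports are drawn from a
user-supplied sampler (default uniform on [0, 1]).

None of the simulators model nucleotide sequences, codon structure,
selection, indel evolution within motifs, horizontal transfer of genomic
context, or correlated domain co-occurrence. Passing the planted-truth tests
therefore demonstrates that the *statistical machinery* is calibrated and
the *bookkeeping* is exact — not that real annotations are free of the
systematic errors (mis-called ORF boundaries, split genes, database bias)
that real comparative-genomics data carry.

## Problem sizes and determinism

The test suite and the acceptance script run the studies at these sizes,
chosen to give stable estimates while keeping a laptop-scale footprint:
200+ tuples for the CI-versus-reference check; 10,000 Monte-Carlo draws for
coverage; 1,000 null replicates at `M = 200` for the familywise error rate;
20 independent simulations of 100 genomes × 200 ORFs at `M = 50` with one
domain at 5× odds for planted-signal recovery; 1,000 random hit sets for
the greedy-selection contract; 100 random alignment merges; 50 seeds ×
`n_spr ∈ {0, 1, 3}` on 16-leaf trees for the discordance study. Every
random quantity flows from an explicit integer seed; identical seeds give
byte-identical outputs, which the pipeline manifest (content hashes per
stage output) makes checkable end to end.

## Known limitations

* The enrichment model treats domain draws as independent across proteins;
  real defense islands have correlated gene content, so real-data intervals
  are anti-conservative to an unknown degree.
* The merge operation requires the two input alignments to agree on the
  backbone column structure (as produced by profile-add alignment work);
  it merges bookkeeping, it does not re-align.
* Conservation is measured by modal-residue frequency only; no
  substitution-matrix weighting.
* RF congruence is a coarse topological statistic: it counts split
  disagreements and is blind to branch lengths and to *which* clades moved.
* The support-collapse step assigns collapsed edge lengths to child edges;
  other conventions (discarding them) change derived branch lengths but not
  topology.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_genomes(genome_sim_spec(
  n_genomes = 100, domain_vocab_size = 50,
  enriched_domains = c(DOM013 = 5), seed = 1
))
res <- neighborhood_enrichment(sim$annotation, sim$hits,
                               sim$truth$focal$protein_id, k = 10)
head(tidy(res))
glance(res)
autoplot(res)
```

The full end-to-end run, including the family and coevolution stages and a
written manifest, is `run_pipeline(pipeline_config(seed = 1), "run_dir")`,
summarized with `summarize_run("run_dir")`.
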