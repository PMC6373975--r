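---
title: "Detecting horizontal transposable element transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transposable element transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httscan)
```

## The inference problem

A transposable element (TE) family found in two host species can be there
for two reasons: it was present in their common ancestor and inherited
vertically, or it crossed between lineages horizontally. Under vertical
inheritance the element has been diverging for as long as the hosts
themselves, so its synonymous divergence (dS) — approximately neutral and
clock-like — should resemble the genome-wide dS between the two species.
A TE dS far below that expectation betrays a horizontal transfer (HTT).

`httscan` operationalizes this in four stages:

1. **Family clustering.** Sequences of one superfamily are single-linkage
   clustered: an edge joins two sequences when a pairwise hit covers at
   least 80% of the shorter sequence at ≥ 80% identity. Within each
   family, species represented by fewer than two specimens are discarded;
   requiring two independent specimens is the contamination control.
2. **Divergence.** Within a family, near-identical copies of the same
   specimen (≥ 99% identity on shared columns) are collapsed to the
   longest representative; then for every species pair the minimum
   Nei–Gojobori dS over all cross-species sequence pairs is retained.
3. **Conservative outlier test.** Each species pair is matched to the
   oldest tree node carrying an empirical housekeeping-gene dS
   distribution *inside* the subtree of the pair's MRCA. Vertical
   inheritance is rejected when the TE dS is strictly below the lower 5%
   order statistic of that distribution.
4. **Event counting and the permutation null.** Minimal event counts and
   random event-to-species assignments ("scenarios") turn pairwise
   verdicts into per-species and per-order transfer counts, which are
   compared with a constrained relabeling null to flag hotspot taxa.

## Why the reference matching is conservative

The matched node is constrained to lie inside the MRCA subtree of the
species pair, so its age — and hence the location of its dS null — can
only be less than or equal to the pair's true divergence. A TE flagged
horizontal is therefore below the 5% quantile of a distribution that, if
anything, understates the vertical expectation. Pairs whose MRCA subtree
contains no reference node are *untestable* and excluded rather than
guessed at; the same pairs are forbidden to the null model, which would
otherwise create links the real analysis could never have observed.

Two further conventions push in the conservative direction:

* **Quantile convention.** `quantile05()` returns the smallest sample
  value with at least 5% of the sample at or below it (a lower order
  statistic, no interpolation). Any interpolated convention would sit at
  or above it, so this choice can only reduce horizontal calls. It is also
  trivially oracle-checkable by sorting.
* **Undefined dS.** NG86 is undefined at saturation (`pS ≥ 3/4`) or when
  fewer than 10 synonymous sites are comparable. Saturated divergence is
  evidence *for* vertical inheritance, so undefined estimates yield an
  `untestable` verdict, never a horizontal one, and are excluded from the
  per-pair minimum rather than treated as infinite-but-present.

Where several eligible nodes tie at maximal age, nodes on the path between
the two species are preferred, then the smallest node number — a
deterministic tie-break. Whether the reference node must lie on that path
or merely inside the MRCA subtree is genuinely open; the subtree rule with
on-path preference is the design adopted here, and it is the weaker
(hence more often testable) of the two.

No multiple-testing correction is applied across the many families in
which one species pair may be tested; each (family, pair) is an
independent report, and the calibration suite measures the realized
false-positive rate directly.

## The NG86 estimator

The estimator is deliberately the classical minimal-assumption one:
per-codon synonymous site fractions averaged over both sequences,
synonymous/nonsynonymous differences counted along all orderings of the
single-base steps between differing codons, and the Jukes–Cantor
correction `dS = -(3/4)·ln(1 - (4/3)·pS)`. Mutations creating a stop codon
count as nonsynonymous when tallying sites; mutational orderings passing
through a stop are excluded (all orderings are used if none avoids one).
Codon columns with a gap, ambiguity or stop in either row are skipped.
No transition/transversion weighting, codon frequencies, or likelihood
machinery (GY94/YN00) is used: the estimator must be independently
checkable by brute force, and it is — the test suite carries a naive
reimplementation plus a hand-computed fixture. The estimator sits behind a
single function (`ds_ng86()`), so a different dS method can be swapped in
without touching callers.

The pipeline accepts externally aligned families; the synthetic generator
emits gapless frame-consistent families, so no aligner is bundled.

## Event counting and scenarios

For a family with horizontal-verdict pairs, one event is counted at every
node of the family's host subtree whose descending clades are connected by
at least one such pair (`minimal_events()`). On binary trees this equals
counting distinct MRCAs of the verdict pairs — the property test suite
verifies the equivalence against that independent oracle. Events are
counted per family and summed within a superfamily: two families crossing
the same node are two transfers.

A *scenario* (`sample_scenarios()`) draws, for every event, one crossing
pair uniformly at random and credits both endpoint species. Per-species
means over 1000 scenarios are the reported "transfers per species";
per-order counts are sums over member species. Endpoint counting (two
endpoints per event) rather than distinct-species counting is the adopted
interpretation — an order can thus accumulate more endpoint counts than
there are events in total — but the distinct-species count per order is
also emitted (`species_involved_means`) for comparison. Inside the null
model the scenario mean is replaced by its exact expectation (each
crossing edge contributes 1/k to its endpoints), which is the infinite-
scenario limit and removes one layer of Monte-Carlo noise at no cost.

## The constrained permutation null

`permute_network()` draws a bijection from the observed network's species
onto a uniformly chosen same-size subset of the superfamily's carriers
(species with at least one family of that superfamily — species not
carrying the element can never appear). This preserves the degree multiset
and the network structure exactly. Draws are rejected while any edge lands
on an untestable pair; after 1000 failed attempts the draw is instead
*repaired* (`repair_forbidden()`): each forbidden edge is replaced,
sequentially with updated connectivity, by a uniform draw among network
node pairs that are neither forbidden nor already connected. The cap
automates the switch between the rejection regime (sparse networks) and
the repair regime (dense networks) without a user-facing knob.

Because real HT networks are phylogenetically clustered, random
relabelings scatter edges and need *more* events than the observed
network — a positive bias verified by a property test. Each simulation's
per-order counts are therefore rescaled multiplicatively so its total
event count equals the observed total. Rescaling per-order counts (rather
than resampling events) preserves within-simulation proportions; the
choice is recorded in the output metadata. After rescaling, per-order
means and 2.5%/97.5% quantiles over simulations form the envelope; an
observed count above the upper quantile is flagged as an excess, with no
further p-value machinery.

One master seed spawns one child seed per simulation, so simulation *i*
depends only on child seed *i* and results are independent of execution
order or thread count.

`distance_profile()` bins events by the age of their node (equivalently,
the MRCA age of any assigned pair) into 25-My windows and reports
observed/expected ratios against the simulation means; the logistic
regression sometimes drawn through such ratios is out of scope here.

## The synthetic-data generator

The generator is first-class, tested code; its defaults describe the
survey design this pipeline targets: 460 species in 19 orders (the first
19 labels are real arthropod order names, assigned largest-first so
Lepidoptera is the largest order), two specimens per species, 163
full-genome reference species, a 500-My chronogram, and the Copia, Jockey
and Mariner superfamilies. Where the survey design fixes no value, the
defaults are one-time choices of realistic magnitudes: a synonymous rate
of 0.003 substitutions/site/My (a typical insect nuclear clock), a
reference-panel coefficient of variation of 0.3 (housekeeping dS sets are
substantially overdispersed around the clock), presence probability 0.3
within a family's anchor clade (matching the 28–55% per-superfamily
prevalence range of such surveys), amplicon length 150 codons, and 1000
panel draws per node.

Mechanically:

* **Tree.** Pure-birth (Yule) branching conditioned on the species count
  (`ape::rphylo`), rescaled to the target root age — simple, reproducible,
  age-controllable. Orders are carved by repeatedly splitting the largest
  clade, so they are monophyletic with naturally unequal sizes.
* **Reference panels.** Gamma samples parameterized by mean
  `2·rate·node age` and the configured CV: positive support and a
  heavier-than-normal tail, as in empirical dS sets. Gamma is a stand-in
  shape, not a claim about the true distribution of housekeeping dS.
* **Sequences.** One random in-frame ancestral sequence per family built
  from codons whose third position is four-fold degenerate; divergence is
  introduced only at third positions under Jukes–Cantor, so every change
  is synonymous and realized NG86 dS tracks the per-branch targets without
  a full substitution simulator. Nonsynonymous evolution, indels,
  sequencing error profiles, chimeras and within-genome copy-number
  dynamics are deliberately not modeled — passing tests certify the
  statistics of the pipeline, not robustness to alignment error or
  assembly artifacts.
* **Planted transfers.** Each planted event gets its own family linking
  two species drawn with hotspot weighting (`hotspot_multiplier` on
  species of the hotspot order); the recipient sequence is regenerated
  from the donor at a dS drawn uniformly in `[0, 0.2 × genomic dS]`.
  `n_planted_ht` counts events *per superfamily*, so multi-superfamily
  hotspot analyses are planted symmetrically. Events whose species pair
  has no reference node in its MRCA subtree are recorded as untestable by
  design in the truth table, not errors.
* **Hit table.** Exact global alignment (match +1, mismatch −1, gap −2)
  via `Biostrings::pairwiseAlignment`, reported in BLAST outfmt-6 field
  order with qlen/slen appended. The generator controls divergence, so a
  global aligner stands in for a local search; the 80% overlap threshold
  is applied to the alignment-length field as-is (gap columns included).

All randomness flows from the single configuration seed through fixed
per-stage stream offsets, so regenerating any stage reproduces its output
byte for byte. Seeds are echoed as `#` comments in every TSV and in the
run manifest (FASTA has no comment syntax; its seed lives in the
manifest).

## Problem sizes and test design

The validation suites run at deliberately modest sizes chosen once as
adequate for their statistical purpose: calibration uses a 40-species
all-reference tree with 120 vertical families (≥ 1000 testable pairs, so
the binomial bound `5% + 3·SE` is tight enough to be meaningful); hotspot
recovery uses 60 species, 40 planted events per superfamily and 200 null
simulations; oracle sweeps use 200 random trees of up to 8 tips, where
brute force is exact. The published-scale survey (460 species, thousands
of families) is summarized through the same `summarize_htt()` arithmetic
but not re-simulated at full size.

## Command-line interface

The package surface is functional; a thin wrapper
(`inst/scripts/htt-pipeline.R`) exposes `simulate`, `run-all` and `report`
subcommands over a flat YAML configuration with flag overrides. Every
stage is equally reachable as an exported, file-driven function
(`read_*`/`write_*` pairs for every artifact), which is what the wrapper
composes; per-stage subcommands would duplicate that surface without
adding capability.

## Known limitations

* The dS estimator is NG86; methods differing in multiple-hit handling
  (e.g. codon-model ML) will shift absolute dS for divergent pairs, and
  with them the outlier threshold crossing for borderline cases.
* Direction of transfer, dating of individual events and ancestral-state
  reconstruction are out of scope; events are localized to nodes only.
* The occurrence filter assumes specimen identity is reliable; it guards
  against cross-specimen contamination, not misassigned species labels.
* The null model conditions on the observed network topology; it tests
  *where* transfers land, not *how many* there are.
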