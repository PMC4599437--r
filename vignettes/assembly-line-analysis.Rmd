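---
title: "Assembly-line analysis of modular NRPS/PKS gene clusters: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-line analysis of modular NRPS/PKS gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgclineage)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the places where the design was genuinely
open. The worked data set throughout is the packaged inventory of modular
NRPS and type-I PKS gene clusters of the five *Herbidospora* type strains
(`bgc_example_table()`).

## The model: assembly lines, modules, and collinearity

NRPSs and type-I PKSs are megasynthases whose catalytic domains are
organized into modules, each performing one cycle of chain elongation: an
NRPS module minimally carries condensation (C), adenylation (A) and
thiolation (T) domains; a PKS module carries ketosynthase (KS),
acyltransferase (AT) and acyl carrier protein (ACP). The assembly-line rule
asserts collinearity between module order and product structure, which is
what makes backbone prediction from annotation possible at all. The core
assumptions inherited from that rule are worth stating:

* every counted module contributes exactly one building block, in order;
* the A/AT substrate annotation (here taken as given, from upstream
  substrate-prediction tools) determines the block's identity;
* β-keto processing is local to the module: no KR → ketone, KR →
  hydroxyl, KR+DH → C=C, KR+DH+ER → fully reduced methylene;
* the loading (first) module contributes the starter unit and its
  reduction domains are not expressed in the product.

None of these hold for trans-AT PKSs, iterative PKSs, or heavily tailored
products; see *Limitations*.

## The domain-string notation and its parser

Inventories are exchanged as one string per gene: domains separated by
`/`, module groups by `-`, substrate subscripts on A/AT (`A_ser`; `A_(lys)`
for a tentative call; `AT_m`/`AT_e` for methylmalonyl/ethylmalonyl with
bare `AT` meaning malonyl; `AT_e(m)` and `AT_(m,e)` for ambiguous
alternative sets; `AT_?` for undetermined), `(KS)` for a tentative domain
call, and `...` for a truncated (partially sequenced) gene end. The
substrate vocabulary is closed — the 20 proteinogenic amino acids plus
ornithine, and the three extender-CoA units — because the worked inventory
uses only these; anything else is a parse error naming the offending symbol
and position, which catches transcription noise early.

Parsing records the verbatim subscript on each token, so
`format_domain_string()` round-trips every inventory row byte-identically
(a property the test suite asserts for all 214 rows). The `-` separators
are kept as soft module *hints* only: real module boundaries are recomputed
by the segmentation grammar below, because genes are routinely split
mid-module.

## Gene ordering and the segmentation grammar

The table order of genes within a cluster is treated as a hint. Two
anchors override it: the gene whose first module is a loading module
(CoL-initiated, or an A/AT not preceded by C/KS within the gene) is placed
first, and the gene carrying TE is placed last. When one gene is both (an
`A/T-TE` didomain gene), TE placement wins, because a termination domain
anywhere but the end would violate the module invariants. Two candidates
for either role trigger a warning and leave the input order untouched.

The concatenated token stream is then segmented:

* a new module opens immediately before every C and every KS;
* an A/AT that *begins a gene* opens a new module **unless** it continues
  an open C/KS-initiated module that still lacks its A/AT — this is the
  cross-gene split rule that stitches, e.g., a gene-terminal bare `C` to a
  following `A_val/T` gene;
* a leading orphan T/ACP with no open module attaches to the preceding
  module if one exists, otherwise it is discarded with a warning;
* TE attaches to the current module;
* a module consisting solely of C/KS merges forward if tokens follow,
  otherwise it is left `incomplete` and not counted.

This grammar was chosen as the smallest rule set that reproduces every
worked module count in the source analysis (35 modules for the largest PKS
cluster, 22 for the largest NRPS, 1 PKS + 13 NRPS modules for the largest
hybrid, 9 modules over 7 genes for the conserved polyene cluster); the
original analysis never states its grammar. A module truncated by a
sequencing gap but already carrying its KS/AT core *is* counted, which
gives partially sequenced clusters "at least N" semantics (`lower_bound`
flag) matching how such counts are reported. Single-domain genes are
excluded before segmentation as atypical — an advisory finding, logged, not
an error. Iterative enediyne-type PKSs, recognized by the PksE signature of
a KR–DH pair directly after an ACP, are classified but not segmented: they
do not elongate collinearly.

One worked inconsistency is deliberately not special-cased: the narrative
for one shared NRPS cluster says "five modules" while its own domain
strings and hexapeptide product imply six; the implementation follows the
domain strings.

## Backbone prediction choices

* **DH or ER without KR is non-functional** (ketone). This reproduces the
  printed "2 double bonds and one hydroxyl" for the hexaketide cluster
  whose second module is `KS/AT/DH/ACP`.
* **The first module of a PKS assembly is the starter even when
  KS-initiated**, and its reduction domains are silent; this is what makes
  the nonaketide cluster come out at "3 double bonds and 5 hydroxyls".
* **Ambiguous AT annotations propagate** as alternative α-substituent sets
  (`methyl-or-ethyl`, `H-or-methyl` for a tentative call); the SMILES
  renderer refuses to pick silently and requires an explicit policy flag.
* **Epimerization sets a configuration flag but never changes the printed
  residue**, matching the inventory's product column; the D- prefix appears
  only in the explicit linear notation.
* Clusters with a single module, and enediyne-class clusters, return a
  backbone marked not-predictable rather than a guess.
* `chain_carbons` is two per polyketide module *including* the starter
  (a heptaketide is a C14 chain).

## Ortholog grouping

Two clusters from different strains are linked when they share at least one
gene pair with the same closest-homolog accession (version suffixes
stripped) **and** the mean domain-organization similarity over best-matched
gene pairs is at least the threshold; groups are connected components of
this relation. Similarity is `1 − edit distance / max length` over the
domain-kind sequences, substrates ignored. The threshold default of
**0.8** operationalizes "identical or almost the same" — the source gives
no number; at 0.8 a one-domain difference in a five-domain gene still
links, while the three-domain stand-alone genes of distinct paralog
families do not.

One genuinely open decision: the inventory contains a paralog family of
stand-alone `KS/AT_?/DH/ACP` genes with *identical* organization and the
*same* closest homolog, curated as two distinct pathways (one in three
strains, one strain-specific) in the source's row alignment — presumably on
genomic-context grounds that the table does not carry. The stated criterion
alone cannot separate them (it yields 31 groups, merging the pair). Since
cross-strain pathway ids in the packaged table encode that manual row
alignment, `group_orthologs(respect_curated_ids = TRUE)` (the default)
treats differing curated ids as a veto on a link — ids never *create*
links, so within-pathway linkage remains fully algorithmic and a broken
pathway would still fall apart into several groups. With
`respect_curated_ids = FALSE` you get the pure criterion; both behaviours
are asserted in the tests.

## Phylogenetics

Distances are JC69 by default (`-(3/4) ln(1 − 4p/3)`) with pairwise
deletion of gap/ambiguous sites; p-distance is available. The source names
only "neighbor joining", so the model choice is ours; JC69 is the minimal
standard correction and at the within-genus divergences involved the choice
is immaterial to topology. Neighbor joining is the standard Saitou–Nei
agglomeration with two numerical policies: ties in the Q-criterion are
broken by the first minimal pair in input order (determinism), and negative
branch lengths are clamped to zero with a warning (common convention).
Bootstrap resamples columns with replacement under a caller-supplied seed
and scores the bipartitions of the full-data tree (majority-rule consensus
is deliberately not the default: supports annotate the reported tree).
Robinson–Foulds distance is the symmetric difference of non-trivial
bipartition sets of the unrooted trees.

The packaged species tree is *reconstructed from the published narrative*
(the original figure is not machine-readable): topology
`(mongoliensis,(cretacea,(yilanensis,(daliensis,sakaeratensis))))` with an
*Acrocarpospora* outgroup, nominal branch lengths. The filename flags the
provenance. Every gain/loss statement in the narrative is consistent with
exactly this topology, which is the check the tests perform.

## Gain/loss reconstruction

Dollo parsimony — exactly one gain, any number of subsequent losses — is
the model, because the source's narrative assigns each pathway a single
acquisition; a probabilistic gain/loss model is out of scope. The gain sits
on the branch *above* the MRCA of the carriers ("just before evolution to
X" = the stem of X), losses on the stems of the maximal all-absent subtrees
below it; this solution is unique and minimal, which the test suite checks
against a brute-force enumeration oracle over all rooted five-leaf
topologies and all presence rows (six-leaf topologies are sampled, for
runtime). The outgroup is pruned before mapping: there is no cluster data
for it. Group classification adds one class beyond
ancestral/recent/gain-then-loss: a lossless gain on an internal branch is
reported as `clade-gain` (the three-strain clade acquisition pattern),
which the three-class scheme cannot express.

## What the simulators emulate — and what they do not

`simulate_inventory()` emulates the *structure* of the real table: planted
ortholog groups with universal/partial/specific sharing at roughly the
observed proportions, module plans with loading and TE anchors, genes
splitting modules at and across module boundaries (including gene-terminal
bare C/KS), ~40 % unpredicted A-domain substrates, and within-group
perturbation limited to single tailoring-domain toggles so that planted
similarity stays above the grouping threshold. It does *not* emulate:
partial sequencing, enediyne clusters, paralog families sharing closest
homologs, or biased substrate composition. A green recovery test therefore
establishes that segmentation and grouping invert the generator exactly —
not that they are robust to curation noise; that robustness is exercised
separately by the real inventory, which contains all of the above.

`simulate_presence_evolution()` draws the gain branch uniformly and loses
independently per descendant branch; it makes no attempt at rate realism
and is used only for parsimony-bound and gain-recovery properties.
`simulate_alignment()` is exact site-independent JC69. All generators are
pure functions of `(parameters, seed)` and restore the caller's RNG state.

## Numerical and degenerate-input policies

* Empty domain string, unknown symbol, substrate on a non-A/AT domain:
  parse errors with position information.
* Empty inventory file with a header: zero inventories, not an error.
* A strain contributing two clusters to one ortholog component: an error
  naming the clusters (it indicates an over-permissive threshold).
* JC69 at p ≥ 0.75, zero comparable sites for a pair, fewer than three
  taxa for NJ, all-absent presence rows, leaf-set mismatches in RF:
  errors naming the offending pair/row.
* Bootstrap replicates whose resampled distances are undefined are dropped
  from the denominator with a warning.

## Limitations

* Domain calls and substrate predictions are *inputs*; no HMM detection,
  no homology search execution, and no GenBank parsing are performed.
* No trans-AT PKSs, docking-domain logic, tailoring reactions,
  macrocyclization or stereochemistry beyond the D/L flag.
* Backbones are reported thioester-bound as assembled; whether TE release
  hydrolyzes or cyclizes is not modelled.
* The ortholog criterion sees only what the table carries; paralogy that
  manual curation resolved from genomic context needs the curated ids.
* The packaged species tree is a narrative reconstruction, not an
  alignment product; analyses needing real branch lengths should supply
  their own tree or alignment.
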