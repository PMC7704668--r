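---
title: "Models and methods in mitohap"
author: "mitohap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitohap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitohap implements the computational chain used in matrilineal population
genetics of livestock mitogenomes: reference-relative variant nomenclature,
motif-based haplogroup classification, mutation-annotated parsimony trees,
strict-clock maximum-likelihood node dating on codon-partitioned
protein-coding genes, and Bayesian skyline demographic inference from
serially sampled control-region sequences. A coalescent simulator generates
every synthetic input the validation suite needs, with truth records, so
the whole chain is testable without any external data. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the simulation-based validation does and does
not demonstrate.

## Coordinates, variant nomenclature, and alignment

All coordinates are 1-based nucleotide positions (np) on the bovine
reference mitogenome (BRS, 16,338 bp). The mitogenome is circular;
internally it is linearised at np 1, which is safe for the analyses here
because the 410-bp control-region window (nps 15,903–16,312) is contiguous
in BRS numbering.

Variants are expressed in the field's standard mtDNA notation relative to
the reference: a bare np is a transition (`16247`), a base suffix marks a
transversion to that base (`9C`), `+` an insertion anchored after the
preceding np (`15+AC`), `d` a deletion (`15d`, `15-17d` for a multi-base
event), and `h` a heteroplasmic position. `parse_variant()` and
`format_variant()` are exact inverses on this label language.

Samples are aligned to the reference with a banded global aligner with
affine gap costs (match +1, mismatch −1, a gap of length *k* costs 4 + *k*).
The band (default ±64, widened automatically) is appropriate because
mitogenomes of one species are ≥99% identical to their reference; the
aligner refuses fragments shorter than half the reference. Because several
gap placements inside a repeat run have the same score, gaps are
canonicalised by **3′ justification**: every gap run is shifted to the
highest-numbered score-equivalent position, matching common mtDNA
nomenclature practice, so a deletion in the run `CCC` at nps 3–5 is always
written `5d`. This convention is pinned by tests that enumerate all
score-equivalent placements. A *k*-base indel is reported as a single
variant at its first affected np, so an indel counts as one variant site in
site summaries.

Heteroplasmies (IUPAC ambiguity codes) are recorded with the `h` suffix but
are excluded from parsimony characters downstream (treated as missing),
since a heteroplasmy is not a fixed state. `N` is missing data, not a
variant.

## Haplogroup classification

The nomenclature is a rooted tree of motifs: each haplogroup has a parent
and the set of diagnostic variants on the branch leading to it. A profile
is scored at every node by `matched − missing` over the node's *cumulative*
(root-path) motif; the best-scoring deepest node wins, with ties broken
toward the shallower node and then lexically. This scoring is the package's
own design (published haplogroup calls are typically made by inspection):
it is robust to private mutations, and a back mutation at a diagnostic site
simply counts as one missing match rather than as evidence against the
clade. The shipped table encodes only what is published for the P branch of
the cattle nomenclature — P1a is defined by six transitions (nps 2171,
5681, 11,468, 12,738, 15,714, 16,247) — with other branches present as
provisional, empty-motif nodes that users can complete; the root is named
T3 because the reference mitogenome is a T3 sequence, so an empty profile
classifies as T3. In control-region mode both the profile and the motifs
are restricted to nps 15,903–16,312, which reproduces control-region-only
assignment (P1a from the single transition at np 16,247).

Frequencies are computed with exact arithmetic and rounded half-up to one
decimal (83/181 → 45.9%).

## Mutation-annotated parsimony trees

Identical profiles are collapsed into haplotypes first. The tree search is
exact — branch and bound over unrooted topologies with the Fitch count of
the partial tree as the bound — up to 12 haplotypes, and NNI hill-climbing
from a neighbour-joining start (Hamming distances, seeded random-addition
restarts) beyond that. Characters are presence/absence of each variant;
heteroplasmic positions are missing. The exhaustive enumerator is kept as
an independent validation oracle and the suite checks the search attains
its optimum on hundreds of random instances.

Mutations are placed on branches by the classical Fitch refinement: the
root prefers the ancestral (variant-absent) state, and each node takes its
parent's state whenever that state is in its first-pass set. For
homoplasy-free characters this places shared mutations exactly on clade
stems; where several most-parsimonious placements exist the choice is
deterministic and the affected mutations are flagged `ambiguous` —
reconstruction of recurrent control-region mutations is genuinely ambiguous
in a number of cases, and the flag makes that visible rather than hiding
it. Gains appearing on two or more branches are flagged recurrent; losses
below a gain are back mutations, printed with the `@` prefix. Internal
branches carrying no mutations are collapsed into polytomies by default, so
a star-like expansion appears as the single multifurcating node it is; the
fully binary search tree is retained in `$tree_binary`, whose Fitch length
always equals the sum of branch mutation counts.

Model selection for the ML-mode claim fits {JC, K80, HKY} × {plain, +I,
+Γ4} on a fixed topology, re-optimising branch lengths per model
(L-BFGS-B on log lengths) with HKY's base frequencies free parameters
(softmax-parameterised, counted as 3 in *k*), and ranks by
BIC = −2 lnL + *k* ln(n sites) with branch lengths counted in *k*. Each
model is warm-started from its nested simpler neighbour - HKY starts at
K80's uniform frequencies - so the likelihood chain JC ≤ K80 ≤ HKY holds
exactly at the optima; +I and +Γ reach their base model only at a parameter-space
boundary (pinv → 0, α → ∞), so those comparisons are near-equalities
rather than exact ones.

## Strict-clock ML dating

Coalescence times are estimated on the concatenated protein-coding genes
(the synthetic stand-in annotation has 13 genes totalling 11,397 bp; ND6,
the single L-strand gene, is reverse-complemented so codon structure reads
5′→3′). Sites are partitioned by codon position — three partitions with
independent HKY parameters and clock rates in `whole` mode, third positions
alone in `third_only` mode — sharing one set of node times. The tree is
ultrametric with tips at age 0 and one internal node fixed by the
calibration (the *Bos taurus* / *Bos indicus* split, 335,000 YBP, in all
shipped examples). Ancient tips cannot carry their ages in this framework,
exactly as in the original ML setting; the `include_aurochs` flag simply
keeps or drops those leaves, and both settings are worth reporting.

Optimisation is coordinate ascent: Brent updates of each internal node age
within its bracket (children's ages, parent's age), alternating with
Nelder-Mead updates of each partition's (log κ, log rate). Convergence is
declared when the log-likelihood improves by less than 10⁻⁶ per sweep, with
a relative floor at 10⁻⁷·|lnL|: on an 11-kb alignment the coordinate
updates zigzag along the rate-age ridge with improvements of that order
indefinitely, while the corresponding age movements are below one year; three restarts with jittered rate
and κ initialisations guard against local optima. Ages are initialised
proportionally to node depth, which is strictly monotone and hits the
calibration exactly. Standard errors are a seeded site bootstrap (default
100 replicates, resampling columns within partitions, refitting from the
MLE); the published ± values' interval type is not stated in the sources
this design follows, so the bootstrap SE is the package's choice and is
used consistently. Near the calibration boundary an ML age can pin to its
bracket edge and the bootstrap SE then understates uncertainty; the
validation trees keep focal nodes well inside the bracket, as real cattle
panels do (taurine MRCA ≈ 100 ky ≪ 335 ky).

The parameter-recovery study simulates 11-kb codon-partitioned panels on a
fixed calibration tree (rates 8×10⁻⁹, 4×10⁻⁹, 4×10⁻⁸ subs/site/year for
positions 1–3 — third positions fastest, overall in the range implied by a
335-ky root and mitogenome-scale divergence — κ = 20, mitochondrial base
composition) and requires ≥90% of non-calibration node ages within 2
bootstrap SE of truth.

## Bayesian skyline inference

The skyline model couples (i) the piecewise-constant coalescent prior over
a tip-dated genealogy — per interval the coalescence rate is
*k*(*k*−1)/(2*N*) with *k* extant lineages, lineage counts stepping up at
sampling times, and *N* constant within groups of coalescent intervals —
with (ii) an HKY(+Γ4) likelihood on the 410-bp control-region alignment,
branch lengths being rate × duration. Population size is reported as the
effective number of females × generation time, in years, so no generation
time needs to be assumed. Group sizes over the *n*−1 coalescent events are
fixed and as equal as possible; the default of 5 groups for the usual
sample sizes is user-overridable. Base frequencies are fixed at their
empirical values.

The sampler is Metropolis-Hastings with: uniform node-time moves, a root
scale move, narrow exchange, Wilson-Balding subtree regraft (re-attachment
above the root excluded; root rearrangements are still reachable because
any subtree can regraft onto either root child's subtree), a whole-tree
internal-time scaling, per-group population-size multipliers, κ, Γ-shape
and clock-rate multipliers, and a joint rate×times tradeoff move (rate
multiplied by *f*, internal times divided by *f*, Jacobian *f*^(2−*n*))
that walks along the rate–time ridge and is essential for mixing when the
rate is estimated. Priors: log-uniform population sizes on [1, 10⁸] years,
uniform κ on (0, 100], Exponential(1) Γ shape, log-uniform rate on
[10⁻¹², 10⁻²]; the sources state no priors, so these deliberately weak
defaults are the package's own and are printed in the run configuration.
The clock rate is identifiable only when tips carry at least two distinct
dates; otherwise a fixed rate must be supplied — typically via
`transfer_rate()`, which fixes the modern run's rate at the posterior
median of a radiocarbon-dated (ancient) run, mirroring the
aurochs-to-cattle rate transfer design. Tip dates are fixed at their point
estimates; the C14 standard deviations are recorded but not sampled, a
noted extension.

The default chain (2×10⁶ steps, thinned every 1,000, 10% burn-in) is a
desk-scale homolog of the published 50M/1,000/5M settings and is what the
validation studies use; full-scale settings are plain arguments. Sampler
correctness is established by three oracle tests rather than by eyeballing
traces: prior-only sampling reproduces Kingman expectations for the
inter-coalescent times; with a fixed genealogy and a single group the
sampled population size matches the analytic inverse-gamma posterior; and
for *n* = 2 the coalescent density equals its closed form. Chains are
bit-identical under identical seeds (the sampler consumes R's RNG stream).

The coverage study simulates constant-size panels (*N*·τ = 5,000 years,
*n* = 20, 410 bp, control-region-scale rate 10⁻⁶ subs/site/year, κ = 10)
and requires the true size inside the 95% HPD at ≥90% of grid points; the
rate-transfer study uses two cohorts sharing that rate, ancient tips spread
over 2,000–12,000 YBP as radiocarbon-dated panels are.

## The synthetic-data generators

`simulate_genealogy()` draws heterochronous Kingman genealogies under
piecewise-constant demographics by integrating the time-varying rate
across epochs and sampling events. `simulate_sequences()` evolves HKY(+Γ)
sequences with the closed-form transition matrices (the same closed form
the likelihood uses is cross-checked in the tests against detailed balance
and enumeration, so simulator and likelihood cannot silently share a
one-sided bug — the simulator is additionally checked against Watterson's
segregating-sites expectation and the stationary composition).
`simulate_panel()` plants a motif tree with private mutations placed
without collision, so parsimony truth is exact unless recurrences or back
mutations are injected explicitly. `simulate_coding_panel()` interleaves
three codon-position site classes with distinct rates into a toy gene
layout with one complemented L-strand gene, exercising the partition
builder end to end. Scenario presets named after the motivating system — a
recent ~10× expansion around 650 YBP (the P1a analogue) and an older
bottleneck at 16,000–13,500 YBP (the aurochs analogue) — are illustrative
demo inputs, not validation surfaces.

What passing these studies shows: the inference machinery recovers the
quantities it claims to estimate when its model assumptions hold, at
realistic sizes, rates and sampling depths. What it does not show:
robustness to ancient-DNA damage, alignment error in diverged taxa,
recombination (absent in mtDNA), model misspecification, or the
correctness of any particular published biological claim — real-data
conclusions still require the real accession sequences.

## Degenerate inputs and edge behaviour

Fewer than two haplotypes yield a degenerate single-node tree, not an
error. Two identical sequences date their MRCA at (numerically) zero. An
alignment with no variable sites is a hard error in dating (ages
unidentifiable) and a warning in the skyline (posterior equals prior).
Fragments below half the reference length are refused by the aligner.
Chains require `chain_length ≥ 100 × thin` so summaries never run on a
handful of samples.

## A worked example

```{r example}
library(mitohap)

# a P1a-like star: 10 carriers of the six diagnostic transitions
spec <- list(motifs = data.frame(
  name = c("root", "P1a"), parent = c("-", "root"),
  variants = c("", "2171,5681,11468,12738,15714,16247")),
  leaves_per_clade = c(P1a = 10, root = 2), n_private = 2,
  positions = c(100, 16000))
pan <- simulate_panel(spec, seed = 42)

mat <- build_tree(pan$profiles, outgroup = "root_1")
find_clade_motif(mat, names(mat$haplotypes)[
  vapply(mat$haplotypes, function(m) all(startsWith(m, "P1a_")),
         logical(1))])

classify(pan$profiles[[1]])
```
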