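# mitohap

Matrilineal population genetics from complete mitogenomes, for researchers
studying the maternal ancestry of livestock (the motivating system is
cattle haplogroup P, the rare lineage inherited from wild aurochs). The
package implements the full computational chain such a study needs:

1. **Variant nomenclature** (`align_to_reference()`, `call_variants()`) —
   banded global alignment against the reference mitogenome and
   reference-relative calls in standard mtDNA notation: transitions as bare
   positions (`16247`), transversions with a base suffix (`9C`), indels
   (`15+AC`, `15d`) 3′-justified in repeat runs, heteroplasmies (`h`).
2. **Haplogroup classification** (`classify()`) — motif-tree scoring of a
   profile against a configurable nomenclature table (shipped with the six
   P1a diagnostic transitions at nps 2171, 5681, 11468, 12738, 15714,
   16247), in whole-mitogenome or 410-bp control-region mode.
3. **Mutation-annotated parsimony trees** (`build_tree()`,
   `find_clade_motif()`) — exact branch-and-bound search for small
   haplotype panels, Fitch assignment of every mutation to a branch with
   recurrence and back-mutation (`@`) flags, clade motif extraction, and
   BIC model selection (`select_model()`).
4. **Strict-clock ML dating** (`build_partition()`, `fit_global_clock()`)
   — codon-position-partitioned HKY likelihood on the concatenated
   protein-coding genes (ND6 complemented), ultrametric node ages
   calibrated by the *Bos taurus* / *Bos indicus* split (335 kya),
   site-bootstrap standard errors, whole-codon vs third-codon modes.
5. **Bayesian skyline plots** (`run_mcmc()`, `summarize_trajectory()`,
   `transfer_rate()`) — MCMC over tip-dated genealogies with a
   piecewise-constant coalescent prior and HKY+Γ likelihood; the clock
   rate is estimated from radiocarbon-dated (heterochronous) samples and
   can be transferred to contemporaneous data sets.
6. **Coalescent simulation** (`simulate_genealogy()`,
   `simulate_sequences()`, `simulate_panel()`, `simulate_coding_panel()`)
   — seeded generators with truth records that make every stage above
   testable end to end without external data.

The core model throughout is HKY85 with closed-form transition
probabilities, optionally with +I / discrete-Γ rate mixtures; the skyline
prior is the standard grouped piecewise-constant coalescent with
heterochronous sampling, rate *k*(*k*−1)/(2*N*) per interval, with *N*
reported as effective females × generation time in years.

## Worked example

```r
library(mitohap)

# a star-like sub-haplogroup: 10 carriers of six diagnostic transitions
spec <- list(motifs = data.frame(
  name = c("root", "P1a"), parent = c("-", "root"),
  variants = c("", "2171,5681,11468,12738,15714,16247")),
  leaves_per_clade = c(P1a = 10, root = 2), n_private = 2,
  positions = c(100, 16000))
pan <- simulate_panel(spec, seed = 42)

mat <- build_tree(pan$profiles, outgroup = "root_1")
mat
#> mutation_annotated_tree: 12 haplotypes, parsimony length 37

clade <- names(mat$haplotypes)[vapply(mat$haplotypes, function(m)
  all(startsWith(m, "P1a_")), logical(1))]
find_clade_motif(mat, clade)
#> [1] "2171"  "5681"  "11468" "12738" "15714" "16247"

classify(pan$profiles[[1]])
#>   sample_id best_haplogroup matched expected missing              private score
#> 1     P1a_1             P1a       6        6         2468;5372;9389;12360     6
```

The stem branch of the simulated clade carries exactly the six planted
diagnostic transitions, and the classifier places a carrier profile in
P1a with all six motif sites matched; the `private` column lists the
sample's own extra mutations.

A frequency table reproduces published-style percentages exactly:

```r
calls <- data.frame(best_haplogroup = c(rep("P", 83), rep("T", 98)),
                    breed = "Japanese Shorthorn")
haplogroup_frequency(calls)
#>                group haplogroup count total percent
#> 1 Japanese Shorthorn          P    83   181    45.9
#> 2 Japanese Shorthorn          T    98   181    54.1
```

A command-line front-end over the same functions is installed at
`inst/cli/mitohap.R` (subcommands `variants`, `classify`, `tree`, `date`,
`skyline`, `simulate`; global `--seed`, `--config`, `--log-level`).

See `vignettes/mitohap-methods.Rmd` for the models, priors, numerical
choices and the design of the validation studies.

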