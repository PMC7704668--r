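# shared fixture builders (everything generated in code, seeded)

# a toy motif table with non-empty motifs at every level
toy_motifs <- function() {
  load_motifs(data.frame(
    name = c("root", "X", "X1", "X1a", "Y"),
    parent = c("-", "root", "X", "X1", "root"),
    variants = c("", "100,200", "300", "400,500,600", "900C"),
    stringsAsFactors = FALSE))
}

# deterministic 20-bp reference with known bases at nps 4, 9, 15/16
toy_ref <- function() {
  paste(c("A", "C", "T", "G", "A", "A", "C", "T", "A", "C",
          "G", "T", "A", "C", "T", "G", "A", "C", "T", "G"),
        collapse = "")
}

# random profiles for parsimony instances: k taxa, each with a random
# subset of a shared variant pool (guarantees shared + private variation)
random_profile_set <- function(k, n_pool = 12, seed = 1) {
  set.seed(seed)
  pool <- as.character(sample(10000, n_pool))
  lapply(seq_len(k), function(i) {
    variant_profile(paste0("s", i),
                    sample(pool, sample.int(n_pool, 1)))
  })
}

# an ultrametric calibration tree (root = calibrated split) in years
clock_test_tree <- function() {
  ape::read.tree(text = paste0(
    "((i1:80000,i2:80000):255000,((t1:100000,(p0:16180,(p1:3720,",
    "p2:3720):12460):83820):150000,t2:250000):85000);"))
}

# leaves of a mutation_annotated_tree whose haplotype members all share a
# sample-id prefix (robust to haplotype collapsing)
clade_leaves <- function(mat, prefix) {
  names(mat$haplotypes)[vapply(mat$haplotypes, function(m)
    all(startsWith(m, prefix)), logical(1))]
}
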