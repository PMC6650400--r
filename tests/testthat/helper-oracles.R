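# Independent oracles and random-input generators used across the suite.

# Floyd-Warshall all-pairs shortest paths on a molecule's bond graph;
# independent of the BFS implementation under test.
fw_distances <- function(mol) {
  n <- nrow(mol$atoms)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(mol$bonds))) {
    D[mol$bonds$a[k], mol$bonds$b[k]] <- 1
    D[mol$bonds$b[k], mol$bonds$a[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# random small-molecule SMILES over a chain/ring/aromatic grammar; valence is
# not enforced (the fingerprint machinery is agnostic to it)
gen_smiles <- function() {
  el <- function() sample(c("C", "C", "C", "N", "O", "S"), 1)
  chain <- function(n) {
    toks <- vapply(seq_len(n), function(i) {
      b <- if (i > 1 && runif(1) < 0.2) "=" else ""
      paste0(b, el())
    }, "")
    paste(toks, collapse = "")
  }
  base <- switch(sample(3, 1),
                 chain(sample(3:8, 1)),
                 paste0("C1", chain(sample(2:4, 1)), "C1"),
                 "c1ccccc1")
  if (runif(1) < 0.5)
    base <- paste0(base, "(", chain(sample(1:3, 1)), ")", el())
  if (runif(1) < 0.3)
    base <- paste0(el(), base)
  base
}

gen_molecule <- function() parse_smiles(gen_smiles())

# random additive distance matrix: patristic distances of a random tree
gen_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(nb) runif(nb, 0.01, 1))
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}

# brute-force two-sided exact binomial p: sum of the pmf over outcomes no
# more likely than the observed one (tiny relative tolerance for fp ties)
exact_binom_oracle <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# tiny no-choice table builder
nochoice_table <- function(treatment, counts, week = "wk1") {
  data.frame(treatment = treatment, week = week,
             cage = seq_along(counts), count = counts,
             stringsAsFactors = FALSE)
}
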