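# Distance tree construction and phylogenetic distance (PD) to the host.
#
# The tree path: pairwise JC69 (or p) distances with pairwise deletion ->
# neighbor-joining -> rooting (midpoint by default, outgroup optional) ->
# per-taxon PD, the branch-length sum from the taxon's tip to its most recent
# common ancestor with the host. An externally inferred Newick tree can be
# supplied instead of the NJ step.

#' Pairwise evolutionary distances from a concatenated alignment
#'
#' Computes per-pair p-distances over sites where neither sequence has a gap
#' or `N` (pairwise deletion), optionally applying the Jukes-Cantor
#' correction `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param aln A `concat_alignment` (or `gene_alignment`).
#' @param model `"jc69"` (default) or `"p_distance"`.
#' @return Symmetric distance matrix with taxa as dimnames.
#' @export
pairwise_distance <- function(aln, model = c("jc69", "p_distance")) {
  model <- match.arg(model)
  seqs <- aln$seqs
  taxa <- names(seqs)
  n <- length(taxa)
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  ok <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns == 0L)
        stop(sprintf("taxa '%s' and '%s' share no ungapped sites", taxa[i], taxa[j]))
      p <- sum(mat[i, shared] != mat[j, shared]) / ns
      if (model == "jc69") {
        if (p >= 0.75)
          stop(sprintf("saturated pair '%s' / '%s': p = %.3f >= 0.75, JC69 undefined",
                       taxa[i], taxa[j], p))
        d <- -0.75 * log(1 - 4 * p / 3)
      } else {
        d <- p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Build a neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor-joining on a symmetric distance matrix
#' (exact on additive matrices). Negative branch-length estimates are clamped
#' to zero; the total clamped deficit is stored as attribute
#' `clamped_deficit` and reported with a message when nonzero.
#'
#' @param D Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return Unrooted `phylo` tree.
#' @export
build_nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("neighbor-joining needs >= 3 taxa")
  tree <- ape::nj(stats::as.dist(D))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  if (deficit > 0) {
    message(sprintf("clamped negative NJ branch lengths (total deficit %.3g)", deficit))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Root a tree
#'
#' @param tree Unrooted `phylo` tree.
#' @param method `"midpoint"` (root at the midpoint of the longest tip-to-tip
#'   path; default) or `"outgroup"`.
#' @param outgroup Outgroup taxon label, required for `method = "outgroup"`;
#'   the root is placed on the outgroup's pendant edge.
#' @return Rooted `phylo` tree.
#' @export
root_tree <- function(tree, method = c("midpoint", "outgroup"), outgroup = NULL) {
  method <- match.arg(method)
  if (method == "midpoint") {
    phangorn::midpoint(tree)
  } else {
    if (is.null(outgroup)) stop("outgroup rooting requires an outgroup taxon")
    if (!outgroup %in% tree$tip.label)
      stop(sprintf("outgroup taxon '%s' not in tree", outgroup))
    rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    # split the outgroup's pendant edge at its midpoint so the root sits on it
    og_tip <- which(rooted$tip.label == outgroup)
    root_node <- ape::Ntip(rooted) + 1L
    kids <- rooted$edge[rooted$edge[, 1L] == root_node, 2L]
    if (og_tip %in% kids && length(kids) == 2L) {
      e_og <- which(rooted$edge[, 1L] == root_node & rooted$edge[, 2L] == og_tip)
      e_in <- which(rooted$edge[, 1L] == root_node & rooted$edge[, 2L] != og_tip)
      total <- rooted$edge.length[e_og] + rooted$edge.length[e_in]
      rooted$edge.length[e_og] <- total / 2
      rooted$edge.length[e_in] <- total / 2
    }
    rooted
  }
}

#' Phylogenetic distance (PD) from a taxon to the host
#'
#' Sums branch lengths on the path from the taxon's tip up to (and excluding
#' branches above) the most recent common ancestor of the taxon and the host.
#' The host's own PD is 0 by definition.
#'
#' @param tree Rooted `phylo` tree.
#' @param taxon Candidate taxon tip label.
#' @param host Host taxon tip label.
#' @return PD in branch-length (substitutions/site) units.
#' @export
pd_to_host <- function(tree, taxon, host) {
  for (tx in c(taxon, host))
    if (!tx %in% tree$tip.label) stop(sprintf("taxon '%s' not in tree", tx))
  if (taxon == host) return(0)
  tip <- which(tree$tip.label == taxon)
  host_tip <- which(tree$tip.label == host)
  mrca <- ape::getMRCA(tree, c(tip, host_tip))
  # walk parent edges from the tip up to the MRCA, summing branch lengths
  total <- 0
  node <- tip
  while (node != mrca) {
    e <- which(tree$edge[, 2L] == node)
    if (length(e) != 1L) stop("tip-to-MRCA walk left the rooted tree; is the tree rooted?")
    total <- total + tree$edge.length[e]
    node <- tree$edge[e, 1L]
  }
  total
}

#' PD scores for all tips of a rooted tree
#'
#' @param tree Rooted `phylo` tree.
#' @param host Host taxon tip label.
#' @return Data frame with columns `taxon`, `PD`, sorted by taxon.
#' @export
pd_table <- function(tree, host) {
  taxa <- sort(tree$tip.label)
  data.frame(taxon = taxa,
             PD = vapply(taxa, function(tx) pd_to_host(tree, tx, host), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write Newick trees
#'
#' Thin wrappers that let an externally inferred tree drop into the PD step.
#' A tree without branch lengths is accepted with all lengths set to 0 and a
#' warning.
#'
#' @param path Newick file path.
#' @return `read_newick`: a `phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop(sprintf("Newick parse error in '%s': %s",
                                                    path, conditionMessage(e))))
  if (is.null(tree)) stop(sprintf("Newick parse error in '%s'", path))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree
}

#' @param tree A `phylo` tree.
#' @rdname read_newick
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
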