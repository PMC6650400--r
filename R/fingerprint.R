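# Carhart-style atom-pair fingerprints and Tanimoto similarity.
#
# Each heavy atom is typed by (element, heavy-atom degree, pi-electron count);
# a fingerprint is the multiset of (type_a, type_b, shortest-bond-path length)
# triples over all unordered atom pairs. Aromatic atoms carry exactly one pi
# electron; a double bond contributes one pi electron per endpoint, a triple
# bond two.

#' Atom types of a molecule
#'
#' Types each heavy atom by element, heavy-atom degree (number of bonded heavy
#' atoms), and pi-electron count. Pi electrons: one per incident double bond,
#' two per incident triple bond; aromatic atoms are assigned exactly 1
#' regardless of their incident bonds.
#'
#' @param mol A `molecule`.
#' @return Data frame with columns `element`, `degree`, `pi`, and `key`
#'   (the canonical `element/degree/pi` string used for descriptor ordering).
#' @export
atom_types <- function(mol) {
  n <- n_atoms(mol)
  degree <- integer(n)
  pi <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
    degree[a] <- degree[a] + 1L
    degree[b] <- degree[b] + 1L
    add <- switch(o, "2" = 1L, "3" = 2L, 0L)
    pi[a] <- pi[a] + add
    pi[b] <- pi[b] + add
  }
  pi[mol$atoms$aromatic] <- 1L
  data.frame(element = mol$atoms$element, degree = degree, pi = pi,
             key = sprintf("%s/%d/%d", mol$atoms$element, degree, pi),
             stringsAsFactors = FALSE)
}

#' Topological distance matrix
#'
#' All-pairs shortest bond-path lengths (in bonds) by breadth-first search.
#'
#' @param mol A connected `molecule`.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
topological_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  if (anyNA(D)) stop("molecule graph is disconnected")
  D
}

#' Atom-pair fingerprint
#'
#' The multiset of atom-pair descriptors `(type_a, type_b, distance)` over all
#' unordered heavy-atom pairs, with `type_a <= type_b` under the canonical
#' type order and path lengths capped at `max_distance` bonds. The total
#' multiplicity is always `n*(n-1)/2` for `n` heavy atoms.
#'
#' @param mol A connected `molecule` (a single-atom molecule yields an empty
#'   fingerprint that is still comparable; see [tanimoto()]).
#' @param max_distance Path-length cap in bonds; longer paths are binned here.
#' @return Object of class `ap_fingerprint`: a named integer vector of
#'   descriptor multiplicities, with attributes `n_atoms` and (for single-atom
#'   molecules) `single_type`.
#' @export
atom_pair_fingerprint <- function(mol, max_distance = 15L) {
  types <- atom_types(mol)$key
  n <- n_atoms(mol)
  if (n == 1L) {
    fp <- integer(0)
    return(structure(fp, n_atoms = 1L, single_type = types[1L],
                     class = "ap_fingerprint"))
  }
  D <- topological_distances(mol)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  d <- pmin(D[idx], as.integer(max_distance))
  ta <- types[idx[, 1L]]
  tb <- types[idx[, 2L]]
  lo <- ifelse(ta <= tb, ta, tb)
  hi <- ifelse(ta <= tb, tb, ta)
  keys <- sprintf("%s|%s|%d", lo, hi, d)
  tab <- table(keys)
  fp <- as.integer(tab)
  names(fp) <- names(tab)
  structure(fp, n_atoms = n, class = "ap_fingerprint")
}

#' @export
print.ap_fingerprint <- function(x, ...) {
  cat(sprintf("<atom-pair fingerprint> %d atoms, %d descriptors (%d distinct)\n",
              attr(x, "n_atoms"), sum(x), length(x)))
  invisible(x)
}

#' Tanimoto similarity of two atom-pair fingerprints
#'
#' Multiset mode (default) computes `sum(min)/sum(max)` of descriptor
#' multiplicities over the union of descriptors; set mode computes the Jaccard
#' index `|A n B| / |A u B|` on distinct descriptors. Two empty fingerprints
#' (single-atom molecules) compare as 1 when both atoms have the same type and
#' 0 otherwise.
#'
#' @param a,b `ap_fingerprint` objects.
#' @param mode `"multiset"` (count-preserving) or `"set"`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, mode = c("multiset", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "ap_fingerprint"), inherits(b, "ap_fingerprint"))
  if (length(a) == 0L && length(b) == 0L) {
    ta <- attr(a, "single_type"); tb <- attr(b, "single_type")
    return(if (!is.null(ta) && !is.null(tb) && identical(ta, tb)) 1 else 0)
  }
  if (length(a) == 0L || length(b) == 0L) return(0)
  keys <- union(names(a), names(b))
  ca <- ifelse(keys %in% names(a), a[keys], 0L)
  cb <- ifelse(keys %in% names(b), b[keys], 0L)
  ca[is.na(ca)] <- 0L; cb[is.na(cb)] <- 0L
  if (mode == "multiset") {
    sum(pmin(ca, cb)) / sum(pmax(ca, cb))
  } else {
    length(intersect(names(a), names(b))) / length(keys)
  }
}

#' Construct a volatile blend
#'
#' A blend is a species' set of volatile compounds, each a parsed molecule.
#'
#' @param species Species (or treatment) name.
#' @param smiles Character vector of SMILES strings (non-empty).
#' @param compound_names Optional compound names; must be unique.
#' @param family Optional plant family annotation.
#' @return Object of class `blend`.
#' @export
blend <- function(species, smiles, compound_names = NULL, family = NA_character_) {
  stopifnot(length(smiles) >= 1L)
  if (is.null(compound_names)) compound_names <- smiles
  if (anyDuplicated(compound_names))
    stop(sprintf("blend '%s': compound names must be unique", species))
  compounds <- mapply(parse_smiles, smiles, compound_names, SIMPLIFY = FALSE)
  structure(list(species = species, family = family,
                 compounds = unname(compounds)),
            class = "blend")
}

#' @export
print.blend <- function(x, ...) {
  cat(sprintf("<blend> %s (%s): %d compounds\n", x$species,
              ifelse(is.na(x$family), "family unknown", x$family),
              length(x$compounds)))
  invisible(x)
}

#' Blend-vs-target physicochemical similarity (PS)
#'
#' Aggregates compound-level Tanimoto similarities between a species' volatile
#' blend and the host kairomone compounds into one PS score. The default
#' `mean_of_max` takes, for each blend compound, its best Tanimoto match among
#' the targets, then averages; this guarantees the host's own blend scores
#' exactly 1. `mean_of_all_pairs` averages over every (blend compound, target
#' compound) pair.
#'
#' @param b A `blend` of candidate compounds.
#' @param targets A `blend` holding the host kairomone compounds.
#' @param aggregator `"mean_of_max"` or `"mean_of_all_pairs"`.
#' @param mode Tanimoto mode, see [tanimoto()].
#' @return PS score in `[0, 1]`.
#' @export
blend_similarity <- function(b, targets,
                             aggregator = c("mean_of_max", "mean_of_all_pairs"),
                             mode = "multiset") {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(b, "blend"), inherits(targets, "blend"))
  if (length(b$compounds) == 0L || length(targets$compounds) == 0L)
    stop("blend_similarity: empty blend")
  fps_b <- lapply(b$compounds, atom_pair_fingerprint)
  fps_t <- lapply(targets$compounds, atom_pair_fingerprint)
  sim <- outer(seq_along(fps_b), seq_along(fps_t),
               Vectorize(function(i, j) tanimoto(fps_b[[i]], fps_t[[j]], mode)))
  if (aggregator == "mean_of_max") mean(apply(sim, 1L, max)) else mean(sim)
}

#' Read blends from CSV
#'
#' Expects UTF-8 CSV with header columns `species`, `compound_name`, `smiles`
#' and optionally `family`.
#'
#' @param path CSV file path.
#' @return Named list of `blend` objects, one per species.
#' @export
read_blend_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "compound_name", "smiles")
  if (!all(need %in% names(df)))
    stop(sprintf("blend CSV must have columns %s", paste(need, collapse = ", ")))
  out <- lapply(split(df, df$species), function(d) {
    fam <- if ("family" %in% names(d)) d$family[1L] else NA_character_
    blend(d$species[1L], d$smiles, d$compound_name, family = fam)
  })
  out[unique(df$species)]
}

#' Write a list of blends to CSV
#'
#' @param blends Named list of `blend` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_blend_csv <- function(blends, path) {
  rows <- do.call(rbind, lapply(blends, function(b) {
    data.frame(species = b$species, family = b$family,
               compound_name = vapply(b$compounds, function(m) m$name, ""),
               smiles = vapply(b$compounds, function(m) m$smiles, ""),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Host kairomone target compounds
#'
#' The four brassica isothiocyanates the specialist herbivore uses for host
#' recognition (allyl, benzyl, 3-(methylthio)propyl, and n-butyl
#' isothiocyanate), shipped with the package as the default PS comparison
#' targets.
#'
#' @return A `blend` holding the four isothiocyanates.
#' @export
isothiocyanate_targets <- function() {
  path <- system.file("extdata", "isothiocyanates.csv", package = "repelscore",
                      mustWork = TRUE)
  read_blend_csv(path)[[1L]]
}
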