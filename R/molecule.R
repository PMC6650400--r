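# Heavy-atom molecular graphs parsed from a SMILES subset.
#
# Only what the atom-pair fingerprint needs is retained: element, aromatic
# flag, and bond orders. Hydrogens are implicit and never stored; bracket-atom
# charges and H counts are parsed but discarded.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic lowercase
#' atoms, bracket atoms (charges and explicit hydrogen counts are accepted and
#' ignored), explicit bonds `-`, `=`, `#`, branches, and single-digit or
#' `%nn` ring closures. Stereochemistry, isotopes, and multi-component
#' (dot-separated) SMILES are rejected. Implicit hydrogens are discarded: the
#' returned graph contains heavy atoms only.
#'
#' @param text A single SMILES string.
#' @param name Optional compound name stored on the molecule.
#' @return An object of class `molecule`: a list with `atoms` (data frame of
#'   `element`, `aromatic`), `bonds` (data frame of `a`, `b`, `order`, where
#'   order is `1`, `2`, `3` or `ar`), `name`, and `smiles`.
#' @examples
#' m <- parse_smiles("C=CCN=C=S", name = "allyl isothiocyanate")
#' nrow(m$atoms) # 6 heavy atoms
#' @export
parse_smiles <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty SMILES string")

  element <- character(0)
  aromatic <- logical(0)
  bond_a <- integer(0)
  bond_b <- integer(0)
  bond_o <- character(0)

  prev <- NA_integer_           # index of the atom a new atom bonds to
  stack <- integer(0)           # branch stack of prev indices
  pending <- NA_character_      # explicit bond symbol awaiting the next atom
  rings <- list()               # open ring closures: label -> list(atom, bond, pos)

  err <- function(msg, pos) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(text, pos, pos), msg), call. = FALSE)
  }

  add_atom <- function(el, arom, pos) {
    element <<- c(element, el)
    aromatic <<- c(aromatic, arom)
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) {
        pending
      } else if (arom && aromatic[prev]) "ar" else "1"
      bond_a <<- c(bond_a, prev)
      bond_b <<- c(bond_b, idx)
      bond_o <<- c(bond_o, ord)
    }
    pending <<- NA_character_
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(label, pos) {
    key <- as.character(label)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending, pos = pos)
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      if (open$atom == prev) err("ring closure bonds an atom to itself", pos)
      ord <- if (!is.na(pending)) {
        pending
      } else if (!is.na(open$bond)) {
        open$bond
      } else if (aromatic[open$atom] && aromatic[prev]) "ar" else "1"
      bond_a <<- c(bond_a, open$atom)
      bond_b <<- c(bond_b, prev)
      bond_o <<- c(bond_o, ord)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == ".") err("disconnected (dot-bond) SMILES not accepted", i)
    if (ch %in% c("/", "\\", "@")) err("stereochemistry not supported", i)
    if (ch == "-" || ch == "=" || ch == "#") {
      pending <- c("-" = "1", "=" = "2", "#" = "3")[[ch]]
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) err("branch cannot open before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) err("unmatched closing parenthesis", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) err("ring closure before any atom", i)
      close_ring(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        err("'%' ring closure needs two digits", i)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) err("unmatched '['", i)
      inner <- substr(text, i + 1L, j - 1L)
      if (grepl("^[0-9]", inner)) err("isotopes not supported", i)
      if (grepl("@", inner)) err("stereochemistry not supported", i)
      m <- regmatches(inner, regexec("^([A-Z][a-z]?|[a-z])(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$", inner))[[1]]
      if (length(m) == 0L || m[2] == "") err("cannot parse bracket atom", i)
      sym <- m[2]
      arom <- sym %in% AROMATIC_SUBSET
      el <- if (arom) toupper(sym) else sym
      known <- c(ORGANIC_SUBSET, "Si", "Se", "As", "Na", "K", "Li", "Mg", "Ca",
                 "Fe", "Zn", "Cu", "Mn", "Al", "Sn", "H")
      if (!el %in% known) err(sprintf("unknown element '%s'", sym), i)
      if (el == "H") err("explicit hydrogen atoms are not stored", i)
      add_atom(el, arom, i)
      i <- j + 1L
    } else {
      # organic-subset atom, two-letter first
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, i)
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, FALSE, i)
        i <- i + 1L
      } else if (ch %in% AROMATIC_SUBSET) {
        add_atom(toupper(ch), TRUE, i)
        i <- i + 1L
      } else {
        err("unknown token", i)
      }
    }
  }
  if (length(stack) > 0L) stop("SMILES parse error: unmatched opening parenthesis", call. = FALSE)
  if (length(rings) > 0L) {
    open <- rings[[1]]
    err("unmatched ring closure", open$pos)
  }
  if (length(element) == 0L) stop("SMILES contains no atoms")

  atoms <- data.frame(element = element, aromatic = aromatic,
                      stringsAsFactors = FALSE)
  bonds <- if (length(bond_a) > 0L) {
    a <- pmin(bond_a, bond_b)
    b <- pmax(bond_a, bond_b)
    bd <- data.frame(a = a, b = b, order = bond_o, stringsAsFactors = FALSE)
    if (anyDuplicated(bd[, c("a", "b")]))
      stop("SMILES parse error: duplicate bond between the same atom pair")
    bd
  } else {
    data.frame(a = integer(0), b = integer(0), order = character(0),
               stringsAsFactors = FALSE)
  }

  mol <- structure(list(name = name, atoms = atoms, bonds = bonds,
                        smiles = text),
                   class = "molecule")
  if (!is_connected(mol))
    stop("SMILES parse error: structure is not a connected graph")
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds (%s)\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# adjacency list over heavy atoms
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

is_connected <- function(mol) {
  n <- n_atoms(mol)
  if (n <= 1L) return(TRUE)
  adj <- adjacency(mol)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' Serialize a molecule back to SMILES
#'
#' Writes a (non-canonical) SMILES string for a heavy-atom graph by
#' depth-first traversal, using ring-closure digits for cycle bonds.
#' `parse_smiles(mol_to_smiles(m))` always reproduces a graph with the same
#' atom-pair fingerprint as `m`.
#'
#' @param mol A `molecule`.
#' @return A SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  n <- n_atoms(mol)
  bonds <- mol$bonds
  inc <- vector("list", n)  # incident bond indices per atom
  for (k in seq_len(nrow(bonds))) {
    inc[[bonds$a[k]]] <- c(inc[[bonds$a[k]]], k)
    inc[[bonds$b[k]]] <- c(inc[[bonds$b[k]]], k)
  }
  other_end <- function(k, v) if (bonds$a[k] == v) bonds$b[k] else bonds$a[k]

  # pass 1: iterative DFS to split bonds into tree and ring edges
  visited <- logical(n)
  tree_children <- vector("list", n)  # list of (bond, child)
  ring_edges <- integer(0)
  used <- logical(nrow(bonds))
  order_seen <- integer(n)
  stack <- 1L
  visited[1L] <- TRUE
  order_seen[1L] <- 1L
  seen_count <- 1L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    advanced <- FALSE
    for (k in inc[[v]]) {
      if (used[k]) next
      w <- other_end(k, v)
      if (!visited[w]) {
        used[k] <- TRUE
        visited[w] <- TRUE
        seen_count <- seen_count + 1L
        order_seen[w] <- seen_count
        tree_children[[v]] <- c(tree_children[[v]], list(list(bond = k, child = w)))
        stack <- c(stack, w)
        advanced <- TRUE
        break
      } else {
        used[k] <- TRUE
        ring_edges <- c(ring_edges, k)
      }
    }
    if (!advanced) stack <- stack[-length(stack)]
  }

  bond_sym <- function(k) {
    o <- bonds$order[k]
    both_ar <- mol$atoms$aromatic[bonds$a[k]] && mol$atoms$aromatic[bonds$b[k]]
    switch(o, "2" = "=", "3" = "#", "ar" = "",
           "1" = if (both_ar) "-" else "")
  }
  ring_label <- function(i) if (i <= 9L) as.character(i) else sprintf("%%%02d", i)
  # ring tokens attached to each endpoint; bond symbol on the earlier atom
  ring_tok <- vector("list", n)
  for (i in seq_along(ring_edges)) {
    k <- ring_edges[i]
    a <- bonds$a[k]; b <- bonds$b[k]
    first <- if (order_seen[a] <= order_seen[b]) a else b
    second <- if (first == a) b else a
    ring_tok[[first]] <- c(ring_tok[[first]], paste0(bond_sym(k), ring_label(i)))
    ring_tok[[second]] <- c(ring_tok[[second]], ring_label(i))
  }

  atom_tok <- function(v) {
    el <- mol$atoms$element[v]
    if (mol$atoms$aromatic[v]) return(tolower(el))
    if (el %in% ORGANIC_SUBSET) el else paste0("[", el, "]")
  }

  # pass 2: emit, branching all but the last child
  emit <- function(v) {
    out <- paste0(atom_tok(v), paste(ring_tok[[v]], collapse = ""))
    kids <- tree_children[[v]]
    if (length(kids) > 0L) {
      for (i in seq_along(kids)) {
        part <- paste0(bond_sym(kids[[i]]$bond), emit(kids[[i]]$child))
        out <- if (i < length(kids)) paste0(out, "(", part, ")")
               else paste0(out, part)
      }
    }
    out
  }
  emit(1L)
}
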