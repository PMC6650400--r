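# Barcode-gene alignments: reading, validation, and multi-gene concatenation.

#' Read one gene's aligned FASTA
#'
#' Reads a pre-aligned FASTA file; the taxon label is the first
#' whitespace-delimited header token. Sequences are upper-cased and must use
#' only `A C G T - N` and have equal lengths.
#'
#' @param path FASTA file path.
#' @param gene Gene name (defaults to the file name without extension).
#' @return Object of class `gene_alignment`: list with `gene` and `seqs`
#'   (named character vector of equal-length aligned sequences).
#' @export
read_gene_fasta <- function(path, gene = sub("\\.[^.]*$", "", basename(path))) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  taxa <- vapply(names(recs), function(h) strsplit(trimws(h), "\\s+")[[1]][1L], "")
  seqs <- toupper(vapply(recs, function(s) as.character(s)[1L], ""))
  names(seqs) <- taxa
  gene_alignment(gene, seqs)
}

#' Construct and validate a gene alignment
#'
#' @param gene Gene name.
#' @param seqs Named character vector, taxon -> aligned sequence.
#' @return `gene_alignment` object.
#' @export
gene_alignment <- function(gene, seqs) {
  if (length(seqs) < 2L) stop(sprintf("gene '%s': need >= 2 taxa", gene))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop(sprintf("gene '%s': all sequences must be named by taxon", gene))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0L)
    stop(sprintf("gene '%s': duplicate taxon '%s'", gene, dup[1L]))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("gene '%s': unequal sequence lengths (%s)", gene,
                 paste(unique(lens), collapse = ", ")))
  for (tx in names(seqs)) {
    bad <- regexpr("[^ACGTN-]", seqs[[tx]])
    if (bad > 0L)
      stop(sprintf("gene '%s', taxon '%s': illegal character '%s' at position %d",
                   gene, tx, substr(seqs[[tx]], bad, bad), bad))
  }
  structure(list(gene = gene, seqs = seqs, length = unname(lens[1L])),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene alignment> %s: %d taxa x %d sites\n",
              x$gene, length(x$seqs), x$length))
  invisible(x)
}

#' Concatenate gene alignments
#'
#' Joins per-gene blocks into one supermatrix over the union of taxa. A taxon
#' missing a gene gets that block gap-filled with `-` (it is still placed on
#' the tree; pairwise-deletion distances then use only its sequenced sites).
#'
#' @param genes List of `gene_alignment` objects.
#' @return Object of class `concat_alignment`: list with `taxa`, `seqs`
#'   (named character vector), `blocks` (data frame gene/start/end), and
#'   `presence` (taxa x genes logical matrix).
#' @export
concatenate_genes <- function(genes) {
  stopifnot(length(genes) >= 1L)
  if (inherits(genes, "gene_alignment")) genes <- list(genes)
  taxa <- sort(unique(unlist(lapply(genes, function(g) names(g$seqs)))))
  if (length(taxa) == 0L) stop("no taxa in any gene")
  lens <- vapply(genes, function(g) g$length, 1L)
  gene_names <- vapply(genes, function(g) g$gene, "")
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  ends <- cumsum(lens)
  blocks <- data.frame(gene = gene_names, start = c(1L, head(ends, -1L) + 1L),
                       end = ends, stringsAsFactors = FALSE)
  presence <- matrix(FALSE, length(taxa), length(genes),
                     dimnames = list(taxa, gene_names))
  seqs <- vapply(taxa, function(tx) {
    parts <- vapply(seq_along(genes), function(i) {
      g <- genes[[i]]
      if (tx %in% names(g$seqs)) {
        presence[tx, i] <<- TRUE
        g$seqs[[tx]]
      } else {
        strrep("-", g$length)
      }
    }, "")
    paste(parts, collapse = "")
  }, "")
  structure(list(taxa = taxa, seqs = seqs, blocks = blocks,
                 presence = presence, length = sum(lens)),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concatenated alignment> %d taxa x %d sites (%s)\n",
              length(x$taxa), x$length, paste(x$blocks$gene, collapse = " + ")))
  invisible(x)
}

#' Write a gene alignment as FASTA
#'
#' @param aln A `gene_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in names(aln$seqs)) {
    writeLines(paste0(">", tx), con)
    writeLines(aln$seqs[[tx]], con)
  }
  invisible(path)
}
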