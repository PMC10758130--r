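# Concatenated supermatrices with partitions, standard phylogenetics exports
# (relaxed PHYLIP, NEXUS with charsets, RAxML partition file), distance-based
# neighbor-joining trees and topology tests (monophyly, Robinson-Foulds).
# Missing taxon-by-gene blocks are '?'; '-' is reserved for alignment gaps.

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are concatenated in the order of `gene_order` (default: the order of
#' `alignments`), so permuting the input list with a fixed order gives
#' identical output. Taxa missing from a gene are filled with `?`. Partition
#' boundaries are 1-based inclusive on the concatenated coordinate and tile
#' the matrix exactly.
#'
#' @param alignments Named list of `codon_alignment` objects.
#' @param taxa Taxon set and row order (default: union over genes, in first
#'   appearance order). A taxon present in no gene is an error.
#' @param gene_order Character vector fixing concatenation order.
#' @return A `concat_matrix`: list with `seqs` (tibble `taxon`, `sequence`)
#'   and `partitions` (tibble `gene`, `start`, `end`).
#' @export
concatenate_genes <- function(alignments, taxa = NULL, gene_order = NULL) {
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    names(alignments) <- vapply(alignments, aln_gene, "")
  }
  gene_order <- gene_order %||% names(alignments)
  stopifnot(all(gene_order %in% names(alignments)))
  alignments <- alignments[gene_order]
  taxa <- taxa %||% unique(unlist(purrr::map(alignments, "taxon")))
  seen <- unique(unlist(purrr::map(alignments, "taxon")))
  orphans <- setdiff(taxa, seen)
  if (length(orphans) > 0) {
    abort(sprintf("taxa present in no gene: %s", paste(orphans, collapse = ", ")))
  }
  lens <- vapply(alignments, function(a) nchar(a$sequence[1]), 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  blocks <- purrr::imap(alignments, function(aln, g) {
    s <- setNames(aln$sequence, aln$taxon)
    out <- s[taxa]
    out[is.na(out)] <- strrep("?", nchar(aln$sequence[1]))
    unname(out)
  })
  seqs <- tibble(
    taxon = taxa,
    sequence = do.call(paste0, blocks)
  )
  structure(
    list(
      seqs = seqs,
      partitions = tibble(gene = gene_order, start = as.integer(starts),
                          end = as.integer(ends))
    ),
    class = "concat_matrix"
  )
}

#' @export
print.concat_matrix <- function(x, ...) {
  cat(sprintf("<concat_matrix> %d taxa x %d sites, %d partitions\n",
              nrow(x$seqs), nchar(x$seqs$sequence[1]), nrow(x$partitions)))
  invisible(x)
}

#' @export
tidy.concat_matrix <- function(x, ...) x$partitions

#' @export
glance.concat_matrix <- function(x, ...) {
  tibble(n_taxa = nrow(x$seqs), n_sites = nchar(x$seqs$sequence[1]),
         n_partitions = nrow(x$partitions),
         pct_missing = 100 * sum(stringr::str_count(x$seqs$sequence, "\\?")) /
           (nrow(x$seqs) * nchar(x$seqs$sequence[1])))
}

sanitize_labels <- function(labels) {
  clean <- gsub("\\s+", "_", labels)
  map <- tibble(original = labels, sanitized = clean)
  list(labels = clean, map = map, changed = any(clean != labels))
}

#' Export a supermatrix
#'
#' `export_phylip()` emits relaxed PHYLIP (name, two spaces, sequence);
#' `export_nexus()` a NEXUS file with DATA and SETS (charset) blocks;
#' `export_partitions_raxml()` RAxML-style lines `DNA, gene = start-end`.
#' Output is byte-stable for fixed input. Taxon labels containing whitespace
#' are sanitized to underscores; the mapping is attached as attribute
#' `label_map` (and a warning is raised).
#'
#' @param m A `concat_matrix`.
#' @param file Optional path to write to.
#' @return File content as a single string (invisibly when `file` is given).
#' @export
export_phylip <- function(m, file = NULL) {
  san <- sanitize_labels(m$seqs$taxon)
  if (san$changed) warn("taxon labels with whitespace sanitized; see attr 'label_map'")
  w <- max(nchar(san$labels))
  body <- sprintf("%-*s  %s", w, san$labels, m$seqs$sequence)
  txt <- paste0(sprintf("%d %d\n", nrow(m$seqs), nchar(m$seqs$sequence[1])),
                paste(body, collapse = "\n"), "\n")
  attr(txt, "label_map") <- san$map
  if (!is.null(file)) { cat(txt, file = file); return(invisible(txt)) }
  txt
}

#' @rdname export_phylip
#' @export
export_nexus <- function(m, file = NULL) {
  san <- sanitize_labels(m$seqs$taxon)
  if (san$changed) warn("taxon labels with whitespace sanitized; see attr 'label_map'")
  w <- max(nchar(san$labels))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m$seqs),
            nchar(m$seqs$sequence[1])),
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "  MATRIX",
    sprintf("    %-*s  %s", w, san$labels, m$seqs$sequence),
    "  ;",
    "END;",
    "BEGIN SETS;",
    sprintf("  CHARSET %s = %d-%d;", m$partitions$gene, m$partitions$start,
            m$partitions$end),
    "END;"
  )
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  attr(txt, "label_map") <- san$map
  if (!is.null(file)) { cat(txt, file = file); return(invisible(txt)) }
  txt
}

#' @rdname export_phylip
#' @export
export_partitions_raxml <- function(m, file = NULL) {
  txt <- paste0(paste(sprintf("DNA, %s = %d-%d", m$partitions$gene,
                              m$partitions$start, m$partitions$end),
                      collapse = "\n"), "\n")
  if (!is.null(file)) { cat(txt, file = file); return(invisible(txt)) }
  txt
}

#' Re-import a NEXUS supermatrix written by [export_nexus()]
#'
#' @param text NEXUS content (string or lines) or `file` a path.
#' @param file Optional path.
#' @return A `concat_matrix`.
#' @export
read_nexus_matrix <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  mi <- grep("^\\s*MATRIX\\s*$", text)
  if (length(mi) != 1) abort("no MATRIX block found")
  end <- grep("^\\s*;\\s*$", text)
  end <- end[end > mi][1]
  rows <- trimws(text[(mi + 1):(end - 1)])
  rows <- rows[rows != ""]
  parts <- strsplit(rows, "\\s+")
  taxa <- vapply(parts, `[[`, "", 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  cs <- regmatches(text, regexec("^\\s*CHARSET\\s+(\\S+)\\s*=\\s*([0-9]+)-([0-9]+);", text))
  cs <- cs[lengths(cs) == 4]
  partitions <- tibble(
    gene = vapply(cs, `[[`, "", 2),
    start = as.integer(vapply(cs, `[[`, "", 3)),
    end = as.integer(vapply(cs, `[[`, "", 4))
  )
  structure(list(seqs = tibble(taxon = taxa, sequence = seqs),
                 partitions = partitions),
            class = "concat_matrix")
}

#' Pairwise distance matrix from aligned sequences
#'
#' Uncorrected p-distances (`model = "raw"`) or Jukes-Cantor distances
#' (`model = "JC69"`) with pairwise deletion of non-ACGT sites, as a symmetric
#' matrix ready for [nj_tree()].
#'
#' @param x A `codon_alignment` or `concat_matrix`.
#' @param model `"raw"` or `"JC69"`.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
distance_matrix <- function(x, model = c("raw", "JC69")) {
  model <- match.arg(model)
  seqs <- if (inherits(x, "concat_matrix")) x$seqs else x
  bin <- ape::as.DNAbin(setNames(strsplit(tolower(seqs$sequence), "", fixed = TRUE),
                                 seqs$taxon))
  as.matrix(ape::dist.dna(bin, model = model, pairwise.deletion = TRUE))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Q criterion) on a symmetric, zero-diagonal
#' distance matrix with `n >= 3` taxa; negative input distances are an error.
#' The resulting tree is unrooted with one degree-3 multifurcation at the
#' join point; on an additive matrix it reproduces the generating topology
#' and branch lengths exactly.
#'
#' @param D Symmetric numeric matrix with taxon dimnames.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) abort("neighbor joining needs >= 3 taxa")
  if (any(D < 0)) abort("negative distances are not allowed")
  if (max(abs(D - t(D))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(diag(D) != 0)) abort("distance matrix must have a zero diagonal")
  ape::nj(D)
}

#' Monophyly of a taxon set on an outgroup-rooted tree
#'
#' The tree is rooted on `outgroup` (the first matching taxon when several
#' are supplied) and the named set is tested for forming a complete clade.
#'
#' @param tree An [ape::phylo] tree.
#' @param taxa Character vector of tip labels.
#' @param outgroup Tip label(s) to root on.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  missing <- setdiff(c(taxa, outgroup[1]), tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("taxa not in tree: %s", paste(missing, collapse = ", ")))
  }
  og <- intersect(outgroup, tree$tip.label)[1]
  rooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Robinson-Foulds distance between two trees
#'
#' Count of bipartitions present in one unrooted topology but not the other;
#' 0 iff the unrooted topologies agree, at most `2(n-3)` for binary trees.
#'
#' @param t1,t2 [ape::phylo] trees on the same tip set.
#' @return Integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees must share the same tip labels")
  }
  as.integer(round(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                                  method = "PH85")))
}
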