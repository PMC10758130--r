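# In-frame codon alignments and per-gene alignment statistics: site
# classification, transition/transversion counts and uncorrected p-distances.

#' Construct a codon alignment
#'
#' An equal-length, in-frame nucleotide alignment of one gene across taxa,
#' stored as a tibble with columns `taxon` and `sequence` (gaps `-`).
#'
#' @param taxa Character vector of taxon labels (unique).
#' @param sequences Character vector of aligned sequences, same length as
#'   `taxa`.
#' @param gene Gene symbol carried as an attribute.
#' @return A `codon_alignment` tibble.
#' @export
codon_alignment <- function(taxa, sequences, gene = NA_character_) {
  stopifnot(length(taxa) == length(sequences), !anyDuplicated(taxa))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    abort(sprintf("alignment rows differ in length: %s",
                  paste(unique(lens), collapse = ", ")))
  }
  out <- tibble(taxon = as.character(taxa), sequence = toupper(sequences))
  class(out) <- c("codon_alignment", class(out))
  attr(out, "gene") <- gene
  out
}

aln_gene <- function(aln) attr(aln, "gene") %||% NA_character_

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$taxon
  m
}

aln_from_matrix <- function(m, gene = NA_character_) {
  codon_alignment(rownames(m), unname(apply(m, 1, paste, collapse = "")), gene)
}

#' Read / write a gene alignment as FASTA
#'
#' @param file FASTA path.
#' @param gene Gene symbol to attach.
#' @return `read_alignment()` returns a `codon_alignment`;
#'   `write_alignment()` writes one and returns the path invisibly.
#' @export
read_alignment <- function(file, gene = NA_character_) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort(sprintf("%s: no FASTA headers", file))
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- sub("\\s.*$", "", taxa)
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  }, "")
  codon_alignment(taxa, gsub("\\s", "", seqs), gene)
}

#' @rdname read_alignment
#' @param aln A `codon_alignment`.
#' @export
write_alignment <- function(aln, file) {
  writeLines(paste0(">", aln$taxon, "\n", aln$sequence), file)
  invisible(file)
}

#' Build an alignment from extracted genes
#'
#' Extracts one gene from every record in coding orientation and assembles a
#' codon alignment. This only works when the extracted sequences are already
#' equal length (true for simulator output and for many congeneric
#' mitogenomes); unequal lengths raise an error directing the user to supply a
#' real alignment.
#'
#' @param records List of `mito_record` objects.
#' @param gene Gene symbol.
#' @param labels Taxon labels (default accessions).
#' @return A `codon_alignment`.
#' @export
alignment_from_records <- function(records, gene, labels = NULL) {
  seqs <- vapply(records, extract_gene, "", name = gene)
  labels <- labels %||% vapply(records, function(r) r$accession, "")
  if (length(unique(nchar(seqs))) != 1) {
    abort(sprintf(
      "gene %s: extracted lengths differ (%s); supply an externally aligned FASTA instead",
      gene, paste(unique(nchar(seqs)), collapse = ", ")))
  }
  codon_alignment(labels, seqs, gene)
}

#' Clean a codon alignment for divergence analysis
#'
#' Removes any trailing partial codon (the 1-2 nt remainder of an incomplete
#' stop), removes each row's terminal complete stop codon, and then deletes
#' every codon
#' column (triplet) containing a gap in any taxon, so the result is gap-free
#' and a multiple of 3. An internal stop codon surviving cleaning indicates a
#' frame problem and raises an error naming the taxon and codon index.
#'
#' @param aln A `codon_alignment`, in frame (length multiple of 3).
#' @return A cleaned `codon_alignment`.
#' @export
clean_alignment <- function(aln) {
  m <- aln_matrix(aln)
  if (ncol(m) %% 3 != 0) {
    # trailing partial codon: the 1-2 nt remainder of an incomplete stop
    m <- m[, seq_len(ncol(m) - ncol(m) %% 3), drop = FALSE]
  }
  stops <- mito_stop_codons()
  # blank each row's last non-gap codon if it is a complete stop
  n_codon <- ncol(m) / 3
  for (r in seq_len(nrow(m))) {
    for (ci in rev(seq_len(n_codon))) {
      cod <- m[r, (3 * ci - 2):(3 * ci)]
      if (all(cod == "-")) next
      if (paste(cod, collapse = "") %in% stops) {
        m[r, (3 * ci - 2):(3 * ci)] <- "-"
      }
      break
    }
  }
  # complete deletion at codon-column granularity
  keep <- vapply(seq_len(n_codon), function(ci) {
    !any(m[, (3 * ci - 2):(3 * ci), drop = FALSE] == "-")
  }, TRUE)
  m2 <- m[, rep(keep, each = 3), drop = FALSE]
  # internal stops remaining => frame problem
  if (ncol(m2) > 0) {
    for (r in seq_len(nrow(m2))) {
      cods <- substring(paste(m2[r, ], collapse = ""),
                        seq(1, ncol(m2), 3), seq(3, ncol(m2), 3))
      hit <- which(cods %in% stops)
      if (length(hit) > 0) {
        abort(sprintf("internal stop codon in taxon %s at codon %d after cleaning (check reading frame)",
                      rownames(m2)[r], hit[1]))
      }
    }
  }
  aln_from_matrix(m2, aln_gene(aln))
}

#' Classify alignment sites
#'
#' A site is *variable* if it shows >= 2 distinct nucleotide states,
#' *parsimony-informative* if >= 2 states are each present in >= 2 taxa, and a
#' *singleton* if variable but not informative. Percentages are over all
#' sites.
#'
#' @param aln A cleaned `codon_alignment` with >= 2 rows.
#' @return One-row tibble: `n_sites`, `n_variable`, `n_pis`, `n_singleton`,
#'   `pct_Vs`, `pct_Pis`, `pct_S`.
#' @export
classify_sites <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2) abort("site classification needs >= 2 sequences")
  stats_per_site <- apply(m, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    tb <- table(col)
    c(variable = length(tb) >= 2, pis = sum(tb >= 2) >= 2)
  })
  n_var <- sum(stats_per_site["variable", ])
  n_pis <- sum(stats_per_site["variable", ] & stats_per_site["pis", ])
  tibble(
    n_sites = ncol(m), n_variable = n_var, n_pis = n_pis,
    n_singleton = n_var - n_pis,
    pct_Vs = 100 * n_var / ncol(m), pct_Pis = 100 * n_pis / ncol(m),
    pct_S = 100 * (n_var - n_pis) / ncol(m)
  )
}

#' Pooled transition/transversion ratio
#'
#' Transitions (A<->G, C<->T) and transversions are counted over every site of
#' every unordered sequence pair (sites where either base is not A/C/G/T are
#' skipped); the ratio is the pooled count ratio. `NA` with a note when no
#' transversions were observed.
#'
#' @param aln A cleaned `codon_alignment` with >= 2 rows.
#' @return One-row tibble: `n_ts`, `n_tv`, `ts_tv`.
#' @export
ts_tv_ratio <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2) abort("ts/tv needs >= 2 sequences")
  pur <- c("A", "G")
  n_ts <- 0L; n_tv <- 0L
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      a <- m[i, ]; b <- m[j, ]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") & a != b
      if (!any(ok)) next
      ts <- (a[ok] %in% pur) == (b[ok] %in% pur)
      n_ts <- n_ts + sum(ts)
      n_tv <- n_tv + sum(!ts)
    }
  }
  if (n_tv == 0) {
    message("no transversions observed: ts/tv undefined")
    return(tibble(n_ts = n_ts, n_tv = 0L, ts_tv = NA_real_))
  }
  tibble(n_ts = n_ts, n_tv = n_tv, ts_tv = n_ts / n_tv)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences have an
#' unambiguous base (pairwise deletion). `NA` when no sites are comparable.
#'
#' @param a,b Equal-length aligned strings.
#' @return Numeric proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- seq_chars(toupper(a)); y <- seq_chars(toupper(b))
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    message("no comparable sites: p-distance undefined")
    return(NA_real_)
  }
  mean(x[ok] != y[ok])
}

#' Average uncorrected pairwise distance (Aupd)
#'
#' Mean [p_distance()] over all unordered pairs of rows.
#'
#' @param aln A `codon_alignment` with >= 2 rows.
#' @return Numeric in `[0, 1]`.
#' @export
aupd <- function(aln) {
  n <- nrow(aln)
  if (n < 2) abort("aupd needs >= 2 sequences")
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(p) p_distance(aln$sequence[p[1]],
                                              aln$sequence[p[2]])))
}
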