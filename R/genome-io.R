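# GenBank flat-file I/O and annotation audits for circular mitogenomes.
# Coordinates are 1-based inclusive throughout (GenBank convention); a feature
# with start > end wraps the circular origin.

#' Canonical mitochondrial gene-name table
#'
#' Maps the gene/product spellings found in GenBank deposits onto the canonical
#' symbols used throughout the package (`ND1..ND6`, `ND4L`, `COI..COIII`,
#' `ATP6`, `ATP8`, `Cyt b`, `12S`, `16S`, `tRNA-Xxx`, `CR`). Users can extend
#' it by passing extra rows to [parse_genbank()].
#'
#' @return Tibble with columns `synonym` (uppercased match key) and
#'   `canonical`.
#' @export
gene_name_table <- function() {
  syn <- c(
    "COX1" = "COI", "COXI" = "COI", "CO1" = "COI", "COI" = "COI",
    "COX2" = "COII", "COXII" = "COII", "CO2" = "COII", "COII" = "COII",
    "COX3" = "COIII", "COXIII" = "COIII", "CO3" = "COIII", "COIII" = "COIII",
    "CYTB" = "Cyt b", "COB" = "Cyt b", "CYT B" = "Cyt b",
    "ATP6" = "ATP6", "ATPASE6" = "ATP6", "ATP8" = "ATP8", "ATPASE8" = "ATP8",
    "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
    "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6",
    "ND1" = "ND1", "ND2" = "ND2", "ND3" = "ND3", "ND4" = "ND4",
    "ND4L" = "ND4L", "ND5" = "ND5", "ND6" = "ND6",
    "S-RRNA" = "12S", "12S RRNA" = "12S", "12S RIBOSOMAL RNA" = "12S",
    "RRNS" = "12S", "12S" = "12S", "SMALL SUBUNIT RIBOSOMAL RNA" = "12S",
    "L-RRNA" = "16S", "16S RRNA" = "16S", "16S RIBOSOMAL RNA" = "16S",
    "RRNL" = "16S", "16S" = "16S", "LARGE SUBUNIT RIBOSOMAL RNA" = "16S",
    "D-LOOP" = "CR", "CONTROL REGION" = "CR", "CR" = "CR"
  )
  tibble(synonym = names(syn), canonical = unname(syn))
}

canonical_gene_name <- function(raw, extra = NULL) {
  tab <- gene_name_table()
  if (!is.null(extra)) tab <- bind_rows(extra, tab)
  key <- toupper(trimws(raw))
  # tRNAs keep their tRNA-Xxx form (optionally with an anticodon/family tag)
  is_trna <- grepl("^TRNA[- ]", key)
  out <- tab$canonical[match(key, tab$synonym)]
  out[is_trna] <- sub("^TRNA[- ]", "tRNA-", raw[is_trna])
  ifelse(is.na(out) & !is_trna, raw, out)
}

new_mito_record <- function(accession, organism, sequence, is_circular,
                            features) {
  rec <- structure(
    list(
      accession = accession,
      organism = organism,
      sequence = sequence,
      length_bp = nchar(sequence),
      is_circular = is_circular,
      features = features
    ),
    class = "mito_record"
  )
  validate_mito_record(rec)
  rec
}

validate_mito_record <- function(rec) {
  stopifnot(inherits(rec, "mito_record"))
  if (rec$length_bp != nchar(rec$sequence)) {
    abort(sprintf("record %s: length_bp does not match sequence length",
                  rec$accession))
  }
  ft <- rec$features
  req <- c("name", "ftype", "start", "end", "strand", "codon_start")
  if (!all(req %in% names(ft))) {
    abort("features table must have columns name, ftype, start, end, strand, codon_start")
  }
  bad <- ft$start < 1 | ft$end < 1 | ft$start > rec$length_bp | ft$end > rec$length_bp
  if (any(bad)) {
    abort(sprintf("record %s: feature(s) %s outside [1, %d]",
                  rec$accession, paste(ft$name[bad], collapse = ", "),
                  rec$length_bp))
  }
  wrapped <- ft$start > ft$end
  if (any(wrapped) && !rec$is_circular) {
    abort(sprintf("record %s: wrapped feature %s on a non-circular record",
                  rec$accession, ft$name[wrapped][1]))
  }
  dup <- ft$name[ft$ftype %in% c("PCG", "rRNA") & duplicated(ft$name)]
  if (length(dup) > 0) {
    abort(sprintf("record %s: duplicated PCG/rRNA name(s): %s",
                  rec$accession, paste(unique(dup), collapse = ", ")))
  }
  if (any(ft$ftype == "PCG" & is.na(ft$codon_start))) {
    abort(sprintf("record %s: PCG feature without codon_start", rec$accession))
  }
  invisible(rec)
}

#' @export
print.mito_record <- function(x, ...) {
  cat(sprintf("<mito_record> %s  %s\n", x$accession, x$organism))
  cat(sprintf("  %s bp, %s, %d features (%d PCG, %d tRNA, %d rRNA, %d CR)\n",
              format(x$length_bp, big.mark = ","),
              if (x$is_circular) "circular" else "linear",
              nrow(x$features),
              sum(x$features$ftype == "PCG"),
              sum(x$features$ftype == "tRNA"),
              sum(x$features$ftype == "rRNA"),
              sum(x$features$ftype == "CR")))
  invisible(x)
}

# --- location strings -------------------------------------------------------

parse_location <- function(loc, feature_label) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  spans <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1L]]
  } else loc
  m <- regmatches(spans, regexec("^([0-9]+)\\.\\.([0-9]+)$", spans))
  single <- grepl("^[0-9]+$", spans)
  if (any(lengths(m) != 3 & !single)) {
    abort(sprintf("malformed coordinates for feature %s: '%s'",
                  feature_label, loc))
  }
  starts <- ifelse(single, as.integer(spans),
                   as.integer(vapply(m, function(z) z[2] %||% NA_character_, "")))
  ends <- ifelse(single, as.integer(spans),
                 as.integer(vapply(m, function(z) z[3] %||% NA_character_, "")))
  if (length(starts) > 2) {
    abort(sprintf("feature %s: join() with more than two spans not supported",
                  feature_label))
  }
  if (length(starts) == 2) {
    # wrap-around join(a..L, 1..b)
    if (ends[1] < starts[1] || starts[2] != 1L) {
      abort(sprintf("feature %s: non-contiguous join() location", feature_label))
    }
    list(start = starts[1], end = ends[2], strand = strand, wraps = TRUE)
  } else {
    list(start = starts[1], end = ends[1], strand = strand, wraps = FALSE)
  }
}

# --- parser -----------------------------------------------------------------

#' Parse GenBank flat-file records
#'
#' Reads one or more annotated mitogenome records from GenBank flat-file text.
#' CDS, tRNA, rRNA and D-loop/control-region features are mapped to canonical
#' gene symbols via [gene_name_table()]; any feature of those classes that
#' cannot be interpreted is reported with a warning, never silently dropped.
#'
#' @param text GenBank flat-file content as a single string or a character
#'   vector of lines. Ignored when `file` is given.
#' @param file Path to a `.gb` flat file.
#' @param extra_names Optional tibble with columns `synonym`, `canonical`
#'   prepended to the built-in synonym table.
#' @return List of `mito_record` objects.
#' @examples
#' gb <- write_genbank(simulate_mitogenomes(sim_config(seed = 1))$records[[1]])
#' rec <- parse_genbank(gb)[[1]]
#' rec
#' @export
parse_genbank <- function(text = NULL, file = NULL, extra_names = NULL) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  ends <- grep("^//\\s*$", text)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  if (length(ends) == 0) abort("no GenBank record terminator '//' found")
  purrr::map2(starts, ends,
              function(s, e) parse_genbank_one(text[s:e], extra_names))
}

parse_genbank_one <- function(lines, extra_names = NULL) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1) abort("expected exactly one LOCUS line per record")
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1L]]
  declared_len <- suppressWarnings(as.integer(locus[3]))
  is_circular <- any(tolower(locus) == "circular")

  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i) > 0) {
    strsplit(trimws(lines[acc_i[1]]), "\\s+")[[1L]][2]
  } else locus[2]

  org_i <- grep("^\\s+ORGANISM", lines)
  organism <- if (length(org_i) > 0) {
    trimws(sub("^\\s+ORGANISM\\s+", "", lines[org_i[1]]))
  } else NA_character_

  # sequence
  ori_i <- grep("^ORIGIN", lines)
  if (length(ori_i) != 1) abort(sprintf("record %s: no ORIGIN block", accession))
  seq_lines <- lines[(ori_i + 1):(length(lines) - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- validate_sequence(sequence, sprintf("record %s sequence", accession))
  if (!is.na(declared_len) && declared_len != nchar(sequence)) {
    abort(sprintf("record %s: LOCUS declares %d bp but ORIGIN has %d",
                  accession, declared_len, nchar(sequence)))
  }

  # feature table
  feat_i <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_i) == 1) {
    block <- lines[(feat_i + 1):(ori_i - 1)]
    key_lines <- grep("^ {5}\\S", block)
    bounds <- c(key_lines, length(block) + 1L)
    rows <- list()
    for (k in seq_along(key_lines)) {
      chunk <- block[key_lines[k]:(bounds[k + 1] - 1L)]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
      loc_txt <- trimws(sub("^ {5}\\S+\\s*", "", chunk[1]))
      quals <- paste(trimws(chunk[-1]), collapse = " ")
      getq <- function(q) {
        m <- regmatches(quals, regexec(sprintf('/%s="?([^"/]+)"?', q), quals))[[1L]]
        if (length(m) == 2) trimws(m[2]) else NA_character_
      }
      raw_name <- getq("gene") %||% NA_character_
      if (is.na(raw_name)) raw_name <- getq("product")
      note <- getq("note")
      ftype <- switch(key,
        CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
        `D-loop` = "CR",
        misc_feature = if (!is.na(note) && grepl("control region", note,
                                                 ignore.case = TRUE)) "CR" else NA_character_
      )
      if (is.na(ftype)) next
      if (ftype == "CR" && is.na(raw_name)) raw_name <- "CR"
      if (is.na(raw_name)) {
        warn(sprintf("record %s: %s feature at '%s' has no /gene or /product; kept as 'unnamed'",
                     accession, key, loc_txt))
        raw_name <- "unnamed"
      }
      loc <- parse_location(loc_txt, raw_name)
      cs <- suppressWarnings(as.integer(getq("codon_start")))
      anticodon <- getq("anticodon")
      rows[[length(rows) + 1L]] <- tibble(
        name = canonical_gene_name(raw_name, extra_names),
        ftype = ftype,
        start = loc$start, end = loc$end, strand = loc$strand,
        codon_start = if (ftype == "PCG") (cs %||% 1L) %|NA|% 1L else NA_integer_,
        anticodon = anticodon %||% NA_character_
      )
    }
    if (length(rows) > 0) features <- bind_rows(rows)
  }
  new_mito_record(accession, organism, sequence, is_circular, features)
}

`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

empty_features <- function() {
  tibble(name = character(), ftype = character(), start = integer(),
         end = integer(), strand = character(), codon_start = integer(),
         anticodon = character())
}

# --- writer -----------------------------------------------------------------

#' Write a mitogenome record as GenBank flat-file text
#'
#' Emits the subset of the flat-file format that [parse_genbank()] reads
#' (LOCUS, ACCESSION, ORGANISM, FEATURES, ORIGIN), so parse-write-parse is the
#' identity on the sequence and feature table.
#'
#' @param records A `mito_record` or list of them.
#' @param file Optional path; when given, text is written there.
#' @return The flat-file text as a single string (invisibly when `file` is
#'   given).
#' @export
write_genbank <- function(records, file = NULL) {
  if (inherits(records, "mito_record")) records <- list(records)
  txt <- paste(vapply(records, write_genbank_one, ""), collapse = "")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

write_genbank_one <- function(rec) {
  validate_mito_record(rec)
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s VRT",
            rec$accession, rec$length_bp,
            if (rec$is_circular) "circular" else "linear  "),
    sprintf("ACCESSION   %s", rec$accession),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", rec$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", rec$length_bp)
  )
  for (i in seq_len(nrow(rec$features))) {
    f <- rec$features[i, ]
    span <- if (f$start <= f$end) {
      sprintf("%d..%d", f$start, f$end)
    } else {
      sprintf("join(%d..%d,1..%d)", f$start, rec$length_bp, f$end)
    }
    loc <- if (f$strand == "-") sprintf("complement(%s)", span) else span
    key <- switch(f$ftype, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf('                     /gene="%s"', f$name))
    if (f$ftype == "PCG") {
      out <- c(out, sprintf("                     /codon_start=%d", f$codon_start))
    }
    if (!is.na(f$anticodon %||% NA)) {
      out <- c(out, sprintf('                     /anticodon="%s"', f$anticodon))
    }
  }
  out <- c(out, "ORIGIN")
  s <- rec$sequence
  pos <- seq(1, nchar(s), by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))))
  }
  paste0(paste(out, collapse = "\n"), "\n//\n")
}

# --- gene extraction --------------------------------------------------------

feature_sequence <- function(rec, start, end) {
  if (start <= end) return(substr(rec$sequence, start, end))
  if (!rec$is_circular) abort("wrapped feature on non-circular record")
  paste0(substr(rec$sequence, start, rec$length_bp),
         substr(rec$sequence, 1, end))
}

#' Extract a gene in coding orientation
#'
#' Returns the nucleotide sequence of a named feature. Minus-strand features
#' are reverse-complemented into coding orientation; protein-coding genes have
#' their `codon_start` offset applied; features wrapping the circular origin
#' are stitched across it.
#'
#' @param record A `mito_record`.
#' @param name Canonical gene symbol (see [gene_name_table()]).
#' @param apply_codon_start Drop `codon_start - 1` leading bases of PCGs
#'   (default `TRUE`).
#' @return Nucleotide string in coding orientation.
#' @export
extract_gene <- function(record, name, apply_codon_start = TRUE) {
  ft <- record$features
  i <- which(ft$name == name)
  if (length(i) == 0) {
    abort(sprintf("gene '%s' not found in %s; available: %s",
                  name, record$accession, paste(ft$name, collapse = ", ")))
  }
  i <- i[1]
  s <- feature_sequence(record, ft$start[i], ft$end[i])
  if (ft$strand[i] == "-") s <- revcomp(s)
  if (apply_codon_start && ft$ftype[i] == "PCG" && !is.na(ft$codon_start[i]) &&
      ft$codon_start[i] > 1) {
    s <- substr(s, ft$codon_start[i], nchar(s))
  }
  s
}

feature_length <- function(rec, i) {
  ft <- rec$features
  if (ft$start[i] <= ft$end[i]) ft$end[i] - ft$start[i] + 1L
  else rec$length_bp - ft$start[i] + 1L + ft$end[i]
}

# --- audits -----------------------------------------------------------------

#' Intergenic spacers and overlaps
#'
#' One row per adjacent feature pair in genomic order; positive `length_bp` is
#' a gap, negative an overlap. For circular records the closing pair (last
#' feature back to the first across the origin) is included.
#'
#' @param record A `mito_record` with at least two features.
#' @return Tibble with columns `left_gene`, `right_gene`, `length_bp`.
#' @export
intergenic_spacers <- function(record) {
  ft <- record$features |> arrange(.data$start)
  if (nrow(ft) < 2) abort("need at least two features to compute spacers")
  n <- nrow(ft)
  lens <- vapply(order(record$features$start), function(i) feature_length(record, i), 1L)
  ends_lin <- ft$start + lens - 1L # may exceed length_bp for wrapped features
  out <- tibble(
    left_gene = ft$name[-n],
    right_gene = ft$name[-1],
    length_bp = as.integer(ft$start[-1] - ends_lin[-n] - 1L)
  )
  if (record$is_circular) {
    closing <- as.integer(record$length_bp - ends_lin[n] + ft$start[1] - 1L)
    out <- bind_rows(out, tibble(left_gene = ft$name[n],
                                 right_gene = ft$name[1],
                                 length_bp = closing))
  }
  out
}

#' Gene order of a record
#'
#' Features ordered by start coordinate from the canonical origin, with
#' strand. Two records are comparable by exact equality of this table.
#'
#' @param record A `mito_record`.
#' @return Tibble with columns `name`, `strand`, `start`, `end`.
#' @export
gene_order <- function(record) {
  record$features |>
    arrange(.data$start) |>
    select("name", "strand", "start", "end")
}

#' @export
tidy.mito_record <- function(x, ...) {
  x$features |> mutate(accession = x$accession, .before = 1)
}

#' @export
glance.mito_record <- function(x, ...) {
  comp <- base_composition(x$sequence)
  tibble(
    accession = x$accession, organism = x$organism, length_bp = x$length_bp,
    is_circular = x$is_circular, n_features = nrow(x$features),
    pct_AT = comp$pct_AT, at_skew = comp$at_skew, gc_skew = comp$gc_skew
  )
}
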