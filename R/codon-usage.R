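# Start/stop codon usage and relative synonymous codon usage (RSCU) of the 13
# mitochondrial protein-coding genes under the vertebrate mitochondrial code.

PCG_NAMES <- c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
               "ND3", "ND4L", "ND4", "ND5", "Cyt b", "ND6")

#' Split a coding sequence into codons
#'
#' Codons are read from the `codon_start` frame offset; a trailing 1-2 nt tail
#' is returned as `remainder` (the candidate incomplete stop codon).
#'
#' @param cds Nucleotide string in coding orientation.
#' @param codon_start Reading-frame offset in `1:3` (GenBank convention;
#'   bases before the offset are discarded).
#' @return List with `codons` (character vector) and `remainder` (string,
#'   possibly empty).
#' @examples
#' codon_split("ATGAAAT") # codons ATG, AAA; remainder "T"
#' @export
codon_split <- function(cds, codon_start = 1) {
  stopifnot(codon_start %in% 1:3)
  s <- substr(cds, codon_start, nchar(cds))
  n <- nchar(s)
  if (n < 3) abort("coding sequence shorter than one codon")
  n_full <- n %/% 3
  starts <- seq(1, by = 3, length.out = n_full)
  list(
    codons = substring(s, starts, starts + 2),
    remainder = if (n %% 3 > 0) substr(s, 3 * n_full + 1, n) else ""
  )
}

#' Start and stop codon usage across records
#'
#' For every protein-coding gene of every record, the first codon is recorded
#' as the start and the terminal codon (or 1-2 nt remainder, padded with `-`
#' and reported as `T--`/`TA-`) as the stop. Annotated terminal codons are recorded verbatim
#' without re-translation, so annotation artefacts (e.g. an `AAA` terminal
#' codon) are preserved and flagged rather than silently corrected. Starts
#' outside the five conventional vertebrate mitochondrial initiators trigger a
#' warning but are still tallied.
#'
#' @param records List of `mito_record` objects (or one record).
#' @param genes Gene symbols to inspect (default the 13 PCGs).
#' @return Tibble with columns `accession`, `gene`, `start_codon`,
#'   `stop_codon`, `stop_class` (`complete`, `TA-` or `T--`) and
#'   `stop_is_canonical`.
#' @export
start_stop_usage <- function(records, genes = PCG_NAMES) {
  if (inherits(records, "mito_record")) records <- list(records)
  rows <- purrr::map(records, function(rec) {
    present <- intersect(genes, rec$features$name)
    purrr::map(present, function(g) {
      cs <- codon_split(extract_gene(rec, g))
      if (cs$remainder == "") {
        stop_codon <- cs$codons[length(cs$codons)]
        stop_class <- "complete"
      } else {
        stop_codon <- paste0(cs$remainder, strrep("-", 3 - nchar(cs$remainder)))
        stop_class <- stop_codon
      }
      tibble(accession = rec$accession, gene = g,
             start_codon = cs$codons[1],
             stop_codon = stop_codon, stop_class = stop_class,
             stop_is_canonical = stop_class != "complete" ||
               stop_codon %in% mito_stop_codons())
    }) |> bind_rows()
  }) |> bind_rows()
  odd <- unique(rows$start_codon[!rows$start_codon %in% mito_start_codons()])
  if (length(odd) > 0) {
    warn(sprintf("non-conventional start codon(s) observed: %s",
                 paste(odd, collapse = ", ")))
  }
  rows
}

#' Aggregate start/stop codon frequencies
#'
#' @param usage A [start_stop_usage()] table.
#' @return Tibble with columns `kind` (`start`/`stop`), `codon`, `count`,
#'   `pct` (percentage within kind, over all genes x records).
#' @export
start_stop_summary <- function(usage) {
  bind_rows(
    usage |> dplyr::count(codon = .data$start_codon, name = "count") |>
      mutate(kind = "start"),
    usage |> dplyr::count(codon = .data$stop_codon, name = "count") |>
      mutate(kind = "stop")
  ) |>
    group_by(.data$kind) |>
    mutate(pct = 100 * .data$count / sum(.data$count)) |>
    ungroup() |>
    select("kind", "codon", "count", "pct") |>
    arrange(.data$kind, dplyr::desc(.data$count))
}

#' Codon counts over protein-coding genes
#'
#' Counts in-frame codons of the named genes. By default all 13 PCGs are
#' pooled per record (one table per species); stop codons -- the terminal one
#' and any annotated in-frame stop -- are tracked in separate rows flagged
#' `is_stop` and excluded from RSCU.
#'
#' @param records List of `mito_record` objects (or one record).
#' @param genes Gene symbols (default the 13 PCGs).
#' @param per_gene Keep a `gene` column instead of pooling (default `FALSE`).
#' @param drop_terminal_stop Exclude each gene's terminal complete stop codon
#'   (default `TRUE`; incomplete-stop remainders are never counted).
#' @return Tibble with columns `accession` (, `gene`), `codon`, `amino_acid`,
#'   `is_stop`, `count`.
#' @export
count_codons <- function(records, genes = PCG_NAMES, per_gene = FALSE,
                         drop_terminal_stop = TRUE) {
  if (inherits(records, "mito_record")) records <- list(records)
  code <- mito_genetic_code()
  rows <- purrr::map(records, function(rec) {
    present <- intersect(genes, rec$features$name)
    purrr::map(present, function(g) {
      cs <- codon_split(extract_gene(rec, g))
      codons <- cs$codons
      if (drop_terminal_stop && cs$remainder == "" &&
          code[[codons[length(codons)]]] == "*") {
        codons <- codons[-length(codons)]
      }
      tibble(accession = rec$accession, gene = g, codon = codons)
    }) |> bind_rows()
  }) |> bind_rows()
  keys <- if (per_gene) c("accession", "gene", "codon") else c("accession", "codon")
  rows |>
    dplyr::count(dplyr::pick(dplyr::all_of(keys)), name = "count") |>
    mutate(amino_acid = unname(code[.data$codon]),
           is_stop = .data$amino_acid == "*") |>
    select(dplyr::all_of(setdiff(keys, "codon")), "codon", "amino_acid",
           "is_stop", "count")
}

#' Relative synonymous codon usage
#'
#' RSCU of codon `c` with `k` synonymous codons and family total `X` is
#' `count(c) * k / X`: the observed count relative to the expectation under
#' uniform usage within the synonymous family. Families with zero total get
#' `NA`. Stop codons are excluded. Codons absent from `counts` are filled in
#' with count 0 so every sense codon appears.
#'
#' @param counts A [count_codons()] table (optionally grouped by `accession`;
#'   RSCU is computed within each accession present).
#' @return Tibble with columns `accession`, `codon`, `amino_acid`,
#'   `family_size`, `count`, `rscu`.
#' @export
rscu <- function(counts) {
  fams <- synonymous_families()
  counts <- counts |> filter(!.data$is_stop)
  accs <- unique(counts$accession)
  tidyr::expand_grid(accession = accs, fams) |>
    left_join(counts |> select("accession", "codon", "count"),
              by = c("accession", "codon")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    group_by(.data$accession, .data$amino_acid) |>
    mutate(rscu = .data$count * .data$family_size /
             dplyr::na_if(sum(.data$count), 0L)) |>
    ungroup() |>
    arrange(.data$accession, .data$amino_acid, .data$codon)
}

#' RSCU bar plot
#'
#' Per-amino-acid stacked codon usage in the style of standard mitogenome
#' codon-usage figures.
#'
#' @param rscu_tbl An [rscu()] table (one accession, or faceted by accession).
#' @return A ggplot object.
#' @export
plot_rscu <- function(rscu_tbl) {
  p <- ggplot2::ggplot(rscu_tbl,
                       ggplot2::aes(x = .data$amino_acid, y = .data$rscu,
                                    fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1,
                      show.legend = FALSE) +
    ggplot2::labs(x = "Amino acid", y = "RSCU",
                  title = "Relative synonymous codon usage") +
    ggplot2::theme_minimal()
  if (length(unique(rscu_tbl$accession)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$accession))
  }
  p
}

#' Start/stop usage plot
#'
#' @param summary_tbl A [start_stop_summary()] table.
#' @return A ggplot object with one panel for starts and one for stops.
#' @export
plot_start_stop <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = stats::reorder(.data$codon, -.data$pct),
                               y = .data$pct)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_x") +
    ggplot2::labs(x = "Codon", y = "Share of genes (%)",
                  title = "Start and stop codon usage") +
    ggplot2::theme_minimal()
}
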