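# Base composition and strand-asymmetry (skew) statistics.
# AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C); both computed on
# whatever strand the sequence is given in, so sign conventions follow the
# strand choice (deposited plus strand for whole genomes, coding orientation
# for per-gene values).

#' Base composition and skew of a nucleotide sequence
#'
#' Exact base counts plus AT%, AT skew `(A - T)/(A + T)` and GC skew
#' `(G - C)/(G + C)`. `N` bases are counted in `n_N` but excluded from all
#' percentages and skews. A skew whose denominator is zero is `NA`.
#'
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @return One-row tibble with columns `n_A`, `n_C`, `n_G`, `n_T`, `n_N`,
#'   `pct_A`, `pct_C`, `pct_G`, `pct_T`, `pct_AT`, `at_skew`, `gc_skew`
#'   (unrounded).
#' @examples
#' base_composition("AAAT")$at_skew # 0.5
#' @export
base_composition <- function(seq) {
  seq <- validate_sequence(seq)
  ch <- seq_chars(seq)
  cnt <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  tb <- table(factor(ch, levels = names(cnt)))
  cnt[names(tb)] <- as.numeric(tb)
  tot <- sum(cnt[c("A", "C", "G", "T")])
  if (tot == 0) {
    warn("empty or all-N sequence: composition statistics are NA")
    return(tibble(n_A = 0L, n_C = 0L, n_G = 0L, n_T = 0L, n_N = as.integer(cnt["N"]),
                  pct_A = NA_real_, pct_C = NA_real_, pct_G = NA_real_,
                  pct_T = NA_real_, pct_AT = NA_real_,
                  at_skew = NA_real_, gc_skew = NA_real_))
  }
  at <- cnt["A"] + cnt["T"]
  gc <- cnt["G"] + cnt["C"]
  tibble(
    n_A = as.integer(cnt["A"]), n_C = as.integer(cnt["C"]),
    n_G = as.integer(cnt["G"]), n_T = as.integer(cnt["T"]),
    n_N = as.integer(cnt["N"]),
    pct_A = unname(100 * cnt["A"] / tot), pct_C = unname(100 * cnt["C"] / tot),
    pct_G = unname(100 * cnt["G"] / tot), pct_T = unname(100 * cnt["T"] / tot),
    pct_AT = unname(100 * at / tot),
    at_skew = if (at > 0) unname((cnt["A"] - cnt["T"]) / at) else NA_real_,
    gc_skew = if (gc > 0) unname((cnt["G"] - cnt["C"]) / gc) else NA_real_
  )
}

#' Composition by region class
#'
#' Composition of the whole genome and of the concatenated protein-coding
#' genes, tRNAs, rRNAs and control region of one record. Gene regions are
#' concatenations of strand-corrected (coding-orientation) extractions; the
#' `whole` row is computed on the deposited plus strand. Region classes absent
#' from the feature table are omitted with a message.
#'
#' @param record A `mito_record`.
#' @return Tibble with a `region` column (`whole`, `PCGs`, `tRNAs`, `rRNAs`,
#'   `CR`) followed by [base_composition()] columns.
#' @export
region_composition <- function(record) {
  classes <- c(PCGs = "PCG", tRNAs = "tRNA", rRNAs = "rRNA", CR = "CR")
  rows <- list(mutate(base_composition(record$sequence), region = "whole",
                      .before = 1))
  for (k in names(classes)) {
    ft <- record$features |> filter(.data$ftype == classes[[k]])
    if (nrow(ft) == 0) {
      message(sprintf("record %s: no %s features; region row omitted",
                      record$accession, k))
      next
    }
    seqs <- vapply(ft$name, function(nm) extract_gene(record, nm,
                                                      apply_codon_start = FALSE), "")
    rows[[length(rows) + 1L]] <-
      mutate(base_composition(paste(seqs, collapse = "")), region = k,
             .before = 1)
  }
  bind_rows(rows)
}

#' Per-genome composition table with summary rows
#'
#' One row per record (accession, organism, length, AT%, AT skew, GC skew plus
#' per-base percentages), rounded half-up to `digits` decimals for display;
#' summary rows (`(mean)`, `(sd)`) are computed from the unrounded values and
#' then rounded. Raw unrounded values are kept in the `raw` attribute.
#'
#' @param records List of `mito_record` objects.
#' @param digits Decimals for display rounding (default 2, table convention).
#' @param summary Append mean/SD rows (default `TRUE`).
#' @return Tibble with columns `accession`, `organism`, `length_bp`, `pct_A`,
#'   `pct_C`, `pct_G`, `pct_T`, `pct_AT`, `at_skew`, `gc_skew`.
#' @export
composition_table <- function(records, digits = 2, summary = TRUE) {
  if (inherits(records, "mito_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  raw <- purrr::map(records, function(r) {
    base_composition(r$sequence) |>
      mutate(accession = r$accession, organism = r$organism,
             length_bp = r$length_bp, .before = 1)
  }) |> bind_rows() |>
    select("accession", "organism", "length_bp", "pct_A", "pct_C", "pct_G",
           "pct_T", "pct_AT", "at_skew", "gc_skew")
  num_cols <- c("pct_A", "pct_C", "pct_G", "pct_T", "pct_AT", "at_skew", "gc_skew")
  out <- raw |> mutate(across(dplyr::all_of(num_cols), ~round_half_up(.x, digits)))
  if (summary) {
    mean_row <- raw |> summarise(across(dplyr::all_of(num_cols), mean)) |>
      mutate(accession = "(mean)", organism = NA_character_,
             length_bp = NA_integer_, .before = 1)
    sd_row <- raw |> summarise(across(dplyr::all_of(num_cols),
                                      ~ if (n() > 1) sd(.x) else 0)) |>
      mutate(accession = "(sd)", organism = NA_character_,
             length_bp = NA_integer_, .before = 1)
    out <- bind_rows(out,
                     mutate(mean_row, across(dplyr::all_of(num_cols),
                                             ~round_half_up(.x, digits))),
                     mutate(sd_row, across(dplyr::all_of(num_cols),
                                           ~round_half_up(.x, digits))))
  }
  attr(out, "raw") <- raw
  out
}

#' Composition/skew overview plot
#'
#' AT% against AT skew per genome, point size by GC skew magnitude; a quick
#' visual check of strand-asymmetry spread across a genome set.
#'
#' @param comp A [composition_table()] result.
#' @return A ggplot object.
#' @export
plot_composition <- function(comp) {
  df <- comp |> filter(!.data$accession %in% c("(mean)", "(sd)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_AT, y = .data$at_skew,
                                   label = .data$accession)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$gc_skew)),
                        colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "A+T content (%)", y = "AT skew",
                  size = "|GC skew|",
                  title = "Whole-genome composition and strand asymmetry") +
    ggplot2::theme_minimal()
}
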