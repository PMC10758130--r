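# Vertebrate mitochondrial genetic code (NCBI translation table 2) and the
# codon-level lookup tables built on it. The code differs from the standard
# nuclear code at four codons: AGA/AGG are stops, ATA is Met, TGA is Trp.

MITO_BASES <- c("T", "C", "A", "G")

# amino acids in TCAG-major codon order (transl_table=2)
MITO_AA_STRING <- "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG"

#' The 64 codons in canonical TCAG order
#' @return Character vector of 64 codons.
#' @keywords internal
mito_codons <- function() {
  if (is.null(.mc_cache$codons)) {
    g <- expand.grid(b3 = MITO_BASES, b2 = MITO_BASES, b1 = MITO_BASES,
                     stringsAsFactors = FALSE)
    .mc_cache$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .mc_cache$codons
}

#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map for NCBI translation table 2 (vertebrate
#' mitochondrial), the code under which all 13 mitochondrial protein-coding
#' genes are read. Stops are `"*"` (TAA, TAG, AGA, AGG).
#'
#' @return Named character vector of length 64: one-letter amino acids named
#'   by codon.
#' @examples
#' mito_genetic_code()[c("ATA", "TGA", "AGA")] # "M" "W" "*"
#' @export
mito_genetic_code <- function() {
  if (is.null(.mc_cache$code)) {
    .mc_cache$code <- setNames(
      strsplit(MITO_AA_STRING, "", fixed = TRUE)[[1L]], mito_codons()
    )
  }
  .mc_cache$code
}

#' Stop and start codons of the vertebrate mitochondrial code
#'
#' `mito_stop_codons()` returns the four stops of translation table 2;
#' `mito_start_codons()` returns the five initiation codons observed in
#' vertebrate mitochondrial protein-coding genes.
#'
#' @return Character vector of codons.
#' @export
mito_stop_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code == "*"]
}

#' @rdname mito_stop_codons
#' @export
mito_start_codons <- function() c("ATG", "GTG", "ATA", "ATC", "ATT")

#' Translate a coding sequence under the vertebrate mitochondrial code
#'
#' @param codons Character vector of codons (3-nt strings).
#' @return Character vector of one-letter amino acids; `"*"` for stops, `NA`
#'   for codons containing non-ACGT characters.
#' @export
translate_mito <- function(codons) {
  unname(mito_genetic_code()[codons])
}

# integer codon index 1..64 (NA for codons with non-ACGT characters)
codon_index <- function(codons) {
  match(codons, mito_codons())
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

# Single-nucleotide neighbourhood of every codon: for codon i, 9 mutant codons
# (3 positions x 3 alternative bases) with their index, whether the change is a
# transition, whether it is synonymous, and whether the mutant is a stop.
codon_neighbors <- function() {
  if (!is.null(.mc_cache$nb)) return(.mc_cache$nb)
  codons <- mito_codons()
  aa <- mito_genetic_code()
  idx <- matrix(NA_integer_, 64, 9)
  ts <- syn <- stp <- matrix(FALSE, 64, 9)
  pos <- matrix(0L, 64, 9)
  for (i in seq_len(64)) {
    cc <- seq_chars(codons[i])
    k <- 0L
    for (p in 1:3) {
      for (b in setdiff(MITO_BASES, cc[p])) {
        k <- k + 1L
        mut <- cc
        mut[p] <- b
        mutc <- paste(mut, collapse = "")
        j <- match(mutc, codons)
        idx[i, k] <- j
        pos[i, k] <- p
        ts[i, k] <- is_transition(cc[p], b)
        syn[i, k] <- aa[[i]] == aa[[j]]
        stp[i, k] <- aa[[j]] == "*"
      }
    }
  }
  .mc_cache$nb <- list(idx = idx, pos = pos, ts = ts, syn = syn, stop = stp)
  .mc_cache$nb
}

#' Synonymous amino-acid families of the mitochondrial code
#'
#' @return Tibble with columns `codon`, `amino_acid`, `family_size` for the 60
#'   sense codons of translation table 2 (the four stops TAA/TAG/AGA/AGG are
#'   excluded).
#' @keywords internal
synonymous_families <- function() {
  code <- mito_genetic_code()
  tibble(codon = names(code), amino_acid = unname(code)) |>
    filter(.data$amino_acid != "*") |>
    group_by(.data$amino_acid) |>
    mutate(family_size = n()) |>
    ungroup()
}
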