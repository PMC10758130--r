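# programmatic fixtures shared across test files

# minimal hand-built record: two plus-strand genes with a known spacer
make_toy_record <- function(seq = NULL, features = NULL, circular = TRUE,
                            accession = "TOY1") {
  seq <- seq %||% paste0(
    "ATGAAACCCGGGTAA",        # 1..15  PCG "ND1"
    "TTTTT",                  # 16..20 spacer (5 bp)
    strrep("ACGT", 5)         # 21..40 tRNA
  )
  features <- features %||% tibble::tibble(
    name = c("ND1", "tRNA-Phe"),
    ftype = c("PCG", "tRNA"),
    start = c(1L, 21L), end = c(15L, 40L),
    strand = c("+", "+"),
    codon_start = c(1L, NA_integer_),
    anticodon = NA_character_
  )
  mitocomp:::new_mito_record(accession, "Toy organism", seq, circular, features)
}

`%||%` <- rlang::`%||%`

# deterministic random CDS pair (gap-free, in-frame, stop-free) for NG tests
random_cds_pair <- function(n_codons, n_diff_codons, seed) {
  set.seed(seed)
  sense <- setdiff(mitocomp::mito_genetic_code(), "*")
  sense_codons <- names(mitocomp::mito_genetic_code())[
    mitocomp::mito_genetic_code() != "*"]
  a <- sample(sense_codons, n_codons, replace = TRUE)
  b <- a
  idx <- sample(n_codons, min(n_diff_codons, n_codons))
  b[idx] <- sample(sense_codons, length(idx), replace = TRUE)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# small cached fixture simulation reused by several files
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mitocomp::fixture_set(seed = 101L)
    cache
  }
})

pcg_names <- function() c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6",
                          "COIII", "ND3", "ND4L", "ND4", "ND5", "Cyt b", "ND6")

fixture_alignments <- function(sim = fixture_sim(), genes = pcg_names()) {
  setNames(
    lapply(genes, function(g) {
      mitocomp::alignment_from_records(unname(sim$records), g,
                                       labels = names(sim$records))
    }),
    genes
  )
}
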