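test_that("GenBank fixture parses with canonical names, strands and coordinates", {
  f <- system.file("extdata", "toy_synthetic.gb", package = "mitocomp")
  rec <- parse_genbank(file = f)[[1]]
  expect_s3_class(rec, "mito_record")
  expect_identical(rec$accession, "TOYSYN1")
  expect_identical(rec$length_bp, 120L)
  expect_true(rec$is_circular)
  ft <- rec$features
  expect_identical(ft$name, c("COI", "tRNA-Gln", "12S", "CR"))
  expect_identical(ft$ftype, c("PCG", "tRNA", "rRNA", "CR"))
  # complement(20..40) keeps GenBank coordinates with a minus strand
  expect_identical(ft$start[2], 20L)
  expect_identical(ft$end[2], 40L)
  expect_identical(ft$strand[2], "-")
})

test_that("parse -> write -> parse is the identity on sequence and features", {
  f <- system.file("extdata", "toy_synthetic.gb", package = "mitocomp")
  r1 <- parse_genbank(file = f)[[1]]
  r2 <- parse_genbank(write_genbank(r1))[[1]]
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(as.data.frame(r1$features), as.data.frame(r2$features))
  # and on a full simulated genome
  s1 <- fixture_sim()$records[[1]]
  s2 <- parse_genbank(write_genbank(s1))[[1]]
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(as.data.frame(s1$features), as.data.frame(s2$features))
})

test_that("parser rejects malformed coordinates and length mismatches", {
  f <- system.file("extdata", "toy_synthetic.gb", package = "mitocomp")
  txt <- readLines(f)
  bad <- sub("1\\.\\.15", "1..xx", txt)
  expect_error(parse_genbank(bad), "malformed coordinates")
  bad2 <- sub("120 bp", "999 bp", txt)
  expect_error(parse_genbank(bad2), "declares 999")
  bad3 <- sub("atgaaacccg", "atgaaacccr", txt)
  expect_error(parse_genbank(bad3), "unsupported characters")
})

test_that("extract_gene honors strand, codon_start and circular wrap", {
  rec <- make_toy_record()
  expect_identical(extract_gene(rec, "ND1"), "ATGAAACCCGGGTAA")
  # minus strand: coding orientation is the reverse complement
  rec2 <- make_toy_record(
    seq = paste0("TTTCAT", strrep("A", 24)),
    features = tibble::tibble(
      name = "ND1", ftype = "PCG", start = 1L, end = 6L, strand = "-",
      codon_start = 1L, anticodon = NA_character_
    )
  )
  expect_identical(extract_gene(rec2, "ND1"), "ATGAAA")
  # revcomp involution: extracting twice through the complement returns start
  expect_identical(revcomp(revcomp(extract_gene(rec2, "ND1"))),
                   extract_gene(rec2, "ND1"))
  # codon_start offset drops leading bases
  rec3 <- make_toy_record(
    seq = paste0("GGATGAAATAA", strrep("C", 19)),
    features = tibble::tibble(
      name = "ND1", ftype = "PCG", start = 1L, end = 11L, strand = "+",
      codon_start = 3L, anticodon = NA_character_
    )
  )
  expect_identical(extract_gene(rec3, "ND1"), "ATGAAATAA")
  expect_error(extract_gene(rec, "ND9"), "not found")
})

test_that("origin-wrapping features match the rotation oracle", {
  set.seed(31)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  for (case in list(c(50L, 10L), c(55L, 3L), c(58L, 20L))) {
    rec <- make_toy_record(
      seq = seq,
      features = tibble::tibble(
        name = c("tRNA-Phe", "tRNA-Val"), ftype = "tRNA",
        start = c(case[1], 30L), end = c(case[2], 40L), strand = "+",
        codon_start = NA_integer_, anticodon = NA_character_
      )
    )
    expect_identical(extract_gene(rec, "tRNA-Phe"),
                     oracle_rotated_slice(seq, case[1], case[2]))
  }
})

test_that("intergenic spacers report gaps and overlaps with 1-based arithmetic", {
  mk <- function(s1, e1, s2, e2, len = 40L) {
    make_toy_record(
      seq = strrep("ACGT", len / 4),
      features = tibble::tibble(
        name = c("tRNA-Phe", "tRNA-Val"), ftype = "tRNA",
        start = c(s1, s2), end = c(e1, e2), strand = "+",
        codon_start = NA_integer_, anticodon = NA_character_
      ),
      circular = FALSE
    )
  }
  expect_identical(intergenic_spacers(mk(1L, 10L, 12L, 20L))$length_bp[1], 1L)
  expect_identical(intergenic_spacers(mk(1L, 10L, 8L, 20L))$length_bp[1], -3L)
  expect_identical(intergenic_spacers(mk(1L, 10L, 11L, 20L))$length_bp[1], 0L)
  expect_error(intergenic_spacers(make_toy_record(
    seq = "ACGTACGT",
    features = tibble::tibble(name = "tRNA-Phe", ftype = "tRNA", start = 1L,
                              end = 4L, strand = "+",
                              codon_start = NA_integer_,
                              anticodon = NA_character_))),
    "at least two")
})

test_that("simulator spacer truth is recovered, including the longest gap", {
  sim <- fixture_sim()
  sp_truth <- sim$truth$spacers
  for (rec in sim$records[1:3]) {
    sp <- intergenic_spacers(rec)
    expect_identical(sp$length_bp, sp_truth$length_bp)
    expect_identical(max(sp$length_bp), 23L)
    longest <- sp[which.max(sp$length_bp), ]
    expect_identical(longest$left_gene, "tRNA-Tyr")
  }
  # features + spacers tile the circular genome exactly
  rec <- sim$records[[1]]
  feat_len <- sum(vapply(seq_len(nrow(rec$features)),
                         function(i) mitocomp:::feature_length(rec, i), 1L))
  expect_identical(feat_len + sum(intergenic_spacers(rec)$length_bp),
                   rec$length_bp)
})

test_that("gene order comparisons localize differences", {
  sim <- fixture_sim()
  o1 <- gene_order(sim$records[[1]])
  o2 <- gene_order(sim$records[[2]])
  expect_identical(o1[, c("name", "strand")], o2[, c("name", "strand")])
  expect_identical(sum(o1$strand == "-"), 9L) # ND6 + 8 tRNAs on minus strand
  # swap two tRNAs in a copy: inequality localized to those positions
  rec <- make_toy_record(
    seq = strrep("ACGT", 10),
    features = tibble::tibble(
      name = c("tRNA-Phe", "tRNA-Val", "tRNA-Ile"), ftype = "tRNA",
      start = c(1L, 11L, 21L), end = c(8L, 18L, 28L), strand = "+",
      codon_start = NA_integer_, anticodon = NA_character_))
  rec_sw <- make_toy_record(
    seq = strrep("ACGT", 10),
    features = tibble::tibble(
      name = c("tRNA-Val", "tRNA-Phe", "tRNA-Ile"), ftype = "tRNA",
      start = c(1L, 11L, 21L), end = c(8L, 18L, 28L), strand = "+",
      codon_start = NA_integer_, anticodon = NA_character_))
  diff_pos <- which(gene_order(rec)$name != gene_order(rec_sw)$name)
  expect_identical(diff_pos, c(1L, 2L))
})

test_that("record validation rejects inconsistent features", {
  expect_error(make_toy_record(
    seq = "ACGTACGT",
    features = tibble::tibble(name = "ND1", ftype = "PCG", start = 1L,
                              end = 20L, strand = "+", codon_start = 1L,
                              anticodon = NA_character_)),
    "outside")
  expect_error(make_toy_record(
    seq = "ACGTACGT",
    features = tibble::tibble(name = "ND1", ftype = "PCG", start = 1L,
                              end = 6L, strand = "+",
                              codon_start = NA_integer_,
                              anticodon = NA_character_)),
    "codon_start")
})
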