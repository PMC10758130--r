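test_that("clean_alignment strips stops, gapped codon columns and remainders", {
  # all rows ending in TAA: 3 nt shorter, otherwise identical
  aln <- codon_alignment(c("a", "b"), c("ATGAAACCCTAA", "ATGAAACCGTAA"), "g")
  cl <- clean_alignment(aln)
  expect_identical(cl$sequence, c("ATGAAACCC", "ATGAAACCG"))
  # a 3-nt gap in one row removes that codon column from all rows
  aln2 <- codon_alignment(c("a", "b"), c("ATGAAACCCTAA", "ATG---CCGTAA"), "g")
  expect_identical(clean_alignment(aln2)$sequence, c("ATGCCC", "ATGCCG"))
  # constructed fixture: 2 gapped codon columns + terminal stops -> length - 9
  aln3 <- codon_alignment(
    c("a", "b", "c"),
    c("ATGAAACCCGGGTAA", "ATG---CCCGGGTAA", "ATGAAA---GGGTAA"), "g")
  expect_identical(nchar(clean_alignment(aln3)$sequence[1]), 15L - 9L)
  # incomplete-stop remainder is dropped before codon logic
  aln4 <- codon_alignment(c("a", "b"), c("ATGAAAT", "ATGAAGT"), "g")
  expect_identical(clean_alignment(aln4)$sequence, c("ATGAAA", "ATGAAG"))
  # internal stop after cleaning names the taxon and codon
  aln5 <- codon_alignment(c("tax1", "tax2"), c("ATGTAACCC", "ATGAAACCC"), "g")
  expect_error(clean_alignment(aln5), "tax1 at codon 2")
})

test_that("site classification matches definitions and the brute-force oracle", {
  # identical rows: all zero
  aln <- codon_alignment(letters[1:4], rep("ATGATGATG", 4), "g")
  cs <- classify_sites(aln)
  expect_identical(cs$n_variable, 0L)
  expect_equal(cs$pct_Vs, 0)
  # {A,A,G,G} at one site: parsimony-informative, not singleton
  aln2 <- codon_alignment(letters[1:4],
                          c("ATGATG", "ATGATG", "GTGATG", "GTGATG"), "g")
  cs2 <- classify_sites(aln2)
  expect_identical(cs2$n_pis, 1L)
  expect_identical(cs2$n_singleton, 0L)
  # {A,A,A,G}: singleton
  aln3 <- codon_alignment(letters[1:4],
                          c("ATGATG", "ATGATG", "ATGATG", "GTGATG"), "g")
  expect_identical(classify_sites(aln3)$n_singleton, 1L)
  # random fixtures against the per-site enumeration oracle
  set.seed(11)
  for (rep in 1:10) {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""), "")
    got <- classify_sites(codon_alignment(paste0("t", 1:4), seqs, "g"))
    want <- oracle_classify_sites(seqs)
    expect_identical(got$n_variable, as.integer(unname(want["variable"])))
    expect_identical(got$n_pis, as.integer(unname(want["pis"])))
    expect_identical(got$n_variable, got$n_pis + got$n_singleton)
  }
  expect_error(classify_sites(codon_alignment("a", "ATG", "g")), ">= 2")
})

test_that("ts/tv ratio matches counting cases and the brute-force oracle", {
  # single A<->G difference: no transversions -> NA
  aln <- codon_alignment(c("a", "b"), c("ATG", "GTG"), "g")
  expect_true(is.na(suppressMessages(ts_tv_ratio(aln))$ts_tv))
  # differences {A->G, C->T, A->C} -> ts 2, tv 1
  aln2 <- codon_alignment(c("a", "b"), c("ACAATG", "GTCATG"), "g")
  tt <- ts_tv_ratio(aln2)
  expect_identical(c(tt$n_ts, tt$n_tv), c(2L, 1L))
  expect_equal(tt$ts_tv, 2)
  # 4-taxon random fixture equals the double-loop oracle
  set.seed(4)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = ""), "")
  got <- ts_tv_ratio(codon_alignment(paste0("t", 1:4), seqs, "g"))
  want <- oracle_ts_tv(seqs)
  expect_identical(c(got$n_ts, got$n_tv),
                   as.integer(unname(c(want["ts"], want["tv"]))))
})

test_that("p-distance and Aupd behave as proportions", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  aln <- codon_alignment(c("a", "b", "c"), c("AAAAAA", "AAAAAT", "AAAATT"), "g")
  # pairs: 1/6, 2/6, 1/6 -> mean 2/9
  expect_equal(aupd(aln), mean(c(1, 2, 1) / 6))
  # pairwise deletion: N sites skipped
  expect_equal(p_distance("ACGN", "ACTA"), 1 / 3)
  expect_true(is.na(suppressMessages(p_distance("NNN", "ACG"))))
  # JC-corrected distances are at least the uncorrected ones
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(jc_correct(p) >= p))
})

test_that("NG site counts match the 9-neighbour enumeration oracle", {
  # TTT: only the third-position change to TTC is synonymous
  expect_equal(unname(ng_site_counts("TTT")["syn"]), 1 / 3)
  # 4-fold degenerate third position contributes a full synonymous site
  expect_equal(unname(ng_site_counts("GTT")["syn"]), 1)
  code <- mito_genetic_code()
  for (codon in names(code)[code != "*"]) {
    got <- ng_site_counts(codon)
    want <- oracle_site_counts(codon)
    expect_equal(unname(got["syn"]), unname(want["syn"]), tolerance = 1e-12,
                 label = codon)
    expect_lte(got["syn"] + got["nonsyn"], 3 + 1e-12)
  }
  # equality with 3 exactly when no neighbour is a stop
  nb <- mitocomp:::codon_neighbors()
  sense <- which(code != "*")
  no_stop_nb <- !apply(nb$stop, 1, any)
  sums <- vapply(sense, function(i) sum(ng_site_counts(names(code)[i])), 1)
  expect_equal(abs(sums - 3) < 1e-12, no_stop_nb[sense], ignore_attr = TRUE)
  expect_error(ng_site_counts("TAA"), "stop codon")
})

test_that("NG pairwise matches trivial cases and is symmetric", {
  pair <- random_cds_pair(10, 0, seed = 1)
  same <- ng_pairwise(pair$a, pair$a)
  expect_equal(c(same$Ka, same$Ks), c(0, 0))
  # one synonymous third-position change: Ks > 0, Ka = 0
  a <- "ATGAAACCCGGGTTTACAGATCATACAGGA"
  b <- a
  substr(b, 9, 9) <- "A" # CCC -> CCA (Pro, synonymous)
  got <- ng_pairwise(a, b)
  expect_gt(got$Ks, 0)
  expect_equal(got$Ka, 0)
  # symmetry
  pr <- random_cds_pair(40, 12, seed = 7)
  expect_equal(ng_pairwise(pr$a, pr$b), ng_pairwise(pr$b, pr$a))
  # codon-block duplication leaves Ka and Ks unchanged
  one <- ng_pairwise(pr$a, pr$b)
  two <- ng_pairwise(strrep(pr$a, 2), strrep(pr$b, 2))
  expect_equal(c(two$Ka, two$Ks), c(one$Ka, one$Ks), tolerance = 1e-12)
})

test_that("NG pairwise equals the pathway-enumeration oracle, including multi-hit codons", {
  # a double-hit pair whose two pathways differ in syn/nonsyn split
  got <- ng_pairwise("TTT", "GTA")
  want <- oracle_ng_pairwise("TTT", "GTA")
  expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
  expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  # random spot checks (the full 100-pair sweep runs in the acceptance suite)
  for (seed in 1:12) {
    pr <- random_cds_pair(15, 6, seed = seed)
    got <- ng_pairwise(pr$a, pr$b)
    want <- oracle_ng_pairwise(pr$a, pr$b)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$N, want$N, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-9)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-9)
  }
})

test_that("gene divergence table has coherent columns on the fixture set", {
  alns <- fixture_alignments(genes = c("ATP8", "COI", "ND5"))
  div <- suppressMessages(gene_divergence_table(alns))
  expect_identical(div$gene, c("ATP8", "COI", "ND5"))
  expect_identical(div$length_bp, c(165L, 1548L, 1812L))
  expect_true(all(div$Ka >= 0 & div$Ks >= 0))
  expect_true(all(div$aupd >= 0 & div$aupd <= 1))
  expect_true(all(div$pct_Vs >= div$pct_Pis))
  # programmed omega ordering: ATP8 (0.16) > ND5 (0.10) > COI (0.02)
  expect_gt(div$ka_ks[div$gene == "ATP8"], div$ka_ks[div$gene == "ND5"])
  expect_gt(div$ka_ks[div$gene == "ND5"], div$ka_ks[div$gene == "COI"])
  g <- glance(div)
  expect_identical(g$max_kaks_gene, "ATP8")
  expect_true(g$all_purifying)
})
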