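toy_alignments <- function() {
  list(
    g1 = codon_alignment(c("A", "B", "C"), c("ATGAAA", "ATGAAG", "ATGAGG"), "g1"),
    g2 = codon_alignment(c("A", "B"), c("CCCTTT", "CCCTTA"), "g2"),
    g3 = codon_alignment(c("A", "B", "C"), c("GGG", "GGA", "GGC"), "g3")
  )
}

test_that("concatenation tiles partitions, fills missing blocks, is order-stable", {
  cm <- concatenate_genes(toy_alignments())
  expect_identical(cm$partitions$start, c(1L, 7L, 13L))
  expect_identical(cm$partitions$end, c(6L, 12L, 15L))
  expect_identical(nchar(cm$seqs$sequence), rep(15L, 3))
  # partitions tile [1, total] without overlap
  expect_identical(cm$partitions$start[-1], cm$partitions$end[-3] + 1L)
  # missing taxon x gene block filled with ?
  expect_identical(substr(cm$seqs$sequence[cm$seqs$taxon == "C"], 7, 12),
                   "??????")
  # permuted input with fixed order gives identical output
  cm2 <- concatenate_genes(rev(toy_alignments()),
                           gene_order = c("g1", "g2", "g3"),
                           taxa = cm$seqs$taxon)
  expect_identical(cm2$seqs, cm$seqs)
  expect_identical(cm2$partitions, cm$partitions)
  # single gene: matrix equals the alignment
  cm1 <- concatenate_genes(toy_alignments()[1])
  expect_identical(cm1$seqs$sequence, toy_alignments()$g1$sequence)
  # orphan taxon is an error
  expect_error(concatenate_genes(toy_alignments(), taxa = c("A", "B", "Z")),
               "present in no gene")
})

test_that("exports are byte-stable, round-trippable and format-exact", {
  cm <- concatenate_genes(toy_alignments())
  # RAxML partition lines follow the exact format contract
  expect_identical(
    export_partitions_raxml(cm),
    "DNA, g1 = 1-6\nDNA, g2 = 7-12\nDNA, g3 = 13-15\n"
  )
  expect_identical(export_phylip(cm), export_phylip(cm)) # deterministic
  # NEXUS parses back to the identical matrix and partitions
  nex <- export_nexus(cm)
  back <- read_nexus_matrix(nex)
  expect_identical(back$seqs, cm$seqs)
  expect_identical(back$partitions, cm$partitions)
  # PHYLIP header and relaxed names
  phy <- strsplit(export_phylip(cm), "\n")[[1]]
  expect_identical(phy[1], "3 15")
  # whitespace labels sanitized with a mapping table
  cmw <- concatenate_genes(list(g1 = codon_alignment(
    c("taxon one", "taxon two", "t3"), c("ATG", "ATA", "ATT"), "g1")))
  expect_warning(out <- export_phylip(cmw), "sanitized")
  expect_identical(attr(out, "label_map")$sanitized[1], "taxon_one")
})

test_that("simulated 20-taxon export has one partition per gene", {
  set.seed(5)
  tr <- ape::rtree(20, br = function(n) runif(n, 0.01, 0.05))
  alns <- lapply(setNames(paste0("gene", 1:4), paste0("gene", 1:4)),
                 function(g) simulate_gene(40, tr, omega = 0.2,
                                           seed = match(g, paste0("gene", 1:4))))
  cm <- concatenate_genes(alns)
  lines <- strsplit(export_partitions_raxml(cm), "\n")[[1]]
  expect_identical(length(lines), 4L)
  expect_identical(nrow(cm$seqs), 20L)
})

test_that("NJ recovers additive trees exactly", {
  # known 4-taxon additive tree
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3,D:0.15);")
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_identical(robinson_foulds(nj, tr), 0L)
  # exact branch lengths: path lengths reproduce D to 1e-9
  expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] - D)),
            1e-9)
  # exhaustive check against the best least-squares fit of the 3 topologies
  tops <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  ss <- vapply(tops, function(t) {
    fit <- phangorn::nnls.tree(as.dist(D), ape::unroot(ape::read.tree(text = t)))
    sum((ape::cophenetic.phylo(fit)[rownames(D), colnames(D)] - D)^2)
  }, 1)
  best <- ape::read.tree(text = tops[which.min(ss)])
  expect_identical(robinson_foulds(nj, best), 0L)
  # larger random additive matrices
  set.seed(12)
  for (i in 1:5) {
    tri <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.3))
    Di <- ape::cophenetic.phylo(tri)
    expect_identical(robinson_foulds(nj_tree(Di), tri), 0L)
  }
})

test_that("NJ input validation and 3-taxon closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  # closed form: a = (dAB + dAC - dBC)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.5, 1.5, 2.5))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- -1
  expect_error(nj_tree(Dn), "negative")
  Da <- D; Da[1, 2] <- 5
  expect_error(nj_tree(Da), "symmetric")
})

test_that("monophyly and RF verdicts match topology cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B"), outgroup = "D"))
  expect_false(is_monophyletic(tr, c("A", "C"), outgroup = "D"))
  expect_error(is_monophyletic(tr, c("A", "Z"), outgroup = "D"), "not in tree")
  expect_identical(robinson_foulds(tr, tr), 0L)
  # RF bounded by 2(n-3), symmetric, positive for different topologies
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_identical(robinson_foulds(tr, t2), robinson_foulds(t2, tr))
  expect_lte(robinson_foulds(tr, t2), 2L * (4L - 3L))
  expect_gt(robinson_foulds(tr, t2), 0L)
})

test_that("competing placement hypotheses give opposite monophyly verdicts", {
  # a plover-like genus either inside the ingroup family or sister to a
  # separate three-family clade; the family monophyly verdict must differ
  family_taxa <- c("Charadrius_1", "Charadrius_2", "Vanellus_1", "Pluvialis_1")
  inside <- ape::read.tree(text = paste0(
    "((Pluvialis_1:1,((Charadrius_1:1,Charadrius_2:1):1,Vanellus_1:1):1):1,",
    "(Haematopus_1:1,(Ibidorhyncha_1:1,Recurvirostra_1:1):1):1,Outgroup:1);"))
  outside <- ape::read.tree(text = paste0(
    "(((Charadrius_1:1,Charadrius_2:1):1,Vanellus_1:1):1,",
    "(Pluvialis_1:1,(Haematopus_1:1,(Ibidorhyncha_1:1,Recurvirostra_1:1):1):1):1,",
    "Outgroup:1);"))
  expect_true(is_monophyletic(inside, family_taxa, outgroup = "Outgroup"))
  expect_false(is_monophyletic(outside, family_taxa, outgroup = "Outgroup"))
  # sister-species claim holds in both hypotheses
  expect_true(is_monophyletic(inside, c("Charadrius_1", "Charadrius_2"),
                              outgroup = "Outgroup"))
})

test_that("distance matrices feed NJ to recover the generating topology", {
  sim <- fixture_sim()
  alns <- fixture_alignments(genes = c("ND5", "COI", "Cyt b", "ND4"))
  cm <- concatenate_genes(alns)
  D <- distance_matrix(cm, model = "JC69")
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # JC >= raw elementwise
  Draw <- distance_matrix(cm, model = "raw")
  expect_true(all(D >= Draw - 1e-12))
  expect_identical(robinson_foulds(nj_tree(D), sim$tree), 0L)
})
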