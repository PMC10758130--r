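# Mitogenome-evolution simulator: an annotated 37-gene + control-region
# circular genome with programmable composition/skew, evolved along a known
# tree under a codon model (transition bias kappa, per-gene omega, stops
# forbidden) for protein-coding genes and an HKY nucleotide model for tRNAs,
# rRNAs, the control region and spacers. Every stage of the analysis pipeline
# can thus be validated against known truth without downloads.

# protein-coding gene plan: cleaned length (bp, multiple of 3, excluding the
# stop), start codon, stop codon ("TAA", "AGA", "AGG" or incomplete "T-")
pcg_plan <- function() {
  tibble(
    name = c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
             "ND3", "ND4L", "ND4", "ND5", "Cyt b", "ND6"),
    core_bp = c(975L, 1038L, 1548L, 681L, 165L, 681L, 783L,
                348L, 294L, 1374L, 1812L, 1110L, 513L),
    start_codon = c("ATG", "ATG", "GTG", "ATG", "ATG", "ATG", "ATG",
                    "ATC", "ATG", "ATG", "GTG", "ATG", "ATG"),
    stop_codon = c("AGG", "T-", "AGG", "TAA", "TAA", "TAA", "T-",
                   "TAA", "TAA", "T-", "AGA", "TAA", "TAA")
  )
}

# canonical avian mitogenome architecture: 37 genes + CR, 9 minus-strand
# features (ND6 and 8 tRNAs)
default_architecture <- function() {
  lay <- tibble(
    name = c("tRNA-Phe", "12S", "tRNA-Val", "16S", "tRNA-Leu(UUR)", "ND1",
             "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2", "tRNA-Trp",
             "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr", "COI",
             "tRNA-Ser(UCN)", "tRNA-Asp", "COII", "tRNA-Lys", "ATP8",
             "ATP6", "COIII", "tRNA-Gly", "ND3", "tRNA-Arg", "ND4L", "ND4",
             "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)", "ND5", "Cyt b",
             "tRNA-Thr", "tRNA-Pro", "ND6", "tRNA-Glu", "CR"),
    strand = "+"
  )
  minus <- c("tRNA-Gln", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr",
             "tRNA-Ser(UCN)", "tRNA-Pro", "ND6", "tRNA-Glu")
  lay$strand[lay$name %in% minus] <- "-"
  lay$ftype <- dplyr::case_when(
    grepl("^tRNA", lay$name) ~ "tRNA",
    lay$name %in% c("12S", "16S") ~ "rRNA",
    lay$name == "CR" ~ "CR",
    TRUE ~ "PCG"
  )
  lay
}

default_tree_newick <- function() {
  paste0(
    "((Pluvialis_squatarola:0.02,Pluvialis_fulva:0.02):0.05,",
    "((Vanellus_cinereus_A:0.005,Vanellus_cinereus_B:0.005):0.02,",
    "Vanellus_vanellus:0.025):0.04,",
    "(((Charadrius_leschenaultii:0.01,(Charadrius_mongolus_A:0.002,",
    "Charadrius_mongolus_B:0.002):0.008):0.01,",
    "(Charadrius_alexandrinus:0.012,Charadrius_placidus:0.012):0.008):0.01,",
    "(Charadrius_vociferus:0.02,Charadrius_dubius:0.02):0.01):0.04);"
  )
}

#' Base frequencies from composition targets
#'
#' Converts an AT% plus AT/GC skew target into the four base frequencies of
#' the analyzed strand (A/T split by the AT skew, G/C by the GC skew).
#'
#' @param pct_at Target A+T percentage.
#' @param at_skew,gc_skew Target skews.
#' @return Named frequency vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
freqs_from_skew <- function(pct_at, at_skew, gc_skew) {
  at <- pct_at / 100
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

#' Simulation configuration
#'
#' Defaults are the study conditions of a 12-genome shorebird comparison: the
#' 37-gene avian architecture with ND6 plus eight tRNAs on the minus strand,
#' protein-coding gene lengths and start/stop codons from the comparative
#' table, per-gene omega equal to the observed per-gene Ka/Ks (ATP8 fastest,
#' COI among the slowest), base frequencies equal to the reported mean
#' composition (AT-rich, positive AT skew, negative GC skew on the plus
#' strand), kappa = 8 (pooled observed ts/tv around 4), and a 12-taxon tree
#' shaped like the study's genus structure.
#'
#' @param tree Newick string with branch lengths in expected substitutions
#'   per site.
#' @param omega Named numeric vector of per-gene dN/dS (names = PCG symbols);
#'   a single unnamed value is recycled to all 13 genes.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freq Named frequencies `c(A=,C=,G=,T=)` of the plus strand;
#'   see [freqs_from_skew()].
#' @param cr_length Control-region length (bp).
#' @param trna_length Baseline tRNA length (bp; per-gene lengths vary by a
#'   couple of bases deterministically).
#' @param spacers Named integer vector of intergenic gap lengths keyed by the
#'   left-hand gene; junctions not named get 0.
#' @param seed Integer seed; all randomness in the simulator derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree = default_tree_newick(),
                       omega = NULL,
                       kappa = 8,
                       base_freq = c(A = 0.3141, C = 0.3106, G = 0.1374, T = 0.2372),
                       cr_length = 1300L,
                       trna_length = 70L,
                       spacers = c("tRNA-Tyr" = 23L, "ND1" = 2L,
                                   "tRNA-Asn" = 5L, "tRNA-Thr" = 1L),
                       seed = 1L) {
  plan <- pcg_plan()
  default_omega <- setNames(
    c(0.03, 0.09, 0.02, 0.04, 0.16, 0.06, 0.02, 0.08, 0.05, 0.09, 0.10,
      0.05, 0.12),
    plan$name
  )
  if (is.null(omega)) {
    omega <- default_omega
  } else if (is.null(names(omega)) && length(omega) == 1) {
    omega <- setNames(rep(omega, nrow(plan)), plan$name)
  } else {
    missing <- setdiff(plan$name, names(omega))
    omega <- c(omega, default_omega[missing])
  }
  stopifnot(all(omega >= 0), kappa > 0)
  base_freq <- base_freq / sum(base_freq)
  structure(
    list(tree = tree, omega = omega, kappa = kappa, base_freq = base_freq,
         cr_length = as.integer(cr_length), trna_length = as.integer(trna_length),
         spacers = spacers, architecture = default_architecture(),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run code under a private RNG stream, restoring any global state after
with_sim_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_bases <- function(n, freq) {
  sample(names(freq), n, replace = TRUE, prob = freq)
}

comp_freq <- function(freq) {
  c(A = unname(freq["T"]), C = unname(freq["G"]),
    G = unname(freq["C"]), T = unname(freq["A"]))
}

# Adjust per-base frequencies so that codon sampling with stop rejection has
# the *target* expected base composition: rejecting the A-rich stops (TAA,
# TAG, AGA, AGG) would otherwise depress realized A content below target.
# Deterministic fixed-point on the 60-sense-codon expectation.
adjust_freq_for_stops <- function(freq) {
  codons <- mito_codons()
  sense <- mito_genetic_code() != "*"
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    stringr::str_count(codons, b), numeric(64))
  freq <- freq[c("A", "C", "G", "T")]
  p <- freq
  for (it in 1:60) {
    q <- exp(counts %*% log(pmax(p, 1e-12)))[, 1] # codon probs up to norm
    q[!sense] <- 0
    q <- q / sum(q)
    realized <- as.vector(q %*% counts) / 3
    names(realized) <- c("A", "C", "G", "T")
    if (max(abs(realized - freq)) < 1e-10) break
    p <- p * freq / realized
    p <- p / sum(p)
  }
  p
}

# sample one in-frame, stop-free coding core of n_codons codons from per-base
# frequencies (rejection on stops); frequencies are pre-adjusted so the
# realized composition matches the requested one
sample_coding_core <- function(n_codons, freq) {
  freq <- adjust_freq_for_stops(freq)
  stops <- mito_stop_codons()
  draw <- function(k) {
    paste0(sample_bases(k, freq), sample_bases(k, freq), sample_bases(k, freq))
  }
  codons <- draw(n_codons)
  bad <- codons %in% stops
  while (any(bad)) {
    codons[bad] <- draw(sum(bad))
    bad <- codons %in% stops
  }
  codons
}

segment_plan <- function(config) {
  arch <- config$architecture
  plan <- pcg_plan()
  lens <- integer(nrow(arch))
  for (i in seq_len(nrow(arch))) {
    f <- arch[i, ]
    lens[i] <- switch(f$ftype,
      PCG = {
        p <- plan[plan$name == f$name, ]
        # core (start codon included) plus the complete or incomplete stop
        p$core_bp + nchar(gsub("-", "", p$stop_codon))
      },
      tRNA = config$trna_length + (i %% 5L),
      rRNA = if (f$name == "12S") 975L else 1590L,
      CR = config$cr_length
    )
  }
  arch$length_bp <- lens
  arch$gap_after <- as.integer(config$spacers[arch$name])
  arch$gap_after[is.na(arch$gap_after)] <- 0L
  arch
}

#' Generate the ancestral annotated mitogenome
#'
#' Builds a circular `mito_record` following the configured architecture:
#' protein-coding genes begin with their designated start codon, contain no
#' internal stops, and end with their designated complete or incomplete stop;
#' minus-strand gene sequences are drawn from complemented base frequencies so
#' that the deposited plus strand is compositionally homogeneous at the target
#' frequencies. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A `mito_record` (accession `SIM_ANC`).
#' @export
make_ancestor <- function(config) {
  with_sim_seed(config$seed, make_ancestor_impl(config))
}

make_ancestor_impl <- function(config) {
  arch <- segment_plan(config)
  plan <- pcg_plan()
  freq <- config$base_freq
  qfreq <- comp_freq(freq)
  segs <- vector("list", nrow(arch))
  for (i in seq_len(nrow(arch))) {
    f <- arch[i, ]
    if (f$ftype == "PCG") {
      p <- plan[plan$name == f$name, ]
      use_freq <- if (f$strand == "-") qfreq else freq
      n_core <- p$core_bp / 3L - 1L # core codons after the start codon
      stop_nt <- gsub("-", "", p$stop_codon)
      coding <- paste0(p$start_codon,
                       paste(sample_coding_core(n_core, use_freq), collapse = ""),
                       stop_nt)
      segs[[i]] <- list(type = "PCG", name = f$name, strand = f$strand,
                        coding = coding,
                        start_codon = p$start_codon, stop_nt = stop_nt)
    } else {
      use_freq <- if (f$strand == "-") qfreq else freq
      coding <- paste(sample_bases(f$length_bp, use_freq), collapse = "")
      segs[[i]] <- list(type = f$ftype, name = f$name, strand = f$strand,
                        coding = coding)
    }
    gap <- arch$gap_after[i]
    segs[[i]]$gap_seq <- if (gap > 0) {
      paste(sample_bases(gap, freq), collapse = "")
    } else ""
  }
  assemble_record(segs, arch, accession = "SIM_ANC", organism = "simulated ancestor")
}

assemble_record <- function(segs, arch, accession, organism) {
  pieces <- character(0)
  feats <- list()
  pos <- 1L
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    plus <- if (s$strand == "-") revcomp(s$coding) else s$coding
    len <- nchar(plus)
    feats[[i]] <- tibble(
      name = s$name,
      ftype = if (s$type == "PCG") "PCG" else s$type,
      start = pos, end = pos + len - 1L, strand = s$strand,
      codon_start = if (s$type == "PCG") 1L else NA_integer_,
      anticodon = NA_character_
    )
    pieces <- c(pieces, plus, s$gap_seq)
    pos <- pos + len + nchar(s$gap_seq)
  }
  new_mito_record(accession, organism, paste(pieces, collapse = ""),
                  is_circular = TRUE, features = bind_rows(feats))
}

# --- codon-model machinery --------------------------------------------------

# per-codon substitution rate tables for given kappa/omega/target frequencies:
# rate to each of the 9 single-nucleotide neighbours is
# pi(target base) * kappa^[transition] * omega^[nonsynonymous], 0 into stops
codon_rate_tables <- function(kappa, omega, freq) {
  nb <- codon_neighbors()
  codons <- mito_codons()
  target_base <- matrix("", 64, 9)
  for (i in 1:64) {
    for (k in 1:9) {
      target_base[i, k] <- substr(codons[nb$idx[i, k]], nb$pos[i, k],
                                  nb$pos[i, k])
    }
  }
  rate <- matrix(unname(freq[target_base]), 64, 9)
  rate <- rate * ifelse(nb$ts, kappa, 1) * ifelse(nb$syn, 1, omega)
  rate[nb$stop] <- 0
  list(nbr = rate, tot = rowSums(rate), idx = nb$idx)
}

# Gillespie evolution of a codon-index vector along one branch; branch length
# is expected substitutions per nucleotide site, normalized at the branch's
# starting state
evolve_codons_branch <- function(cidx, brlen, tabs) {
  L <- length(cidx)
  if (L == 0 || brlen <= 0) return(cidx)
  r <- tabs$tot[cidx]
  R <- sum(r)
  scale <- R / (3 * L) # rate units per (substitution/site) at branch start
  if (scale <= 0) return(cidx)
  t <- 0
  repeat {
    t <- t + rexp(1, R / scale)
    if (t > brlen) break
    i <- sample.int(L, 1L, prob = r)
    k <- sample.int(9L, 1L, prob = tabs$nbr[cidx[i], ])
    cidx[i] <- tabs$idx[cidx[i], k]
    R <- R - r[i] + tabs$tot[cidx[i]]
    r[i] <- tabs$tot[cidx[i]]
  }
  cidx
}

# HKY transition-probability matrix, mean rate 1 at frequencies pi
hky_P <- function(t, kappa, freq) {
  b <- names(freq)
  Q <- matrix(0, 4, 4, dimnames = list(b, b))
  for (i in b) for (j in b) {
    if (i != j) Q[i, j] <- unname(freq[j]) * if (is_transition(i, j)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(b, b)
  P
}

evolve_nucleotides_branch <- function(chars, brlen, P) {
  if (brlen <= 0) return(chars)
  out <- chars
  for (b in c("A", "C", "G", "T")) {
    idx <- which(chars == b)
    if (length(idx) > 0) {
      out[idx] <- sample(colnames(P), length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

#' Evolve an ancestral mitogenome along a tree
#'
#' Protein-coding genes evolve under a continuous-time codon model simulated
#' with exponential waiting times (rate proportional to the target-base
#' frequency, times `kappa` for transitions and times the gene's `omega` for
#' nonsynonymous changes; substitutions into stop codons are forbidden); the
#' designated start and stop codons are held fixed. tRNAs, rRNAs, the control
#' region and spacers evolve under an HKY nucleotide model with the same
#' `kappa`. Branch lengths are expected substitutions per site. Gene order is
#' never rearranged, so all tips share the ancestral architecture.
#'
#' @param ancestor A `mito_record` from [make_ancestor()] (same config).
#' @param config The [sim_config()] used to build the ancestor.
#' @return Named list of tip-label -> `mito_record`.
#' @export
evolve_genomes <- function(ancestor, config) {
  with_sim_seed(config$seed + 1L, evolve_genomes_impl(ancestor, config))
}

evolve_genomes_impl <- function(ancestor, config) {
  tree <- ape::read.tree(text = config$tree)
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  if (length(tree$tip.label) < 2) abort("tree must have >= 2 tips")
  arch <- segment_plan(config)
  plan <- pcg_plan()
  freq <- config$base_freq
  qfreq <- comp_freq(freq)

  # decompose the ancestor back into coding-orientation segments
  segs <- purrr::map(seq_len(nrow(arch)), function(i) {
    f <- arch[i, ]
    coding <- extract_gene(ancestor, f$name, apply_codon_start = FALSE)
    gap <- arch$gap_after[i]
    ft <- ancestor$features
    j <- which(ft$name == f$name)
    gap_seq <- if (gap > 0) {
      substr(ancestor$sequence, ft$end[j] + 1L, ft$end[j] + gap)
    } else ""
    if (f$ftype == "PCG") {
      p <- plan[plan$name == f$name, ]
      stop_nt <- gsub("-", "", p$stop_codon)
      core <- substr(coding, 4L, nchar(coding) - nchar(stop_nt))
      list(type = "PCG", name = f$name, strand = f$strand,
           start_codon = substr(coding, 1, 3), stop_nt = stop_nt,
           state = codon_index(codon_split(core)$codons),
           tabs = codon_rate_tables(config$kappa, config$omega[[f$name]],
                                    if (f$strand == "-") qfreq else freq),
           gap_seq = gap_seq)
    } else {
      list(type = f$ftype, name = f$name, strand = f$strand,
           state = seq_chars(coding),
           hky_freq = if (f$strand == "-") qfreq else freq,
           gap_seq = gap_seq)
    }
  })

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", max(tree$edge))
  states[[root]] <- segs
  tips <- list()
  reord <- ape::reorder.phylo(tree, "cladewise") # preorder traversal
  for (k in seq_len(nrow(reord$edge))) {
    parent <- reord$edge[k, 1]; child <- reord$edge[k, 2]
    brlen <- reord$edge.length[k]
    s <- states[[parent]]
    s2 <- purrr::map(s, function(seg) {
      if (seg$type == "PCG") {
        seg$state <- evolve_codons_branch(seg$state, brlen, seg$tabs)
      } else if (length(seg$state) > 0) {
        P <- hky_P(brlen, config$kappa, seg$hky_freq)
        seg$state <- evolve_nucleotides_branch(seg$state, brlen, P)
      }
      if (nchar(seg$gap_seq) > 0) {
        P <- hky_P(brlen, config$kappa, freq)
        seg$gap_seq <- paste(
          evolve_nucleotides_branch(seq_chars(seg$gap_seq), brlen, P),
          collapse = "")
      }
      seg
    })
    if (child <= n_tip) {
      tips[[tree$tip.label[child]]] <- s2
    } else {
      states[[child]] <- s2
    }
  }

  purrr::imap(tips, function(s, label) {
    segs_out <- purrr::map(s, function(seg) {
      coding <- if (seg$type == "PCG") {
        paste0(seg$start_codon,
               paste(mito_codons()[seg$state], collapse = ""), seg$stop_nt)
      } else {
        paste(seg$state, collapse = "")
      }
      list(type = seg$type, name = seg$name, strand = seg$strand,
           coding = coding, gap_seq = seg$gap_seq)
    })
    assemble_record(segs_out, arch, accession = label,
                    organism = gsub("_", " ", label))
  })
}

#' Simulate one protein-coding gene alignment along a tree
#'
#' Lightweight single-gene counterpart of [evolve_genomes()] for estimator
#' validation: a stop-free ancestral coding sequence of `n_codons` codons is
#' drawn from `base_freq` and evolved along `tree` under the codon model
#' (`kappa`, `omega`, stops forbidden). Because all tips share coordinates,
#' the result is a gap-free in-frame `codon_alignment`.
#'
#' @param n_codons Number of codons.
#' @param tree Newick string or [ape::phylo] with branch lengths.
#' @param omega dN/dS of the gene.
#' @param kappa Transition/transversion rate ratio.
#' @param base_freq Named base frequencies.
#' @param seed Integer seed.
#' @return A `codon_alignment` across the tree's tips.
#' @export
simulate_gene <- function(n_codons, tree, omega, kappa = 8,
                          base_freq = c(A = 0.3141, C = 0.3106, G = 0.1374,
                                        T = 0.2372),
                          seed = 1L) {
  with_sim_seed(seed, {
    phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
    if (is.null(phy$edge.length)) abort("tree must have branch lengths")
    if (any(phy$edge.length < 0)) abort("negative branch lengths are not allowed")
    base_freq <- base_freq / sum(base_freq)
    tabs <- codon_rate_tables(kappa, omega, base_freq)
    root_state <- codon_index(sample_coding_core(n_codons, base_freq))
    n_tip <- length(phy$tip.label)
    states <- vector("list", max(phy$edge))
    states[[n_tip + 1L]] <- root_state
    tips <- vector("list", n_tip)
    reord <- ape::reorder.phylo(phy, "cladewise")
    for (k in seq_len(nrow(reord$edge))) {
      parent <- reord$edge[k, 1]; child <- reord$edge[k, 2]
      st <- evolve_codons_branch(states[[parent]], reord$edge.length[k], tabs)
      if (child <= n_tip) tips[[child]] <- st else states[[child]] <- st
    }
    codon_alignment(
      phy$tip.label,
      vapply(tips, function(s) paste(mito_codons()[s], collapse = ""), ""),
      gene = "simulated"
    )
  })
}

#' Simulate a full mitogenome dataset
#'
#' [make_ancestor()] plus [evolve_genomes()] plus the ground truth needed to
#' validate every downstream module.
#'
#' @param config A [sim_config()].
#' @return List with `ancestor`, `records` (named list of tip records),
#'   `tree` (the generating [ape::phylo]), `config`, and `truth` (programmed
#'   AT/GC skew and AT%, per-gene omega, spacer table of the ancestor).
#' @export
simulate_mitogenomes <- function(config = sim_config()) {
  anc <- make_ancestor(config)
  recs <- evolve_genomes(anc, config)
  f <- config$base_freq
  list(
    ancestor = anc,
    records = recs,
    tree = ape::read.tree(text = config$tree),
    config = config,
    truth = list(
      at_skew = unname((f["A"] - f["T"]) / (f["A"] + f["T"])),
      gc_skew = unname((f["G"] - f["C"]) / (f["G"] + f["C"])),
      pct_AT = unname(100 * (f["A"] + f["T"])),
      omega = config$omega,
      spacers = intergenic_spacers(anc)
    )
  )
}

#' Bundled small simulated dataset
#'
#' Twelve genomes on the default study-shaped tree with every truth value
#' (skew targets, per-gene omega, spacer table, generating tree) attached;
#' consumed by the test-suites of every other module.
#'
#' @param seed Integer seed.
#' @return See [simulate_mitogenomes()].
#' @export
fixture_set <- function(seed = 1L) {
  simulate_mitogenomes(sim_config(seed = seed))
}
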