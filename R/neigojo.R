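# Nei-Gojobori (1986) synonymous/nonsynonymous analysis under the vertebrate
# mitochondrial code, with Jukes-Cantor correction. Site counting treats each
# codon position as three possible single-nucleotide changes; changes to stop
# codons are skipped (not counted on either side), so a codon's S + N can fall
# below 3 when it neighbours a stop. Per differing codon pair, synonymous and
# nonsynonymous differences are averaged with equal weight over all minimal
# mutational pathways that avoid stop codons (the original unweighted method,
# as in DnaSP).

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous contributes to the
#' synonymous site count and the nonsynonymous fraction to the nonsynonymous
#' count; changes creating a stop codon are excluded from the tally, so
#' `syn + nonsyn <= 3` with equality exactly when no neighbour is a stop.
#'
#' @param codon A non-stop codon string under the vertebrate mitochondrial
#'   code.
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @examples
#' ng_site_counts("TTT") # syn = 1/3
#' @export
ng_site_counts <- function(codon) {
  tabs <- ng_site_tables()
  i <- codon_index(codon)
  if (is.na(i)) abort(sprintf("'%s' is not an unambiguous codon", codon))
  if (mito_genetic_code()[[i]] == "*") {
    abort(sprintf("'%s' is a stop codon: no site counts defined", codon))
  }
  c(syn = tabs$syn[i], nonsyn = tabs$nonsyn[i])
}

ng_site_tables <- function() {
  if (!is.null(.mc_cache$ng_sites)) return(.mc_cache$ng_sites)
  nb <- codon_neighbors()
  syn <- rowSums(nb$syn & !nb$stop) / 3
  nonsyn <- rowSums(!nb$syn & !nb$stop) / 3
  .mc_cache$ng_sites <- list(syn = syn, nonsyn = nonsyn)
  .mc_cache$ng_sites
}

# 64x64 tables of synonymous (sd) / nonsynonymous (nd) difference counts per
# codon pair, averaged over minimal stop-avoiding mutational pathways.
# blocked[i, j] is TRUE when every minimal pathway passes through a stop; the
# average over all pathways is then stored and the pair flagged uncorrectable.
ng_pair_tables <- function() {
  if (!is.null(.mc_cache$ng_pairs)) return(.mc_cache$ng_pairs)
  codons <- mito_codons()
  aa <- mito_genetic_code()
  chars <- strsplit(codons, "", fixed = TRUE)
  sd <- nd <- matrix(0, 64, 64)
  blocked <- matrix(FALSE, 64, 64)
  sense <- which(aa != "*")
  step_counts <- function(from, to) {
    # one single-nucleotide step from codon index `from` to `to`
    if (aa[[from]] == aa[[to]]) c(1, 0) else c(0, 1)
  }
  for (i in sense) {
    for (j in sense) {
      if (i == j) next
      diffpos <- which(chars[[i]] != chars[[j]])
      k <- length(diffpos)
      if (k == 1) {
        cnt <- step_counts(i, j)
        sd[i, j] <- cnt[1]; nd[i, j] <- cnt[2]
        next
      }
      perms <- if (k == 2) list(diffpos, rev(diffpos)) else {
        do.call(c, lapply(seq_len(3), function(f) {
          rest <- diffpos[diffpos != diffpos[f]]
          list(c(diffpos[f], rest), c(diffpos[f], rev(rest)))
        }))
      }
      path_s <- path_n <- numeric(0)
      all_s <- all_n <- numeric(0)
      for (ord in perms) {
        cur <- i
        s <- 0; n <- 0
        viable <- TRUE
        for (p in ord) {
          mut <- chars[[cur]]
          mut[p] <- chars[[j]][p]
          nxt <- match(paste(mut, collapse = ""), codons)
          if (aa[[nxt]] == "*") { viable <- FALSE }
          else {
            cnt <- step_counts(cur, nxt)
            s <- s + cnt[1]; n <- n + cnt[2]
          }
          cur <- nxt
          if (!viable) break
        }
        if (viable) { path_s <- c(path_s, s); path_n <- c(path_n, n) }
        # unconditional tally (used only when every pathway is blocked)
        cur <- i; s2 <- 0; n2 <- 0
        for (p in ord) {
          mut <- chars[[cur]]
          mut[p] <- chars[[j]][p]
          nxt <- match(paste(mut, collapse = ""), codons)
          cnt <- step_counts(cur, nxt)
          s2 <- s2 + cnt[1]; n2 <- n2 + cnt[2]
          cur <- nxt
        }
        all_s <- c(all_s, s2); all_n <- c(all_n, n2)
      }
      if (length(path_s) > 0) {
        sd[i, j] <- mean(path_s); nd[i, j] <- mean(path_n)
      } else {
        sd[i, j] <- mean(all_s); nd[i, j] <- mean(all_n)
        blocked[i, j] <- TRUE
      }
    }
  }
  .mc_cache$ng_pairs <- list(sd = sd, nd = nd, blocked = blocked)
  .mc_cache$ng_pairs
}

#' Jukes-Cantor distance correction
#'
#' `d = -3/4 * log(1 - 4/3 * p)`; `NA` when `p >= 3/4`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance.
#' @export
jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

#' Pairwise Nei-Gojobori Ka and Ks
#'
#' Classic Nei-Gojobori (1986) counting on a gap-free, in-frame pair of coding
#' sequences: synonymous (S) and nonsynonymous (N) site totals are averaged
#' over the two sequences; synonymous (Sd) and nonsynonymous (Nd) differences
#' are summed over codon pairs, averaging each multi-hit codon pair over all
#' minimal stop-avoiding mutational pathways with equal weight. Proportions
#' `pS = Sd/S`, `pN = Nd/N` receive the Jukes-Cantor correction to give Ks and
#' Ka. `ka_ks` is `NA` when Ks is 0 or undefined. Codons containing non-ACGT
#' characters in either sequence are excluded from both sites and differences.
#'
#' @param a,b Equal-length, in-frame, gap-free coding sequences (no terminal
#'   stop).
#' @return One-row tibble: `n_codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `ka_ks`, `n_blocked` (codon pairs whose minimal pathways all pass
#'   through stops; counted via the all-pathway average and flagged here).
#' @export
ng_pairwise <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences must be equal length")
  if (nchar(a) %% 3 != 0) abort("sequence length must be a multiple of 3")
  ca <- codon_index(codon_split(a)$codons)
  cb <- codon_index(codon_split(b)$codons)
  ok <- !is.na(ca) & !is.na(cb)
  ca <- ca[ok]; cb <- cb[ok]
  aa <- mito_genetic_code()
  if (any(aa[ca] == "*") || any(aa[cb] == "*")) {
    abort("stop codon inside coding sequence; clean the alignment first")
  }
  sites <- ng_site_tables()
  pairs <- ng_pair_tables()
  S <- (sum(sites$syn[ca]) + sum(sites$syn[cb])) / 2
  N <- (sum(sites$nonsyn[ca]) + sum(sites$nonsyn[cb])) / 2
  idx <- cbind(ca, cb)
  Sd <- sum(pairs$sd[idx])
  Nd <- sum(pairs$nd[idx])
  n_blocked <- sum(pairs$blocked[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  if (!is.na(pS) && pS >= 0.75) message("pS >= 3/4: Ks undefined after JC correction")
  if (!is.na(pN) && pN >= 0.75) message("pN >= 3/4: Ka undefined after JC correction")
  tibble(
    n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, Ks = Ks, Ka = Ka,
    ka_ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
    n_blocked = n_blocked
  )
}

#' Per-gene divergence and selection table
#'
#' One row per gene alignment with the full comparative-table column set:
#' cleaned length, coding-strand composition averaged over taxa, site
#' classification, pooled ts/tv, mean pairwise Ka and Ks, Ka/Ks and the
#' average uncorrected p-distance (Aupd). Per-gene Ka/Ks is the ratio of mean
#' Ka over mean Ks across all sequence pairs (ratio of means, robust to pairs
#' with undefined ratios); set `ratio_of_means = FALSE` for the mean of
#' pairwise ratios instead.
#'
#' @param alignments Named list of `codon_alignment` objects (names are gene
#'   symbols; unnamed lists use each alignment's `gene` attribute).
#' @param clean Run [clean_alignment()] first (default `TRUE`).
#' @param composition_on Either `"alignment"` (default: cleaned coding-strand
#'   alignment, averaged over taxa) or `"rows"` (uncleaned input rows).
#' @param ratio_of_means See above.
#' @return A `gene_divergence` tibble, one row per gene: `gene`, `length_bp`,
#'   `pct_AT`, `at_skew`, `gc_skew`, `pct_Vs`, `pct_Pis`, `pct_S`, `ts_tv`,
#'   `Ks`, `Ka`, `ka_ks`, `aupd`.
#' @export
gene_divergence_table <- function(alignments, clean = TRUE,
                                  composition_on = c("alignment", "rows"),
                                  ratio_of_means = TRUE) {
  composition_on <- match.arg(composition_on)
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    names(alignments) <- vapply(alignments, aln_gene, "")
  }
  rows <- purrr::imap(alignments, function(aln, gene) {
    raw <- aln
    if (clean) aln <- clean_alignment(aln)
    comp_src <- if (composition_on == "alignment") aln else raw
    comp <- purrr::map(comp_src$sequence,
                       ~base_composition(gsub("-", "", .x))) |> bind_rows()
    sites <- classify_sites(aln)
    tstv <- ts_tv_ratio(aln)
    n <- nrow(aln)
    prs <- utils::combn(n, 2)
    ng <- purrr::map(seq_len(ncol(prs)), function(k) {
      ng_pairwise(aln$sequence[prs[1, k]], aln$sequence[prs[2, k]])
    }) |> bind_rows()
    mean_ka <- mean(ng$Ka, na.rm = TRUE)
    mean_ks <- mean(ng$Ks, na.rm = TRUE)
    kaks <- if (ratio_of_means) {
      if (is.finite(mean_ks) && mean_ks > 0) mean_ka / mean_ks else NA_real_
    } else {
      mean(ng$ka_ks, na.rm = TRUE)
    }
    tibble(
      gene = gene, length_bp = nchar(aln$sequence[1]),
      pct_AT = mean(comp$pct_AT), at_skew = mean(comp$at_skew),
      gc_skew = mean(comp$gc_skew),
      pct_Vs = sites$pct_Vs, pct_Pis = sites$pct_Pis, pct_S = sites$pct_S,
      ts_tv = tstv$ts_tv, Ks = mean_ks, Ka = mean_ka, ka_ks = kaks,
      aupd = aupd(aln)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("gene_divergence", class(out))
  out
}

#' @export
tidy.gene_divergence <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.gene_divergence <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    fastest_gene = x$gene[which.max(x$aupd)],
    slowest_gene = x$gene[which.min(x$aupd)],
    max_kaks_gene = x$gene[which.max(x$ka_ks)],
    max_kaks = max(x$ka_ks, na.rm = TRUE),
    mean_kaks = mean(x$ka_ks, na.rm = TRUE),
    all_purifying = all(x$ka_ks < 1, na.rm = TRUE)
  )
}

#' Per-gene Ka/Ks and divergence plot
#'
#' @param div A [gene_divergence_table()] result.
#' @return A ggplot object: Ka/Ks per gene, ordered, with Aupd as point size.
#' @export
plot_divergence <- function(div) {
  ggplot2::ggplot(div,
                  ggplot2::aes(x = stats::reorder(.data$gene, .data$ka_ks),
                               y = .data$ka_ks)) +
    ggplot2::geom_col(fill = "indianred3") +
    ggplot2::geom_point(ggplot2::aes(size = .data$aupd), colour = "grey25") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Ka/Ks", size = "Aupd",
                  title = "Per-gene selection and divergence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gene_divergence <- function(object, ...) plot_divergence(object)
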