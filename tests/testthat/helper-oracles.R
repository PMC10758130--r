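# Independent brute-force oracles. These deliberately avoid the package's
# lookup tables: translation goes through seqinr (numcode = 2) and every
# enumeration is explicit.

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 2)
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

oracle_codon_split <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# per-position synonymous fraction; mutations into stops skipped entirely
oracle_site_counts <- function(codon) {
  cc <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate(codon)
  syn <- 0; nonsyn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), cc[p])) {
      mut <- cc; mut[p] <- b
      mutc <- paste(mut, collapse = "")
      if (oracle_is_stop(mutc)) next
      if (oracle_translate(mutc) == aa0) syn <- syn + 1 / 3
      else nonsyn <- nonsyn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# synonymous/nonsynonymous differences between two codons, averaged over all
# minimal mutational pathways that avoid stop intermediates (equal weights);
# if every pathway is blocked, fall back to the all-pathways average
oracle_pair_diffs <- function(c1, c2) {
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  diffpos <- which(p1 != p2)
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  res_ok <- list(); res_all <- list()
  for (ord in oracle_permutations(diffpos)) {
    cur <- p1; s <- 0; n <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- p2[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (oracle_is_stop(to)) blocked <- TRUE
      if (oracle_translate(from) == oracle_translate(to)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    res_all[[length(res_all) + 1]] <- c(s, n)
    if (!blocked) res_ok[[length(res_ok) + 1]] <- c(s, n)
  }
  use <- if (length(res_ok) > 0) res_ok else res_all
  m <- do.call(rbind, use)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# full Nei-Gojobori Ka/Ks with Jukes-Cantor correction, brute force
oracle_ng_pairwise <- function(a, b) {
  ca <- oracle_codon_split(a); cb <- oracle_codon_split(b)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    s1 <- oracle_site_counts(ca[k]); s2 <- oracle_site_counts(cb[k])
    S <- S + (s1["syn"] + s2["syn"]) / 2
    N <- N + (s1["nonsyn"] + s2["nonsyn"]) / 2
    d <- oracle_pair_diffs(ca[k], cb[k])
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  pS <- unname(Sd / S); pN <- unname(Nd / N)
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       Ks = jc(pS), Ka = jc(pN))
}

# per-site brute-force site classification
oracle_classify_sites <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n_var <- 0; n_pis <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tb <- table(col)
    if (length(tb) >= 2) {
      n_var <- n_var + 1
      if (sum(tb >= 2) >= 2) n_pis <- n_pis + 1
    }
  }
  c(variable = n_var, pis = n_pis, singleton = n_var - n_pis)
}

# extract a possibly origin-wrapping slice by rotating the genome string first
oracle_rotated_slice <- function(seq, start, end) {
  rot <- paste0(substr(seq, start, nchar(seq)), substr(seq, 1, start - 1))
  len <- if (end >= start) end - start + 1 else nchar(seq) - start + 1 + end
  substr(rot, 1, len)
}

# brute-force ts/tv over all pairs and sites
oracle_ts_tv <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  ts <- 0; tv <- 0
  pur <- c("A", "G")
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    for (k in seq_len(ncol(m))) {
      x <- m[i, k]; y <- m[j, k]
      if (!x %in% c("A", "C", "G", "T") || !y %in% c("A", "C", "G", "T")) next
      if (x == y) next
      if ((x %in% pur) == (y %in% pur)) ts <- ts + 1 else tv <- tv + 1
    }
  }
  c(ts = ts, tv = tv)
}
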