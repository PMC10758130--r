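---
title: "Methods: comparative mitogenomics with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

This vignette is the package's account of its methods: the models and
statistics it implements, the conventions and numerical choices behind them,
what the simulator does and does not emulate, and the known limitations. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The data model

A `mito_record` is one annotated mitogenome: the deposited plus-strand
sequence, a feature table (canonical gene symbols, 1-based inclusive
coordinates, strand, `codon_start`), circularity, and metadata. Coordinates
follow the GenBank convention throughout; a feature whose start exceeds its
end wraps the circular origin. Sequences are restricted to `A,C,G,T,N`: other
IUPAC ambiguity codes are rejected at parse time with a named error rather
than silently reinterpreted, because every downstream count (skews, codon
tallies, site classes) would be corrupted by a guess. `N` is permitted but
excluded from all composition denominators.

Gene names are canonicalized through a synonym table (`gene_name_table()`,
user-extensible), so `COX1`, `CO1` and `COI` are one gene. The control region
is a feature like any other (`ftype = "CR"`); when a deposit does not
annotate one, the longest unannotated stretch is *not* auto-called — an
explicit annotation is required, since a heuristic call would silently change
composition tables.

## Composition and strand asymmetry

For a sequence with base counts $n_A, n_C, n_G, n_T$:

$$\mathrm{AT\ skew} = \frac{n_A - n_T}{n_A + n_T}, \qquad
  \mathrm{GC\ skew} = \frac{n_G - n_C}{n_G + n_C},$$

with a skew reported as `NA` when its denominator is zero. Whole-genome
statistics are computed on the deposited plus strand; per-gene and per-region
statistics on the coding orientation (minus-strand features are
reverse-complemented first). This distinction matters: a minus-strand gene
such as ND6 has its skews sign-flipped relative to the genome strand, which
is exactly how it appears as a skew outlier in per-gene tables. Whether a
published per-gene table used coding or genomic strand for minus-strand genes
is often unstated; `region_composition()` and the per-gene columns of
`gene_divergence_table()` therefore document their convention (coding
orientation) and the composition source is switchable
(`composition_on = "rows"` vs `"alignment"`).

Display rounding is half-away-from-zero at 2 decimals (the convention of
printed composition tables; R's `round()` is banker's rounding and disagrees
on exact .005 boundaries). Summary rows are computed from unrounded values
and rounded last; raw values stay available in the `raw` attribute.

## Codon usage

Codon statistics use the vertebrate mitochondrial code (NCBI translation
table 2), embedded as a constant and cross-checked in the test suite against
an independent translation routine. Note that table 2 has 60 sense codons
(TAA, TAG, AGA and AGG are stops); published counts of "62 amino-acid
encoding codons" correspond to excluding only TAA/TAG, and annotated terminal
AGA/AGG (and even AAA) codons do occur in deposits. The package records each
gene's annotated terminal codon *verbatim* — artifacts included — rather than
re-translating it, so such rows are preserved and flaggable
(`stop_is_canonical`). Incomplete stops (a trailing 1–2 nt remainder,
completed in vivo by polyadenylation) are reported as `T--`/`TA-` and are
only possible when the CDS length mod 3 is 1 or 2.

RSCU for a codon $c$ in a synonymous family of size $k$ with counts $n$:
$\mathrm{RSCU}(c) = k\, n_c / \sum_{c'} n_{c'}$, `NA` for unobserved
families. By default the 13 PCGs are pooled per species (one table per
genome, as in per-species codon-usage figures); per-gene tables are available
via `per_gene = TRUE`.

## Divergence and selection

`clean_alignment()` implements the standard preparation: drop any trailing
partial codon, blank each row's terminal complete stop, then delete every
codon column containing a gap in any taxon (complete deletion at codon
granularity — required by the "termination codons and indels removed"
convention, and the reason cleaned lengths are multiples of 3). An internal
stop surviving cleaning is a reading-frame error and aborts with the taxon
and codon index.

Site classes use the standard definitions: variable = ≥2 states at a site;
parsimony-informative = ≥2 states each in ≥2 taxa; singleton = variable but
not informative. The transition/transversion ratio is the pooled count ratio
over all sites of all unordered sequence pairs — a deliberate choice of the
simple count statistic over a model-based estimate, since published tables
rarely state which was used; the choice is documented and the counts
(`n_ts`, `n_tv`) are returned alongside the ratio. Aupd is the mean
uncorrected p-distance over all pairs with pairwise deletion.

### Nei–Gojobori Ka/Ks

The selection statistic is the classic Nei–Gojobori (1986) method under
translation table 2:

* **Sites.** For each codon position, each of the three possible
  single-nucleotide changes contributes 1/3 of a site to the synonymous or
  nonsynonymous total according to its effect; changes *into a stop codon are
  skipped* (contributing to neither side), so a codon's S + N can be less
  than 3 — equality holds exactly when no neighbour is a stop. Per-pair S and
  N are the average of the two sequences' totals.
* **Differences.** Codon pairs differing at $k$ positions are resolved over
  all $k!$ minimal mutational pathways with equal weight, excluding pathways
  that pass through a stop codon (the original unweighted method, as
  implemented in DnaSP). In the rare case that every pathway is blocked, the
  all-pathway average is used and the pair is flagged (`n_blocked`).
* **Correction.** $p_S = S_d/S$ and $p_N = N_d/N$ receive the Jukes–Cantor
  correction $d = -\tfrac34 \ln(1 - \tfrac43 p)$; $p \ge 3/4$ yields `NA`
  with a note.

The per-gene Ka/Ks in `gene_divergence_table()` is the **ratio of means**
(mean pairwise Ka over mean pairwise Ks), not the mean of pairwise ratios:
pairwise ratios are undefined whenever a pair has $K_s = 0$ and are wildly
unstable for short genes, while the ratio of means degrades gracefully. The
mean-of-ratios variant is available (`ratio_of_means = FALSE`). One
published-methods caveat is recorded here: the reference workflow computed
"π-modified" Ka/Ks in DnaSP, a variant that is not precisely defined in
print; this package implements classic NG + JC, and the acceptance checks
against published per-gene values therefore carry a tolerance of one unit in
the last printed digit.

The implementation is table-driven (precomputed 64×64 pathway-averaged
difference matrices); its correctness oracle is an independently written
brute-force pathway enumerator in the test suite, and the two agree to
1e−9 on random codon-pair sweeps.

## Phylogenetics plumbing

Bayesian/ML tree inference engines are out of scope by design: partitioned
supermatrices are *exported* (relaxed PHYLIP, NEXUS with charsets,
RAxML-style partition files, byte-stable for fixed input) for external
engines, while in-repo topology checks use neighbor joining on p/JC
distances. NJ, rooting, Robinson–Foulds distances and distance matrices are
delegated to `ape` behind thin validated wrappers (`nj_tree()` checks
symmetry, zero diagonal, non-negativity). Monophyly is judged on the tree
rooted at a stated outgroup. Missing taxon-by-gene blocks in supermatrices
are `?`; `-` is reserved for alignment gaps.

Alignments are consumed, not produced: mitochondrial PCGs are nearly
indel-free among congeners, and `alignment_from_records()` assembles an
alignment directly whenever the extracted genes are equal-length (always true
for simulator output). Real datasets with length variation need an external
aligner; the package deliberately does not guess one.

## The simulator

The simulator exists so that every statistic above can be validated against
known truth. Its defaults are the study conditions of a 12-genome shorebird
comparison:

| parameter | default | rationale |
|---|---|---|
| architecture | 37 genes + CR, avian order; ND6 + 8 tRNAs on minus strand | the conserved layout of the genomes under study |
| PCG lengths | the published per-gene cleaned lengths (165 bp ATP8 … 1,812 bp ND5) | so cleaned-length checks are meaningful |
| start/stop codons | per-gene as reported (GTG starts for COI/ND5, ATC for ND3; incomplete `T--` stops for ND2/COIII/ND4; AGG/AGA terminal codons preserved) | reproduces the start/stop usage table structure |
| per-gene omega | the published per-gene Ka/Ks column (0.02 COI … 0.16 ATP8) | heterogeneous selection with a known ordering to recover |
| kappa | 8 | pooled observed ts/tv ≈ 4 and the count ratio ≈ κ/2 at these frequencies |
| base frequencies | A 31.41, C 31.06, G 13.74, T 23.72 % | the reported mean composition (AT-rich, A-skewed, C-skewed) |
| tree | 12-taxon, two-genera-plus-clade shape, depth ≈ 0.07 subst/site | congeneric mitogenome divergence scale |
| spacers | 0–23 bp, longest 23 bp at a designated junction | the reported 1–23 bp spacer range |

Protein-coding genes evolve under a continuous-time codon model simulated
with exponential waiting times (Gillespie): the rate of each single-nucleotide
codon change is proportional to the target base frequency, multiplied by κ
for transitions and by the gene's ω for nonsynonymous changes; substitutions
into stops are forbidden, and the designated start/stop codons are held
fixed. Rates are normalized at each branch's starting state so branch lengths
are expected substitutions per nucleotide site. tRNAs, rRNAs, the control
region and spacers evolve under an HKY model with the same κ. Ancestor
composition targeting accounts for stop-codon rejection: the per-base
frequencies used for codon sampling are pre-adjusted by a deterministic
fixed-point so the *realized* composition matches the requested one
(rejection of the A-rich stops would otherwise depress A content). Coding
sequences of minus-strand genes are drawn from complemented frequencies so
the deposited plus strand is compositionally homogeneous — which also
reproduces the sign-flipped skew of minus-strand genes for free.

What the simulator does **not** emulate: indels and rearrangements (gene
order is invariant by construction), replication-origin mutational gradients,
tRNA secondary-structure constraints, feature overlaps (real mitogenomes
overlap ATP8/ATP6 and ND4L/ND4 by a few bases; overlap arithmetic is instead
exercised by hand-built parser fixtures), and among-site rate variation
within genes. Passing tests on simulated data therefore demonstrate the
correctness of the statistics under the stated model, not robustness to
alignment error or annotation noise in real deposits.

## Validation harnesses and problem sizes

The acceptance suite runs entirely offline at these sizes, chosen to give
stable pass/fail behaviour at interactive runtimes:

* NG vs brute-force oracle: 100 random 12-codon pairs, agreement to 1e−9.
* Omega-ordering recovery: 50 replicates × 3 genes (ω = 0.05/0.2/0.8), 300
  codons, 10 taxa; the estimated ordering must match in ≥95% of replicates.
* Neutral recovery: 50 two-taxon replicates at ω = 1, total divergence 0.1.
  This check runs at κ = 1 and uniform base frequencies — the regime where
  NG's unweighted site counting is unbiased. Under transition bias the
  estimator is *known* to be conservatively biased downward (more of the
  realized substitutions are synonymous than its site counts assume), which
  is visible in the package's own harness: with the full biased defaults the
  estimated Ka/Ks sits below the programmed ω while preserving orderings.
  This is a property of the NG method, faithfully reproduced, not a defect
  of the simulator.
* NJ recovery: exact on additive matrices (10 random trees, path lengths to
  1e−9), and RF = 0 in ≥90% of 20 low-noise simulated replicates.

The published-value checks (composition table, cleaned lengths, start-codon
shares, ATP8 statistics) require the 12 deposited GenBank records, which are
third-party data the package does not bundle; those tests state how to fetch
them and fail otherwise rather than silently skipping.

## Degenerate inputs and tie-breaks

Empty or all-`N` sequences give `NA` composition with a warning; zero
transversions give `NA` ts/tv with a note; zero comparable sites give `NA`
p-distance; $K_s = 0$ gives `NA` Ka/Ks; single records are rejected by the
comparative pipeline (≥2 needed, ≥3 for NJ). Concatenation order is fixed by
configuration, not input order, so permuted inputs give byte-identical
exports; taxon labels with whitespace are sanitized with an emitted mapping
table. All simulator entry points take explicit seeds and restore the
caller's RNG state.
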