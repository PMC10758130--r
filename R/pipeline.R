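# One-command reproduction of the comparative-mitogenomics analysis surface
# from a directory of GenBank flat files (or in-memory records): composition
# and skew tables, gene-order and spacer audits, codon-usage and RSCU tables,
# per-gene divergence/selection table, supermatrix exports and an NJ tree,
# with a checksum manifest for byte-reproducibility.

DATASET_A_GENES <- c("Cyt b", "12S", "ND2")
DATASET_B_GENES <- c(PCG_NAMES, "12S", "16S")

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Parses (or accepts) at least two annotated mitogenome records, then writes
#' the complete report bundle to `output_dir`: composition table with summary
#' rows, per-region composition, gene order and intergenic spacer audits,
#' start/stop codon usage, RSCU, the per-gene divergence/selection table,
#' concatenated supermatrices for the configured gene sets with PHYLIP/NEXUS/
#' RAxML-partition exports, a neighbor-joining tree on JC distances, optional
#' monophyly verdicts, a structured run log and a checksum manifest.
#' Unparseable inputs are quarantined and logged; the run continues while at
#' least two records survive. Per-gene divergence and supermatrix stages need
#' per-taxon gene sequences of equal length; supply `alignments` (a named
#' list of `codon_alignment` or a directory of per-gene FASTA files) for real
#' data whose gene lengths differ.
#'
#' @param input Directory containing `.gb`/`.gbk` flat files, a character
#'   vector of file paths, or a list of `mito_record` objects.
#' @param output_dir Output directory (created if needed).
#' @param alignments Optional named list of `codon_alignment` objects or a
#'   directory of `<gene>.fasta` files.
#' @param gene_sets Named list of gene symbol vectors to concatenate
#'   (default: dataset `a` = Cyt b + 12S + ND2; dataset `b` = 13 PCGs + both
#'   rRNAs).
#' @param monophyly Optional named list; each element a list with `taxa` and
#'   `outgroup` giving a monophyly hypothesis to evaluate on the NJ tree.
#' @param digits Rounding for display tables (default 2).
#' @return Invisibly, a list with the computed tables, the NJ tree, the
#'   manifest tibble and the path of every file written.
#' @export
run_pipeline <- function(input, output_dir, alignments = NULL,
                         gene_sets = list(a = DATASET_A_GENES,
                                          b = DATASET_B_GENES),
                         monophyly = NULL, digits = 2) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # -- ingest ---------------------------------------------------------------
  if (is.character(input)) {
    files <- if (length(input) == 1 && dir.exists(input)) {
      list.files(input, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
    } else input
    records <- list()
    for (f in sort(files)) {
      parsed <- tryCatch(parse_genbank(file = f), error = function(e) e)
      if (inherits(parsed, "error")) {
        say("parse", "QUARANTINED %s: %s", basename(f), conditionMessage(parsed))
      } else {
        records <- c(records, parsed)
      }
    }
  } else {
    records <- input
  }
  if (length(records) < 2) {
    abort("comparative analysis needs >= 2 parseable records")
  }
  say("parse", "%d records ingested", length(records))

  files_out <- character(0)
  emit <- function(df, name) {
    p <- write_tsv_file(df, file.path(output_dir, name))
    files_out <<- c(files_out, p)
    p
  }

  # -- audits ---------------------------------------------------------------
  orders <- purrr::map(records, function(r) {
    gene_order(r) |> mutate(accession = r$accession, .before = 1)
  }) |> bind_rows()
  emit(orders, "gene_order.tsv")
  spacers <- purrr::map(records, function(r) {
    intergenic_spacers(r) |> mutate(accession = r$accession, .before = 1)
  }) |> bind_rows()
  emit(spacers, "spacers.tsv")
  say("audit", "gene order and spacers written for %d records", length(records))

  # -- composition ----------------------------------------------------------
  comp <- composition_table(records, digits = digits)
  emit(comp, "composition.tsv")
  regions <- purrr::map(records, function(r) {
    region_composition(r) |> mutate(accession = r$accession, .before = 1)
  }) |> bind_rows()
  emit(regions, "region_composition.tsv")
  say("composition", "tables written")

  # -- codon usage ----------------------------------------------------------
  usage <- start_stop_usage(records)
  emit(usage, "start_stop_usage.tsv")
  emit(start_stop_summary(usage), "start_stop_summary.tsv")
  rscu_tbl <- rscu(count_codons(records))
  emit(rscu_tbl, "rscu.tsv")
  say("codon", "start/stop and RSCU tables written")

  # -- per-gene alignments --------------------------------------------------
  if (is.character(alignments) && length(alignments) == 1 &&
      dir.exists(alignments)) {
    fa <- list.files(alignments, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    alignments <- setNames(
      purrr::map(fa, ~read_alignment(.x, gene = tools::file_path_sans_ext(basename(.x)))),
      tools::file_path_sans_ext(basename(fa))
    )
  }
  labels <- vapply(records, function(r) r$accession, "")
  build_aln <- function(gene) {
    tryCatch(alignment_from_records(records, gene, labels = labels),
             error = function(e) { say("align", "SKIP %s: %s", gene,
                                       conditionMessage(e)); NULL })
  }
  get_aln <- function(gene) {
    if (!is.null(alignments) && gene %in% names(alignments)) {
      alignments[[gene]]
    } else build_aln(gene)
  }

  pcg_alns <- purrr::compact(setNames(purrr::map(PCG_NAMES, get_aln), PCG_NAMES))
  divergence <- NULL
  if (length(pcg_alns) > 0) {
    divergence <- gene_divergence_table(pcg_alns)
    emit(divergence |> mutate(across(dplyr::where(is.numeric),
                                     ~round_half_up(.x, max(digits, 2)))),
         "gene_divergence.tsv")
    say("divergence", "table written for %d genes", nrow(divergence))
  } else {
    say("divergence", "no usable gene alignments; stage skipped")
  }

  # -- supermatrices and tree -----------------------------------------------
  matrices <- list()
  for (set_name in names(gene_sets)) {
    alns <- purrr::compact(setNames(purrr::map(gene_sets[[set_name]], get_aln),
                                    gene_sets[[set_name]]))
    if (length(alns) == 0) {
      say("concat", "dataset %s: no alignments available; skipped", set_name)
      next
    }
    cm <- concatenate_genes(alns)
    matrices[[set_name]] <- cm
    base <- file.path(output_dir, sprintf("supermatrix_%s", set_name))
    export_phylip(cm, paste0(base, ".phy"))
    export_nexus(cm, paste0(base, ".nex"))
    export_partitions_raxml(cm, paste0(base, ".partitions"))
    files_out <- c(files_out, paste0(base, c(".phy", ".nex", ".partitions")))
    say("concat", "dataset %s: %d taxa x %d sites, %d partitions",
        set_name, nrow(cm$seqs), nchar(cm$seqs$sequence[1]), nrow(cm$partitions))
  }

  tree <- NULL
  verdicts <- NULL
  if (length(matrices) > 0 && length(records) >= 3) {
    cm <- matrices[[length(matrices)]] # the largest configured set
    D <- distance_matrix(cm, model = "JC69")
    tree <- nj_tree(D)
    tree_path <- file.path(output_dir, "nj_tree.nwk")
    ape::write.tree(tree, tree_path)
    files_out <- c(files_out, tree_path)
    say("nj", "tree written on dataset '%s'", names(matrices)[length(matrices)])
    if (!is.null(monophyly)) {
      verdicts <- purrr::imap(monophyly, function(h, nm) {
        tibble(hypothesis = nm,
               monophyletic = is_monophyletic(tree, h$taxa, h$outgroup))
      }) |> bind_rows()
      emit(verdicts, "monophyly.tsv")
      say("nj", "%d monophyly verdicts written", nrow(verdicts))
    }
  } else if (length(records) < 3) {
    say("nj", "fewer than 3 records: tree stage skipped")
  }

  # -- manifest and log -----------------------------------------------------
  log_path <- file.path(output_dir, "run.log")
  writeLines(log_lines, log_path)
  manifest <- tibble(
    file = basename(files_out),
    md5 = unname(tools::md5sum(files_out))
  ) |> arrange(.data$file)
  write_tsv_file(manifest, file.path(output_dir, "manifest.tsv"))

  invisible(list(
    records = records, composition = comp, divergence = divergence,
    rscu = rscu_tbl, start_stop = usage, matrices = matrices, tree = tree,
    monophyly = verdicts, manifest = manifest,
    files = c(files_out, log_path, file.path(output_dir, "manifest.tsv"))
  ))
}
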