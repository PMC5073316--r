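# One-call report regenerating the descriptive tables of a mitogenome study
# from an annotated genome (with sequence) or from annotation-only inputs
# (a gene table and a codon-count table).

#' Generate an end-to-end descriptive report
#'
#' Runs every applicable pipeline stage and bundles the results: per-partition
#' composition (sequence inputs only), codon usage and RSCU, the circular
#' adjacency ledger with overlap/spacer summaries, start/stop-codon
#' classification (sequence inputs only), strand census, gene-order
#' comparison against a reference arrangement, and control-region element
#' scanning (sequence inputs only). Stages whose inputs are missing are
#' skipped and listed in `skipped`. Deterministic: identical inputs give an
#' identical bundle.
#'
#' @param genome Optional [mitogenome()]; when it has a sequence, the
#'   sequence-dependent stages run.
#' @param gene_table Optional `gene_table`; defaults to `genome$features`.
#' @param codon_counts Optional `codon_count_tbl` used when no sequence is
#'   available.
#' @param genome_length Genome length for the adjacency ledger when only a
#'   gene table is supplied (defaults to the maximum feature end).
#' @param reference_order Reference circular gene order for rearrangement
#'   detection: a preset name (see [gene_order_preset()]) or a character
#'   vector. `NULL` skips the comparison.
#' @param rscu_scheme Family scheme passed to [rscu()].
#' @param cr_motif Motif scanned for in the control region.
#' @param with_provenance Attach input hashes (set `FALSE` for byte-stable
#'   output across renamed inputs).
#' @return A `mito_report` list with elements `composition_table`,
#'   `codon_table`, `adjacency_table`, `adjacency_summary`, `codon_calls`,
#'   `strand_census`, `gene_order_findings`, `cr_findings`, `skipped`,
#'   `provenance`.
#' @export
#' @examples
#' rep <- generate_report(gene_table = table2_fixture(),
#'                        codon_counts = table3_fixture())
#' rep$adjacency_summary
generate_report <- function(genome = NULL, gene_table = NULL,
                            codon_counts = NULL, genome_length = NULL,
                            reference_order = "ancestral_insect",
                            rscu_scheme = "pooled",
                            cr_motif = "ATAGA",
                            with_provenance = TRUE) {
  if (is.null(genome) && is.null(gene_table)) {
    abort("supply at least a genome or a gene table")
  }
  gene_table <- gene_table %||% genome$features
  L <- genome_length %||% genome$length %||% max(gene_table$end, gene_table$start)
  has_seq <- !is.null(genome) && !is.null(genome$sequence)
  skipped <- character()

  ledger <- adjacency_ledger(gene_table, L = L)
  adjacency_summary <- glance(ledger)
  census <- strand_census(gene_table)

  composition_table <- NULL
  codon_calls <- NULL
  cr_findings <- NULL
  if (has_seq) {
    composition_table <- partition_composition(genome)
    pcgs <- feature_sequences(genome)
    pcg_rows <- pcgs[pcgs$category == "PCG", ]
    codon_calls <- classify_start_stop(setNames(pcg_rows$sequence, pcg_rows$gene))
    cr_row <- gene_table[gene_table$category == "control_region", ]
    if (nrow(cr_row) == 1) {
      cr_seq <- extract_feature_sequence(genome, cr_row)
      cr_findings <- list(
        motif = find_motif(cr_seq, cr_motif),
        poly_T = longest_run(cr_seq, "T"),
        poly_A = longest_run(cr_seq, "A"),
        microsatellite = find_microsatellite(cr_seq, "AT", min_copies = 5),
        tandem = find_tandem_repeats(cr_seq, min_unit = 10,
                                     max_unit = min(60L, nchar(cr_seq) %/% 2L))
      )
    } else {
      skipped <- c(skipped, "cr_findings: no control region annotated")
    }
    if (is.null(codon_counts)) {
      pcg_seqs <- setNames(pcg_rows$sequence, pcg_rows$gene)
      codon_counts <- count_codons(pcg_seqs)
    }
  } else {
    skipped <- c(skipped,
                 "composition_table: missing sequence",
                 "codon_calls: missing sequence",
                 "cr_findings: missing sequence")
  }

  codon_table <- NULL
  if (!is.null(codon_counts)) {
    codon_table <- rscu(codon_counts, scheme = rscu_scheme)
  } else {
    skipped <- c(skipped, "codon_table: no codon counts available")
  }

  gene_order_findings <- NULL
  if (!is.null(reference_order)) {
    ref <- if (length(reference_order) == 1) {
      gene_order_preset(reference_order)
    } else {
      reference_order
    }
    observed <- gene_table$gene
    if (setequal(observed, ref)) {
      gene_order_findings <- compare_gene_order(observed, ref)
    } else {
      skipped <- c(skipped,
                   "gene_order_findings: observed and reference name sets differ")
    }
  }

  provenance <- list(tool = "mitoprofiler", version = as.character(utils::packageVersion("mitoprofiler")),
                     rscu_scheme = rscu_scheme, cr_motif = cr_motif)
  if (with_provenance) {
    provenance$input_hashes <- list(
      gene_table = rlang::hash(as.data.frame(gene_table)),
      sequence = if (has_seq) rlang::hash(genome$sequence) else NULL,
      codon_counts = if (!is.null(codon_counts))
        rlang::hash(as.data.frame(codon_counts)) else NULL
    )
  }

  structure(
    list(composition_table = composition_table, codon_table = codon_table,
         adjacency_table = ledger, adjacency_summary = adjacency_summary,
         codon_calls = codon_calls, strand_census = census,
         gene_order_findings = gene_order_findings, cr_findings = cr_findings,
         skipped = skipped, provenance = provenance),
    class = "mito_report"
  )
}

#' @export
print.mito_report <- function(x, ...) {
  cat("<mito_report>\n")
  s <- x$adjacency_summary
  cat(sprintf("  adjacency: %d junctions; overlap %d bp / %d sites; spacer %d bp / %d sites\n",
              s$n_pairs, s$total_overlap_bp, s$overlap_locations,
              s$total_spacer_bp, s$spacer_locations))
  cat(sprintf("  strand census: %d forward / %d reverse\n",
              x$strand_census[["forward"]], x$strand_census[["reverse"]]))
  if (!is.null(x$codon_table)) {
    cat(sprintf("  codon table: %d codons counted\n", sum(x$codon_table$count)))
  }
  if (!is.null(x$gene_order_findings)) {
    cat(sprintf("  gene order: %d breakpoint(s) vs reference; moved: %s\n",
                x$gene_order_findings$breakpoint_count,
                paste(x$gene_order_findings$moved_genes, collapse = ", ")))
  }
  if (length(x$skipped) > 0) {
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname generate_report
#' @param x A `mito_report`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble of headline numbers.
#' @method glance mito_report
#' @export
glance.mito_report <- function(x, ...) {
  dplyr::bind_cols(
    x$adjacency_summary,
    tibble(forward_genes = x$strand_census[["forward"]],
           reverse_genes = x$strand_census[["reverse"]],
           codon_total = if (is.null(x$codon_table)) NA_integer_
                         else sum(x$codon_table$count),
           breakpoints = if (is.null(x$gene_order_findings)) NA_integer_
                         else x$gene_order_findings$breakpoint_count,
           moved_genes = if (is.null(x$gene_order_findings)) NA_character_
                         else paste(x$gene_order_findings$moved_genes, collapse = ","))
  )
}

#' Write a report bundle to machine-readable files
#'
#' Tables go to TSV, summaries and control-region findings to JSON.
#'
#' @param report A `mito_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(dir, name)
  if (!is.null(report$composition_table)) {
    readr::write_tsv(report$composition_table, out("composition.tsv"))
  }
  if (!is.null(report$codon_table)) {
    readr::write_tsv(report$codon_table, out("codon_usage.tsv"))
  }
  readr::write_tsv(report$adjacency_table, out("adjacency.tsv"))
  summary <- c(
    as.list(report$adjacency_summary),
    list(strand_census = as.list(report$strand_census),
         moved_genes = report$gene_order_findings$moved_genes %||% character(),
         skipped = report$skipped, provenance = report$provenance)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(report$cr_findings)) {
    jsonlite::write_json(report$cr_findings, out("cr_findings.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
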