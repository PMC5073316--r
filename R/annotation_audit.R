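# Circular gene-adjacency auditing, start/stop classification, strand census,
# and gene-order comparison.
#
# For consecutive features in genomic order (wrapping last -> first across
# the origin) the signed gap is downstream.start - upstream.end - 1: positive
# values are intergenic spacers, negative values overlaps, zero abutment.
# Gaps are always computed from coordinates; if the source table carries a
# declared intergenic column (as published gene tables do), it is joined in
# as a cross-check and summaries can be drawn from either column.

#' Circular adjacency ledger of a gene table
#'
#' @param table A `gene_table` (control region included as a feature).
#' @param L Genome length in bp (needed to close the circle).
#' @return An `adjacency_ledger` tibble with one row per ordered neighbour
#'   pair (`upstream`, `downstream`, `gap`, and `declared_gap` when the table
#'   carried a declared intergenic column), `nrow == nrow(table)` by circular
#'   closure. Attribute `L` stores the genome length.
#' @export
#' @examples
#' led <- adjacency_ledger(table2_fixture(), L = 15396)
#' glance(led)
adjacency_ledger <- function(table, L) {
  if (nrow(table) == 0) abort("cannot audit an empty gene table")
  key <- paste(table$start, table$end)
  if (anyDuplicated(key) > 0) {
    dup <- table$gene[key %in% key[duplicated(key)]]
    abort(sprintf("duplicated coordinates for: %s", paste(dup, collapse = ", ")))
  }
  validate_gene_table(table, L = L)
  n <- nrow(table)
  up <- table
  down <- table[c(seq_len(n)[-1], 1L), ]
  gap <- down$start - up$end - 1L
  # close the circle: add L unless the last feature already wraps the origin
  gap[n] <- if (up$end[n] < up$start[n]) {
    down$start[n] - up$end[n] - 1L
  } else {
    down$start[n] + L - up$end[n] - 1L
  }
  out <- tibble(upstream = up$gene, downstream = down$gene, gap = as.integer(gap))
  if ("intergenic" %in% names(table)) out$declared_gap <- up$intergenic
  attr(out, "L") <- as.integer(L)
  class(out) <- c("adjacency_ledger", class(tibble()))
  out
}

ledger_gap_column <- function(ledger, source = c("computed", "declared")) {
  source <- match.arg(source)
  if (source == "declared") {
    if (!"declared_gap" %in% names(ledger)) {
      abort("ledger has no declared intergenic column")
    }
    ledger$declared_gap
  } else {
    ledger$gap
  }
}

#' Overlap totals of an adjacency ledger
#'
#' @param ledger An [adjacency_ledger()].
#' @param source `"computed"` (coordinate-derived gaps, default) or
#'   `"declared"` (the gene table's printed intergenic column, as a
#'   cross-check against the source publication).
#' @return Named integer vector `c(total_bp, locations)`: summed absolute
#'   overlap and the number of overlapping junctions.
#' @export
overlap_summary <- function(ledger, source = c("computed", "declared")) {
  gap <- ledger_gap_column(ledger, source)
  neg <- gap[!is.na(gap) & gap < 0]
  c(total_bp = as.integer(sum(-neg)), locations = length(neg))
}

#' Spacer totals of an adjacency ledger
#'
#' @inheritParams overlap_summary
#' @return Named integer vector `c(total_bp, locations)` over positive gaps.
#' @export
spacer_summary <- function(ledger, source = c("computed", "declared")) {
  gap <- ledger_gap_column(ledger, source)
  pos <- gap[!is.na(gap) & gap > 0]
  c(total_bp = as.integer(sum(pos)), locations = length(pos))
}

#' @method glance adjacency_ledger
#' @export
glance.adjacency_ledger <- function(x, ...) {
  ov <- overlap_summary(x)
  sp <- spacer_summary(x)
  i_ov <- which(x$gap == min(x$gap))[1]
  i_sp <- which(x$gap == max(x$gap))[1]
  tibble(
    n_pairs = nrow(x),
    total_overlap_bp = ov[["total_bp"]], overlap_locations = ov[["locations"]],
    total_spacer_bp = sp[["total_bp"]], spacer_locations = sp[["locations"]],
    longest_overlap_bp = max(0L, -min(x$gap)),
    longest_overlap_pair = if (x$gap[i_ov] < 0)
      paste(x$upstream[i_ov], x$downstream[i_ov], sep = "/") else NA_character_,
    longest_spacer_bp = max(0L, max(x$gap)),
    longest_spacer_pair = if (x$gap[i_sp] > 0)
      paste(x$upstream[i_sp], x$downstream[i_sp], sep = "/") else NA_character_
  )
}

#' @method autoplot adjacency_ledger
#' @export
autoplot.adjacency_ledger <- function(object, ...) {
  df <- mutate(object,
               junction = factor(paste(.data$upstream, .data$downstream, sep = " / "),
                                 levels = paste(.data$upstream, .data$downstream, sep = " / ")),
               kind = dplyr::case_when(.data$gap < 0 ~ "overlap",
                                       .data$gap > 0 ~ "spacer",
                                       TRUE ~ "abutting"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$junction, y = .data$gap,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Signed gap (bp); < 0 = overlap") +
    ggplot2::theme_minimal()
}

#' Classify start and stop codons of coding sequences
#'
#' The start codon is the first triplet, canonical iff it matches `ATN`.
#' The stop literal is the trailing `length %% 3` nucleotides when the length
#' is not a codon multiple (a truncated stop, completed to UAA by
#' polyadenylation; a warning is raised when the literal is not `T`, `TA` or
#' `A` and so cannot be completed that way), otherwise the final triplet
#' (complete iff `TAA`/`TAG`, else flagged `noncanonical_complete`).
#' Complete in-frame stops before the final codon raise a warning listing
#' their positions.
#'
#' @param cds Character vector of CDS strings in coding orientation, each
#'   at least 4 nt; names are used as gene labels.
#' @return Tibble with `gene`, `start_codon`, `start_class`, `stop_literal`,
#'   `stop_class`.
#' @export
#' @examples
#' classify_start_stop(c(cox2 = paste0("ATG", strrep("AAA", 226), "T")))
classify_start_stop <- function(cds) {
  ids <- names(cds) %||% as.character(seq_along(cds))
  rows <- purrr::map(seq_along(cds), function(i) {
    s <- toupper(cds[[i]])
    n <- nchar(s)
    if (n < 4) abort(sprintf("CDS '%s' is too short (%d nt)", ids[i], n))
    start_codon <- substr(s, 1, 3)
    start_class <- if (grepl("^AT[ACGT]$", start_codon)) "canonical_ATN" else "noncanonical"
    r <- n %% 3
    if (r > 0) {
      stop_literal <- substr(s, n - r + 1, n)
      stop_class <- "truncated"
      if (!stop_literal %in% c("T", "TA", "A")) {
        warn(sprintf("CDS '%s': truncated stop '%s' cannot extend to TAA by polyadenylation",
                     ids[i], stop_literal))
      }
    } else {
      stop_literal <- substr(s, n - 2, n)
      stop_class <- if (stop_literal %in% c("TAA", "TAG")) "complete" else "noncanonical_complete"
    }
    body_end <- n - (if (r > 0) r else 3L)
    if (body_end >= 6) {
      codons <- substring(s, seq(4, body_end - 2, 3), seq(6, body_end, 3))
      internal <- which(codons %in% c("TAA", "TAG"))
      if (length(internal) > 0) {
        warn(sprintf("CDS '%s': internal stop codon(s) at nt position(s) %s",
                     ids[i], paste(3 * internal + 1, collapse = ", ")))
      }
    }
    tibble(gene = ids[i], start_codon = start_codon, start_class = start_class,
           stop_literal = stop_literal, stop_class = stop_class)
  })
  dplyr::bind_rows(rows)
}

#' Strand census of a gene table
#'
#' Counts genes encoded on the majority (forward/J) and minority (reverse/N)
#' strands; the control region is excluded.
#'
#' @param table A `gene_table`.
#' @return Named integer vector `c(forward, reverse)`.
#' @export
#' @examples
#' strand_census(table2_fixture())  # c(forward = 23, reverse = 14)
strand_census <- function(table) {
  genes <- table[table$category != "control_region", ]
  c(forward = sum(genes$strand == "forward"),
    reverse = sum(genes$strand == "reverse"))
}

# TRUE iff circular orders a and b are identical up to rotation (reflection
# is deliberately NOT an equivalence: mitogenome strand conventions fix the
# reading direction).
rotation_equal <- function(a, b) {
  n <- length(a)
  if (n != length(b)) return(FALSE)
  if (n == 0) return(TRUE)
  for (j in which(b == a[1])) {
    idx <- ((j - 1L + seq_len(n) - 1L) %% n) + 1L
    if (all(b[idx] == a)) return(TRUE)
  }
  FALSE
}

#' Compare two circular gene orders
#'
#' Breakpoints are directed adjacencies (circular successor pairs) present in
#' the observed order but absent from the reference; zero breakpoints iff the
#' two circular orders are identical up to rotation. `moved_genes` lists each
#' gene whose single removal reconciles the two orders, i.e. candidate single
#' translocations.
#'
#' @param observed,reference Character vectors holding the same set of gene
#'   names in circular order.
#' @return A `gene_order_diff` object (list with `breakpoint_count`,
#'   `moved_genes`, `n_genes`); see [tidy.gene_order_diff()].
#' @export
#' @examples
#' d <- compare_gene_order(gene_order_preset("lepidopteran"),
#'                         gene_order_preset("ancestral_insect"))
#' d$moved_genes
compare_gene_order <- function(observed, reference) {
  sd <- c(setdiff(observed, reference), setdiff(reference, observed))
  if (length(sd) > 0 || length(observed) != length(reference)) {
    abort(sprintf("gene name sets differ: %s",
                  paste(unique(sd), collapse = ", ")))
  }
  succ <- function(x) paste(x, x[c(seq_along(x)[-1], 1L)], sep = "\r")
  breakpoints <- sum(!succ(observed) %in% succ(reference))
  moved <- character()
  if (!rotation_equal(observed, reference)) {
    for (g in observed) {
      if (rotation_equal(observed[observed != g], reference[reference != g])) {
        moved <- c(moved, g)
      }
    }
  }
  structure(
    list(breakpoint_count = as.integer(breakpoints), moved_genes = moved,
         n_genes = length(observed)),
    class = "gene_order_diff"
  )
}

#' @export
print.gene_order_diff <- function(x, ...) {
  cat(sprintf("<gene_order_diff> %d genes, %d breakpoint(s)\n",
              x$n_genes, x$breakpoint_count))
  if (length(x$moved_genes) > 0) {
    cat("  single-relocation candidates:", paste(x$moved_genes, collapse = ", "), "\n")
  } else if (x$breakpoint_count == 0) {
    cat("  orders identical up to rotation\n")
  }
  invisible(x)
}

#' @rdname compare_gene_order
#' @param x A `gene_order_diff`.
#' @param ... Unused.
#' @method tidy gene_order_diff
#' @export
tidy.gene_order_diff <- function(x, ...) {
  tibble(breakpoint_count = x$breakpoint_count,
         n_moved = length(x$moved_genes),
         moved_genes = paste(x$moved_genes, collapse = ","),
         n_genes = x$n_genes)
}

#' Built-in circular gene-order references
#'
#' `"ancestral_insect"` is the plesiomorphic insect arrangement
#' (Drosophila-type, trnM between trnQ and nad2); `"lepidopteran"` is the
#' derived arrangement shared by ditrysian Lepidoptera, in which trnM sits
#' between the control region and trnI.
#'
#' @param name `"lepidopteran"` or `"ancestral_insect"`.
#' @return Character vector of 38 feature names (37 genes + control region)
#'   in circular order.
#' @export
gene_order_preset <- function(name = c("lepidopteran", "ancestral_insect")) {
  name <- match.arg(name)
  core <- c("nad2", "trnW", "trnC", "trnY", "cox1", "trnL2(UUR)", "cox2",
            "trnK", "trnD", "atp8", "atp6", "cox3", "trnG", "nad3", "trnA",
            "trnR", "trnN", "trnS1(AGN)", "trnE", "trnF", "nad5", "trnH",
            "nad4", "nad4L", "trnT", "trnP", "nad6", "cob", "trnS2(UCN)",
            "nad1", "trnL1(CUN)", "rrnL", "trnV", "rrnS", "A+T-rich region")
  switch(name,
    lepidopteran = c("trnM", "trnI", "trnQ", core),
    ancestral_insect = c("trnI", "trnQ", "trnM", core)
  )
}
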