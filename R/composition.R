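# Nucleotide composition and strand skew.
#
# AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C). Both accept raw
# counts or percentages (the formula is scale-invariant), and both modes are
# first-class: published composition tables usually print percentages rounded
# to one decimal, and skews recomputed from those rounded percentages can
# differ in the third decimal from skews computed from raw counts. Profiles
# therefore carry a `source_mode` label saying which mode produced them.

#' Count nucleotides in a DNA string
#'
#' Exact counts of A, C, G, T. `N` is tolerated, excluded from the four base
#' counts and reported separately; any other character is an error naming the
#' offending offset.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @return Named integer vector with elements `A`, `C`, `G`, `T`, `N`.
#' @export
#' @examples
#' count_nucleotides("AATG")
count_nucleotides <- function(seq) {
  seq <- check_dna(seq)
  if (nchar(seq) == 0) {
    return(c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L))
  }
  tab <- table(factor(str_chars(seq), levels = c(DNA_BASES, "N")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' AT skew
#'
#' `(a - t) / (a + t)`, computed at full precision; rounding is a report-time
#' concern (see [round_half_up()]). Counts and percentages are both accepted.
#'
#' @param a,t Numeric measures of A and T (counts or percentages).
#' @return Numeric skew in `[-1, 1]`.
#' @export
#' @examples
#' at_skew(40.8, 39.7)
at_skew <- function(a, t) {
  if (any(a + t == 0)) abort("AT skew is undefined when a + t = 0")
  (a - t) / (a + t)
}

#' GC skew
#'
#' `(g - c) / (g + c)` at full precision.
#'
#' @param g,c Numeric measures of G and C (counts or percentages).
#' @return Numeric skew in `[-1, 1]`.
#' @export
#' @examples
#' gc_skew(7.5, 12.0)
gc_skew <- function(g, c) {
  if (any(g + c == 0)) abort("GC skew is undefined when g + c = 0")
  (g - c) / (g + c)
}

new_composition_row <- function(partition, size, counts = NULL,
                                pcts = NULL, source_mode) {
  if (!is.null(counts)) {
    denom <- sum(counts[DNA_BASES])
    pcts <- 100 * counts[DNA_BASES] / denom
  }
  tibble(
    partition = partition,
    size = as.integer(size),
    count_A = if (is.null(counts)) NA_integer_ else counts[["A"]],
    count_C = if (is.null(counts)) NA_integer_ else counts[["C"]],
    count_G = if (is.null(counts)) NA_integer_ else counts[["G"]],
    count_T = if (is.null(counts)) NA_integer_ else counts[["T"]],
    pct_A = pcts[["A"]], pct_C = pcts[["C"]],
    pct_G = pcts[["G"]], pct_T = pcts[["T"]],
    pct_AT = pcts[["A"]] + pcts[["T"]],
    at_skew = at_skew(pcts[["A"]], pcts[["T"]]),
    gc_skew = gc_skew(pcts[["G"]], pcts[["C"]]),
    source_mode = source_mode
  )
}

as_composition_tbl <- function(df) {
  class(df) <- c("composition_tbl", class(tibble()))
  df
}

#' Per-partition composition profiles of an annotated genome
#'
#' One row per partition: the whole genome plus each feature category
#' present (PCGs, tRNAs, rRNAs, control region). A partition's sequence is
#' the concatenation of its member features in genomic order; by default
#' PCGs/tRNAs/rRNAs are taken in coding orientation (reverse-strand genes
#' reverse-complemented), switchable to the stored genomic strand with
#' `orientation = "genomic"`. Overlapping features contribute their full
#' sequence to their own partition, so partitions are independent and may
#' double-count shared bases. Missing categories are skipped with a warning.
#'
#' @param genome A [mitogenome()] with a sequence.
#' @param orientation `"coding"` (default) or `"genomic"`.
#' @return A `composition_tbl` tibble (see [profile_from_percentages()] for
#'   the percentage-mode constructor).
#' @export
partition_composition <- function(genome, orientation = c("coding", "genomic")) {
  orientation <- match.arg(orientation)
  if (is.null(genome$sequence)) abort("genome has no sequence")
  fs <- feature_sequences(genome)
  if (orientation == "genomic") {
    fs$sequence <- ifelse(fs$strand == "reverse", revcomp(fs$sequence), fs$sequence)
  }
  partitions <- c(PCG = "PCGs", tRNA = "tRNAs", rRNA = "rRNAs",
                  control_region = "control region")
  rows <- list(new_composition_row(
    "mitogenome", genome$length, counts = count_nucleotides(genome$sequence),
    source_mode = "from_counts"
  ))
  for (cat in names(partitions)) {
    members <- fs[fs$category == cat, ]
    if (nrow(members) == 0) {
      warn(sprintf("no %s features; partition '%s' omitted", cat, partitions[[cat]]))
      next
    }
    seq <- paste(members$sequence, collapse = "")
    rows[[length(rows) + 1L]] <- new_composition_row(
      partitions[[cat]], nchar(seq), counts = count_nucleotides(seq),
      source_mode = "from_counts"
    )
  }
  as_composition_tbl(dplyr::bind_rows(rows))
}

#' Composition profile from printed percentages
#'
#' Reconstructs a profile row from the rounded percentages a published table
#' prints (order A, G, T, C, as such tables are laid out). Skews computed in
#' this mode reproduce printed table skews exactly; count-based skews on the
#' same data can differ in the last decimal.
#'
#' @param partition Partition label.
#' @param size Partition size in bp.
#' @param p_a,p_g,p_t,p_c Percentages of A, G, T, C; must sum to 100 +/- 0.5.
#' @return A one-row `composition_tbl` with `source_mode = "from_percentages"`.
#' @export
#' @examples
#' profile_from_percentages("rRNAs", 2151, 43.3, 4.6, 41.2, 10.9)
profile_from_percentages <- function(partition, size, p_a, p_g, p_t, p_c) {
  pcts <- c(A = p_a, G = p_g, T = p_t, C = p_c)
  if (any(pcts < 0)) abort("percentages must be non-negative")
  if (abs(sum(pcts) - 100) > 0.5) {
    abort(sprintf("percentages sum to %.2f; expected 100 +/- 0.5", sum(pcts)))
  }
  as_composition_tbl(new_composition_row(
    partition, size, pcts = as.list(pcts), source_mode = "from_percentages"
  ))
}

#' @method autoplot composition_tbl
#' @export
autoplot.composition_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("pct_A", "pct_T", "pct_G", "pct_C"),
    names_to = "base", values_to = "pct"
  )
  long$base <- factor(sub("pct_", "", long$base), levels = c("A", "T", "G", "C"))
  long$partition <- factor(long$partition, levels = unique(object$partition))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$partition, y = .data$pct,
                                     fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of partition", fill = "Base") +
    ggplot2::theme_minimal()
}
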