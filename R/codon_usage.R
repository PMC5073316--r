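# Codon usage and RSCU under the invertebrate mitochondrial genetic code
# (translation table 5: AGA/AGG = Ser, AUA = Met, UGA = Trp).
#
# RSCU_c = n_c * k / sum over the codon's synonymous family, k = family size.
# Two family schemes are supported:
#   * "pooled" (default): leucine is one six-codon family (UUR + CUN), serine
#     one eight-codon family (UCN + AGN), tryptophan {UGA, UGG}, methionine
#     {AUA, AUG}, and the two termination codons {UAA, UAG} form their own
#     family. This is the scheme codon-usage software such as MEGA applies
#     and the one that reproduces published mitogenome RSCU tables.
#   * "split": L1 (CUN) / L2 (UUR) and S1 (AGN) / S2 (UCN) are separate
#     families.

RNA_BASES <- c("U", "C", "A", "G")

codon_order <- function() {
  as.vector(vapply(RNA_BASES, function(b1)
    vapply(RNA_BASES, function(b2)
      paste0(b1, b2, RNA_BASES), character(4)), character(16)))
}

# Per-codon annotation under the invertebrate mitochondrial code, with the
# sub-family labels (L1/L2, S1/S2) mitogenome tables use.
invmito_codon_table <- function() {
  codons <- codon_order()
  code <- Biostrings::getGeneticCode("5")  # invertebrate mitochondrial
  aa <- unname(code[chartr("U", "T", codons)])
  label <- aa
  label[codons %in% c("UUA", "UUG")] <- "L2"
  label[substr(codons, 1, 2) == "CU"] <- "L1"
  label[substr(codons, 1, 2) == "UC"] <- "S2"
  label[substr(codons, 1, 2) == "AG"] <- "S1"
  pooled <- dplyr::case_when(
    aa == "L" ~ "Leu", aa == "S" ~ "Ser", aa == "*" ~ "Ter",
    TRUE ~ aa
  )
  tibble(codon = codons, aa = label, family_pooled = pooled,
         family_split = label)
}

rna_codon <- function(x) chartr("Tt", "Uu", toupper(x))

new_codon_count_tbl <- function(counts_by_codon) {
  info <- invmito_codon_table()
  out <- tibble(codon = info$codon, aa = info$aa,
                count = as.integer(counts_by_codon[info$codon]))
  out$count[is.na(out$count)] <- 0L
  attr(out, "code") <- "invertebrate mitochondrial (transl_table=5)"
  attr(out, "total") <- sum(out$count)
  class(out) <- c("codon_count_tbl", class(tibble()))
  out
}

#' Count codons across coding sequences
#'
#' For each CDS (given in coding orientation), the initiation codon and the
#' terminator are excluded, mirroring how published mitogenome codon totals
#' are compiled: the first triplet is dropped; a trailing 1-2 nt remainder is
#' dropped as a truncated stop; a final complete `TAA`/`TAG` is dropped; a
#' final complete non-stop codon is kept. Remaining in-frame triplets are
#' tallied and keyed as RNA codons (`U`, not `T`).
#'
#' @param cds_list Character vector of CDS strings (DNA or RNA), each at
#'   least 6 nt; names (if any) are used in error messages.
#' @return A `codon_count_tbl`: tibble with `codon`, `aa`, `count` over all
#'   64 codons, with attributes `total` and `code`.
#' @export
#' @examples
#' count_codons("ATGAAATTTTAA")  # counts AAA and UUU only
count_codons <- function(cds_list) {
  stopifnot(is.character(cds_list))
  ids <- names(cds_list) %||% as.character(seq_along(cds_list))
  all_codons <- character()
  for (i in seq_along(cds_list)) {
    s <- rna_codon(cds_list[[i]])
    n <- nchar(s)
    if (n < 6) {
      abort(sprintf("CDS '%s' is shorter than a start codon plus one codon (%d nt)",
                    ids[i], n))
    }
    r <- n %% 3
    if (r > 0) {
      s <- substr(s, 1, n - r)  # drop truncated stop
      n <- n - r
    }
    codons <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
    codons <- codons[-1]  # drop initiation codon
    k <- length(codons)
    if (r == 0 && k > 0 && codons[k] %in% c("UAA", "UAG")) {
      codons <- codons[-k]  # drop complete terminator
    }
    all_codons <- c(all_codons, codons)
  }
  new_codon_count_tbl(table(all_codons))
}

#' Codon count table from a ready-made count column
#'
#' @param counts Named numeric vector (names = codons, DNA or RNA) or a data
#'   frame with `codon` and `count` columns.
#' @return A `codon_count_tbl`.
#' @export
codon_count_table <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$codon)
  }
  names(counts) <- rna_codon(names(counts))
  if (any(counts < 0)) abort("codon counts must be non-negative")
  extra <- setdiff(names(counts), codon_order())
  if (length(extra) > 0) {
    abort(sprintf("unknown codon(s): %s", paste(extra, collapse = ", ")))
  }
  new_codon_count_tbl(counts)
}

family_map <- function(scheme = c("pooled", "split")) {
  scheme <- match.arg(scheme)
  info <- invmito_codon_table()
  fam <- if (scheme == "pooled") info$family_pooled else info$family_split
  setNames(fam, info$codon)
}

#' Relative synonymous codon usage
#'
#' `RSCU_c = n_c * k / sum(n_c' over the family)`, `k` the family size. In a
#' family with zero total every codon's RSCU is 0; in a nonzero family the
#' RSCU values sum to the family size (mean 1, i.e. 1 = no bias).
#'
#' @param table A `codon_count_tbl` (from [count_codons()],
#'   [codon_count_table()] or [table3_fixture()]).
#' @param scheme Synonymous-family scheme: `"pooled"` (default; Leu as one
#'   6-codon family, Ser as one 8-codon family) or `"split"` (L1/L2 and
#'   S1/S2 separate).
#' @return An `rscu_tbl`: tibble with `codon`, `aa`, `family`, `count`,
#'   `rscu`; attribute `family_scheme`.
#' @export
#' @examples
#' rscu(table3_fixture())
rscu <- function(table, scheme = c("pooled", "split")) {
  scheme <- match.arg(scheme)
  fam <- family_map(scheme)
  out <- mutate(as_tibble(table), family = unname(fam[.data$codon]))
  out <- out |>
    group_by(.data$family) |>
    mutate(
      family_size = dplyr::n(),
      family_total = sum(.data$count),
      rscu = ifelse(.data$family_total == 0, 0,
                    .data$count * .data$family_size / .data$family_total)
    ) |>
    ungroup() |>
    select("codon", "aa", "family", "count", "rscu")
  attr(out, "family_scheme") <- scheme
  class(out) <- c("rscu_tbl", class(tibble()))
  out
}

#' Amino-acid usage from a codon count table
#'
#' Counts are summed per table label (L1/L2 and S1/S2 kept separate, as
#' mitogenome papers report them), and combined `Leu` and `Ser` rows are
#' appended with `combined = TRUE` for convenience. The sum over the
#' non-combined rows equals the table's codon total.
#'
#' @param table A `codon_count_tbl`.
#' @return Tibble with `aa`, `count`, `combined`.
#' @export
aa_usage <- function(table) {
  base <- as_tibble(table) |>
    group_by(aa = .data$aa) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(combined = FALSE)
  pooled <- tibble(
    aa = c("Leu", "Ser"),
    count = c(sum(base$count[base$aa %in% c("L1", "L2")]),
              sum(base$count[base$aa %in% c("S1", "S2")])),
    combined = TRUE
  )
  bind_rows(base, pooled)
}

#' @method autoplot rscu_tbl
#' @export
autoplot.rscu_tbl <- function(object, ...) {
  df <- filter(object, .data$family != "Ter")
  df$codon <- factor(df$codon, levels = df$codon)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$rscu,
                                   fill = .data$codon)) +
    ggplot2::geom_col(position = "stack", show.legend = FALSE) +
    ggplot2::labs(x = "Amino acid family", y = "RSCU") +
    ggplot2::theme_minimal()
}

#' @method glance rscu_tbl
#' @export
glance.rscu_tbl <- function(x, ...) {
  tibble(
    n_codons = sum(x$count),
    n_families = dplyr::n_distinct(x$family),
    n_unused_codons = sum(x$count == 0),
    max_rscu = max(x$rscu),
    family_scheme = attr(x, "family_scheme") %||% "pooled"
  )
}
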