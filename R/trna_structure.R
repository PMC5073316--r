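# tRNA stem base-pair auditing.
#
# Cloverleaf stem layouts (acceptor, D, anticodon, T) are inputs: either
# produced by the simulator's truth ledger or supplied by the user (e.g.
# transcribed from a structure-prediction tool). Each paired position is
# classified as Watson-Crick, G-U wobble, or mismatch. Published mitogenome
# descriptions count wobble and mismatch together as "unmatched"/non-WC
# pairs, so the audit reports that combined tally alongside the split.

#' Classify one base pair
#'
#' Vectorised. `A:U`, `U:A`, `G:C`, `C:G` are Watson-Crick; `G:U`/`U:G` are
#' wobble; anything else is a mismatch. `T` is accepted as `U`; `N` is an
#' error (ambiguous).
#'
#' @param b1,b2 Nucleotide characters.
#' @return Character vector over `watson_crick`, `wobble`, `mismatch`.
#' @export
#' @examples
#' classify_pair("G", "U")
classify_pair <- function(b1, b2) {
  norm <- function(b) {
    b <- chartr("Tt", "Uu", toupper(b))
    bad <- which(!b %in% c("A", "C", "G", "U"))
    if (length(bad) > 0) {
      abort(sprintf("cannot classify ambiguous base '%s'", b[bad[1]]))
    }
    b
  }
  b1 <- norm(b1); b2 <- norm(b2)
  pair <- paste0(b1, b2)
  dplyr::case_when(
    pair %in% c("AU", "UA", "GC", "CG") ~ "watson_crick",
    pair %in% c("GU", "UG") ~ "wobble",
    TRUE ~ "mismatch"
  )
}

# normalise a layout (named list of pair lists / matrices / data frames)
# into a tibble with stem, i, j
layout_pairs <- function(layout) {
  stems <- layout$stems %||% layout
  rows <- purrr::imap(stems, function(pairs, stem) {
    if (is.null(pairs) || length(pairs) == 0) return(NULL)
    m <- if (is.data.frame(pairs)) {
      as.matrix(pairs[, 1:2])
    } else if (is.matrix(pairs)) {
      pairs
    } else {
      do.call(rbind, lapply(pairs, function(p) as.integer(p[1:2])))
    }
    tibble(stem = stem, i = as.integer(m[, 1]), j = as.integer(m[, 2]))
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$i >= out$j)) abort("stem layout pairs must satisfy i < j")
  if (anyDuplicated(c(out$i, out$j)) > 0) abort("stem layout pairs must be disjoint")
  out
}

#' Audit base pairing across the stems of a tRNA
#'
#' @param seq tRNA sequence (DNA or RNA, coding orientation).
#' @param layout Stem layout: a named list mapping stem name (e.g.
#'   `acceptor`, `D`, `anticodon`, `T`) to a list of `c(i, j)` position
#'   pairs (1-based into `seq`), or a list with a `stems` element of that
#'   shape (the simulator's and the JSON layout file's format).
#' @return A `stem_audit` tibble with one row per pair: `stem`, `i`, `j`,
#'   `base_i`, `base_j`, `pair_class`. Use [glance.stem_audit()] for
#'   per-class totals.
#' @export
#' @examples
#' audit_stems("GGGAAACCC", list(acceptor = list(c(1, 9), c(2, 8), c(3, 7))))
audit_stems <- function(seq, layout) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  pairs <- layout_pairs(layout)
  if (nrow(pairs) == 0) abort("layout contains no pairs")
  if (max(pairs$j) > nchar(seq)) {
    abort(sprintf("layout position %d is beyond the %d nt sequence",
                  max(pairs$j), nchar(seq)))
  }
  ch <- str_chars(seq)
  out <- mutate(pairs,
                base_i = ch[.data$i], base_j = ch[.data$j],
                pair_class = classify_pair(ch[.data$i], ch[.data$j]))
  class(out) <- c("stem_audit", class(tibble()))
  out
}

#' @rdname audit_stems
#' @param x A `stem_audit` tibble.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with `n_pairs`, `watson_crick`,
#'   `wobble`, `mismatch`, and `non_wc` (= wobble + mismatch, the combined
#'   "unmatched" tally of the descriptive literature).
#' @method glance stem_audit
#' @export
glance.stem_audit <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    watson_crick = sum(x$pair_class == "watson_crick"),
    wobble = sum(x$pair_class == "wobble"),
    mismatch = sum(x$pair_class == "mismatch"),
    non_wc = sum(x$pair_class != "watson_crick")
  )
}

#' Per-stem tallies of a stem audit
#'
#' @param audit A `stem_audit` tibble from [audit_stems()].
#' @return Tibble with one row per stem and columns for each pair class.
#' @export
stem_tallies <- function(audit) {
  audit |>
    group_by(.data$stem) |>
    summarise(
      n_pairs = dplyr::n(),
      watson_crick = sum(.data$pair_class == "watson_crick"),
      wobble = sum(.data$pair_class == "wobble"),
      mismatch = sum(.data$pair_class == "mismatch"),
      .groups = "drop"
    )
}

#' Read a stem layout from JSON
#'
#' The JSON format maps stem names to lists of `[i, j]` pairs.
#'
#' @param path JSON file path.
#' @return A layout list usable by [audit_stems()].
#' @export
read_stem_layout <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(raw, function(m) {
    if (is.data.frame(m)) m <- as.matrix(m)
    m
  })
}
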