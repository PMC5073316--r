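# Control-region element scanning: conserved motifs, homopolymer runs,
# microsatellites, and a desk-scale exact tandem-repeat finder.
#
# The A+T-rich region of insect mitogenomes carries short structural
# elements (a conserved pentamer next to the poly-T stretch marking the
# light-strand replication origin, poly-A tracts, (AT)n microsatellites,
# and longer tandem repeats). These scanners are exact (no mismatches or
# indels) and deterministic: identical input gives identical ordered output.

repeat_hit <- function(kind, unit, copies, start) {
  unit_length <- nchar(unit)
  tibble(kind = kind, unit = unit, unit_length = as.integer(unit_length),
         copies = copies, start = as.integer(start),
         # floor() with a tiny tolerance so span/p * p rounds back exactly
         total_length = as.integer(floor(copies * unit_length + 1e-9)))
}

empty_hits <- function() {
  tibble(kind = character(), unit = character(), unit_length = integer(),
         copies = numeric(), start = integer(), total_length = integer())
}

# all (possibly overlapping) exact occurrence starts of `pattern` in `seq`
match_starts <- function(seq, pattern) {
  n <- nchar(seq); m <- nchar(pattern)
  if (m > n) return(integer())
  cand <- seq_len(n - m + 1L)
  cand[substring(seq, cand, cand + m - 1L) == pattern]
}

#' Find exact motif occurrences
#'
#' @param seq DNA string to scan.
#' @param motif Motif string, at least 3 nt (e.g. the lepidopteran
#'   control-region pentamer `"ATAGA"`; `"ATATG"` is a common variant).
#' @param both_strands Also report occurrences of the reverse complement,
#'   flagged `strand = "reverse_complement"`, in `seq` coordinates.
#' @return Tibble with `motif`, `position` (1-based start), `strand`,
#'   ordered by position.
#' @export
#' @examples
#' find_motif("TTATAGATT", "ATAGA")
find_motif <- function(seq, motif, both_strands = FALSE) {
  seq <- check_dna(seq)
  motif <- check_dna(motif, arg = "motif")
  if (nchar(motif) < 3) abort("motif must be at least 3 nt")
  hits <- tibble(motif = motif, position = match_starts(seq, motif),
                 strand = "given")
  if (both_strands) {
    rc <- revcomp(motif)
    rc_pos <- match_starts(seq, rc)
    if (rc != motif) {
      hits <- bind_rows(hits, tibble(motif = motif, position = rc_pos,
                                     strand = "reverse_complement"))
    }
  }
  arrange(hits, .data$position)
}

#' Longest homopolymer run
#'
#' Maximal run of `base`; ties broken by smallest start. A base absent from
#' the sequence yields a zero-length sentinel hit (`start = NA`).
#'
#' @param seq DNA string.
#' @param base Single nucleotide.
#' @return One-row repeat-hit tibble with `kind = "homopolymer"`.
#' @export
#' @examples
#' longest_run("AATTTTTA", "T")
longest_run <- function(seq, base) {
  seq <- check_dna(seq)
  stopifnot(nchar(seq) >= 1, nchar(base) == 1)
  r <- rle(str_chars(seq) == toupper(base))
  if (!any(r$values)) {
    out <- repeat_hit("homopolymer", toupper(base), 0, NA_integer_)
    out$start <- NA_integer_
    return(out)
  }
  lens <- r$lengths[r$values]
  ends <- cumsum(r$lengths)[r$values]
  best <- which.max(lens)  # first max = smallest start
  repeat_hit("homopolymer", toupper(base), as.numeric(lens[best]),
             ends[best] - lens[best] + 1L)
}

# reduce a unit to its primitive root (shortest w with unit == w^k)
primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(unit, 1, d), u / d) == unit) {
      return(substr(unit, 1, d))
    }
  }
  unit
}

#' Find microsatellite runs of a given unit
#'
#' Maximal non-overlapping runs of an exact 1-6 bp unit with at least
#' `min_copies` copies; a partial trailing copy counts fractionally. A
#' non-primitive unit (e.g. `"ATAT"`) is normalised to its primitive root
#' with a warning. Overlapping candidate runs (different phases) are
#' resolved longest-first, then smallest start.
#'
#' @param seq DNA string.
#' @param unit Repeat unit, 1-6 bp.
#' @param min_copies Minimum copy number (>= 3 for a reportable
#'   microsatellite; fractional thresholds allowed).
#' @return Repeat-hit tibble (`kind = "microsatellite"`), ordered by start.
#' @export
#' @examples
#' find_microsatellite(paste0("GG", strrep("AT", 10), "CC"), "AT", 5)
find_microsatellite <- function(seq, unit, min_copies = 3) {
  seq <- check_dna(seq)
  unit <- check_dna(unit, allow_n = FALSE, arg = "unit")
  if (nchar(unit) < 1 || nchar(unit) > 6) abort("unit must be 1-6 bp")
  prim <- primitive_unit(unit)
  if (prim != unit) {
    warn(sprintf("unit '%s' is not primitive; using '%s'", unit, prim))
    unit <- prim
  }
  u <- nchar(unit)
  if (u == 1) {
    hit <- longest_run(seq, unit)
    hit$kind <- "microsatellite"
    return(if (!is.na(hit$start) && hit$copies >= min_copies) hit else empty_hits())
  }
  occ <- match_starts(seq, unit)
  if (length(occ) == 0) return(empty_hits())
  # chain in-phase consecutive occurrences
  cands <- list()
  i <- 1L
  while (i <= length(occ)) {
    run_start <- occ[i]
    k <- 1L
    while (i + 1L <= length(occ) && occ[i + 1L] == occ[i] + u) {
      i <- i + 1L; k <- k + 1L
    }
    # partial trailing copy
    after <- occ[i] + u
    e <- 0L
    while (e < u - 1L && after + e <= nchar(seq) &&
           substr(seq, after + e, after + e) == substr(unit, e + 1L, e + 1L)) {
      e <- e + 1L
    }
    cands[[length(cands) + 1L]] <- repeat_hit("microsatellite", unit,
                                              k + e / u, run_start)
    i <- i + 1L
  }
  cands <- bind_rows(cands)
  cands <- cands[cands$copies >= min_copies, , drop = FALSE]
  if (nrow(cands) == 0) return(empty_hits())
  select_nonoverlapping(cands)
}

# greedy non-overlap selection: longest total span first, then smallest
# unit, then smallest start (the tie-break order used for all repeat scans)
select_nonoverlapping <- function(cands) {
  cands <- cands[order(-cands$total_length, cands$unit_length, cands$start), ]
  taken <- logical(0)
  sel_start <- integer(0); sel_end <- integer(0)
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    s <- cands$start[i]; e <- cands$start[i] + cands$total_length[i] - 1L
    if (all(e < sel_start | s > sel_end)) {
      keep[i] <- TRUE
      sel_start <- c(sel_start, s); sel_end <- c(sel_end, e)
    }
  }
  arrange(cands[keep, , drop = FALSE], .data$start)
}

#' Find tandem repeats by exhaustive exact scanning
#'
#' Scans every unit length `p` in `[min_unit, max_unit]` for maximal regions
#' where each base equals the base `p` positions earlier (exact matching, no
#' mismatches or indels). A region spanning `s` bases is a run of `s / p`
#' copies of its leading `p`-mer; runs whose unit is itself a repetition are
#' dropped (they re-appear at the smaller period), and overlapping runs at
#' different periods are resolved by longest total length, then smallest
#' unit. For units below 5 bp use [find_microsatellite()].
#'
#' @param seq DNA string.
#' @param min_unit Minimum unit length, >= 5.
#' @param max_unit Maximum unit length; defaults to `nchar(seq) %/% 2`.
#' @param min_copies Minimum copy number (real-valued; default 2).
#' @param min_total Minimum total span in bp (default `2 * min_unit`).
#' @return Repeat-hit tibble (`kind = "tandem"`), ordered by start.
#' @export
#' @examples
#' find_tandem_repeats(strrep("GATTACAC", 3), min_unit = 5, max_unit = 10)
find_tandem_repeats <- function(seq, min_unit = 5L, max_unit = NULL,
                                min_copies = 2, min_total = NULL) {
  seq <- check_dna(seq)
  n <- nchar(seq)
  if (min_unit < 5) abort("min_unit must be >= 5 (use find_microsatellite below that)")
  if (is.null(max_unit)) max_unit <- n %/% 2L
  if (max_unit > n %/% 2L) abort("max_unit cannot exceed half the sequence length")
  if (is.null(min_total)) min_total <- 2L * min_unit
  if (max_unit < min_unit) return(empty_hits())
  ch <- str_chars(seq)
  cands <- list()
  for (p in min_unit:max_unit) {
    eq <- ch[(p + 1L):n] == ch[1L:(n - p)]
    r <- rle(eq)
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- r$lengths[j] + p          # repeat region length in bp
      start <- run_starts[j]            # region start (eq index == seq index)
      if (span < min_total) next
      if (span / p < min_copies) next
      unit <- substr(seq, start, start + p - 1L)
      if (nchar(primitive_unit(unit)) < p) next
      cands[[length(cands) + 1L]] <- repeat_hit("tandem", unit, span / p, start)
    }
  }
  if (length(cands) == 0) return(empty_hits())
  select_nonoverlapping(bind_rows(cands))
}

#' Re-validate a repeat hit against its sequence
#'
#' Checks that the claimed span literally equals the unit repeated `copies`
#' times (up to the partial final copy). Used by the test-suite invariants
#' but exported because it is handy for auditing scanner output.
#'
#' @param seq The scanned DNA string.
#' @param hits A repeat-hit tibble.
#' @return Logical vector, one entry per hit.
#' @export
validate_repeat_hits <- function(seq, hits) {
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (is.na(h$start)) return(h$total_length == 0)
    claimed <- substr(seq, h$start, h$start + h$total_length - 1L)
    expected <- substr(strrep(h$unit, ceiling(h$copies)), 1, h$total_length)
    claimed == expected
  }, logical(1))
}
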