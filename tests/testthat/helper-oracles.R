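# Test helpers: random-sequence generators and an independent brute-force
# oracle for the tandem-repeat scanner.

random_dna <- function(n, p = c(A = 0.35, C = 0.1, G = 0.1, T = 0.45)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force tandem-repeat oracle, written against the same contract as
# find_tandem_repeats() but by a different route: it enumerates every
# (start, period) pair with string comparisons on substrings, extends each
# match base by base, keeps only left-maximal runs, and then applies the
# primitivity filter and the longest-span/smallest-period/smallest-start
# greedy selection.
oracle_tandem <- function(seq, min_unit = 5L, max_unit = NULL,
                          min_copies = 2, min_total = NULL) {
  n <- nchar(seq)
  if (is.null(max_unit)) max_unit <- n %/% 2L
  if (is.null(min_total)) min_total <- 2L * min_unit
  is_primitive <- function(u) {
    L <- nchar(u)
    for (d in seq_len(L - 1)) {
      if (L %% d == 0 && paste(rep(substr(u, 1, d), L / d), collapse = "") == u) {
        return(FALSE)
      }
    }
    TRUE
  }
  cands <- list()
  for (p in seq.int(min_unit, max_unit)) {
    i <- 1L
    while (i + 2L * p - 1L <= n) {
      if (substr(seq, i, i + p - 1L) == substr(seq, i + p, i + 2L * p - 1L)) {
        left_max <- i == 1L ||
          substr(seq, i - 1L, i - 1L) != substr(seq, i - 1L + p, i - 1L + p)
        if (left_max) {
          e <- i + 2L * p - 1L
          while (e < n && substr(seq, e + 1L, e + 1L) == substr(seq, e + 1L - p, e + 1L - p)) {
            e <- e + 1L
          }
          span <- e - i + 1L
          unit <- substr(seq, i, i + p - 1L)
          if (span >= min_total && span / p >= min_copies && is_primitive(unit)) {
            cands[[length(cands) + 1L]] <-
              data.frame(unit = unit, unit_length = p, copies = span / p,
                         start = i, total_length = span)
          }
        }
      }
      i <- i + 1L
    }
  }
  if (length(cands) == 0) {
    return(data.frame(unit = character(), unit_length = integer(),
                      copies = numeric(), start = integer(),
                      total_length = integer()))
  }
  df <- do.call(rbind, cands)
  df <- df[order(-df$total_length, df$unit_length, df$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df))
  sel <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(df))) {
    s <- df$start[k]; e <- df$start[k] + df$total_length[k] - 1L
    if (nrow(sel) == 0 || all(e < sel[, 1] | s > sel[, 2])) {
      keep[k] <- TRUE
      sel <- rbind(sel, c(s, e))
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

expect_tandem_agrees_with_oracle <- function(seq, min_unit = 5L, max_unit = NULL,
                                             min_copies = 2, min_total = NULL) {
  got <- find_tandem_repeats(seq, min_unit, max_unit, min_copies, min_total)
  exp <- oracle_tandem(seq, min_unit, max_unit, min_copies, min_total)
  expect_equal(nrow(got), nrow(exp), info = seq)
  if (nrow(exp) > 0) {
    expect_equal(got$start, exp$start, info = seq)
    expect_equal(got$unit_length, exp$unit_length, info = seq)
    expect_equal(got$unit, exp$unit, info = seq)
    expect_equal(got$copies, exp$copies, tolerance = 1e-12, info = seq)
    expect_equal(got$total_length, exp$total_length, info = seq)
  }
}

write_temp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# all 64 RNA codons (any order; used to build synthetic count tables)
codon_order_for_test <- function() {
  b <- c("U", "C", "A", "G")
  grid <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(grid$b1, grid$b2, grid$b3)
}
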