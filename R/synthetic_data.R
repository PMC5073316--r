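# Synthetic annotated mitogenomes with a machine-readable truth ledger.
#
# The generator emulates the canonical 37-gene + control-region circular
# mitogenome of a lepidopteran insect: a configurable circular gene order
# (derived lepidopteran arrangement by default, ancestral insect arrangement
# as the built-in alternative), per-partition A+T content and AT/GC skews
# matching the published composition of such genomes, protein-coding genes
# built codon-by-codon with start/stop conventions taken from the packaged
# gene table (including truncated stops), tRNAs with explicit cloverleaf
# stem layouts and planted wobble/mismatch pairs, and a control region with
# planted structural elements (conserved pentamer motif, poly-T and poly-A
# runs, an (AT)n microsatellite, and a long tandem repeat). Everything
# planted or realized is recorded in a truth ledger so downstream analyses
# can be checked for exact recovery.
#
# Composition targets are met in expectation, not exactly; the ledger stores
# the realized counts. All randomness flows through R's RNG from the single
# config seed, so a config reproduces its genome byte-for-byte.

#' Packaged gene-table fixture
#'
#' The packaged 38-row annotated gene table of the Monema flavescens
#' mitogenome (13 PCGs, 22 tRNAs, 2 rRNAs, control region; 15,396 bp), with
#' declared sizes, anticodons, start/stop codons and the declared intergenic
#' column carried as extras.
#'
#' @return A `gene_table` tibble.
#' @export
table2_fixture <- function() {
  read_gene_table(system.file("extdata", "mflavescens_table2.tsv",
                              package = "mitoprofiler", mustWork = TRUE))
}

#' Packaged codon-count fixture
#'
#' The packaged 64-row codon-count table of the Monema flavescens
#' protein-coding genes (3,716 codons, initiation and termination codons of
#' each gene excluded; the two termination codons UAA/UAG carry the counts
#' the source table prints). The printed RSCU column is attached as
#' attribute `rscu_printed` for cross-checking.
#'
#' @return A `codon_count_tbl`.
#' @export
table3_fixture <- function() {
  raw <- readr::read_tsv(
    system.file("extdata", "mflavescens_table3.tsv",
                package = "mitoprofiler", mustWork = TRUE),
    col_types = "ccid", progress = FALSE
  )
  out <- codon_count_table(raw)
  attr(out, "rscu_printed") <- setNames(raw$rscu_printed, raw$codon)
  out
}

# ---- configuration -----------------------------------------------------------

default_partition_targets <- function() {
  list(
    at_content = c("mitogenome" = 0.805, "PCGs" = 0.787, "tRNAs" = 0.824,
                   "rRNAs" = 0.845, "control region" = 0.933),
    at_skew = c("mitogenome" = 0.014, "PCGs" = 0.014, "tRNAs" = 0.010,
                "rRNAs" = 0.025, "control region" = -0.063),
    gc_skew = c("mitogenome" = -0.231, "PCGs" = -0.202, "tRNAs" = -0.148,
                "rRNAs" = -0.406, "control region" = -0.403)
  )
}

default_cr_elements <- function() {
  list(motif = "ATAGA", poly_t = 12L, poly_a = 10L,
       microsat_unit = "AT", microsat_copies = 10L,
       tandem_unit_length = 51L, tandem_copies = 2L)
}

#' Build a simulation configuration
#'
#' Defaults describe the study system the generator emulates: the derived
#' lepidopteran gene order, per-partition A+T content and skews of a typical
#' lepidopteran mitogenome (whole genome 80.5% A+T with slightly positive AT
#' skew and negative GC skew; control region 93.3% A+T), and the canonical
#' control-region elements (ATAGA pentamer, poly-T, poly-A, (AT)10
#' microsatellite, a 51 bp tandem repeat in two copies). Gene sizes, strands,
#' anticodons, start/stop codons and default inter-gene gaps (including
#' overlaps) come from the packaged gene table.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param gene_order `"lepidopteran"`, `"ancestral_insect"`, or an explicit
#'   circular order over the 38 packaged feature names.
#' @param genome_length_target Optional total length; reached by padding the
#'   terminal spacer with background sequence.
#' @param partition_at_content,partition_at_skew,partition_gc_skew Named
#'   numeric vectors overriding the per-partition defaults (names among
#'   `mitogenome`, `PCGs`, `tRNAs`, `rRNAs`, `control region`).
#' @param codon_bias Optional Dirichlet concentration for per-family
#'   synonymous-codon weights. `NULL` (default) samples codons from the
#'   composition-calibrated codon distribution instead.
#' @param cr_elements Named list overriding [default_cr_elements()] entries.
#' @param overlaps,spacers Lists of `list(pair = c(upstream, downstream),
#'   bp = n)` overriding the default signed gap at that junction (overlaps
#'   store `-bp`).
#' @param trna_wobble_rate,trna_mismatch_rate Per-stem-pair planting rates
#'   for G-U wobble and mismatch pairs (defaults emulate the ~18 wobble and
#'   ~7 mismatch pairs observed across the 22 tRNAs of a real mitogenome).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed,
                              gene_order = "lepidopteran",
                              genome_length_target = NULL,
                              partition_at_content = NULL,
                              partition_at_skew = NULL,
                              partition_gc_skew = NULL,
                              codon_bias = NULL,
                              cr_elements = NULL,
                              overlaps = NULL,
                              spacers = NULL,
                              trna_wobble_rate = 18 / 440,
                              trna_mismatch_rate = 7 / 440) {
  defaults <- default_partition_targets()
  merge_named <- function(base, override) {
    if (!is.null(override)) base[names(override)] <- override
    base
  }
  at <- merge_named(defaults$at_content, partition_at_content)
  ask <- merge_named(defaults$at_skew, partition_at_skew)
  gsk <- merge_named(defaults$gc_skew, partition_gc_skew)
  if (any(at <= 0 | at >= 1)) abort("A+T content targets must lie in (0, 1)")
  if (any(abs(ask) >= 1) || any(abs(gsk) >= 1)) abort("skew targets must lie in (-1, 1)")
  el <- default_cr_elements()
  if (!is.null(cr_elements)) el[names(cr_elements)] <- cr_elements
  if (is.character(gene_order) && length(gene_order) == 1) {
    gene_order <- gene_order_preset(gene_order)
  }
  structure(
    list(seed = as.integer(seed), gene_order = gene_order,
         genome_length_target = genome_length_target,
         at_content = at, at_skew = ask, gc_skew = gsk,
         codon_bias = codon_bias, cr_elements = el,
         overlaps = overlaps, spacers = spacers,
         trna_wobble_rate = trna_wobble_rate,
         trna_mismatch_rate = trna_mismatch_rate),
    class = "sim_config"
  )
}

# base probabilities (A, C, G, T) realizing an A+T fraction and both skews
base_probs <- function(at, at_sk, gc_sk) {
  c(A = at * (1 + at_sk) / 2,
    C = (1 - at) * (1 - gc_sk) / 2,
    G = (1 - at) * (1 + gc_sk) / 2,
    T = at * (1 - at_sk) / 2)
}

dna_codons64 <- function() chartr("U", "T", codon_order())

# codon distribution induced by iid base probabilities, with the two stop
# codons (TAA, TAG) excluded and renormalised
codon_dist_from_bases <- function(p) {
  codons <- dna_codons64()
  w <- vapply(codons, function(cd) prod(p[str_chars(cd)]), numeric(1))
  w[codons %in% c("TAA", "TAG")] <- 0
  w / sum(w)
}

# Solve for the base-level A+T parameter whose stop-excluded codon
# distribution realises `target_at` in expectation (stop exclusion removes
# AT-rich codons, so the raw parameter must sit slightly above the target).
calibrated_codon_dist <- function(target_at, at_sk, gc_sk) {
  codons <- dna_codons64()
  n_at <- vapply(codons, function(cd) sum(str_chars(cd) %in% c("A", "T")), numeric(1))
  f <- function(at) {
    q <- codon_dist_from_bases(base_probs(at, at_sk, gc_sk))
    sum(q * n_at) / 3 - target_at
  }
  at <- uniroot(f, c(0.05, 0.995))$root
  codon_dist_from_bases(base_probs(at, at_sk, gc_sk))
}

sample_bases <- function(n, p) {
  if (n == 0) return(character(0))
  sample(names(p), n, replace = TRUE, prob = p)
}

# ---- per-feature generators --------------------------------------------------

# protein-coding gene: printed start codon + sampled internal codons + stop
# derived from size mod 3 (coordinates are authoritative, so a printed
# complete stop on a non-multiple-of-three size becomes a truncated stop)
sim_pcg <- function(size, start_codon, stop_codon, codon_dist) {
  r <- size %% 3L
  stop <- if (r == 1L) "T" else if (r == 2L) "TA"
          else if (!is.na(stop_codon) && stop_codon %in% c("TAA", "TAG")) stop_codon
          else "TAA"
  n_internal <- (size - 3L - nchar(stop)) / 3L
  codons <- sample(dna_codons64(), n_internal, replace = TRUE, prob = codon_dist)
  list(seq = paste0(start_codon, paste(codons, collapse = ""), stop),
       stop = stop,
       codon_counts = table(rna_codon(codons)))
}

# cloverleaf stem layout for a tRNA of `len` nt (>= 62); positions are
# 1-based into the coding-orientation gene
trna_layout <- function(len, d_arm = TRUE) {
  stopifnot(len >= 62)
  acceptor <- cbind(1:7, len - (0:6))
  d <- cbind(10:13, 25:22)
  anticodon <- cbind(27:31, 43:39)
  t_arm <- cbind((len - 16):(len - 13), (len - 8):(len - 11))
  stems <- list(acceptor = acceptor, anticodon = anticodon, T = t_arm)
  if (d_arm) stems$D <- d
  list(stems = stems, d_arm_present = d_arm, anticodon_site = 34:36)
}

MISMATCH_PAIRS <- list(c("T", "T"), c("C", "T"), c("A", "C"), c("A", "A"))

sim_trna <- function(len, anticodon, p, wobble_rate, mismatch_rate,
                     d_arm = TRUE) {
  layout <- trna_layout(len, d_arm)
  ch <- sample_bases(len, p)
  if (!is.na(anticodon)) {
    ch[layout$anticodon_site] <- str_chars(anticodon)
  }
  pairs <- layout_pairs(layout$stems)
  u <- runif(nrow(pairs))
  cls <- ifelse(u < wobble_rate, "wobble",
                ifelse(u < wobble_rate + mismatch_rate, "mismatch", "watson_crick"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (cls[k] == "watson_crick") {
      ch[j] <- comp[[ch[i]]]
    } else if (cls[k] == "wobble") {
      gu <- if (runif(1) < 0.5) c("G", "T") else c("T", "G")
      ch[i] <- gu[1]; ch[j] <- gu[2]
    } else {
      mm <- MISMATCH_PAIRS[[sample.int(length(MISMATCH_PAIRS), 1)]]
      if (runif(1) < 0.5) mm <- rev(mm)
      ch[i] <- mm[1]; ch[j] <- mm[2]
    }
  }
  list(seq = paste(ch, collapse = ""), layout = layout,
       classes = mutate(pairs, pair_class = cls))
}

# ---- control region ----------------------------------------------------------

# chains of the microsatellite unit with >= min_copies full+partial copies
offending_microsat_starts <- function(s, unit, min_copies, allowed_start) {
  hits <- suppressWarnings(find_microsatellite(s, unit, min_copies))
  hits$start[hits$start != allowed_start]
}

# runs of `base` with length >= lim whose span is not exactly `allowed`
offending_runs <- function(ch, base, lim, allowed) {
  r <- rle(ch == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values & r$lengths >= lim)
  out <- list()
  for (j in idx) {
    if (!is.null(allowed) && starts[j] == allowed[1] && ends[j] == allowed[2]) next
    out[[length(out) + 1L]] <- c(starts[j], ends[j])
  }
  out
}

sim_control_region <- function(len, p, el) {
  unit_u <- toupper(el$microsat_unit)
  # tandem unit: resampled until it cannot shadow any other planted element
  sample_tandem_unit <- function() {
    repeat {
      u <- paste(sample_bases(el$tandem_unit_length, p), collapse = "")
      reps <- paste0(u, u)
      ok <- !grepl(el$motif, reps, fixed = TRUE) &&
        !grepl(strrep("T", el$poly_t), reps, fixed = TRUE) &&
        !grepl(strrep("A", el$poly_a), reps, fixed = TRUE) &&
        !grepl(strrep(unit_u, el$microsat_copies), reps, fixed = TRUE) &&
        nchar(primitive_unit(u)) == nchar(u)
      if (ok) return(u)
    }
  }
  tandem_unit <- sample_tandem_unit()
  strings <- list(
    motif = el$motif,
    homopolymer_T = strrep("T", el$poly_t),
    microsatellite = strrep(unit_u, el$microsat_copies),
    tandem = strrep(tandem_unit, el$tandem_copies),
    homopolymer_A = strrep("A", el$poly_a)
  )
  units <- c(el$motif, "T", unit_u, tandem_unit, "A")
  copies <- c(1, el$poly_t, el$microsat_copies, el$tandem_copies, el$poly_a)
  widths <- vapply(strings, nchar, integer(1))
  n_e <- length(strings)
  slack <- len - sum(widths) - 2L * n_e
  if (slack < 0) {
    abort(sprintf("control-region elements need %d bp but the region is %d bp",
                  sum(widths) + 2L * n_e, len))
  }
  gaps <- as.vector(rmultinom(1, slack, rep(1, n_e + 1L)))
  ch <- sample_bases(len, p)
  # flank base: kills runs/motifs/microsatellites; G only when C would
  # extend the tandem period
  flank_for <- function(avoid) if ("C" %in% avoid) "G" else "C"
  pos <- 0L
  starts <- integer(n_e)
  protected <- list()  # spans (incl. flanks) that the sanitiser must not touch
  tandem_span <- NULL
  for (k in seq_len(n_e)) {
    pos <- pos + gaps[k] + 1L  # left flank position
    avoid_l <- avoid_r <- character(0)
    if (names(strings)[k] == "tandem") {
      avoid_l <- substr(tandem_unit, nchar(tandem_unit), nchar(tandem_unit))
      avoid_r <- substr(tandem_unit, 1, 1)
    }
    ch[pos] <- flank_for(avoid_l)
    starts[k] <- pos + 1L
    ch[starts[k]:(starts[k] + widths[k] - 1L)] <- str_chars(strings[[k]])
    pos <- starts[k] + widths[k]
    ch[pos] <- flank_for(avoid_r)
    protected[[k]] <- c(starts[k] - 1L, pos)
    if (names(strings)[k] == "tandem") tandem_span <- c(starts[k], pos - 1L)
  }
  # sanitise the background: no stray motif, no competing homopolymer runs,
  # no competing microsatellite chain. Flips go to C (which no element
  # contains); a flip that must land inside the tandem is applied to both
  # copies so the repeat stays exact.
  in_protected <- function(q) {
    any(vapply(protected, function(sp) q >= sp[1] && q <= sp[2], logical(1)))
  }
  flip <- function(ch, span) {
    cand <- span[1]:span[2]
    free <- cand[!vapply(cand, in_protected, logical(1))]
    if (length(free) > 0) {
      ch[free[ceiling(length(free) / 2)]] <- "C"
    } else {
      # fully inside the tandem: flip the same offset in both copies
      q <- cand[ceiling(length(cand) / 2)]
      rel <- (q - tandem_span[1]) %% nchar(tandem_unit)
      sisters <- tandem_span[1] + rel +
        nchar(tandem_unit) * (0:(el$tandem_copies - 1L))
      ch[sisters] <- "C"
    }
    ch
  }
  for (iter in 1:50) {
    s <- paste(ch, collapse = "")
    dirty <- FALSE
    stray <- setdiff(match_starts(s, el$motif), starts[1])
    for (q in stray) { ch <- flip(ch, c(q, q + nchar(el$motif) - 1L)); dirty <- TRUE }
    if (!dirty) {
      for (sp in offending_runs(ch, "T", el$poly_t,
                                c(starts[2], starts[2] + el$poly_t - 1L))) {
        ch <- flip(ch, sp); dirty <- TRUE
      }
      for (sp in offending_runs(ch, "A", el$poly_a,
                                c(starts[5], starts[5] + el$poly_a - 1L))) {
        ch <- flip(ch, sp); dirty <- TRUE
      }
    }
    if (!dirty) {
      s <- paste(ch, collapse = "")
      for (q in offending_microsat_starts(s, unit_u, el$microsat_copies, starts[3])) {
        ch <- flip(ch, c(q, q + 2L * nchar(unit_u) - 1L)); dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  truth <- tibble(
    kind = c("motif", "homopolymer", "microsatellite", "tandem", "homopolymer"),
    element = names(strings),
    unit = units,
    unit_length = nchar(units),
    copies = copies,
    start = starts,
    total_length = widths
  )
  list(seq = paste(ch, collapse = ""), truth = truth, tandem_unit = tandem_unit)
}

# ---- whole-genome assembly ---------------------------------------------------

# default signed gap after each feature, taken from the packaged gene table
# where the junction exists there, 2 bp otherwise
default_gaps <- function(order) {
  fix <- table2_fixture()
  led <- adjacency_ledger(fix, L = 15396L)
  key <- paste(led$upstream, led$downstream, sep = "\r")
  n <- length(order)
  nxt <- order[c(seq_len(n)[-1], 1L)]
  gaps <- led$gap[match(paste(order, nxt, sep = "\r"), key)]
  gaps[is.na(gaps)] <- 2L
  gaps
}

#' Simulate an annotated circular mitogenome
#'
#' Deterministic given the config seed. Returns the assembled genome and a
#' truth ledger recording the realized per-partition composition counts, the
#' per-gene internal codon counts, each tRNA's stem layout and planted pair
#' classes, the control-region element positions, and every inter-gene gap.
#' Features overlapped by an upstream neighbour (overlapping junctions share
#' sequence; the upstream feature owns the shared bases) have their ledger
#' entries recomputed from the realized sequence, so the ledger always
#' describes the genome as built.
#'
#' @param config A [simulation_config()].
#' @return A `mito_simulation` list with elements `genome` ([mitogenome()])
#'   and `truth`.
#' @export
#' @examples
#' sim <- simulate_mitogenome(simulation_config(seed = 1))
#' sim$genome
simulate_mitogenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  template <- table2_fixture()
  order <- config$gene_order
  unknown <- setdiff(order, template$gene)
  if (length(unknown) > 0) {
    abort(sprintf("gene_order names not in the packaged template: %s",
                  paste(unknown, collapse = ", ")))
  }
  rows <- template[match(order, template$gene), ]
  # computed lengths are authoritative; declared sizes can disagree with
  # coordinates (e.g. trnY prints 67 where its span is 69)
  rows$gen_size <- feature_length(rows$start, rows$end, L = 15396L)
  n <- nrow(rows)

  p_bg <- base_probs(config$at_content[["mitogenome"]],
                     config$at_skew[["mitogenome"]],
                     config$gc_skew[["mitogenome"]])
  p_trna <- base_probs(config$at_content[["tRNAs"]],
                       config$at_skew[["tRNAs"]], config$gc_skew[["tRNAs"]])
  p_rrna <- base_probs(config$at_content[["rRNAs"]],
                       config$at_skew[["rRNAs"]], config$gc_skew[["rRNAs"]])
  p_cr <- base_probs(config$at_content[["control region"]],
                     config$at_skew[["control region"]],
                     config$gc_skew[["control region"]])
  codon_dist <- if (is.null(config$codon_bias)) {
    calibrated_codon_dist(config$at_content[["PCGs"]],
                          config$at_skew[["PCGs"]], config$gc_skew[["PCGs"]])
  } else {
    # family-wise Dirichlet weights with the configured concentration
    fam <- family_map("pooled")[codon_order()]
    w <- numeric(64)
    for (f in unique(fam)) {
      idx <- which(fam == f)
      g <- stats::rgamma(length(idx), shape = config$codon_bias)
      w[idx] <- g / sum(g)
    }
    names(w) <- dna_codons64()
    w[c("TAA", "TAG")] <- 0
    w / sum(w)
  }

  gen <- vector("list", n)
  pcg_truth <- list()
  trna_truth <- list()
  cr_truth <- NULL
  stops <- setNames(rep(NA_character_, n), rows$gene)
  for (i in seq_len(n)) {
    g <- rows[i, ]
    if (g$category == "PCG") {
      sp <- sim_pcg(g$gen_size, g$start_codon, g$stop_codon, codon_dist)
      gen[[i]] <- sp$seq
      stops[i] <- sp$stop
      pcg_truth[[g$gene]] <- sp$codon_counts
    } else if (g$category == "tRNA") {
      st <- sim_trna(g$gen_size, g$anticodon, p_trna,
                     config$trna_wobble_rate, config$trna_mismatch_rate,
                     d_arm = !grepl("^trnS1", g$gene))
      gen[[i]] <- st$seq
      trna_truth[[g$gene]] <- st
    } else if (g$category == "rRNA") {
      gen[[i]] <- paste(sample_bases(g$gen_size, p_rrna), collapse = "")
    } else {
      cr <- sim_control_region(g$gen_size, p_cr, config$cr_elements)
      gen[[i]] <- cr$seq
      cr_truth <- cr$truth
    }
  }

  gaps <- default_gaps(order)
  override_gap <- function(gaps, lst, sign) {
    for (ov in lst %||% list()) {
      i <- which(order == ov$pair[1])
      j <- which(order == ov$pair[2])
      if (length(i) != 1 || length(j) != 1 || order[(i %% n) + 1L] != ov$pair[2]) {
        abort(sprintf("pair %s/%s is not adjacent in the configured order",
                      ov$pair[1], ov$pair[2]))
      }
      gaps[i] <- sign * abs(ov$bp)
    }
    gaps
  }
  gaps <- override_gap(gaps, config$overlaps, -1L)
  gaps <- override_gap(gaps, config$spacers, +1L)

  sizes <- vapply(gen, nchar, integer(1))
  starts <- integer(n); ends <- integer(n)
  starts[1] <- 1L
  for (i in seq_len(n)) {
    ends[i] <- starts[i] + sizes[i] - 1L
    if (i < n) starts[i + 1L] <- ends[i] + gaps[i] + 1L
  }
  L <- ends[n] + max(0L, gaps[n])
  if (!is.null(config$genome_length_target)) {
    if (config$genome_length_target < L) {
      warn("genome_length_target is below the natural length; ignored")
    } else {
      L <- as.integer(config$genome_length_target)
    }
  }

  gseq <- rep(NA_character_, L)
  for (i in seq_len(n)) {
    oriented <- if (rows$strand[i] == "reverse") revcomp(gen[[i]]) else gen[[i]]
    idx <- starts[i]:ends[i]
    free <- is.na(gseq[idx])
    gseq[idx[free]] <- str_chars(oriented)[free]
  }
  open <- is.na(gseq)
  gseq[open] <- sample_bases(sum(open), p_bg)
  sequence <- paste(gseq, collapse = "")

  # realized coding-orientation strings (overlaps may have reshaped prefixes)
  realized <- vapply(seq_len(n), function(i) {
    s <- substr(sequence, starts[i], ends[i])
    if (rows$strand[i] == "reverse") revcomp(s) else s
  }, character(1))
  for (i in seq_len(n)) {
    if (realized[i] == gen[[i]]) next
    g <- rows[i, ]
    if (g$category == "PCG") {
      body <- substr(realized[i], 4L, nchar(realized[i]) - nchar(stops[i]))
      cods <- substring(body, seq(1, nchar(body) - 2, 3), seq(3, nchar(body), 3))
      pcg_truth[[g$gene]] <- table(rna_codon(cods))
    } else if (g$category == "tRNA") {
      st <- trna_truth[[g$gene]]
      ch <- str_chars(realized[i])
      st$classes$pair_class <- classify_pair(ch[st$classes$i], ch[st$classes$j])
      trna_truth[[g$gene]] <- st
    }
  }

  features <- tibble(
    gene = rows$gene, category = rows$category, strand = rows$strand,
    start = starts, end = ends,
    declared_size = sizes, anticodon = rows$anticodon
  )
  genome <- mitogenome(features, length = L, sequence = sequence,
                       accession = sprintf("SIM%06d", config$seed %% 1000000L))

  cat_seqs <- split(realized, rows$category)
  partition_counts <- lapply(
    c(mitogenome = NA, PCG = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      control_region = "control_region"),
    function(cat) {
      s <- if (is.na(cat)) sequence else paste(cat_seqs[[cat]], collapse = "")
      tab <- table(factor(str_chars(s), levels = DNA_BASES))
      setNames(as.integer(tab), names(tab))
    })

  cr_row <- which(rows$category == "control_region")
  if (length(cr_row) == 1 && !is.null(cr_truth)) {
    cr_truth$start_genomic <- cr_truth$start + starts[cr_row] - 1L
  }

  truth <- list(
    seed = config$seed,
    gene_order = order,
    genome_length = L,
    features = mutate(features, gap_after = gaps),
    partition_counts = partition_counts,
    pcg_codon_counts = lapply(pcg_truth, function(tb) {
      setNames(as.integer(tb), names(tb))
    }),
    pcg_stops = stops[rows$category == "PCG"],
    trna = lapply(trna_truth, function(st) {
      list(layout = st$layout$stems, d_arm_present = st$layout$d_arm_present,
           classes = st$classes)
    }),
    cr_elements = cr_truth,
    config = unclass(config)
  )
  structure(list(genome = genome, truth = truth), class = "mito_simulation")
}

#' Write a simulation as a GenBank + FASTA + truth-ledger JSON triplet
#'
#' @param sim A `mito_simulation` from [simulate_mitogenome()].
#' @param prefix Output path prefix; writes `<prefix>.gb`, `<prefix>.fa`,
#'   `<prefix>.truth.json`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(genbank = paste0(prefix, ".gb"),
             fasta = paste0(prefix, ".fa"),
             truth = paste0(prefix, ".truth.json"))
  write_genbank(sim$genome, paths[["genbank"]])
  write_fasta(setNames(sim$genome$sequence, sim$genome$accession),
              paths[["fasta"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
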