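# Domain model for circular annotated mitogenomes.
#
# A gene table is a tibble (subclass "gene_table") with one row per annotated
# feature: gene, category, strand, start, end, declared_size, anticodon, plus
# any extra columns carried through from the source file (e.g. start/stop
# codons or a declared intergenic column). Coordinates are 1-based and fully
# inclusive; a feature wrapping the circular origin is stored with end < start
# and sorted last. A mitogenome is a light S3 list holding the (optional)
# sequence, the total length, and the gene table.

GENE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control_region")

#' Infer the feature category from a gene label
#'
#' `trn*` is tRNA, `rrn*` is rRNA, labels mentioning "A+T", "control" or
#' "D-loop" are the control region, anything else is a protein-coding gene.
#'
#' @param name Character vector of gene labels.
#' @return Character vector over `PCG`, `tRNA`, `rRNA`, `control_region`.
#' @export
infer_gene_category <- function(name) {
  dplyr::case_when(
    stringr::str_detect(name, stringr::regex("^trn", ignore_case = TRUE)) ~ "tRNA",
    stringr::str_detect(name, stringr::regex("^rrn", ignore_case = TRUE)) ~ "rRNA",
    stringr::str_detect(
      name, stringr::regex("A\\s*\\+\\s*T|control|D-?loop", ignore_case = TRUE)
    ) ~ "control_region",
    TRUE ~ "PCG"
  )
}

new_gene_table <- function(df) {
  # wrap-around feature (end < start), if any, goes last; others by start
  wraps <- !is.na(df$end) & df$end < df$start
  df <- dplyr::bind_rows(
    dplyr::arrange(df[!wraps, ], .data$start),
    df[wraps, ]
  )
  class(df) <- c("gene_table", class(tibble()))
  df
}

#' Read a feature table (TSV) into a gene table
#'
#' Expects tab-separated columns `gene`, `direction` (`F`/`R`), `start`,
#' `end`, `size`, `anticodon`; extra columns (for example declared start/stop
#' codons or a declared intergenic column) are carried through untouched.
#' The declared `size` is preserved verbatim as `declared_size` but never
#' trusted: computed lengths from coordinates are authoritative.
#'
#' @param path Path to the TSV file.
#' @return A `gene_table` tibble with columns `gene`, `category`, `strand`
#'   (`forward`/`reverse`), `start`, `end`, `declared_size`, `anticodon`,
#'   plus any extras.
#' @export
#' @examples
#' tab <- table2_fixture()
#' dplyr::count(tab, category)
read_gene_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  need <- c("gene", "direction", "start", "end", "size", "anticodon")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("feature table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  parse_int <- function(x, col) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("malformed %s '%s' in row %d (gene '%s')",
                    col, x[bad[1]], bad[1], raw$gene[bad[1]]))
    }
    out
  }
  start <- parse_int(raw$start, "start coordinate")
  end <- parse_int(raw$end, "end coordinate")
  declared_size <- parse_int(raw$size, "size")
  category <- infer_gene_category(raw$gene)

  dir <- raw$direction
  # an unstranded control-region row defaults to forward (it is excluded from
  # strand censuses anyway)
  dir[is.na(dir) & category == "control_region"] <- "F"
  bad_dir <- which(is.na(dir) | !dir %in% c("F", "R"))
  if (length(bad_dir) > 0) {
    abort(sprintf("unknown direction symbol '%s' in row %d (gene '%s'); expected F or R",
                  dir[bad_dir[1]], bad_dir[1], raw$gene[bad_dir[1]]))
  }

  extras <- raw[setdiff(names(raw), need)]
  if ("intergenic" %in% names(extras)) {
    extras$intergenic <- parse_int(extras$intergenic, "intergenic")
  }
  df <- tibble(
    gene = raw$gene,
    category = category,
    strand = ifelse(dir == "F", "forward", "reverse"),
    start = start,
    end = end,
    declared_size = declared_size,
    anticodon = toupper(raw$anticodon)
  )
  df <- dplyr::bind_cols(df, extras)
  validate_gene_table(df)
  new_gene_table(df)
}

validate_gene_table <- function(df, L = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 1, na.rm = TRUE) || any(df$end < 1, na.rm = TRUE)) {
    abort("feature coordinates must be >= 1")
  }
  if (!is.null(L) && any(df$start > L | df$end > L)) {
    off <- df$gene[df$start > L | df$end > L]
    abort(sprintf("feature(s) out of bounds [1, %d]: %s", L,
                  paste(off, collapse = ", ")))
  }
  cr <- df$category == "control_region"
  if (sum(cr) > 1) abort("at most one control_region feature is allowed")
  if (any(cr & !is.na(df$anticodon))) {
    abort("a control_region feature cannot carry an anticodon")
  }
  invisible(df)
}

#' Feature length on a circular molecule
#'
#' 1-based inclusive coordinates; `end < start` denotes a feature wrapping
#' the circular origin, in which case the genome length `L` is required.
#'
#' @param start,end Integer vectors of coordinates.
#' @param L Genome length (only needed for wrap-around features).
#' @return Integer vector of lengths in bp.
#' @export
#' @examples
#' feature_length(252, 1266)  # 1015
#' feature_length(95, 5, L = 100)  # 11
feature_length <- function(start, end, L = NULL) {
  wrap <- end < start
  if (any(wrap) && is.null(L)) {
    abort("`L` (genome length) is required for features wrapping the origin")
  }
  out <- ifelse(wrap, L - start + 1L + end, end - start + 1L)
  as.integer(out)
}

#' Construct a mitogenome object
#'
#' @param features A `gene_table` (or plain data frame with its columns).
#' @param length Total genome length in bp. Defaults to the maximum feature
#'   end when a sequence is absent.
#' @param sequence Optional circular DNA string over `A,C,G,T,N`
#'   (the linearised majority strand).
#' @param accession Text identifier.
#' @return An object of class `mitogenome`: a list with elements `accession`,
#'   `length`, `sequence` (possibly `NULL`), `features`, `topology`.
#' @export
mitogenome <- function(features, length = NULL, sequence = NULL,
                       accession = "unnamed") {
  features <- new_gene_table(as_tibble(features))
  if (!is.null(sequence)) {
    sequence <- check_dna(sequence, arg = "sequence")
    if (!is.null(length) && nchar(sequence) != length) {
      abort(sprintf("sequence length (%d) does not match `length` (%d)",
                    nchar(sequence), length))
    }
    length <- nchar(sequence)
  }
  if (is.null(length)) length <- max(features$start, features$end)
  validate_gene_table(features, L = length)
  structure(
    list(accession = accession, length = as.integer(length),
         sequence = sequence, features = features, topology = "circular"),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: circular, %s bp, %d features%s\n",
              x$accession, format(x$length, big.mark = ","),
              nrow(x$features),
              if (is.null(x$sequence)) " (annotation only)" else ""))
  tally <- table(factor(x$features$category, levels = GENE_CATEGORIES))
  cat("  ", paste(sprintf("%s: %d", names(tally), tally), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the sequence of one feature in coding orientation
#'
#' Forward-strand features return the subsequence as stored; reverse-strand
#' features are reverse-complemented; wrap-around features are read through
#' the circular origin.
#'
#' @param genome A [mitogenome()] with a sequence.
#' @param feature A gene name, or a one-row data frame with `start`, `end`,
#'   `strand`.
#' @return DNA string in coding orientation.
#' @export
extract_feature_sequence <- function(genome, feature) {
  if (is.null(genome$sequence)) {
    abort("genome has no sequence; annotation-only mode cannot extract sequences")
  }
  if (is.character(feature)) {
    row <- genome$features[genome$features$gene == feature, , drop = FALSE]
    if (nrow(row) != 1) abort(sprintf("feature '%s' not found (or ambiguous)", feature))
    feature <- row
  }
  s <- circular_substr(genome$sequence, feature$start[1], feature$end[1])
  if (identical(feature$strand[1], "reverse")) s <- revcomp(s)
  s
}

#' All feature sequences of a genome, as a tibble
#'
#' @param genome A [mitogenome()] with a sequence.
#' @return Tibble with `gene`, `category`, `strand`, `length`, `sequence`
#'   (coding orientation).
#' @export
feature_sequences <- function(genome) {
  if (is.null(genome$sequence)) {
    abort("genome has no sequence; annotation-only mode cannot extract sequences")
  }
  f <- genome$features
  seqs <- vapply(seq_len(nrow(f)), function(i) {
    extract_feature_sequence(genome, f[i, , drop = FALSE])
  }, character(1))
  tibble(gene = f$gene, category = f$category, strand = f$strand,
         length = nchar(seqs), sequence = seqs)
}

# ---- GenBank flat-file I/O ---------------------------------------------------
# Minimal single-record reader/writer: LOCUS, FEATURES, ORIGIN. Locations
# supported: a..b, complement(a..b), and a single origin-wrapping
# join(a..L,1..b) (optionally complemented). This covers what the simulator
# writes and what a desk-scale annotated mitogenome needs; multi-record files
# and other join() forms are rejected.

gb_feature_key <- function(category) {
  c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control_region = "misc_feature")[category]
}

gb_location <- function(start, end, strand, L) {
  loc <- if (end >= start) {
    sprintf("%d..%d", start, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start, L, end)
  }
  if (strand == "reverse") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' @param genome A [mitogenome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  f <- genome$features
  validate_gene_table(f, L = genome$length)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular INV 01-JAN-2026",
            substr(genome$accession, 1, 16), genome$length),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", genome$accession),
    sprintf("ACCESSION   %s", genome$accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", genome$length),
    "                     /organism=\"synthetic construct\""
  )
  for (i in seq_len(nrow(f))) {
    key <- gb_feature_key(f$category[i])
    lines <- c(lines,
      sprintf("     %-15s %s", key, gb_location(f$start[i], f$end[i], f$strand[i], genome$length)),
      sprintf("                     /gene=\"%s\"", f$gene[i]))
    if (f$category[i] == "control_region") {
      lines <- c(lines, "                     /note=\"control region; A+T-rich region\"")
    }
    if (!is.null(f$anticodon) && !is.na(f$anticodon[i])) {
      lines <- c(lines, sprintf("                     /note=\"anticodon:%s\"", f$anticodon[i]))
    }
  }
  if (!is.null(genome$sequence)) {
    lines <- c(lines, "ORIGIN")
    s <- tolower(genome$sequence)
    starts <- seq(1, nchar(s), by = 60)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

parse_gb_location <- function(loc, L) {
  strand <- "forward"
  if (grepl("^complement\\(", loc)) {
    strand <- "reverse"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    iv <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    ok <- length(iv) == 2 && length(iv[[1]]) == 2 && length(iv[[2]]) == 2 &&
      (is.na(L) || iv[[1]][2] == L) && iv[[2]][1] == 1
    if (!ok) {
      abort(sprintf("unsupported join() location '%s': only a single origin wrap join(a..L,1..b) is supported", loc))
    }
    return(list(start = iv[[1]][1], end = iv[[2]][2], strand = strand))
  }
  xy <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(xy) != 2 || anyNA(xy)) abort(sprintf("cannot parse location '%s'", loc))
  list(start = xy[1], end = xy[2], strand = strand)
}

#' Read a GenBank flat file into a mitogenome
#'
#' Maps `CDS`/`gene` features to PCGs, `tRNA`/`rRNA` to their categories, and
#' `misc_feature`/`D-loop` to the control region. `complement(...)` locations
#' become reverse-strand features; a single origin-wrapping `join()` is
#' honoured. A record without an `ORIGIN` section yields an annotation-only
#' genome whose length comes from the LOCUS line.
#'
#' @param path Path to a single-record GenBank flat file.
#' @return A [mitogenome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort("not a GenBank flat file: no LOCUS line")
  if (length(locus) > 1) abort("multi-record GenBank files are not supported")
  L <- as.integer(sub("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp.*$", "\\1", locus[1]))
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line) > 0) {
    sub("^ACCESSION\\s+(\\S+).*$", "\\1", acc_line[1])
  } else {
    sub("^LOCUS\\s+(\\S+).*$", "\\1", locus[1])
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  end_rec <- grep("^//", lines)
  feat_end <- min(c(origin_start, end_rec, length(lines) + 1L)) - 1L

  feats <- list()
  cur <- NULL
  if (length(feat_start) == 1) {
    for (ln in lines[(feat_start + 1L):feat_end]) {
      if (grepl("^\\s{5}\\S", ln) && !grepl("^\\s{21}", ln)) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        key <- sub("^\\s{5}(\\S+)\\s+.*$", "\\1", ln)
        loc <- sub("^\\s{5}\\S+\\s+(\\S+)\\s*$", "\\1", ln)
        cur <- list(key = key, loc = loc, quals = character())
      } else if (!is.null(cur) && grepl("^\\s{21}", ln)) {
        q <- trimws(ln)
        if (grepl("^/", q)) {
          cur$quals <- c(cur$quals, q)
        } else {
          # continuation of a wrapped location line
          cur$loc <- paste0(cur$loc, q)
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  qual_value <- function(quals, name) {
    hit <- grep(sprintf("^/%s=", name), quals, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    gsub("\"", "", sub(sprintf("^/%s=", name), "", hit[1]))
  }

  rows <- purrr::map(feats, function(ft) {
    if (ft$key %in% c("source", "gene")) return(NULL)
    category <- switch(ft$key,
      CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      misc_feature = "control_region", D_loop = "control_region",
      "D-loop" = "control_region",
      NULL)
    if (is.null(category)) return(NULL)
    loc <- parse_gb_location(ft$loc, L)
    name <- qual_value(ft$quals, "gene")
    if (is.na(name)) name <- qual_value(ft$quals, "product")
    if (is.na(name)) name <- ft$key
    notes <- grep("^/note=", ft$quals, value = TRUE)
    anticodon <- NA_character_
    ac <- regmatches(notes, regexpr("anticodon:[ACGTU]{3}", notes))
    if (length(ac) > 0) anticodon <- sub("anticodon:", "", ac[1])
    tibble(gene = name, category = category, strand = loc$strand,
           start = loc$start, end = loc$end,
           declared_size = NA_integer_, anticodon = anticodon)
  })
  features <- dplyr::bind_rows(rows)

  sequence <- NULL
  if (length(origin_start) == 1) {
    seq_lines <- lines[(origin_start + 1L):(min(end_rec[end_rec > origin_start]) - 1L)]
    sequence <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
    if (nchar(sequence) == 0) sequence <- NULL
  }
  mitogenome(features, length = L, sequence = sequence, accession = accession)
}

# ---- FASTA I/O ---------------------------------------------------------------

#' Read a single-record FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of length 1 (name = record id).
#' @export
read_fasta_sequence <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1) abort("expected a single FASTA record")
  setNames(toupper(as.character(x[[1]])), sub("\\s.*$", "", names(x)[1]))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA (or amino acid) strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
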