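# Concatenated protein-coding-gene supermatrix construction.
#
# This module prepares the input to external tree inference: it extracts the
# 13 canonical PCGs in coding orientation, translates them under the
# invertebrate mitochondrial code, concatenates pre-aligned per-gene blocks
# into a partitioned supermatrix, and serialises it as FASTA (+ RAxML-style
# partition sidecar), relaxed PHYLIP, or NEXUS with a sets block. Alignment
# and masking themselves are left to the standard external tools.

CANONICAL_PCGS <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
                    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")

#' Extract the 13 canonical protein-coding genes
#'
#' @param genome A [mitogenome()] with a sequence and 13 annotated PCGs.
#' @return Named character vector of coding-orientation DNA, keyed by the
#'   canonical names (atp6, atp8, cob, cox1-3, nad1-6, nad4L).
#' @export
extract_pcgs <- function(genome) {
  fs <- feature_sequences(genome)
  pcgs <- fs[fs$category == "PCG", ]
  key <- sub("\\(.*$", "", pcgs$gene)
  missing <- setdiff(CANONICAL_PCGS, key)
  if (length(missing) > 0) {
    abort(sprintf("missing canonical PCG(s): %s", paste(missing, collapse = ", ")))
  }
  setNames(pcgs$sequence[match(CANONICAL_PCGS, key)], CANONICAL_PCGS)
}

#' Translate a CDS under the invertebrate mitochondrial code
#'
#' Translation table 5 (AGA/AGG = Ser, AUA = Met, UGA = Trp). A trailing
#' 1-2 nt truncated-stop remainder is dropped, as is a final complete stop;
#' internal stops are rendered `*` with a warning. The first codon is
#' translated by the table (a noncanonical CGA start therefore yields `R`,
#' not a forced `M`). Codons containing `N` translate to `X`.
#'
#' @param cds CDS string (DNA or RNA, coding orientation), length >= 3.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_mito("ATGAGATGA")  # "MSW": AGA = Ser, UGA = Trp
translate_mito <- function(cds) {
  s <- chartr("Uu", "Tt", toupper(cds))
  n <- nchar(s)
  if (n < 3) abort("CDS must be at least 3 nt")
  n <- n - n %% 3  # drop truncated-stop remainder
  codons <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  code <- Biostrings::getGeneticCode("5")
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # ambiguous bases
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]  # final complete stop
  if (any(aa == "*")) {
    warn(sprintf("internal stop codon(s) at residue position(s) %s",
                 paste(which(aa == "*"), collapse = ", ")))
  }
  paste(aa, collapse = "")
}

#' Concatenate pre-aligned gene blocks into a supermatrix
#'
#' @param alignments Named list of gene blocks; each block is a named
#'   character vector (taxon -> aligned row, all rows in a block the same
#'   width) over an identical taxon set.
#' @param gene_order Order in which blocks are concatenated (default: the
#'   list order).
#' @param alphabet `"nucleotide"` or `"amino_acid"`; guessed from the
#'   residues when omitted.
#' @return A `supermatrix`: list with `taxa`, `alphabet`, `sequences`
#'   (named character rows), and `partitions` (tibble `gene`, `start`,
#'   `end` of 1-based inclusive column intervals tiling the matrix).
#' @export
concatenate_alignments <- function(alignments, gene_order = names(alignments),
                                   alphabet = NULL) {
  stopifnot(length(alignments) > 0, !is.null(names(alignments)))
  if (!setequal(gene_order, names(alignments))) {
    abort("gene_order must be a permutation of the block names")
  }
  taxa <- names(alignments[[1]])
  for (g in names(alignments)) {
    blk <- alignments[[g]]
    if (!setequal(names(blk), taxa)) {
      diff <- c(setdiff(taxa, names(blk)), setdiff(names(blk), taxa))
      abort(sprintf("taxon sets differ at block '%s': %s", g,
                    paste(unique(diff), collapse = ", ")))
    }
    if (length(unique(nchar(blk))) != 1) {
      abort(sprintf("block '%s' rows are not equal length (is it aligned?)", g))
    }
  }
  widths <- unname(vapply(alignments[gene_order], function(b) nchar(b[[1]]),
                          integer(1)))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(taxa, function(tx) {
    paste(vapply(gene_order, function(g) alignments[[g]][[tx]], character(1)),
          collapse = "")
  }, character(1))
  if (is.null(alphabet)) {
    residues <- unique(str_chars(paste(rows, collapse = "")))
    alphabet <- if (all(residues %in% c(DNA_BASES, "U", "N", "-", "?")))
      "nucleotide" else "amino_acid"
  }
  structure(
    list(taxa = taxa, alphabet = alphabet, sequences = rows,
         partitions = tibble(gene = gene_order, start = starts, end = ends)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d %s columns, %d partitions\n",
              length(x$taxa), nchar(x$sequences[[1]]), x$alphabet,
              nrow(x$partitions)))
  invisible(x)
}

sanitize_taxa <- function(taxa) {
  clean <- gsub("\\s+", "_", taxa)
  if (any(clean != taxa)) warn("whitespace in taxon labels replaced with '_'")
  clean
}

#' Write a supermatrix to disk
#'
#' Formats: `"fasta"` (plus a RAxML-style partition sidecar at
#' `<path>.partitions` unless `partition_path` says otherwise), `"phylip"`
#' (relaxed: full labels, single space), `"nexus"` (data block plus a sets
#' block of charset lines mirroring the partitions).
#'
#' @param m A `supermatrix`.
#' @param path Output path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param partition_path Sidecar path for FASTA partitions.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("fasta", "phylip", "nexus"),
                         partition_path = NULL) {
  format <- match.arg(format)
  taxa <- sanitize_taxa(m$taxa)
  rows <- setNames(unname(m$sequences), taxa)
  ncol <- nchar(rows[[1]])
  ptype <- if (m$alphabet == "nucleotide") "DNA" else "PROT"
  if (format == "fasta") {
    write_fasta(rows, path)
    partition_path <- partition_path %||% paste0(path, ".partitions")
    writeLines(sprintf("%s, %s = %d-%d", ptype, m$partitions$gene,
                       m$partitions$start, m$partitions$end), partition_path)
  } else if (format == "phylip") {
    writeLines(c(sprintf("%d %d", length(taxa), ncol),
                 sprintf("%s  %s", taxa, rows)), path)
  } else {
    datatype <- if (m$alphabet == "nucleotide") "DNA" else "PROTEIN"
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa), ncol),
      sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=-;", datatype),
      "  MATRIX",
      sprintf("    %s  %s", taxa, rows),
      "  ;",
      "END;",
      "BEGIN SETS;",
      sprintf("  CHARSET %s = %d-%d;", m$partitions$gene,
              m$partitions$start, m$partitions$end),
      "END;"
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a FASTA supermatrix and its partition sidecar
#'
#' Inverse of `write_matrix(format = "fasta")`.
#'
#' @param path FASTA path.
#' @param partition_path Partition sidecar path (default `<path>.partitions`).
#' @return A `supermatrix`.
#' @export
read_matrix_fasta <- function(path, partition_path = paste0(path, ".partitions")) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  taxa <- sub("^>", "", lines[hdr])
  seq_to <- c(hdr[-1] - 1L, length(lines))
  rows <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):seq_to[i]], collapse = "")
  }, character(1))
  plines <- readLines(partition_path, warn = FALSE)
  pm <- regmatches(plines, regexec("^(\\S+), (\\S+) = (\\d+)-(\\d+)$", plines))
  partitions <- tibble(
    gene = vapply(pm, `[`, character(1), 3),
    start = as.integer(vapply(pm, `[`, character(1), 4)),
    end = as.integer(vapply(pm, `[`, character(1), 5))
  )
  alphabet <- if (vapply(pm, `[`, character(1), 2)[1] == "DNA")
    "nucleotide" else "amino_acid"
  structure(
    list(taxa = taxa, alphabet = alphabet,
         sequences = setNames(rows, taxa), partitions = partitions),
    class = "supermatrix"
  )
}
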