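test_that("read_gene_table parses rows, infers categories, preserves extras", {
  path <- write_temp_tsv(c(
    "gene\tdirection\tstart\tend\tsize\tanticodon",
    "nad2\tF\t252\t1266\t1015\t",
    "trnM\tF\t1\t68\t68\tCAT",
    "rrnS\tR\t14204\t14995\t792\t",
    "A+T-rich region\t\t14996\t15396\t401\t"
  ))
  tab <- read_gene_table(path)
  expect_s3_class(tab, "gene_table")
  expect_equal(tab$gene[1], "trnM")  # sorted by start
  nad2 <- tab[tab$gene == "nad2", ]
  expect_equal(nad2$category, "PCG")
  expect_equal(nad2$strand, "forward")
  expect_equal(c(nad2$start, nad2$end, nad2$declared_size), c(252L, 1266L, 1015L))
  expect_equal(tab$anticodon[tab$gene == "trnM"], "CAT")
  expect_equal(tab$category[tab$gene == "trnM"], "tRNA")
  expect_equal(tab$category[tab$gene == "rrnS"], "rRNA")
  expect_equal(tab$category[tab$gene == "A+T-rich region"], "control_region")
})

test_that("read_gene_table handles the empty and malformed cases", {
  empty <- read_gene_table(write_temp_tsv(
    "gene\tdirection\tstart\tend\tsize\tanticodon"))
  expect_equal(nrow(empty), 0L)

  bad_coord <- write_temp_tsv(c(
    "gene\tdirection\tstart\tend\tsize\tanticodon",
    "nad2\tF\ttwo52\t1266\t1015\t"
  ))
  expect_error(read_gene_table(bad_coord), "nad2")

  bad_dir <- write_temp_tsv(c(
    "gene\tdirection\tstart\tend\tsize\tanticodon",
    "nad2\tX\t252\t1266\t1015\t"
  ))
  expect_error(read_gene_table(bad_dir), "direction")
})

test_that("feature_length follows inclusive and wrap-around arithmetic", {
  expect_equal(feature_length(252, 1266), 1015L)
  expect_equal(feature_length(1466, 2996), 1531L)
  expect_equal(feature_length(95, 5, L = 100), 11L)
  expect_error(feature_length(95, 5), "genome length")
})

test_that("extract_feature_sequence honours strand and circular wrap", {
  g <- mitogenome(
    tibble::tibble(gene = c("a", "b"), category = c("PCG", "tRNA"),
                   strand = c("forward", "reverse"),
                   start = c(1L, 4L), end = c(3L, 6L),
                   declared_size = NA_integer_, anticodon = NA_character_),
    sequence = "AAACCC"
  )
  expect_equal(extract_feature_sequence(g, "a"), "AAA")
  expect_equal(extract_feature_sequence(g, "b"), "GGG")

  wrap <- mitogenome(
    tibble::tibble(gene = "w", category = "control_region", strand = "forward",
                   start = 5L, end = 2L, declared_size = NA_integer_,
                   anticodon = NA_character_),
    sequence = "ATGCAT"
  )
  expect_equal(extract_feature_sequence(wrap, "w"), "ATAT")
  expect_equal(nchar(extract_feature_sequence(wrap, "w")),
               feature_length(5, 2, L = 6))
})

test_that("the packaged gene table matches the published genome architecture", {
  tab <- table2_fixture()
  expect_equal(nrow(tab), 38L)
  expect_equal(max(tab$end), 15396L)
  census <- table(tab$category)
  expect_equal(census[["PCG"]], 13L)
  expect_equal(census[["tRNA"]], 22L)
  expect_equal(census[["rRNA"]], 2L)
  expect_equal(census[["control_region"]], 1L)
  cr <- tab[tab$category == "control_region", ]
  expect_equal(c(cr$start, cr$end), c(14996L, 15396L))
  # declared sizes are carried but not trusted: trnY prints 67 where its
  # coordinates span 69
  trnY <- tab[tab$gene == "trnY", ]
  expect_equal(trnY$declared_size, 67L)
  expect_equal(feature_length(trnY$start, trnY$end), 69L)
})

test_that("GenBank write/read round-trips the domain model", {
  sim <- simulate_mitogenome(simulation_config(seed = 402))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  back <- read_genbank(path)
  expect_equal(back$length, sim$genome$length)
  expect_equal(back$sequence, sim$genome$sequence)
  core <- c("gene", "category", "strand", "start", "end", "anticodon")
  expect_equal(as.data.frame(back$features[core]),
               as.data.frame(sim$genome$features[core]))

  # reverse-strand features round-trip through complement(...)
  raw <- readLines(path)
  expect_true(any(grepl("complement\\(6418\\.\\.8136\\)", raw)))
})

test_that("GenBank handles wrap-around joins and annotation-only records", {
  g <- mitogenome(
    tibble::tibble(gene = c("x", "cr"), category = c("PCG", "control_region"),
                   strand = c("forward", "forward"),
                   start = c(15L, 90L), end = c(80L, 10L),
                   declared_size = NA_integer_, anticodon = NA_character_),
    length = 100L,
    sequence = strrep("ACGTA", 20)
  )
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  expect_true(any(grepl("join(90..100,1..10)", readLines(path), fixed = TRUE)))
  back <- read_genbank(path)
  cr <- back$features[back$features$gene == "cr", ]
  expect_equal(c(cr$start, cr$end), c(90L, 10L))
  expect_equal(extract_feature_sequence(back, "cr"),
               extract_feature_sequence(g, "cr"))

  # annotation-only: strip the ORIGIN block
  lines <- readLines(path)
  writeLines(c(lines[seq_len(grep("^ORIGIN", lines) - 1)], "//"), path)
  bare <- read_genbank(path)
  expect_null(bare$sequence)
  expect_equal(bare$length, 100L)
  expect_error(extract_feature_sequence(bare, "x"), "annotation-only")
})

test_that("unsupported join() locations are rejected", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       X                100 bp    DNA     circular INV 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..10,50..60)",
    "                     /gene=\"bad\"",
    "//"
  ), path)
  expect_error(read_genbank(path), "join")
})

test_that("FASTA I/O round-trips a single record", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(rec1 = "ACGTACGT"), path)
  back <- read_fasta_sequence(path)
  expect_equal(back, c(rec1 = "ACGTACGT"))
})
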