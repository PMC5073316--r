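test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_mito("ATGAGATGA"), "MSW")  # AGA=Ser, UGA=Trp
  expect_equal(translate_mito("ATTTAA"), "I")       # terminal TAA dropped
  expect_equal(translate_mito("CGAATT"), "RI")      # CGA start stays Arg
  expect_equal(translate_mito("ATGAAAT"), "MK")     # truncated stop dropped
  expect_equal(translate_mito("ATGAAATA"), "MK")
  expect_equal(translate_mito("ATGANAAAA"), "MXK")  # ambiguity -> X
  expect_warning(out <- translate_mito("ATGTAAAAA"), "internal stop")
  expect_equal(out, "M*K")
  expect_error(translate_mito("AT"), "at least 3")
})

test_that("translation length and alphabet invariants hold on random CDS", {
  set.seed(11)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    n <- sample(30:300, 1)
    s <- random_dna(n)
    aa <- suppressWarnings(translate_mito(s))
    res <- strsplit(aa, "")[[1]]
    expect_true(all(res %in% c(aa20, "*")))
    full <- n %/% 3
    expect_true(nchar(aa) %in% c(full, full - 1))  # minus a final stop
  }
})

test_that("extract_pcgs returns the 13 canonical genes in coding orientation", {
  sim <- simulate_mitogenome(simulation_config(seed = 5))
  pcgs <- extract_pcgs(sim$genome)
  expect_named(pcgs, c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
                       "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6"))
  f <- sim$genome$features
  for (g in names(pcgs)) {
    row <- f[f$gene == g, ]
    expect_equal(nchar(pcgs[[g]]), feature_length(row$start, row$end,
                                                  sim$genome$length))
  }
  # a reverse-strand gene comes back reverse-complemented
  nad5 <- f[f$gene == "nad5", ]
  expect_equal(pcgs[["nad5"]],
               revcomp(substr(sim$genome$sequence, nad5$start, nad5$end)))

  # dropping a gene is an error naming the absentee
  crippled <- sim$genome
  crippled$features <- crippled$features[crippled$features$gene != "nad3", ]
  expect_error(extract_pcgs(crippled), "nad3")
})

toy_blocks <- function() {
  list(
    g1 = c(t1 = "AAACCCGGG", t2 = "AAAGGGCCC", t3 = "TTTAAACCC"),
    g2 = c(t1 = "ACGTACGTACGT", t2 = "TGCATGCATGCA", t3 = "AAAACCCCGGGG")
  )
}

test_that("concatenation records tiling partitions", {
  m <- concatenate_alignments(toy_blocks())
  expect_equal(nchar(m$sequences[["t1"]]), 21L)
  expect_equal(m$partitions$start, c(1L, 10L))
  expect_equal(m$partitions$end, c(9L, 21L))
  expect_equal(m$alphabet, "nucleotide")

  single <- concatenate_alignments(toy_blocks()["g1"])
  expect_equal(unname(single$sequences), unname(toy_blocks()$g1))

  bad <- toy_blocks()
  names(bad$g2) <- c("t1", "t2", "OTHER")
  expect_error(concatenate_alignments(bad), "taxon sets differ")
  ragged <- toy_blocks()
  ragged$g1[["t1"]] <- "AAA"
  expect_error(concatenate_alignments(ragged), "equal length")
})

test_that("concatenation is associative", {
  blocks <- c(toy_blocks(), list(g3 = c(t1 = "GG", t2 = "CC", t3 = "AT")))
  all_at_once <- concatenate_alignments(blocks)
  nested <- concatenate_alignments(list(
    g1 = blocks$g1,
    g23 = concatenate_alignments(blocks[c("g2", "g3")])$sequences
  ))
  expect_equal(unname(nested$sequences), unname(all_at_once$sequences))
})

test_that("13 simulated gene blocks tile the supermatrix", {
  sim <- simulate_mitogenome(simulation_config(seed = 9))
  pcgs <- extract_pcgs(sim$genome)
  # one-taxon "alignment" blocks straight from the genome
  blocks <- lapply(pcgs, function(s) c(simtax = s))
  m <- concatenate_alignments(blocks)
  expect_equal(sum(m$partitions$end - m$partitions$start + 1L),
               nchar(m$sequences[[1]]))
  expect_equal(m$partitions$gene, names(pcgs))
})

test_that("matrix writers emit the advertised formats and round-trip", {
  m <- concatenate_alignments(toy_blocks())
  phy <- withr::local_tempfile(fileext = ".phy")
  write_matrix(m, phy, format = "phylip")
  expect_equal(readLines(phy)[1], "3 21")

  nex <- withr::local_tempfile(fileext = ".nex")
  write_matrix(m, nex, format = "nexus")
  nex_lines <- readLines(nex)
  expect_equal(sum(grepl("CHARSET", nex_lines)), nrow(m$partitions))
  expect_true(any(grepl("NTAX=3", nex_lines)))

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_matrix(m, fa, format = "fasta")
  back <- read_matrix_fasta(fa)
  expect_equal(back$sequences, m$sequences)
  expect_equal(back$partitions, m$partitions)
  expect_equal(back$alphabet, m$alphabet)
  # independent reader sees the same rows
  bs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(bs), m$sequences)

  # whitespace in taxon labels is sanitised with a warning
  ws <- m
  names(ws$sequences) <- ws$taxa <- c("taxon one", "t2", "t3")
  expect_warning(write_matrix(ws, phy, format = "phylip"), "whitespace")
  expect_true(grepl("^taxon_one", readLines(phy)[2]))
})

test_that("amino-acid supermatrices are labelled PROT in the partition file", {
  aa_blocks <- list(g1 = c(t1 = "MKV", t2 = "MRV"))
  m <- concatenate_alignments(aa_blocks)
  expect_equal(m$alphabet, "amino_acid")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_matrix(m, fa, format = "fasta")
  expect_true(grepl("^PROT,", readLines(paste0(fa, ".partitions"))[1]))
})
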