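test_that("simulation is deterministic given the seed", {
  a <- simulate_mitogenome(simulation_config(seed = 12))
  b <- simulate_mitogenome(simulation_config(seed = 12))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)
  c <- simulate_mitogenome(simulation_config(seed = 13))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("simulated genomes carry the configured architecture", {
  sim <- simulate_mitogenome(simulation_config(seed = 2))
  g <- sim$genome
  census <- table(g$features$category)
  expect_equal(census[["PCG"]], 13L)
  expect_equal(census[["tRNA"]], 22L)
  expect_equal(census[["rRNA"]], 2L)
  expect_equal(census[["control_region"]], 1L)
  expect_equal(g$features$gene, gene_order_preset("lepidopteran"))
  expect_equal(nchar(g$sequence), g$length)
  # gaps in the truth ledger equal the coordinate-derived adjacency ledger
  led <- adjacency_ledger(g$features, L = g$length)
  expect_equal(led$gap, sim$truth$features$gap_after)
})

test_that("realized whole-genome A+T content lands within a point of target", {
  sim <- simulate_mitogenome(simulation_config(seed = 11))
  comp <- partition_composition(sim$genome)
  expect_lt(abs(comp$pct_AT[comp$partition == "mitogenome"] - 80.5), 1)
  expect_lt(abs(comp$pct_AT[comp$partition == "control region"] - 93.3), 3)
  # partition counts in the ledger equal pipeline counts exactly
  pc <- sim$truth$partition_counts
  m <- comp[comp$partition == "mitogenome", ]
  expect_equal(c(m$count_A, m$count_C, m$count_G, m$count_T),
               unname(pc$mitogenome[c("A", "C", "G", "T")]))
  p <- comp[comp$partition == "PCGs", ]
  expect_equal(c(p$count_A, p$count_C, p$count_G, p$count_T),
               unname(pc$PCG[c("A", "C", "G", "T")]))
})

test_that("configured gene orders propagate to rearrangement detection", {
  lep <- simulate_mitogenome(simulation_config(seed = 4))
  d <- compare_gene_order(lep$genome$features$gene,
                          gene_order_preset("ancestral_insect"))
  expect_equal(d$moved_genes, "trnM")

  anc <- simulate_mitogenome(simulation_config(seed = 4,
                                               gene_order = "ancestral_insect"))
  d0 <- compare_gene_order(anc$genome$features$gene,
                           gene_order_preset("ancestral_insect"))
  expect_equal(d0$breakpoint_count, 0L)
})

test_that("planted control-region elements are recovered exactly", {
  for (seed in c(7, 21)) {
    sim <- simulate_mitogenome(simulation_config(seed = seed))
    cr <- extract_feature_sequence(sim$genome, "A+T-rich region")
    el <- sim$truth$cr_elements
    pick <- function(e) el[el$element == e, ]

    m <- find_motif(cr, "ATAGA")
    expect_equal(nrow(m), 1L)
    expect_equal(m$position, pick("motif")$start)

    pt <- longest_run(cr, "T")
    expect_equal(c(pt$start, pt$total_length),
                 c(pick("homopolymer_T")$start, 12L))
    pa <- longest_run(cr, "A")
    expect_equal(c(pa$start, pa$total_length),
                 c(pick("homopolymer_A")$start, 10L))

    ms <- find_microsatellite(cr, "AT", min_copies = 10)
    expect_equal(nrow(ms), 1L)
    expect_equal(ms$start, pick("microsatellite")$start)
    expect_equal(ms$copies, 10)

    td <- find_tandem_repeats(cr, min_unit = 40, max_unit = 60)
    expect_equal(nrow(td), 1L)
    expect_equal(td$start, pick("tandem")$start)
    expect_equal(td$unit, pick("tandem")$unit)
    expect_equal(td$copies, 2)
  }
})

test_that("planted overlaps and spacers override the default junction gaps", {
  cfg <- simulation_config(
    seed = 6,
    overlaps = list(list(pair = c("trnA", "trnR"), bp = 3),
                    list(pair = c("cox3", "trnG"), bp = 7)),
    spacers = list(list(pair = c("trnK", "trnD"), bp = 40))
  )
  sim <- simulate_mitogenome(cfg)
  led <- adjacency_ledger(sim$genome$features, L = sim$genome$length)
  expect_equal(led$gap[led$upstream == "trnA"], -3L)
  expect_equal(led$gap[led$upstream == "cox3"], -7L)
  expect_equal(led$gap[led$upstream == "trnK"], 40L)
  ov <- overlap_summary(led)
  truth_gaps <- sim$truth$features$gap_after
  expect_equal(ov[["total_bp"]], sum(-truth_gaps[truth_gaps < 0]))

  expect_error(
    simulate_mitogenome(simulation_config(
      seed = 6, overlaps = list(list(pair = c("trnA", "nad1"), bp = 3)))),
    "not adjacent")
})

test_that("genome_length_target pads the terminal spacer", {
  sim <- simulate_mitogenome(simulation_config(seed = 8,
                                               genome_length_target = 16000))
  expect_equal(sim$genome$length, 16000L)
  expect_warning(
    simulate_mitogenome(simulation_config(seed = 8,
                                          genome_length_target = 1000)),
    "below")
})

test_that("infeasible control-region configs fail before sampling", {
  expect_error(
    simulate_mitogenome(simulation_config(
      seed = 1, cr_elements = list(tandem_unit_length = 190L))),
    "control-region")
  expect_error(simulation_config(seed = 1,
                                 partition_at_content = c(mitogenome = 1.2)),
               "0, 1")
})

test_that("the simulation triplet round-trips from disk", {
  sim <- simulate_mitogenome(simulation_config(seed = 14))
  prefix <- file.path(withr::local_tempdir(), "sim14")
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))

  gb <- read_genbank(paths[["genbank"]])
  expect_equal(gb$sequence, sim$genome$sequence)
  fa <- read_fasta_sequence(paths[["fasta"]])
  expect_equal(unname(fa), sim$genome$sequence)
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_equal(truth$genome_length, sim$genome$length)
  expect_equal(truth$gene_order, sim$truth$gene_order)
})

test_that("table3_fixture matches its published counts and totals", {
  t3 <- table3_fixture()
  cnt <- function(cod) t3$count[t3$codon == cod]
  expect_equal(cnt("UUU"), 370L)
  expect_equal(cnt("CUC"), 0L)
  expect_equal(cnt("UGG"), 6L)
  expect_equal(attr(t3, "total"), sum(t3$count))
  # fixture re-serialised and re-read is identical
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(codon = t3$codon, count = t3$count), path)
  back <- codon_count_table(readr::read_tsv(path, col_types = "ci"))
  expect_equal(back$count, t3$count)
  expect_equal(back$codon, t3$codon)
})

test_that("Dirichlet codon-bias mode produces valid genomes with exact codon truth", {
  sim <- simulate_mitogenome(simulation_config(seed = 3, codon_bias = 0.5))
  counts <- count_codons(extract_pcgs(sim$genome))
  truth <- Reduce(`+`, lapply(sim$truth$pcg_codon_counts, function(x) {
    v <- setNames(rep(0L, 64L), counts$codon)
    v[names(x)] <- x
    v
  }))
  expect_equal(counts$count, unname(truth[counts$codon]))
})
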