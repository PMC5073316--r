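fixture_ledger <- function() adjacency_ledger(table2_fixture(), L = 15396L)

test_that("adjacency ledger reproduces the published junction geometry", {
  led <- fixture_ledger()
  expect_s3_class(led, "adjacency_ledger")
  expect_equal(nrow(led), 38L)  # circular closure: one pair per feature
  gap_of <- function(up) led$gap[led$upstream == up]
  expect_equal(gap_of("trnQ"), 50L)    # longest spacer, trnQ/nad2
  expect_equal(gap_of("trnW"), -9L)    # longest overlap, trnW/trnC
  expect_equal(gap_of("atp8"), -7L)
  expect_equal(gap_of("A+T-rich region"), 0L)  # CR abuts the origin
  s <- glance(led)
  expect_equal(s$longest_overlap_bp, 9L)
  expect_equal(s$longest_overlap_pair, "trnW/trnC")
  expect_equal(s$longest_spacer_bp, 50L)
  expect_equal(s$longest_spacer_pair, "trnQ/nad2")
})

test_that("overlap summaries separate coordinate-derived and declared gaps", {
  led <- fixture_ledger()
  # coordinates give 24 bp over 5 junctions; the published intergenic column
  # prints 29 bp over 6 (its trnS2 row prints -5 where coordinates give +25)
  expect_equal(overlap_summary(led),
               c(total_bp = 24L, locations = 5L))
  expect_equal(overlap_summary(led, source = "declared"),
               c(total_bp = 29L, locations = 6L))
  trnS2 <- led[led$upstream == "trnS2(UCN)", ]
  expect_equal(trnS2$gap, 25L)
  expect_equal(trnS2$declared_gap, -5L)
  # a ledger without a declared column refuses declared-mode summaries
  sim_led <- adjacency_ledger(simulate_mitogenome(simulation_config(1))$genome$features,
                              L = 15396L)
  expect_error(overlap_summary(sim_led, source = "declared"), "declared")
})

test_that("abutting features tile with all-zero gaps", {
  tab <- read_gene_table(write_temp_tsv(c(
    "gene\tdirection\tstart\tend\tsize\tanticodon",
    "g1\tF\t1\t10\t10\t",
    "g2\tF\t11\t20\t10\t"
  )))
  led <- adjacency_ledger(tab, L = 20L)
  expect_equal(led$gap, c(0L, 0L))
  expect_error(adjacency_ledger(tab[c(1, 1), ], L = 20L), "duplicated")
})

test_that("start/stop classification covers canonical, CGA, and truncated stops", {
  calls <- classify_start_stop(c(
    cox1 = paste0("CGA", strrep("GCT", 8)),
    plain = "ATGAAATAA",
    cox2 = paste0("ATG", strrep("CAT", 10), "T")
  ))
  expect_equal(calls$start_class,
               c("noncanonical", "canonical_ATN", "canonical_ATN"))
  expect_equal(calls$stop_literal[calls$gene == "plain"], "TAA")
  expect_equal(calls$stop_class[calls$gene == "plain"], "complete")
  expect_equal(calls$stop_literal[calls$gene == "cox2"], "T")
  expect_equal(calls$stop_class[calls$gene == "cox2"], "truncated")

  # truncated stops are never longer than 2 nt, whatever the input length
  set.seed(42)
  for (n in 7:30) {
    s <- paste0("ATG", paste(sample(c("A", "C", "G"), n, TRUE), collapse = ""))
    cl <- suppressWarnings(classify_start_stop(s))
    if (cl$stop_class == "truncated") {
      expect_lte(nchar(cl$stop_literal), 2L)
    }
  }

  # 'A' is an accepted truncated stop (silent); 'GG' cannot polyadenylate
  expect_silent(out <- classify_start_stop("ATGAAAA"))
  expect_equal(out$stop_literal, "A")
  expect_warning(classify_start_stop("ATGAAAGG"), "polyadenylation")
  # internal complete stop warns but does not error
  expect_warning(classify_start_stop("ATGTAAAAATAA"), "internal stop")
  expect_error(classify_start_stop("ATG"), "too short")
})

test_that("strand census counts the 37 genes and excludes the control region", {
  expect_equal(strand_census(table2_fixture()),
               c(forward = 23L, reverse = 14L))
  empty <- table2_fixture()[0, ]
  expect_equal(strand_census(empty), c(forward = 0L, reverse = 0L))
  allf <- table2_fixture()
  allf$strand <- "forward"
  expect_equal(strand_census(allf), c(forward = 37L, reverse = 0L))
})

test_that("gene-order comparison detects the trnM translocation", {
  lep <- gene_order_preset("lepidopteran")
  anc <- gene_order_preset("ancestral_insect")
  d <- compare_gene_order(lep, anc)
  expect_equal(d$moved_genes, "trnM")
  expect_equal(d$breakpoint_count, 3L)
  expect_equal(tidy(d)$moved_genes, "trnM")

  same <- compare_gene_order(lep, lep)
  expect_equal(same$breakpoint_count, 0L)
  expect_equal(same$moved_genes, character(0))

  expect_error(compare_gene_order(lep, c(anc[-1], "novel")), "differ")
})

test_that("rotation closure: every rotation of an order has zero breakpoints", {
  lep <- gene_order_preset("lepidopteran")
  n <- length(lep)
  # brute force over all rotations
  for (k in c(1, 5, 17, n - 1)) {
    rot <- lep[((seq_len(n) - 1 + k) %% n) + 1]
    expect_equal(compare_gene_order(rot, lep)$breakpoint_count, 0L)
  }
  # reflection is NOT an equivalence
  expect_gt(compare_gene_order(rev(lep), lep)$breakpoint_count, 0L)
})

test_that("breakpoint counts are symmetric", {
  set.seed(9)
  lep <- gene_order_preset("lepidopteran")
  for (i in 1:10) {
    shuf <- sample(lep)
    expect_equal(compare_gene_order(shuf, lep)$breakpoint_count,
                 compare_gene_order(lep, shuf)$breakpoint_count)
  }
})

test_that("ledger conservation holds on simulated genomes", {
  for (seed in c(2, 13)) {
    sim <- simulate_mitogenome(simulation_config(seed))
    f <- sim$genome$features
    L <- sim$genome$length
    led <- adjacency_ledger(f, L = L)
    lens <- feature_length(f$start, f$end, L = L)
    expect_equal(sum(lens) + sum(led$gap), L)  # signed-gap form
    s <- glance(led)
    expect_equal(sum(lens) + s$total_spacer_bp - s$total_overlap_bp, L)
  }
})
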