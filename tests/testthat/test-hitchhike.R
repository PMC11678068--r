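test_that("positive-selection flagging is strict at omega = 1", {
  loci <- make_loci(c(0.5, 1.0, 1.0000001, 2))
  expect_equal(flag_positive(loci), c("L003", "L004"))
  # the published example locus with ka 0.0043, ks 0.0035 is flagged
  tab1 <- read_locus_table(system.file("extdata",
                                       "arabidopsis_example_loci.tsv",
                                       package = "selexpr"))
  expect_true("AT2G28240" %in% flag_positive(tab1))
  expect_error(assign_bands(loci, character(0)), "no anchor")
})

test_that("band assignment uses min ordinal distance within chromosomes", {
  omega <- rep(0.2, 40)
  omega[21] <- 2  # anchor at order_index 20
  loci <- make_loci(omega)
  ba <- assign_bands(loci, flag_positive(loci))
  expect_equal(sum(ba$band == "1-5"), 10)
  expect_equal(sum(ba$band == "6-10"), 10)
  expect_equal(sum(ba$band == "11-15"), 10)
  expect_equal(sum(ba$band == "anchor"), 1)
  expect_equal(ba$min_distance[ba$band == "anchor"], 0L)

  # two anchors: min-distance rule, each locus counted once
  omega2 <- rep(0.2, 30)
  omega2[c(11, 14)] <- 2  # order_index 10 and 13
  loci2 <- make_loci(omega2)
  ba2 <- assign_bands(loci2, flag_positive(loci2))
  l12 <- ba2[ba2$locus_id == "L012", ]   # order_index 11, between anchors
  expect_equal(l12$min_distance, 1L)
  expect_equal(l12$band, "1-5")

  # anchors never capture loci on another chromosome
  omega3 <- rep(0.2, 20)
  omega3[5] <- 2
  loci3 <- make_loci(omega3, chromosome = rep(c("chr1", "chr2"), each = 10))
  ba3 <- assign_bands(loci3, flag_positive(loci3))
  expect_true(all(ba3$band[11:20] == "background"))
  expect_true(all(is.na(ba3$min_distance[11:20])))

  expect_error(assign_bands(loci, flag_positive(loci),
                            bands = c("1-5", "4-8")), "overlap")
})

test_that("band assignment partitions non-anchors and survives order reversal", {
  set.seed(12)
  ds <- generate_genome(synth_config(n_loci = 2000, seed = 12))
  anchors <- flag_positive(ds$loci)
  ba <- assign_bands(ds$loci, anchors)
  expect_equal(nrow(ba), nrow(ds$loci))
  expect_true(all(ba$band %in% c("anchor", "background",
                                 "1-5", "6-10", "11-15")))
  expect_equal(sum(ba$band == "anchor"), length(anchors))

  rev_loci <- ds$loci
  rev_loci$order_index <- as.integer(stats::ave(
    rev_loci$order_index, rev_loci$chromosome,
    FUN = function(v) max(v) - v))
  ba_rev <- assign_bands(rev_loci, anchors)
  expect_equal(ba_rev$min_distance[match(ba$locus_id, ba_rev$locus_id)],
               ba$min_distance)
})

test_that("equal band and background values give zero difference and p = 1", {
  # 41-locus chromosome, anchor in the middle; both flanks carry the same
  # 5-value multiset in every distance band, so each band and the background
  # share mean and variance exactly
  v <- rep(c(0.19, 0.195, 0.2, 0.205, 0.21), 4)
  omega <- numeric(41)
  omega[21] <- 2
  for (d in 1:20) omega[c(21 - d, 21 + d)] <- v[d]
  loci <- make_loci(omega)
  cmp <- compare_bands(assign_bands(loci, flag_positive(loci)), loci)
  first <- cmp$tests[cmp$tests$group_a == "1-5" &
                       cmp$tests$group_b == "all_loci", ]
  expect_equal(first$mean_a, first$mean_b)
  expect_equal(first$t, 0)
  expect_equal(first$p, 1)
})

test_that("synthetic hitchhiking elevates omega near anchors", {
  ds <- generate_genome(synth_config(n_loci = 10000, seed = 4))
  ba <- assign_bands(ds$loci, flag_positive(ds$loci))
  cmp <- compare_bands(ba, ds$loci)
  first <- cmp$tests[cmp$tests$group_a == "1-5" &
                       cmp$tests$group_b == "all_loci", ]
  expect_gt(first$mean_a, first$mean_b)
  expect_lt(first$p, 0.01)
  # triangular decay: band means non-increasing with distance
  g <- cmp$groups
  m <- g$mean_omega[match(c("1-5", "6-10", "11-15"), as.character(g$band))]
  expect_true(all(diff(m) < 0))
})

test_that("without hitchhiking the band-1 test rejects at the nominal rate", {
  cfg <- lapply(1:100, function(s)
    synth_config(n_loci = 1500, hitch_amplitude = 0, seed = 1000 + s))
  p <- vapply(cfg, function(cf) {
    loci <- generate_genome(cf)$loci
    ba <- assign_bands(loci, flag_positive(loci))
    cmp <- suppressWarnings(compare_bands(ba, loci))
    cmp$tests$p[cmp$tests$group_a == "1-5" &
                  cmp$tests$group_b == "all_loci"]
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0)
  expect_lte(rate, 0.13)   # ~3 binomial sd above the nominal 0.05
})
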