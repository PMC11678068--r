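test_that("incidence tables reproduce the 2x2 Pearson value and its degenerate cases", {
  loci <- make_loci(c(rep(2, 5), rep(0.5, 45), rep(2, 10), rep(0.5, 40)))
  grp <- rep(c("a", "b"), each = 50)
  inc <- incidence_by_group(loci, grp)
  expect_equal(inc$n_positive, c(5L, 10L))
  expect_equal(attr(inc, "statistic"), 1.9608, tolerance = 1e-4)
  expect_equal(attr(inc, "df"), 1L)

  # identical incidence in all groups: statistic 0
  loci2 <- make_loci(rep(c(2, 0.5, 0.5, 0.5), 10))
  inc2 <- incidence_by_group(loci2, rep(c("a", "b"), each = 20))
  expect_equal(attr(inc2, "statistic"), 0, tolerance = 1e-12)

  # no positive locus anywhere: degenerate association
  inc3 <- incidence_by_group(make_loci(rep(0.5, 40)),
                             rep(c("a", "b"), each = 20))
  expect_equal(attr(inc3, "statistic"), 0)
  expect_equal(attr(inc3, "p"), 1)

  expect_error(incidence_by_group(loci, rep("a", 100)), "at least 2")
  # marginals conserve the global omega > 1 count
  expect_equal(sum(inc$n_positive), sum(loci$omega > 1))
})

test_that("group profiles assign compact letters consistent with the pairwise tests", {
  set.seed(21)
  v <- c(rnorm(30, 0), rnorm(30, 0.05), rnorm(30, 5))
  loci <- make_loci(rep(0.5, 90))
  loci$value <- v
  g <- rep(c("g1", "g2", "g3"), each = 30)
  gp <- group_profile(loci, g, value = "value")
  let <- gp$groups$letters
  names(let) <- gp$groups$group
  # g1 and g2 indistinguishable -> share a letter; g3 stands alone
  expect_true(any(strsplit(let[["g1"]], "")[[1]] %in%
                    strsplit(let[["g2"]], "")[[1]]))
  expect_false(any(strsplit(let[["g3"]], "")[[1]] %in%
                     c(strsplit(let[["g1"]], "")[[1]],
                       strsplit(let[["g2"]], "")[[1]])))
  expect_lt(gp$anova_p, 0.001)
  expect_equal(nrow(gp$pairwise), 3)

  # two identical groups share one letter and the ANOVA finds nothing
  loci2 <- make_loci(rep(0.5, 40))
  loci2$value <- rep(c(1, 2, 3, 4), 10)
  gp2 <- group_profile(loci2, rep(c("a", "b"), each = 20), value = "value")
  expect_equal(gp2$groups$letters, c("a", "a"))
})

test_that("chromosome summaries match hand-computed means and skip singletons", {
  loci <- make_loci(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                    chromosome = rep(c("chr1", "chr2"), each = 3),
                    ks = c(0.1, 0.2, 0.3, 0.1, 0.1, 0.1))
  cs <- chromosome_summary(loci)
  expect_equal(cs$table$mean_omega, c(0.2, 0.5))
  expect_equal(cs$table$mean_ks, c(0.2, 0.1))
  expect_equal(nrow(cs$tests), 1)

  expect_message(one <- chromosome_summary(make_loci(runif(5) + 0.1)),
                 "single chromosome")
  expect_equal(nrow(one$tests), 0)
})

test_that("a shifted chromosome is detected by the pairwise omega tests", {
  set.seed(22)
  omega <- c(rlnorm(500, -1.9, 0.8), rlnorm(500, -1.9, 0.8) + 0.5)
  loci <- make_loci(omega, chromosome = rep(c("chr1", "chr2"), each = 500))
  cs <- chromosome_summary(loci)
  expect_lt(cs$tests$p[1], 0.01)
})

test_that("synthetic couplings drive tertile incidence and breadth profiles", {
  ds <- generate_dataset(synth_config(n_loci = 6000, seed = 23))
  tert <- gea_tertiles(ds$table)
  inc <- incidence_by_group(tert, "gea_tertile")
  f <- inc$fraction[match(c("low", "medium", "high"), inc$group)]
  expect_gt(f[1], f[3])
  tert$breadth_class <- classify_breadth(tert$geb)
  gp <- group_profile(tert, "breadth_class", value = "ps")
  m <- gp$groups$mean[match(c("specific", "broad"), gp$groups$group)]
  expect_gt(m[1], m[2])
})
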