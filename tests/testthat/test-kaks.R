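test_that("codon site counts match single-mutant enumeration", {
  expect_equal(codon_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(codon_site_counts("ATG"), c(s = 0, n = 3))
  expect_equal(codon_site_counts("CTT"), c(s = 1, n = 2))
  expect_error(codon_site_counts("TAA"), "sense codon")
  expect_error(codon_site_counts("ANT"), "sense codon")
  # every sense codon agrees with the independent oracle
  for (codon in oracle_sense_codons) {
    expect_equal(codon_site_counts(codon), oracle_sites(codon),
                 tolerance = 1e-12)
  }
  total <- sum(vapply(oracle_sense_codons,
                      function(c) sum(codon_site_counts(c)), numeric(1)))
  expect_equal(total, 183)
})

test_that("pathway difference counts average minimal mutational pathways", {
  expect_equal(pathway_diffs("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(pathway_diffs("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(pathway_diffs("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
})

test_that("pathway counts are symmetric and sum to the codon Hamming distance", {
  set.seed(42)
  for (i in 1:200) {
    pair <- sample(oracle_sense_codons, 2)
    fwd <- pathway_diffs(pair[1], pair[2])
    rev <- pathway_diffs(pair[2], pair[1])
    expect_equal(fwd, rev, tolerance = 1e-12)
    expect_equal(fwd, oracle_diffs(pair[1], pair[2]), tolerance = 1e-12)
    hamming <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    # sd + nd can only fall below the Hamming distance if a pathway was
    # stop-excluded, which never changes the total step count either
    expect_equal(unname(fwd["sd"] + fwd["nd"]), hamming, tolerance = 1e-12)
  }
})

test_that("kaks_pair reproduces the hand-computed example", {
  r <- kaks_pair(strrep("TTT", 10), paste0("TTC", strrep("TTT", 9)))
  expect_equal(r$s_sites, 10 / 3)
  expect_equal(r$n_sites, 80 / 3)
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$ks, -0.75 * log(1 - (4 / 3) * (1 / (10 / 3))))
  expect_equal(r$ks, 0.38312, tolerance = 1e-4)
  expect_equal(r$ka, 0)
  expect_equal(r$omega, 0)
})

test_that("kaks_pair handles identity, gaps and degenerate input", {
  r <- kaks_pair("ATGAAA", "ATGAAA")
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$omega))
  # gap/N codons dropped from both sequences
  r2 <- kaks_pair("ATG---AAA", "ATGCCCAAA")
  expect_equal(r2$n_codons_used, 2)
  r3 <- kaks_pair("ATGNNNAAA", "ATGCCCAAA")
  expect_equal(r3$n_codons_used, 2)
  expect_error(kaks_pair("---", "AAA"), "no usable codons")
  expect_error(kaks_pair("ATGA", "ATGA"), "multiple of 3")
  expect_error(kaks_pair("ATG", "ATGAAA"), "equal length")
  # site counts always satisfy s + n = 3 * codons used
  expect_equal(r2$s_sites + r2$n_sites, 3 * r2$n_codons_used)
})

test_that("ortholog pair selection applies cut-offs and is one-to-one", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q3", "q4"),
    subject_id = c("s1", "s2", "s1", "s3", "s4"),
    identity_pct = c(95, 98, 97, 89.9, 95),
    evalue = c(1e-10, 1e-10, 1e-20, 1e-30, 1e-3),
    bitscore = c(200, 150, 180, 500, 300))
  sel <- select_ortholog_pairs(hits)
  # q1 keeps its bitscore-200 hit; q2 loses s1 to q1? no: q1->s1 (200) beats
  # q2->s1 (180); q3 fails identity; q4 fails evalue
  expect_equal(sel$subject_id[sel$query_id == "q1"], "s1")
  expect_false("q2" %in% sel$query_id)
  expect_false("q3" %in% sel$query_id)
  expect_false("q4" %in% sel$query_id)
  expect_equal(anyDuplicated(sel$subject_id), 0)

  # single clean hit is kept; empty input allowed
  one <- select_ortholog_pairs(hits[1, ])
  expect_equal(nrow(one), 1)
  none <- select_ortholog_pairs(hits[4, ])
  expect_equal(nrow(none), 0)
})

test_that("quality-control filters apply each rule and log removals", {
  rec <- tibble::tibble(ka = c(0.1, 1.2, 0.1, 0),
                        ks = c(0.2, 0.3, 6.0, 0.1))
  out <- apply_qc_filters(rec, ks_trim_alpha = 0)
  expect_equal(nrow(out), 1)
  expect_equal(out$ka, 0.1)
  expect_equal(out$ks, 0.2)
  log <- filter_log(out)
  expect_equal(log$n_removed[log$rule == "zero_or_na"], 1)
  expect_equal(log$n_removed[log$rule == "ka_above_max"], 1)
  expect_equal(log$n_removed[log$rule == "ks_above_max"], 1)

  # all example-table rows pass the ka/ks/zero rules
  loci <- read_locus_table(system.file("extdata",
                                       "arabidopsis_example_loci.tsv",
                                       package = "selexpr"))
  expect_equal(nrow(apply_qc_filters(loci, ks_trim_alpha = 0)), nrow(loci))

  # symmetric 5% trim of 1000 distinct Ks values keeps 950
  rec2 <- tibble::tibble(ka = rep(0.1, 1000), ks = seq_len(1000) / 100)
  out2 <- apply_qc_filters(rec2, ks_max = Inf, ks_trim_alpha = 0.05)
  expect_equal(nrow(out2), 950)

  expect_error(apply_qc_filters(tibble::tibble(ka = 2, ks = 9)),
               "all records removed")
})

test_that("FASTA pair input reproduces per-pair estimates", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a1", strrep("TTT", 10),
               ">a2", paste0("TTC", strrep("TTT", 9)),
               ">b1", "ATGAAA", ">b2", "ATGAAA"), path)
  res <- kaks_fasta(path)
  expect_equal(nrow(res), 2)
  expect_equal(res$ks[1], 0.38312, tolerance = 1e-4)
  expect_equal(res$ks[2], 0)
})
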