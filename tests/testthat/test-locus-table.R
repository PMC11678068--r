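example_loci_path <- system.file("extdata", "arabidopsis_example_loci.tsv",
                                 package = "selexpr")

test_that("the example locus table parses with published values intact", {
  loci <- read_locus_table(example_loci_path)
  expect_equal(nrow(loci), 5)
  row <- loci[loci$locus_id == "AT2G28240", ]
  expect_equal(row$ka, 0.0043)
  expect_equal(row$ks, 0.0035)
  expect_equal(row$omega, 1.2273)  # printed omega kept, not recomputed
  expect_equal(row$ps, 11L)
  # "n.a." microarray cells become NA but the record is retained
  expect_true(is.na(row$microarray))
  expect_false(is.na(loci$microarray[loci$locus_id == "AT2G13560"]))
})

test_that("write/read round trip is lossless, including missing markers", {
  loci <- read_locus_table(example_loci_path)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_locus_table(loci, path)
  again <- read_locus_table(path)
  expect_equal(as.data.frame(again), as.data.frame(loci))
})

test_that("malformed locus tables fail loudly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tka\tks", "A\t0.1\t0.2", "A\t0.3\t0.4"), path)
  expect_error(read_locus_table(path), "duplicate locus_id.*A")
  writeLines(c("locus_id\tka\tks", "A\t0.1\t0.2", "B\tbogus\t0.4"), path)
  expect_error(read_locus_table(path), "row 2")
  writeLines(c("locus_id\tka", "A\t0.1"), path)
  expect_error(read_locus_table(path), "missing required column")
  writeLines(c("locus_id\tka\tks\tps", "A\t0.1\t0.2\t14"), path)
  expect_error(read_locus_table(path), "ps")
})

test_that("omega is filled from ka/ks only where absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus_id,ka,ks,omega", "A,0.2,0.4,n.a.", "B,0.1,0,n.a."),
             path)
  loci <- read_locus_table(path)
  expect_equal(loci$omega[1], 0.5)
  expect_true(is.na(loci$omega[2]))  # ks = 0: ratio undefined
})

test_that("wide expression tables melt to one record per cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\ts1\ts2", "A\t1.0\t0", "B\t2\t3", "C\t\t4"), path)
  rec <- read_expression_table(path, assay = "rnaseq_rpm")
  expect_equal(nrow(rec), 6)
  expect_equal(rec$abundance[rec$locus_id == "A" & rec$sample_id == "s1"], 1.0)
  # absent cell -> abundance 0, present undetermined
  expect_equal(rec$abundance[rec$locus_id == "C" & rec$sample_id == "s1"], 0)
  expect_true(all(is.na(rec$present)))

  writeLines(c("locus_id\ts1", "A\t-2"), path)
  expect_error(read_expression_table(path, assay = "est"), "negative")
  expect_error(read_expression_table(path, assay = "nanostring"))
})

test_that("the analysis-table join keeps every locus and never invents one", {
  loci <- make_loci(rep(0.2, 5))
  expr <- tibble::tibble(
    locus_id = rep(c("L001", "L002", "L003"), each = 2),
    sample_id = rep(c("s1", "s2"), 3),
    assay = "rnaseq_rpm",
    abundance = c(5, 0, 1, 1, 0, 0),
    present = NA)
  tab <- join_analysis_table(loci, expr, n_samples = 2)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$geb[tab$locus_id %in% c("L004", "L005")], 0L)
  expect_equal(tab$geb[tab$locus_id == "L002"], 2L)
  expect_equal(tab$gea_rnaseq_rpm[tab$locus_id == "L001"], 5)

  dup <- dplyr::bind_rows(expr, expr[1, ])
  expect_error(join_analysis_table(loci, dup, n_samples = 2), "duplicate")

  alien <- dplyr::mutate(expr, locus_id = paste0("X", locus_id))
  expect_error(join_analysis_table(loci, alien, n_samples = 2),
               "no expression record")

  mixed <- dplyr::bind_rows(expr, alien[1, ])
  expect_message(join_analysis_table(loci, mixed, n_samples = 2), "dropped")
})

test_that("joining synthetic output yields one row per generated locus", {
  ds <- generate_dataset(synth_config(n_loci = 400, seed = 3))
  expect_equal(nrow(ds$table), 400)
  expect_true(all(ds$table$geb <= 11))
})
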