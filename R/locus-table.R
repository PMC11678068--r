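#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

locus_columns <- c("locus_id", "chromosome", "order_index", "ka", "ks",
                   "omega", "ps", "comparison")
comparison_levels <- c("intergenus", "interspecies", "intraspecies")
assay_levels <- c("est", "cdna", "rnaseq_rpm", "microarray")

# Accepted spellings of "missing" in incoming tables ("n.a." as printed in
# published per-locus tables, plus the usual ones).
na_markers <- c("n.a.", "NA", "na", "")

#' Read a per-locus Ka/Ks table
#'
#' Reads a delimited table with one row per gene locus carrying the
#' substitution-rate estimates (`ka`, `ks`, their ratio `omega`), the
#' phylostratum (`ps`, gene-age class 1--13), the chromosome and the ordinal
#' position of the locus along its chromosome. Missing values may be encoded
#' as `"n.a."`, `"NA"` or an empty cell. Columns beyond the required set are
#' carried through untouched, so tables that also hold per-locus expression
#' summaries can be read with the same function.
#'
#' When `ka` and `ks` are both finite and `ks > 0` but `omega` is absent (or
#' disagrees with `ka/ks` by more than `1e-9`), `omega` is (re)computed as
#' `ka/ks`.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param delim Field delimiter; `NULL` (default) guesses from the file
#'   extension (`.csv` means comma, anything else tab).
#' @param required Character vector of columns that must be present.
#' @return A tibble with one row per locus. `order_index` is an integer
#'   (0-based ordinal rank along the chromosome), `ps` an integer in 1--13 or
#'   `NA`, `comparison` one of `"intergenus"`, `"interspecies"`,
#'   `"intraspecies"` or `NA`.
#' @examples
#' path <- system.file("extdata", "arabidopsis_example_loci.tsv",
#'                     package = "selexpr")
#' read_locus_table(path)
#' @export
read_locus_table <- function(path, delim = NULL,
                             required = c("locus_id", "ka", "ks")) {
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, na = na_markers,
                           trim_ws = TRUE, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("locus table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$locus_id)) {
    dup <- unique(raw$locus_id[duplicated(raw$locus_id)])
    stop("duplicate locus_id in locus table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("ka", "ks", "omega"), names(raw))) {
    raw[[col]] <- parse_numeric_column(raw[[col]], col)
    if (any(raw[[col]] < 0, na.rm = TRUE)) {
      stop("negative values in column ", col, call. = FALSE)
    }
  }
  if ("order_index" %in% names(raw)) {
    raw$order_index <- as.integer(parse_numeric_column(raw$order_index, "order_index"))
    bad <- !is.na(raw$order_index) & raw$order_index < 0
    if (any(bad)) stop("order_index must be >= 0", call. = FALSE)
    if ("chromosome" %in% names(raw)) {
      dup <- duplicated(raw[, c("chromosome", "order_index")]) &
        !is.na(raw$order_index)
      if (any(dup)) {
        stop("order_index not unique within chromosome (row ",
             which(dup)[1], ")", call. = FALSE)
      }
    }
  }
  if ("ps" %in% names(raw)) {
    raw$ps <- as.integer(parse_numeric_column(raw$ps, "ps"))
    if (any(!is.na(raw$ps) & (raw$ps < 1 | raw$ps > 13))) {
      stop("ps (phylostratum) must lie in [1, 13]", call. = FALSE)
    }
  }
  if ("comparison" %in% names(raw)) {
    bad <- !is.na(raw$comparison) & !raw$comparison %in% comparison_levels
    if (any(bad)) {
      stop("unknown comparison label: ", raw$comparison[which(bad)[1]],
           call. = FALSE)
    }
  }
  if (all(c("ka", "ks") %in% names(raw))) {
    ratio <- ifelse(is.finite(raw$ka) & is.finite(raw$ks) & raw$ks > 0,
                    raw$ka / raw$ks, NA_real_)
    if (!"omega" %in% names(raw)) {
      raw$omega <- ratio
    } else {
      # stored omega (e.g. printed to 4 decimals) is kept; only absent values
      # are filled from ka/ks
      fill <- is.na(raw$omega) & !is.na(ratio)
      raw$omega[fill] <- ratio[fill]
    }
  }
  tibble::as_tibble(raw)
}

parse_numeric_column <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  x[x %in% na_markers] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("unparseable numeric value in column ", name, ", row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out
}

#' Write a per-locus table
#'
#' Inverse of [read_locus_table()]: writes a tibble to TSV/CSV, encoding
#' missing values as `"n.a."` so a round trip through
#' `write_locus_table()` / `read_locus_table()` is lossless.
#'
#' @param loci Tibble of loci.
#' @param path Output path (`.csv` means comma-delimited, else tab).
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(loci, path, delim = delim, na = "n.a.")
  invisible(path)
}

#' Read an expression table into long (locus, sample) records
#'
#' Reads expression measurements for one assay into the long layout used
#' throughout the package: one row per `(locus_id, sample_id)` with a
#' non-negative `abundance` (EST/cDNA counts, RNA-Seq reads-per-million or a
#' microarray signal) and a logical `present` call, `NA` until
#' [present_calls()] fills it (or, for microarrays, until supplied
#' externally).
#'
#' @param path Path to a delimited file with a header.
#' @param assay One of `"est"`, `"cdna"`, `"rnaseq_rpm"`, `"microarray"`.
#' @param layout `"wide"` (default; `locus_id` column plus one column per
#'   sample) or `"long"` (columns `locus_id`, `sample_id`, `abundance` and
#'   optionally `present`).
#' @param delim Field delimiter; `NULL` guesses from the extension.
#' @return A tibble with columns `locus_id`, `sample_id`, `assay`,
#'   `abundance`, `present`. Empty cells in a wide layout become abundance 0
#'   with `present` missing.
#' @export
read_expression_table <- function(path, assay,
                                  layout = c("wide", "long"), delim = NULL) {
  assay <- match.arg(assay, assay_levels)
  layout <- match.arg(layout)
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, na = na_markers,
                           trim_ws = TRUE, show_col_types = FALSE)
  if (layout == "wide") {
    stopifnot("locus_id" %in% names(raw))
    out <- tidyr::pivot_longer(raw, -"locus_id", names_to = "sample_id",
                               values_to = "abundance")
    out$abundance <- parse_numeric_column(out$abundance, "abundance")
    out$abundance[is.na(out$abundance)] <- 0
    out$present <- NA
  } else {
    stopifnot(all(c("locus_id", "sample_id", "abundance") %in% names(raw)))
    out <- raw
    out$abundance <- parse_numeric_column(out$abundance, "abundance")
    if (!"present" %in% names(out)) out$present <- NA
    out$present <- as.logical(out$present)
  }
  if (any(out$abundance < 0, na.rm = TRUE)) {
    stop("negative expression abundance", call. = FALSE)
  }
  out$assay <- assay
  out <- out[, c("locus_id", "sample_id", "assay", "abundance", "present")]
  if (anyDuplicated(out[, c("locus_id", "sample_id", "assay")])) {
    stop("duplicate (locus_id, sample_id, assay) record", call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Build the per-locus analysis table
#'
#' Joins a locus table with long expression records into the one-row-per-locus
#' table the downstream analyses consume: per-assay total abundance
#' (`gea_<assay>`) and, for the breadth assay, the expression breadth `geb`
#' (number of samples with a present call). Loci without expression records
#' get abundance 0 and breadth 0. Expression records whose locus is not in
#' `loci` are dropped with a message.
#'
#' @param loci Locus tibble (see [read_locus_table()]).
#' @param expression Long expression records (see [read_expression_table()]);
#'   present calls are filled via [present_calls()] before counting.
#' @param n_samples Size of the sample universe for breadth (default 11).
#' @param breadth_assay Assay whose present calls define `geb`.
#' @param rpm_threshold Present-call threshold for RNA-Seq, in RPM.
#' @return A tibble with one row per locus in `loci`.
#' @export
join_analysis_table <- function(loci, expression, n_samples = 11,
                                breadth_assay = "rnaseq_rpm",
                                rpm_threshold = 1.0) {
  stopifnot(is.data.frame(loci), is.data.frame(expression))
  if (anyDuplicated(expression[, c("locus_id", "sample_id", "assay")])) {
    stop("duplicate (locus_id, sample_id, assay) expression record",
         call. = FALSE)
  }
  unmatched <- setdiff(unique(expression$locus_id), loci$locus_id)
  if (length(unmatched) == length(unique(expression$locus_id))) {
    stop("no expression record matches any locus", call. = FALSE)
  }
  if (length(unmatched) > 0) {
    message(length(unmatched),
            " expression locus id(s) not in the locus table; dropped")
    expression <- expression[!expression$locus_id %in% unmatched, ]
  }
  expression <- present_calls(expression, rpm_threshold = rpm_threshold)

  gea <- expression %>%
    dplyr::group_by(.data$locus_id, .data$assay) %>%
    dplyr::summarise(gea = sum(.data$abundance), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "gea",
                       names_prefix = "gea_", values_fill = 0)

  geb <- geb_counts(expression[expression$assay == breadth_assay, ],
                    n_samples = n_samples)

  out <- loci %>%
    dplyr::left_join(gea, by = "locus_id") %>%
    dplyr::left_join(geb, by = "locus_id")
  for (col in grep("^gea_", names(out), value = TRUE)) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  if (!"geb" %in% names(out)) out$geb <- 0L
  out$geb[is.na(out$geb)] <- 0L
  stopifnot(nrow(out) == nrow(loci))
  tibble::as_tibble(out)
}
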