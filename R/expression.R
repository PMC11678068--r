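#' Fill present/absent calls in expression records
#'
#' Applies the assay-specific presence rule to long expression records:
#' EST/cDNA loci are present when at least one sequence was recorded
#' (abundance >= 1); RNA-Seq loci are present when the abundance reaches
#' `rpm_threshold` reads per million (inclusive); microarray calls come from
#' an external present/absent algorithm, so records lacking one keep
#' `present = NA` and are excluded from breadth counting.
#'
#' @param records Long expression records (see [read_expression_table()]).
#' @param rpm_threshold RNA-Seq presence threshold in RPM (default 1.0).
#' @return The records with the `present` column filled where the rule
#'   applies.
#' @export
present_calls <- function(records, rpm_threshold = 1.0) {
  stopifnot(all(c("assay", "abundance", "present") %in% names(records)))
  unknown <- setdiff(unique(records$assay), assay_levels)
  if (length(unknown) > 0) {
    stop("unknown assay tag: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  records %>%
    dplyr::mutate(present = dplyr::case_when(
      .data$assay %in% c("est", "cdna") ~ .data$abundance >= 1,
      .data$assay == "rnaseq_rpm" ~ .data$abundance >= rpm_threshold,
      TRUE ~ .data$present))
}

#' Expression-abundance windows of a fixed number of loci
#'
#' Sorts the loci of an analysis table by expression abundance for one assay
#' (zero-abundance loci excluded, ties broken by `locus_id`) and cuts the
#' sorted loci into consecutive non-overlapping windows of exactly `window`
#' loci (default 100; a trailing partial window is dropped). Each window is
#' summarised by the mean of `log10(abundance)` and the means of `ks`,
#' `omega` and `ps`, the level of resolution at which abundance-vs-divergence
#' trends are read.
#'
#' @param table Analysis table (see [join_analysis_table()]) with a
#'   `gea_<assay>` column.
#' @param assay Assay whose abundance defines the windows.
#' @param window Window size in loci (default 100).
#' @return A tibble of class `window_points`: one row per window with
#'   `window_rank`, `mean_log10_gea`, `mean_ks`, `mean_omega`, `mean_ps` and
#'   `n_loci`.
#' @export
gea_windows <- function(table, assay = "rnaseq_rpm", window = 100) {
  col <- paste0("gea_", assay)
  stopifnot(col %in% names(table))
  pos <- table[table[[col]] > 0 & !is.na(table[[col]]), ]
  if (nrow(pos) < window) {
    stop("fewer than ", window, " loci with positive abundance for assay '",
         assay, "'", call. = FALSE)
  }
  pos <- pos[order(pos[[col]], pos$locus_id), ]
  n_windows <- nrow(pos) %/% window
  pos <- pos[seq_len(n_windows * window), ]
  pos$window_rank <- rep(seq_len(n_windows) - 1L, each = window)
  out <- pos %>%
    dplyr::group_by(.data$window_rank) %>%
    dplyr::summarise(
      mean_log10_gea = mean(log10(.data[[col]])),
      mean_ks = mean(.data$ks, na.rm = TRUE),
      mean_omega = mean(.data$omega, na.rm = TRUE),
      mean_ps = if ("ps" %in% names(pos)) mean(.data$ps, na.rm = TRUE) else NA_real_,
      n_loci = dplyr::n(),
      .groups = "drop")
  class(out) <- c("window_points", class(out))
  out
}

#' Expression breadth (number of samples with a present call)
#'
#' @param records Long expression records for a single assay with `present`
#'   filled (see [present_calls()]); records with `present = NA` are ignored.
#' @param n_samples Size of the sample universe (default 11). Supplying fewer
#'   samples than appear in the data is an error.
#' @return Tibble with columns `locus_id` and `geb` (integer in
#'   `[0, n_samples]`).
#' @export
geb_counts <- function(records, n_samples = 11) {
  stopifnot(all(c("locus_id", "sample_id", "present") %in% names(records)))
  n_seen <- length(unique(records$sample_id))
  if (n_seen > n_samples) {
    stop("data contain ", n_seen, " samples but n_samples = ", n_samples,
         call. = FALSE)
  }
  records %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::summarise(geb = sum(.data$present, na.rm = TRUE), .groups = "drop") %>%
    dplyr::mutate(geb = as.integer(.data$geb))
}

#' Classify expression breadth
#'
#' Maps a breadth count to the three classes used for the
#' specific-versus-broad contrasts: `not_expressed` (0 samples), `specific`
#' (exactly 1 sample) and `broad` (2 or more samples).
#'
#' @param geb Integer vector of breadth counts.
#' @return Factor with levels `not_expressed`, `specific`, `broad`.
#' @export
classify_breadth <- function(geb) {
  stopifnot(all(geb >= 0))
  cut(geb, breaks = c(-Inf, 0, 1, Inf),
      labels = c("not_expressed", "specific", "broad"))
}

#' Rank-based abundance tertiles
#'
#' Splits loci into `low`, `medium` and `high` abundance groups of equal size
#' (plus/minus one; the remainder goes to the lower groups). The split is by
#' abundance rank with ties broken by `locus_id`, so zero-abundance loci land
#' in `low` and the grouping is invariant to input row order.
#'
#' @param table Analysis table with a `gea_<assay>` column.
#' @param assay Assay whose abundance defines the tertiles.
#' @return `table` with an added factor column `gea_tertile`
#'   (levels `low < medium < high`).
#' @export
gea_tertiles <- function(table, assay = "rnaseq_rpm") {
  col <- paste0("gea_", assay)
  stopifnot(col %in% names(table))
  n <- nrow(table)
  if (n < 3) stop("need at least 3 loci for tertiles", call. = FALSE)
  ord <- order(table[[col]], table$locus_id)
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(c("low", "medium", "high"), times = sizes)
  table$gea_tertile <- factor(NA, levels = c("low", "medium", "high"))
  table$gea_tertile[ord] <- labels
  table
}
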