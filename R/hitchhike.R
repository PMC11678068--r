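# Proximity analysis around positively selected loci: are the omega values of
# loci close (in gene-order units) to omega > 1 loci elevated relative to the
# rest of the genome, as expected under genetic hitchhiking?

#' Flag positively selected loci
#'
#' A locus is flagged as a positive-selection anchor when its `omega` is
#' strictly greater than 1.
#'
#' @param loci Data frame with `locus_id` and `omega`.
#' @return Character vector of anchor locus ids (possibly empty).
#' @export
flag_positive <- function(loci) {
  stopifnot(all(c("locus_id", "omega") %in% names(loci)))
  loci$locus_id[!is.na(loci$omega) & loci$omega > 1]
}

#' Parse band labels such as "1-5" into inclusive distance ranges
#'
#' @param bands Character vector like `c("1-5", "6-10", "11-15")`.
#' @return Tibble with columns `label`, `lo`, `hi`.
#' @export
parse_bands <- function(bands) {
  m <- regmatches(bands, regexec("^(\\d+)-(\\d+)$", bands))
  if (any(lengths(m) != 3)) {
    stop("band labels must look like 'lo-hi', e.g. '1-5'", call. = FALSE)
  }
  out <- tibble::tibble(label = bands,
                        lo = as.integer(vapply(m, `[`, character(1), 2)),
                        hi = as.integer(vapply(m, `[`, character(1), 3)))
  if (any(out$lo < 1 | out$lo > out$hi)) {
    stop("bands need 1 <= lo <= hi", call. = FALSE)
  }
  ov <- out[order(out$lo), ]
  if (nrow(ov) > 1 && any(ov$lo[-1] <= ov$hi[-nrow(ov)])) {
    stop("band definitions overlap", call. = FALSE)
  }
  out
}

#' Assign loci to distance bands around positive-selection anchors
#'
#' For every locus, computes the minimal ordinal distance (in loci, along the
#' gene order of its own chromosome; distances never cross chromosome
#' boundaries) to any anchor on that chromosome, and assigns the locus to the
#' band containing that distance. Anchors themselves get distance 0 and band
#' `"anchor"`; loci outside every band get `"background"`; loci on
#' chromosomes without anchors get distance `NA` and `"background"`. Each
#' locus is counted exactly once (minimum-distance rule), so the bands
#' partition the non-anchor loci.
#'
#' @param loci Data frame with `locus_id`, `chromosome`, `order_index`.
#' @param anchors Character vector of anchor locus ids (see
#'   [flag_positive()]); must be a subset of `loci$locus_id`.
#' @param bands Band labels (default `c("1-5", "6-10", "11-15")`).
#' @return Tibble with columns `locus_id`, `min_distance`, `band`.
#' @export
assign_bands <- function(loci, anchors,
                         bands = c("1-5", "6-10", "11-15")) {
  stopifnot(all(c("locus_id", "chromosome", "order_index") %in% names(loci)))
  if (length(anchors) == 0) {
    stop("no anchor loci (no omega > 1 locus found)", call. = FALSE)
  }
  if (!all(anchors %in% loci$locus_id)) {
    stop("anchors must be a subset of loci", call. = FALSE)
  }
  band_def <- parse_bands(bands)
  is_anchor <- loci$locus_id %in% anchors
  out <- purrr::map_dfr(split(seq_len(nrow(loci)), loci$chromosome),
                        function(idx) {
    pos <- loci$order_index[idx]
    anc <- pos[is_anchor[idx]]
    if (length(anc) == 0) {
      d <- rep(NA_integer_, length(idx))
    } else {
      d <- vapply(pos, function(p) min(abs(p - anc)), numeric(1))
      d <- as.integer(d)
    }
    tibble::tibble(locus_id = loci$locus_id[idx], min_distance = d)
  })
  band_of <- function(d, anchor) {
    if (anchor) return("anchor")
    if (is.na(d)) return("background")
    hit <- which(band_def$lo <= d & d <= band_def$hi)
    if (length(hit) == 1) band_def$label[hit] else "background"
  }
  out <- out[match(loci$locus_id, out$locus_id), ]
  out$band <- mapply(band_of, out$min_distance, is_anchor)
  tibble::as_tibble(out)
}

#' Compare omega between distance bands and the genomic background
#'
#' Summarises `omega` per band and tests each band against the background of
#' all non-anchor loci, and against the adjacent (next-farther) band, with
#' Welch two-sample t-tests. Anchors are excluded from every group (their
#' omega exceeds 1 by construction).
#'
#' @param assignments Output of [assign_bands()].
#' @param loci Data frame with `locus_id` and `omega`.
#' @return A list of class `band_comparison` with tibbles `groups` (band,
#'   `n`, `mean_omega`, `sd_omega`) and `tests` (comparison, group means,
#'   `t`, `df`, `p`). Undersized groups (< 2 members) are skipped with a
#'   warning.
#' @export
compare_bands <- function(assignments, loci) {
  stopifnot(all(c("locus_id", "band") %in% names(assignments)))
  dat <- dplyr::inner_join(assignments,
                           loci[, c("locus_id", "omega")], by = "locus_id")
  dat <- dat[!is.na(dat$omega), ]
  non_anchor <- dat[dat$band != "anchor", ]
  band_labels <- setdiff(unique(dat$band), c("anchor", "background"))
  band_labels <- band_labels[order(as.integer(sub("-.*", "", band_labels)))]

  groups <- non_anchor %>%
    dplyr::mutate(band = factor(.data$band,
                                levels = c(band_labels, "background"))) %>%
    dplyr::group_by(.data$band) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean_omega = mean(.data$omega),
                     sd_omega = stats::sd(.data$omega), .groups = "drop")
  all_row <- tibble::tibble(band = factor("all_loci"),
                            n = nrow(non_anchor),
                            mean_omega = mean(non_anchor$omega),
                            sd_omega = stats::sd(non_anchor$omega))
  groups <- dplyr::bind_rows(groups, all_row)

  welch <- function(a, b, label_a, label_b) {
    if (length(a) < 2 || length(b) < 2) {
      warning("comparison ", label_a, " vs ", label_b,
              " skipped (group with fewer than 2 members)")
      return(NULL)
    }
    tt <- stats::t.test(a, b)
    tibble::tibble(group_a = label_a, group_b = label_b,
                   mean_a = mean(a), mean_b = mean(b),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  }
  tests <- list()
  bg <- non_anchor$omega
  for (b in band_labels) {
    vals <- non_anchor$omega[non_anchor$band == b]
    tests[[paste0(b, "_vs_all")]] <- welch(vals, bg, b, "all_loci")
  }
  if (length(band_labels) > 1) {
    for (i in seq_len(length(band_labels) - 1)) {
      a <- non_anchor$omega[non_anchor$band == band_labels[i]]
      b <- non_anchor$omega[non_anchor$band == band_labels[i + 1]]
      tests[[paste0(band_labels[i], "_vs_", band_labels[i + 1])]] <-
        welch(a, b, band_labels[i], band_labels[i + 1])
    }
  }
  structure(list(groups = groups, tests = dplyr::bind_rows(tests)),
            class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  cat("Omega by distance band around omega > 1 loci\n")
  print(x$groups)
  cat("\nWelch t-tests\n")
  print(x$tests)
  invisible(x)
}
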