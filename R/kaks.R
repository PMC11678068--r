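# NG86-style codon counting with Jukes-Cantor multiple-hit correction.
# All site/pathway bookkeeping lives here; the genetic code is the standard
# nuclear code.

.codon_env <- new.env(parent = emptyenv())

standard_genetic_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

sense_codons <- function() {
  names(standard_genetic_code)[standard_genetic_code != "*"]
}

translate_codon <- function(codon) {
  aa <- standard_genetic_code[codon]
  unname(aa)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three codon positions, each of the three possible
#' single-nucleotide mutants is classified as synonymous (same amino acid) or
#' nonsynonymous; mutations to a stop codon count as nonsynonymous. The
#' synonymous site count `s` is the number of synonymous mutants divided by 3
#' (so `s + n = 3` for every sense codon).
#'
#' @param codon A single sense codon (3-letter string over A, C, G, T).
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' codon_site_counts("TTT")  # c(s = 1/3, n = 8/3)
#' codon_site_counts("ATG")  # Met has no synonymous mutant
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% sense_codons()) {
    stop("'", codon, "' is not a sense codon of the standard genetic code",
         call. = FALSE)
  }
  tab <- codon_site_table()
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

codon_site_table <- function() {
  if (!is.null(.codon_env$site_table)) return(.codon_env$site_table)
  bases <- c("A", "C", "G", "T")
  codons <- sense_codons()
  tab <- matrix(0, nrow = length(codons), ncol = 2,
                dimnames = list(codons, c("s", "n")))
  for (codon in codons) {
    aa <- translate_codon(codon)
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- b
        maa <- translate_codon(mut)
        if (maa != "*" && maa == aa) syn <- syn + 1
      }
    }
    tab[codon, "s"] <- syn / 3
    tab[codon, "n"] <- 3 - syn / 3
  }
  .codon_env$site_table <- tab
  tab
}

#' Synonymous/nonsynonymous step counts between two codons
#'
#' Averages the numbers of synonymous and nonsynonymous single-nucleotide
#' steps over all minimal mutational pathways between two sense codons,
#' weighting pathways equally. Pathways passing through a stop codon are
#' excluded and the weights renormalised; in the (rare) case that every
#' pathway passes through a stop, all pathways are weighted equally instead.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd = ..., nd = ...)`; `sd + nd` equals the
#'   number of differing positions whenever no pathway is stop-excluded.
#' @examples
#' pathway_diffs("TTT", "TTC")  # one synonymous step
#' pathway_diffs("TTT", "GTA")  # two pathways averaged: c(sd = 0.5, nd = 1.5)
#' @export
pathway_diffs <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  ok <- sense_codons()
  if (!codon_a %in% ok || !codon_b %in% ok) {
    stop("both codons must be sense codons", call. = FALSE)
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(diff_pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  orderings <- position_orderings(diff_pos)
  steps <- lapply(orderings, function(ord) pathway_steps(codon_a, codon_b, ord))
  valid <- !vapply(steps, is.null, logical(1))
  if (any(valid)) {
    steps <- steps[valid]
  } else {
    # all pathways pass through stops: equal weighting over all of them,
    # counting the stop-crossing steps as nonsynonymous
    steps <- lapply(orderings, function(ord) {
      pathway_steps(codon_a, codon_b, ord, allow_stops = TRUE)
    })
  }
  m <- do.call(rbind, steps)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

position_orderings <- function(pos) {
  if (length(pos) == 1) return(list(pos))
  out <- list()
  for (i in seq_along(pos)) {
    rest <- position_orderings(pos[-i])
    out <- c(out, lapply(rest, function(r) c(pos[i], r)))
  }
  out
}

# One pathway: mutate codon_a towards codon_b in the given position order.
# Returns c(syn, nonsyn) or NULL if an intermediate codon is a stop.
pathway_steps <- function(codon_a, codon_b, ord, allow_stops = FALSE) {
  cur <- codon_a
  syn <- 0; nonsyn <- 0
  for (pos in ord) {
    nxt <- cur
    substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
    aa_cur <- translate_codon(cur)
    aa_nxt <- translate_codon(nxt)
    if (aa_nxt == "*" && !allow_stops && nxt != codon_b) return(NULL)
    if (aa_nxt != "*" && aa_cur != "*" && aa_cur == aa_nxt) {
      syn <- syn + 1
    } else {
      nonsyn <- nonsyn + 1
    }
    cur <- nxt
  }
  c(syn, nonsyn)
}

#' NG86 Ka/Ks for one aligned codon sequence pair
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and pathway-averaged differences, converts them to proportions
#' `pS = Sd/S`, `pN = Nd/N` and applies the Jukes-Cantor multiple-hit
#' correction `d = -(3/4) log(1 - (4/3) p)`. Codon columns containing a gap
#' (`-`) or an ambiguous base (`N`) in either sequence, or a stop codon, are
#' dropped from both sequences before counting.
#'
#' `ks` (or `ka`) is undefined (`NA`) when the corresponding site count is 0
#' or when `p >= 3/4` (the correction diverges); `omega = ka/ks` is defined
#' only when both rates are defined and `ks > 0`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length, a multiple
#'   of 3, over A, C, G, T, `-`, N.
#' @return A one-row tibble with columns `s_sites`, `n_sites`, `sd`, `nd`,
#'   `ka`, `ks`, `omega`, `n_codons_used`.
#' @examples
#' kaks_pair(strrep("TTT", 10), paste0("TTC", strrep("TTT", 9)))
#' @export
kaks_pair <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("sequence length must be a multiple of 3", call. = FALSE)
  }
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  keep <- !grepl("[-N]", ca) & !grepl("[-N]", cb) &
    ca %in% sense_codons() & cb %in% sense_codons()
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) stop("no usable codons in the alignment", call. = FALSE)

  tab <- codon_site_table()
  s_sites <- (sum(tab[ca, "s"]) + sum(tab[cb, "s"])) / 2
  n_sites <- (sum(tab[ca, "n"]) + sum(tab[cb, "n"])) / 2
  differs <- ca != cb
  sd_tot <- 0; nd_tot <- 0
  if (any(differs)) {
    key <- paste(ca[differs], cb[differs])
    per <- vapply(unique(key), function(k) {
      parts <- strsplit(k, " ")[[1]]
      pathway_diffs(parts[1], parts[2])
    }, numeric(2))
    counts <- table(key)[unique(key)]
    sd_tot <- sum(per["sd", ] * as.numeric(counts))
    nd_tot <- sum(per["nd", ] * as.numeric(counts))
  }
  ks <- jc_correct(sd_tot, s_sites)
  ka <- jc_correct(nd_tot, n_sites)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  tibble::tibble(s_sites = s_sites, n_sites = n_sites,
                 sd = sd_tot, nd = nd_tot,
                 ka = ka, ks = ks, omega = omega,
                 n_codons_used = length(ca))
}

codon_split <- function(seq) {
  n <- nchar(seq) / 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

jc_correct <- function(d, sites) {
  if (sites <= 0) return(NA_real_)
  p <- d / sites
  if (p >= 3 / 4) return(NA_real_)
  -0.75 * log(1 - (4 / 3) * p)
}

#' NG86 Ka/Ks for a FASTA file of aligned pairs
#'
#' Reads an interleaved FASTA of aligned coding sequences (2k records) and
#' runs [kaks_pair()] on each pair. Pairs are matched consecutively
#' (records 1+2, 3+4, ...) or by shared identifier prefix.
#'
#' @param path FASTA file of aligned CDS pairs.
#' @param pairing `"consecutive"` (default) or `"prefix"` (identifier up to
#'   the first `|`, `_` or space shared by exactly two records).
#' @return A tibble with one row per pair, columns `id_a`, `id_b` plus the
#'   [kaks_pair()] columns.
#' @export
kaks_fasta <- function(path, pairing = c("consecutive", "prefix")) {
  pairing <- match.arg(pairing)
  seqs <- read_fasta(path)
  if (length(seqs) %% 2 != 0) {
    stop("FASTA must contain an even number of records (aligned pairs)",
         call. = FALSE)
  }
  if (pairing == "consecutive") {
    idx_a <- seq(1, length(seqs), by = 2)
    idx_b <- idx_a + 1
  } else {
    prefix <- sub("[|_ ].*$", "", names(seqs))
    groups <- split(seq_along(seqs), prefix)
    if (any(lengths(groups) != 2)) {
      stop("prefix pairing requires exactly two records per prefix",
           call. = FALSE)
    }
    idx_a <- vapply(groups, `[`, integer(1), 1)
    idx_b <- vapply(groups, `[`, integer(1), 2)
  }
  purrr::map2_dfr(idx_a, idx_b, function(i, j) {
    dplyr::bind_cols(tibble::tibble(id_a = names(seqs)[i],
                                    id_b = names(seqs)[j]),
                     kaks_pair(seqs[[i]], seqs[[j]]))
  })
}

# Minimal FASTA reader (plain text, possibly multi-line records).
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  names(seqs) <- ids
  as.list(seqs)
}

#' Select one-to-one best ortholog pairs from a hit table
#'
#' Applies the similarity-search cut-offs (E-value at most `evalue_max`,
#' percent identity at least `identity_min`), then keeps for every query its
#' best surviving hit and for every subject its best query, so the returned
#' mapping is one-to-one ("all but one member of duplicated genes removed").
#' Best = maximal bitscore, ties broken by smaller E-value, then by
#' lexicographically smallest subject (or query) identifier.
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `identity_pct`, `evalue`, `bitscore`.
#' @param evalue_max E-value cut-off (default `1e-5`).
#' @param identity_min Percent-identity cut-off (default 90).
#' @return Tibble with columns `query_id`, `subject_id` (one row per retained
#'   pair); may have zero rows.
#' @export
select_ortholog_pairs <- function(hits, evalue_max = 1e-5, identity_min = 90) {
  stopifnot(all(c("query_id", "subject_id", "identity_pct", "evalue",
                  "bitscore") %in% names(hits)))
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100)) {
    stop("identity_pct must lie in [0, 100]", call. = FALSE)
  }
  kept <- hits %>%
    dplyr::filter(.data$evalue <= evalue_max,
                  .data$identity_pct >= identity_min)
  if (nrow(kept) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character()))
  }
  best_per_query <- kept %>%
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore),
                   .data$evalue, .data$subject_id) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  best_per_query %>%
    dplyr::arrange(.data$subject_id, dplyr::desc(.data$bitscore),
                   .data$evalue, .data$query_id) %>%
    dplyr::distinct(.data$subject_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$query_id) %>%
    dplyr::select("query_id", "subject_id")
}

#' Quality-control filters for a Ka/Ks table
#'
#' Removes loci with `ka > ka_max`, `ks > ks_max`, and (optionally) loci with
#' `ka` or `ks` equal to 0 or undefined, then applies a symmetric two-tailed
#' trim of the Ks distribution at level `ks_trim_alpha` (rows below the
#' `alpha/2` or above the `1 - alpha/2` empirical Ks quantile are dropped).
#' The trim can be disabled with `ks_trim_alpha = 0`.
#'
#' @param records Data frame with `ka` and `ks` columns.
#' @param ka_max,ks_max Upper bounds on `ka` and `ks` (defaults 1 and 5).
#' @param drop_zero_or_na Drop rows with `ka`/`ks` zero or missing (default
#'   `TRUE`).
#' @param ks_trim_alpha Two-tailed Ks trim level (default 0.05).
#' @return The filtered tibble, with an attribute `"filter_log"`: a tibble of
#'   per-rule removal counts (also retrievable with [filter_log()]).
#' @export
apply_qc_filters <- function(records, ka_max = 1, ks_max = 5,
                             drop_zero_or_na = TRUE, ks_trim_alpha = 0.05) {
  stopifnot(all(c("ka", "ks") %in% names(records)))
  n0 <- nrow(records)
  log <- list()
  if (drop_zero_or_na) {
    bad <- is.na(records$ka) | is.na(records$ks) |
      records$ka == 0 | records$ks == 0
    log$zero_or_na <- sum(bad)
    records <- records[!bad, ]
  }
  bad <- !is.na(records$ka) & records$ka > ka_max
  log$ka_above_max <- sum(bad)
  records <- records[!bad, ]
  bad <- !is.na(records$ks) & records$ks > ks_max
  log$ks_above_max <- sum(bad)
  records <- records[!bad, ]
  if (ks_trim_alpha > 0 && nrow(records) > 0) {
    q <- stats::quantile(records$ks,
                         c(ks_trim_alpha / 2, 1 - ks_trim_alpha / 2),
                         na.rm = TRUE, names = FALSE, type = 7)
    bad <- records$ks < q[1] | records$ks > q[2]
    log$ks_trim <- sum(bad)
    records <- records[!bad, ]
  } else {
    log$ks_trim <- 0L
  }
  if (nrow(records) == 0) {
    stop("all records removed by quality-control filters", call. = FALSE)
  }
  out <- tibble::as_tibble(records)
  attr(out, "filter_log") <- tibble::tibble(
    rule = names(log),
    n_removed = unlist(log, use.names = FALSE),
    n_input = n0)
  out
}

#' Retrieve the filter log attached by [apply_qc_filters()]
#' @param records A tibble returned by [apply_qc_filters()].
#' @return A tibble of per-rule removal counts.
#' @export
filter_log <- function(records) attr(records, "filter_log")
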