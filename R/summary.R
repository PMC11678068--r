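# Group-level summaries: incidence of positive selection, per-group profiles
# with compact-letter displays, and per-chromosome overviews.

#' Incidence of positive selection by group
#'
#' Counts, per group, the loci under putative positive selection
#' (`omega > 1`) and tests the group-by-status association with a Pearson
#' chi-square on the G x 2 contingency table (no continuity correction).
#'
#' @param loci Data frame with an `omega` column.
#' @param group Name of the grouping column in `loci` (e.g. `"gea_tertile"`
#'   after [gea_tertiles()], or a breadth class column), or a vector of group
#'   labels of length `nrow(loci)`.
#' @return A tibble of class `incidence_table` with columns `group`,
#'   `n_loci`, `n_positive`, `fraction`, and attributes `statistic`, `df`,
#'   `p` for the association test. Empty groups are dropped with a warning.
#' @export
incidence_by_group <- function(loci, group) {
  stopifnot("omega" %in% names(loci))
  g <- if (length(group) == 1 && is.character(group)) {
    stopifnot(group %in% names(loci))
    loci[[group]]
  } else {
    stopifnot(length(group) == nrow(loci))
    group
  }
  keep <- !is.na(g) & !is.na(loci$omega)
  g <- factor(g[keep])
  pos <- loci$omega[keep] > 1
  empty <- levels(g)[table(g) == 0]
  if (length(empty) > 0) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  if (nlevels(g) < 2) stop("need at least 2 nonempty groups", call. = FALSE)
  tab <- table(g, factor(pos, levels = c(FALSE, TRUE)))
  out <- tibble::tibble(group = levels(g),
                        n_loci = as.integer(rowSums(tab)),
                        n_positive = as.integer(tab[, "TRUE"]),
                        fraction = as.numeric(tab[, "TRUE"] / rowSums(tab)))
  if (all(tab[, "TRUE"] == 0) || all(tab[, "FALSE"] == 0)) {
    # no variation in status: association is degenerate
    chi <- list(statistic = 0, parameter = nlevels(g) - 1L, p.value = 1)
  } else {
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  attr(out, "statistic") <- unname(chi$statistic)
  attr(out, "df") <- as.integer(unname(chi$parameter))
  attr(out, "p") <- unname(chi$p.value)
  class(out) <- c("incidence_table", class(out))
  out
}

#' Per-group profile of a divergence measure
#'
#' Summarises a value (`omega`, `ks` or `ps`) per group, runs a one-way
#' ANOVA across groups, and performs all pairwise Welch t-tests, assigning
#' compact-letter-display letters at level `alpha` (groups sharing a letter
#' are not significantly different). By default no multiple-testing
#' correction is applied; set `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param loci Data frame.
#' @param group Grouping column name or label vector (as in
#'   [incidence_by_group()]).
#' @param value Name of the value column (default `"omega"`).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param p_adjust Multiple-testing correction for the pairwise p-values
#'   (default `"none"`).
#' @return A list of class `group_profile` with tibbles `groups` (`group`,
#'   `n`, `mean`, `sd`, `letters`), `pairwise` (pairwise Welch results) and
#'   scalars `anova_f`, `anova_p`.
#' @export
group_profile <- function(loci, group, value = "omega", alpha = 0.05,
                          p_adjust = "none") {
  g <- if (length(group) == 1 && is.character(group)) loci[[group]] else group
  v <- loci[[value]]
  keep <- !is.na(g) & !is.na(v)
  g <- factor(g[keep]); v <- v[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("dropping degenerate group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep2 <- !g %in% small
    g <- droplevels(g[keep2]); v <- v[keep2]
  }
  if (nlevels(g) < 2) stop("need at least 2 groups of size >= 2",
                           call. = FALSE)
  groups <- tibble::tibble(group = levels(g),
                           n = as.integer(table(g)),
                           mean = as.numeric(tapply(v, g, mean)),
                           sd = as.numeric(tapply(v, g, stats::sd)))
  av <- stats::oneway.test(v ~ g, var.equal = TRUE)
  pairs <- utils::combn(levels(g), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- v[g == pairs[1, i]]; b <- v[g == pairs[2, i]]
    tt <- stats::t.test(a, b)
    tibble::tibble(group_a = pairs[1, i], group_b = pairs[2, i],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  pw$p_adj <- stats::p.adjust(pw$p, method = p_adjust)
  groups$letters <- compact_letters(levels(g), pw$group_a, pw$group_b,
                                    pw$p_adj, alpha)
  structure(list(groups = groups, pairwise = pw,
                 anova_f = unname(av$statistic),
                 anova_p = av$p.value, value = value),
            class = "group_profile")
}

# Compact letter display by the insert-then-absorb algorithm: start with one
# letter covering all groups; for each significantly different pair found in
# a shared letter, duplicate the letter, removing one group from each copy;
# absorb letters that become subsets of others.
compact_letters <- function(groups, a, b, p, alpha) {
  sets <- list(groups)
  sig <- which(!is.na(p) & p < alpha)
  for (i in sig) {
    for (j in seq_along(sets)) {
      s <- sets[[j]]
      if (all(c(a[i], b[i]) %in% s)) {
        sets[[j]] <- setdiff(s, a[i])
        sets <- c(sets, list(setdiff(s, b[i])))
      }
    }
    # absorb duplicated / contained sets
    keep <- rep(TRUE, length(sets))
    for (j in seq_along(sets)) {
      for (k in seq_along(sets)) {
        if (j != k && keep[k] &&
            all(sets[[j]] %in% sets[[k]]) &&
            (length(sets[[j]]) < length(sets[[k]]) || j > k)) {
          keep[j] <- FALSE
        }
      }
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)),
                            numeric(1)))]
  unname(vapply(groups, function(grp) {
    paste0(letters[which(vapply(sets, function(s) grp %in% s, logical(1)))],
           collapse = "")
  }, character(1)))
}

#' @export
print.group_profile <- function(x, ...) {
  cat("Group profile of", x$value, "\n")
  print(x$groups)
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n", x$anova_f, x$anova_p))
  invisible(x)
}

#' Per-chromosome divergence summary
#'
#' Summarises locus counts and mean Ks / mean omega per chromosome and runs
#' pairwise Welch t-tests on omega between chromosomes (skipped, with a
#' message, when only one chromosome is present).
#'
#' @param loci Data frame with `chromosome`, `ks`, `omega`.
#' @param n_genome Optional total number of loci in the genome per
#'   chromosome (named vector) for the "fraction analyzed" column.
#' @return A list of class `chromosome_summary` with tibbles `table` and
#'   `tests` (pairwise omega comparisons; empty when skipped).
#' @export
chromosome_summary <- function(loci, n_genome = NULL) {
  stopifnot(all(c("chromosome", "ks", "omega") %in% names(loci)))
  tab <- loci %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean_ks = mean(.data$ks, na.rm = TRUE),
                     mean_omega = mean(.data$omega, na.rm = TRUE),
                     .groups = "drop")
  if (!is.null(n_genome)) {
    tab$fraction_analyzed <- tab$n / as.numeric(n_genome[tab$chromosome])
  }
  chroms <- tab$chromosome
  if (length(chroms) < 2) {
    message("single chromosome; pairwise tests skipped")
    tests <- tibble::tibble(group_a = character(), group_b = character(),
                            t = numeric(), df = numeric(), p = numeric())
  } else {
    pairs <- utils::combn(chroms, 2)
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- loci$omega[loci$chromosome == pairs[1, i]]
      b <- loci$omega[loci$chromosome == pairs[2, i]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      tt <- stats::t.test(a, b)
      tibble::tibble(group_a = pairs[1, i], group_b = pairs[2, i],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
    })
  }
  structure(list(table = tab, tests = tests), class = "chromosome_summary")
}

#' @export
print.chromosome_summary <- function(x, ...) {
  print(x$table)
  if (nrow(x$tests) > 0) {
    cat("\nPairwise omega t-tests\n")
    print(x$tests)
  }
  invisible(x)
}
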