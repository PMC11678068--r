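#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname selexpr_tidiers
#' @title Broom-style tidiers for selexpr result objects
#' @description `tidy()` returns the per-group or per-bin detail of a result
#'   as a tibble; `glance()` returns its one-row test summary.
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.chisq_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p)
}

#' @rdname selexpr_tidiers
#' @export
glance.chisq_result <- tidy.chisq_result

#' @rdname selexpr_tidiers
#' @export
tidy.bin_summary <- function(x, ...) {
  tibble::tibble(bin = seq_len(x$k),
                 lower = x$breaks[-(x$k + 1)],
                 upper = x$breaks[-1],
                 obs_count = x$obs_counts,
                 ref_count = x$ref_counts)
}

#' @rdname selexpr_tidiers
#' @export
tidy.perm_cor_diff <- function(x, ...) {
  tibble::tibble(perm_diff = x$perm_diffs)
}

#' @rdname selexpr_tidiers
#' @export
glance.perm_cor_diff <- function(x, ...) {
  tibble::tibble(cor_xz = x$cor_xz, cor_yz = x$cor_yz, diff = x$diff,
                 p.value = x$p, n_perm = x$n_perm,
                 exhaustive = x$exhaustive, mode = x$mode,
                 alternative = x$alternative)
}

#' @rdname selexpr_tidiers
#' @export
tidy.band_comparison <- function(x, ...) x$tests

#' @rdname selexpr_tidiers
#' @export
glance.band_comparison <- function(x, ...) {
  first <- x$tests[1, , drop = FALSE]
  tibble::tibble(n_bands = sum(!x$groups$band %in% c("background", "all_loci")),
                 band1_vs_all_p = first$p)
}

#' @rdname selexpr_tidiers
#' @export
tidy.group_profile <- function(x, ...) x$groups

#' @rdname selexpr_tidiers
#' @export
glance.group_profile <- function(x, ...) {
  tibble::tibble(statistic = x$anova_f, p.value = x$anova_p,
                 n_groups = nrow(x$groups))
}

#' @rdname selexpr_tidiers
#' @export
tidy.incidence_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname selexpr_tidiers
#' @export
glance.incidence_table <- function(x, ...) {
  tibble::tibble(statistic = attr(x, "statistic"),
                 df = attr(x, "df"), p.value = attr(x, "p"))
}

#' @rdname selexpr_tidiers
#' @export
tidy.smooth_cor <- function(x, ...) {
  old <- as.data.frame(as.table(x$old_cor))
  new <- as.data.frame(as.table(x$new_cor))
  tibble::tibble(var1 = as.character(old$Var1),
                 var2 = as.character(old$Var2),
                 old_cor = old$Freq, new_cor = new$Freq)
}
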