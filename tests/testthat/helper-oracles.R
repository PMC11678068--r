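# Independent oracles for the codon-counting machinery. Translation goes
# through Biostrings' genetic code table, and pathway enumeration is written
# from scratch (hard-coded permutations), so these share no code with the
# package internals they check.

oracle_aa <- local({
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  code
})

oracle_sense_codons <- names(oracle_aa)[oracle_aa != "*"]

# synonymous/nonsynonymous site counts by direct enumeration of the 9
# single-nucleotide mutants
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_aa[mut] != "*" && oracle_aa[mut] == oracle_aa[codon]) {
        syn <- syn + 1
      }
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

oracle_permutations <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# pathway-averaged difference counts by explicit enumeration
oracle_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- oracle_permutations[[length(pos)]]
  walk <- function(ord) {
    cur <- a; syn <- 0; nonsyn <- 0; through_stop <- FALSE
    for (k in ord) {
      p <- pos[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_aa[nxt] == "*" && nxt != b) through_stop <- TRUE
      if (oracle_aa[nxt] != "*" && oracle_aa[cur] != "*" &&
          oracle_aa[nxt] == oracle_aa[cur]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(steps = c(syn, nonsyn), ok = !through_stop)
  }
  walks <- lapply(perms, walk)
  ok <- vapply(walks, `[[`, logical(1), "ok")
  use <- if (any(ok)) walks[ok] else walks
  m <- do.call(rbind, lapply(use, `[[`, "steps"))
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracle_kaks_counts <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  ca <- substring(seq_a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(seq_b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  keep <- ca %in% oracle_sense_codons & cb %in% oracle_sense_codons
  ca <- ca[keep]; cb <- cb[keep]
  s <- (sum(vapply(ca, function(c) oracle_sites(c)["s"], numeric(1))) +
        sum(vapply(cb, function(c) oracle_sites(c)["s"], numeric(1)))) / 2
  n_sites <- 3 * length(ca) - s
  sd_tot <- 0; nd_tot <- 0
  for (i in seq_along(ca)) {
    d <- oracle_diffs(ca[i], cb[i])
    sd_tot <- sd_tot + d["sd"]; nd_tot <- nd_tot + d["nd"]
  }
  c(s = unname(s), n = unname(n_sites), sd = unname(sd_tot),
    nd = unname(nd_tot))
}

# Pearson chi-square on the cross-tabulation of two paired vectors, written
# out from the O/E definition
oracle_pearson_pair <- function(u, v) {
  tab <- table(u, v)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# small deterministic locus table builder for unit tests
make_loci <- function(omega, chromosome = "chr1", ks = NULL, ps = NULL) {
  n <- length(omega)
  tibble::tibble(
    locus_id = sprintf("L%03d", seq_len(n)),
    chromosome = rep_len(chromosome, n),
    order_index = as.integer(stats::ave(seq_len(n), rep_len(chromosome, n),
                                        FUN = seq_along)) - 1L,
    ka = (if (is.null(ks)) rep(0.1, n) else ks) * omega,
    ks = if (is.null(ks)) rep(0.1, n) else ks,
    omega = omega,
    ps = if (is.null(ps)) rep(1L, n) else as.integer(ps),
    comparison = "interspecies")
}
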