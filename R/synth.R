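# Seeded synthetic-data generator: genomes (Ks, omega, phylostratum,
# hitchhiking structure), expression matrices (abundance + presence calls)
# and codon-sequence pairs, with ground truth for recovery tests.

#' Synthetic-genome configuration
#'
#' Bundles the generator parameters with defaults representing a plausible
#' between-species comparison of crucifer genomes: 20,000 analyzable loci on
#' 5 chromosomes, Ks approximately normal (truncated to `(0, 5]`), a
#' right-skewed lognormal omega with a rare forced tail of `omega > 1`
#' anchors (rate 0.015, about the printed interspecies incidence of
#' 341/20,729), a triangular hitchhiking kernel around anchors, expression
#' abundance log-linearly anti-correlated with the omega rank and with
#' phylostratum (but independent of Ks), and presence calls over 11 samples
#' whose breadth tracks abundance.
#'
#' @param n_loci Number of loci.
#' @param n_chromosomes Number of chromosomes (loci split evenly).
#' @param n_samples Sample universe for expression breadth.
#' @param ps_probs Length-13 probability vector for phylostrata 1..13
#'   (default decays geometrically: most genes are ancient).
#' @param ks_mean,ks_sd Mean/sd of the truncated normal Ks.
#' @param omega_logmean,omega_logsd Parameters of the lognormal base omega.
#' @param ps_omega_slope Increase of `log(omega)` per unit of scaled gene age
#'   `(ps - 1) / 12` (younger genes evolve faster).
#' @param anchor_rate Fraction of loci forced to `omega > 1`.
#' @param hitch_amplitude,hitch_range Hitchhiking kernel: omega at ordinal
#'   distance `d` from an anchor gains `amplitude * max(0, 1 - d / range)`.
#' @param gea_intercept,gea_omega_slope,gea_ps_slope,gea_noise_sd Log-linear
#'   expression model: `log10(GEA) = intercept - gea_omega_slope *
#'   rank01(omega) - gea_ps_slope * (ps - 1) / 12 + Normal(0, gea_noise_sd)`.
#' @param breadth_steepness Logistic steepness linking a locus's abundance
#'   (relative to the median) to its per-sample presence probability.
#' @param seed Integer seed; every sampling step derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_loci = 20000,
                         n_chromosomes = 5,
                         n_samples = 11,
                         ps_probs = NULL,
                         ks_mean = 0.25, ks_sd = 0.10,
                         omega_logmean = -1.9, omega_logsd = 0.8,
                         ps_omega_slope = 0.8,
                         anchor_rate = 0.015,
                         hitch_amplitude = 0.15, hitch_range = 15,
                         gea_intercept = 1.5,
                         gea_omega_slope = 1.5, gea_ps_slope = 1.0,
                         gea_noise_sd = 0.5,
                         breadth_steepness = 6,
                         seed = 1) {
  if (is.null(ps_probs)) {
    ps_probs <- 0.7^(0:12)
    ps_probs <- ps_probs / sum(ps_probs)
  }
  stopifnot(length(ps_probs) == 13, abs(sum(ps_probs) - 1) < 1e-8,
            all(ps_probs >= 0), n_loci >= n_chromosomes,
            anchor_rate >= 0, anchor_rate <= 1,
            hitch_amplitude >= 0, hitch_range >= 1,
            gea_omega_slope >= 0, gea_ps_slope >= 0, gea_noise_sd >= 0)
  structure(list(n_loci = n_loci, n_chromosomes = n_chromosomes,
                 n_samples = n_samples, ps_probs = ps_probs,
                 ks_mean = ks_mean, ks_sd = ks_sd,
                 omega_logmean = omega_logmean, omega_logsd = omega_logsd,
                 ps_omega_slope = ps_omega_slope,
                 anchor_rate = anchor_rate,
                 hitch_amplitude = hitch_amplitude,
                 hitch_range = hitch_range,
                 gea_intercept = gea_intercept,
                 gea_omega_slope = gea_omega_slope,
                 gea_ps_slope = gea_ps_slope,
                 gea_noise_sd = gea_noise_sd,
                 breadth_steepness = breadth_steepness,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic genome of loci
#'
#' Places loci in order on chromosomes, samples phylostrata, Ks (i.i.d.
#' truncated normal on `(0, 5]`, statistically independent of everything
#' else) and a lognormal base omega shifted upward for younger phylostrata,
#' forces a random anchor set to `omega > 1` (resampled from the lognormal
#' upper tail) and inflates omega at loci flanking anchors with a triangular
#' decay kernel. `ka` is defined as `omega * ks` so emitted tables are
#' internally consistent.
#'
#' @param config A [synth_config()].
#' @return A list with `loci` (tibble in [read_locus_table()] layout plus
#'   truth columns stripped) and `truth` (list: `anchor_ids`, `base_omega`,
#'   `omega_added`, `gea_coefficients`).
#' @export
generate_genome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    n <- cf$n_loci
    chrom_sizes <- rep(n %/% cf$n_chromosomes, cf$n_chromosomes)
    extra <- n %% cf$n_chromosomes
    if (extra > 0) chrom_sizes[seq_len(extra)] <- chrom_sizes[seq_len(extra)] + 1L
    chromosome <- rep(paste0("chr", seq_len(cf$n_chromosomes)), chrom_sizes)
    order_index <- unlist(lapply(chrom_sizes, function(k) seq_len(k) - 1L))
    locus_id <- sprintf("SYN%05d", seq_len(n))

    ps <- sample.int(13, n, replace = TRUE, prob = cf$ps_probs)
    ks <- rtrunc_norm(n, cf$ks_mean, cf$ks_sd, lower = 0, upper = 5)
    age <- (ps - 1) / 12
    base_omega <- stats::rlnorm(n, cf$omega_logmean +
                                  cf$ps_omega_slope * age, cf$omega_logsd)

    anchors <- which(stats::runif(n) < cf$anchor_rate)
    if (length(anchors) > 0) {
      # anchors resampled from the > 1 tail of the lognormal
      base_omega[anchors] <- vapply(anchors, function(i) {
        repeat {
          v <- stats::rlnorm(1, cf$omega_logmean + cf$ps_omega_slope * age[i],
                             cf$omega_logsd)
          if (v > 1) return(v)
        }
      }, numeric(1))
    }
    omega_added <- numeric(n)
    if (cf$hitch_amplitude > 0 && length(anchors) > 0) {
      anc_by_chrom <- split(order_index[anchors], chromosome[anchors])
      for (ch in names(anc_by_chrom)) {
        idx <- which(chromosome == ch)
        anc <- anc_by_chrom[[ch]]
        d <- vapply(order_index[idx], function(p) min(abs(p - anc)),
                    numeric(1))
        add <- cf$hitch_amplitude * pmax(0, 1 - d / cf$hitch_range)
        add[d == 0] <- 0  # anchors keep their forced omega
        omega_added[idx] <- add
      }
    }
    omega <- base_omega + omega_added
    loci <- tibble::tibble(locus_id = locus_id, chromosome = chromosome,
                           order_index = order_index,
                           ka = omega * ks, ks = ks, omega = omega,
                           ps = as.integer(ps),
                           comparison = "interspecies")
    truth <- list(anchor_ids = locus_id[anchors],
                  base_omega = base_omega,
                  omega_added = omega_added,
                  config = cf)
    list(loci = loci, truth = truth)
  })
}

# truncated normal via rejection (the default truncation barely cuts mass)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)), mean, sd)
    out <- c(out, draw[draw > lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate synthetic expression records for a genome
#'
#' Draws per-locus total abundance from the log-linear model
#' `log10(GEA) = intercept - gea_omega_slope * rank01(omega) - gea_ps_slope *
#' (ps - 1)/12 + noise` (so abundance is anti-correlated with omega and with
#' gene age but independent of Ks by construction), converts abundance into
#' per-sample presence via independent Bernoulli draws whose probability
#' rises with abundance (`breadth_steepness` controls how sharply breadth
#' tracks abundance), splits the total abundance across the present samples,
#' and emits EST counts as Poisson draws proportional to abundance.
#'
#' @param genome Output of [generate_genome()].
#' @return A list with `expression` (long records: `rnaseq_rpm` over
#'   `n_samples` samples plus pooled `est` counts) and `truth` (per-locus
#'   `log10_gea`, presence probabilities).
#' @export
generate_expression <- function(genome) {
  cf <- genome$truth$config
  loci <- genome$loci
  n <- nrow(loci)
  withr::with_seed(cf$seed + 1L, {
    r01 <- (rank(loci$omega, ties.method = "first") - 1) / (n - 1)
    age <- (loci$ps - 1) / 12
    log10_gea <- cf$gea_intercept - cf$gea_omega_slope * r01 -
      cf$gea_ps_slope * age + stats::rnorm(n, 0, cf$gea_noise_sd)
    gea <- 10^log10_gea
    pi_present <- stats::plogis(cf$breadth_steepness *
                                  (log10_gea - stats::median(log10_gea)) /
                                  stats::sd(log10_gea) + 1)
    pres <- matrix(stats::runif(n * cf$n_samples) <
                     matrix(pi_present, n, cf$n_samples),
                   nrow = n)
    # split each locus's total abundance across its present samples
    w <- matrix(stats::runif(n * cf$n_samples), n) * pres
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
    abund <- w * gea
    sample_ids <- sprintf("sample%02d", seq_len(cf$n_samples))
    rnaseq <- tibble::tibble(
      locus_id = rep(loci$locus_id, times = cf$n_samples),
      sample_id = rep(sample_ids, each = n),
      assay = "rnaseq_rpm",
      abundance = as.vector(abund),
      present = NA)
    est <- tibble::tibble(
      locus_id = loci$locus_id,
      sample_id = "est_pool",
      assay = "est",
      abundance = as.numeric(stats::rpois(n, lambda = gea)),
      present = NA)
    truth <- list(log10_gea = log10_gea, pi_present = pi_present)
    list(expression = dplyr::bind_rows(rnaseq, est), truth = truth)
  })
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper: [generate_genome()], [generate_expression()] and
#' [join_analysis_table()] in one call.
#'
#' @param config A [synth_config()].
#' @return A list with `loci`, `expression`, `table` (analysis table) and
#'   `truth`.
#' @export
generate_dataset <- function(config = synth_config()) {
  genome <- generate_genome(config)
  expr <- generate_expression(genome)
  table <- join_analysis_table(genome$loci, expr$expression,
                               n_samples = config$n_samples)
  list(loci = genome$loci, expression = expr$expression, table = table,
       truth = c(genome$truth, expr$truth))
}

#' Evolve a codon-sequence pair with controlled substitution types
#'
#' Draws a random sense-codon ancestor of `n_codons` codons and applies the
#' requested numbers of synonymous and nonsynonymous single-nucleotide
#' substitutions to one copy (rejection-sampling the mutation type; stop
#' codons are never created). Useful for checking that the Ka/Ks estimator
#' recovers the synonymous:nonsynonymous event ratio.
#'
#' @param n_codons Number of codons.
#' @param n_syn_events,n_nonsyn_events Numbers of synonymous / nonsynonymous
#'   events to apply.
#' @param seed Integer seed.
#' @param max_tries Bound on rejection sampling per event (default 10000).
#' @return A list with `seq_a` (ancestor), `seq_b` (derived) and the realised
#'   event log (`event_type`, `codon_index`).
#' @export
evolve_codon_pair <- function(n_codons, n_syn_events, n_nonsyn_events, seed,
                              max_tries = 10000) {
  stopifnot(n_codons >= 1, n_syn_events >= 0, n_nonsyn_events >= 0)
  withr::with_seed(seed, {
    codons <- sample(sense_codons(), n_codons, replace = TRUE)
    derived <- codons
    bases <- c("A", "C", "G", "T")
    want <- c(rep("syn", n_syn_events), rep("nonsyn", n_nonsyn_events))
    want <- sample(want)
    log_idx <- integer(0)
    for (type in want) {
      done <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(n_codons, 1)
        pos <- sample.int(3, 1)
        cur <- derived[ci]
        b <- sample(setdiff(bases, substr(cur, pos, pos)), 1)
        mut <- cur
        substr(mut, pos, pos) <- b
        if (translate_codon(mut) == "*") next
        is_syn <- translate_codon(mut) == translate_codon(cur)
        if ((type == "syn") == is_syn) {
          derived[ci] <- mut
          log_idx <- c(log_idx, ci)
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop("could not realise a ", type,
             " event within the retry bound", call. = FALSE)
      }
    }
    list(seq_a = paste0(codons, collapse = ""),
         seq_b = paste0(derived, collapse = ""),
         events = tibble::tibble(event_type = want, codon_index = log_idx))
  })
}
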