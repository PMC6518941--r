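#' Configuration for the genotype simulator
#'
#' Describes a multi-population SNP dataset generated under the
#' Balding-Nichols model: each SNP has an ancestral allele frequency drawn
#' Uniform(0.05, 0.95), and each population's frequency is drawn from a Beta
#' distribution parameterized so that the expected fixation index among
#' populations equals `fst_target`. Chromosomal inversions are layered on
#' top as non-recombining regions (see [inversion_spec()]).
#'
#' @param n_populations number of populations.
#' @param n_per_pop individuals per population (scalar or vector).
#' @param n_chromosomes number of chromosomes (named LG01, LG02, ...).
#' @param chrom_length_bp chromosome length in bp.
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param fst_target target Weir-Cockerham FST among populations, in
#'   `[0, 1)`. `0` gives identical population frequencies (no Beta draw).
#' @param inversion_specs list of [inversion_spec()] objects.
#' @param missing_rate fraction of genotypes masked to missing.
#' @param dp_mean mean simulated per-genotype read depth (Poisson).
#' @param seed integer seed; the same config + seed is bit-reproducible.
#' @return A list of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_populations = 3, n_per_pop = 20,
                            n_chromosomes = 3, chrom_length_bp = 5e6,
                            n_snps_per_chrom = 1000, fst_target = 0.05,
                            inversion_specs = list(), missing_rate = 0.02,
                            dp_mean = 10, seed = 1) {
  stopifnot(fst_target >= 0, fst_target < 1,
            missing_rate >= 0, missing_rate <= 1,
            n_snps_per_chrom >= 1, chrom_length_bp > n_snps_per_chrom)
  n_per_pop <- rep_len(n_per_pop, n_populations)
  for (sp in inversion_specs) {
    stopifnot(inherits(sp, "inversion_spec"))
    if (length(sp$arrangement_freq_per_pop) != n_populations)
      stopf("inversion on %s: need %d arrangement frequencies",
            sp$chromosome, n_populations)
    if (sp$end > chrom_length_bp)
      stopf("inversion on %s extends past chromosome end", sp$chromosome)
  }
  structure(list(n_populations = n_populations, n_per_pop = n_per_pop,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 n_snps_per_chrom = n_snps_per_chrom,
                 fst_target = fst_target, inversion_specs = inversion_specs,
                 missing_rate = missing_rate, dp_mean = dp_mean, seed = seed),
            class = "geno_sim_config")
}

#' Specify a simulated chromosomal inversion
#'
#' An inversion is modelled as a single non-recombining bi-allelic
#' "arrangement locus": each chromosome copy carries either the ancestral or
#' the inverted arrangement, and each arrangement has its own pool of SNP
#' allele frequencies. Haplotypes within the region are drawn from the pool
#' of the carried arrangement with no recombination between pools, which
#' reproduces the three-cluster PCA signature of real inversions.
#'
#' @param chromosome chromosome id (e.g. `"LG02"`).
#' @param start,end region bounds, 1-based inclusive bp.
#' @param arrangement_freq_per_pop frequency of the *inverted* arrangement
#'   among chromosomes, one value per population.
#' @param pool_divergence mean absolute allele-frequency difference between
#'   the ancestral and inverted haplotype pools.
#' @return A list of class `inversion_spec`.
#' @export
inversion_spec <- function(chromosome, start, end, arrangement_freq_per_pop,
                           pool_divergence = 0.4) {
  stopifnot(start < end, all(arrangement_freq_per_pop >= 0),
            all(arrangement_freq_per_pop <= 1),
            pool_divergence >= 0, pool_divergence < 1)
  structure(list(chromosome = chromosome, start = as.integer(start),
                 end = as.integer(end),
                 arrangement_freq_per_pop = arrangement_freq_per_pop,
                 pool_divergence = pool_divergence),
            class = "inversion_spec")
}

#' The four inversion regions of the Atlantic cod reference genome
#'
#' Coordinates (GadMor2 assembly, 1-based inclusive) of the large inversions
#' on linkage groups 01, 02, 07 and 12 routinely karyotyped in Atlantic cod
#' population genomics.
#'
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
cod_inversion_regions <- function() {
  data.frame(chrom = c("LG01", "LG02", "LG07", "LG12"),
             start = c(9114741L, 18609260L, 13622710L, 426531L),
             end = c(26192386L, 23660985L, 23019113L, 13445150L))
}

#' Simulate multi-population genotypes under the Balding-Nichols model
#'
#' Generates a [genotype_matrix()] plus a ground-truth record. SNP ancestral
#' frequencies are Uniform(0.05, 0.95); population frequencies are
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with `F = fst_target` (exactly `p` when
#' `F = 0`); genotypes are Binomial(2, p_pop). Sites inside configured
#' inversion regions are instead generated by [simulate_inversion_region()].
#' Genotypes are masked to missing at `missing_rate`, and Poisson DP /
#' capped-Poisson GQ annotations are attached.
#'
#' @param cfg a [geno_sim_config()].
#' @return A list with elements `genotypes` (a `genotype_matrix`) and
#'   `truth` (list with `population`, `karyotype` data frame, and the
#'   generating per-population allele frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "geno_sim_config"))
  local_seed(cfg$seed)
  n_pop <- cfg$n_populations
  n_ind <- sum(cfg$n_per_pop)
  pops <- sprintf("POP%02d", seq_len(n_pop))
  pop_of <- rep(pops, cfg$n_per_pop)
  ids <- sprintf("%s_i%03d", pop_of, unlist(lapply(cfg$n_per_pop, seq_len)))
  chroms <- sprintf("LG%02d", seq_len(cfg$n_chromosomes))

  call_list <- list(); chrom_v <- character(0); pos_v <- integer(0)
  freq_list <- list()
  karyo <- list()
  for (ch in chroms) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_snps_per_chrom))
    specs <- Filter(function(s) s$chromosome == ch, cfg$inversion_specs)
    in_inv <- rep(FALSE, length(pos))
    for (sp in specs) in_inv <- in_inv | (pos >= sp$start & pos <= sp$end)

    m <- matrix(NA_integer_, n_ind, length(pos))
    pfreq <- matrix(NA_real_, n_pop, length(pos), dimnames = list(pops, NULL))
    bg <- which(!in_inv)
    if (length(bg)) {
      p_anc <- runif(length(bg), 0.05, 0.95)
      F <- cfg$fst_target
      for (k in seq_len(n_pop)) {
        p_pop <- if (F == 0) p_anc else
          rbeta(length(bg), p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
        pfreq[k, bg] <- p_pop
        rows <- which(pop_of == pops[k])
        m[rows, bg] <- matrix(
          rbinom(length(rows) * length(bg), 2L, rep(p_pop, each = length(rows))),
          nrow = length(rows))
      }
    }
    for (sp in specs) {
      idx <- which(pos >= sp$start & pos <= sp$end)
      if (length(idx) < 2) next
      reg <- simulate_inversion_region(sp, cfg$n_per_pop, n_snps = length(idx),
                                       seed = NULL)
      m[, idx] <- reg$calls
      karyo[[paste(ch, sp$start, sep = ":")]] <-
        data.frame(individual = ids,
                   region = sprintf("%s:%d-%d", ch, sp$start, sp$end),
                   karyotype = reg$karyotype, stringsAsFactors = FALSE)
    }
    call_list[[ch]] <- m
    chrom_v <- c(chrom_v, rep(ch, length(pos)))
    pos_v <- c(pos_v, pos)
    freq_list[[ch]] <- pfreq
  }
  calls <- do.call(cbind, call_list)
  if (cfg$missing_rate > 0) {
    mask <- runif(length(calls)) < cfg$missing_rate
    calls[mask] <- NA_integer_
  }
  dp <- matrix(rpois(length(calls), cfg$dp_mean), nrow(calls))
  gq <- matrix(pmin(99L, rpois(length(calls), 40)), nrow(calls))
  g <- genotype_matrix(calls, chrom_v, pos_v, ids, pop_of, dp = dp, gq = gq)
  truth <- list(population = setNames(pop_of, ids),
                karyotype = if (length(karyo)) do.call(rbind, karyo) else NULL,
                pop_freq = freq_list)
  list(genotypes = g, truth = truth)
}

#' Simulate a non-recombining inversion region
#'
#' Each individual draws two arrangement labels (ancestral/inverted) at its
#' population's inverted-arrangement frequency; each label indexes a
#' haplotype pool whose per-SNP allele frequencies differ on average by
#' `pool_divergence`; the genotype is the sum of two pool-conditioned
#' haplotype draws, with no recombination between pools. Truth karyotype is
#' `anc`/`het`/`inv` by the label pair. Very small `pool_divergence` makes
#' the pools statistically indistinguishable; downstream calling accuracy
#' then degrades (this is expected, not an error).
#'
#' @param spec an [inversion_spec()].
#' @param pop_sizes integer vector of individuals per population.
#' @param n_snps number of SNPs in the region (>= 2).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `calls` (individuals x SNPs dosage matrix),
#'   `karyotype` (character vector `anc`/`het`/`inv`), and the two pools'
#'   allele frequencies `pool_freq` (2 x SNPs).
#' @export
simulate_inversion_region <- function(spec, pop_sizes, n_snps = 500,
                                      seed = NULL) {
  stopifnot(inherits(spec, "inversion_spec"), n_snps >= 2)
  local_seed(seed)
  d <- spec$pool_divergence
  q_anc <- runif(n_snps, 0.05, 0.95)
  dir_up <- (q_anc + d <= 0.98) & (runif(n_snps) < 0.5 | q_anc - d < 0.02)
  q_inv <- pmin(0.98, pmax(0.02, ifelse(dir_up, q_anc + d, q_anc - d)))
  pool_freq <- rbind(anc = q_anc, inv = q_inv)

  n_ind <- sum(pop_sizes)
  freq_inv <- rep(spec$arrangement_freq_per_pop, pop_sizes)
  n_inv_alleles <- rbinom(n_ind, 2L, freq_inv)  # 0, 1 or 2 inverted copies
  karyotype <- c("anc", "het", "inv")[n_inv_alleles + 1L]
  calls <- matrix(0L, n_ind, n_snps)
  for (k in 0:2) {
    rows <- which(n_inv_alleles == k)
    if (!length(rows)) next
    # k inverted haplotypes + (2-k) ancestral haplotypes per individual
    h1 <- matrix(rbinom(length(rows) * n_snps, 1L,
                        rep(if (k >= 1) q_inv else q_anc, each = length(rows))),
                 nrow = length(rows))
    h2 <- matrix(rbinom(length(rows) * n_snps, 1L,
                        rep(if (k == 2) q_inv else q_anc, each = length(rows))),
                 nrow = length(rows))
    calls[rows, ] <- h1 + h2
  }
  list(calls = calls, karyotype = karyotype, pool_freq = pool_freq)
}
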