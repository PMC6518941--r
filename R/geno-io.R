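#' Load genotypes from a VCF and population map
#'
#' Reads biallelic SNP records from a VCF (via vcfR), drops multiallelic and
#' indel records with a message, and attaches per-genotype DP/GQ annotations
#' where present. Half-missing diploid calls (e.g. `./0`) are treated as
#' missing.
#'
#' @param vcf_path path to a VCF (plain or gzipped).
#' @param popmap_path two-column tab-separated file `sample<TAB>population`,
#'   no header. Every VCF sample must appear.
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(vcf_path, popmap_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(sprintf("dropped %d multiallelic/indel record(s)", n_drop))
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dosage <- function(x) {
    a <- substr(x, 1, 1); b <- substr(x, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out[!(a %in% c("0", "1")) | !(b %in% c("0", "1"))] <- NA_integer_
    out
  }
  calls <- t(apply(gt, 2, dosage))  # samples x sites
  rownames(calls) <- colnames(gt)
  get_num <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    t(m[snp, , drop = FALSE])
  }
  dp <- get_num("DP"); gq <- get_num("GQ")
  if (!is.null(dp) && all(is.na(dp))) dp <- NULL
  if (!is.null(gq) && all(is.na(gq))) gq <- NULL

  pm <- read.table(popmap_path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("sample", "population"))
  missing_samples <- setdiff(rownames(calls), pm$sample)
  if (length(missing_samples))
    stopf("sample(s) absent from population map: %s",
          paste(missing_samples, collapse = ", "))
  pop <- pm$population[match(rownames(calls), pm$sample)]
  genotype_matrix(calls, chrom = fix[snp, "CHROM"],
                  pos = as.integer(fix[snp, "POS"]),
                  sample_ids = rownames(calls), pop = pop, dp = dp, gq = gq)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Plain-text VCF with contig headers, `GT:DP:GQ` genotype fields (DP/GQ
#' only when present) and arbitrary REF=A / ALT=C alleles (the container
#' does not track nucleotides). Missing calls are written `./.`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths optional named lengths for `##contig` headers;
#'   defaults to max position per chromosome.
#' @export
write_genotypes_vcf <- function(g, path, contig_lengths = NULL) {
  chroms <- unique(g$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(chroms, function(ch) max(g$pos[g$chrom == ch]),
                             numeric(1))
  has_dp <- !is.null(g$dp); has_gq <- !is.null(g$gq)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=fjordcod",
           sprintf("##contig=<ID=%s,length=%d>", chroms,
                   as.integer(contig_lengths[chroms])),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           if (has_gq) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$calls + 1L], nrow(g$calls))
  gt_str[is.na(g$calls)] <- "./."
  cells <- gt_str
  if (has_dp) cells <- matrix(paste(cells, ifelse(is.na(g$dp), ".", g$dp),
                                    sep = ":"), nrow(cells))
  if (has_gq) cells <- matrix(paste(cells, ifelse(is.na(g$gq), ".", g$gq),
                                    sep = ":"), nrow(cells))
  body <- vapply(seq_len(ncol(g$calls)), function(j)
    paste(c(g$chrom[j], g$pos[j], ".", "A", "C", ".", "PASS", ".", fmt,
            cells[, j]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a population map
#' @param g a [genotype_matrix()].
#' @param path output path (tab-separated `sample<TAB>population`).
#' @export
write_popmap <- function(g, path) {
  write.table(data.frame(g$sample_ids, g$pop), path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mask genotypes by depth and quality
#'
#' Per-genotype filters of the variant filter chain: genotypes are kept only
#' if `DP > min_dp` and `GQ > min_gq` (strict inequalities); failing
#' genotypes are set missing. `mask_dp_below` additionally masks genotypes
#' with `DP < mask_dp_below` (so `DP = 7` is retained at the default
#' landscape-analysis threshold of 7), which counters the biased
#' heterozygote call probability at low coverage in population-level
#' (landscape) statistics.
#'
#' @param g a [genotype_matrix()] with DP/GQ annotations as required.
#' @param min_dp,min_gq keep genotypes with DP/GQ strictly above these;
#'   `NULL` skips the rule.
#' @param mask_dp_below mask genotypes with DP strictly below this; `NULL`
#'   skips.
#' @return filtered `genotype_matrix`.
#' @export
apply_genotype_filters <- function(g, min_dp = 3, min_gq = 20,
                                   mask_dp_below = NULL) {
  calls <- g$calls
  if (!is.null(min_dp) || !is.null(mask_dp_below)) {
    if (is.null(g$dp)) stopf("DP annotation absent but a DP threshold given")
    if (!is.null(min_dp)) calls[!(g$dp > min_dp) | is.na(g$dp)] <- NA_integer_
    if (!is.null(mask_dp_below))
      calls[g$dp < mask_dp_below | is.na(g$dp)] <- NA_integer_
  }
  if (!is.null(min_gq)) {
    if (is.null(g$gq)) stopf("GQ annotation absent but a GQ threshold given")
    calls[!(g$gq > min_gq) | is.na(g$gq)] <- NA_integer_
  }
  genotype_matrix(calls, g$chrom, g$pos, g$sample_ids, g$pop,
                  dp = g$dp, gq = g$gq)
}

#' Site-level filter chain
#'
#' Keeps a site iff all of: missing fraction strictly below `max_missing`;
#' minor allele count strictly above `min_mac`; minor allele frequency
#' strictly above `min_maf` (computed on called genotypes only);
#' heterozygote-*excess* one-sided exact test p >= `het_excess_p`; and mean
#' DP across called genotypes strictly below `max_mean_dp` (skipped when DP
#' absent). A site may fail several rules; the report itemizes each.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing,min_mac,min_maf,het_excess_p,max_mean_dp thresholds;
#'   set any to `NULL` to skip that rule.
#' @return list with `genotypes` (filtered matrix) and `report` (class
#'   `filter_report`: sites in/out and per-rule removal counts).
#' @export
apply_site_filters <- function(g, max_missing = 0.20, min_mac = 3,
                               min_maf = 0.03, het_excess_p = 0.001,
                               max_mean_dp = 30) {
  if (ncol(g$calls) == 0) stopf("empty genotype matrix")
  calls <- g$calls
  n <- nrow(calls)
  called <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  mac <- pmin(alt, 2 * called - alt)
  maf <- ifelse(called > 0, mac / (2 * called), 0)
  miss_frac <- 1 - called / n

  keep <- rep(TRUE, ncol(calls))
  removed <- list()
  rule <- function(fail, name) {
    removed[[name]] <<- sum(fail)
    keep <<- keep & !fail
  }
  # count-based comparison so a fraction exactly at the threshold is
  # removed (strict "<") without floating-point leakage
  if (!is.null(max_missing))
    rule(!(n - called < max_missing * n - 1e-9), "missing")
  if (!is.null(min_mac)) rule(!(mac > min_mac - 1), "mac")
  if (!is.null(min_maf)) rule(!(maf > min_maf), "maf")
  if (!is.null(het_excess_p)) {
    n_het <- colSums(calls == 1L, na.rm = TRUE)
    n_hom_alt <- colSums(calls == 2L, na.rm = TRUE)
    n_hom_ref <- called - n_het - n_hom_alt
    p_exc <- vapply(seq_along(n_het), function(j)
      hwe_exact(n_hom_ref[j], n_het[j], n_hom_alt[j],
                alternative = "excess"),
      numeric(1))
    rule(p_exc < het_excess_p, "het_excess")
  }
  if (!is.null(max_mean_dp) && !is.null(g$dp)) {
    mean_dp <- colSums(g$dp * !is.na(calls), na.rm = TRUE) / pmax(1, called)
    rule(!(mean_dp < max_mean_dp), "mean_dp")
  }
  report <- structure(list(sites_in = ncol(calls), sites_out = sum(keep),
                           removed_by_rule = unlist(removed),
                           sites_removed = sum(!keep)),
                      class = "filter_report")
  list(genotypes = subset_genotypes(g, sites = which(keep)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("sites: %d in, %d out (%d removed)\n",
              x$sites_in, x$sites_out, x$sites_removed))
  for (nm in names(x$removed_by_rule))
    cat(sprintf("  failed %-11s %d\n", paste0(nm, ":"),
                x$removed_by_rule[[nm]]))
  invisible(x)
}

#' Prune sites in high linkage disequilibrium
#'
#' Greedy left-to-right pruning within sliding windows: for each kept site,
#' any later site within `window_bp` whose genotype-dosage squared
#' correlation with it exceeds `r2_max` is dropped. Idempotent.
#'
#' @param g a [genotype_matrix()] with sites sorted by position.
#' @param window_bp window size in bp (default 10 kb).
#' @param r2_max r-squared threshold above which the later site is dropped.
#' @return pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, window_bp = 10000, r2_max = 0.8) {
  keep <- rep(TRUE, ncol(g$calls))
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    pos <- g$pos[idx]
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      b <- a + 1
      while (b <= length(idx) && pos[b] - pos[a] <= window_bp) {
        if (keep[idx[b]]) {
          r2 <- pairwise_r2(g$calls[, idx[a]], g$calls[, idx[b]])
          if (!is.na(r2) && r2 > r2_max) keep[idx[b]] <- FALSE
        }
        b <- b + 1
      }
    }
  }
  subset_genotypes(g, sites = which(keep))
}

# squared Pearson correlation of two dosage vectors, pairwise-complete
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Randomly downsample individuals per population
#'
#' Seeded uniform sampling without replacement to an equal number of
#' individuals per population, as done before between-population landscape
#' statistics so sample sizes do not drive the estimates.
#'
#' @param g a [genotype_matrix()].
#' @param per_pop_n individuals to retain per population (default 20).
#' @param pops populations to retain (default all).
#' @param seed integer seed.
#' @return downsampled `genotype_matrix`.
#' @export
downsample_individuals <- function(g, per_pop_n = 20, pops = unique(g$pop),
                                   seed = 1) {
  local_seed(seed)
  keep <- integer(0)
  for (p in pops) {
    rows <- which(g$pop == p)
    if (length(rows) < per_pop_n)
      stopf("population %s has only %d individuals (< %d)",
            p, length(rows), per_pop_n)
    keep <- c(keep, if (length(rows) == per_pop_n) rows else
      sample(rows, per_pop_n))
  }
  subset_genotypes(g, samples = sort(keep))
}
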