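#' Construct a genotype matrix
#'
#' The central container for diploid biallelic SNP data: a samples-by-sites
#' matrix of alternate-allele dosages (0, 1, 2, or `NA` for missing), with
#' site coordinates, per-sample population labels and optional per-genotype
#' read depth (DP) and genotype quality (GQ) annotations.
#'
#' @param calls integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param chrom character vector of chromosome ids, one per site.
#' @param pos integer vector of 1-based site positions; must be strictly
#'   increasing within each chromosome.
#' @param sample_ids character vector of sample names (row names of `calls`).
#' @param pop character vector of population labels, one per sample.
#' @param dp,gq optional matrices, same shape as `calls`, with per-genotype
#'   read depth and phred-scaled genotype quality.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, chrom, pos, sample_ids = rownames(calls),
                            pop, dp = NULL, gq = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (length(chrom) != ncol(calls) || length(pos) != ncol(calls))
    stopf("chrom/pos length (%d/%d) must equal number of sites (%d)",
          length(chrom), length(pos), ncol(calls))
  if (length(pop) != nrow(calls))
    stopf("pop has %d labels for %d samples", length(pop), nrow(calls))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stopf("calls must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) stopf("positions not strictly increasing on %s", ch)
  }
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(calls)))
  if (!is.null(gq)) stopifnot(all(dim(gq) == dim(calls)))
  rownames(calls) <- sample_ids
  structure(list(calls = calls, chrom = as.character(chrom),
                 pos = as.integer(pos), sample_ids = as.character(sample_ids),
                 pop = as.character(pop), dp = dp, gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$chrom))))
  tb <- table(x$pop)
  cat("populations:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

n_sites <- function(g) ncol(g$calls)
n_samples <- function(g) nrow(g$calls)

# Subset sites (columns) and/or samples (rows), keeping annotations in step.
subset_genotypes <- function(g, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(g$calls))
  if (is.null(sites)) sites <- seq_len(ncol(g$calls))
  genotype_matrix(g$calls[samples, sites, drop = FALSE],
                  g$chrom[sites], g$pos[sites],
                  g$sample_ids[samples], g$pop[samples],
                  dp = if (!is.null(g$dp)) g$dp[samples, sites, drop = FALSE],
                  gq = if (!is.null(g$gq)) g$gq[samples, sites, drop = FALSE])
}

# Column indices of sites inside a [start, end] 1-based inclusive interval.
sites_in_region <- function(g, chromosome, start, end) {
  which(g$chrom == chromosome & g$pos >= start & g$pos <= end)
}

# Per-population alternate-allele frequency and called-chromosome count at
# selected sites. Returns list(freq = pops x sites, n_chr = pops x sites).
pop_allele_freqs <- function(g, sites = seq_len(ncol(g$calls)),
                             pops = unique(g$pop)) {
  freq <- n_chr <- matrix(NA_real_, length(pops), length(sites),
                          dimnames = list(pops, NULL))
  for (i in seq_along(pops)) {
    m <- g$calls[g$pop == pops[i], sites, drop = FALSE]
    called <- colSums(!is.na(m))
    n_chr[i, ] <- 2 * called
    s <- colSums(m, na.rm = TRUE)
    freq[i, ] <- ifelse(called > 0, s / (2 * called), NA_real_)
  }
  list(freq = freq, n_chr = n_chr)
}
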