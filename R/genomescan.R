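#' Tile chromosomes into nonoverlapping windows
#'
#' Tiles `[0, size)`, `[size, 2*size)`, ... along each chromosome
#' (half-open, 0-based internally). A trailing partial window is kept and
#' flagged.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param size_bp window size; genome scans conventionally use 50,000 or
#'   100,000.
#' @return data frame `chrom, start, end, partial` (start/end 0-based
#'   half-open).
#' @export
make_windows <- function(chrom_lengths, size_bp = 50000) {
  stopifnot(size_bp > 0, all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = size_bp)
    ends <- pmin(starts + size_bp, L)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = ends - starts < size_bp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for two or
# more populations of diploids, from per-population allele frequencies,
# heterozygote frequencies and sample sizes (individuals).
# Returns a 3-row matrix (a, b, c) x sites; sites with < 2 usable pops NA.
wc_components <- function(freq, het, n_ind) {
  r <- nrow(freq)
  usable <- colSums(!is.na(freq) & n_ind > 0) >= 2
  a <- b <- cc <- rep(NA_real_, ncol(freq))
  if (!any(usable)) return(rbind(a = a, b = b, c = cc))
  f <- freq[, usable, drop = FALSE]
  h <- het[, usable, drop = FALSE]
  n <- n_ind[, usable, drop = FALSE]
  n[is.na(f)] <- 0
  f[is.na(f)] <- 0; h[is.na(h)] <- 0
  r_eff <- colSums(n > 0)
  nbar <- colSums(n) / r_eff
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r_eff - 1)
  pbar <- colSums(n * f) / (r_eff * nbar)
  s2 <- colSums(n * sweep(f, 2, pbar)^2) / ((r_eff - 1) * nbar)
  hbar <- colSums(n * h) / (r_eff * nbar)
  av <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 -
                               hbar / 4) / (nbar - 1))
  bv <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                 (r_eff - 1) / r_eff * s2 -
                                 (2 * nbar - 1) / (4 * nbar) * hbar)
  cv <- hbar / 2
  a[usable] <- av; b[usable] <- bv; cc[usable] <- cv
  rbind(a = a, b = b, c = cc)
}

# per-population freq/het/n (individuals) at given sites, with a minimum
# called-chromosome requirement per population per site
site_pop_stats <- function(g, sites, pops, min_chr = 4) {
  freq <- het <- nind <- matrix(NA_real_, length(pops), length(sites),
                                dimnames = list(pops, NULL))
  for (i in seq_along(pops)) {
    m <- g$calls[g$pop == pops[i], sites, drop = FALSE]
    called <- colSums(!is.na(m))
    ok <- 2 * called >= min_chr
    freq[i, ok] <- (colSums(m, na.rm = TRUE) / (2 * called))[ok]
    het[i, ok] <- (colSums(m == 1L, na.rm = TRUE) / called)[ok]
    nind[i, ok] <- called[ok]
  }
  nind[is.na(nind)] <- 0
  list(freq = freq, het = het, n_ind = nind)
}

#' Windowed Weir-Cockerham FST
#'
#' Two-population FST over the sites falling in a window, as the
#' ratio-of-sums estimate `sum(a) / sum(a + b + c)` of the per-site
#' Weir-Cockerham variance components (among-population `a`,
#' among-individual `b`, within-individual `c`). Sites need at least
#' `min_chr` called chromosomes in each population; sites with zero total
#' variance are skipped. Negative estimates are retained (not clamped), so
#' genome-wide summaries stay unbiased.
#'
#' @param g a [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @param chrom,start,end window (1-based inclusive `start`..`end`; pass a
#'   `make_windows()` row as `start = row$start + 1, end = row$end`).
#' @param min_chr minimum called chromosomes per population per site.
#' @return FST estimate, or `NA` if no usable site.
#' @export
wc_fst_window <- function(g, pop_a, pop_b, chrom, start, end, min_chr = 4) {
  sites <- sites_in_region(g, chrom, start, end)
  if (!length(sites)) return(NA_real_)
  st <- site_pop_stats(g, sites, c(pop_a, pop_b), min_chr)
  comp <- wc_components(st$freq, st$het, st$n_ind)
  tot <- colSums(comp)
  use <- !is.na(tot) & tot != 0
  if (!any(use)) return(NA_real_)
  sum(comp["a", use]) / sum(tot[use])
}

#' Windowed between-population sequence divergence (dxy)
#'
#' `sum over sites of p_A (1 - p_B) + p_B (1 - p_A)` divided by the window
#' length in bp; unreported sites are assumed invariant and contribute zero
#' to the numerator, so the statistic is per-bp.
#'
#' @inheritParams wc_fst_window
#' @return dxy per bp.
#' @export
dxy_window <- function(g, pop_a, pop_b, chrom, start, end, min_chr = 4) {
  L <- end - start + 1
  if (L <= 0) stopf("zero-length window")
  sites <- sites_in_region(g, chrom, start, end)
  if (!length(sites)) return(0)
  st <- site_pop_stats(g, sites, c(pop_a, pop_b), min_chr)
  pa <- st$freq[1, ]; pb <- st$freq[2, ]
  use <- !is.na(pa) & !is.na(pb)
  sum(pa[use] * (1 - pb[use]) + pb[use] * (1 - pa[use])) / L
}

#' Windowed proportion of fixed differences (df)
#'
#' Fraction of usable variant sites in the window at which the two
#' populations are fixed for alternate alleles (`|p_A - p_B| = 1`). The
#' denominator is the count of variant sites used (a per-bp "proportion"
#' would not be a proportion).
#'
#' @inheritParams wc_fst_window
#' @return df in `[0, 1]`, or `NA` if no usable variant site.
#' @export
df_window <- function(g, pop_a, pop_b, chrom, start, end, min_chr = 4) {
  sites <- sites_in_region(g, chrom, start, end)
  if (!length(sites)) return(NA_real_)
  st <- site_pop_stats(g, sites, c(pop_a, pop_b), min_chr)
  pa <- st$freq[1, ]; pb <- st$freq[2, ]
  use <- !is.na(pa) & !is.na(pb)
  variant <- use & !(pa == pb & (pa == 0 | pa == 1))
  if (!any(variant)) return(NA_real_)
  mean(abs(pa[variant] - pb[variant]) == 1)
}

#' Windowed nucleotide diversity (pi)
#'
#' `sum over sites of (n / (n - 1)) * 2 p (1 - p)` divided by the window
#' length in bp, with `n` the called chromosomes at the site (the unbiased
#' per-site mean pairwise difference).
#'
#' @inheritParams wc_fst_window
#' @param pop population label.
#' @return pi per bp.
#' @export
pi_window <- function(g, pop, chrom, start, end) {
  L <- end - start + 1
  if (L <= 0) stopf("zero-length window")
  sites <- sites_in_region(g, chrom, start, end)
  if (!length(sites)) return(0)
  m <- g$calls[g$pop == pop, sites, drop = FALSE]
  n <- 2 * colSums(!is.na(m))
  p <- ifelse(n > 0, colSums(m, na.rm = TRUE) / n, NA_real_)
  use <- !is.na(p) & n >= 2
  sum((n[use] / (n[use] - 1)) * 2 * p[use] * (1 - p[use])) / L
}

#' Windowed mean LD (r-squared)
#'
#' Mean pairwise squared Pearson correlation between genotype-dosage
#' vectors over all SNP pairs in the window, pairwise-complete over
#' missing data. Computed across all samples (no population split).
#'
#' @inheritParams pi_window
#' @return mean r-squared, or `NA` with fewer than 2 usable SNPs.
#' @export
ld_window <- function(g, chrom, start, end) {
  sites <- sites_in_region(g, chrom, start, end)
  if (length(sites) < 2) return(NA_real_)
  m <- g$calls[, sites, drop = FALSE]
  if (!anyNA(m)) {
    sds <- apply(m, 2, sd)
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2) return(NA_real_)
    C <- cor(m)^2
    return(mean(C[upper.tri(C)]))
  }
  pr <- utils::combn(ncol(m), 2)
  r2 <- vapply(seq_len(ncol(pr)), function(j)
    pairwise_r2(m[, pr[1, j]], m[, pr[2, j]]), numeric(1))
  if (all(is.na(r2))) return(NA_real_)
  mean(r2, na.rm = TRUE)
}

#' Windowed genome scan
#'
#' Runs the full nonoverlapping windowed scan: for every window and every
#' population pair, Weir-Cockerham FST, dxy and df; per population,
#' nucleotide diversity; plus the window's mean r-squared over all samples.
#'
#' @param g a [genotype_matrix()].
#' @param pops populations to scan (default all); all unordered pairs are
#'   evaluated.
#' @param size_bp window size in bp.
#' @param chrom_lengths named lengths; defaults to the max site position
#'   per chromosome.
#' @param min_chr minimum called chromosomes per population per site.
#' @return data frame, one row per window per population pair, with columns
#'   `chrom, start, end, partial, n_sites, pop_a, pop_b, fst, dxy, df,
#'   mean_r2` and one `pi_<pop>` column per population.
#' @export
scan_windows <- function(g, pops = unique(g$pop), size_bp = 50000,
                         chrom_lengths = NULL, min_chr = 4) {
  stopifnot(all(pops %in% g$pop))
  if (is.null(chrom_lengths)) {
    chroms <- unique(g$chrom)
    chrom_lengths <- setNames(
      vapply(chroms, function(ch) max(g$pos[g$chrom == ch]), numeric(1)),
      chroms)
  }
  win <- make_windows(chrom_lengths, size_bp)
  pairs <- if (length(pops) >= 2) utils::combn(pops, 2) else
    matrix(character(0), 2, 0)
  rows <- vector("list", nrow(win) * max(1, ncol(pairs)))
  k <- 0
  for (w in seq_len(nrow(win))) {
    ch <- win$chrom[w]; s1 <- win$start[w] + 1; e1 <- win$end[w]
    sites <- sites_in_region(g, ch, s1, e1)
    r2 <- ld_window(g, ch, s1, e1)
    pi_vals <- setNames(vapply(pops, function(p)
      pi_window(g, p, ch, s1, e1), numeric(1)), paste0("pi_", pops))
    for (j in seq_len(max(1, ncol(pairs)))) {
      k <- k + 1
      has_pair <- ncol(pairs) > 0
      row <- data.frame(chrom = ch, start = win$start[w], end = win$end[w],
                        partial = win$partial[w], n_sites = length(sites),
                        pop_a = if (has_pair) pairs[1, j] else NA_character_,
                        pop_b = if (has_pair) pairs[2, j] else NA_character_,
                        fst = if (has_pair)
                          wc_fst_window(g, pairs[1, j], pairs[2, j], ch,
                                        s1, e1, min_chr) else NA_real_,
                        dxy = if (has_pair)
                          dxy_window(g, pairs[1, j], pairs[2, j], ch,
                                     s1, e1, min_chr) else NA_real_,
                        df = if (has_pair)
                          df_window(g, pairs[1, j], pairs[2, j], ch,
                                    s1, e1, min_chr) else NA_real_,
                        mean_r2 = r2, stringsAsFactors = FALSE)
      rows[[k]] <- cbind(row, as.data.frame(as.list(pi_vals)))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Write a scan table as BED-compatible TSV
#'
#' First three columns are `chrom, start, end` (0-based half-open), so the
#' file loads directly into BED-aware tools.
#'
#' @param scan data frame from [scan_windows()].
#' @param path output path.
#' @export
write_scan_tsv <- function(scan, path) {
  write.table(scan, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
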