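# Independent oracle implementations used to cross-check the package's
# statistics. These are deliberately written from different formulations
# (scalar loops, allele-level enumeration, recurrences) than the package
# code paths they validate.

# --- Weir-Cockerham two-population FST, per-site scalar implementation ---
# Follows the 1984 variance-component definitions term by term on a single
# site; window estimate = ratio of sums.
oracle_wc_fst <- function(mA, mB) {
  num <- den <- 0
  for (j in seq_len(ncol(mA))) {
    gA <- mA[!is.na(mA[, j]), j]; gB <- mB[!is.na(mB[, j]), j]
    nA <- length(gA); nB <- length(gB)
    if (nA < 2 || nB < 2) next
    pA <- sum(gA) / (2 * nA); pB <- sum(gB) / (2 * nB)
    hA <- mean(gA == 1); hB <- mean(gB == 1)
    r <- 2
    nbar <- (nA + nB) / 2
    nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (nA + nB)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (nA + nB)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) next
    num <- num + a; den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

# --- per-site pi by enumerating chromosome pairs ---
# expand each called genotype into two allele copies; pi = fraction of
# differing pairs among all chromosome pairs (unbiased: distinct pairs)
oracle_pi_site <- function(genos) {
  g <- genos[!is.na(genos)]
  alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(0)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    if (alleles[i] != alleles[j]) diffs <- diffs + 1
  }
  diffs / pairs
}

# --- per-site dxy by enumerating between-population chromosome pairs ---
oracle_dxy_site <- function(genosA, genosB) {
  expand <- function(g) unlist(lapply(g[!is.na(g)],
                                      function(x) c(rep(1, x), rep(0, 2 - x))))
  a <- expand(genosA); b <- expand(genosB)
  if (!length(a) || !length(b)) return(NA_real_)
  mean(outer(a, b, "!="))
}

# --- HWE exact p via the Levene recurrence on heterozygote counts ---
# weights w(h) proportional to 2^h / (homA! h! homB!) built by the ratio
# w(h+2)/w(h) = 4 homA(h) homB(h) / ((h+1)(h+2))
oracle_hwe <- function(nAA, nAB, nBB, alternative = "two.sided") {
  nA <- 2 * nAA + nAB; nB <- 2 * nBB + nAB
  rare <- min(nA, nB)
  hs <- seq(rare %% 2, rare, by = 2)
  w <- numeric(length(hs)); w[1] <- 1
  if (length(hs) > 1) for (k in 2:length(hs)) {
    h <- hs[k - 1]
    homA <- (nA - h) / 2; homB <- (nB - h) / 2
    w[k] <- w[k - 1] * 4 * homA * homB / ((h + 1) * (h + 2))
  }
  p <- w / sum(w)
  obs <- match(nAB, hs)
  if (alternative == "excess") sum(p[hs >= nAB])
  else min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

# --- HWE by brute-force allele-slot assignment (tiny n only) ---
# place the nA copies of allele A among the 2n ordered slots; slots (1,2),
# (3,4), ... form individuals; tabulate heterozygote counts over all
# assignments
oracle_hwe_bruteforce <- function(nAA, nAB, nBB, alternative = "two.sided") {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  slots <- utils::combn(2 * n, nA)
  het_of <- function(idx) {
    v <- rep(0L, 2 * n); v[idx] <- 1L
    sum(v[seq(1, 2 * n, 2)] != v[seq(2, 2 * n, 2)])
  }
  hets <- apply(slots, 2, het_of)
  tab <- table(hets) / length(hets)
  p_obs <- tab[[as.character(nAB)]]
  if (alternative == "excess") sum(tab[as.numeric(names(tab)) >= nAB])
  else sum(tab[tab <= p_obs * (1 + 1e-12)])
}

# --- mean pairwise r2 by explicit sums ---
oracle_mean_r2 <- function(m) {
  vals <- c()
  for (a in seq_len(ncol(m) - 1)) for (b in (a + 1):ncol(m)) {
    x <- m[, a]; y <- m[, b]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    sxy <- sum(x * y) - sum(x) * sum(y) / n
    sxx <- sum(x^2) - sum(x)^2 / n
    syy <- sum(y^2) - sum(y)^2 / n
    vals <- c(vals, if (sxx == 0 || syy == 0) NA else sxy^2 / (sxx * syy))
  }
  mean(vals, na.rm = TRUE)
}

# --- brute-force greedy LD pruning on a toy matrix ---
oracle_ld_prune_keep <- function(calls, pos, window_bp, r2_max) {
  keep <- rep(TRUE, length(pos))
  for (a in seq_along(pos)) {
    if (!keep[a]) next
    for (b in seq_along(pos)) {
      if (b <= a || !keep[b] || pos[b] - pos[a] > window_bp) next
      x <- calls[, a]; y <- calls[, b]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      if (cor(x[ok], y[ok])^2 > r2_max) keep[b] <- FALSE
    }
  }
  keep
}

# --- Michalsky (1988) approximate solar position ---
oracle_solar_elevation <- function(time, lon, lat) {
  t <- as.POSIXct(time, tz = "UTC")
  jd <- as.numeric(t) / 86400 + 2440587.5
  n <- jd - 2451545
  d2r <- pi / 180
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * d2r
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * d2r
  eps <- (23.439 - 0.0000004 * n) * d2r
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) / d2r
  ra <- ra %% 360
  dec <- asin(sin(eps) * sin(lambda))
  hour <- (as.numeric(t) %% 86400) / 3600
  n0 <- floor(jd - 0.5) + 0.5 - 2451545  # midnight UT of the date
  gmst <- (6.697375 + 0.0657098242 * n0 + 1.0027379 * hour) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- (lmst * 15 - ra + 180) %% 360 - 180
  el <- asin(sin(dec) * sin(lat * d2r) +
               cos(dec) * cos(lat * d2r) * cos(ha * d2r))
  el / d2r
}

# small helper: build a genotype_matrix from a plain dosage matrix
toy_geno <- function(calls, pop, chrom = "LG01",
                     pos = seq_len(ncol(calls)) * 100, ...) {
  genotype_matrix(calls, chrom = rep(chrom, ncol(calls)), pos = pos,
                  sample_ids = sprintf("S%02d", seq_len(nrow(calls))),
                  pop = pop, ...)
}

# planar metres -> lon/lat about a reference point (test-side helper)
xy_to_ll <- function(x, y, lon0, lat0) {
  cbind(lon0 + x / (111320 * cos(lat0 * pi / 180)), lat0 + y / 111320)
}
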