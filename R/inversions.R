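#' Region-restricted PCA of genotype dosages
#'
#' PCA of the SNPs inside one putative inversion region, with
#' smartPCA-style normalization: dosages are mean-centred per SNP and
#' scaled by `sqrt(p(1-p))` where `p = (1 + sum g) / (2 + 2n)` is the
#' shrunk allele frequency; missing dosages are imputed to the column mean
#' before scaling. For a segregating inversion the first axis separates
#' the two homozygote arrangement classes with heterozygotes intermediate.
#'
#' PC1 sign is fixed so that the minor (inverted) homozygote cluster lies
#' on the positive side; see [call_karyotypes()] for the orientation rule.
#'
#' @param g a [genotype_matrix()].
#' @param chrom,start,end region, 1-based inclusive.
#' @return data frame `individual, pc1, pc2` plus attributes
#'   `var_explained` (length-2) and `sites` (column indices used).
#' @export
region_pca <- function(g, chrom, start, end) {
  sites <- sites_in_region(g, chrom, start, end)
  if (length(sites) < 2) stopf("degenerate region: fewer than 2 SNPs")
  if (nrow(g$calls) < 3) stopf("need at least 3 individuals")
  out <- pca_dosage(g$calls[, sites, drop = FALSE], g$sample_ids)
  attr(out, "sites") <- sites[attr(out, "cols_used")]
  out
}

# smartPCA-normalized PCA of a dosage matrix (samples x sites)
pca_dosage <- function(m, sample_ids) {
  keep <- apply(m, 2, function(x) length(unique(na.omit(x))) > 1)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) stopf("degenerate region: fewer than 2 polymorphic SNPs")
  n_called <- colSums(!is.na(m))
  p <- (1 + colSums(m, na.rm = TRUE)) / (2 + 2 * n_called)
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  z <- sweep(sweep(m, 2, mu), 2, sqrt(p * (1 - p)), "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out <- data.frame(individual = sample_ids, pc1 = scores[, 1],
                    pc2 = if (ncol(scores) > 1) scores[, 2] else 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "var_explained") <- ve
  attr(out, "cols_used") <- which(keep)
  out
}

#' Call inversion karyotypes from PC1 scores
#'
#' One-dimensional k-means on PC1 with k chosen from \{1, 2, 3\} — k = 2
#' and 3 compete by average silhouette width, and k = 1 is selected when
#' the best silhouette falls below `min_silhouette` (unstructured PC1 has
#' an expected silhouette near 0.57, well below genuine inversion
#' clusters). Clusters are ordered by centroid; with k = 3 the middle
#' cluster is `het` and the *minor* extreme cluster (fewer chromosomes) is
#' `inv`, since the ancestral arrangement is by definition the more common
#' one. With k = 2 the minor cluster is called `het` (a segregating but
#' inv-homozygote-free region); k = 1 calls everything `anc`.
#'
#' Orientation is validated: the het cluster must have the highest mean
#' observed heterozygosity across the region SNPs; calls are flagged
#' low-confidence if not.
#'
#' @param pc data frame from [region_pca()].
#' @param region_genotypes the [genotype_matrix()] restricted to the
#'   region (or the full matrix; heterozygosity is computed on the sites
#'   recorded in `attr(pc, "sites")` when present).
#' @param min_silhouette silhouette threshold below which k = 1 is used.
#' @param seed k-means seed (tie-breaking).
#' @return data frame `individual, state, pc1, confidence` with attribute
#'   `k` (clusters used) and `low_confidence` flag.
#' @export
call_karyotypes <- function(pc, region_genotypes, min_silhouette = 0.75,
                            seed = 1) {
  local_seed(seed)
  x <- pc$pc1
  sil_for <- function(km) mean(silhouette_1d(x, km$cluster, km$centers))
  km2 <- kmeans(x, centers = quantile(x, c(0.25, 0.75)), nstart = 5)
  km3 <- kmeans(x, centers = quantile(x, c(0.1, 0.5, 0.9)), nstart = 5)
  sils <- c(`2` = sil_for(km2), `3` = sil_for(km3))
  if (max(sils) < min_silhouette) {
    k <- 1L
    cl <- rep(1L, length(x))
    centers <- mean(x)
    conf <- rep(1, length(x))
  } else {
    k <- if (which.max(sils) == 1) 2L else 3L
    km <- if (k == 2) km2 else km3
    cl <- km$cluster; centers <- drop(km$centers)
    conf <- silhouette_1d(x, cl, centers)
  }
  ord <- order(centers)
  rank_of <- match(cl, ord)  # 1 = lowest centroid
  sizes <- tabulate(rank_of, nbins = k)
  if (k == 3L) {
    # minor extreme cluster carries the inverted arrangement
    extremes <- c(1L, k)
    inv_rank <- extremes[which.min(sizes[extremes])]
    state <- character(length(x))
    state[rank_of == 2L] <- "het"
    state[rank_of == inv_rank] <- "inv"
    state[state == ""] <- "anc"
  } else if (k == 2L) {
    minor <- which.min(sizes)
    state <- ifelse(rank_of == minor, "het", "anc")
  } else {
    state <- rep("anc", length(x))
  }

  # orient PC1 so the inverted-homozygote cluster sits on the positive side
  if (k == 3L) {
    inv_mean <- mean(x[state == "inv"])
    anc_mean <- mean(x[state == "anc"])
    if (is.finite(inv_mean) && is.finite(anc_mean) && inv_mean < anc_mean)
      x <- -x
  }

  sites <- attr(pc, "sites")
  m <- if (!is.null(sites)) region_genotypes$calls[, sites, drop = FALSE]
       else region_genotypes$calls
  het_rate <- rowMeans(m == 1L, na.rm = TRUE)
  low_conf <- FALSE
  if (k == 3L) {
    mh <- tapply(het_rate, state, mean)
    if (!("het" %in% names(mh)) ||
        mh[["het"]] < max(mh[setdiff(names(mh), "het")]))
      low_conf <- TRUE
  }
  out <- data.frame(individual = pc$individual, state = state, pc1 = x,
                    confidence = conf, stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "low_confidence") <- low_conf
  out
}

# average silhouette widths for 1-D k-means clusters (centroid distances)
silhouette_1d <- function(x, cluster, centers) {
  k <- length(centers)
  if (k < 2) return(rep(1, length(x)))
  s <- numeric(length(x))
  for (i in seq_along(x)) {
    own <- cluster[i]
    a <- mean(abs(x[i] - x[cluster == own]))
    b <- min(vapply(setdiff(seq_len(k), own), function(cj) {
      xs <- x[cluster == cj]
      if (!length(xs)) Inf else mean(abs(x[i] - xs))
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Tabulate karyotype and arrangement frequencies per population
#'
#' Counts `anc`/`het`/`inv` individuals per population and derives
#' chromosome-level arrangement counts (`anc_chr = 2*anc + het`,
#' `inv_chr = 2*inv + het`). An optional `class_map` (named vector
#' individual -> derived group, e.g. fjord vs North Sea genotype class)
#' adds rows for those derived groups.
#'
#' @param calls data frame from [call_karyotypes()] (columns `individual`,
#'   `state`).
#' @param popmap named character vector mapping individual -> population.
#' @param class_map optional named vector individual -> derived group.
#' @return data frame of class `arrangement_table`: `population, anc, het,
#'   inv, n, anc_chr, inv_chr`.
#' @export
arrangement_frequencies <- function(calls, popmap, class_map = NULL) {
  unknown <- setdiff(calls$individual, names(popmap))
  if (length(unknown))
    stopf("individual(s) without population: %s",
          paste(unknown, collapse = ", "))
  groups <- list()
  pop <- popmap[calls$individual]
  for (p in unique(popmap)) groups[[p]] <- calls$state[pop == p]
  if (!is.null(class_map)) {
    cm <- class_map[calls$individual]
    for (p in setdiff(unique(na.omit(cm)), names(groups)))
      groups[[p]] <- calls$state[!is.na(cm) & cm == p]
  }
  out <- do.call(rbind, lapply(names(groups), function(p) {
    s <- factor(groups[[p]], levels = c("anc", "het", "inv"))
    tb <- table(s)
    data.frame(population = p, anc = as.integer(tb[["anc"]]),
               het = as.integer(tb[["het"]]), inv = as.integer(tb[["inv"]]),
               stringsAsFactors = FALSE)
  }))
  out$n <- out$anc + out$het + out$inv
  out$anc_chr <- 2L * out$anc + out$het
  out$inv_chr <- 2L * out$inv + out$het
  class(out) <- c("arrangement_table", "data.frame")
  out
}

#' Bootstrap test for arrangement over-representation
#'
#' For each population and each arrangement (ancestral, inverted), tests
#' the null hypothesis that the frequency of that arrangement within the
#' population equals its overall frequency across all populations. Each of
#' `B` seeded replicates draws `2n` arrangements Binomial(2n, q) at the
#' pooled frequency `q`; the one-sided p-value is
#' `(1 + #\{replicate count >= observed\}) / (B + 1)`. Bonferroni
#' correction uses the number of tests performed in the call as the family
#' size.
#'
#' Derived-group rows whose individuals are already counted in a source
#' population (e.g. fjord/North Sea genotype classes within one sampling
#' site) can be listed in `exclude_from_pool` so the pooled frequency is
#' not double-counted.
#'
#' @param table an [arrangement_frequencies()] table.
#' @param B bootstrap replicates (default 1e6, minimum 1000).
#' @param seed integer seed.
#' @param exclude_from_pool populations excluded from the pooled frequency
#'   (still tested).
#' @return data frame `population, arrangement, observed, n_chr, pooled_freq,
#'   p_raw, p_bonferroni` with `B` and family size as attributes.
#' @export
bootstrap_overrep_test <- function(table, B = 1e6, seed = 1,
                                   exclude_from_pool = character(0)) {
  stopifnot(inherits(table, "arrangement_table"))
  if (B < 1000) stopf("B < 1000 is rejected (unstable p-values)")
  pool <- table[!(table$population %in% exclude_from_pool), , drop = FALSE]
  if (nrow(pool) < 1) stopf("no populations contribute to the pool")
  if (nrow(pool) < 2)
    warning("single population: the pooled frequency is its own, so the ",
            "test is null by construction", call. = FALSE)
  local_seed(seed)
  q_inv <- sum(pool$inv_chr) / sum(2 * pool$n)
  rows <- list()
  for (i in seq_len(nrow(table))) {
    n2 <- 2L * table$n[i]
    if (n2 == 0) next
    for (arr in c("anc", "inv")) {
      q <- if (arr == "inv") q_inv else 1 - q_inv
      obs <- if (arr == "inv") table$inv_chr[i] else table$anc_chr[i]
      sim <- rbinom(B, n2, q)
      p_raw <- (1 + sum(sim >= obs)) / (B + 1)
      rows[[length(rows) + 1]] <-
        data.frame(population = table$population[i], arrangement = arr,
                   observed = obs, n_chr = n2, pooled_freq = q,
                   p_raw = p_raw, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fam <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * fam)
  attr(out, "B") <- B
  attr(out, "family_size") <- fam
  out
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact p-value from the conditional (Levene) distribution of the
#' heterozygote count given the allele counts: all heterozygote counts of
#' the same parity are enumerated, and the p-value sums the probabilities
#' of configurations no more probable than the observed one (two-sided) or
#' of configurations with at least the observed heterozygote count
#' (`alternative = "excess"`, the one-sided heterozygote-excess test used
#' in site filtering).
#'
#' @param n_anc,n_het,n_inv genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @param alternative `"two.sided"` or `"excess"`.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact <- function(n_anc, n_het, n_inv,
                      alternative = c("two.sided", "excess")) {
  alternative <- match.arg(alternative)
  stopifnot(n_anc >= 0, n_het >= 0, n_inv >= 0)
  n <- n_anc + n_het + n_inv
  if (n == 0) stopf("all genotype counts zero")
  n_a <- 2 * n_anc + n_het  # minor/major irrelevant: symmetric
  n_b <- 2 * n_inv + n_het
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each possible het count (Levene)
  logp <- vapply(hets, function(h) {
    hom_a <- (n_a - h) / 2; hom_b <- (n_b - h) / 2
    if (hom_a < 0 || hom_b < 0) return(-Inf)
    lgamma(n + 1) - lgamma(hom_a + 1) - lgamma(h + 1) - lgamma(hom_b + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs_idx <- match(n_het, hets)
  if (is.na(obs_idx)) stopf("inconsistent genotype counts")
  if (alternative == "excess") {
    sum(p[hets >= n_het])
  } else {
    min(1, sum(p[p <= p[obs_idx] * (1 + 1e-12)]))
  }
}

#' Census of observed karyotype combinations across three regions
#'
#' Enumerates the 27 possible (anc/het/inv)^3 state triples across three
#' inversion regions and reports which are observed. Individuals lacking a
#' call at any region are excluded with a message.
#'
#' @param calls data frame with columns `individual, region, state`
#'   covering three regions.
#' @return list with `possible` (all 27 triples), `observed` (observed
#'   subset), `n_observed`, and `counts` (per observed triple).
#' @export
combination_census <- function(calls) {
  regions <- unique(calls$region)
  if (length(regions) != 3) stopf("need calls at exactly 3 regions")
  wide <- lapply(regions, function(r) {
    s <- calls[calls$region == r, ]
    setNames(s$state, s$individual)
  })
  inds <- Reduce(intersect, lapply(wide, names))
  dropped <- setdiff(unique(calls$individual), inds)
  if (length(dropped))
    message(sprintf("excluded %d individual(s) missing a call", length(dropped)))
  states <- c("anc", "het", "inv")
  possible <- do.call(paste, c(expand.grid(states, states, states,
                                           stringsAsFactors = FALSE)[, 3:1],
                               sep = "/"))
  triple <- paste(wide[[1]][inds], wide[[2]][inds], wide[[3]][inds],
                  sep = "/")
  counts <- table(triple)
  list(possible = possible, observed = sort(unique(triple)),
       n_observed = length(unique(triple)), counts = counts)
}

#' Probability of sampling every karyotype combination
#'
#' Monte-Carlo estimate of the chance that an iid sample of `N` individuals
#' contains all 27 state triples, given per-region genotype (karyotype)
#' frequencies and independent segregation of the regions. With `N < 27`
#' the probability is exactly 0 (pigeonhole) and no simulation runs.
#'
#' @param genotype_freqs list of three length-3 numeric vectors (anc, het,
#'   inv proportions per region, each summing to 1).
#' @param N sample size.
#' @param B Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list `estimate, se, B`.
#' @export
combo_coverage_probability <- function(genotype_freqs, N, B = 1e5, seed = 1) {
  stopifnot(length(genotype_freqs) == 3)
  for (f in genotype_freqs)
    if (abs(sum(f) - 1) > 1e-8) stopf("genotype frequencies must sum to 1")
  p27 <- as.numeric(outer(outer(genotype_freqs[[1]], genotype_freqs[[2]]),
                          genotype_freqs[[3]]))
  if (N < 27 || any(p27 == 0))
    return(list(estimate = 0, se = 0, B = 0))
  local_seed(seed)
  draws <- rmultinom(B, N, p27)
  hits <- colSums(draws > 0) == 27
  est <- mean(hits)
  list(estimate = est, se = sqrt(est * (1 - est) / B), B = B)
}

#' Assign individuals to genotype classes from whole-genome PC scores
#'
#' Nearest-centroid classification on the first two PCs of an
#' inversion-free whole-genome PCA: class centroids are the PC1/PC2 means
#' of reference-labelled individuals; an individual is assigned its nearest
#' centroid's class iff the nearest distance is less than `tau` times the
#' distance to the second-nearest centroid, otherwise `"intermediate"`.
#'
#' @param pc_scores data frame `individual, pc1, pc2` (e.g. from
#'   [genome_pca()]).
#' @param reference_labels named vector individual -> class for the
#'   reference individuals (at least 2 classes).
#' @param tau ambiguity ratio threshold (default 0.5).
#' @return data frame `individual, class, d_nearest, d_second`.
#' @export
assign_genotype_class <- function(pc_scores, reference_labels, tau = 0.5) {
  refs <- intersect(pc_scores$individual, names(reference_labels))
  labs <- reference_labels[refs]
  classes <- unique(labs)
  if (length(refs) < length(classes) || length(classes) < 2)
    stopf("fewer reference individuals than classes")
  cent <- t(vapply(classes, function(cl) {
    rows <- pc_scores$individual %in% refs[labs == cl]
    c(mean(pc_scores$pc1[rows]), mean(pc_scores$pc2[rows]))
  }, numeric(2)))
  d <- sqrt(outer(pc_scores$pc1, cent[, 1], "-")^2 +
              outer(pc_scores$pc2, cent[, 2], "-")^2)
  nearest <- apply(d, 1, which.min)
  d_sorted <- t(apply(d, 1, sort))
  cls <- ifelse(d_sorted[, 1] < tau * d_sorted[, 2],
                classes[nearest], "intermediate")
  data.frame(individual = pc_scores$individual, class = cls,
             d_nearest = d_sorted[, 1], d_second = d_sorted[, 2],
             stringsAsFactors = FALSE)
}

#' Whole-genome PCA excluding inversion-bearing chromosomes
#'
#' Same normalization as [region_pca()] but over all sites outside the
#' excluded chromosomes (by default the four inversion-carrying linkage
#' groups), as used to define population structure unconfounded by the
#' inversions.
#'
#' @param g a [genotype_matrix()].
#' @param exclude_chroms chromosomes to drop.
#' @return data frame `individual, pc1, pc2` with `var_explained`
#'   attribute.
#' @export
genome_pca <- function(g, exclude_chroms = c("LG01", "LG02", "LG07",
                                             "LG12")) {
  keep <- which(!(g$chrom %in% exclude_chroms))
  if (length(keep) < 2) stopf("fewer than 2 sites outside excluded chromosomes")
  out <- pca_dosage(g$calls[, keep, drop = FALSE], g$sample_ids)
  attr(out, "cols_used") <- NULL
  out
}
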