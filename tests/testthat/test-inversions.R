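sim_inversion_genome <- function(freq = c(0.3, 0.3), div = 0.4, seed = 7,
                                 n_per_pop = 100, n_snps = 1500) {
  isp <- inversion_spec("LG01", 1e6, 2e6, freq, pool_divergence = div)
  cfg <- geno_sim_config(n_populations = length(freq),
                         n_per_pop = n_per_pop, n_chromosomes = 1,
                         chrom_length_bp = 3e6, n_snps_per_chrom = n_snps,
                         fst_target = 0.02, inversion_specs = list(isp),
                         missing_rate = 0.02, seed = seed)
  simulate_genotypes(cfg)
}

test_that("region PCA separates arrangements on PC1 and rejects degenerate input", {
  sim <- sim_inversion_genome(freq = c(0.3, 0.3), div = 0.4, seed = 7)
  pc <- region_pca(sim$genotypes, "LG01", 1e6, 2e6)
  ve <- attr(pc, "var_explained")
  expect_gt(ve[1], 3 * ve[2])

  # identical individuals -> degenerate region
  g_flat <- toy_geno(matrix(1L, 5, 4), pop = rep("P", 5))
  expect_error(region_pca(g_flat, "LG01", 1, 1000), "degenerate")
})

test_that("karyotype calls match simulated truth and order heterozygosity", {
  sim <- sim_inversion_genome(freq = c(0.3, 0.3), div = 0.4, seed = 7)
  pc <- region_pca(sim$genotypes, "LG01", 1e6, 2e6)
  kc <- call_karyotypes(pc, sim$genotypes, seed = 1)
  expect_identical(attr(kc, "k"), 3L)
  truth <- sim$truth$karyotype
  acc <- mean(kc$state == truth$karyotype[match(kc$individual,
                                                truth$individual)])
  expect_gte(acc, 0.95)

  # het cluster has the highest mean region heterozygosity
  sites <- attr(pc, "sites")
  het <- rowMeans(sim$genotypes$calls[, sites] == 1L, na.rm = TRUE)
  mh <- tapply(het, kc$state, mean)
  expect_gt(mh[["het"]], mh[["anc"]])
  expect_gt(mh[["het"]], mh[["inv"]])
  expect_false(attr(kc, "low_confidence"))

  # orientation rule: inverted homozygotes on the positive PC1 side
  expect_gt(mean(kc$pc1[kc$state == "inv"]), mean(kc$pc1[kc$state == "anc"]))
})

test_that("karyotype accuracy does not decrease with pool divergence", {
  acc <- vapply(c(0.1, 0.2, 0.4), function(d) {
    sim <- sim_inversion_genome(freq = c(0.3, 0.3), div = d, seed = 17)
    pc <- region_pca(sim$genotypes, "LG01", 1e6, 2e6)
    kc <- call_karyotypes(pc, sim$genotypes, seed = 1)
    truth <- sim$truth$karyotype
    mean(kc$state == truth$karyotype[match(kc$individual,
                                           truth$individual)])
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gte(acc[3], 0.95)
})

test_that("arrangement tables conserve counts and include empty populations", {
  calls <- data.frame(individual = sprintf("I%02d", 1:10),
                      state = rep("het", 10), stringsAsFactors = FALSE)
  popmap <- setNames(rep("P1", 10), calls$individual)
  tab <- arrangement_frequencies(calls, popmap)
  expect_equal(tab$anc_chr, 10L)
  expect_equal(tab$inv_chr, 10L)
  expect_equal(tab$anc_chr + tab$inv_chr, 2L * tab$n)

  # a population in the popmap with no calls gets a zero row
  popmap2 <- c(popmap, EMPTY = "P2")
  names(popmap2)[11] <- "I99"
  tab2 <- arrangement_frequencies(calls, popmap2)
  expect_true("P2" %in% tab2$population)
  expect_equal(tab2$n[tab2$population == "P2"], 0L)

  expect_error(arrangement_frequencies(
    data.frame(individual = "UNKNOWN", state = "anc"), popmap), "UNKNOWN")
})

test_that("bootstrap p-values agree with exact binomial tails", {
  # population at the pooled frequency: p ~ P(X >= 10 | 20, 0.5) = 0.588
  # (each population: 2 anc / 6 het / 2 inv -> 10 inverted of 20 chromosomes)
  tab <- arrangement_frequencies(
    data.frame(individual = sprintf("I%02d", 1:20),
               state = rep(rep(c("anc", "het", "inv"), c(2, 6, 2)), 2)),
    setNames(rep(c("P1", "P2"), each = 10), sprintf("I%02d", 1:20)))
  B <- 2e5
  bt <- bootstrap_overrep_test(tab, B = B, seed = 3)
  p_exact <- pbinom(9, 20, 0.5, lower.tail = FALSE)   # 0.588
  got <- bt$p_raw[bt$population == "P1" & bt$arrangement == "inv"]
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(got - p_exact), 3 * mc_se)

  # extreme observation: p ~ 0.5^20
  tab2 <- arrangement_frequencies(
    data.frame(individual = sprintf("I%02d", 1:20),
               state = rep(c("inv", "anc"), each = 10)),
    setNames(rep(c("P1", "P2"), each = 10), sprintf("I%02d", 1:20)))
  bt2 <- bootstrap_overrep_test(tab2, B = 1e6, seed = 4)
  got2 <- bt2$p_raw[bt2$population == "P1" & bt2$arrangement == "inv"]
  expect_lt(got2, 1e-5)

  # grid of (n, q): max |p_raw - exact tail| < 4 sqrt(p(1-p)/B)
  for (n2 in c(20, 60)) for (obs_frac in c(0.5, 0.7)) {
    n_ind <- n2 / 2
    n_inv_ind <- round(obs_frac * n_ind)
    st <- rep(c("inv", "anc"), c(n_inv_ind, n_ind - n_inv_ind))
    ids <- sprintf("X%03d", seq_len(2 * n_ind))
    tabg <- arrangement_frequencies(
      data.frame(individual = ids, state = c(st, rep(c("anc", "inv"),
                                                     length.out = n_ind))),
      setNames(rep(c("PA", "PB"), each = n_ind), ids))
    btg <- bootstrap_overrep_test(tabg, B = 5e4, seed = 5)
    for (i in seq_len(nrow(btg))) {
      ex <- pbinom(btg$observed[i] - 1, btg$n_chr[i], btg$pooled_freq[i],
                   lower.tail = FALSE)
      expect_lt(abs(btg$p_raw[i] - ex),
                4 * sqrt(max(ex * (1 - ex), 1e-6) / 5e4))
    }
  }

  # single population: null by construction, never significant
  tab1 <- tab[tab$population == "P1", ]
  class(tab1) <- class(tab)
  expect_warning(bt1 <- bootstrap_overrep_test(tab1, B = 2e4, seed = 6),
                 "single population")
  expect_true(all(bt1$p_raw > 0.05))

  expect_error(bootstrap_overrep_test(tab, B = 500), "B < 1000")
})

test_that("HWE exact p matches enumeration oracles and its symmetries", {
  # spec-style toy: (21, 48, 31) against the recurrence oracle
  expect_equal(hwe_exact(21, 48, 31), oracle_hwe(21, 48, 31),
               tolerance = 1e-12)
  # and a brute-force allele-assignment oracle at tiny n
  for (cnt in list(c(2, 2, 1), c(3, 1, 2), c(1, 4, 1))) {
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe_bruteforce(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3], alternative = "excess"),
                 oracle_hwe_bruteforce(cnt[1], cnt[2], cnt[3],
                                       alternative = "excess"),
                 tolerance = 1e-10)
  }
  # monomorphic
  expect_equal(hwe_exact(10, 0, 0), 1)
  # label-swap symmetry
  expect_equal(hwe_exact(21, 48, 31), hwe_exact(31, 48, 21))
  expect_error(hwe_exact(0, 0, 0), "zero")
})

test_that("the combination census enumerates exactly 27 triples", {
  mk_calls <- function(states_by_region) {
    do.call(rbind, lapply(names(states_by_region), function(r)
      data.frame(individual = sprintf("I%03d",
                                      seq_along(states_by_region[[r]])),
                 region = r, state = states_by_region[[r]],
                 stringsAsFactors = FALSE)))
  }
  one <- mk_calls(list(R1 = "anc", R2 = "het", R3 = "inv"))
  cen1 <- combination_census(one)
  expect_length(cen1$possible, 27)
  expect_equal(cen1$n_observed, 1)

  # individuals covering all 27 triples
  grid <- expand.grid(s1 = c("anc", "het", "inv"),
                      s2 = c("anc", "het", "inv"),
                      s3 = c("anc", "het", "inv"),
                      stringsAsFactors = FALSE)
  all27 <- mk_calls(list(R1 = grid$s1, R2 = grid$s2, R3 = grid$s3))
  cen <- combination_census(all27)
  expect_equal(cen$n_observed, 27)
  expect_setequal(cen$observed, cen$possible)

  # an individual missing a call is excluded with a message
  partial <- rbind(all27, data.frame(individual = "I999", region = "R1",
                                     state = "anc"))
  expect_message(combination_census(partial), "excluded 1")
})

test_that("coverage probability obeys pigeonhole and matches an independent MC", {
  zero <- list(c(0.5, 0.5, 0), c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25))
  expect_equal(combo_coverage_probability(zero, 204)$estimate, 0)
  hwe <- rep(list(c(0.25, 0.5, 0.25)), 3)
  expect_equal(combo_coverage_probability(hwe, 26)$estimate, 0)

  est <- combo_coverage_probability(hwe, 204, B = 4e4, seed = 8)
  # independent MC: sample triples directly
  set.seed(999)
  p27 <- as.numeric(outer(outer(hwe[[1]], hwe[[2]]), hwe[[3]]))
  B2 <- 4e4
  hits <- vapply(seq_len(B2), function(i)
    length(unique(sample.int(27, 204, replace = TRUE, prob = p27))) == 27,
    logical(1))
  est2 <- mean(hits)
  se <- sqrt(est$se^2 + est2 * (1 - est2) / B2)
  expect_lt(abs(est$estimate - est2), 3 * se)
})

test_that("genotype-class assignment uses the nearest-centroid ambiguity rule", {
  # constructed PC scores: three tight reference clusters + admixed points
  set.seed(12)
  mk <- function(n, cx, cy) data.frame(pc1 = rnorm(n, cx, 0.05),
                                       pc2 = rnorm(n, cy, 0.05))
  ref <- rbind(cbind(mk(20, -1, 0), class = "TVEf"),
               cbind(mk(20, 1, 0), class = "TVEn"),
               cbind(mk(20, 0, 1.5), class = "KIE"))
  adm <- cbind(mk(30, 0, 0.05), class = "admixed")  # between TVEf and TVEn
  pcs <- data.frame(individual = sprintf("I%03d", seq_len(nrow(ref) +
                                                            nrow(adm))),
                    pc1 = c(ref$pc1, adm$pc1), pc2 = c(ref$pc2, adm$pc2),
                    stringsAsFactors = FALSE)
  labels <- setNames(ref$class, pcs$individual[seq_len(nrow(ref))])
  res <- assign_genotype_class(pcs, labels, tau = 0.5)

  ref_res <- res[seq_len(nrow(ref)), ]
  expect_gt(mean(ref_res$class == ref$class), 0.95)
  adm_res <- res[-seq_len(nrow(ref)), ]
  expect_gte(mean(adm_res$class == "intermediate"), 0.8)

  # an individual exactly at a centroid gets that class
  cent_f <- c(mean(ref$pc1[ref$class == "TVEf"]),
              mean(ref$pc2[ref$class == "TVEf"]))
  pcs2 <- rbind(pcs, data.frame(individual = "AT_CENTROID",
                                pc1 = cent_f[1], pc2 = cent_f[2]))
  res2 <- assign_genotype_class(pcs2, labels, tau = 0.5)
  expect_equal(res2$class[res2$individual == "AT_CENTROID"], "TVEf")

  expect_error(assign_genotype_class(pcs, labels[1], tau = 0.5), "fewer")
})
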