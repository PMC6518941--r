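test_that("null simulations are calibrated: estimates within 2 SE per coefficient", {
  co <- c("(Intercept)" = 0, "genotypeTVEf" = 0, "length" = 0,
          "sexmale" = 0)
  n_rep <- 100
  within <- matrix(NA, n_rep, 4)
  for (r in seq_len(n_rep)) {
    s <- simulate_trait_tables(48, 12, ~ genotype + length + sex, co,
                               sd_id = 1, sd_res = 1, seed = 10000 + r)
    f <- fit_trait_lmm(s$data, model_spec("trait", "genotype + length + sex"))
    within[r, ] <- abs(f$coefficients$estimate) < 2 * f$coefficients$se
  }
  # per-coefficient coverage of the ~95% Wald band must exceed 90%
  expect_true(all(colMeans(within) >= 0.9))
})

test_that("the mixed model recovers ICC and the variance partition", {
  s <- simulate_trait_tables(200, 12, ~ length, c("(Intercept)" = 5,
                                                  "length" = 0),
                             sd_id = sqrt(1 / 3), sd_res = 1, seed = 202)
  f <- fit_trait_lmm(s$data, model_spec("trait", "length"))
  expect_lt(abs(f$icc - 0.25), 0.05)
  vp <- variance_partition(f)
  expect_true(vp[["icc"]] >= 0 && vp[["icc"]] <= 1)
  expect_lt(vp[["marginal_r2"]], 0.02)   # null fixed effects

  # near-zero ICC: dropping the random intercept barely moves estimates
  s0 <- simulate_trait_tables(100, 12, ~ length,
                              c("(Intercept)" = 2, "length" = 0.1),
                              sd_id = 1e-4, sd_res = 1, seed = 203)
  suppressWarnings({
    fm <- fit_trait_lmm(s0$data, model_spec("trait", "length"))
    fl <- fit_trait_lmm(s0$data, model_spec("trait", "length",
                                            random_intercept = FALSE))
  })
  d <- abs(coef(fm)[["length"]] - coef(fl)[["length"]])
  expect_lt(d, fm$coefficients$se[fm$coefficients$term == "length"])
})

test_that("AIC selection ranks by AIC with ties to fewer parameters", {
  set.seed(7)
  d <- data.frame(fish_id = rep(sprintf("F%02d", 1:30), each = 6),
                  y = rnorm(180), x = rnorm(180))
  d$z <- d$x   # collinear duplicate: identical fit, no extra information
  sel <- suppressWarnings(suppressMessages(
    aic_select(list(model_spec("y", "x", random_intercept = FALSE),
                    model_spec("y", "x + z", random_intercept = FALSE)),
               d)))
  # identical-fit nested models: the simpler one is selected
  expect_identical(sel$selected$fixed, "x")
  expect_equal(nrow(sel$table), 2)
  expect_true(all(diff(sel$table$aic) >= 0))
  # refitting the selected model reproduces its AIC exactly
  f2 <- fit_trait_lmm(d, sel$selected)
  expect_equal(f2$aic, sel$selected_fit$aic)
})

test_that("precomputed AIC ladders select the published winners", {
  # home-range ladder (AIC values as given inputs)
  hr <- data.frame(
    model = c("S'LG02 + S'LG07 + S'LG12 + S'L + S'GS",
              "S'LG02 + S'LG07 + S'LG12 + S'L + GS",
              "S'LG02 + S'LG07 + S'LG12 + S'L",
              "S'LG02 + S'LG07 + S'LG12 + L",
              "S'LG02 + S'LG07 + LG12 + S'L",
              "S'LG02 + S'LG07 + S'L",
              "S'LG02 + LG07 + S'L",
              "LG02 + S'LG07 + S'L",
              "S'LG07 + S'L",
              "S'L"),
    aic = c(1689.3, 1687.3, 1685.7, 1695.0, 1683.4, 1679.9, 1683.3,
            1677.8, 1677.0, 1677.3))
  expect_equal(select_min_aic(hr)$aic, 1677.0)
  expect_equal(select_min_aic(hr)$model, "S'LG07 + S'L")

  # survival ladder
  sv <- data.frame(
    model = c("LG02 + LG07 + LG12 + L + GS", "LG02 + LG07 + LG12 + L",
              "LG02 + LG07 + LG12", "LG02 + LG12 + L", "LG12 + L",
              "LG12", "L"),
    aic = c(51.4, 51.9, 52.5, 47.9, 44.5, 44.8, 47.7))
  expect_equal(select_min_aic(sv)$aic, 44.5)
  expect_equal(select_min_aic(sv)$model, "LG12 + L")

  # ties break toward fewer parameters
  tie <- data.frame(model = c("big", "small"), aic = c(10, 10),
                    df = c(5, 3))
  expect_equal(select_min_aic(tie)$model, "small")
})

test_that("the two-step ladder keeps the season x LG07 interaction when generated", {
  eff <- default_behaviour_effects()$home_range
  n_rep <- 100
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    s <- simulate_trait_tables(eff$n_fish, eff$n_months, eff$formula,
                               eff$coefficients, sd_id = eff$sd_id,
                               sd_res = eff$sd_res,
                               response_name = "log_hr", seed = 30000 + r)
    sel <- aic_select(list(
      model_spec("log_hr", "season * lg07 + season * length"),
      model_spec("log_hr", "lg07 + season * length"),
      model_spec("log_hr", "season * length")), s$data)
    hits[r] <- sel$selected$fixed == "season * lg07 + season * length"
  }
  expect_gte(mean(hits), 0.7)
})

test_that("the two-step ladder orders size/sex before inversion structure", {
  eff <- default_behaviour_effects()$home_range
  s <- simulate_trait_tables(eff$n_fish, eff$n_months, eff$formula,
                             eff$coefficients, sd_id = eff$sd_id,
                             sd_res = eff$sd_res, response_name = "log_hr",
                             seed = 999)
  lad <- aic_two_step(s$data, "log_hr",
                      inversion_full = "season * lg07",
                      size_sex_options = c("season * length + season * sex",
                                           "season * length + sex",
                                           "season * length"),
                      inversion_options = c("season * lg07", "lg07", ""))
  expect_s3_class(lad$step1, "aic_selection")
  expect_s3_class(lad$step2, "aic_selection")
  # the final model carries terms from both steps
  expect_true(grepl("length", lad$selected$fixed))
})

test_that("the selection model estimates gradients and respects conservation", {
  # identical S for all fish: zero slopes, intercept 1
  set.seed(11)
  d <- data.frame(
    fish_id = sprintf("F%02d", 1:40), S = 1,
    length = rnorm(40, 46, 8),
    lg12 = factor(sample(c("anc", "het", "inv"), 40, TRUE),
                  c("anc", "het", "inv")))
  f <- suppressWarnings(fit_selection_model(d, "lg12 + length"))
  est <- coef(f)
  expect_equal(unname(est[["(Intercept)"]]), 1, tolerance = 1e-10)
  expect_true(all(abs(est[names(est) != "(Intercept)"]) < 1e-10))

  # genotype-class variant recovers a configured North Sea survival deficit
  co <- c("(Intercept)" = 1.1, "genotypeTVEf" = 0.27)
  est_g <- vapply(1:40, function(r) {
    s <- simulate_relative_longevity(64, ~ genotype, co, sd_res = 0.4,
                                     seed = 40000 + r)
    # recode with TVEf as reference so the TVEn deficit is the coefficient
    s$data$genotype <- stats::relevel(s$data$genotype, "TVEf")
    coef(fit_selection_model(s$data, "genotype"))[["genotypeTVEn"]]
  }, numeric(1))
  expect_lt(abs(mean(est_g) - (-0.27)), 3 * sd(est_g) / sqrt(40))

  # relative-longevity conservation: mean fitted response is 1 on any
  # included set
  fates <- data.frame(fish_id = sprintf("F%02d", 1:30),
                      fate = rep(c("dead", "alive"), 15),
                      days_survived = runif(30, 50, 600))
  class(fates) <- c("fate_table", "data.frame")
  s <- relative_longevity(fates)
  s$length <- rnorm(30, 46, 8)
  fs <- fit_selection_model(s, "length")
  expect_equal(mean(fitted(fs$fit)), 1, tolerance = 1e-12)
})
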