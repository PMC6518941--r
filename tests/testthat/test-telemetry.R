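utc <- function(s) as.POSIXct(s, tz = "UTC")

mk_det <- function(fish, times, rec = "R01", lon = 8.93, lat = 58.62,
                   depth = 10) {
  data.frame(fish_id = fish, timestamp = times, receiver_id = rec,
             lon = lon, lat = lat, depth_m = depth,
             stringsAsFactors = FALSE)
}

test_that("false-detection filtering enforces the per-day minimum", {
  d <- rbind(
    mk_det("F1", utc("2012-06-01 10:00:00")),                 # 1/day: drop
    mk_det("F1", utc(c("2012-06-02 10:00:00",
                       "2012-06-02 11:00:00"))),              # 2/day: keep
    mk_det("F2", utc("2012-06-01 12:00:00")))                 # 1/day: drop
  f <- filter_false_detections(d)
  expect_equal(nrow(f), 2)
  expect_true(all(format(f$timestamp, "%d") == "02"))

  # injected 1/day noise removed, dense true track intact
  cfg <- telem_sim_config(n_fish = 1, study_days = 10, seed = 91)
  sim <- simulate_detections(cfg)
  noise <- mk_det("GHOST", utc("2012-03-22 03:00:00") + (0:9) * 86400)
  ff <- filter_false_detections(rbind(sim$detections, noise))
  expect_false(any(ff$fish_id == "GHOST"))
  expect_equal(sum(ff$fish_id == "F001"), nrow(sim$detections))
})

test_that("post-mortem truncation finds the flat tail and spares moving fish", {
  t0 <- utc("2012-06-01 00:00:00")
  times <- t0 + seq(0, 20 * 86400, by = 600)
  n <- length(times)
  moving <- 10 + 3 * sin(seq_len(n) / 20) + rnorm(n, 0, 0.5)
  dead_at <- times >= t0 + 10 * 86400
  depth <- ifelse(dead_at, 7.25, moving)
  d <- mk_det("F1", times, depth = depth)
  tr <- truncate_post_mortem(d)
  expect_true(tr$flags$flagged_dead)
  expect_lt(abs(as.numeric(tr$flags$t_death - (t0 + 10 * 86400),
                           units = "hours")), 24)
  expect_true(all(tr$detections$timestamp <= tr$flags$t_death))

  # continuously moving fish untouched
  d2 <- mk_det("F2", times, depth = moving)
  tr2 <- truncate_post_mortem(d2)
  expect_false(tr2$flags$flagged_dead)
  expect_equal(nrow(tr2$detections), n)

  # all-constant record flagged from the first record
  d3 <- mk_det("F3", times, depth = 5)
  tr3 <- truncate_post_mortem(d3)
  expect_true(tr3$flags$flagged_dead)
  expect_equal(tr3$flags$t_death, times[1])
})

test_that("COAs are detection-weighted receiver means and conserve counts", {
  t0 <- utc("2012-06-01 12:00:00")
  d <- rbind(mk_det("F1", t0 + 1:3, rec = "RA", lon = 8.90, lat = 58.60,
                    depth = 10),
             mk_det("F1", t0 + 4, rec = "RB", lon = 8.94, lat = 58.64,
                    depth = 20))
  coa <- compute_coa(d)
  expect_equal(nrow(coa), 1)
  expect_equal(coa$lon, 0.75 * 8.90 + 0.25 * 8.94)
  expect_equal(coa$lat, 0.75 * 58.60 + 0.25 * 58.64)
  expect_equal(coa$depth_m, 0.75 * 10 + 0.25 * 20)
  expect_equal(coa$n_detections, 4L)
  expect_equal(as.numeric(coa$bin_start) %% 1800, 0)

  # conservation across many bins
  cfg <- telem_sim_config(n_fish = 2, study_days = 5, seed = 92)
  sim <- simulate_detections(cfg)
  coa2 <- compute_coa(sim$detections)
  expect_equal(sum(coa2$n_detections), nrow(sim$detections))
})

test_that("day/night classification agrees with an independent ephemeris", {
  # canonical checks at 58.62N
  expect_equal(classify_daynight(utc("2012-06-21 11:00:00"), 8.93, 58.62),
               "day")    # ~ local solar noon in June
  expect_equal(classify_daynight(utc("2012-06-21 23:30:00"), 8.93, 58.62),
               "night")  # ~ local midnight
  expect_equal(classify_daynight(utc("2012-12-21 12:00:00"), 8.93, 58.62),
               "day")
  expect_equal(classify_daynight(utc("2012-12-21 20:00:00"), 8.93, 58.62),
               "night")

  # sunrise crossing within +/- 2 min of the Michalsky oracle over a year
  for (m in 1:12) {
    day0 <- utc(sprintf("2012-%02d-15 00:00:00", m))
    grid <- day0 + seq(0, 86399, by = 30)
    el_pkg <- solar_elevation(grid, 8.93, 58.62)
    el_orc <- oracle_solar_elevation(grid, 8.93, 58.62)
    cross <- function(el) grid[which(el[-1] > 0 & el[-length(el)] <= 0)[1]]
    t_pkg <- cross(el_pkg); t_orc <- cross(el_orc)
    expect_lt(abs(as.numeric(t_pkg - t_orc, units = "mins")), 2)
  }
})

test_that("monthly DVM and daytime depth follow their definitions", {
  # two COAs per day at local solar noon and midnight, June (day at noon,
  # night at midnight at this latitude)
  days <- utc("2012-06-01 11:00:00") + (0:19) * 86400
  coa <- rbind(
    data.frame(fish_id = "F1", bin_start = days, lon = 8.93, lat = 58.62,
               depth_m = 10, n_detections = 1L),
    data.frame(fish_id = "F1", bin_start = days + 12.5 * 3600, lon = 8.93,
               lat = 58.62, depth_m = 4, n_detections = 1L))
  dvm <- monthly_dvm(coa)
  expect_equal(dvm$dvm_m, 6)

  # constant depth: DVM 0
  coa0 <- coa; coa0$depth_m <- 8
  expect_equal(monthly_dvm(coa0)$dvm_m, 0)

  # day-weighted daytime depth: two days at 10 m and 20 m with unequal
  # detection counts average to 15
  d1 <- utc("2012-06-01 11:00:00"); d2 <- utc("2012-06-02 11:00:00")
  coa_d <- data.frame(fish_id = "F1",
                      bin_start = c(d1, d1 + 1800, d1 + 3600, d2),
                      lon = 8.93, lat = 58.62,
                      depth_m = c(10, 10, 10, 20),
                      n_detections = c(5L, 5L, 5L, 1L))
  dd <- monthly_mean_daytime_depth(coa_d)
  expect_equal(dd$daytime_depth_m, 15)
  expect_equal(dd$n_days, 2L)
})

test_that("kernel home ranges match the bivariate-normal analytic area", {
  lon0 <- 8.93; lat0 <- 58.62
  mk_coa <- function(n, sigma_m, month_start, seed) {
    set.seed(seed)
    ll <- xy_to_ll(rnorm(n, 0, sigma_m), rnorm(n, 0, sigma_m), lon0, lat0)
    # spread over 25 distinct days so presence thresholds pass
    data.frame(fish_id = "F1",
               bin_start = utc(month_start) +
                 rep(seq(0, 24, by = 1) * 86400, length.out = n) +
                 (seq_len(n) %% 40) * 1800,
               lon = ll[, 1], lat = ll[, 2], depth_m = 10,
               n_detections = 1L)
  }
  coa <- mk_coa(500, 100, "2012-06-01 00:00:00", seed = 42)
  hr <- monthly_home_range(coa, prob = 0.95, min_days = 20, min_coas = 30)
  analytic <- pi * 5.9915 * 100^2 / 1e6     # 0.188 km2
  expect_lt(abs(hr$home_range_km2 - analytic) / analytic, 0.15)

  # doubling sigma roughly quadruples the area
  coa2 <- mk_coa(500, 200, "2012-06-01 00:00:00", seed = 43)
  hr2 <- monthly_home_range(coa2, prob = 0.95, min_days = 20, min_coas = 30)
  expect_lt(abs(hr2$home_range_km2 / hr$home_range_km2 - 4), 0.5)

  # 50% area strictly below 95% area
  set.seed(44)
  x <- rnorm(300, 0, 150); y <- rnorm(300, 0, 150)
  expect_lt(kud_area(x, y, prob = 0.5), kud_area(x, y, prob = 0.95))

  # under 20 days present: no estimate
  coa19 <- coa[as.numeric(coa$bin_start - coa$bin_start[1],
                          units = "days") < 18, ]
  hr19 <- monthly_home_range(coa19, min_days = 20, min_coas = 30)
  expect_true(all(is.na(hr19$home_range_km2)))
})

test_that("fate classification separates dead, dispersed and alive fish", {
  cfg <- telem_sim_config(n_fish = 6, study_days = 40, fraction_dying = 1 / 3,
                          fraction_dispersing = 1 / 3, seed = 93)
  sim <- simulate_detections(cfg)
  fates <- classify_fate(filter_false_detections(sim$detections),
                         sim$receivers, tagging_date = cfg$start,
                         battery_end = cfg$start + 40 * 86400)
  got <- setNames(fates$fate, fates$fish_id)
  truth <- setNames(sim$truth$fate, sim$truth$fish_id)
  expect_identical(got[names(truth)], truth)

  # each fish gets exactly one fate
  expect_equal(anyDuplicated(fates$fish_id), 0)

  # dead fish: death day within 2 days of truth
  dd <- merge(fates, sim$truth)
  dead <- dd[dd$fate == "dead", ]
  expect_true(all(abs(dead$days_survived - dead$death_day) <= 2))
})

test_that("relative longevity excludes dispersers and averages to one", {
  fates <- data.frame(fish_id = c("A", "B", "C"),
                      fate = c("dead", "alive", "dispersed"),
                      days_survived = c(100, 300, 50),
                      stringsAsFactors = FALSE)
  class(fates) <- c("fate_table", "data.frame")
  s <- relative_longevity(fates)
  expect_equal(nrow(s), 2)
  expect_equal(s$S, c(0.5, 1.5))
  expect_equal(mean(s$S), 1)

  all_disp <- fates; all_disp$fate <- "dispersed"
  expect_error(relative_longevity(all_disp), "dispersed")
})
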