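#' Configuration for the acoustic-telemetry simulator
#'
#' Emulates a fixed array of ultrasonic receivers logging depth-coded
#' transmitter pings from tagged fish. The default array is a regular grid
#' of 33 receivers over a 3 km x 1 km rectangle (schematic fjord geometry).
#' Transmitters ping at random intervals of 110-250 s; depth follows a mean
#' level plus a diel cycle (deeper by day when `diel_amplitude_m > 0`) and
#' mean-reverting (OU-style) noise; horizontal movement is a reflected
#' random walk inside the array. A configurable fraction of fish die
#' (constant-depth transmissions from the death day until battery end) or
#' disperse (monotone movement to the array edge, then silence).
#'
#' The diel term is a sinusoid in local solar time whose peak is scaled so
#' that the analytic day-minus-night depth difference equals
#' `diel_amplitude_m` (see the methods vignette).
#'
#' @param n_fish number of tagged fish.
#' @param n_receivers number of receivers (default 33).
#' @param receiver_layout optional data frame `receiver_id, lon, lat`;
#'   default is a regular grid over a 3 km x 1 km rectangle centred on
#'   `(centre_lon, centre_lat)`.
#' @param centre_lon,centre_lat array centre in degrees.
#' @param transmit_interval_s length-2 range of seconds between pings.
#' @param study_days length of the study; battery life equals this.
#' @param start start of the study (tagging date for all fish), `Date` or
#'   ISO string; default `"2012-03-20"`.
#' @param depth_mean_m,diel_amplitude_m,depth_noise_sd_m depth process:
#'   mean depth, day-minus-night difference, OU stationary noise sd.
#' @param depth_reversion_hr OU mean-reversion time constant in hours.
#' @param step_sd_m random-walk step sd per ping, metres.
#' @param detection_range_m detection-probability range rho in
#'   `p = exp(-d / rho)`.
#' @param fraction_dying,fraction_dispersing fractions of fish assigned
#'   those fates (the rest remain alive to battery end).
#' @param death_day if non-`NULL`, all dying fish die on this study day;
#'   otherwise death days are uniform over the middle of the study.
#' @param genotype_depth_effect_m additive depth offset for fish of the
#'   `"deep"` genotype class (half the fish); 0 disables.
#' @param tz time zone used downstream for day/month bucketing.
#' @param seed integer seed.
#' @return list of class `telem_sim_config`.
#' @export
telem_sim_config <- function(n_fish = 10, n_receivers = 33,
                             receiver_layout = NULL,
                             centre_lon = 8.93, centre_lat = 58.62,
                             transmit_interval_s = c(110, 250),
                             study_days = 120, start = "2012-03-20",
                             depth_mean_m = 15, diel_amplitude_m = 4,
                             depth_noise_sd_m = 1.5, depth_reversion_hr = 2,
                             step_sd_m = 60, detection_range_m = 250,
                             fraction_dying = 0, fraction_dispersing = 0,
                             death_day = NULL, genotype_depth_effect_m = 0,
                             tz = "Europe/Oslo", seed = 1) {
  stopifnot(all(transmit_interval_s > 0), depth_mean_m >= 0,
            fraction_dying + fraction_dispersing <= 1, study_days >= 1)
  if (is.null(receiver_layout)) {
    if (n_receivers < 1) stop("no detection possible: zero receivers")
    nx <- ceiling(sqrt(n_receivers * 3)); ny <- ceiling(n_receivers / nx)
    gx <- seq(-1500, 1500, length.out = nx)
    gy <- seq(-500, 500, length.out = ny)
    grid <- expand.grid(x = gx, y = gy)[seq_len(n_receivers), ]
    receiver_layout <- data.frame(
      receiver_id = sprintf("R%02d", seq_len(n_receivers)),
      lon = centre_lon + grid$x / (111320 * cos(centre_lat * pi / 180)),
      lat = centre_lat + grid$y / 111320)
  }
  if (nrow(receiver_layout) < 1) stop("no detection possible: zero receivers")
  structure(list(n_fish = n_fish, receiver_layout = receiver_layout,
                 centre_lon = centre_lon, centre_lat = centre_lat,
                 transmit_interval_s = transmit_interval_s,
                 study_days = study_days,
                 start = as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
                 depth_mean_m = depth_mean_m,
                 diel_amplitude_m = diel_amplitude_m,
                 depth_noise_sd_m = depth_noise_sd_m,
                 depth_reversion_hr = depth_reversion_hr,
                 step_sd_m = step_sd_m, detection_range_m = detection_range_m,
                 fraction_dying = fraction_dying,
                 fraction_dispersing = fraction_dispersing,
                 death_day = death_day,
                 genotype_depth_effect_m = genotype_depth_effect_m,
                 tz = tz, seed = seed),
            class = "telem_sim_config")
}

# local planar metres about the array centre (equirectangular)
lonlat_to_xy <- function(lon, lat, lon0, lat0) {
  cbind(x = (lon - lon0) * 111320 * cos(lat0 * pi / 180),
        y = (lat - lat0) * 111320)
}
xy_to_lonlat <- function(x, y, lon0, lat0) {
  cbind(lon = lon0 + x / (111320 * cos(lat0 * pi / 180)),
        lat = lat0 + y / 111320)
}

#' Simulate acoustic detection records
#'
#' Runs the movement/depth/fate model described in [telem_sim_config()] and
#' returns the detection log a real receiver array would produce, together
#' with the ground truth per fish.
#'
#' @param cfg a [telem_sim_config()].
#' @return list with `detections` (data frame `fish_id, timestamp,
#'   receiver_id, lon, lat, depth_m`, timestamps POSIXct UTC), `truth`
#'   (data frame per fish: fate, death/dispersal day, genotype class,
#'   tagging date, battery end) and `receivers` (the layout).
#' @export
simulate_detections <- function(cfg) {
  stopifnot(inherits(cfg, "telem_sim_config"))
  local_seed(cfg$seed)
  rec <- cfg$receiver_layout
  rxy <- lonlat_to_xy(rec$lon, rec$lat, cfg$centre_lon, cfg$centre_lat)
  xr <- range(rxy[, 1]); yr <- range(rxy[, 2])
  battery_end <- cfg$start + cfg$study_days * 86400

  n <- cfg$n_fish
  fate <- rep("alive", n)
  n_die <- round(cfg$fraction_dying * n)
  n_disp <- round(cfg$fraction_dispersing * n)
  fate[seq_len(n_die)] <- "dead"
  if (n_disp > 0) fate[n_die + seq_len(n_disp)] <- "dispersed"
  death_day <- ifelse(fate == "dead",
                      if (!is.null(cfg$death_day)) cfg$death_day else
                        runif(n, 0.3, 0.8) * cfg$study_days, NA_real_)
  disp_day <- ifelse(fate == "dispersed",
                     runif(n, 0.3, 0.8) * cfg$study_days, NA_real_)
  gclass <- rep(c("deep", "shallow"), length.out = n)
  # outermost receiver: farthest from the receiver centroid
  rcen <- colMeans(rxy)
  out_idx <- which.max((rxy[, 1] - rcen[1])^2 + (rxy[, 2] - rcen[2])^2)

  res <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- cfg$start +
      cumsum(runif(ceiling(cfg$study_days * 86400 / cfg$transmit_interval_s[1]) + 10,
                   cfg$transmit_interval_s[1], cfg$transmit_interval_s[2]))
    tt <- tt[tt <= battery_end]
    m <- length(tt)
    day_frac <- as.numeric(tt - cfg$start, units = "days")

    # depth: mean + diel sinusoid (peak pi/4 * amplitude) + OU noise
    solar_hr <- ((as.numeric(tt) %% 86400) / 3600 + cfg$centre_lon / 15) %% 24
    mu <- cfg$depth_mean_m +
      (pi / 4) * cfg$diel_amplitude_m * cos(2 * pi * (solar_hr - 12) / 24) +
      if (gclass[i] == "deep") cfg$genotype_depth_effect_m else 0
    dt_hr <- c(0, diff(as.numeric(tt)) / 3600)
    phi <- exp(-dt_hr / cfg$depth_reversion_hr)
    e <- numeric(m)
    e[1] <- rnorm(1, 0, cfg$depth_noise_sd_m)
    innov <- rnorm(m, 0, 1)
    for (k in 2:m)
      e[k] <- e[k - 1] * phi[k] +
        cfg$depth_noise_sd_m * sqrt(1 - phi[k]^2) * innov[k]
    depth <- pmax(0, mu + e)

    # horizontal reflected random walk inside the array rectangle
    sx <- rnorm(m, 0, cfg$step_sd_m); sy <- rnorm(m, 0, cfg$step_sd_m)
    x <- reflect_walk(runif(1, xr[1], xr[2]) + cumsum(sx), xr)
    y <- reflect_walk(runif(1, yr[1], yr[2]) + cumsum(sy), yr)

    if (fate[i] == "dead") {
      dead <- day_frac >= death_day[i]
      if (any(dead)) {
        k0 <- which(dead)[1]
        depth[dead] <- depth[max(1, k0 - 1)]   # constant-depth tail
        x[dead] <- x[max(1, k0 - 1)]; y[dead] <- y[max(1, k0 - 1)]
      }
    } else if (fate[i] == "dispersed") {
      # move monotonically to the outermost receiver over ~2 days, then silence
      ramp <- day_frac >= disp_day[i] & day_frac < disp_day[i] + 2
      gone <- day_frac >= disp_day[i] + 2
      if (any(ramp)) {
        w <- (day_frac[ramp] - disp_day[i]) / 2
        k0 <- which(ramp)[1]
        x[ramp] <- x[k0] + w * (rxy[out_idx, 1] - x[k0])
        y[ramp] <- y[k0] + w * (rxy[out_idx, 2] - y[k0])
      }
      keep <- !gone
      tt <- tt[keep]; depth <- depth[keep]; x <- x[keep]; y <- y[keep]
      m <- length(tt)
    }

    # detection: every receiver within hearing logs independently
    d2 <- outer(x, rxy[, 1], "-")^2 + outer(y, rxy[, 2], "-")^2
    pdet <- exp(-sqrt(d2) / cfg$detection_range_m)
    hit <- matrix(runif(length(pdet)) < pdet, nrow = m)
    idx <- which(hit, arr.ind = TRUE)
    if (!nrow(idx)) { res[[i]] <- NULL; next }
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    res[[i]] <- data.frame(
      fish_id = sprintf("F%03d", i),
      timestamp = tt[idx[, 1]],
      receiver_id = rec$receiver_id[idx[, 2]],
      lon = rec$lon[idx[, 2]], lat = rec$lat[idx[, 2]],
      depth_m = round(depth[idx[, 1]], 2), stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, res)
  rownames(det) <- NULL
  truth <- data.frame(fish_id = sprintf("F%03d", seq_len(n)),
                      fate = fate, death_day = death_day,
                      dispersal_day = disp_day, genotype_class = gclass,
                      tagging_date = cfg$start, battery_end = battery_end,
                      stringsAsFactors = FALSE)
  list(detections = det, truth = truth, receivers = rec)
}

# reflect a random walk into [r[1], r[2]]
reflect_walk <- function(v, r) {
  w <- r[2] - r[1]
  u <- (v - r[1]) %% (2 * w)
  r[1] + ifelse(u > w, 2 * w - u, u)
}

#' Write a detection table as CSV
#'
#' Emits the standard header `fish_id,timestamp_iso8601,receiver_id,lon,
#' lat,depth_m` with UTC ISO-8601 timestamps.
#'
#' @param detections data frame as returned by [simulate_detections()].
#' @param path output file.
#' @export
write_detections_csv <- function(detections, path) {
  out <- data.frame(fish_id = detections$fish_id,
                    timestamp_iso8601 = format(detections$timestamp,
                                               "%Y-%m-%dT%H:%M:%SZ",
                                               tz = "UTC"),
                    receiver_id = detections$receiver_id,
                    lon = detections$lon, lat = detections$lat,
                    depth_m = detections$depth_m)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detection CSV
#'
#' @param path CSV with header `fish_id,timestamp_iso8601,receiver_id,lon,
#'   lat,depth_m`.
#' @return data frame with POSIXct UTC `timestamp`.
#' @export
read_detections_csv <- function(path) {
  d <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  d$timestamp_iso8601 <- NULL
  d[, c("fish_id", "timestamp", "receiver_id", "lon", "lat", "depth_m")]
}
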