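#' Remove false detections
#'
#' Code collisions and spurious single pings are eliminated by requiring a
#' minimum number of detections per fish per calendar day (local time
#' zone); days below the minimum have all their detections for that fish
#' removed.
#'
#' @param detections data frame `fish_id, timestamp, receiver_id, lon, lat,
#'   depth_m`.
#' @param min_per_day minimum detections per fish-day (default 2).
#' @param tz time zone for the calendar-day boundary.
#' @return filtered detection data frame.
#' @export
filter_false_detections <- function(detections, min_per_day = 2,
                                    tz = "Europe/Oslo") {
  day <- format(detections$timestamp, "%Y-%m-%d", tz = tz)
  key <- paste(detections$fish_id, day)
  n <- table(key)
  detections[n[key] >= min_per_day, , drop = FALSE]
}

#' Truncate post-mortem transmissions
#'
#' A dead fish with a live transmitter keeps pinging from a fixed depth.
#' Scanning each fish's depth series, this finds the earliest time t* such
#' that the depth standard deviation within every subsequent `window_h`-hour
#' window stays below `depth_sd_threshold` through the end of the record;
#' detections after t* are removed and the fish flagged as a candidate
#' mortality. Fish whose whole record is flat are flagged from the first
#' record.
#'
#' @param detections detection data frame (see
#'   [filter_false_detections()]).
#' @param depth_sd_threshold maximum depth sd (m) regarded as "no
#'   movement" (default 0.5).
#' @param window_h window length in hours (default 24).
#' @return list with `detections` (truncated) and `flags` (data frame
#'   `fish_id, flagged_dead, t_death`).
#' @export
truncate_post_mortem <- function(detections, depth_sd_threshold = 0.5,
                                 window_h = 24) {
  keep <- rep(TRUE, nrow(detections))
  flags <- list()
  for (f in unique(detections$fish_id)) {
    rows <- which(detections$fish_id == f)
    ord <- rows[order(detections$timestamp[rows])]
    tt <- as.numeric(detections$timestamp[ord])
    dd <- detections$depth_m[ord]
    t_star <- flat_tail_start(tt, dd, depth_sd_threshold, window_h * 3600)
    flagged <- !is.na(t_star)
    if (flagged) keep[ord[tt > t_star]] <- FALSE
    flags[[f]] <- data.frame(fish_id = f, flagged_dead = flagged,
                             t_death = if (flagged)
                               as.POSIXct(t_star, origin = "1970-01-01",
                                          tz = "UTC") else
                               as.POSIXct(NA),
                             stringsAsFactors = FALSE)
  }
  list(detections = detections[keep, , drop = FALSE],
       flags = do.call(rbind, flags))
}

# earliest time t* (seconds) from which every subsequent window of length
# win_s has depth sd < thr through the end; NA if no flat tail
flat_tail_start <- function(tt, dd, thr, win_s) {
  n <- length(tt)
  if (n < 2) return(NA_real_)
  # per start index i, the window covers points with tt in [tt[i], tt[i]+win_s)
  j <- findInterval(tt + win_s - 1e-6, tt)
  cs <- cumsum(dd); cs2 <- cumsum(dd^2)
  m <- j - seq_len(n) + 1
  s1 <- cs[j] - c(0, cs)[seq_len(n)]  # sum over i..j = cs[j] - cs[i-1]
  s2 <- cs2[j] - c(0, cs2)[seq_len(n)]
  v <- pmax(0, (s2 - s1^2 / m) / pmax(1, m - 1))
  flat <- m < 2 | sqrt(v) < thr
  bad <- which(!flat)
  flat_from <- if (!length(bad)) 1L else max(bad) + 1L
  if (flat_from > n) return(NA_real_)
  # require the flat tail to span at least one full window
  if (tt[n] - tt[flat_from] < win_s) return(NA_real_)
  tt[flat_from]
}

#' Centres of activity in fixed time bins
#'
#' Per fish and time bin, the centre of activity (COA) is the mean of the
#' detecting receivers' coordinates over all detections in the bin —
#' receivers are thereby weighted by their detection counts — and the mean
#' transmitted depth likewise.
#'
#' @param detections detection data frame.
#' @param bin_min bin width in minutes (default 30).
#' @return data frame `fish_id, bin_start (POSIXct UTC), lon, lat,
#'   depth_m, n_detections`.
#' @export
compute_coa <- function(detections, bin_min = 30) {
  bin <- as.POSIXct(floor(as.numeric(detections$timestamp) / (bin_min * 60)) *
                      bin_min * 60, origin = "1970-01-01", tz = "UTC")
  key <- interaction(detections$fish_id, as.numeric(bin), drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  out <- data.frame(fish_id = tapply(detections$fish_id, key, `[`, 1),
                    bin_start = as.POSIXct(tapply(as.numeric(bin), key, `[`, 1),
                                           origin = "1970-01-01", tz = "UTC"),
                    lon = agg(detections$lon), lat = agg(detections$lat),
                    depth_m = agg(detections$depth_m),
                    n_detections = as.integer(table(key)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$fish_id, out$bin_start), ]
  rownames(out) <- NULL
  out
}

# annotate COAs with local day, month and day/night class
coa_annotate <- function(coa, tz = "Europe/Oslo") {
  coa$day <- format(coa$bin_start, "%Y-%m-%d", tz = tz)
  coa$month <- format(coa$bin_start, "%Y-%m", tz = tz)
  coa$daynight <- classify_daynight(coa$bin_start, coa$lon, coa$lat)
  coa
}

#' Monthly diel vertical migration
#'
#' Per fish-day, the mean daytime depth minus the mean night-time depth
#' (positive = deeper by day); the month's DVM is the mean over days with
#' both defined.
#'
#' @param coa COA table from [compute_coa()].
#' @param tz local time zone for day/month bucketing.
#' @return data frame `fish_id, month, dvm_m, n_days`.
#' @export
monthly_dvm <- function(coa, tz = "Europe/Oslo") {
  coa <- coa_annotate(coa, tz)
  sp <- split(coa, list(coa$fish_id, coa$day), drop = TRUE)
  daily <- do.call(rbind, lapply(sp, function(d) {
    dep <- tapply(d$depth_m, d$daynight, mean)
    if (!all(c("day", "night") %in% names(dep))) return(NULL)
    data.frame(fish_id = d$fish_id[1], month = d$month[1],
               diff = dep[["day"]] - dep[["night"]])
  }))
  if (is.null(daily)) return(data.frame(fish_id = character(0),
                                        month = character(0),
                                        dvm_m = numeric(0),
                                        n_days = integer(0)))
  out <- aggregate(diff ~ fish_id + month, daily, mean)
  names(out)[3] <- "dvm_m"
  out$n_days <- aggregate(diff ~ fish_id + month, daily, length)$diff
  out
}

#' Monthly mean daytime depth
#'
#' Mean over days of each day's mean daytime COA depth; days are weighted
#' equally regardless of how many detections they carry.
#'
#' @inheritParams monthly_dvm
#' @return data frame `fish_id, month, daytime_depth_m, n_days`.
#' @export
monthly_mean_daytime_depth <- function(coa, tz = "Europe/Oslo") {
  coa <- coa_annotate(coa, tz)
  coa <- coa[coa$daynight == "day", , drop = FALSE]
  if (!nrow(coa)) return(data.frame(fish_id = character(0),
                                    month = character(0),
                                    daytime_depth_m = numeric(0),
                                    n_days = integer(0)))
  daily <- aggregate(depth_m ~ fish_id + month + day, coa, mean)
  out <- aggregate(depth_m ~ fish_id + month, daily, mean)
  names(out)[3] <- "daytime_depth_m"
  out$n_days <- aggregate(depth_m ~ fish_id + month, daily, length)$depth_m
  out
}

#' Monthly kernel home range
#'
#' 95% kernel-utilization-distribution area from a month's COAs: positions
#' are projected to local planar metres (equirectangular about the array
#' centroid), smoothed with a 2-D Gaussian KDE using the normal-reference
#' bandwidth per axis ([stats::bw.nrd()]), evaluated on a `grid_n` x
#' `grid_n` grid padded by 3 bandwidths; the area is that of the smallest
#' set of grid cells containing `prob` of the UD mass, in km².
#'
#' @param coa COA table from [compute_coa()].
#' @param prob utilization probability level (default 0.95).
#' @param min_days minimum distinct days present in the month (default 20).
#' @param min_coas minimum COAs (default 30).
#' @param grid_n evaluation grid size per axis.
#' @param tz local time zone for month bucketing.
#' @return data frame `fish_id, month, home_range_km2, n_days, n_coas`
#'   (fish-months below the presence thresholds get `NA` area).
#' @export
monthly_home_range <- function(coa, prob = 0.95, min_days = 20,
                               min_coas = 30, grid_n = 256,
                               tz = "Europe/Oslo") {
  coa <- coa_annotate(coa, tz)
  lon0 <- mean(coa$lon); lat0 <- mean(coa$lat)
  sp <- split(coa, list(coa$fish_id, coa$month), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    nd <- length(unique(d$day))
    area <- NA_real_
    if (nd >= min_days && nrow(d) >= min_coas) {
      xy <- lonlat_to_xy(d$lon, d$lat, lon0, lat0)
      area <- kud_area(xy[, 1], xy[, 2], prob = prob, grid_n = grid_n)
    }
    data.frame(fish_id = d$fish_id[1], month = d$month[1],
               home_range_km2 = area, n_days = nd, n_coas = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$fish_id, out$month), ]
}

#' Kernel utilization distribution area
#'
#' Area (km²) of the smallest region containing `prob` of the mass of a
#' 2-D Gaussian KDE of points given in metres, normal-reference bandwidth
#' per axis.
#'
#' @param x,y point coordinates in metres.
#' @param prob probability level.
#' @param grid_n grid cells per axis.
#' @param pad_bw grid padding in bandwidths.
#' @return area in km².
#' @export
kud_area <- function(x, y, prob = 0.95, grid_n = 256, pad_bw = 3) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  hx <- stats::bw.nrd(x); hy <- stats::bw.nrd(y)
  if (hx == 0 || hy == 0) stopf("degenerate positions: zero variance")
  gx <- seq(min(x) - pad_bw * hx, max(x) + pad_bw * hx, length.out = grid_n)
  gy <- seq(min(y) - pad_bw * hy, max(y) + pad_bw * hy, length.out = grid_n)
  # product-Gaussian KDE evaluated on the grid
  kx <- dnorm(outer(gx, x, "-") / hx) / hx       # grid_n x n
  ky <- dnorm(outer(gy, y, "-") / hy) / hy
  dens <- kx %*% t(ky) / length(x)               # sum over points / n
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  mass <- as.numeric(dens) * cell
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord]) / sum(mass)
  n_in <- which(cum >= prob)[1]
  n_in * cell / 1e6
}

#' Classify the fate of each fish
#'
#' Applies the standard detection-pattern rules: *dead* when
#' [truncate_post_mortem()] flags a persistent constant-depth tail, or when
#' transmissions cease well before battery end while the last COAs are
#' interior; *dispersed* when the distance to the array centroid over the
#' last `k` COAs increases monotonically, the track ends near an outermost
#' receiver, and silence follows; otherwise *alive*. Days survived run
#' from tagging to the last valid detection (alive fish: to battery end).
#'
#' @param detections filtered detection data frame.
#' @param receivers receiver layout `receiver_id, lon, lat`.
#' @param tagging_date,battery_end POSIXct scalars or named vectors per
#'   fish.
#' @param k number of trailing COAs for the dispersal test.
#' @param silence_days minimum pre-battery-end silence (days) for a
#'   non-alive classification.
#' @param edge_quantile COA distance quantile of receivers regarded as
#'   "outermost".
#' @param depth_sd_threshold,window_h passed to [truncate_post_mortem()].
#' @return data frame of class `fate_table`: `fish_id, fate,
#'   last_valid_timestamp, days_survived`.
#' @export
classify_fate <- function(detections, receivers, tagging_date, battery_end,
                          k = 10, silence_days = 7, edge_quantile = 0.9,
                          depth_sd_threshold = 0.5, window_h = 24) {
  tp <- truncate_post_mortem(detections, depth_sd_threshold, window_h)
  coa <- compute_coa(tp$detections)
  cen <- c(mean(receivers$lon), mean(receivers$lat))
  rxy <- lonlat_to_xy(receivers$lon, receivers$lat, cen[1], cen[2])
  rdist <- sqrt(rxy[, 1]^2 + rxy[, 2]^2)
  edge_d <- quantile(rdist, edge_quantile)

  fish <- unique(detections$fish_id)
  tag <- expand_per_fish(tagging_date, fish)
  bat <- expand_per_fish(battery_end, fish)
  out <- do.call(rbind, lapply(fish, function(f) {
    cf <- coa[coa$fish_id == f, ]
    flg <- tp$flags[tp$flags$fish_id == f, ]
    last_t <- max(cf$bin_start)
    silent <- as.numeric(bat[[f]] - last_t, units = "days") > silence_days
    fate <- "alive"
    if (nrow(flg) && flg$flagged_dead) {
      fate <- "dead"
      last_t <- flg$t_death
    } else if (silent) {
      xy <- lonlat_to_xy(cf$lon, cf$lat, cen[1], cen[2])
      dist <- sqrt(xy[, 1]^2 + xy[, 2]^2)
      lastk <- tail(dist, k)
      # outward trend over the last k COAs (receiver-weighted COAs are
      # noisy and saturate near the array edge, so a regression slope
      # stands in for strict monotonicity)
      outward <- length(lastk) >= 3 &&
        unname(coef(lm(lastk ~ seq_along(lastk)))[2]) >= 0 &&
        mean(tail(lastk, 3)) >= mean(head(lastk, 3))
      # "ends at an outermost receiver": the modal receiver among the
      # fish's final detections lies in the outermost distance band
      dets_f <- detections[detections$fish_id == f, ]
      last_rec <- tail(dets_f$receiver_id[order(dets_f$timestamp)], 50)
      modal <- names(sort(table(last_rec), decreasing = TRUE))[1]
      at_edge <- rdist[match(modal, receivers$receiver_id)] >= edge_d
      fate <- if (outward && at_edge) "dispersed" else "dead"
    }
    days <- as.numeric((if (fate == "alive") bat[[f]] else last_t) - tag[[f]],
                       units = "days")
    data.frame(fish_id = f, fate = fate, last_valid_timestamp = last_t,
               days_survived = days, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("fate_table", "data.frame")
  out
}

expand_per_fish <- function(v, fish) {
  if (length(v) == 1) return(setNames(rep(list(v), length(fish)), fish))
  stopifnot(!is.null(names(v)), all(fish %in% names(v)))
  as.list(v[fish])
}

#' Relative longevity
#'
#' Fitness proxy S = days survived / mean days survived over the included
#' fish. Dispersed fish are excluded (their fate is unobservable); the mean
#' of S over included fish is exactly 1.
#'
#' @param fates a [classify_fate()] table.
#' @return data frame `fish_id, fate, days_survived, S` (included fish
#'   only).
#' @export
relative_longevity <- function(fates) {
  inc <- fates[fates$fate != "dispersed", , drop = FALSE]
  if (!nrow(inc)) stopf("all fish dispersed; S undefined")
  inc$S <- inc$days_survived / mean(inc$days_survived)
  inc[, c("fish_id", "fate", "days_survived", "S")]
}

#' Build the monthly behavioural-trait table
#'
#' Convenience wrapper running the full telemetry chain: false-detection
#' filtering, post-mortem truncation, COAs, then monthly home range,
#' daytime depth and DVM joined into one table.
#'
#' @param detections raw detection data frame.
#' @param min_days,min_coas presence thresholds for home range.
#' @param tz local time zone.
#' @return data frame `fish_id, month, home_range_km2, daytime_depth_m,
#'   dvm_m, days_present`.
#' @export
monthly_traits <- function(detections, min_days = 20, min_coas = 30,
                           tz = "Europe/Oslo") {
  d <- filter_false_detections(detections, tz = tz)
  d <- truncate_post_mortem(d)$detections
  coa <- compute_coa(d)
  hr <- monthly_home_range(coa, min_days = min_days, min_coas = min_coas,
                           tz = tz)
  dd <- monthly_mean_daytime_depth(coa, tz = tz)
  dvm <- monthly_dvm(coa, tz = tz)
  out <- merge(hr[, c("fish_id", "month", "home_range_km2", "n_days")],
               dd[, c("fish_id", "month", "daytime_depth_m")],
               by = c("fish_id", "month"), all = TRUE)
  out <- merge(out, dvm[, c("fish_id", "month", "dvm_m")],
               by = c("fish_id", "month"), all = TRUE)
  names(out)[names(out) == "n_days"] <- "days_present"
  out[order(out$fish_id, out$month), ]
}
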