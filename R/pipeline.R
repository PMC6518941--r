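#' Pipeline configuration
#'
#' End-to-end configuration for [run_all()]: either synthetic-data blocks
#' (`geno_sim`, `telem_sim`) or input paths (`vcf`, `popmap`,
#' `detections_csv`), plus stage parameters. Validated up front so a
#' misconfigured stage fails before any work runs.
#'
#' @param out_dir output directory (created if needed).
#' @param geno_sim optional [geno_sim_config()].
#' @param telem_sim optional [telem_sim_config()].
#' @param vcf,popmap,detections_csv optional input paths (used when the
#'   corresponding simulator block is absent).
#' @param window_sizes genome-scan window sizes in bp.
#' @param inversion_regions data frame `chrom, start, end` (default: the
#'   regions inside the simulated/provided data that match
#'   [cod_inversion_regions()], else none).
#' @param filter genotype/site filter thresholds (list; see
#'   [apply_genotype_filters()] and [apply_site_filters()]).
#' @param bootstrap_B bootstrap replicates for the arrangement test.
#' @param seed master seed; stage seeds derive from it.
#' @param tz local time zone for telemetry bucketing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, geno_sim = NULL, telem_sim = NULL,
                            vcf = NULL, popmap = NULL,
                            detections_csv = NULL,
                            window_sizes = c(50000, 100000),
                            inversion_regions = NULL,
                            filter = list(min_dp = 3, min_gq = 20,
                                          max_missing = 0.20, min_mac = 3,
                                          min_maf = 0.03,
                                          het_excess_p = 0.001,
                                          max_mean_dp = 30),
                            bootstrap_B = 1e5, seed = 1,
                            tz = "Europe/Oslo") {
  if (is.null(geno_sim) && (is.null(vcf) || is.null(popmap)))
    stopf("config invalid: need either geno_sim or vcf + popmap")
  if (!is.null(geno_sim)) stopifnot(inherits(geno_sim, "geno_sim_config"))
  if (!is.null(telem_sim)) stopifnot(inherits(telem_sim, "telem_sim_config"))
  stopifnot(all(window_sizes > 0), bootstrap_B >= 1000)
  structure(list(out_dir = out_dir, geno_sim = geno_sim,
                 telem_sim = telem_sim, vcf = vcf, popmap = popmap,
                 detections_csv = detections_csv,
                 window_sizes = window_sizes,
                 inversion_regions = inversion_regions, filter = filter,
                 bootstrap_B = bootstrap_B, seed = seed, tz = tz),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — genotype acquisition
#' (simulate or load), filtering, windowed genome scan, inversion
#' karyotyping + arrangement tests, telemetry trait extraction (when
#' telemetry is configured) — writing each stage's artefact plus a
#' provenance JSON (inputs, parameters, seed) into `out_dir`. A stage
#' whose inputs and parameters are unchanged (content hash match) is
#' skipped on rerun; deterministic stages are bit-identical across reruns
#' with the same config. A failing stage halts the pipeline with its name.
#'
#' @param cfg a [pipeline_config()].
#' @param force rerun all stages even when cached.
#' @return invisible list of stage results (`genotypes`, `filter_report`,
#'   `scan`, `inversions`, `telemetry`).
#' @export
run_all <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list(seed = cfg$seed, started = format(Sys.time(), tz = "UTC"),
                   stages = list())

  run_stage <- function(name, params, produce) {
    hash <- stage_hash(params)
    prov_path <- file.path(cfg$out_dir, paste0(name, ".provenance.json"))
    cached <- !force && file.exists(prov_path) &&
      identical(jsonlite::read_json(prov_path)$hash, hash)
    if (cached) {
      message(sprintf("[%s] cached, skipping", name))
      prov <- jsonlite::read_json(prov_path)
      return(list(cached = TRUE, artefacts = unlist(prov$artefacts)))
    }
    res <- tryCatch(produce(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    prov <- list(stage = name, hash = hash, seed = cfg$seed,
                 parameters = params_for_json(params),
                 artefacts = res$artefacts,
                 written = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
    manifest$stages[[name]] <<- prov_path
    res
  }

  # --- genotypes ---
  geno_stage <- run_stage("genotypes",
    list(sim = cfg$geno_sim, vcf = cfg$vcf, popmap = cfg$popmap),
    function() {
      if (!is.null(cfg$geno_sim)) {
        sim <- simulate_genotypes(cfg$geno_sim)
        vcf <- file.path(cfg$out_dir, "genotypes.vcf")
        pm <- file.path(cfg$out_dir, "popmap.tsv")
        write_genotypes_vcf(sim$genotypes, vcf)
        write_popmap(sim$genotypes, pm)
        jsonlite::write_json(sim$truth["population"],
                             file.path(cfg$out_dir, "truth.json"),
                             auto_unbox = TRUE)
        list(genotypes = sim$genotypes, truth = sim$truth,
             artefacts = c(vcf, pm))
      } else {
        list(genotypes = load_genotypes(cfg$vcf, cfg$popmap),
             truth = NULL, artefacts = character(0))
      }
    })
  g <- geno_stage$genotypes
  if (is.null(g)) {  # cached: reload
    g <- load_genotypes(file.path(cfg$out_dir, "genotypes.vcf"),
                        file.path(cfg$out_dir, "popmap.tsv"))
  }
  results$genotypes <- g

  # --- filter ---
  flt <- cfg$filter
  filt_stage <- run_stage("filter", flt, function() {
    gg <- apply_genotype_filters(g, min_dp = flt$min_dp,
                                 min_gq = flt$min_gq)
    sf <- apply_site_filters(gg, max_missing = flt$max_missing,
                             min_mac = flt$min_mac, min_maf = flt$min_maf,
                             het_excess_p = flt$het_excess_p,
                             max_mean_dp = flt$max_mean_dp)
    rep_path <- file.path(cfg$out_dir, "filter_report.json")
    jsonlite::write_json(unclass(sf$report), rep_path, auto_unbox = TRUE)
    vcf <- file.path(cfg$out_dir, "filtered.vcf")
    write_genotypes_vcf(sf$genotypes, vcf)
    list(genotypes = sf$genotypes, report = sf$report,
         artefacts = c(vcf, rep_path))
  })
  gf <- filt_stage$genotypes
  if (is.null(gf))
    gf <- load_genotypes(file.path(cfg$out_dir, "filtered.vcf"),
                         file.path(cfg$out_dir, "popmap.tsv"))
  results$filter_report <- filt_stage$report

  # --- genome scan ---
  scan_stage <- run_stage("scan", list(sizes = cfg$window_sizes),
    function() {
      paths <- character(0)
      tabs <- list()
      for (s in cfg$window_sizes) {
        tab <- scan_windows(gf, size_bp = s)
        p <- file.path(cfg$out_dir, sprintf("scan_%dkb.tsv", s / 1000))
        write_scan_tsv(tab, p)
        paths <- c(paths, p)
        tabs[[as.character(s)]] <- tab
      }
      list(tables = tabs, artefacts = paths)
    })
  results$scan <- scan_stage$tables

  # --- inversions ---
  regions <- cfg$inversion_regions
  if (is.null(regions) && !is.null(cfg$geno_sim) &&
      length(cfg$geno_sim$inversion_specs)) {
    regions <- do.call(rbind, lapply(cfg$geno_sim$inversion_specs,
      function(s) data.frame(chrom = s$chromosome, start = s$start,
                             end = s$end)))
  }
  if (!is.null(regions) && nrow(regions)) {
    inv_stage <- run_stage("inversions",
      list(regions = regions, B = cfg$bootstrap_B), function() {
        calls_all <- list()
        tests <- list()
        for (i in seq_len(nrow(regions))) {
          pc <- region_pca(gf, regions$chrom[i], regions$start[i],
                           regions$end[i])
          kc <- call_karyotypes(pc, gf, seed = cfg$seed)
          kc$region <- sprintf("%s:%d-%d", regions$chrom[i],
                               regions$start[i], regions$end[i])
          calls_all[[i]] <- kc
          tab <- arrangement_frequencies(kc, setNames(gf$pop, gf$sample_ids))
          tests[[i]] <- cbind(region = kc$region[1],
                              bootstrap_overrep_test(tab, B = cfg$bootstrap_B,
                                                     seed = cfg$seed + i))
        }
        calls <- do.call(rbind, calls_all)
        p1 <- file.path(cfg$out_dir, "karyotypes.tsv")
        write.table(calls[, c("individual", "region", "state", "pc1",
                              "confidence")],
                    p1, sep = "\t", row.names = FALSE, quote = FALSE)
        tests <- do.call(rbind, tests)
        p2 <- file.path(cfg$out_dir, "arrangement_tests.tsv")
        write.table(tests, p2, sep = "\t", row.names = FALSE, quote = FALSE)
        list(calls = calls, tests = tests, artefacts = c(p1, p2))
      })
    results$inversions <- inv_stage[c("calls", "tests")]
  }

  # --- telemetry ---
  if (!is.null(cfg$telem_sim) || !is.null(cfg$detections_csv)) {
    tel_stage <- run_stage("telemetry",
      list(sim = cfg$telem_sim, csv = cfg$detections_csv, tz = cfg$tz),
      function() {
        if (!is.null(cfg$telem_sim)) {
          sim <- simulate_detections(cfg$telem_sim)
          det <- sim$detections; recv <- sim$receivers
          dcsv <- file.path(cfg$out_dir, "detections.csv")
          write_detections_csv(det, dcsv)
        } else {
          det <- read_detections_csv(cfg$detections_csv)
          recv <- unique(det[, c("receiver_id", "lon", "lat")])
          dcsv <- cfg$detections_csv
        }
        traits <- monthly_traits(det, tz = cfg$tz)
        p1 <- file.path(cfg$out_dir, "monthly_traits.tsv")
        write.table(traits, p1, sep = "\t", row.names = FALSE, quote = FALSE)
        tag <- min(det$timestamp); bat <- max(det$timestamp)
        fates <- classify_fate(det, recv, tag, bat)
        p2 <- file.path(cfg$out_dir, "fates.tsv")
        write.table(fates, p2, sep = "\t", row.names = FALSE, quote = FALSE)
        list(traits = traits, fates = fates, artefacts = c(p1, p2, dcsv))
      })
    results$telemetry <- tel_stage[c("traits", "fates")]
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

# content hash of a parameter list (stage caching key)
stage_hash <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(params_for_json(params), tf, version = 2)
  unname(tools::md5sum(tf))
}

# strip classes and non-serializable bits (POSIXct as epoch seconds)
params_for_json <- function(p) {
  if (inherits(p, "POSIXct")) return(as.numeric(p))
  if (is.data.frame(p)) return(as.data.frame(lapply(p, params_for_json)))
  if (is.list(p)) return(lapply(unclass(p), params_for_json))
  p
}
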