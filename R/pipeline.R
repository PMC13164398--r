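# One-call pipeline: simulate/load -> filter -> stats -> scan -> report.

#' Build a pipeline run configuration
#'
#' A run is reproducible from its configuration plus the root seed alone:
#' all stage randomness is drawn from named sub-seeds derived from `seed`.
#'
#' @param variants Path to a VCF/TSV variant file, or a `variant_table`,
#'   or `NULL` to simulate input.
#' @param format,sample_roles Passed to [read_variants()] when `variants`
#'   is a path.
#' @param sim List with `genome` ([genome_map()]), `trait` ([trait_model()]
#'   or `NULL`), `n` and `cfg` ([sim_config()]); used when `variants` is
#'   `NULL`.
#' @param thresholds A [filter_thresholds()].
#' @param scan A [scan_config()].
#' @param channels Scan channels to run.
#' @param segregation_counts Optional length-2 vector (dominant, recessive)
#'   to run the segregation test.
#' @param panel Optional panel TSV path or `recombinant_panel` for
#'   fine-mapping.
#' @param out_dir Output directory (created if absent).
#' @param seed Root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(variants = NULL, format = "auto", sample_roles = NULL,
                       sim = NULL, thresholds = filter_thresholds(),
                       scan = scan_config(),
                       channels = c("delta", "gprime", "ed4"),
                       segregation_counts = NULL, panel = NULL,
                       out_dir = tempfile("bsaqtl_run_"), seed = 1L) {
  if (is.null(variants) && is.null(sim))
    stop("provide either 'variants' or 'sim'", call. = FALSE)
  structure(list(variants = variants, format = format,
                 sample_roles = sample_roles, sim = sim,
                 thresholds = thresholds, scan = scan, channels = channels,
                 segregation_counts = segregation_counts, panel = panel,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full BSA-seq pipeline
#'
#' Executes simulate/load, informative-marker filtering, per-site
#' statistics, the genome scan with interval calling, and the optional
#' segregation test and fine-mapping stages, in order. Every stage writes
#' its artifact into `out_dir` (variants, filtered variants, site stats,
#' per-channel window tracks and BED intervals) and the run ends with a
#' machine-readable `report.json` holding filter counts, per-channel
#' cutoffs and intervals, the pairwise interval overlap matrix, and any
#' segregation or fine-mapping results. Reruns with the same configuration
#' and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed)

  # stage: acquire variants
  if (!is.null(config$variants)) {
    if (inherits(config$variants, "variant_table")) {
      log_msg("using in-memory variant table")
      variants <- config$variants
    } else {
      log_msg("loading variants from ", config$variants)
      variants <- read_variants(config$variants, config$format,
                                config$sample_roles)
    }
    chrom_lengths <- NULL
  } else {
    log_msg("simulating F2 population and bulk sequencing")
    sim <- simulate_bsa(config$sim$genome, config$sim$trait, config$sim$n,
                        config$sim$cfg, config$seed)
    variants <- sim$variants
    chrom_lengths <- config$sim$genome$chromosomes
    write_variants(variants, file.path(config$out_dir, "variants.tsv"))
  }
  report$n_variants_input <- nrow(variants)

  # stage: filter
  log_msg("filtering informative markers")
  flt <- filter_informative(variants, config$thresholds)
  report$filter <- list(n_input = flt$n_input, n_retained = flt$n_retained,
                        exclusions = as.list(flt$exclusions))
  write_variants(flt$variants, file.path(config$out_dir, "filtered.tsv"))

  # stage: per-site statistics
  log_msg("computing per-site statistics for ", flt$n_retained, " sites")
  stats <- compute_site_stats(flt$variants)
  write_site_stats(stats, file.path(config$out_dir, "site_stats.tsv"))

  # stage: scan
  log_msg("scanning channels: ", paste(config$channels, collapse = ", "))
  scan <- bsa_scan(stats, config$channels, config$scan, chrom_lengths)
  report$scan <- list()
  for (ch in names(scan)) {
    write_window_track(scan[[ch]]$track,
                       file.path(config$out_dir, paste0("track_", ch, ".tsv")))
    write_intervals_bed(scan[[ch]]$intervals,
                        file.path(config$out_dir,
                                  paste0("intervals_", ch, ".bed")))
    iv <- scan[[ch]]$intervals
    report$scan[[ch]] <- list(
      cutoff = scan[[ch]]$cutoff,
      quantile = config$scan$quantile,
      intervals = if (nrow(iv)) iv[, c("chrom", "start", "end", "length",
                                       "n_variants", "n_above", "peak")]
                  else list())
  }
  report$overlap <- interval_overlap_matrix(scan)

  # stage: segregation test
  if (!is.null(config$segregation_counts)) {
    log_msg("segregation test on counts ",
            paste(config$segregation_counts, collapse = "/"))
    seg <- chisq_goodness_of_fit(config$segregation_counts)
    report$segregation <- list(
      observed = seg$observed, expected = seg$expected,
      chi_square = seg$chi_square, df = seg$df, p_value = seg$p_value,
      proportion = seg$proportion, conf_int = seg$conf_int)
  }

  # stage: fine-mapping
  if (!is.null(config$panel)) {
    log_msg("fine-mapping from recombinant panel")
    panel <- if (inherits(config$panel, "recombinant_panel")) config$panel
             else read_panel(config$panel)
    dl <- delimit_locus(panel)
    report$finemap <- list(
      chrom = dl$chrom, left = dl$left_pos, right = dl$right_pos,
      consistent = dl$consistent, offending = dl$offending)
  }

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  echo_config(config, file.path(config$out_dir, "config.yaml"))
  log_msg("report written to ", report_path)
  invisible(report)
}

# Pairwise overlap/containment between the first interval of each channel.
interval_overlap_matrix <- function(scan) {
  chans <- names(scan)
  out <- list()
  for (i in seq_along(chans)) for (j in seq_along(chans)) {
    if (i >= j) next
    a <- scan[[chans[i]]]$intervals
    b <- scan[[chans[j]]]$intervals
    if (nrow(a) == 0 || nrow(b) == 0) next
    a <- a[which.max(a$peak), ]
    b <- b[which.max(b$peak), ]
    ov <- interval_overlap(a, b)
    out[[paste(chans[i], chans[j], sep = "_vs_")]] <- ov
  }
  out
}

# Serializable echo of the run configuration (paths and scalars; in-memory
# objects are recorded by their class).
echo_config <- function(config, path) {
  as_plain <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, c("variant_table", "recombinant_panel")))
      return(paste0("<in-memory ", class(x)[1], ">"))
    if (inherits(x, "genome_map"))
      return(list(chromosomes = as.list(x$chromosomes),
                  n_markers = lengths(x$marker_positions),
                  cm_per_mb = x$cm_per_mb))
    if (is.list(x)) return(lapply(x, as_plain))
    x
  }
  yaml::write_yaml(as_plain(unclass(config)), path)
  invisible(path)
}
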