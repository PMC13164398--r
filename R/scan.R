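# Genome scan: window smoothing, empirical thresholds, interval calling.

#' Sliding-window mean of a per-site statistic
#'
#' Windows are anchored at fixed genomic offsets 1, 1+step, 1+2*step, ...
#' on each chromosome; a window's value is the arithmetic mean of the
#' non-missing site values with position in [start, start + window_size - 1].
#' Empty windows carry `NA`. Window ends are truncated at the chromosome
#' end when chromosome lengths are supplied (otherwise at the last site).
#'
#' @param sites Data frame with columns `chrom`, `pos`, `value`.
#' @param window_size,step Window size and step in bp; `window_size >= step > 0`.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp.
#' @return A `window_track` data frame: `chrom`, `start`, `end`, `value`,
#'   `n_sites`.
#' @export
smooth_window_mean <- function(sites, window_size, step,
                               chrom_lengths = NULL) {
  stopifnot(window_size >= step, step > 0)
  out <- lapply(split(sites, sites$chrom), function(s) {
    s <- s[order(s$pos), ]
    ok <- !is.na(s$value)
    pos <- s$pos[ok]
    val <- s$value[ok]
    chrom <- s$chrom[1]
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      chrom_lengths[[chrom]] else max(s$pos)
    starts <- seq.int(1, max(1, len), by = step)
    ends <- pmin(starts + window_size - 1, len)
    cs <- c(0, cumsum(val))
    hi <- findInterval(ends, pos)
    lo <- findInterval(starts - 1, pos)
    n <- hi - lo
    value <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
    data.frame(chrom = chrom, start = starts, end = ends, value = value,
               n_sites = n, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  class(track) <- c("window_track", "data.frame")
  track
}

#' Tricube kernel smoothing of a per-site statistic
#'
#' At each focal site the smoothed value is the tricube-weighted mean of
#' the statistic over sites within half a window of the focal position:
#' w_j = (1 - (d_j / D)^3)^3 with d_j the distance to the focal site and
#' D = `window_size / 2`. A site exactly at distance D gets weight 0; an
#' isolated site keeps its own value (weight 1 at distance 0).
#'
#' @param pos Sorted positions (one chromosome).
#' @param value Per-site statistic; `NA` sites contribute nothing.
#' @param window_size Full window size in bp.
#' @return Smoothed values, `NA` where the focal value and all neighbours
#'   are missing.
#' @export
tricube_smooth <- function(pos, value, window_size) {
  d_half <- window_size / 2
  n <- length(pos)
  lo <- findInterval(pos - d_half - 1e-9, pos) + 1L
  hi <- findInterval(pos + d_half + 1e-9, pos)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    d <- abs(pos[j] - pos[i])
    keep <- d <= d_half & !is.na(value[j])
    if (!any(keep)) next
    w <- (1 - (d[keep] / d_half)^3)^3
    sw <- sum(w)
    if (sw > 0) out[i] <- sum(w * value[j][keep]) / sw
  }
  out
}

#' Smooth per-site G values into a G' window track
#'
#' G' at each variant site is the tricube-weighted mean of G over sites
#' within half a window (see [tricube_smooth()]); the site-level G' values
#' are then aggregated to anchored windows with [smooth_window_mean()] so
#' that interval calling is channel-agnostic.
#'
#' @param sites Data frame `chrom`, `pos`, `value` holding per-site G.
#' @param window_size Kernel window size in bp (default 1 Mb).
#' @param step Window step for the aggregated track.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A list with `sites` (input plus column `g_prime`) and `track`
#'   (a `window_track` of window-mean G').
#' @export
smooth_g_prime <- function(sites, window_size = 1e6, step = 1e4,
                           chrom_lengths = NULL) {
  sites <- sites[order(sites$chrom, sites$pos), ]
  gp <- unlist(lapply(split(seq_len(nrow(sites)), sites$chrom), function(i)
    tricube_smooth(sites$pos[i], sites$value[i], window_size)),
    use.names = FALSE)
  sites$g_prime <- gp
  gp_sites <- data.frame(chrom = sites$chrom, pos = sites$pos, value = gp,
                         stringsAsFactors = FALSE)
  list(sites = sites,
       track = smooth_window_mean(gp_sites, window_size, step, chrom_lengths))
}

#' Empirical quantile threshold of a window track
#'
#' The cutoff is the linear-interpolation sample quantile of all
#' non-missing window values pooled across chromosomes.
#'
#' @param track A `window_track`.
#' @param quantile Quantile level in (0, 1); default 0.999.
#' @return The cutoff value.
#' @export
empirical_threshold <- function(track, quantile = 0.999) {
  stopifnot(quantile > 0, quantile < 1)
  v <- track$value[!is.na(track$value)]
  if (length(v) == 0) stop("window track has no non-missing values", call. = FALSE)
  stats::quantile(v, quantile, type = 7, names = FALSE)
}

#' Call candidate intervals from a window track
#'
#' Maximal runs of windows with value above the cutoff are merged (windows
#' whose spans overlap or touch union their spans). Within each merged
#' region the supporting variant sites are counted; regions with fewer
#' than `min_variants_above` supporting sites are dropped. Interval
#' boundaries snap to the first and last variant position inside the
#' region, so reported coordinates are at variant resolution.
#'
#' Two readings of "variant sites above the threshold" are provided:
#' `count_above = "site"` (default) counts sites whose own per-site value
#' exceeds the cutoff, `"window"` counts sites lying inside at least one
#' above-cutoff window of the region.
#'
#' @param track A `window_track`.
#' @param sites Data frame `chrom`, `pos`, `value` of the channel's
#'   per-site statistic (used for boundary snapping and support counting).
#' @param cutoff Threshold value, e.g. from [empirical_threshold()].
#' @param min_variants_above Minimum supporting variants per region.
#' @param count_above Support-counting rule (see Details).
#' @param channel Optional channel label carried into the output.
#' @return A `candidate_intervals` data frame: `chrom`, `start`, `end`,
#'   `length`, `n_variants`, `n_above`, `peak`, `channel`. Zero rows when
#'   nothing passes.
#' @export
call_intervals <- function(track, sites, cutoff, min_variants_above = 10,
                           count_above = c("site", "window"),
                           channel = NA_character_) {
  count_above <- match.arg(count_above)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length = numeric(), n_variants = integer(),
                      n_above = integer(), peak = numeric(),
                      channel = character(), stringsAsFactors = FALSE)
  rows <- list(empty)
  for (chrom in unique(track$chrom)) {
    w <- track[track$chrom == chrom, ]
    w <- w[order(w$start), ]
    supra <- which(!is.na(w$value) & w$value > cutoff)
    if (length(supra) == 0) next
    s <- sites[sites$chrom == chrom, ]
    # group supra windows whose spans overlap or touch
    grp <- cumsum(c(1, cummax(w$end[supra])[-length(supra)] + 1 <
                      w$start[supra][-1]))
    for (g in unique(grp)) {
      wg <- supra[grp == g]
      span_lo <- min(w$start[wg]); span_hi <- max(w$end[wg])
      in_span <- !is.na(s$pos) & s$pos >= span_lo & s$pos <= span_hi
      if (!any(in_span)) next
      if (count_above == "site") {
        above <- in_span & !is.na(s$value) & s$value > cutoff
      } else {
        above <- rep(FALSE, nrow(s))
        for (k in wg)
          above <- above | (s$pos >= w$start[k] & s$pos <= w$end[k])
        above <- above & in_span
      }
      if (sum(above) < min_variants_above) next
      p <- s$pos[in_span]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = min(p), end = max(p),
        length = max(p) - min(p),
        n_variants = sum(in_span), n_above = sum(above),
        peak = max(w$value[wg]), channel = channel,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("candidate_intervals", "data.frame")
  out
}

#' Interval length in bp and Mb
#'
#' Length is `end - start` in bp (the convention of coordinate-difference
#' interval spans); the Mb value is rounded half-up to two decimals for
#' display.
#'
#' @param start,end 1-based interval coordinates with `start < end`.
#'   Vectorized.
#' @return A data frame with columns `bp` and `mb`.
#' @export
interval_length <- function(start, end) {
  if (any(start >= end)) stop("'start' must be < 'end'", call. = FALSE)
  bp <- end - start
  data.frame(bp = bp, mb = round_half_up(bp / 1e6, 2))
}

round_half_up <- function(x, digits) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Overlap and containment between two intervals
#'
#' @param a,b Lists or one-row data frames with `chrom`, `start`, `end`.
#' @return A list with `overlap_bp`, `frac_a`, `frac_b` (overlap as a
#'   fraction of each interval's length), and containment flags `a_in_b`,
#'   `b_in_a`. Different chromosomes give zero overlap and no containment.
#' @export
interval_overlap <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom)))
    return(list(overlap_bp = 0, frac_a = 0, frac_b = 0,
                a_in_b = FALSE, b_in_a = FALSE))
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  list(overlap_bp = ov,
       frac_a = ov / (a$end - a$start),
       frac_b = ov / (b$end - b$start),
       a_in_b = a$start >= b$start && a$end <= b$end,
       b_in_a = b$start >= a$start && b$end <= a$end)
}

#' Per-channel scan settings
#'
#' Defaults follow common BSA-seq practice: the delta SNP-index track uses
#' a 4 Mb window with 10 kb step (the classic QTL-seq smoothing scale,
#' which keeps the called interval wide enough to absorb peak-localization
#' noise), G' a 1 Mb tricube kernel aggregated on a 10 kb grid, and ED^4 a
#' 4 Mb window with 200 kb step; all channels use the 0.999 genome-wide
#' quantile and require at least 10 supporting variants per interval,
#' counted as sites whose own statistic exceeds the cutoff (see
#' [call_intervals()]).
#'
#' @param window,step Window size and step in bp per channel.
#' @param quantile Genome-wide quantile for the threshold.
#' @param min_variants_above Minimum supporting variants per interval.
#' @param count_above Support-counting rule, see [call_intervals()].
#' @return A list of per-channel settings.
#' @export
scan_config <- function(window = c(delta = 4e6, gprime = 1e6, ed4 = 4e6),
                        step = c(delta = 1e4, gprime = 1e4, ed4 = 2e5),
                        quantile = 0.999, min_variants_above = 10,
                        count_above = "site") {
  list(window = window, step = step, quantile = quantile,
       min_variants_above = min_variants_above, count_above = count_above)
}

#' Run the three-channel genome scan
#'
#' Smooths the per-site statistics of each requested channel into a window
#' track, derives the empirical genome-wide threshold, and calls candidate
#' intervals.
#'
#' @param stats A `site_stats` data frame from [compute_site_stats()].
#' @param channels Channels to scan: any of `"delta"`, `"gprime"`, `"ed4"`.
#' @param config Settings from [scan_config()].
#' @param chrom_lengths Optional named chromosome lengths in bp.
#' @return A list of class `bsa_scan`, one element per channel, each with
#'   `sites` (chrom, pos, value), `track`, `cutoff` and `intervals`.
#' @export
bsa_scan <- function(stats, channels = c("delta", "gprime", "ed4"),
                     config = scan_config(), chrom_lengths = NULL) {
  stopifnot(inherits(stats, "site_stats"))
  channels <- match.arg(channels, several.ok = TRUE)
  out <- list()
  for (ch in channels) {
    if (ch == "gprime") {
      g_sites <- data.frame(chrom = stats$chrom, pos = stats$pos,
                            value = stats$g_stat, stringsAsFactors = FALSE)
      sm <- smooth_g_prime(g_sites, config$window[["gprime"]],
                           config$step[["gprime"]], chrom_lengths)
      sites <- data.frame(chrom = sm$sites$chrom, pos = sm$sites$pos,
                          value = sm$sites$g_prime, stringsAsFactors = FALSE)
      track <- sm$track
    } else {
      col <- if (ch == "delta") "delta_index" else "ed4"
      sites <- data.frame(chrom = stats$chrom, pos = stats$pos,
                          value = stats[[col]], stringsAsFactors = FALSE)
      track <- smooth_window_mean(sites, config$window[[ch]],
                                  config$step[[ch]], chrom_lengths)
    }
    cutoff <- empirical_threshold(track, config$quantile)
    intervals <- call_intervals(track, sites, cutoff,
                                config$min_variants_above,
                                config$count_above, channel = ch)
    out[[ch]] <- list(sites = sites, track = track, cutoff = cutoff,
                      intervals = intervals)
  }
  class(out) <- "bsa_scan"
  out
}

#' Write a window track as Manhattan-plot-ready TSV
#'
#' @param track A `window_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write candidate intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so `start - 1` is written.
#'
#' @param intervals A `candidate_intervals` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(intervals$end, scientific = FALSE,
                                 trim = TRUE),
                    name = ifelse(is.na(intervals$channel), "interval",
                                  intervals$channel),
                    score = intervals$n_above)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
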