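# Per-site bulk association statistics: SNP-index, G, ED.

#' SNP-index: depth fraction of the parent-B allele
#'
#' The SNP-index of a bulk at a site is the fraction of its reads carrying
#' the allele inherited from parent B (the branched parent), so the
#' statistic is polarized identically at every site regardless of which
#' allele is ref or alt. Vectorized.
#'
#' @param ref_depth,alt_depth Read counts for the ref and alt allele.
#' @param parentB_allele `"ref"` or `"alt"`: which allele parent B carries.
#' @return Frequencies in [0, 1]; `NA` where total depth is zero (such
#'   sites are excluded from smoothing, never coerced to 0).
#' @export
snp_index <- function(ref_depth, alt_depth, parentB_allele) {
  stopifnot(all(parentB_allele %in% c("ref", "alt")))
  tot <- ref_depth + alt_depth
  b <- ifelse(parentB_allele == "alt", alt_depth, ref_depth)
  ifelse(tot > 0, b / tot, NA_real_)
}

#' Delta SNP-index between bulks
#'
#' @param index_low,index_high SNP-index of the low (non-branched) and high
#'   (branched) bulk.
#' @return `index_high - index_low`, in [-1, 1]; `NA` if either is `NA`.
#' @export
delta_index <- function(index_low, index_high) index_high - index_low

#' G statistic for a 2x2 bulk-by-allele read-count table
#'
#' The likelihood-ratio statistic G = 2 * sum(obs * ln(obs/exp)) over the
#' four cells of the (bulk x allele) table, with expected counts from the
#' row/column marginals under independence and the convention
#' 0 * ln(0) = 0. Natural logarithm. Vectorized over sites.
#'
#' @param low_ref,low_alt,high_ref,high_alt Cell counts: ref/alt read depths
#'   in the low and high bulk (the rows of the 2x2 table).
#' @return Nonnegative G values; `NA` where any marginal is zero (e.g. a
#'   bulk with zero depth), in which case the site is excluded from
#'   smoothing.
#' @export
g_statistic <- function(low_ref, low_alt, high_ref, high_alt) {
  n <- low_ref + low_alt + high_ref + high_alt
  r1 <- low_ref + low_alt
  r2 <- high_ref + high_alt
  c1 <- low_ref + high_ref
  c2 <- low_alt + high_alt
  term <- function(obs, expd) ifelse(obs > 0, obs * log(obs / expd), 0)
  g <- 2 * (term(low_ref, r1 * c1 / n) + term(low_alt, r1 * c2 / n) +
              term(high_ref, r2 * c1 / n) + term(high_alt, r2 * c2 / n))
  g[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- NA_real_
  pmax(g, 0)  # clamp tiny negative rounding residue
}

#' Euclidean distance between bulk allele-frequency vectors
#'
#' With biallelic frequencies the two-dimensional allele-frequency vectors
#' are (p, 1-p) and (q, 1-q), so ED = sqrt(2) * |p - q|; ED^4 sharpens
#' peaks relative to background before window smoothing.
#'
#' @param freq_low,freq_high Parent-B allele frequency in each bulk.
#' @return A list with `ed` and `ed4`; `NA` propagates.
#' @export
euclidean_distance <- function(freq_low, freq_high) {
  ed <- sqrt((freq_low - freq_high)^2 + ((1 - freq_low) - (1 - freq_high))^2)
  list(ed = ed, ed4 = ed^4)
}

#' Compute all per-site association statistics
#'
#' For every site of a (filtered) variant table, computes the SNP-index of
#' each bulk polarized to the parent-B allele, the delta SNP-index, the G
#' statistic on the bulk-by-allele read counts, and ED / ED^4. The
#' parent-B allele is taken from the majority allele of parent B's reads.
#' Statistics undefined at a site (zero depth, zero marginal) are carried
#' as `NA` and excluded from that channel's smoothing only.
#'
#' @param table A `variant_table`, normally after [filter_informative()].
#' @return A data frame of class `site_stats` with columns `chrom`, `pos`,
#'   `index_low`, `index_high`, `delta_index`, `g_stat`, `ed`, `ed4`.
#' @export
compute_site_stats <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  if (nrow(table) == 0) {
    out <- data.frame(chrom = character(), pos = numeric(),
                      index_low = numeric(), index_high = numeric(),
                      delta_index = numeric(), g_stat = numeric(),
                      ed = numeric(), ed4 = numeric())
    class(out) <- c("site_stats", "data.frame")
    return(out)
  }
  pb_allele <- ifelse(table$parentB_alt >= table$parentB_ref, "alt", "ref")
  idx_low <- snp_index(table$bulkLow_ref, table$bulkLow_alt, pb_allele)
  idx_high <- snp_index(table$bulkHigh_ref, table$bulkHigh_alt, pb_allele)
  edist <- euclidean_distance(idx_low, idx_high)
  out <- data.frame(
    chrom = table$chrom, pos = table$pos,
    index_low = idx_low, index_high = idx_high,
    delta_index = delta_index(idx_low, idx_high),
    g_stat = g_statistic(table$bulkLow_ref, table$bulkLow_alt,
                         table$bulkHigh_ref, table$bulkHigh_alt),
    ed = edist$ed, ed4 = edist$ed4,
    stringsAsFactors = FALSE)
  class(out) <- c("site_stats", "data.frame")
  out
}

#' Write per-site statistics as sorted TSV
#'
#' @param stats A `site_stats` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_stats <- function(stats, path) {
  utils::write.table(stats[order(stats$chrom, stats$pos), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
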