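#' Define a genome map for simulation
#'
#' A genome map holds chromosome lengths, per-chromosome marker positions and
#' the genetic-to-physical scaling used by the meiosis simulator.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp
#'   (names are chromosome identifiers).
#' @param marker_positions Named list (one element per chromosome, same names
#'   as `chromosomes`) of strictly increasing 1-based marker positions in bp.
#' @param cm_per_mb Genetic-to-physical scaling in centimorgan per megabase.
#'   May be zero (no recombination); must not be negative.
#'
#' @return An object of class `genome_map`.
#' @export
#' @examples
#' gm <- genome_map(c(chr1 = 1e6), list(chr1 = c(1e5, 5e5, 9e5)))
genome_map <- function(chromosomes, marker_positions, cm_per_mb = 1) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("'chromosomes' must be a named vector of lengths", call. = FALSE)
  if (any(chromosomes < 1))
    stop("chromosome lengths must be >= 1 bp", call. = FALSE)
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1 || cm_per_mb < 0)
    stop("'cm_per_mb' must be a single non-negative number", call. = FALSE)
  if (!setequal(names(marker_positions), names(chromosomes)))
    stop("'marker_positions' must have one element per chromosome", call. = FALSE)
  marker_positions <- lapply(marker_positions[names(chromosomes)], as.integer)
  for (chrom in names(chromosomes)) {
    pos <- marker_positions[[chrom]]
    if (length(pos) == 0) next
    if (is.unsorted(pos, strictly = TRUE))
      stop("marker positions on ", chrom, " must be strictly increasing",
           call. = FALSE)
    if (pos[1] < 1 || pos[length(pos)] > chromosomes[[chrom]])
      stop("marker positions on ", chrom, " fall outside [1, length]",
           call. = FALSE)
  }
  structure(
    list(chromosomes = chromosomes,
         marker_positions = marker_positions,
         cm_per_mb = cm_per_mb),
    class = "genome_map")
}

#' Define a monogenic dominant trait model
#'
#' The trait is controlled by a single causal locus with complete dominance of
#' the parent-A allele: genotypes AA and AH express the `"none"` (non-branched)
#' phenotype, BB expresses `"whole_plant"` branching. The causal position need
#' not coincide with a marker; meiosis is simulated at the exact position.
#'
#' @param causal_chrom Chromosome carrying the causal locus.
#' @param causal_pos 1-based bp position of the causal locus.
#' @param misclassification_rate Probability that a phenotype label is flipped
#'   (scoring error); must lie in [0, 0.5).
#'
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(causal_chrom, causal_pos, misclassification_rate = 0) {
  if (misclassification_rate < 0 || misclassification_rate >= 0.5)
    stop("'misclassification_rate' must be in [0, 0.5)", call. = FALSE)
  structure(
    list(causal_chrom = as.character(causal_chrom),
         causal_pos = as.numeric(causal_pos),
         dominance = "A-dominant",
         misclassification_rate = misclassification_rate),
    class = "trait_model")
}

#' Simulation configuration for bulk sequencing
#'
#' @param bulk_size Number of individuals pooled per bulk.
#' @param mean_depth_bulk Mean sequencing depth per bulk at a site.
#' @param mean_depth_parent Mean sequencing depth per parent at a site.
#' @param sequencing_error_rate Per-read probability of reading the opposite
#'   allele (applied symmetrically).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(bulk_size = 30, mean_depth_bulk = 30,
                       mean_depth_parent = 30, sequencing_error_rate = 0.001) {
  stopifnot(bulk_size >= 1, mean_depth_bulk > 0, mean_depth_parent > 0,
            sequencing_error_rate >= 0, sequencing_error_rate < 0.5)
  structure(
    list(bulk_size = as.integer(bulk_size),
         mean_depth_bulk = mean_depth_bulk,
         mean_depth_parent = mean_depth_parent,
         sequencing_error_rate = sequencing_error_rate),
    class = "sim_config")
}
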