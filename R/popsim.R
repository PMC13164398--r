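# F2 meiosis and bulk-sequencing simulator.
#
# Crossovers follow the Haldane model: a Poisson number with mean equal to
# the chromosome's genetic length in Morgans, placed uniformly, no
# interference. Each F2 individual is the union of two independent F1
# gametes, so marker genotypes segregate 1:2:1 and a fully dominant locus
# yields a 3:1 phenotype ratio.

# Phase vector (0 = parent-A strand, 1 = parent-B strand) of one gamete at
# the query positions. `xo` are crossover positions, `start` the phase at
# the chromosome origin.
gamete_phase <- function(query_pos, xo, start) {
  if (length(xo) == 0) return(rep.int(start, length(query_pos)))
  (start + findInterval(query_pos, sort(xo))) %% 2L
}

#' Simulate an F2 population
#'
#' Simulates `n` F2 individuals from a cross of two fully homozygous, fully
#' diverged inbred parents. Each individual is formed from two independent
#' F1 gametes; each gamete draws a Poisson number of crossovers with mean
#' equal to the chromosome's genetic length in Morgans (Haldane mapping, no
#' interference), places them uniformly, and alternates parental phase.
#' Phenotypes follow the causal-locus genotype under complete dominance of
#' the parent-A allele and are then flipped with the model's
#' misclassification rate.
#'
#' @param genome A [genome_map()].
#' @param trait A [trait_model()], or `NULL` for a null population in which
#'   phenotypes are drawn independently of genotype with branching
#'   probability 1/4 (the expected recessive-class frequency).
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; fully determines the output.
#'
#' @return An `f2_population`: a list with `geno` (n x markers integer matrix
#'   of parent-B allele dosages 0/1/2, i.e. codes A/H/B), `markers` (data
#'   frame of `chrom`, `pos`), `phenotype` (character, `"none"` or
#'   `"whole_plant"`), and `causal_dosage` (dosage at the exact causal
#'   position; `NA` for null populations).
#' @export
simulate_f2 <- function(genome, trait, n, seed) {
  stopifnot(inherits(genome, "genome_map"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("'n' must be a count >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(trait)) {
    stopifnot(inherits(trait, "trait_model"))
    if (!trait$causal_chrom %in% names(genome$chromosomes))
      stop("causal chromosome '", trait$causal_chrom,
           "' not present in genome", call. = FALSE)
    if (trait$causal_pos < 1 ||
        trait$causal_pos > genome$chromosomes[[trait$causal_chrom]])
      stop("causal position outside chromosome bounds", call. = FALSE)
  }

  withr::with_seed(seed, {
    chroms <- names(genome$chromosomes)
    geno_blocks <- vector("list", length(chroms))
    causal_dosage <- rep(NA_integer_, n)

    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      len <- genome$chromosomes[[chrom]]
      pos <- genome$marker_positions[[chrom]]
      is_causal_chrom <- !is.null(trait) && identical(chrom, trait$causal_chrom)
      # evaluate the gamete phase at markers plus, if needed, the causal point
      query <- pos
      if (is_causal_chrom) query <- c(pos, trait$causal_pos)
      morgans <- len / 1e6 * genome$cm_per_mb / 100
      dos <- matrix(0L, nrow = n, ncol = length(query))
      n_xo <- stats::rpois(2L * n, morgans)
      starts <- sample(c(0L, 1L), 2L * n, replace = TRUE)
      for (i in seq_len(n)) {
        g1 <- 2L * i - 1L
        g2 <- 2L * i
        p1 <- gamete_phase(query, stats::runif(n_xo[g1], 0, len), starts[g1])
        p2 <- gamete_phase(query, stats::runif(n_xo[g2], 0, len), starts[g2])
        dos[i, ] <- p1 + p2
      }
      if (is_causal_chrom) {
        causal_dosage <- dos[, length(query)]
        dos <- dos[, seq_along(pos), drop = FALSE]
      }
      geno_blocks[[ci]] <- dos
    }

    geno <- do.call(cbind, geno_blocks)
    markers <- data.frame(
      chrom = rep(chroms, lengths(genome$marker_positions)),
      pos = unlist(genome$marker_positions, use.names = FALSE),
      stringsAsFactors = FALSE)
    colnames(geno) <- paste(markers$chrom, markers$pos, sep = "_")

    if (is.null(trait)) {
      phenotype <- ifelse(stats::runif(n) < 0.25, "whole_plant", "none")
    } else {
      phenotype <- ifelse(causal_dosage == 2L, "whole_plant", "none")
      if (trait$misclassification_rate > 0) {
        flip <- stats::runif(n) < trait$misclassification_rate
        phenotype[flip] <- ifelse(phenotype[flip] == "none",
                                  "whole_plant", "none")
      }
    }

    structure(
      list(geno = geno, markers = markers, phenotype = phenotype,
           causal_dosage = if (is.null(trait)) rep(NA_integer_, n) else causal_dosage),
      class = "f2_population")
  })
}

#' Select extreme-phenotype bulks from an F2 population
#'
#' Draws `bulk_size` individuals uniformly without replacement from each of
#' the two phenotype classes: the low bulk from the `"none"` (non-branched)
#' class and the high bulk from the `"whole_plant"` (branched) class. The
#' bulks are disjoint by construction because the classes are.
#'
#' @param pop An `f2_population`.
#' @param bulk_size Individuals per bulk; each class must have at least this
#'   many members.
#' @param seed Integer seed.
#'
#' @return A list with integer index vectors `low` and `high`.
#' @export
make_bulks <- function(pop, bulk_size, seed) {
  stopifnot(inherits(pop, "f2_population"), bulk_size >= 1)
  none_idx <- which(pop$phenotype == "none")
  branched_idx <- which(pop$phenotype == "whole_plant")
  if (length(none_idx) < bulk_size)
    stop("phenotype class 'none' has ", length(none_idx),
         " members; need >= ", bulk_size, call. = FALSE)
  if (length(branched_idx) < bulk_size)
    stop("phenotype class 'whole_plant' has ", length(branched_idx),
         " members; need >= ", bulk_size, call. = FALSE)
  withr::with_seed(seed, {
    list(low = sort(sample(none_idx, bulk_size)),
         high = sort(sample(branched_idx, bulk_size)))
  })
}

#' Simulate bulk and parent sequencing of all markers
#'
#' Emulates whole-genome resequencing of the two parents and the two DNA
#' bulks at every marker. For each marker the true parent-B allele frequency
#' in a bulk is the dosage mean over bulk members; per-sample site depth is
#' Poisson, and read counts are binomial with the frequency shifted toward
#' the opposite allele by the sequencing error rate. Parents are emitted as
#' fixed opposite homozygotes. Ref/alt orientation is randomized per site
#' (parent B carries the alt allele at roughly half of sites), so downstream
#' statistics must polarize explicitly.
#'
#' @param pop An `f2_population` covering all markers of `genome`.
#' @param bulks Index sets from [make_bulks()].
#' @param genome The [genome_map()] used to simulate `pop`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#'
#' @return A `variant_table` data frame (see [variant_table()]).
#' @export
sequence_bulks <- function(pop, bulks, genome, cfg, seed) {
  stopifnot(inherits(pop, "f2_population"), inherits(cfg, "sim_config"))
  m <- nrow(pop$markers)
  if (ncol(pop$geno) != m)
    stop("population genotype matrix does not cover the genome's markers",
         call. = FALSE)
  err <- cfg$sequencing_error_rate

  withr::with_seed(seed, {
    freq_low <- colSums(pop$geno[bulks$low, , drop = FALSE]) /
      (2 * length(bulks$low))
    freq_high <- colSums(pop$geno[bulks$high, , drop = FALSE]) /
      (2 * length(bulks$high))

    # parent B carries alt where orient is TRUE
    orient <- stats::runif(m) < 0.5
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")

    draw_bulk <- function(freq, depth_mean) {
      dp <- stats::rpois(m, depth_mean)
      f_obs <- freq * (1 - err) + (1 - freq) * err
      b_reads <- stats::rbinom(m, dp, f_obs)
      list(dp = dp, b = b_reads)
    }
    low <- draw_bulk(freq_low, cfg$mean_depth_bulk)
    high <- draw_bulk(freq_high, cfg$mean_depth_bulk)
    pa <- draw_bulk(rep(0, m), cfg$mean_depth_parent)   # parent A: all A allele
    pb <- draw_bulk(rep(1, m), cfg$mean_depth_parent)   # parent B: all B allele

    # map parent-B-allele read counts onto ref/alt given orientation
    to_ref_alt <- function(x) {
      alt_d <- ifelse(orient, x$b, x$dp - x$b)
      data.frame(ref = x$dp - alt_d, alt = alt_d)
    }
    pa_d <- to_ref_alt(pa); pb_d <- to_ref_alt(pb)
    lo_d <- to_ref_alt(low); hi_d <- to_ref_alt(high)

    variant_table(data.frame(
      chrom = pop$markers$chrom, pos = pop$markers$pos,
      ref = ref, alt = alt,
      qual = 100, mq = 60,
      parentA_ref = pa_d$ref, parentA_alt = pa_d$alt,
      parentB_ref = pb_d$ref, parentB_alt = pb_d$alt,
      bulkLow_ref = lo_d$ref, bulkLow_alt = lo_d$alt,
      bulkHigh_ref = hi_d$ref, bulkHigh_alt = hi_d$alt,
      stringsAsFactors = FALSE))
  })
}

#' Convenience wrapper: simulate a full BSA-seq variant table
#'
#' Runs [simulate_f2()], [make_bulks()] and [sequence_bulks()] with
#' sub-seeds derived from one root seed.
#'
#' @inheritParams simulate_f2
#' @param cfg A [sim_config()].
#' @return A list with `pop`, `bulks` and `variants`.
#' @export
simulate_bsa <- function(genome, trait, n, cfg, seed) {
  pop <- simulate_f2(genome, trait, n, derive_seed(seed, "simulate_f2"))
  bulks <- make_bulks(pop, cfg$bulk_size, derive_seed(seed, "make_bulks"))
  variants <- sequence_bulks(pop, bulks, genome, cfg,
                             derive_seed(seed, "sequence_bulks"))
  list(pop = pop, bulks = bulks, variants = variants)
}

#' Reference F2/BSA study design
#'
#' The experimental design the simulator emulates: a sunflower-scale genome
#' of 17 chromosomes x 176 Mb at 1 cM/Mb, an F2 of 660 individuals from two
#' fully diverged inbreds, a single causal locus on chromosome 10 with the
#' non-branching allele completely dominant, bulks of 30 extreme individuals
#' each, and ~30x short-read depth per bulk and parent. Markers are placed
#' uniformly at random: 2,000 on the causal chromosome and 500 on each other
#' chromosome (10,000 genome-wide), a density at which the ten-variant
#' interval-support rule retains its discriminating power.
#'
#' @param design_seed Seed for the (fixed) marker placement; the default
#'   defines the reference design.
#' @return A list with `genome` ([genome_map()]), `trait` ([trait_model()]),
#'   `cfg` ([sim_config()]), `n`, and `causal_pos`.
#' @export
study_design <- function(design_seed = 99) {
  chroms <- stats::setNames(rep(176e6, 17), paste0("Chr", 1:17))
  mk <- withr::with_seed(design_seed, {
    lapply(seq_along(chroms), function(i)
      sort(sample.int(176e6, if (i == 10) 2000 else 500)))
  })
  names(mk) <- names(chroms)
  genome <- genome_map(chroms, mk, cm_per_mb = 1)
  causal_pos <- mk$Chr10[which.min(abs(mk$Chr10 - 88e6))]
  list(genome = genome,
       trait = trait_model("Chr10", causal_pos),
       cfg = sim_config(bulk_size = 30, mean_depth_bulk = 30,
                        mean_depth_parent = 30,
                        sequencing_error_rate = 0.001),
       n = 660,
       causal_pos = causal_pos)
}

# Deterministic per-stage sub-seed below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) * 97561.0
  as.integer((as.numeric(seed) + offs) %% 2147483647)
}
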