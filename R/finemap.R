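# Recombinant-breakpoint fine-mapping under a dominance model.

#' Construct a recombinant panel
#'
#' A recombinant panel holds ordered markers on one chromosome, genotype
#' codes per individual (`A` = parent-A homozygote, `H` = heterozygote,
#' `B` = parent-B homozygote, `NA` = missing) and a binary phenotype.
#'
#' @param markers Data frame with `chrom` (single chromosome) and sorted
#'   `pos`.
#' @param geno Character matrix (individuals x markers) of codes.
#' @param phenotype Character vector, `"none"` or `"whole_plant"`.
#' @return An object of class `recombinant_panel`.
#' @export
recombinant_panel <- function(markers, geno, phenotype) {
  geno <- as.matrix(geno)
  if (length(unique(markers$chrom)) != 1)
    stop("panel markers must lie on a single chromosome", call. = FALSE)
  if (is.unsorted(markers$pos, strictly = TRUE))
    stop("marker positions must be strictly increasing", call. = FALSE)
  if (ncol(geno) != nrow(markers))
    stop("genotype matrix must have one column per marker", call. = FALSE)
  if (length(phenotype) != nrow(geno))
    stop("one phenotype per individual required", call. = FALSE)
  if (!all(geno %in% c("A", "H", "B") | is.na(geno)))
    stop("genotype codes must be A, H, B or NA", call. = FALSE)
  if (!all(phenotype %in% c("none", "whole_plant")))
    stop("phenotypes must be 'none' or 'whole_plant'", call. = FALSE)
  if (any(rowSums(!is.na(geno)) == 0))
    stop("each individual needs at least one non-missing call", call. = FALSE)
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  colnames(geno) <- NULL
  structure(list(markers = as.data.frame(markers), geno = geno,
                 phenotype = phenotype),
            class = "recombinant_panel")
}

#' Maximal same-genotype blocks along ordered markers
#'
#' Merges consecutive identical genotype codes of one individual into
#' blocks. Missing calls are absorbed into neither block: a breakpoint
#' between two blocks is localized to the span between the flanking
#' non-missing markers.
#'
#' @param codes Character vector of genotype codes along ordered markers
#'   (`A`/`H`/`B`/`NA`).
#' @return A data frame with one row per block: `code`, `from`, `to`
#'   (indices of the block's first and last non-missing marker).
#' @export
genotype_blocks <- function(codes) {
  obs <- which(!is.na(codes))
  if (length(obs) == 0)
    stop("individual has no non-missing genotype call", call. = FALSE)
  r <- rle(codes[obs])
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  data.frame(code = r$values, from = obs[starts], to = obs[ends],
             stringsAsFactors = FALSE)
}

#' Delimit the causal locus from recombinant genotypes and phenotypes
#'
#' Under complete dominance of the parent-A allele, a branched
#' (`whole_plant`) individual must be `B` at the causal locus, so its `A`
#' and `H` blocks are excluded; a non-branched (`none`) individual cannot
#' be `B` there, so its `B` blocks are excluded. Missing calls constrain
#' nothing. The allowed region is the intersection of all individuals'
#' constraints; boundaries are reported at the nearest excluded marker
#' flanking the allowed run (the locus lies between those markers), or at
#' the panel's outermost marker when the allowed run reaches the panel
#' edge. An empty intersection sets `consistent = FALSE` and lists the
#' individuals whose removal would restore consistency.
#'
#' @param panel A [recombinant_panel()].
#' @param dominance Only `"A-dominant"` is implemented (non-branched
#'   phenotype dominant); the flag exists so the direction is explicit.
#' @return An object of class `delimited_interval`: `chrom`, `left_pos`,
#'   `right_pos`, marker indices, `allowed` marker indices, `contiguous`,
#'   `consistent`, `offending` individuals, and `boundary_individuals`
#'   (those whose constraints set each boundary).
#' @export
delimit_locus <- function(panel, dominance = "A-dominant") {
  stopifnot(inherits(panel, "recombinant_panel"))
  dominance <- match.arg(dominance)
  geno <- panel$geno
  m <- ncol(geno)
  excl <- matrix(FALSE, nrow(geno), m, dimnames = dimnames(geno))
  branched <- panel$phenotype == "whole_plant"
  excl[branched, ] <- !is.na(geno[branched, , drop = FALSE]) &
    geno[branched, , drop = FALSE] != "B"
  excl[!branched, ] <- !is.na(geno[!branched, , drop = FALSE]) &
    geno[!branched, , drop = FALSE] == "B"

  allowed <- which(colSums(excl) == 0)
  chrom <- panel$markers$chrom[1]
  ind_names <- rownames(geno)

  if (length(allowed) == 0) {
    offending <- ind_names[vapply(seq_len(nrow(geno)), function(i) {
      others <- colSums(excl[-i, , drop = FALSE]) == 0
      any(others)
    }, TRUE)]
    if (length(offending) == 0) offending <- ind_names
    return(structure(
      list(chrom = chrom, left_pos = NA_real_, right_pos = NA_real_,
           left_marker = NA_integer_, right_marker = NA_integer_,
           allowed = integer(0), contiguous = NA, consistent = FALSE,
           offending = offending,
           boundary_individuals = list(left = character(0),
                                       right = character(0))),
      class = "delimited_interval"))
  }

  lo <- min(allowed); hi <- max(allowed)
  left_marker <- if (lo > 1) lo - 1L else lo
  right_marker <- if (hi < m) hi + 1L else hi
  bnd <- function(j) ind_names[excl[, j]]
  structure(
    list(chrom = chrom,
         left_pos = panel$markers$pos[left_marker],
         right_pos = panel$markers$pos[right_marker],
         left_marker = left_marker, right_marker = right_marker,
         allowed = allowed,
         contiguous = length(allowed) == hi - lo + 1,
         consistent = TRUE, offending = character(0),
         boundary_individuals = list(
           left = if (lo > 1) bnd(lo - 1L) else character(0),
           right = if (hi < m) bnd(hi + 1L) else character(0))),
    class = "delimited_interval")
}

#' @method print delimited_interval
#' @export
print.delimited_interval <- function(x, ...) {
  if (!x$consistent) {
    cat("Inconsistent panel; offending individual(s):",
        paste(x$offending, collapse = ", "), "\n")
  } else {
    cat(sprintf("Locus delimited to %s:%s-%s (%s markers allowed)\n",
                x$chrom, format(x$left_pos, big.mark = ",", scientific = FALSE),
                format(x$right_pos, big.mark = ",", scientific = FALSE),
                length(x$allowed)))
  }
  invisible(x)
}

#' Select well-spaced genotyping-marker candidates in a region
#'
#' Candidates are sites of the variant table inside the region that pass
#' the informative-marker filters (including fixed opposite parental
#' homozygosity) and have no other variant within `flank_clear` bp on
#' either side (a proxy for stable flanking sequence in allele-specific
#' PCR design). From the candidates, `n_markers` are chosen to maximize
#' the minimum spacing, where spacing is measured between chosen markers
#' and also to the region endpoints; the maximal feasible spacing is found
#' by bisection with a left-to-right greedy feasibility check.
#'
#' @param table A `variant_table` (unfiltered is fine; filters are applied
#'   internally, clearance is checked against every input variant).
#' @param chrom,start,end Target region (1-based inclusive).
#' @param n_markers Number of markers wanted.
#' @param flank_clear Minimum clear flank in bp.
#' @param thresholds A [filter_thresholds()] for candidate eligibility.
#' @return A data frame of selected markers (`chrom`, `pos`,
#'   `clearance_bp`), with attribute `n_candidates`. If fewer candidates
#'   than `n_markers` exist, all are returned with a warning.
#' @export
select_markers <- function(table, chrom, start, end, n_markers,
                           flank_clear = 50,
                           thresholds = filter_thresholds()) {
  stopifnot(start < end, n_markers >= 1)
  on_chrom <- table[table$chrom == chrom, ]
  all_pos <- sort(on_chrom$pos)
  flt <- filter_informative(on_chrom, thresholds)$variants
  cand <- flt$pos[flt$pos >= start & flt$pos <= end]
  # clearance to the nearest other variant (any variant, filtered or not)
  clearance <- vapply(cand, function(p) {
    d <- abs(all_pos - p)
    min(d[d > 0], Inf)
  }, 0)
  keep <- clearance > flank_clear
  cand <- cand[keep]
  clearance <- clearance[keep]

  if (length(cand) == 0) {
    warning("no eligible marker candidates in region")
    out <- data.frame(chrom = character(), pos = numeric(),
                      clearance_bp = numeric())
    attr(out, "n_candidates") <- 0L
    return(out)
  }
  if (length(cand) <= n_markers) {
    if (length(cand) < n_markers)
      warning("only ", length(cand), " candidate(s) for ", n_markers,
              " requested markers; returning all")
    sel <- cand
  } else {
    sel <- max_min_spacing_select(cand, start, end, n_markers)
  }
  out <- data.frame(chrom = chrom, pos = sel,
                    clearance_bp = clearance[match(sel, cand)])
  attr(out, "n_candidates") <- length(cand)
  out
}

# Greedy feasibility: can n points with pairwise-and-endpoint spacing >= d
# be chosen from sorted candidates in [start, end]?
spacing_feasible <- function(cand, start, end, n, d) {
  last <- start
  sel <- numeric(0)
  for (p in cand) {
    if (p - last >= d) {
      sel <- c(sel, p)
      last <- p
      if (length(sel) == n) break
    }
  }
  if (length(sel) < n || end - last < d) NULL else sel
}

max_min_spacing_select <- function(cand, start, end, n) {
  lo <- 0
  hi <- (end - start) / (n + 1) + 1
  best <- spacing_feasible(cand, start, end, n, 0)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    sel <- spacing_feasible(cand, start, end, n, mid)
    if (!is.null(sel)) {
      best <- sel
      lo <- mid
    } else hi <- mid
  }
  best
}

#' Build a recombinant panel from a simulated population
#'
#' Extracts the genotype codes of a marker subset on one chromosome and,
#' optionally, keeps only individuals that are recombinant across those
#' markers (not uniformly A, H or B), which is how informative individuals
#' are chosen for fine-mapping.
#'
#' @param pop An `f2_population` from [simulate_f2()].
#' @param chrom Chromosome name.
#' @param positions Marker positions to genotype (must exist in `pop`).
#' @param recombinants_only Keep only non-uniform individuals.
#' @param max_individuals Optional cap on panel size (the first
#'   `max_individuals` qualifying individuals, in population order) —
#'   recombinant screens typically genotype a handful of informative
#'   plants, not the whole population.
#' @return A [recombinant_panel()].
#' @export
panel_from_population <- function(pop, chrom, positions,
                                  recombinants_only = TRUE,
                                  max_individuals = NULL) {
  stopifnot(inherits(pop, "f2_population"))
  idx <- match(paste(chrom, as.integer(positions), sep = "_"),
               colnames(pop$geno))
  if (anyNA(idx))
    stop("some requested positions are not markers of the population",
         call. = FALSE)
  codes <- matrix(c("A", "H", "B")[pop$geno[, idx, drop = FALSE] + 1L],
                  nrow = nrow(pop$geno))
  rownames(codes) <- paste0("ind", seq_len(nrow(codes)))
  keep <- rep(TRUE, nrow(codes))
  if (recombinants_only)
    keep <- apply(codes, 1, function(r) length(unique(r)) > 1)
  keep <- which(keep)
  if (!is.null(max_individuals)) keep <- utils::head(keep, max_individuals)
  recombinant_panel(
    markers = data.frame(chrom = chrom, pos = positions),
    geno = codes[keep, , drop = FALSE],
    phenotype = pop$phenotype[keep])
}

#' Read / write a recombinant panel as TSV
#'
#' Markers are columns named `chrom:pos`, individuals are rows (first
#' column `individual`), and the final column is `phenotype`.
#'
#' @param panel A `recombinant_panel`.
#' @param path File path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   `recombinant_panel`.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel$geno, stringsAsFactors = FALSE)
  names(df) <- paste(panel$markers$chrom, panel$markers$pos, sep = ":")
  df <- cbind(individual = rownames(panel$geno), df,
              phenotype = panel$phenotype)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  marker_cols <- setdiff(names(df), c("individual", "phenotype"))
  parts <- strsplit(marker_cols, ":", fixed = TRUE)
  markers <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.numeric(vapply(parts, `[`, "", 2)))
  geno <- as.matrix(df[, marker_cols, drop = FALSE])
  rownames(geno) <- df$individual
  recombinant_panel(markers, geno, df$phenotype)
}
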