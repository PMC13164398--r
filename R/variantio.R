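# Variant table I/O and informative-marker filtering.

VT_COLS <- c("chrom", "pos", "ref", "alt", "qual", "mq",
             "parentA_ref", "parentA_alt", "parentB_ref", "parentB_alt",
             "bulkLow_ref", "bulkLow_alt", "bulkHigh_ref", "bulkHigh_alt")

#' Construct a variant table
#'
#' A variant table holds one biallelic site per row with per-sample ref/alt
#' allele depths for the two parents and the two bulks. Positions are
#' 1-based and sorted within chromosome. A `class` column tags each site as
#' `snp` or `indel` from the allele lengths.
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `mq`, and `<sample>_ref`/`<sample>_alt` depth pairs for samples
#'   `parentA`, `parentB`, `bulkLow`, `bulkHigh`.
#'
#' @return A data frame of class `variant_table`.
#' @export
variant_table <- function(df) {
  missing_cols <- setdiff(VT_COLS, names(df))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, c(VT_COLS, setdiff(names(df), VT_COLS))]
  depth_cols <- grep("_(ref|alt)$", names(df), value = TRUE)
  for (col in depth_cols) {
    df[[col]][is.na(df[[col]])] <- 0L
    if (any(df[[col]] < 0))
      stop("negative depth in column ", col, call. = FALSE)
    df[[col]] <- as.integer(df[[col]])
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df$class <- ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1, "snp", "indel")
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Load a parent-plus-bulk variant table from VCF or TSV
#'
#' Reads a four-sample variant file into a [variant_table()]. For VCF input,
#' per-sample allele depths come from the `AD` FORMAT field and mapping
#' quality from the `MQ` INFO field; `sample_roles` maps the VCF sample
#' names onto the four roles. Multi-allelic records are dropped and counted
#' (the count is reported in attribute `n_multiallelic` and a message).
#' Missing depth fields are treated as zero depth.
#'
#' @param path Input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param sample_roles Named character vector mapping roles to sample names,
#'   e.g. `c(parentA = "150A", parentB = "PT326", bulkLow = "pool_none",
#'   bulkHigh = "pool_branched")`. Required for VCF unless the file's
#'   samples are already named after the roles; ignored for TSV, whose
#'   column order is fixed.
#'
#' @return A `variant_table` with attribute `n_multiallelic`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          sample_roles = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") read_variants_tsv(path) else
    read_variants_vcf(path, sample_roles)
}

read_variants_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  multi <- grepl(",", df$alt, fixed = TRUE)
  if (any(multi)) {
    message("dropped ", sum(multi), " multi-allelic record(s)")
    df <- df[!multi, , drop = FALSE]
  }
  out <- variant_table(df)
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

read_variants_vcf <- function(path, sample_roles) {
  roles <- c("parentA", "parentB", "bulkLow", "bulkHigh")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_roles)) {
    if (!all(roles %in% samples))
      stop("'sample_roles' is required unless VCF samples are named ",
           paste(roles, collapse = "/"), call. = FALSE)
    sample_roles <- stats::setNames(roles, roles)
  }
  if (!all(roles %in% names(sample_roles)))
    stop("sample_roles must assign all of: ", paste(roles, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_roles[roles]))
    stop("sample_roles must map roles to distinct samples", call. = FALSE)
  missing_s <- setdiff(unname(sample_roles[roles]), samples)
  if (length(missing_s))
    stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "),
         call. = FALSE)

  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) message("dropped ", sum(multi), " multi-allelic record(s)")
  keep <- !multi

  ad <- vcfR::extract.gt(vcf, element = "AD")
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "MQ")))

  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x) | x == ".", "0,0", x), ",", fixed = TRUE)
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else "0", "")))
    ref[is.na(ref)] <- 0L; alt[is.na(alt)] <- 0L
    data.frame(ref = ref, alt = alt)
  }

  df <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = mq, stringsAsFactors = FALSE)
  for (role in roles) {
    d <- parse_ad(ad[, sample_roles[[role]]])
    df[[paste0(role, "_ref")]] <- d$ref
    df[[paste0(role, "_alt")]] <- d$alt
  }
  out <- variant_table(df[keep, , drop = FALSE])
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Write a variant table to TSV or VCF
#'
#' The TSV dialect is the table's own column layout (chrom, pos, ref, alt,
#' qual, mq, then ref/alt depth per sample in the fixed order parentA,
#' parentB, bulkLow, bulkHigh) and round-trips exactly through
#' [read_variants()]. The VCF output is minimal VCF 4.2 with `GT:AD:DP`
#' FORMAT fields, `MQ` in INFO, and parent genotypes called from their
#' majority allele.
#'
#' @param table A `variant_table`.
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(table, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(table[, VT_COLS], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  gt_parent <- function(ref_d, alt_d) ifelse(alt_d > ref_d, "1/1", "0/0")
  fmt <- function(gt, ref_d, alt_d)
    sprintf("%s:%d,%d:%d", gt, ref_d, alt_d, ref_d + alt_d)
  body <- data.frame(
    CHROM = table$chrom, POS = format(table$pos, scientific = FALSE, trim = TRUE),
    ID = ".", REF = table$ref, ALT = table$alt,
    QUAL = table$qual, FILTER = "PASS",
    INFO = sprintf("MQ=%g", table$mq), FORMAT = "GT:AD:DP",
    parentA = fmt(gt_parent(table$parentA_ref, table$parentA_alt),
                  table$parentA_ref, table$parentA_alt),
    parentB = fmt(gt_parent(table$parentB_ref, table$parentB_alt),
                  table$parentB_ref, table$parentB_alt),
    bulkLow = fmt("./.", table$bulkLow_ref, table$bulkLow_alt),
    bulkHigh = fmt("./.", table$bulkHigh_ref, table$bulkHigh_alt),
    stringsAsFactors = FALSE, check.names = FALSE)
  contigs <- unique(table$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    paste0("##contig=<ID=", contigs, ">"),
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "parentA", "parentB", "bulkLow", "bulkHigh"),
          collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filtering thresholds for informative markers
#'
#' @param min_qual Minimum site quality (QUAL).
#' @param min_mq Minimum mapping quality (MQ).
#' @param min_parent_depth Minimum total depth in each parent.
#' @param min_bulk_depth Minimum total depth in each bulk.
#' @param hom_frac Fraction of a parent's reads that must support a single
#'   allele for the parent to be called homozygous. The fixed-opposite-
#'   homozygote rule uses this call; 0.9 tolerates sequencing error while
#'   rejecting genuinely heterozygous parents.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_qual = 30, min_mq = 30,
                              min_parent_depth = 10, min_bulk_depth = 15,
                              hom_frac = 0.9) {
  stopifnot(min_qual >= 0, min_mq >= 0, min_parent_depth >= 0,
            min_bulk_depth >= 0, hom_frac > 0.5, hom_frac <= 1)
  structure(list(min_qual = min_qual, min_mq = min_mq,
                 min_parent_depth = min_parent_depth,
                 min_bulk_depth = min_bulk_depth, hom_frac = hom_frac),
            class = "filter_thresholds")
}

#' Filter a variant table down to informative markers
#'
#' Applies, in a fixed order, the site-quality, mapping-quality, parent-
#' depth, bulk-depth and parental-fixation rules. A site is retained when
#' QUAL and MQ meet their minima, each parent's total depth meets
#' `min_parent_depth`, each bulk's total depth meets `min_bulk_depth`, and
#' the two parents are homozygous (>= `hom_frac` of reads on one allele)
#' for opposite alleles. Each excluded site is attributed to the first rule
#' it fails, so the per-rule exclusion counts plus the retained count equal
#' the input count. The operation is idempotent.
#'
#' @param table A `variant_table`.
#' @param thresholds A [filter_thresholds()].
#'
#' @return A list of class `filtered_variants` with elements `variants`
#'   (the retained `variant_table`), `exclusions` (named integer vector of
#'   per-rule exclusion counts, in rule order), `n_input` and `n_retained`.
#' @export
filter_informative <- function(table, thresholds = filter_thresholds()) {
  stopifnot(inherits(table, "variant_table"),
            inherits(thresholds, "filter_thresholds"))
  th <- thresholds
  pa_tot <- table$parentA_ref + table$parentA_alt
  pb_tot <- table$parentB_ref + table$parentB_alt
  lo_tot <- table$bulkLow_ref + table$bulkLow_alt
  hi_tot <- table$bulkHigh_ref + table$bulkHigh_alt

  hom_allele <- function(ref_d, alt_d, tot) {
    # 1 = hom ref, 2 = hom alt, NA = not homozygous (or zero depth)
    out <- rep(NA_integer_, length(tot))
    ok_ref <- tot > 0 & ref_d / tot >= th$hom_frac
    ok_alt <- tot > 0 & alt_d / tot >= th$hom_frac
    out[ok_ref] <- 1L
    out[ok_alt] <- 2L
    out
  }
  pa_hom <- hom_allele(table$parentA_ref, table$parentA_alt, pa_tot)
  pb_hom <- hom_allele(table$parentB_ref, table$parentB_alt, pb_tot)

  rules <- list(
    qual = !is.na(table$qual) & table$qual >= th$min_qual,
    mapping_quality = !is.na(table$mq) & table$mq >= th$min_mq,
    parent_depth = pa_tot >= th$min_parent_depth & pb_tot >= th$min_parent_depth,
    bulk_depth = lo_tot >= th$min_bulk_depth & hi_tot >= th$min_bulk_depth,
    parent_fixation = !is.na(pa_hom) & !is.na(pb_hom) & pa_hom != pb_hom)

  remaining <- rep(TRUE, nrow(table))
  exclusions <- integer(length(rules))
  names(exclusions) <- names(rules)
  for (rule in names(rules)) {
    failed <- remaining & !rules[[rule]]
    exclusions[[rule]] <- sum(failed)
    remaining <- remaining & rules[[rule]]
  }
  kept <- table[remaining, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("variant_table", "data.frame")
  structure(list(variants = kept, exclusions = exclusions,
                 n_input = nrow(table), n_retained = nrow(kept)),
            class = "filtered_variants")
}

#' @method print filtered_variants
#' @export
print.filtered_variants <- function(x, ...) {
  cat("Informative-marker filter:", x$n_retained, "of", x$n_input,
      "sites retained\n")
  for (rule in names(x$exclusions))
    cat(sprintf("  excluded by %-16s %d\n", paste0(rule, ":"),
                x$exclusions[[rule]]))
  invisible(x)
}
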