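# Shared in-code fixtures: small genomes and hand-sized variant tables.

toy_genome <- function(cm_per_mb = 1, n_markers = 20, len = 5e7) {
  chroms <- c(chrA = len, chrB = len)
  withr::with_seed(7, {
    mk <- lapply(chroms, function(L) sort(sample.int(L, n_markers)))
  })
  genome_map(chroms, mk, cm_per_mb = cm_per_mb)
}

# One variant-table row with sensible defaults, overridable per field.
vt_row <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                   qual = 100, mq = 60,
                   pa = c(20, 0), pb = c(0, 20),
                   lo = c(15, 15), hi = c(15, 15)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             qual = qual, mq = mq,
             parentA_ref = pa[1], parentA_alt = pa[2],
             parentB_ref = pb[1], parentB_alt = pb[2],
             bulkLow_ref = lo[1], bulkLow_alt = lo[2],
             bulkHigh_ref = hi[1], bulkHigh_alt = hi[2],
             stringsAsFactors = FALSE)
}

vt_bind <- function(...) variant_table(do.call(rbind, list(...)))

# A seven-site toy table where exactly two sites pass all filter rules and
# one site fails each rule (one per rule, in rule order, plus a bulk-depth
# failure at the spec boundary).
toy_filter_table <- function() {
  vt_bind(
    vt_row(pos = 100),                               # passes everything
    vt_row(pos = 200, qual = 10),                    # fails qual
    vt_row(pos = 300, mq = 20),                      # fails mapping quality
    vt_row(pos = 400, pa = c(4, 0)),                 # parent depth 4 < 10
    vt_row(pos = 500, lo = c(7, 7)),                 # bulk depth 14 < 15
    vt_row(pos = 600, pa = c(10, 10)),               # parent A 50/50, not fixed
    vt_row(pos = 700, ref = "G", alt = "GTT",        # passing indel, swapped
           pa = c(0, 20), pb = c(20, 0)))            #   ref/alt orientation
}
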