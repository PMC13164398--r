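test_that("genotype blocks merge runs and localize breakpoints", {
  b <- genotype_blocks(c("A", "A", "H", "H", "B"))
  expect_equal(b$code, c("A", "H", "B"))
  expect_equal(b$from, c(1, 3, 5))
  expect_equal(b$to, c(2, 4, 5))

  u <- genotype_blocks(rep("H", 6))
  expect_equal(nrow(u), 1)

  # missing call absorbed into neither block: breakpoint spans markers 1-3
  m <- genotype_blocks(c("A", NA, "B"))
  expect_equal(m$from, c(1, 3))
  expect_equal(m$to, c(1, 3))

  expect_error(genotype_blocks(c(NA, NA)), "non-missing")
})

# Nine recombinants over ten markers at 10,20,...,100; constructed so the
# constraint intersection is markers {5,6}, flanked by markers 4 and 7.
figure_panel <- function() {
  g <- rbind(
    RT1 = c("B", "B", "B", "H", "H", "H", "H", "H", "H", "H"),  # none
    RT2 = c("H", "H", "B", "B", "B", "B", "B", "B", "B", "B"),  # branched
    RT3 = c("B", "B", "B", "B", "B", "B", "B", "B", "H", "H"),  # branched
    RT4 = c("H", "H", "H", "H", "B", "B", "B", "B", "B", "B"),  # branched
    RT5 = c("H", "H", "H", "H", "H", "H", "B", "B", "B", "B"),  # none
    RT6 = c("A", "A", "A", "A", "A", "A", "A", "A", "A", "A"),  # none
    RT7 = c("H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),  # none
    RT8 = c("B", "B", "B", "B", "B", "B", "B", "H", "H", "H"),  # branched
    RT9 = c("H", "H", "H", "H", "H", "H", "H", "H", "H", "H"))  # none, uninformative
  recombinant_panel(
    markers = data.frame(chrom = "Chr10", pos = seq(10, 100, by = 10)),
    geno = g,
    phenotype = c("none", "whole_plant", "whole_plant", "whole_plant",
                  "none", "none", "none", "whole_plant", "none"))
}

test_that("locus delimitation intersects recombinant constraints", {
  dl <- delimit_locus(figure_panel())
  expect_true(dl$consistent)
  expect_equal(dl$allowed, c(5, 6))
  expect_equal(dl$left_pos, 40)    # flanking excluded marker positions
  expect_equal(dl$right_pos, 70)
  expect_true("RT4" %in% dl$boundary_individuals$left)   # H at marker 4
  expect_true("RT5" %in% dl$boundary_individuals$right)  # B at marker 7
})

test_that("an all-heterozygous non-branched individual constrains nothing", {
  p <- recombinant_panel(
    markers = data.frame(chrom = "c1", pos = c(10, 20, 30)),
    geno = matrix("H", 1, 3), phenotype = "none")
  dl <- delimit_locus(p)
  expect_true(dl$consistent)
  expect_equal(dl$allowed, 1:3)
  expect_equal(c(dl$left_pos, dl$right_pos), c(10, 30))  # full marker span
})

test_that("contradictory panels are flagged, never resolved silently", {
  p <- recombinant_panel(
    markers = data.frame(chrom = "c1", pos = c(10, 20, 30)),
    geno = rbind(bad = c("A", "A", "A")), phenotype = "whole_plant")
  dl <- delimit_locus(p)
  expect_false(dl$consistent)
  expect_equal(dl$offending, "bad")
})

test_that("delimitation contains the causal locus on simulated panels", {
  chroms <- c(Chr1 = 5e7)
  mpos <- seq(2e6, 47e6, by = 5e6)
  gm <- genome_map(chroms, list(Chr1 = mpos), cm_per_mb = 1)
  causal <- 24.5e6  # between markers 22e6 and 27e6
  tr <- trait_model("Chr1", causal)
  n_consistent <- 0; n_contained <- 0
  for (r in 1:20) {
    pop <- simulate_f2(gm, tr, 660, seed = 700 + r)
    panel <- panel_from_population(pop, "Chr1", mpos, max_individuals = 12)
    dl <- delimit_locus(panel)
    if (dl$consistent) {
      n_consistent <- n_consistent + 1
      n_contained <- n_contained +
        (dl$left_pos <= causal && dl$right_pos >= causal)
    }
  }
  expect_gt(n_consistent, 0)
  expect_equal(n_contained, n_consistent)  # 100% of consistent panels
})

test_that("the interval never grows as informative recombinants accumulate", {
  chroms <- c(Chr1 = 5e7)
  mpos <- seq(2e6, 47e6, by = 5e6)
  gm <- genome_map(chroms, list(Chr1 = mpos), cm_per_mb = 1)
  pop <- simulate_f2(gm, trait_model("Chr1", 24.5e6), 660, seed = 731)
  panel <- panel_from_population(pop, "Chr1", mpos, max_individuals = 12)
  prev_left <- -Inf; prev_right <- Inf
  for (k in seq(2, nrow(panel$geno), by = 2)) {
    sub <- recombinant_panel(panel$markers,
                             panel$geno[1:k, , drop = FALSE],
                             panel$phenotype[1:k])
    dl <- delimit_locus(sub)
    if (!dl$consistent) break
    expect_gte(dl$left_pos, prev_left)
    expect_lte(dl$right_pos, prev_right)
    prev_left <- dl$left_pos; prev_right <- dl$right_pos
  }

  # a non-recombinant heterozygous individual adds no constraint
  full <- delimit_locus(panel)
  aug <- recombinant_panel(panel$markers,
                           rbind(panel$geno, extra = rep("H", 10)),
                           c(panel$phenotype, "none"))
  dl_aug <- delimit_locus(aug)
  expect_equal(dl_aug$left_pos, full$left_pos)
  expect_equal(dl_aug$right_pos, full$right_pos)
})

test_that("marker selection enforces clearance and near-optimal spacing", {
  # three eligible candidates, three requested: all returned
  tab <- vt_bind(vt_row(pos = 1000), vt_row(pos = 3000), vt_row(pos = 5000))
  sel <- select_markers(tab, "chr1", 1, 6000, 3)
  expect_equal(sel$pos, c(1000, 3000, 5000))

  # a variant 30 bp away disqualifies a candidate at flank_clear = 50
  tab2 <- vt_bind(vt_row(pos = 1000), vt_row(pos = 1030), vt_row(pos = 5000))
  sel2 <- suppressWarnings(select_markers(tab2, "chr1", 1, 6000, 3,
                                          flank_clear = 50))
  expect_equal(sel2$pos, 5000)

  # 100 evenly spaced candidates, 10 chosen: spacing near region/(n+1)
  pos <- round(seq(1000, 99000, length.out = 100))
  tab3 <- variant_table(do.call(rbind, lapply(pos, function(p) vt_row(pos = p))))
  sel3 <- select_markers(tab3, "chr1", 0, 1e5, 10)
  gaps <- diff(c(0, sort(sel3$pos), 1e5))
  expect_gte(min(gaps), 1e5 / 11 * 0.9)
})

test_that("spacing selection matches the exhaustive oracle on small instances", {
  oracle_best <- function(cand, start, end, n) {
    best <- -Inf
    for (idx in utils::combn(length(cand), n, simplify = FALSE)) {
      sp <- min(diff(c(start, cand[idx], end)))
      if (sp > best) best <- sp
    }
    best
  }
  withr::with_seed(61, {
    for (i in 1:10) {
      m <- sample(6:12, 1)
      n <- sample(2:4, 1)
      cand <- sort(sample(seq(100, 9900, by = 50), m))
      tab <- variant_table(do.call(rbind, lapply(cand, function(p)
        vt_row(pos = p))))
      sel <- select_markers(tab, "chr1", 0, 1e4, n, flank_clear = 10)
      got <- min(diff(c(0, sort(sel$pos), 1e4)))
      expect_equal(got, oracle_best(cand, 0, 1e4, n), tolerance = 1e-6)
    }
  })
})

test_that("panels survive a TSV round trip", {
  panel <- figure_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$geno, panel$geno)
  expect_equal(back$phenotype, panel$phenotype)
  expect_equal(back$markers$pos, panel$markers$pos)
})
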