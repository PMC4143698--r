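test_that("QC/biallelic filter retains and tallies correctly", {
  v <- data.frame(variant_id = sprintf("v%d", 1:10),
                  qc_pass = rep(TRUE, 10),
                  biallelic = c(rep(TRUE, 8), FALSE, FALSE))
  flt <- filter_variants(v)
  expect_equal(nrow(flt$variants), 8)
  expect_equal(flt$n_excluded, 2)
  expect_equal(unname(flt$reasons["multiallelic"]), 2)

  all_pass <- filter_variants(v[1:8, ])
  expect_identical(all_pass$variants, v[1:8, ])
  expect_equal(all_pass$n_excluded, 0)
})

test_that("MAF is computed on non-missing calls and folded", {
  expect_equal(compute_maf(c(0, 0, 1)), 1 / 6)
  expect_equal(compute_maf(c(2, 2, 2)), 0)
  expect_equal(compute_maf(c(1, 1)), 0.5)
  expect_equal(compute_maf(c(0, NA, 1, 2)), 0.5)
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "missing")
  expect_error(compute_maf(c(0, 3)), "dosages")
})

test_that("MAF folding is invariant to allele-coding swaps", {
  set.seed(7)
  for (i in 1:20) {
    g <- sample(0:2, 30, replace = TRUE)
    expect_equal(compute_maf(g), compute_maf(2 - g))
  }
  X <- matrix(sample(0:2, 200, replace = TRUE), nrow = 20)
  expect_equal(compute_maf_matrix(X), compute_maf_matrix(2 - X))
})

test_that("MAF classes partition [0, 0.5] with boundaries in 'rare'", {
  expect_equal(as.character(classify_maf(c(0.005, 0.01, 0.05, 0.25, 0,
                                           0.0099999, 0.050001))),
               c("very_rare", "rare", "rare", "common", "very_rare",
                 "very_rare", "common"))
  expect_error(classify_maf(0.6), "0.5")
  expect_error(classify_maf(-0.01), "0.5")
  # exhaustive: no NA for any valid maf
  expect_false(anyNA(classify_maf(seq(0, 0.5, by = 0.001))))
})

test_that("region classification honours boundaries and precedence", {
  genes <- data.frame(chrom = "c1", start = 1000, end = 2000, name = "G1")
  v <- data.frame(chrom = "c1", pos = c(1500, 51999, 52000, 52001, 1001,
                                        1000, 2000, 2001))
  reg <- annotate_region(v, genes, flank_bp = 50000)
  expect_equal(as.character(reg$region_class),
               c("genic", "flanking", "flanking", "outside", "genic",
                 "flanking", "genic", "flanking"))

  # genic takes precedence over a neighbouring gene's flank
  genes2 <- rbind(genes,
                  data.frame(chrom = "c1", start = 10000, end = 11000,
                             name = "G2"))
  both <- annotate_region(data.frame(chrom = "c1", pos = 1500), genes2,
                          flank_bp = 50000)
  expect_equal(as.character(both$region_class), "genic")
  expect_equal(both$genes, "G1")

  expect_error(annotate_region(v, data.frame(chrom = "c1", start = 10,
                                             end = 10, name = "bad")),
               "malformed")
})

test_that("region annotation matches a brute-force scan on random instances", {
  set.seed(11)
  for (rep in 1:5) {
    n_genes <- sample(3:20, 1)
    start <- sort(sample.int(500000, n_genes))
    genes <- data.frame(chrom = "c1", start = start,
                        end = start + sample(500:5000, n_genes,
                                             replace = TRUE),
                        name = sprintf("g%d", seq_len(n_genes)))
    v <- data.frame(chrom = "c1",
                    pos = sample.int(520000, 1000, replace = TRUE))
    flank <- sample(c(100, 1000, 50000), 1)
    got <- annotate_region(v, genes, flank_bp = flank)
    expect_equal(as.character(got$region_class),
                 brute_force_region(v$pos, genes, flank))
  }
})

test_that("marker sets cover the 12 categories with exact marginals", {
  ann <- data.frame(
    variant_id = sprintf("v%d", 1:7),
    maf_class = factor(c("common", "common", "rare", "very_rare",
                         "very_rare", "very_rare", "common"),
                       levels = c("very_rare", "rare", "common")),
    region_class = factor(c("genic", "genic", "genic", "flanking",
                            "flanking", "flanking", "outside"),
                          levels = c("genic", "flanking", "outside")))
  ms <- build_marker_sets(ann)
  expect_length(ms$sets, 12)
  sz <- vapply(ms$sets, length, integer(1))
  expect_equal(unname(sz[c("all_all", "genic_all", "flanking_very_rare",
                           "genic_very_rare")]), c(6L, 3L, 3L, 0L))
  # "outside" variant 7 appears in no set
  expect_false(any(vapply(ms$sets, function(s) 7 %in% s, logical(1))))
  # marginal consistency for every region row
  ct <- ms$crosstab
  for (r in 1:3)
    expect_equal(ct$all[r], ct$common[r] + ct$rare[r] + ct$very_rare[r])
  expect_equal(ct$all[1], ct$all[2] + ct$all[3])
})

test_that("every retained variant lands in exactly one class pair", {
  sim <- simulate_dataset(small_spec(seed = 55))
  cohort <- suppressMessages(prepare_cohort(sim$phenotypes))
  flt <- filter_variants(sim$variants)
  G <- sim$genotypes[match(cohort$records$subject_id,
                           rownames(sim$genotypes)), flt$idx]
  ann <- annotate_variants(flt$variants, G, sim$genes)
  expect_false(anyNA(ann$maf_class))
  expect_false(anyNA(ann$region_class))
  ms <- build_marker_sets(ann)
  inside <- which(ann$region_class != "outside")
  # each inside variant in exactly 1 of the 6 atomic region x MAF sets
  atomic <- ms$sets[c("genic_common", "genic_rare", "genic_very_rare",
                      "flanking_common", "flanking_rare",
                      "flanking_very_rare")]
  membership <- table(unlist(atomic))
  expect_true(all(membership == 1))
  expect_equal(sort(as.integer(names(membership))), inside)
})

test_that("integer percents reproduce printed rounding", {
  counts <- matrix(c(49839, 11414, 6611, 31814,
                     16790, 2949, 4763, 9078,
                     33049, 8465, 1848, 22736),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("all", "genic", "flanking"),
                                   c("all", "common", "rare", "very_rare")))
  ct <- crosstab_percent(counts)
  expect_equal(ct$very_rare_pct, c(64L, 18L, 46L))
  expect_equal(ct$all_pct, c(100L, 34L, 66L))
  expect_equal(ct$common_pct, c(23L, 6L, 17L))
  expect_equal(ct$rare_pct, c(13L, 10L, 4L))
})
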