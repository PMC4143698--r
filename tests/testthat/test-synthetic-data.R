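test_that("gene models pack without overlapping footprints", {
  spec <- sim_spec(n_genes = 2, gene_length_bp = 10000, flank_bp = 50000,
                   chrom_length_bp = 1e6, seed = 1)
  set.seed(1)
  g <- simulate_gene_models(spec)
  expect_equal(nrow(g), 2)
  expect_true(all(g$end - g$start == 10000))
  # footprints (gene +/- flank) disjoint
  expect_true(g$start[2] - 50000 >= g$end[1] + 50000 ||
              g$start[2] - g$start[1] >= 110000)

  expect_equal(nrow(simulate_gene_models(sim_spec(n_genes = 0))), 0)

  set.seed(1)
  g31 <- simulate_gene_models(sim_spec(n_genes = 31))
  expect_equal(nrow(g31), 31)
  expect_true(all(diff(g31$start) > 0))

  expect_error(simulate_gene_models(
    sim_spec(n_genes = 10, gene_length_bp = 50000, flank_bp = 50000,
             chrom_length_bp = 1e6)), "cannot pack")
})

test_that("MAF class counts are allocated deterministically and exactly", {
  spec <- sim_spec(n_subjects = 50, n_variants = 1000, n_genes = 2,
                   gene_length_bp = 10000, chrom_length_bp = 1e6, seed = 3)
  set.seed(3)
  genes <- simulate_gene_models(spec)
  sim <- simulate_genotypes(spec, genes)
  counts <- table(sim$variants$true_maf_class)
  expect_equal(unname(counts[c("very_rare", "rare", "common")]),
               c(640L, 130L, 230L), ignore_attr = TRUE)
})

test_that("genotypes follow Hardy-Weinberg expectations", {
  near_half <- data.frame(class = "common", fraction = 1,
                          lo = 0.4990, hi = 0.4999)
  spec <- sim_spec(n_subjects = 10000, n_variants = 20, n_genes = 1,
                   gene_length_bp = 10000, chrom_length_bp = 1e6,
                   maf_mix = near_half, geno_missing_prob = 0, seed = 5)
  set.seed(5)
  sim <- simulate_genotypes(spec, simulate_gene_models(spec))
  m <- colMeans(sim$genotypes)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  # each variant's mean dosage near its own 2f; pooled mean near 1
  expect_true(all(abs(m - 2 * sim$variants$true_freq) < 4 * se))
  expect_lt(abs(mean(m) - 1), 3 * se / sqrt(20) + 0.002)
})

test_that("degenerate simulation inputs error", {
  expect_error(sim_spec(n_subjects = 0) |> (\(s) {
    set.seed(1); simulate_genotypes(s, simulate_gene_models(s))
  })(), "n_subjects")
  expect_error(sim_spec(resid_sd = 0), "resid_sd")
  expect_error(sim_spec(maf_mix = data.frame(class = "a", fraction = 1,
                                             lo = 0, hi = 0.1)),
               "subintervals")
  expect_error(sim_spec(maf_mix = data.frame(class = c("a", "b"),
                                             fraction = c(0.5, 0.5),
                                             lo = c(0.01, 0.04),
                                             hi = c(0.05, 0.2))),
               "disjoint")
})

test_that("same seed gives bit-identical data, different seeds differ", {
  a <- simulate_dataset(small_spec(seed = 9))
  b <- simulate_dataset(small_spec(seed = 9))
  c <- simulate_dataset(small_spec(seed = 10))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("generated region labels agree with the gene intervals", {
  sim <- simulate_dataset(small_spec(seed = 21))
  v <- sim$variants
  g <- sim$genes
  genic <- v$true_region == "genic"
  # every genic variant inside its gene body (0-based [s, e) vs 1-based pos)
  expect_true(all(vapply(which(genic), function(i) {
    any(v$pos[i] >= g$start + 1 & v$pos[i] <= g$end)
  }, logical(1))))
  flank <- v$true_region == "flanking"
  expect_true(all(vapply(which(flank), function(i) {
    inside <- any(v$pos[i] >= g$start + 1 & v$pos[i] <= g$end)
    near <- any(v$pos[i] >= g$start + 1 - 50000 &
                v$pos[i] <= g$end + 50000)
    !inside && near
  }, logical(1))))
})

test_that("phenotype generator hits its variance targets", {
  # null model: Var(logSBP) ~= sigma_eps^2
  null_spec <- clean_spec(3000, 50, seed = 31, h2_markers = 0,
                          covariate_effects = c(0, 0, 0, 0))
  sim <- simulate_dataset(null_spec)
  v1 <- sim$phenotypes[sim$phenotypes$visit == 1, ]
  expect_lt(abs(var(log(v1$SBP)) / null_spec$resid_sd^2 - 1), 0.15)

  # realized marker share close to h2_markers at large n
  spec <- clean_spec(5000, 500, seed = 32, h2_markers = 0.3)
  sim2 <- simulate_dataset(spec)
  expect_lt(abs(sim2$realized$marker_share - 0.3), 0.05)
})

test_that("variance components sum to the total log-scale variance", {
  sim <- simulate_dataset(small_spec(seed = 33))
  r <- sim$realized
  parts <- sim$truth$mu_true + r$linpred_cov + r$linpred_markers +
    r$resid[, 1]
  expect_lt(abs(var(parts) - var(r$log_sbp_visit1)), 1e-10)
})

test_that("all-missing first visit pushes selection to visit 2", {
  spec <- clean_spec(100, 50, seed = 34,
                     visit_missing_prob = c(1, 0, 0, 0))
  sim <- simulate_dataset(spec)
  rec <- select_first_visit(sim$phenotypes)
  expect_true(all(rec$source_visit == 2))
})

test_that("pedigree mode induces sibling genotype correlation", {
  common <- data.frame(class = "common", fraction = 1, lo = 0.2, hi = 0.45)
  spec <- sim_spec(n_subjects = 500, n_variants = 300, n_genes = 2,
                   gene_length_bp = 10000, chrom_length_bp = 1e6,
                   maf_mix = common, geno_missing_prob = 0,
                   pedigree_mode = TRUE, family_kids = 3, seed = 35)
  set.seed(35)
  sim <- simulate_genotypes(spec, simulate_gene_models(spec))
  G <- sim$genotypes
  # subjects are laid out family-wise: (mother, father, kid1..kid3)
  sib1 <- G[seq(3, 500, by = 5), ]
  sib2 <- G[seq(4, 500, by = 5), ]
  unrel <- G[seq(1, 496, by = 5), ]
  r_sib <- cor(as.vector(sib1), as.vector(sib2))
  r_unrel <- cor(as.vector(unrel[-1, ]), as.vector(sib2[-nrow(sib2), ]))
  expect_gt(r_sib, 0.3)
  expect_lt(abs(r_unrel), 0.1)
})

test_that("VCF round trip preserves dosages and QC flags", {
  sim <- simulate_dataset(small_spec(seed = 36))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim, f)
  back <- read_genotype_vcf(f)
  expect_equal(unname(back$genotypes), unname(sim$genotypes))
  expect_equal(back$variants$pos, sim$variants$pos)
  expect_equal(back$variants$qc_pass, sim$variants$qc_pass)
  expect_equal(back$variants$biallelic, sim$variants$biallelic)
  unlink(f)
})
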