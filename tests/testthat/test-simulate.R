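test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  cfg <- sim_config(seed = 5, n_founders = 20, n_generations = 1, n_markers = 50,
                    n_chromosomes = 1)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(p1$truth$bv, p2$truth$bv)
  cfg2 <- sim_config(seed = 6, n_founders = 20, n_generations = 1, n_markers = 50,
                     n_chromosomes = 1)
  p3 <- simulate_population(cfg2)
  expect_false(identical(p1$genotypes$dosage, p3$genotypes$dosage))
})

test_that("a zero-generation population is all founders with identity A", {
  cfg <- sim_config(seed = 2, n_founders = 15, n_generations = 0, n_markers = 30,
                    n_chromosomes = 1)
  pop <- simulate_population(cfg)
  expect_true(all(is.na(pop$pedigree$sire)))
  A <- build_A(pop$pedigree)
  expect_equal(unclass(A), diag(15), ignore_attr = TRUE)
})

test_that("offspring dosages obey the Mendelian bound against the mid-parent", {
  cfg <- sim_config(seed = 3, n_founders = 30, n_generations = 2, n_markers = 200,
                    n_chromosomes = 2)
  pop <- simulate_population(cfg)
  ped <- pop$pedigree
  d <- pop$genotypes$dosage
  kids <- which(!is.na(ped$sire))
  expect_true(all(d %in% 0:2))
  for (i in kids) {
    mid <- (d[ped$sire[i], ] + d[ped$dam[i], ]) / 2
    expect_true(all(abs(d[ped$animal[i], ] - mid) <= 1))
  }
})

test_that("founder MAF covers the configured range and LD decays with distance", {
  cfg <- sim_config(seed = 9, n_founders = 150, n_generations = 0, n_markers = 2000,
                    n_chromosomes = 2, maf_range = c(0.05, 0.5))
  pop <- simulate_population(cfg)
  maf <- pop$truth$founder_maf
  expect_gt(mean(maf < 0.15), 0.05)   # low end populated
  expect_gt(mean(maf > 0.35), 0.05)   # high end populated
  d <- pop$genotypes$dosage
  map <- pop$genotypes$map
  on1 <- which(map$chrom == "1")
  adj <- abs(sapply(on1[-length(on1)], function(j)
    suppressWarnings(cor(d[, j], d[, j + 1L]))))
  far_pairs <- cbind(sample(on1, 300, replace = TRUE), sample(on1, 300, replace = TRUE))
  far_pairs <- far_pairs[abs(map$pos[far_pairs[, 1]] - map$pos[far_pairs[, 2]]) > 2e7, ]
  far <- abs(apply(far_pairs, 1, function(ij) suppressWarnings(cor(d[, ij[1]], d[, ij[2]]))))
  expect_gt(mean(adj, na.rm = TRUE), 3 * mean(far, na.rm = TRUE))
})

test_that("with no permanent-environment or residual variance a single record equals the true BV", {
  cfg <- sim_config(seed = 4, n_founders = 40, n_generations = 0, n_markers = 100,
                    n_chromosomes = 1, mean_records_per_animal = 1e-6,
                    traits = list(y = trait_spec(0, 2, 1, 0, "continuous")),
                    year_season_sd_frac = 0, parity_sd_frac = 0,
                    age_slope_frac = 0, interval_slope_frac = 0)
  pop <- simulate_population(cfg)
  rec <- simulate_records(pop$pedigree, pop$truth, cfg)
  expect_equal(nrow(rec), 40L)
  expect_equal(rec$y, unname(pop$truth$bv[rec$animal, "y"]), tolerance = 1e-12)
})

test_that("intra-animal correlation of records matches the configured repeatability", {
  cfg <- sim_config(seed = 8, n_founders = 200, n_generations = 0, n_markers = 100,
                    n_chromosomes = 1, mean_records_per_animal = 20,
                    traits = list(y = trait_spec(0, 10, 0.3, 0.1, "continuous")),
                    year_season_sd_frac = 0, parity_sd_frac = 0,
                    age_slope_frac = 0, interval_slope_frac = 0)
  pop <- simulate_population(cfg)
  rec <- simulate_records(pop$pedigree, pop$truth, cfg)
  # one-way ANOVA intraclass correlation estimates (sa2 + sp2) / stot
  fit <- stats::anova(stats::lm(y ~ animal, data = rec))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  k <- nrow(rec) / length(unique(rec$animal))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  expect_gt(icc, 0.33)
  expect_lt(icc, 0.47)
})

test_that("percent traits are clipped with a reported sub-1% clipping rate", {
  cfg <- sim_config(seed = 12, n_founders = 150, n_generations = 1)
  pop <- simulate_population(cfg)
  rec <- simulate_records(pop$pedigree, pop$truth, cfg)
  expect_true(all(rec$spmot >= 0 & rec$spmot <= 100))
  expect_true(all(rec$spcount > 0))
  expect_lt(max(attr(rec, "clip_rate")), 0.01)
})

test_that("cis-regulated expression tracks dosage and null genes do not", {
  cfg <- sim_config(seed = 21, n_founders = 150, n_generations = 0, n_markers = 300,
                    n_chromosomes = 1, n_genes = 20, n_expr_samples = 150,
                    eqtl_spec = list(list(gene_id = "gene_c1_003",
                                          marker_id = "snp_c1_000100",
                                          effect_size = 0, noise_sd = 1)))
  pop <- simulate_population(cfg)
  expr <- simulate_expression(pop$genotypes, cfg)
  expect_true(all(expr$mat >= 0))
  j <- match("snp_c1_000100", pop$genotypes$map$marker_id)
  dos <- pop$genotypes$dosage[match(colnames(expr$mat), pop$genotypes$animal_ids), j]
  expect_lt(abs(cor(expr$mat["gene_c1_003", ], dos)), 0.2)  # zero effect size

  # near-zero noise: expression is affine in dosage, scan recovers the marker
  cfg2 <- sim_config(seed = 21, n_founders = 150, n_generations = 0, n_markers = 300,
                     n_chromosomes = 1, n_genes = 20, n_expr_samples = 150,
                     eqtl_spec = list(list(gene_id = "gene_c1_003",
                                           marker_id = "snp_c1_000100",
                                           effect_size = 1, noise_sd = 1e-9)))
  pop2 <- simulate_population(cfg2)
  expr2 <- simulate_expression(pop2$genotypes, cfg2)
  genes2 <- attr(expr2, "genes")
  dos2 <- pop2$genotypes$dosage[match(colnames(expr2$mat), pop2$genotypes$animal_ids),
                                match("snp_c1_000100", pop2$genotypes$map$marker_id)]
  fit <- stats::lm(expr2$mat["gene_c1_003", ] ~ dos2)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-6)
  eq <- cis_eqtl_scan(expr2, pop2$genotypes, genes2, log_transform = FALSE)
  eg <- eq[eq$gene_id == "gene_c1_003", ]
  expect_equal(eg$marker_id[which.min(eg$p)], "snp_c1_000100")
})
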