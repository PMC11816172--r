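mk_genes <- function(...) {
  rows <- list(...)
  gene_annotation(do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]], start = as.numeric(r[[3]]),
               end = as.numeric(r[[4]]), stringsAsFactors = FALSE))))
}

test_that("gene windows are +/- 1 Mb, clamped at 1, inclusive at the edges", {
  genes <- mk_genes(list("gA", "1", 4.2e6, 4.3e6),
                    list("gB", "1", 2e6, 3e6),
                    list("gC", "1", 7e6, 8e6))
  hits <- data.frame(marker_id = "snp1", chrom = "1", bp = 5e6)
  ann <- annotate_genes(hits, genes)
  expect_setequal(ann$gene_id, "gA")   # gB and gC fall outside [4e6, 6e6]
  expect_equal(ann$distance_bp[ann$gene_id == "gA"], 7e5)
  # window clamped to [1, 1.4e6] near the chromosome start
  hits2 <- data.frame(marker_id = "snp2", chrom = "1", bp = 4e5)
  ann2 <- annotate_genes(hits2, genes)
  expect_equal(unique(ann2$window_start), 1)
  expect_equal(unique(ann2$window_end), 1.4e6)
  # a gene ending exactly at window_start is included (inclusive bounds)
  genes3 <- mk_genes(list("gE", "1", 3.5e6, 4e6))
  ann3 <- annotate_genes(data.frame(marker_id = "s", chrom = "1", bp = 5e6), genes3)
  expect_equal(ann3$gene_id, "gE")
  # marker inside a gene has distance zero
  ann4 <- annotate_genes(data.frame(marker_id = "s", chrom = "1", bp = 2.5e6), genes)
  expect_equal(ann4$distance_bp[ann4$gene_id == "gB"], 0)
  # unknown chromosome warns and yields an empty gene list
  expect_warning(ann5 <- annotate_genes(
    data.frame(marker_id = "s", chrom = "9", bp = 1e6), genes), "absent")
  expect_equal(ann5$n_genes, 0L)
})

test_that("windowing agrees with a brute-force all-pairs interval check", {
  set.seed(71)
  for (rep in 1:20) {
    ng <- 30
    genes <- gene_annotation(data.frame(
      gene_id = paste0("g", 1:ng), chrom = sample(c("1", "2"), ng, TRUE),
      start = s <- sample.int(2e7, ng), end = s + sample.int(5e5, ng),
      stringsAsFactors = FALSE))
    hits <- data.frame(marker_id = paste0("s", 1:5),
                       chrom = sample(c("1", "2"), 5, TRUE),
                       bp = sample.int(2e7, 5), stringsAsFactors = FALSE)
    ann <- annotate_genes(hits, genes, window_bp = 1e6)
    for (i in 1:5) {
      ws <- max(1, hits$bp[i] - 1e6); we <- hits$bp[i] + 1e6
      brute <- genes$gene_id[genes$chrom == hits$chrom[i] &
                               pmax(genes$start, ws) <= pmin(genes$end, we)]
      got <- ann$gene_id[ann$marker_id == hits$marker_id[i] & !is.na(ann$gene_id)]
      expect_setequal(got, brute)
    }
  }
})

test_that("cis-eQTL scan stays inside the cis window and is uniform under permutation", {
  set.seed(72)
  n <- 150; m <- 300
  d <- sapply(runif(m, 0.1, 0.5), function(pp) rbinom(n, 2, pp))
  geno <- toy_geno(d, pos = seq(1e6, 2e7, length.out = m))
  genes <- mk_genes(list("g1", "1", 5e6, 5.1e6))
  emat <- matrix(rexp(n), 1, n, dimnames = list("g1", geno$animal_ids))
  eq <- cis_eqtl_scan(expression_matrix(emat), geno, genes, cis_window_bp = 1e6)
  inwin <- geno$map$marker_id[geno$map$pos >= 4e6 & geno$map$pos <= 6.1e6]
  expect_setequal(eq$marker_id, inwin)
  # permutation null: many genes x markers, p-values uniform
  ng <- 40
  genes2 <- gene_annotation(data.frame(
    gene_id = paste0("g", 1:ng), chrom = "1",
    start = s <- seq(1.2e6, 1.9e7, length.out = ng), end = s + 1e4,
    stringsAsFactors = FALSE))
  emat2 <- matrix(rexp(ng * n), ng, n,
                  dimnames = list(genes2$gene_id, geno$animal_ids))
  eq2 <- cis_eqtl_scan(expression_matrix(emat2), geno, genes2, cis_window_bp = 2e6)
  expect_gt(nrow(eq2), 2000)
  ks <- suppressWarnings(stats::ks.test(eq2$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # constant-expression gene skipped with a count
  emat3 <- rbind(emat2, matrix(5, 1, n, dimnames = list("gflat", NULL)))
  genes3 <- gene_annotation(rbind(as.data.frame(genes2)[, c("gene_id", "chrom", "start", "end")],
                                  data.frame(gene_id = "gflat", chrom = "1",
                                             start = 2e6, end = 2.1e6)))
  eq3 <- cis_eqtl_scan(expression_matrix(emat3), geno, genes3)
  expect_equal(attr(eq3, "n_skipped_genes"), 1L)
  expect_false("gflat" %in% eq3$gene_id)
})

test_that("EM LD equals direct haplotype counting when phase is unambiguous", {
  # diplotypes built from known haplotypes with no double heterozygotes
  haps <- list(c(1, 1), c(1, 0), c(0, 0))
  pairs <- rbind(c(1, 1), c(1, 2), c(2, 3), c(3, 3), c(2, 2), c(1, 1), c(2, 3))
  counts <- c(10, 8, 12, 15, 6, 4, 5)
  h1 <- do.call(rbind, rep(lapply(seq_len(nrow(pairs)), function(i) haps[[pairs[i, 1]]]),
                           counts))
  h2 <- do.call(rbind, rep(lapply(seq_len(nrow(pairs)), function(i) haps[[pairs[i, 2]]]),
                           counts))
  d <- h1 + h2
  expect_false(any(d[, 1] == 1 & d[, 2] == 1))    # no double hets by construction
  geno <- toy_geno(d, pos = c(1000, 2000))
  ld <- ld_r2(geno, "m1", "m2")
  hap_all <- rbind(h1, h2)
  fAB <- mean(hap_all[, 1] == 1 & hap_all[, 2] == 1)
  pA <- mean(hap_all[, 1]); pB <- mean(hap_all[, 2])
  D <- fAB - pA * pB
  expect_equal(ld$D, D, tolerance = 1e-9)
  expect_equal(ld$r2, D^2 / (pA * (1 - pA) * pB * (1 - pB)), tolerance = 1e-9)
})

test_that("LD r2 is 1 for duplicated markers and near 0 for independent ones", {
  set.seed(73)
  x <- rbinom(500, 2, 0.4)
  geno <- toy_geno(cbind(x, x), pos = c(1, 2))
  expect_equal(ld_r2(geno, "m1", "m2")$r2, 1, tolerance = 1e-9)
  r2s <- replicate(30, {
    d <- cbind(rbinom(500, 2, 0.3), rbinom(500, 2, 0.4))
    ld_r2(toy_geno(d, pos = c(1, 2)), "m1", "m2")$r2
  })
  expect_lt(mean(r2s), 0.02)
  expect_error(ld_r2(toy_geno(cbind(x, 2L), pos = c(1, 2)), "m1", "m2"), "monomorphic")
})

test_that("the LSD procedure reduces to the pooled t-test for two groups", {
  set.seed(74)
  y <- rnorm(40); g <- rep(c(0, 1), each = 20)
  lsd <- lsd_genotype_expression(y, g)
  tt <- t.test(y[g == 0], y[g == 1], var.equal = TRUE)
  expect_equal(lsd$pairwise$p, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(lsd$pairwise$t), abs(unname(tt$statistic)), tolerance = 1e-12)
  expect_error(lsd_genotype_expression(rep(5, 30), rep(0:2, 10)), "degenerate")
  expect_error(lsd_genotype_expression(rnorm(3), c(0, 1, 2)), "2 samples")
})

test_that("an additive shift of 1 SD per allele is detected in nearly all replicates", {
  set.seed(75)
  hits <- replicate(50, {
    g <- rep(0:2, each = 30)
    y <- g * 1 + rnorm(90)
    all(lsd_genotype_expression(y, g)$pairwise$p < 0.05)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("co-localization reports direct overlap and respects the gene window", {
  genes <- mk_genes(list("g1", "1", 4.9e6, 5.2e6), list("gfar", "1", 9e6, 9.3e6))
  geno <- toy_geno(cbind(rbinom(100, 2, 0.4), rbinom(100, 2, 0.3)),
                   pos = c(5e6, 9.1e6))
  hits <- data.frame(marker_id = "m1", chrom = "1", bp = 5e6)
  eqtls <- data.frame(gene_id = c("g1", "gfar"), marker_id = c("m1", "m2"),
                      tissue = "testis_like", beta = 1, se = 0.1,
                      p = c(1e-8, 1e-8), q = c(1e-5, 1e-5), n_samples = 100,
                      stringsAsFactors = FALSE)
  cl <- colocalize(hits, eqtls, genes, geno)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$mechanism, "direct")
  expect_equal(cl$r2, 1)
  expect_equal(cl$gene_id, "g1")       # gfar lies outside the +/- 1 Mb window
})
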