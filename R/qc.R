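#' Phenotype quality control for repeated semen records
#'
#' Applies the record-level rules in order, then the animal-level rule:
#' (2) volume <= 50 mL removed; (3) sperm motility < 10% removed;
#' (4) collection interval > 60 days or equal to 0 days removed, with the
#' interval recomputed per animal from the sorted collection dates of the
#' records surviving rules (2)-(3) (an animal's first record has no interval
#' and is exempt); finally (1) animals with fewer than 5 remaining
#' collections are excluded. Rule (1) is applied to post-filter counts.
#'
#' @param records a [phenotype_table] or plain data.frame with at least
#'   `animal`, `date` and the trait columns present.
#' @param min_records,volume_max_removed,motility_min,interval_max rule
#'   thresholds (defaults: 5 collections, 50 mL, 10%, 60 days).
#' @return list with `records` (filtered table, `interval_days` recomputed)
#'   and `report` (per-rule removal counts).
#' @export
filter_phenotypes <- function(records, min_records = 5L, volume_max_removed = 50,
                              motility_min = 10, interval_max = 60) {
  df <- as.data.frame(records)
  df$date <- as.Date(df$date)
  df <- df[order(df$animal, df$date), , drop = FALSE]
  n0 <- nrow(df)
  steps <- list()

  keep <- if ("volume_ml" %in% names(df)) {
    is.na(df$volume_ml) | df$volume_ml > volume_max_removed
  } else rep(TRUE, nrow(df))
  steps$volume <- sum(!keep); df <- df[keep, , drop = FALSE]

  keep <- if ("spmot" %in% names(df)) {
    is.na(df$spmot) | df$spmot >= motility_min
  } else rep(TRUE, nrow(df))
  steps$motility <- sum(!keep); df <- df[keep, , drop = FALSE]

  # rule (4): interval from sorted dates of surviving records
  iv <- stats::ave(as.numeric(df$date), df$animal,
                   FUN = function(x) c(NA_real_, diff(x)))
  keep <- is.na(iv) | (iv > 0 & iv <= interval_max)
  steps$interval <- sum(!keep); df <- df[keep, , drop = FALSE]

  cnt <- table(df$animal)
  bad_animals <- names(cnt)[cnt < min_records]
  keep <- !(df$animal %in% bad_animals)
  steps$min_collections <- sum(!keep); df <- df[keep, , drop = FALSE]

  df$interval_days <- stats::ave(as.numeric(df$date), df$animal,
                                 FUN = function(x) c(NA_real_, diff(x)))
  rownames(df) <- NULL
  report <- data.frame(
    rule = c("volume_le_50", "motility_lt_10", "interval_gt_60_or_0",
             "animal_lt_5_collections"),
    removed = unlist(steps, use.names = FALSE), stringsAsFactors = FALSE)
  report$retained_after <- n0 - cumsum(report$removed)
  list(records = df, report = report,
       n_input = n0, n_retained = nrow(df),
       n_animals_removed = length(bad_animals))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, the probability of each
#' attainable heterozygote count (same parity as the minor-allele count)
#' under the Hardy-Weinberg null is computed, and the p-value is the sum of
#' the probabilities of all configurations no more probable than the
#' observed one (two-sided by probability mass, no mid-p).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  n1 <- 2 * min(n_AA, n_aa) + n_Aa          # minor allele count
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  # log P(het = h | n, n1) up to a constant: multinomial x 2^h
  logp <- vapply(hs, function(h) {
    hom1 <- (n1 - h) / 2
    hom2 <- n - h - hom1
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2)
  }, numeric(1))
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Genotype quality control
#'
#' Sequential marker filters in a fixed, reported order: unmapped markers
#' (missing or non-positive coordinates) dropped first, then call rate below
#' threshold, then minor allele frequency below threshold (computed from
#' non-missing dosages), then exact Hardy-Weinberg p below threshold.
#'
#' @param geno a [genotype_data].
#' @param call_rate_min,maf_min,hwe_min thresholds (defaults 0.9, 0.01, 1e-6).
#' @return list with `genotypes` (filtered) and `report` (per-step counts and
#'   a per-marker stats table with the first failing rule).
#' @export
genotype_qc <- function(geno, call_rate_min = 0.9, maf_min = 0.01, hwe_min = 1e-6) {
  stopifnot(inherits(geno, "genotype_data"),
            call_rate_min > 0, call_rate_min <= 1, maf_min > 0, maf_min <= 1)
  d <- geno$dosage
  m <- ncol(d)
  unmapped <- is.na(geno$map$chrom) | geno$map$chrom %in% c("0", "") |
    is.na(geno$map$pos) | geno$map$pos <= 0
  call_rate <- colMeans(!is.na(d))
  pB <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(pB, 1 - pB)
  maf[is.nan(maf)] <- 0
  hwe_p <- rep(NA_real_, m)
  status <- rep("ok", m)
  status[unmapped] <- "unmapped"
  low_cr <- !unmapped & call_rate < call_rate_min
  status[low_cr] <- "call_rate"
  low_maf <- status == "ok" & maf < maf_min
  status[low_maf] <- "maf"
  test_hwe <- which(status == "ok")
  for (j in test_hwe) {
    x <- d[, j]
    hwe_p[j] <- hwe_exact_test(sum(x == 0, na.rm = TRUE),
                               sum(x == 1, na.rm = TRUE),
                               sum(x == 2, na.rm = TRUE))
  }
  low_hwe <- status == "ok" & !is.na(hwe_p) & hwe_p < hwe_min
  status[low_hwe] <- "hwe"
  keep <- status == "ok"
  steps <- data.frame(
    step = c("unmapped", "call_rate", "maf", "hwe"),
    removed = c(sum(unmapped), sum(low_cr), sum(low_maf), sum(low_hwe)),
    stringsAsFactors = FALSE)
  steps$retained_after <- m - cumsum(steps$removed)
  stats_tab <- data.frame(marker_id = geno$map$marker_id,
                          call_rate = call_rate, maf = maf, hwe_p = hwe_p,
                          status = status, stringsAsFactors = FALSE)
  out <- genotype_data(d[, keep, drop = FALSE],
                       geno$map[keep, , drop = FALSE], geno$animal_ids)
  list(genotypes = out, report = steps, marker_stats = stats_tab,
       n_input = m, n_retained = sum(keep))
}

#' Genotype principal components
#'
#' Missing dosages are mean-imputed per marker; markers are centered by twice
#' the allele frequency and scaled by `sqrt(2p(1-p))` (monomorphic markers
#' skipped); animal coordinates and variance fractions come from the
#' singular value decomposition of the standardized matrix.
#'
#' @param geno a [genotype_data].
#' @param k number of components (k >= 1).
#' @return list with `scores` (animals x k), `var_frac` (length k,
#'   non-increasing), `n_markers_used`.
#' @export
genotype_pca <- function(geno, k = 2L) {
  d <- geno$dosage
  if (k < 1) stop("k must be >= 1")
  p <- colMeans(d, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- 2 * p[j]
  poly <- p > 0 & p < 1
  if (sum(poly) < 1L) stop("no polymorphic markers")
  if (k > min(nrow(d), sum(poly))) stop("k exceeds min(n_animals, n_markers)")
  z <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly])
  z <- sweep(z, 2L, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  sv <- svd(z, nu = k, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(geno$animal_ids, paste0("PC", seq_len(k)))
  list(scores = scores,
       var_frac = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       n_markers_used = sum(poly))
}
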