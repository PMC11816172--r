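#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = M M' / (2 sum p_j (1 - p_j))` with `M` the dosage matrix centered by
#' twice the sample allele frequency. Missing dosages are mean-imputed per
#' marker; monomorphic markers are excluded; a small ridge (1e-6) is added
#' to the diagonal for invertibility.
#'
#' @param geno a [genotype_data] (after QC).
#' @param ridge diagonal ridge (default 1e-6).
#' @return list of class `grm`: `G`, `p` (allele frequencies used),
#'   `animal_ids`, `n_markers`.
#' @export
build_grm <- function(geno, ridge = 1e-6) {
  d <- geno$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("fewer than 2 polymorphic markers")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- 2 * p[j]
  M <- sweep(d, 2L, 2 * p)
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  diag(G) <- diag(G) + ridge
  dimnames(G) <- list(geno$animal_ids, geno$animal_ids)
  structure(list(G = G, p = p, animal_ids = geno$animal_ids,
                 n_markers = sum(poly)), class = "grm")
}

#' Null (no-marker) fit of the weighted polygenic model
#'
#' REML fit of `y = 1 mu + g + e` with `Var(y) = G sigma_g2 + R sigma_e2`,
#' `R = diag(1/weight_i)`: the observations are whitened by `R^{-1/2}`, the
#' whitened GRM eigendecomposed once, and the restricted likelihood profiled
#' over the variance ratio in one dimension; the cached spectrum makes each
#' subsequent per-SNP test O(n).
#'
#' @param debv numeric response vector (DEBVs), aligned to `weights`.
#' @param weights positive residual weights (larger = more reliable).
#' @param grm a [build_grm()] result whose ordering matches `debv`
#'   (or supply `animal_ids` to subset it).
#' @param animal_ids optional ids aligning `debv` to the GRM.
#' @return list of class `wgwas_null`: `sigma_g2`, `sigma_e2`, `loglik`,
#'   and the spectral cache used by [weighted_gwas()].
#' @export
fit_null_model <- function(debv, weights, grm, animal_ids = NULL) {
  stopifnot(length(debv) == length(weights), all(weights > 0))
  G <- grm$G
  if (!is.null(animal_ids)) {
    miss <- setdiff(animal_ids, rownames(G))
    if (length(miss)) stop("animals not in GRM: ", paste(utils::head(miss, 5L), collapse = ", "))
    G <- G[animal_ids, animal_ids]
  } else if (length(debv) != nrow(G)) {
    stop("debv length does not match GRM order; supply animal_ids")
  }
  n <- length(debv)
  sw <- sqrt(weights)
  Gt <- G * tcrossprod(sw)                 # R^{-1/2} G R^{-1/2}
  eg <- eigen(Gt, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  if (stats::sd(lam) < 1e-8 * max(mean(lam), 1e-12)) {
    warning("flat GRM spectrum: sigma_g2 and sigma_e2 are not separately identifiable; only their weighted total is estimated")
  }
  ys <- crossprod(U, sw * debv)[, 1L]
  xs <- crossprod(U, sw)[, 1L]             # intercept column, whitened+rotated
  p <- 1L
  negll <- function(log_delta) {           # delta = sigma_e2 / sigma_g2
    delta <- exp(log_delta)
    dvec <- lam + delta
    xd <- xs / dvec
    xtx <- sum(xs * xd)
    beta <- sum(xd * ys) / xtx
    r <- ys - xs * beta
    rss <- sum(r^2 / dvec)
    sg <- rss / (n - p)
    0.5 * ((n - p) * log(sg) + sum(log(dvec)) + log(xtx) + (n - p))
  }
  opt <- stats::optimize(negll, c(-12, 12), tol = 1e-9)
  delta <- exp(opt$minimum)
  dvec <- lam + delta
  xd <- xs / dvec
  xtx <- sum(xs * xd)
  beta <- sum(xd * ys) / xtx
  r <- ys - xs * beta
  sigma_g2 <- sum(r^2 / dvec) / (n - p)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
                 delta = delta, mu = beta, loglik = -opt$objective,
                 U = U, lambda = lam, sqrt_w = sw, n = n,
                 animal_ids = animal_ids %||% rownames(G)),
            class = "wgwas_null")
}

#' Reliability-weighted single-SNP mixed-model association
#'
#' For each marker, the allele-substitution effect is estimated by
#' generalized least squares with the covariance fixed at the null fit
#' (`Var(y) = G sigma_g2 + R sigma_e2`), followed by a 1-df Wald test.
#' Monomorphic and all-missing markers are skipped (counted in the result's
#' attributes); missing dosages are mean-imputed. The genomic inflation
#' factor, q-values and the percentage of genetic variance explained are
#' attached per marker.
#'
#' @param debv response vector aligned to `null$animal_ids`.
#' @param geno a [genotype_data]; rows are matched to `null$animal_ids`.
#' @param null a [fit_null_model()] cache.
#' @param fdr_method `"storey"` (default) or `"bh"`, see [fdr_qvalues()].
#' @return data.frame of class `gwas_result` with columns `marker_id`,
#'   `chrom`, `bp`, `maf`, `beta`, `se`, `p`, `q`, `gvar_pct`; attributes
#'   `lambda`, `sigma_g2`, `sigma_e2`, `n_skipped`.
#' @export
weighted_gwas <- function(debv, geno, null, fdr_method = c("storey", "bh")) {
  fdr_method <- match.arg(fdr_method)
  ids <- null$animal_ids
  ridx <- match(ids, geno$animal_ids)
  if (anyNA(ridx)) stop("GRM/DEBV animals missing from genotypes")
  d <- geno$dosage[ridx, , drop = FALSE]
  n <- length(ids)
  p_all <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_all, 1 - p_all)
  usable <- !is.na(p_all) & p_all > 0 & p_all < 1
  n_skipped <- sum(!usable)
  for (j in which(usable & colSums(is.na(d)) > 0L)) {
    d[is.na(d[, j]), j] <- 2 * p_all[j]
  }
  dvec <- null$lambda + null$delta
  scale_v <- 1 / sqrt(dvec)
  # full whitening transform t(x) = D^{-1/2} U' R^{-1/2} x ; Var(t(y)) = sigma_g2 I
  Xs <- crossprod(null$U, null$sqrt_w * d[, usable, drop = FALSE]) * scale_v
  ys <- crossprod(null$U, null$sqrt_w * debv)[, 1L] * scale_v
  ones <- crossprod(null$U, null$sqrt_w)[, 1L] * scale_v

  s11 <- sum(ones^2)
  s1y <- sum(ones * ys)
  s1x <- crossprod(Xs, ones)[, 1L]
  sxx <- colSums(Xs^2)
  sxy <- crossprod(Xs, ys)[, 1L]
  det_ <- s11 * sxx - s1x^2
  beta <- (s11 * sxy - s1x * s1y) / det_
  var_beta <- null$sigma_g2 * s11 / det_
  se <- sqrt(var_beta)
  chi <- (beta / se)^2
  pvals <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)

  res <- data.frame(marker_id = geno$map$marker_id[usable],
                    chrom = geno$map$chrom[usable],
                    bp = geno$map$pos[usable],
                    maf = maf[usable],
                    beta = beta, se = se, p = pvals,
                    stringsAsFactors = FALSE)
  res$q <- fdr_qvalues(res$p, method = fdr_method)
  res$gvar_pct <- variance_explained(res$beta, res$maf, null$sigma_g2)
  attr(res, "lambda") <- inflation_factor(res$p)
  attr(res, "sigma_g2") <- null$sigma_g2
  attr(res, "sigma_e2") <- null$sigma_e2
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364` (the median of a 1-df
#' chi-square), computed from raw p-values.
#'
#' @param p_values p-values in (0, 1\].
#' @return lambda.
#' @export
inflation_factor <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied")
  stats::median(stats::qchisq(p, df = 1L, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1L)
}

#' False-discovery-rate q-values
#'
#' `method = "bh"` is Benjamini-Hochberg (`pi0 = 1`). `method = "storey"`
#' estimates `pi0` on the lambda grid 0.05, 0.10, ..., 0.95 with a cubic
#' smoothing spline evaluated at the largest lambda, then scales the BH
#' step-up values, enforcing monotonicity; with too few p-values to smooth,
#' it falls back to `pi0 = 1`.
#'
#' @param p_values p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"bh"`.
#' @return q-values in input order.
#' @export
fdr_qvalues <- function(p_values, method = c("storey", "bh")) {
  method <- match.arg(method)
  p <- p_values
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (method == "storey" && m >= 2L) {
    lam <- seq(0.05, 0.95, by = 0.05)
    lam <- lam[lam < max(p)]
    if (length(lam) >= 4L) {
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  ord <- order(p)
  bh <- p[ord] * m / seq_len(m)
  bh <- rev(cummin(rev(bh)))
  q <- numeric(m)
  q[ord] <- pmin(pi0 * bh, 1)
  q
}

#' Percentage of genetic variance explained by a SNP
#'
#' `100 * 2 maf (1 - maf) beta^2 / sigma_g2` — the additive variance of the
#' marker under Hardy-Weinberg relative to the polygenic variance.
#'
#' @param beta allele-substitution effect(s).
#' @param maf minor allele frequency in (0, 0.5\].
#' @param sigma_g2 genetic variance of the null model (> 0).
#' @return percentage(s), invariant to allele-orientation flips.
#' @export
variance_explained <- function(beta, maf, sigma_g2) {
  stopifnot(sigma_g2 > 0)
  if (any(maf <= 0 | maf > 0.5, na.rm = TRUE)) {
    stop("maf must lie in (0, 0.5]")
  }
  100 * 2 * maf * (1 - maf) * beta^2 / sigma_g2
}
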