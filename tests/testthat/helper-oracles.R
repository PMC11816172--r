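# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Exact HWE test by direct enumeration with choose(): P(het = h | n, n1)
# proportional to n! / (hom1! h! hom2!) * 2^h, normalized over attainable h.
brute_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- 2 * min(n_AA, n_aa) + n_Aa
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  pr <- sapply(hs, function(h) {
    hom1 <- (n1 - h) / 2
    hom2 <- n - h - hom1
    choose(n, hom1) * choose(n - hom1, h) * 2^h
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Exact relationship matrix by enumeration of inheritance vectors: every
# known-parent link is a meiosis bit choosing which parental allele is
# transmitted; unknown parents contribute fresh founder alleles. A_ij is
# twice the expected fraction of identical allele pairs.
oracle_A_enum <- function(sire_idx, dam_idx) {
  n <- length(sire_idx)
  links <- list()
  for (i in seq_len(n)) {
    if (sire_idx[i] > 0) links[[length(links) + 1L]] <- c(i, sire_idx[i], 1L)
    if (dam_idx[i] > 0)  links[[length(links) + 1L]] <- c(i, dam_idx[i], 2L)
  }
  L <- length(links)
  stopifnot(L <= 14L)
  Aacc <- matrix(0, n, n)
  n_vec <- 2^L
  for (v in seq_len(n_vec) - 1L) {
    bits <- bitwAnd(bitwShiftR(v, seq_len(max(L, 1L)) - 1L), 1L)
    # allele labels: slot 1 = paternal, slot 2 = maternal
    al <- matrix(0L, n, 2L)
    nxt <- 1L
    link_no <- 1L
    for (i in seq_len(n)) {
      for (slot in 1:2) {
        par <- if (slot == 1L) sire_idx[i] else dam_idx[i]
        if (par == 0L) {
          al[i, slot] <- nxt; nxt <- nxt + 1L
        } else {
          al[i, slot] <- al[par, 1L + bits[link_no]]
          link_no <- link_no + 1L
        }
      }
    }
    ident <- outer(al[, 1L], al[, 1L], "==") + outer(al[, 1L], al[, 2L], "==") +
      outer(al[, 2L], al[, 1L], "==") + outer(al[, 2L], al[, 2L], "==")
    Aacc <- Aacc + ident / 4
  }
  2 * Aacc / n_vec
}

# Dense restricted log-likelihood of the repeatability model (up to the
# usual constant), via explicit V and P matrices.
dense_reml_ll <- function(y, X, ai, A_rr, sa, sp, se) {
  n <- length(y)
  q <- nrow(A_rr)
  Z <- matrix(0, n, q); Z[cbind(seq_len(n), ai)] <- 1
  V <- Z %*% (sa * A_rr + sp * diag(q)) %*% t(Z) + se * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XVX)$modulus +
                       t(y) %*% P %*% y))
}

# Dense GLS per-marker association with fixed V (single-marker mixed model).
dense_gls_scan <- function(y, Xmat, V) {
  Vi <- solve(V)
  t(apply(Xmat, 2L, function(x) {
    X <- cbind(1, x)
    XtVi <- t(X) %*% Vi
    cov_b <- solve(XtVi %*% X)
    b <- cov_b %*% (XtVi %*% y)
    se <- sqrt(cov_b[2L, 2L])
    c(beta = b[2L], se = se,
      p = stats::pchisq((b[2L] / se)^2, 1, lower.tail = FALSE))
  }))
}

# Random acyclic pedigree with at most `max_links` known-parent links.
random_pedigree_idx <- function(n, max_links = 12L) {
  repeat {
    sire <- integer(n); dam <- integer(n)
    for (i in 2:n) {
      if (stats::runif(1) < 0.6) sire[i] <- sample.int(i - 1L, 1L)
      if (stats::runif(1) < 0.6) dam[i] <- sample.int(i - 1L, 1L)
    }
    if (sum(sire > 0) + sum(dam > 0) <= max_links) return(list(sire = sire, dam = dam))
  }
}

# small genotype_data constructor for tests
toy_geno <- function(dosage, chrom = "1", pos = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_data(dosage,
                data.frame(marker_id = paste0("m", seq_len(m)),
                           chrom = rep(chrom, length.out = m), pos = pos,
                           allele_A = "A", allele_B = "G",
                           stringsAsFactors = FALSE),
                paste0("an", seq_len(nrow(dosage))))
}
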