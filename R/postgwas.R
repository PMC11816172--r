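#' Candidate genes within +/- 1 Mb of significant SNPs
#'
#' For each significant marker the window is
#' `[max(1, pos - window_bp), pos + window_bp]` (1-based inclusive on both
#' sides); every gene whose interval intersects the window is listed,
#' sorted by distance from the marker (0 if the marker lies inside the
#' gene). Strand is ignored. Markers on chromosomes absent from the
#' annotation get a warning and an empty gene list.
#'
#' @param hits data.frame with `marker_id`, `chrom`, `bp` (e.g. the
#'   significant subset of a [weighted_gwas()] result).
#' @param genes a [gene_annotation].
#' @param window_bp half-window size (default 1e6).
#' @return data.frame with one row per (marker, gene) pair plus markers with
#'   zero overlaps (`gene_id = NA`); columns `marker_id`, `chrom`, `bp`,
#'   `window_start`, `window_end`, `gene_id`, `gene_name`, `gene_start`,
#'   `gene_end`, `distance_bp`, `n_genes`.
#' @export
annotate_genes <- function(hits, genes, window_bp = 1e6) {
  hits <- as.data.frame(hits)
  if (!nrow(hits)) {
    return(data.frame(marker_id = character(), chrom = character(),
                      bp = numeric(), window_start = numeric(),
                      window_end = numeric(), gene_id = character(),
                      gene_name = character(), gene_start = numeric(),
                      gene_end = numeric(), distance_bp = numeric(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    pos <- hits$bp[i]; chr <- as.character(hits$chrom[i])
    ws <- max(1, pos - window_bp); we <- pos + window_bp
    if (!chr %in% genes$chrom) {
      warning("chromosome ", chr, " of marker ", hits$marker_id[i],
              " absent from gene annotation")
      gg <- genes[0, ]
    } else {
      gg <- genes[genes$chrom == chr & genes$start <= we & genes$end >= ws, ,
                  drop = FALSE]
    }
    base <- data.frame(marker_id = hits$marker_id[i], chrom = chr, bp = pos,
                       window_start = ws, window_end = we,
                       stringsAsFactors = FALSE)
    if (!nrow(gg)) {
      row <- cbind(base, data.frame(gene_id = NA_character_,
                                    gene_name = NA_character_,
                                    gene_start = NA_real_, gene_end = NA_real_,
                                    distance_bp = NA_real_, n_genes = 0L,
                                    stringsAsFactors = FALSE))
    } else {
      dist <- ifelse(pos >= gg$start & pos <= gg$end, 0,
                     pmin(abs(pos - gg$start), abs(pos - gg$end)))
      o <- order(dist, gg$gene_id)
      row <- cbind(base[rep(1L, nrow(gg)), , drop = FALSE],
                   data.frame(gene_id = gg$gene_id[o], gene_name = gg$gene_name[o],
                              gene_start = gg$start[o], gene_end = gg$end[o],
                              distance_bp = dist[o], n_genes = nrow(gg),
                              stringsAsFactors = FALSE))
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' cis-eQTL scan by per-gene marker regression
#'
#' For every gene, simple linear regression of (optionally log(x+1)
#' transformed) expression on dosage for each marker within `cis_window_bp`
#' of the gene body, with a t-test per marker. Genes with zero expression
#' variance are skipped (counted in attribute `n_skipped_genes`).
#'
#' @param expr an [expression_matrix]; sample ids must map to genotyped
#'   animal ids.
#' @param geno a [genotype_data].
#' @param genes a [gene_annotation].
#' @param cis_window_bp cis window around the gene body (default 1e6).
#' @param log_transform apply `log(x + 1)` before regression (default TRUE).
#' @param fdr_method passed to [fdr_qvalues()] for the per-tissue q-values.
#' @return data.frame of eQTL records: `gene_id`, `marker_id`, `tissue`,
#'   `beta`, `se`, `p`, `q`, `n_samples`.
#' @export
cis_eqtl_scan <- function(expr, geno, genes, cis_window_bp = 1e6,
                          log_transform = TRUE, fdr_method = "storey") {
  samp <- intersect(colnames(expr$mat), geno$animal_ids)
  if (length(samp) < 3L) stop("fewer than 3 expression samples map to genotyped animals")
  E <- expr$mat[, samp, drop = FALSE]
  if (log_transform) E <- log(E + 1)
  D <- geno$dosage[match(samp, geno$animal_ids), , drop = FALSE]
  out <- list()
  n_skipped <- 0L
  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    if (!gid %in% rownames(E)) next
    yv <- E[gid, ]
    if (stats::var(yv) < 1e-12) { n_skipped <- n_skipped + 1L; next }
    jj <- which(geno$map$chrom == genes$chrom[gi] &
                  geno$map$pos >= genes$start[gi] - cis_window_bp &
                  geno$map$pos <= genes$end[gi] + cis_window_bp)
    for (j in jj) {
      x <- D[, j]
      ok <- !is.na(x)
      nn <- sum(ok)
      if (nn < 3L || stats::var(x[ok]) < 1e-12) next
      xx <- x[ok]; yy <- yv[ok]
      sxx <- sum((xx - mean(xx))^2)
      b <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
      res2 <- sum((yy - mean(yy) - b * (xx - mean(xx)))^2)
      sig2 <- res2 / (nn - 2L)
      se <- sqrt(sig2 / sxx)
      tval <- if (se > 0) b / se else sign(b) * Inf
      pv <- 2 * stats::pt(abs(tval), df = nn - 2L, lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, marker_id = geno$map$marker_id[j], tissue = expr$tissue,
        beta = b, se = se, p = pv, n_samples = nn, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), marker_id = character(),
               tissue = character(), beta = numeric(), se = numeric(),
               p = numeric(), n_samples = integer(), stringsAsFactors = FALSE)
  res$q <- if (nrow(res)) fdr_qvalues(res$p, method = fdr_method) else numeric(0)
  attr(res, "n_skipped_genes") <- n_skipped
  res
}

#' Linkage disequilibrium r^2 between two markers (EM over unphased genotypes)
#'
#' Two-locus haplotype frequencies are fitted by expectation-maximization
#' (double heterozygotes split between the two phase configurations at each
#' iteration; initialization at linkage equilibrium; convergence at 1e-10
#' change, max 1000 iterations). `D = f_AB - p_A p_B` and
#' `r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`.
#'
#' @param geno a [genotype_data].
#' @param marker_a,marker_b marker ids.
#' @return list of class `ld_pair`: `marker_a`, `marker_b`, `r2`, `D`,
#'   `Dprime`, `hap_freq` (AB, Ab, aB, ab), `n`.
#' @export
ld_r2 <- function(geno, marker_a, marker_b) {
  ja <- match(marker_a, geno$map$marker_id)
  jb <- match(marker_b, geno$map$marker_id)
  if (is.na(ja) || is.na(jb)) stop("marker not found in map")
  ga <- geno$dosage[, ja]; gb <- geno$dosage[, jb]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  if (n < 2L) stop("fewer than 2 complete genotype pairs")
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  if (pA <= 0 || pA >= 1) stop("marker ", marker_a, " is monomorphic")
  if (pB <= 0 || pB >= 1) stop("marker ", marker_b, " is monomorphic")
  cnt <- table(factor(ga, 0:2), factor(gb, 0:2))   # rows: dosage at A
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))                 # linkage equilibrium start
  # known haplotype counts from the 8 unambiguous cells (allele "A" here
  # denotes the B-allele/dosage-counted allele of each marker)
  hap_base <- c(AB = 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"],
                Ab = 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"],
                aB = 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"],
                ab = 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"])
  ndh <- cnt["1", "1"]                             # double heterozygotes
  for (it in seq_len(1000L)) {
    # P(phase AB/ab) vs (Ab/aB) for a double heterozygote
    w <- f["AB"] * f["ab"]
    w <- if (w + f["Ab"] * f["aB"] > 0) w / (w + f["Ab"] * f["aB"]) else 0.5
    hap <- hap_base + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- hap / (2 * n)
    if (max(abs(f_new - f)) < 1e-10) { f <- f_new; break }
    f <- f_new
  }
  D <- f[["AB"]] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(marker_a = marker_a, marker_b = marker_b,
                 r2 = unname(r2), D = unname(D),
                 Dprime = unname(if (dmax > 0) abs(D) / dmax else NA_real_),
                 hap_freq = f, n = n), class = "ld_pair")
}

#' Genotype-stratified expression comparison (least significant difference)
#'
#' One-way analysis of variance of expression across the (up to three)
#' genotype classes, followed by the least-significant-difference procedure:
#' pairwise two-sided t-tests using the pooled within-group mean square and
#' its degrees of freedom, without multiplicity correction. Significance
#' stars: * < 0.05, ** < 0.01, *** < 0.001, ns otherwise.
#'
#' @param expr_values numeric vector of expression values.
#' @param dosages genotype dosages (0/1/2) aligned to `expr_values`.
#' @return list: `group_means`, `group_n`, `anova_p`, `pairwise`
#'   (data.frame with groups, difference, t, df, p, stars; pairs with a
#'   class below 2 samples are flagged `skipped`).
#' @export
lsd_genotype_expression <- function(expr_values, dosages) {
  ok <- !is.na(expr_values) & !is.na(dosages)
  y <- expr_values[ok]; g <- factor(dosages[ok], levels = sort(unique(dosages[ok])))
  if (nlevels(g) < 2L) stop("need at least 2 genotype classes")
  ns <- tabulate(g)
  if (sum(ns >= 2L) < 2L) stop("need at least 2 genotype classes with >= 2 samples")
  means <- tapply(y, g, mean)
  N <- length(y); k <- nlevels(g)
  sse <- sum((y - means[g])^2)
  df_err <- N - k
  mse <- sse / df_err
  if (mse <= 0) stop("zero within-group variance: LSD comparisons are degenerate")
  ssb <- sum(ns * (means - mean(y))^2)
  f_stat <- (ssb / (k - 1)) / mse
  anova_p <- stats::pf(f_stat, k - 1, df_err, lower.tail = FALSE)
  cmb <- utils::combn(levels(g), 2L)
  pw <- lapply(seq_len(ncol(cmb)), function(i) {
    g1 <- cmb[1L, i]; g2 <- cmb[2L, i]
    n1 <- ns[match(g1, levels(g))]; n2 <- ns[match(g2, levels(g))]
    if (n1 < 2L || n2 < 2L) {
      return(data.frame(group1 = g1, group2 = g2, diff = NA_real_,
                        t = NA_real_, df = df_err, p = NA_real_,
                        stars = "skipped", skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    dd <- means[[g1]] - means[[g2]]
    tval <- dd / sqrt(mse * (1 / n1 + 1 / n2))
    pv <- 2 * stats::pt(abs(tval), df_err, lower.tail = FALSE)
    data.frame(group1 = g1, group2 = g2, diff = dd, t = tval, df = df_err,
               p = pv, stars = p_stars(pv), skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  list(group_means = means, group_n = stats::setNames(ns, levels(g)),
       anova_p = anova_p, mse = mse, df = df_err,
       pairwise = do.call(rbind, pw))
}

p_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", "ns"))))
}

#' GWAS / eQTL co-localization
#'
#' For each significant GWAS SNP and each gene in its +/- 1 Mb window, the
#' report lists (a) direct overlaps — the SNP is itself a significant eQTL
#' for the gene (r^2 = 1) — and (b) LD-mediated overlaps — some significant
#' eQTL marker for the gene has `r^2 >= ld_threshold` with the GWAS SNP.
#'
#' @param gwas_hits significant GWAS subset (`marker_id`, `chrom`, `bp`).
#' @param eqtls [cis_eqtl_scan()] output with q-values.
#' @param genes a [gene_annotation].
#' @param geno a [genotype_data] for LD computation.
#' @param ld_threshold r^2 threshold for LD-mediated overlap (default 0.8).
#' @param eqtl_q_max eQTL significance threshold (FDR, default 0.05).
#' @param window_bp gene window around GWAS SNPs (default 1e6).
#' @return data.frame: `gwas_marker`, `gene_id`, `tissue`, `mechanism`
#'   (`"direct"` or `"ld"`), `eqtl_marker`, `r2`, `eqtl_q`.
#' @export
colocalize <- function(gwas_hits, eqtls, genes, geno, ld_threshold = 0.8,
                       eqtl_q_max = 0.05, window_bp = 1e6) {
  sig_e <- eqtls[!is.na(eqtls$q) & eqtls$q < eqtl_q_max, , drop = FALSE]
  empty <- data.frame(gwas_marker = character(), gene_id = character(),
                      tissue = character(), mechanism = character(),
                      eqtl_marker = character(), r2 = numeric(),
                      eqtl_q = numeric(), stringsAsFactors = FALSE)
  if (!nrow(sig_e) || !nrow(as.data.frame(gwas_hits))) return(empty)
  ann <- annotate_genes(gwas_hits, genes, window_bp)
  out <- list()
  for (i in seq_len(nrow(as.data.frame(gwas_hits)))) {
    mk <- gwas_hits$marker_id[i]
    win_genes <- ann$gene_id[ann$marker_id == mk & !is.na(ann$gene_id)]
    ee <- sig_e[sig_e$gene_id %in% win_genes, , drop = FALSE]
    if (!nrow(ee)) next
    for (r in seq_len(nrow(ee))) {
      if (ee$marker_id[r] == mk) {
        out[[length(out) + 1L]] <- data.frame(
          gwas_marker = mk, gene_id = ee$gene_id[r], tissue = ee$tissue[r],
          mechanism = "direct", eqtl_marker = mk, r2 = 1,
          eqtl_q = ee$q[r], stringsAsFactors = FALSE)
      } else {
        r2 <- tryCatch(ld_r2(geno, mk, ee$marker_id[r])$r2,
                       error = function(e) NA_real_)
        if (!is.na(r2) && r2 >= ld_threshold) {
          out[[length(out) + 1L]] <- data.frame(
            gwas_marker = mk, gene_id = ee$gene_id[r], tissue = ee$tissue[r],
            mechanism = "ld", eqtl_marker = ee$marker_id[r], r2 = r2,
            eqtl_q = ee$q[r], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
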