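#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator. Defaults
#' emulate a scaled-down boar AI-station study: a multi-generation pedigree,
#' a medium-density SNP panel with local LD, repeated semen-trait records
#' with additive + permanent-environment + residual structure at moderate
#' heritability/repeatability, and cis-regulated expression in one
#' testis-like tissue.
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @param n_founders founders in generation 0 (half sires, half dams).
#' @param n_generations number of descendant generations.
#' @param n_per_generation offspring per generation (default `n_founders`).
#' @param mean_records_per_animal Poisson mean of record counts (min 1).
#' @param n_chromosomes,chrom_length_bp,n_markers marker panel geometry.
#' @param maf_range founder minor-allele-frequency range.
#' @param ld_decay_bp e-folding distance of the latent AR(1) haplotype
#'   correlation that generates local LD among founders.
#' @param traits named list of trait specs; see [trait_spec()].
#' @param year_season_sd_frac,parity_sd_frac fixed-effect level SDs as
#'   fractions of each trait's phenotypic SD.
#' @param n_parity_levels number of birth-parity classes.
#' @param age_slope_frac,interval_slope_frac covariate slopes as fractions of
#'   phenotypic SD per month of age / per day of interval.
#' @param qtl_spec list of `list(trait=, chrom=, pos=, frac=)` causal QTL;
#'   `frac` is the fraction of additive variance at the nearest marker.
#' @param eqtl_spec list of `list(gene_id=, marker_id=, effect_size=, noise_sd=)`.
#' @param n_genes,n_expr_samples,expr_baseline,expr_noise_sd expression layer.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 100L,
                       n_generations = 3L,
                       n_per_generation = n_founders,
                       mean_records_per_animal = 8,
                       n_chromosomes = 5L,
                       chrom_length_bp = 1e8,
                       n_markers = 5000L,
                       maf_range = c(0.05, 0.5),
                       ld_decay_bp = 2e5,
                       traits = default_traits(),
                       year_season_sd_frac = 0.2,
                       parity_sd_frac = 0.15,
                       n_parity_levels = 4L,
                       age_slope_frac = 0.02,
                       interval_slope_frac = 0.01,
                       qtl_spec = list(),
                       eqtl_spec = list(),
                       n_genes = 100L,
                       n_expr_samples = 300L,
                       expr_baseline = 10,
                       expr_noise_sd = 1) {
  cfg <- as.list(environment())
  for (tn in names(cfg$traits)) {
    tr <- cfg$traits[[tn]]
    if (tr$h2 + tr$pe_ratio > 1 + 1e-12) {
      stop("trait ", tn, ": h2 + pe_ratio must be <= 1")
    }
  }
  fr <- vapply(cfg$qtl_spec, function(q) q$frac, numeric(1))
  if (length(fr)) {
    by_tr <- tapply(fr, vapply(cfg$qtl_spec, function(q) q$trait, character(1)), sum)
    if (any(by_tr > 1)) stop("QTL variance fractions exceed 1 for some trait")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Trait specification for the simulator
#'
#' @param mean,sd_phen trait mean and phenotypic SD (random part,
#'   additive + permanent environment + residual) in trait units.
#' @param h2 narrow-sense heritability sigma_a^2 / sigma_phen^2.
#' @param pe_ratio sigma_pe^2 / sigma_phen^2 (so repeatability = h2 + pe_ratio).
#' @param type `"percent"` (clipped to \[0,100\]), `"count"` (clipped to > 0)
#'   or `"continuous"`.
#' @export
trait_spec <- function(mean, sd_phen, h2, pe_ratio, type = "continuous") {
  list(mean = mean, sd_phen = sd_phen, h2 = h2, pe_ratio = pe_ratio, type = type)
}

#' @rdname trait_spec
#' @export
default_traits <- function() {
  list(
    spmot     = trait_spec(72, 10, 0.30, 0.10, "percent"),
    sppmot    = trait_spec(40, 15, 0.19, 0.04, "percent"),
    spabr     = trait_spec(25, 10, 0.30, 0.30, "percent"),
    spcount   = trait_spec(38, 15, 0.25, 0.08, "count"),
    volume_ml = trait_spec(180, 30, 0.20, 0.10, "count")
  )
}

#' Simulate a pedigree, genotypes and the genetic truth
#'
#' Founder haplotypes use a latent Gaussian first-order autoregressive
#' process thresholded at each marker's allele frequency: marginal MAF is
#' exact while correlation (hence LD) decays with physical distance.
#' Offspring genotypes arise by Mendelian gamete dropping with Haldane
#' recombination at 1 cM/Mb. True breeding values are marker-based: optional
#' large-effect QTL (allele-substitution effect sized from its variance
#' fraction) plus an infinitesimal tail over all remaining markers, rescaled
#' so the founder additive variance equals each trait's sigma_a^2.
#'
#' @param config a [sim_config].
#' @return list with `pedigree` ([pedigree_table]), `genotypes`
#'   ([genotype_data]) and `truth` (true BVs, variance components, causal
#'   markers and effects).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "population"))
  n_f <- as.integer(config$n_founders)
  n_gen <- as.integer(config$n_generations)
  n_pg <- as.integer(config$n_per_generation)
  n_tot <- n_f + n_gen * n_pg

  ## --- marker map -----------------------------------------------------
  m_per <- diff(round(seq(0, config$n_markers, length.out = config$n_chromosomes + 1L)))
  map <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(cc) {
    pos <- sort(sample.int(config$chrom_length_bp, m_per[cc]))
    ref <- sample(c("A", "C", "G", "T"), m_per[cc], replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1))
    data.frame(marker_id = sprintf("snp_c%d_%06d", cc, seq_len(m_per[cc])),
               chrom = as.character(cc), pos = as.numeric(pos),
               allele_A = ref, allele_B = alt, stringsAsFactors = FALSE)
  }))
  m <- nrow(map)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  ## --- founder haplotypes (latent AR(1), marginal Bern(maf)) ----------
  n_hap <- 2L * n_f
  hap <- matrix(0L, n_hap, m)
  thr <- stats::qnorm(maf)
  for (cc in unique(map$chrom)) {
    jj <- which(map$chrom == cc)
    d <- diff(map$pos[jj])
    phi <- exp(-d / config$ld_decay_bp)
    u <- matrix(0, n_hap, length(jj))
    u[, 1L] <- stats::rnorm(n_hap)
    for (k in seq_along(d)) {
      u[, k + 1L] <- phi[k] * u[, k] + sqrt(1 - phi[k]^2) * stats::rnorm(n_hap)
    }
    hap[, jj] <- (u < rep(thr[jj], each = n_hap)) + 0L
  }

  ## --- pedigree + gamete dropping ------------------------------------
  ids <- sprintf("A%05d", seq_len(n_tot))
  sire <- rep(NA_character_, n_tot); dam <- rep(NA_character_, n_tot)
  sex <- rep_len(c("M", "F"), n_tot)   # deterministic alternating sexes
  gen <- c(rep(0L, n_f), rep(seq_len(n_gen), each = n_pg))
  hap1 <- matrix(0L, n_tot, m); hap2 <- matrix(0L, n_tot, m)
  hap1[seq_len(n_f), ] <- hap[seq(1L, n_hap, 2L), ]
  hap2[seq_len(n_f), ] <- hap[seq(2L, n_hap, 2L), ]

  # Haldane recombination fractions between adjacent markers (1 cM/Mb)
  rec <- lapply(unique(map$chrom), function(cc) {
    jj <- which(map$chrom == cc)
    list(idx = jj, r = 0.5 * (1 - exp(-2 * diff(map$pos[jj]) * 1e-8)))
  })
  gamete <- function(h1, h2) {
    g <- integer(m)
    for (blk in rec) {
      jj <- blk$idx
      sw <- c(stats::rbinom(1L, 1L, 0.5), stats::rbinom(length(blk$r), 1L, blk$r))
      cur <- cumsum(sw) %% 2L
      g[jj] <- ifelse(cur == 0L, h1[jj], h2[jj])
    }
    g
  }
  for (g_i in seq_len(n_gen)) {
    prev <- which(gen == g_i - 1L)
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    kids <- which(gen == g_i)
    s_pick <- sample(males, length(kids), replace = TRUE)
    d_pick <- sample(females, length(kids), replace = TRUE)
    for (k in seq_along(kids)) {
      i <- kids[k]
      sire[i] <- ids[s_pick[k]]; dam[i] <- ids[d_pick[k]]
      hap1[i, ] <- gamete(hap1[s_pick[k], ], hap2[s_pick[k], ])
      hap2[i, ] <- gamete(hap1[d_pick[k], ], hap2[d_pick[k], ])
    }
  }
  dosage <- hap1 + hap2
  geno <- genotype_data(dosage, map, ids)
  ped <- pedigree_table(ids, sire, dam)

  ## --- true breeding values -------------------------------------------
  p_found <- colMeans(dosage[seq_len(n_f), , drop = FALSE]) / 2
  centered <- sweep(geno$dosage, 2L, 2 * p_found)
  traits <- config$traits
  bv <- matrix(0, n_tot, length(traits),
               dimnames = list(ids, names(traits)))
  qtl_rows <- list()
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    sa2 <- tr$h2 * tr$sd_phen^2
    qtls <- Filter(function(q) identical(q$trait, tn), config$qtl_spec)
    qtl_j <- integer(0); qtl_beta <- numeric(0)
    g_qtl <- rep(0, n_tot)
    for (q in qtls) {
      jj <- which(geno$map$chrom == as.character(q$chrom))
      if (!length(jj)) stop("QTL chromosome ", q$chrom, " not on the marker map")
      j <- jj[which.min(abs(geno$map$pos[jj] - q$pos))]
      pq <- p_found[j] * (1 - p_found[j])
      if (pq <= 0) stop("QTL marker ", geno$map$marker_id[j], " is monomorphic in founders")
      beta <- sqrt(q$frac * sa2 / (2 * pq))
      qtl_j <- c(qtl_j, j); qtl_beta <- c(qtl_beta, beta)
      g_qtl <- g_qtl + beta * centered[, j]
      qtl_rows[[length(qtl_rows) + 1L]] <-
        data.frame(trait = tn, marker_id = geno$map$marker_id[j],
                   chrom = geno$map$chrom[j], pos = geno$map$pos[j],
                   effect = beta, frac = q$frac, stringsAsFactors = FALSE)
    }
    frac_tot <- sum(vapply(qtls, function(q) q$frac, numeric(1)))
    rest <- (1 - frac_tot) * sa2
    poly_j <- setdiff(seq_len(m), qtl_j)
    u <- stats::rnorm(length(poly_j))
    g_poly <- as.vector(centered[, poly_j, drop = FALSE] %*% u)
    v_f <- stats::var(g_poly[seq_len(n_f)])
    if (rest > 0 && v_f > 0) {
      g_poly <- g_poly * sqrt(rest / v_f)
    } else {
      g_poly <- rep(0, n_tot)
    }
    bv[, tn] <- g_qtl + g_poly
  }
  vc <- lapply(traits, function(tr) {
    s2 <- tr$sd_phen^2
    list(sigma_a2 = tr$h2 * s2, sigma_p2 = tr$pe_ratio * s2,
         sigma_e2 = (1 - tr$h2 - tr$pe_ratio) * s2,
         h2 = tr$h2, re = tr$h2 + tr$pe_ratio)
  })
  truth <- list(bv = bv, vc = vc,
                qtl = if (length(qtl_rows)) do.call(rbind, qtl_rows) else
                  data.frame(trait = character(), marker_id = character(),
                             chrom = character(), pos = numeric(),
                             effect = numeric(), frac = numeric()),
                founder_maf = pmin(p_found, 1 - p_found),
                generation = stats::setNames(gen, ids))
  list(pedigree = ped, genotypes = geno, truth = truth)
}

#' Simulate repeated phenotype records
#'
#' Generative counterpart of the repeatability animal model: each record is
#' mean + year-season effect + parity effect + age and interval covariate
#' terms + true breeding value + a permanent-environment deviate (one draw
#' per animal, reused across its records) + residual. Percent traits are
#' clipped to \[0,100\] and counts to > 0; clipping rates are attached as an
#' attribute.
#'
#' @param pedigree a [pedigree_table] (record counts are drawn per animal).
#' @param truth truth list from [simulate_population()].
#' @param config the same [sim_config].
#' @return a [phenotype_table] with attribute `clip_rate` (named per trait).
#' @export
simulate_records <- function(pedigree, truth, config) {
  set.seed(derive_seed(config$seed, "records"))
  ids <- pedigree$animal
  n <- length(ids)
  gen <- truth$generation[ids]
  gen[is.na(gen)] <- 0L
  n_rec <- pmax(1L, stats::rpois(n, config$mean_records_per_animal))
  birth <- as.Date("2018-01-01") + as.integer(gen) * 365L
  parity <- sample.int(config$n_parity_levels, n, replace = TRUE)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    age0 <- stats::runif(1, 7, 12)                       # months at first collection
    gaps <- sample(3:7, n_rec[i], replace = TRUE)        # days between collections
    offs <- cumsum(gaps) - gaps[1L]
    dates <- birth[i] + round(age0 * 30.44) + offs
    rows[[i]] <- data.frame(
      animal = ids[i], date = dates,
      parity = paste0("P", parity[i]),
      age_months = as.numeric(dates - birth[i]) / 30.44,
      interval_days = c(NA_real_, diff(offs)),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  yr <- as.integer(format(rec$date, "%Y"))
  qtr <- (as.integer(format(rec$date, "%m")) - 1L) %/% 3L + 1L
  rec$year_season <- sprintf("%dQ%d", yr, qtr)

  ys_levels <- sort(unique(rec$year_season))
  par_levels <- sort(unique(rec$parity))
  clip <- numeric(0)
  for (tn in names(config$traits)) {
    tr <- config$traits[[tn]]
    vc <- truth$vc[[tn]]
    ys_eff <- stats::setNames(stats::rnorm(length(ys_levels),
                                           sd = config$year_season_sd_frac * tr$sd_phen), ys_levels)
    par_eff <- stats::setNames(stats::rnorm(length(par_levels),
                                            sd = config$parity_sd_frac * tr$sd_phen), par_levels)
    pe <- stats::setNames(stats::rnorm(n, sd = sqrt(vc$sigma_p2)), ids)
    e <- stats::rnorm(nrow(rec), sd = sqrt(vc$sigma_e2))
    y <- tr$mean +
      ys_eff[rec$year_season] + par_eff[rec$parity] +
      config$age_slope_frac * tr$sd_phen * rec$age_months +
      config$interval_slope_frac * tr$sd_phen * ifelse(is.na(rec$interval_days), 0, rec$interval_days) +
      truth$bv[rec$animal, tn] + pe[rec$animal] + e
    if (tr$type == "percent") {
      n_clip <- sum(y < 0 | y > 100)
      y <- pmin(pmax(y, 0), 100)
      clip[tn] <- n_clip / length(y)
    } else if (tr$type == "count") {
      n_clip <- sum(y <= 0)
      y <- pmax(y, 0.1)
      clip[tn] <- n_clip / length(y)
    } else clip[tn] <- 0
    rec[[tn]] <- as.numeric(y)
  }
  out <- phenotype_table(rec)
  attr(out, "clip_rate") <- clip
  out
}

#' Simulate a gene annotation matched to the marker map
#'
#' Genes are tiled uniformly along the simulated chromosomes; any gene named
#' in `eqtl_spec` is placed so that its cis-window contains its causal
#' marker.
#'
#' @param geno a [genotype_data].
#' @param config a [sim_config].
#' @return a [gene_annotation].
#' @export
simulate_genes <- function(geno, config) {
  set.seed(derive_seed(config$seed, "genes"))
  chroms <- unique(geno$map$chrom)
  per <- diff(round(seq(0, config$n_genes, length.out = length(chroms) + 1L)))
  df <- do.call(rbind, lapply(seq_along(chroms), function(k) {
    if (per[k] == 0L) return(NULL)
    start <- round(seq(1, config$chrom_length_bp * 0.95, length.out = per[k]))
    data.frame(gene_id = sprintf("gene_c%s_%03d", chroms[k], seq_len(per[k])),
               chrom = chroms[k], start = start,
               end = start + round(stats::runif(per[k], 5e3, 5e4)),
               strand = rep_len(c("+", "-"), per[k]), stringsAsFactors = FALSE)
  }))
  for (eq in config$eqtl_spec) {
    j <- match(eq$marker_id, geno$map$marker_id)
    if (is.na(j)) stop("eqtl_spec marker ", eq$marker_id, " not on the map")
    hit <- which(df$gene_id == eq$gene_id)
    row <- data.frame(gene_id = eq$gene_id, chrom = geno$map$chrom[j],
                      start = max(1, geno$map$pos[j] - 5e4),
                      end = geno$map$pos[j] + 5e4, strand = "+",
                      stringsAsFactors = FALSE)
    if (length(hit)) df[hit, ] <- row else df <- rbind(df, row)
  }
  df$gene_name <- df$gene_id
  gene_annotation(df)
}

#' Simulate cis-regulated expression
#'
#' Expression of a cis-regulated gene is baseline + effect_size x dosage +
#' Gaussian noise; unregulated genes are baseline + noise. Each gene is
#' shifted so its minimum is non-negative (a location shift, irrelevant to
#' downstream regression).
#'
#' @param geno a [genotype_data].
#' @param config a [sim_config] whose `eqtl_spec` markers exist in `geno`.
#' @param genes optional [gene_annotation] supplying the gene universe
#'   (default [simulate_genes()]).
#' @return an [expression_matrix] for one testis-like tissue; causal pairs in
#'   attribute `eqtl_truth`.
#' @export
simulate_expression <- function(geno, config, genes = NULL) {
  set.seed(derive_seed(config$seed, "expression"))
  if (is.null(genes)) genes <- simulate_genes(geno, config)
  n <- length(geno$animal_ids)
  ns <- min(config$n_expr_samples, n)
  samp <- sort(sample.int(n, ns))
  sample_ids <- geno$animal_ids[samp]
  mat <- matrix(stats::rnorm(nrow(genes) * ns, mean = config$expr_baseline,
                             sd = config$expr_noise_sd),
                nrow(genes), ns, dimnames = list(genes$gene_id, sample_ids))
  eqtl_truth <- list()
  for (eq in config$eqtl_spec) {
    j <- match(eq$marker_id, geno$map$marker_id)
    if (is.na(j)) stop("eqtl_spec marker ", eq$marker_id, " not on the map")
    dos <- geno$dosage[samp, j]
    dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
    noise <- stats::rnorm(ns, sd = eq$noise_sd)
    mat[eq$gene_id, ] <- config$expr_baseline + eq$effect_size * dos + noise
    eqtl_truth[[length(eqtl_truth) + 1L]] <-
      data.frame(gene_id = eq$gene_id, marker_id = eq$marker_id,
                 effect_size = eq$effect_size, noise_sd = eq$noise_sd,
                 stringsAsFactors = FALSE)
  }
  mat <- mat - pmin(0, apply(mat, 1L, min))   # per-gene non-negativity shift
  out <- expression_matrix(mat, tissue = "testis_like")
  attr(out, "eqtl_truth") <- if (length(eqtl_truth)) do.call(rbind, eqtl_truth) else NULL
  attr(out, "genes") <- genes
  out
}
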