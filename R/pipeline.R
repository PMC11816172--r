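#' Run the full weighted-GWAS pipeline
#'
#' Orchestrates simulate (or load) -> phenotype/genotype QC -> REML -> BLUP
#' -> deregression -> weights -> weighted GWAS -> gene annotation -> cis-eQTL
#' -> co-localization, independently per breed and per trait. Every stage
#' writes its artifact under `out_dir/<breed>/`; a stage failure aborts the
#' remaining stages for that breed/trait only. The final report aggregates a
#' descriptive/heritability summary (one row per breed x trait) and a
#' significant-SNP table with candidate-gene counts.
#'
#' @param config a list or path to a YAML file. Top-level fields: `out_dir`,
#'   `seed`, `traits` (character vector), `breeds` (named list; each breed
#'   either `simulate: true` plus [sim_config()] overrides, or input paths
#'   `pedigree`, `phenotypes`, `ped`, `map`, `genes`, `expression`), and
#'   optional blocks `qc` (call_rate_min, maf_min, hwe_min), `weights` (c),
#'   `fdr` (method, threshold), `windows` (gene_bp, cis_bp, ld_threshold).
#' @param resume if TRUE, stages whose artifacts already exist are reloaded
#'   instead of recomputed.
#' @param seed optional override of `config$seed`.
#' @return invisible list with `status` (0 = all stages succeeded), `summary`
#'   and `snps` report tables, per-breed results, and any `errors`.
#' @export
run_pipeline <- function(config, resume = FALSE, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$out_dir, "pipeline.log")
  if (!resume && file.exists(logfile)) unlink(logfile)
  errors <- list()
  summary_rows <- list(); snp_rows <- list(); coloc_rows <- list()
  breed_out <- list()

  for (breed in names(cfg$breeds)) {
    res <- tryCatch(
      run_breed(breed, cfg, resume, logfile),
      error = function(e) {
        wg_log("[", breed, "] FAILED: ", conditionMessage(e), logfile = logfile)
        structure(list(error = conditionMessage(e)), class = "wgwas_stage_error")
      })
    breed_out[[breed]] <- res
    if (inherits(res, "wgwas_stage_error")) {
      errors[[breed]] <- res$error
      next
    }
    summary_rows[[breed]] <- res$summary
    snp_rows[[breed]] <- res$snps
    coloc_rows[[breed]] <- res$coloc
    for (nm in names(res$trait_errors)) errors[[paste(breed, nm)]] <- res$trait_errors[[nm]]
  }

  bindr <- function(lst) {
    lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
    if (length(lst)) do.call(rbind, c(lst, make.row.names = FALSE)) else NULL
  }
  summary_tab <- bindr(summary_rows) %||% data.frame(
    breed = character(), trait = character(), n_animals = integer(),
    n_records = integer(), mean = numeric(), sd = numeric(), h2 = numeric(),
    h2_se = numeric(), re = numeric(), re_se = numeric(), lambda = numeric())
  snp_tab <- bindr(snp_rows) %||% data.frame(
    breed = character(), trait = character(), chrom = character(),
    bp = numeric(), marker_id = character(), maf = numeric(), p = numeric(),
    q = numeric(), gvar_pct = numeric(), n_window_genes = integer())
  coloc_tab <- bindr(coloc_rows)
  write_results(summary_tab, file.path(cfg$out_dir, "summary.tsv"))
  write_results(snp_tab, file.path(cfg$out_dir, "report.tsv"))
  if (!is.null(coloc_tab)) write_results(coloc_tab, file.path(cfg$out_dir, "coloc.tsv"))
  status <- if (length(errors)) 1L else 0L
  wg_log("pipeline finished with status ", status, logfile = logfile)
  invisible(list(status = status, summary = summary_tab, snps = snp_tab,
                 coloc = coloc_tab, breeds = breed_out, errors = errors,
                 out_dir = cfg$out_dir))
}

validate_pipeline_config <- function(config) {
  if (is.null(config$out_dir)) stop("config needs out_dir")
  if (is.null(config$breeds) || !length(config$breeds)) stop("config needs at least one breed")
  if (is.null(config$traits) || !length(config$traits)) stop("config needs traits")
  config$seed <- as.integer(config$seed %||% 1L)
  config$qc <- utils::modifyList(
    list(call_rate_min = 0.9, maf_min = 0.01, hwe_min = 1e-6), config$qc %||% list())
  config$weights <- utils::modifyList(list(c = 0.1), config$weights %||% list())
  config$fdr <- utils::modifyList(list(method = "storey", threshold = 0.05),
                                  config$fdr %||% list())
  config$windows <- utils::modifyList(
    list(gene_bp = 1e6, cis_bp = 1e6, ld_threshold = 0.8), config$windows %||% list())
  # referenced input paths must exist before any stage runs
  for (breed in names(config$breeds)) {
    bc <- config$breeds[[breed]]
    if (!isTRUE(bc$simulate)) {
      for (key in c("pedigree", "phenotypes", "ped", "map")) {
        if (is.null(bc[[key]])) {
          stop("breed '", breed, "': input path '", key,
               "' is required when simulate is not TRUE")
        }
        if (!file.exists(bc[[key]])) {
          stop("breed '", breed, "': input file not found: ", bc[[key]])
        }
      }
      for (key in c("genes", "expression")) {
        if (!is.null(bc[[key]]) && !file.exists(bc[[key]])) {
          stop("breed '", breed, "': input file not found: ", bc[[key]])
        }
      }
    }
  }
  config
}

# one breed: data acquisition, QC, then the per-trait chain
run_breed <- function(breed, cfg, resume, logfile) {
  bdir <- file.path(cfg$out_dir, breed)
  dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
  bc <- cfg$breeds[[breed]]
  art <- function(...) file.path(bdir, paste0(...))

  ## --- stage: data (simulate or load) ---------------------------------
  truth <- NULL; expr <- NULL; genes <- NULL
  if (isTRUE(bc$simulate)) {
    sim_args <- bc[setdiff(names(bc), c("simulate"))]
    sim_args$seed <- derive_seed(cfg$seed, paste0("breed_", breed))
    scfg <- do.call(sim_config, sim_args)
    have <- all(file.exists(art("genotypes.ped"), art("genotypes.map"),
                            art("pedigree.csv"), art("phenotypes.csv")))
    if (!resume || !have) {
      pop <- simulate_population(scfg)
      truth <- pop$truth
      phen0 <- simulate_records(pop$pedigree, truth, scfg)
      genes0 <- simulate_genes(pop$genotypes, scfg)
      expr0 <- simulate_expression(pop$genotypes, scfg, genes0)
      write_plink_text(pop$genotypes, art("genotypes.ped"), art("genotypes.map"))
      utils::write.csv(as.data.frame(pop$pedigree), art("pedigree.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(phen0), art("phenotypes.csv"), row.names = FALSE)
      write_gene_annotation(genes0, art("genes.gff3"))
      write_expression(expr0, art("expression.tsv"))
      jsonlite::write_json(list(vc = truth$vc, qtl = truth$qtl),
                           art("truth.json"), auto_unbox = TRUE, digits = NA)
      wg_log("[", breed, "] simulated ", nrow(pop$pedigree), " animals, ",
             nrow(phen0), " records, ", ncol(pop$genotypes$dosage), " markers",
             logfile = logfile)
    } else {
      wg_log("[", breed, "] resume: reusing simulated artifacts", logfile = logfile)
    }
    # downstream stages always consume the serialized artifacts, so fresh
    # and resumed runs see bit-identical inputs
    geno <- read_plink_text(art("genotypes.ped"), art("genotypes.map"))
    tb <- read_tables(art("pedigree.csv"), art("phenotypes.csv"),
                      if (file.exists(art("genes.gff3"))) art("genes.gff3"))
    ped <- tb$pedigree; phen <- tb$phenotypes; genes <- tb$genes
    if (file.exists(art("expression.tsv"))) {
      expr <- read_expression(art("expression.tsv"), "testis_like")
    }
  } else {
    tb <- read_tables(bc$pedigree, bc$phenotypes, bc$genes)
    ped <- tb$pedigree; phen <- tb$phenotypes; genes <- tb$genes
    geno <- read_plink_text(bc$ped, bc$map)
    if (!is.null(bc$expression)) expr <- read_expression(bc$expression, bc$tissue %||% "tissue")
    wg_log("[", breed, "] loaded ", nrow(ped), " animals, ", nrow(phen),
           " records, ", ncol(geno$dosage), " markers", logfile = logfile)
  }

  ## --- stage: QC ------------------------------------------------------
  pq <- filter_phenotypes(phen)
  gq <- genotype_qc(geno, cfg$qc$call_rate_min, cfg$qc$maf_min, cfg$qc$hwe_min)
  pca <- genotype_pca(gq$genotypes, k = 2L)
  qc_report <- list(phenotype = pq$report, genotype = gq$report,
                    pca_var_frac = pca$var_frac)
  jsonlite::write_json(qc_report, art("qc_report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  write_results(gq$report, art("qc_report.tsv"))
  wg_log("[", breed, "] QC: ", pq$n_retained, "/", pq$n_input, " records, ",
         gq$n_retained, "/", gq$n_input, " markers retained", logfile = logfile)
  phen_qc <- pq$records
  geno_qc <- gq$genotypes
  A <- build_A(ped)
  grm <- build_grm(geno_qc)

  if (!is.null(expr) && !is.null(genes)) {
    eqtls <- cis_eqtl_scan(expr, geno_qc, genes, cfg$windows$cis_bp,
                           fdr_method = cfg$fdr$method)
    write_results(eqtls, art("eqtl.tsv"))
  } else eqtls <- NULL

  ## --- per-trait chain ------------------------------------------------
  summary_rows <- list(); snp_rows <- list(); coloc_rows <- list()
  trait_errors <- list(); traits_out <- list()
  for (trait in cfg$traits) {
    tr_res <- tryCatch({
      if (!trait %in% names(phen_qc)) stop("trait '", trait, "' not in phenotypes")
      vc <- reml_repeatability(phen_qc, A, trait)
      jsonlite::write_json(
        list(trait = trait, sigma_a2 = vc$sigma_a2, sigma_p2 = vc$sigma_p2,
             sigma_e2 = vc$sigma_e2, h2 = vc$h2, h2_se = vc$h2_se,
             re = vc$re, re_se = vc$re_se, loglik = vc$loglik),
        art("vc_", trait, ".json"), auto_unbox = TRUE, digits = NA)
      bv <- solve_mme_blup(phen_qc, A, vc, trait)
      bv <- deregress(bv, ped, vc$h2)
      bv <- compute_weights(bv, vc$h2, cfg$weights$c)
      write_results(bv[, c("animal", "ebv", "rel", "pa", "debv",
                           "rel_animal", "weight")], art("debv_", trait, ".tsv"))
      use <- !bv$excluded & bv$animal %in% rownames(grm$G)
      ids <- bv$animal[use]
      null <- fit_null_model(bv$debv[use], bv$weight[use], grm, animal_ids = ids)
      gw <- weighted_gwas(bv$debv[use], geno_qc, null, fdr_method = cfg$fdr$method)
      write_results(gw, art("gwas_", trait, ".tsv"))
      jsonlite::write_json(list(trait = trait, lambda = attr(gw, "lambda"),
                                sigma_g2 = attr(gw, "sigma_g2"),
                                sigma_e2 = attr(gw, "sigma_e2")),
                           art("lambda_", trait, ".json"), auto_unbox = TRUE, digits = NA)
      sig <- gw[!is.na(gw$q) & gw$q < cfg$fdr$threshold, , drop = FALSE]
      ann <- if (!is.null(genes)) annotate_genes(sig, genes, cfg$windows$gene_bp) else NULL
      if (!is.null(ann)) write_results(ann, art("genes_", trait, ".tsv"))
      cl <- if (!is.null(eqtls) && nrow(sig)) {
        colocalize(sig, eqtls, genes, geno_qc, cfg$windows$ld_threshold,
                   cfg$fdr$threshold, cfg$windows$gene_bp)
      } else NULL
      if (!is.null(cl) && nrow(cl)) write_results(cl, art("coloc_", trait, ".tsv"))
      wg_log("[", breed, "/", trait, "] h2=", round(vc$h2, 3),
             " re=", round(vc$re, 3), " lambda=", round(attr(gw, "lambda"), 3),
             " sig SNPs=", nrow(sig), logfile = logfile)
      yv <- phen_qc[[trait]]
      list(summary = data.frame(
        breed = breed, trait = trait,
        n_animals = length(unique(phen_qc$animal)), n_records = length(yv),
        mean = mean(yv), sd = stats::sd(yv),
        h2 = vc$h2, h2_se = vc$h2_se, re = vc$re, re_se = vc$re_se,
        lambda = attr(gw, "lambda"), stringsAsFactors = FALSE),
        snps = if (nrow(sig)) data.frame(
          breed = breed, trait = trait, chrom = sig$chrom, bp = sig$bp,
          marker_id = sig$marker_id, maf = sig$maf, p = sig$p, q = sig$q,
          gvar_pct = sig$gvar_pct,
          n_window_genes = if (!is.null(ann)) ann$n_genes[match(sig$marker_id, ann$marker_id)] else NA_integer_,
          stringsAsFactors = FALSE) else NULL,
        coloc = if (!is.null(cl) && nrow(cl)) cbind(breed = breed, trait = trait, cl) else NULL,
        vc = vc, gwas = gw, bv = bv)
    }, error = function(e) structure(list(error = conditionMessage(e)),
                                     class = "wgwas_stage_error"))
    if (inherits(tr_res, "wgwas_stage_error")) {
      trait_errors[[trait]] <- tr_res$error
      wg_log("[", breed, "/", trait, "] FAILED: ", tr_res$error, logfile = logfile)
      next
    }
    summary_rows[[trait]] <- tr_res$summary
    snp_rows[[trait]] <- tr_res$snps
    coloc_rows[[trait]] <- tr_res$coloc
    traits_out[[trait]] <- tr_res[c("vc", "gwas", "bv")]
  }
  bindr <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst)) do.call(rbind, c(lst, make.row.names = FALSE)) else NULL
  }
  list(summary = bindr(summary_rows), snps = bindr(snp_rows),
       coloc = bindr(coloc_rows), trait_errors = trait_errors,
       traits = traits_out, qc = qc_report, pca = pca,
       genotypes = geno_qc, pedigree = ped, genes = genes, eqtls = eqtls)
}
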