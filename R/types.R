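#' Domain containers
#'
#' The pipeline passes a handful of light S3 containers between stages:
#' pedigrees, repeated phenotype records, dosage genotypes with a marker map,
#' gene annotations and expression matrices. Constructors validate the
#' invariants each downstream stage relies on.
#'
#' @name wgwas-types
NULL

#' Construct and validate a pedigree table
#'
#' @param animal,sire,dam character vectors; `NA` (or `"0"`/`""`) marks an
#'   unknown parent. Parents that never appear as animals are auto-added as
#'   founders. Rows are re-ordered topologically (parents before offspring).
#' @return a `data.frame` of class `pedigree_table` with columns
#'   `animal`, `sire`, `dam`.
#' @export
pedigree_table <- function(animal, sire, dam) {
  animal <- as.character(animal)
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("0", "", ".", "NA")] <- NA_character_
    x
  }
  sire <- clean(sire); dam <- clean(dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal ids in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  ord <- pedigree_topo_order(ped)   # errors on cycles
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# Kahn topological sort; on failure reports the animals stuck in a cycle.
pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  NA_integer_, idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving: ",
         paste(ped$animal[cyc], collapse = " -> "))
  }
  out
}

#' Construct and validate a phenotype table of repeated records
#'
#' One row per (animal, collection date). Trait percentages must lie in
#' \[0, 100\] and sperm counts must be positive.
#'
#' @param df data.frame with columns `animal`, `date` (coercible to `Date`),
#'   `year_season`, `parity`, `age_months`, `interval_days` (may be `NA` for
#'   an animal's first record), and trait columns among
#'   `spmot`, `sppmot`, `spabr`, `spcount`, `volume_ml`.
#' @return the validated data.frame, class `phenotype_table`, sorted by
#'   animal then date.
#' @export
phenotype_table <- function(df) {
  need <- c("animal", "date", "year_season", "parity", "age_months")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing columns: ", paste(miss, collapse = ", "))
  df$animal <- as.character(df$animal)
  df$date <- as.Date(df$date)
  key <- paste(df$animal, df$date)
  if (anyDuplicated(key)) {
    stop("duplicate (animal, date) phenotype rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  for (tr in intersect(c("spmot", "sppmot", "spabr"), names(df))) {
    bad <- !is.na(df[[tr]]) & (df[[tr]] < 0 | df[[tr]] > 100)
    if (any(bad)) stop("trait ", tr, " outside [0,100] in ", sum(bad), " rows")
  }
  if ("spcount" %in% names(df) && any(!is.na(df$spcount) & df$spcount <= 0)) {
    stop("spcount must be > 0")
  }
  df <- df[order(df$animal, df$date), , drop = FALSE]
  rownames(df) <- NULL
  if (!"interval_days" %in% names(df)) df$interval_days <- NA_real_
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Construct a genotype container (dosage matrix + marker map)
#'
#' @param dosage integer/numeric matrix, animals x markers, entries in
#'   `{0, 1, 2, NA}`; dosage counts copies of `allele_B`.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos`,
#'   `allele_A`, `allele_B` (one row per dosage column).
#' @param animal_ids character vector aligned to dosage rows.
#' @return list of class `genotype_data`.
#' @export
genotype_data <- function(dosage, map, animal_ids) {
  dosage <- as.matrix(dosage)
  if (nrow(map) != ncol(dosage)) {
    stop("marker map has ", nrow(map), " rows but dosage has ", ncol(dosage), " columns")
  }
  if (length(animal_ids) != nrow(dosage)) stop("animal_ids length != dosage rows")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  need <- c("marker_id", "chrom", "pos")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("marker map missing columns: ", paste(miss, collapse = ", "))
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  if (!"allele_A" %in% names(map)) map$allele_A <- "A"
  if (!"allele_B" %in% names(map)) map$allele_B <- "B"
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(map) <- NULL
  dimnames(dosage) <- list(as.character(animal_ids), map$marker_id)
  structure(list(dosage = dosage, map = map,
                 animal_ids = as.character(animal_ids)),
            class = "genotype_data")
}

#' Construct a gene annotation table (1-based inclusive intervals)
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `gene_name`, `strand`.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene annotation missing columns: ", paste(miss, collapse = ", "))
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  if (!"strand" %in% names(df)) df$strand <- "+"
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
  if (any(df$start > df$end)) stop("gene start > end")
  if (any(df$start < 1)) stop("1-based coordinates required (start >= 1)")
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df <- df[order(df$chrom, df$start), c("gene_id", "gene_name", "chrom", "start", "end", "strand")]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Construct an expression matrix (genes x samples, TPM-like)
#'
#' @param mat non-negative numeric matrix, genes in rows, samples in columns.
#' @param tissue single tissue label.
#' @return list of class `expression_matrix` with `mat` and `tissue`.
#' @export
expression_matrix <- function(mat, tissue = "tissue") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("expression matrix needs gene rownames")
  if (is.null(colnames(mat))) stop("expression matrix needs sample colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids in expression matrix")
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression values")
  structure(list(mat = mat, tissue = as.character(tissue)),
            class = "expression_matrix")
}
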