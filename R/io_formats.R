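#' Read PLINK text PED/MAP genotypes
#'
#' Parses the PLINK v1 text dialect: the PED file carries six leading columns
#' (family, individual, sire, dam, sex, phenotype) followed by two allele
#' columns per marker; the MAP file carries (chrom, marker_id, cM, bp).
#' Dosage counts copies of the file's minor allele (`allele_B` in the map),
#' determined per marker at read time so orientation is recorded and
#' reproducible. `0 0` allele pairs (and half-missing pairs) become `NA`.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return a [genotype_data] object.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                               col.names = c("chrom", "marker_id", "cm", "pos"))
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("empty PED file: ", ped_path)
  ids <- character(n)
  a1 <- matrix("", n, m); a2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * m) {
      stop("PED line ", i, " has ", length(f), " fields; expected ",
           6L + 2L * m, " for ", m, " MAP markers")
    }
    ids[i] <- f[2L]
    al <- f[-(1:6)]
    bad <- !al %in% c("A", "C", "G", "T", "0")
    if (any(bad)) {
      stop("PED line ", i, ": invalid allele code(s) ",
           paste(unique(al[bad]), collapse = ", "), " (expected A/C/G/T/0)")
    }
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  dosage <- matrix(NA_real_, n, m)
  allele_A <- character(m); allele_B <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) == 0L) {            # fully missing marker
      allele_A[j] <- "A"; allele_B[j] <- "B"
      next
    }
    # major first; deterministic alphabetical tie-break
    als <- names(tab)
    if (length(als) == 2L && tab[1L] == tab[2L]) als <- sort(als)
    allele_A[j] <- als[1L]
    allele_B[j] <- if (length(als) >= 2L) als[2L] else paste0("(", als[1L], ")")
    missing <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == allele_B[j]) + (a2[, j] == allele_B[j])
    d[missing] <- NA_real_
    dosage[, j] <- d
  }
  map <- data.frame(marker_id = as.character(map_raw$marker_id),
                    chrom = as.character(map_raw$chrom),
                    pos = as.numeric(map_raw$pos),
                    allele_A = allele_A, allele_B = allele_B,
                    stringsAsFactors = FALSE)
  genotype_data(dosage, map, ids)
}

#' Write genotypes as PLINK text PED/MAP
#'
#' Inverse of [read_plink_text()]: dosage 0/1/2 becomes `A_A`, `A_B`, `B_B`
#' allele pairs using the map's recorded alleles; `NA` becomes `0 0`.
#'
#' @param geno a [genotype_data] object.
#' @param ped_path,map_path output paths.
#' @export
write_plink_text <- function(geno, ped_path, map_path) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0, format(map$pos, scientific = FALSE, trim = TRUE)),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  con <- file(ped_path, "w"); on.exit(close(con))
  for (i in seq_len(n)) {
    pair <- character(2L * m)
    d <- geno$dosage[i, ]
    for (j in seq_len(m)) {
      pr <- switch(as.character(d[j]),
                   "0" = c(map$allele_A[j], map$allele_A[j]),
                   "1" = c(map$allele_A[j], map$allele_B[j]),
                   "2" = c(map$allele_B[j], map$allele_B[j]),
                   c("0", "0"))
      pair[c(2L * j - 1L, 2L * j)] <- pr
    }
    cat(paste(c("FAM", geno$animal_ids[i], "0", "0", "0", "-9", pair), collapse = " "),
        "\n", file = con, sep = "")
  }
  invisible(NULL)
}

#' Read pedigree, phenotype and gene-annotation files
#'
#' Pedigree and phenotypes are CSV with headers; genes are GFF3 (gene
#' features) or BED, sniffed from the extension. BED's 0-based half-open
#' intervals are converted to the package's 1-based inclusive convention.
#'
#' @param pedigree_path CSV with columns animal, sire, dam.
#' @param phenotype_path CSV with the [phenotype_table] columns.
#' @param genes_path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) gene file.
#' @return list with elements `pedigree`, `phenotypes`, `genes`.
#' @export
read_tables <- function(pedigree_path = NULL, phenotype_path = NULL,
                        genes_path = NULL) {
  out <- list()
  if (!is.null(pedigree_path)) {
    pd <- utils::read.csv(pedigree_path, stringsAsFactors = FALSE)
    names(pd) <- tolower(names(pd))
    out$pedigree <- pedigree_table(pd$animal, pd$sire, pd$dam)
  }
  if (!is.null(phenotype_path)) {
    ph <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
    out$phenotypes <- phenotype_table(ph)
  }
  if (!is.null(genes_path)) out$genes <- read_gene_annotation(genes_path)
  out
}

#' Read a gene annotation from GFF3 or BED
#'
#' @param path file path; format sniffed from extension (`.bed` vs
#'   `.gff`/`.gff3`).
#' @return a [gene_annotation] table, 1-based inclusive.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) stop("BED gene file needs at least 4 columns (name in column 4)")
    df <- data.frame(gene_id = bed[[4L]], gene_name = bed[[4L]],
                     chrom = as.character(bed[[1L]]),
                     start = bed[[2L]] + 1L,   # 0-based half-open -> 1-based inclusive
                     end = bed[[3L]],
                     strand = if (ncol(bed) >= 6L) bed[[6L]] else "+",
                     stringsAsFactors = FALSE)
    return(gene_annotation(df))
  }
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9L && x[3L] == "gene", logical(1))
  f <- f[keep]
  if (!length(f)) stop("no gene features found in GFF3 file ", path)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))[[1L]]
    if (length(m) >= 3L) m[3L] else NA_character_
  }
  df <- do.call(rbind, lapply(f, function(x) {
    gid <- attr_get(x[9L], "ID")
    if (is.na(gid)) gid <- attr_get(x[9L], "gene_id")
    gname <- attr_get(x[9L], "Name")
    data.frame(gene_id = sub("^gene:", "", gid),
               gene_name = if (is.na(gname)) sub("^gene:", "", gid) else gname,
               chrom = x[1L], start = as.numeric(x[4L]), end = as.numeric(x[5L]),
               strand = x[7L], stringsAsFactors = FALSE)
  }))
  gene_annotation(df)
}

#' Write a gene annotation as GFF3
#' @param genes a [gene_annotation] table.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat("##gff-version 3\n", file = con)
  for (i in seq_len(nrow(genes))) {
    cat(paste(genes$chrom[i], "wgwas", "gene",
              format(genes$start[i], scientific = FALSE),
              format(genes$end[i], scientific = FALSE), ".", genes$strand[i], ".",
              paste0("ID=", genes$gene_id[i], ";Name=", genes$gene_name[i]),
              sep = "\t"), "\n", file = con, sep = "")
  }
  invisible(NULL)
}

#' Read / write a tissue expression matrix (TSV, genes x samples)
#'
#' @param path TSV with gene ids in the first column, sample ids as header.
#' @param tissue tissue label attached to the matrix.
#' @return an [expression_matrix].
#' @export
read_expression <- function(path, tissue = "tissue") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  expression_matrix(mat, tissue)
}

#' @rdname read_expression
#' @param expr an [expression_matrix] to write.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$mat), expr$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; numeric columns rendered at 6 significant
#' digits; `NA` written as the literal `NA`. Column order is preserved as
#' given (the pipeline's documented orders: gwas.tsv = marker_id, chrom, bp,
#' maf, beta, se, p, q, gvar_pct; genes.tsv; eqtl.tsv; ld.tsv; coloc.tsv).
#'
#' @param table a data.frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !all(df[[j]] == round(df[[j]]), na.rm = TRUE)) {
      df[[j]] <- format_num(df[[j]])
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}

#' Read back a TSV written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
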