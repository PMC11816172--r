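#' De-regress breeding values (VanRaden deregression)
#'
#' Removes the parent-average contribution and undoes BLUP shrinkage so the
#' result is suitable as a single-value GWAS response:
#' `PA = (EBV_s + EBV_d)/2`, `REL_PA = (REL_s + REL_d)/4` (a missing parent
#' contributes EBV 0, REL 0), daughter equivalents `DE = k REL/(1-REL)` with
#' `k = (1-h2)/h2`, `R_i = (DE_i - DE_PA)/DE_i`, and
#' `DEBV_i = PA + (EBV_i - PA)/R_i`. Animals with `R_i <= 0` (or undefined,
#' i.e. `DE_i = 0`) are flagged `excluded` and dropped from the GWAS stage.
#' The DEBV reliability is `(DE_i - DE_PA)/(DE_i - DE_PA + k)` by default,
#' or simply `REL_i` with `rel_debv_method = "rel_i"`.
#'
#' @param bv a [solve_mme_blup()] result (columns animal, ebv, rel).
#' @param pedigree a [pedigree_table] linking animals to parents.
#' @param h2 trait heritability in (0, 1).
#' @param rel_debv_method `"de_based"` (default) or `"rel_i"`.
#' @return `bv` with added columns `pa`, `rel_pa`, `de_i`, `de_pa`, `r_i`,
#'   `debv`, `rel_debv`, `excluded`.
#' @export
deregress <- function(bv, pedigree, h2, rel_debv_method = c("de_based", "rel_i")) {
  rel_debv_method <- match.arg(rel_debv_method)
  stopifnot(h2 > 0, h2 < 1)
  if (any(bv$rel >= 1)) stop("REL = 1 implies infinite daughter equivalents")
  k <- (1 - h2) / h2
  idx <- stats::setNames(seq_len(nrow(bv)), bv$animal)
  ped <- as.data.frame(pedigree)
  si <- idx[ped$sire[match(bv$animal, ped$animal)]]
  di <- idx[ped$dam[match(bv$animal, ped$animal)]]
  ebv_s <- ifelse(is.na(si), 0, bv$ebv[si])
  ebv_d <- ifelse(is.na(di), 0, bv$ebv[di])
  rel_s <- ifelse(is.na(si), 0, bv$rel[si])
  rel_d <- ifelse(is.na(di), 0, bv$rel[di])

  bv$pa <- (ebv_s + ebv_d) / 2
  bv$rel_pa <- (rel_s + rel_d) / 4
  bv$de_i <- k * bv$rel / (1 - bv$rel)
  bv$de_pa <- k * bv$rel_pa / (1 - bv$rel_pa)
  bv$r_i <- ifelse(bv$de_i > 0, (bv$de_i - bv$de_pa) / bv$de_i, NA_real_)
  bv$debv <- ifelse(!is.na(bv$r_i) & bv$r_i > 0,
                    bv$pa + (bv$ebv - bv$pa) / bv$r_i, NA_real_)
  bv$rel_debv <- if (rel_debv_method == "rel_i") bv$rel else {
    de_net <- bv$de_i - bv$de_pa
    ifelse(de_net > 0, de_net / (de_net + k), 0)
  }
  bv$excluded <- is.na(bv$r_i) | bv$r_i <= 0
  attr(bv, "h2") <- h2
  attr(bv, "k") <- k
  bv
}

#' Residual weights for the weighted GWAS
#'
#' Reliability-based weights entering the diagonal residual covariance of
#' the association model. Unscaled daughter equivalents
#' `DE_DEBV = Rel_DEBV/(1-Rel_DEBV)` and `DE_PA = Rel_PA/(1-Rel_PA)` give
#' `Rel_Animal = (DE_DEBV - DE_PA)/(DE_DEBV - DE_PA + 1)` and
#' `weight = (1-h2) / (c + (1-Rel_Animal)/Rel_Animal * h2)`, where `c` is
#' the fraction of genetic variance not captured by the markers. Animals
#' with `Rel_Animal <= 0` are flagged `excluded` (count reported via a
#' message).
#'
#' @param bv a [deregress()] result.
#' @param h2 trait heritability.
#' @param c proportion of genetic variance not explained by markers
#'   (default 0.1, under which the DEBVs have high reliability).
#' @return `bv` with added columns `de_debv_u`, `de_pa_u`, `rel_animal`,
#'   `weight`; `excluded` updated.
#' @export
compute_weights <- function(bv, h2, c = 0.1) {
  stopifnot(h2 > 0, h2 < 1, c >= 0)
  if (any(bv$rel_debv >= 1, na.rm = TRUE)) stop("Rel_DEBV = 1 is not allowed")
  if (any(bv$rel_pa >= 1, na.rm = TRUE)) stop("Rel_PA = 1 is not allowed")
  bv$de_debv_u <- bv$rel_debv / (1 - bv$rel_debv)
  bv$de_pa_u <- bv$rel_pa / (1 - bv$rel_pa)
  de_net <- bv$de_debv_u - bv$de_pa_u
  bv$rel_animal <- de_net / (de_net + 1)
  usable <- !is.na(bv$rel_animal) & bv$rel_animal > 0 & !bv$excluded
  bv$weight <- ifelse(usable,
                      (1 - h2) / (c + (1 - bv$rel_animal) / bv$rel_animal * h2),
                      NA_real_)
  n_drop <- sum(!is.na(bv$rel_animal) & bv$rel_animal <= 0 & !bv$excluded)
  if (n_drop > 0) {
    message(n_drop, " animal(s) with Rel_Animal <= 0 excluded from the GWAS")
  }
  bv$excluded <- bv$excluded | is.na(bv$weight) | bv$weight <= 0
  attr(bv, "c") <- c
  bv
}
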