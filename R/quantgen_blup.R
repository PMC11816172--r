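#' BLUP breeding values with reliabilities from Henderson's MME
#'
#' Solves the mixed-model equations of the repeatability animal model at the
#' (converged) REML variance components, with variance ratios
#' `lambda_a = sigma_e2/sigma_a2` and `lambda_p = sigma_e2/sigma_p2`.
#' Additive effects are fitted for every pedigree animal (animals without
#' records receive EBVs through A); permanent-environment effects only for
#' recorded animals. Reliability comes from the prediction error variance:
#' `REL_i = 1 - PEV_i / sigma_a2` with `PEV_i` from the additive block of
#' the inverse coefficient matrix times `sigma_e2`.
#'
#' @param phenotypes a [phenotype_table].
#' @param A relationship matrix over all pedigree animals ([build_A()]).
#' @param vc converged [reml_repeatability()] fit.
#' @param trait trait column name.
#' @return data.frame of class `breeding_value_set` with columns `animal`,
#'   `ebv`, `rel`, `n_records`; attributes `trait` and `vc`.
#' @export
solve_mme_blup <- function(phenotypes, A, vc, trait) {
  if (!inherits(vc, "variance_components") || !isTRUE(vc$converged)) {
    stop("vc must be a converged variance_components fit")
  }
  df <- as.data.frame(phenotypes)
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  y <- df[[trait]]
  n <- length(y)
  all_ids <- rownames(A)
  if (length(missing <- setdiff(unique(df$animal), all_ids))) {
    stop("recorded animals missing from A: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  rec_ids <- sort(unique(df$animal))
  qa <- length(all_ids); qp <- length(rec_ids)
  ia <- match(df$animal, all_ids)           # record -> column of a
  ip <- match(df$animal, rec_ids)           # record -> column of p
  X <- build_fixed_design(df)
  p <- ncol(X)

  la <- vc$sigma_e2 / vc$sigma_a2
  lp <- vc$sigma_e2 / vc$sigma_p2
  Ainv <- chol2inv(chol(unclass(A)))

  cnt_a <- tabulate(ia, qa)
  cnt_p <- tabulate(ip, qp)
  XtZa <- t(rowsum_pad(X, ia, qa))          # p x qa
  XtZp <- t(rowsum_pad(X, ip, qp))
  Zaty <- rowsum_pad(y, ia, qa)[, 1L]
  Zpty <- rowsum_pad(y, ip, qp)[, 1L]

  Caa <- Ainv * la
  diag(Caa) <- diag(Caa) + cnt_a
  Zap <- matrix(0, qa, qp)                  # Za'Zp: counts where same animal
  Zap[cbind(match(rec_ids, all_ids), seq_len(qp))] <- cnt_p
  Cpp <- diag(cnt_p + lp, qp)

  Cmat <- rbind(
    cbind(crossprod(X), XtZa, XtZp),
    cbind(t(XtZa), Caa, Zap),
    cbind(t(XtZp), t(Zap), Cpp))
  rhs <- c(crossprod(X, y)[, 1L], Zaty, Zpty)
  Cinv <- chol2inv(chol(Cmat))
  sol <- (Cinv %*% rhs)[, 1L]
  a_idx <- p + seq_len(qa)
  ebv <- sol[a_idx]
  pev <- diag(Cinv)[a_idx] * vc$sigma_e2
  rel <- pmin(pmax(1 - pev / vc$sigma_a2, 0), 1)
  out <- data.frame(animal = all_ids, ebv = ebv, rel = rel,
                    n_records = cnt_a, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "vc") <- vc
  class(out) <- c("breeding_value_set", "data.frame")
  out
}

# rowsum over groups 1..q returning a q-row matrix (zero rows for absent groups)
rowsum_pad <- function(x, g, q) {
  x <- as.matrix(x)
  out <- matrix(0, q, ncol(x))
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}
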