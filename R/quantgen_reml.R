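# Fixed-effects design shared by REML and BLUP: intercept, year-season and
# parity factors (reference level dropped), age and interval covariates
# (an animal's first record has no interval; imputed at the mean).
build_fixed_design <- function(df) {
  n <- nrow(df)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (fac in c("year_season", "parity")) {
    if (!fac %in% names(df)) next
    f <- factor(df[[fac]])
    if (nlevels(f) >= 2L) {
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(fac, levels(f)[-1L])
      X <- cbind(X, mm)
    }
  }
  if ("age_months" %in% names(df)) X <- cbind(X, age_months = df$age_months)
  if ("interval_days" %in% names(df)) {
    iv <- df$interval_days
    iv[is.na(iv)] <- mean(iv, na.rm = TRUE)
    if (all(is.nan(iv))) iv <- rep(0, n)
    X <- cbind(X, interval_days = iv)
  }
  # constant covariates carry no information beyond the intercept
  const <- c(FALSE, apply(X[, -1L, drop = FALSE], 2L, stats::var) < 1e-12)
  X <- X[, !const, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fixed-effects design is singular; confounded columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

# Z'w for an incidence of records onto q animal levels (ai in 1..q)
cross_z <- function(w, ai, q) {
  out <- numeric(q)
  rs <- rowsum(w, ai)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' AI-REML variance components for the repeatability animal model
#'
#' Fits `y = Xf + Z a + W p + e` with `a ~ N(0, A sigma_a^2)` (pedigree
#' relationship matrix), `p ~ N(0, I sigma_p^2)` (permanent environment, one
#' level per animal, W = Z) and `e ~ N(0, I sigma_e^2)`, by restricted
#' maximum likelihood with average-information updates. The record-level
#' covariance `V = Z K Z' + I sigma_e^2` (K = A sigma_a^2 + I sigma_p^2 over
#' recorded animals) is handled through the Woodbury identity, so every
#' heavy operation is at the animal dimension. AI steps are halved when they
#' leave the parameter space or decrease the likelihood, with an EM-REML
#' fallback; components are bounded below at `1e-8` times the phenotypic
#' variance. Convergence at `|delta logL| < tol`.
#'
#' @param phenotypes a [phenotype_table] (fixed effects: year_season, parity;
#'   covariates: age_months, interval_days).
#' @param A relationship matrix from [build_A()] covering all recorded animals.
#' @param trait name of the trait column.
#' @param start optional starting values `c(sigma_a2, sigma_p2, sigma_e2)`.
#' @param max_iter,tol iteration control.
#' @return object of class `variance_components`: the three components, h2,
#'   repeatability, approximate standard errors (inverse AI), restricted
#'   log-likelihood, convergence flag and iteration trajectory.
#' @export
reml_repeatability <- function(phenotypes, A, trait, start = NULL,
                               max_iter = 100L, tol = 1e-8) {
  df <- as.data.frame(phenotypes)
  if (!trait %in% names(df)) stop("trait column '", trait, "' not found")
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  y <- df[[trait]]
  n <- length(y)
  animals <- sort(unique(df$animal))
  missing_ped <- setdiff(animals, rownames(A))
  if (length(missing_ped)) {
    stop("recorded animals absent from relationship matrix: ",
         paste(utils::head(missing_ped, 5L), collapse = ", "))
  }
  q <- length(animals)
  ai <- match(df$animal, animals)
  A_rr <- unclass(A)[animals, animals, drop = FALSE]
  X <- build_fixed_design(df)
  p <- ncol(X)

  # data summaries fixed across iterations
  D <- tabulate(ai, q)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1L]
  ZtX <- rowsum(X, ai)                       # q x p (all animals have records)
  XZ <- t(ZtX)                               # p x q
  Zty <- cross_z(y, ai, q)

  vy <- stats::var(y)
  lb <- 1e-8 * vy
  theta <- if (is.null(start)) c(0.3, 0.1, 0.6) * vy else as.numeric(start)
  theta <- pmax(theta, lb)

  eval_state <- function(theta) {
    sa <- theta[1L]; sp <- theta[2L]; se <- theta[3L]
    K <- sa * A_rr; diag(K) <- diag(K) + sp
    Kc <- chol(K)
    Kinv <- chol2inv(Kc)
    M <- se * Kinv; diag(M) <- diag(M) + D
    Mc <- chol(M)
    C <- chol2inv(Mc)
    logdetV <- n * log(se) + 2 * sum(log(diag(Kc))) + 2 * sum(log(diag(Mc))) -
      q * log(se)
    CZty <- C %*% Zty
    XTy <- (Xty - XZ %*% CZty)[, 1L] / se
    XZC <- XZ %*% C                          # p x q
    Sxx <- (XtX - XZC %*% t(XZ)) / se
    Sxx_c <- chol(Sxx)
    Sxx_inv <- chol2inv(Sxx_c)
    beta <- Sxx_inv %*% XTy
    Ty <- (y - (CZty[, 1L])[ai]) / se
    Xb <- (X %*% beta)[, 1L]
    ZtXb <- (ZtX %*% beta)[, 1L]
    TXb <- (Xb - (C %*% ZtXb)[, 1L][ai]) / se
    v <- Ty - TXb                            # v = P y
    yPy <- sum(y * v)
    logL <- -0.5 * (logdetV + 2 * sum(log(diag(Sxx_c))) + yPy)
    list(sa = sa, sp = sp, se = se, C = C, Sxx_inv = Sxx_inv, v = v,
         logL = logL, XZC = XZC)
  }

  derivs <- function(st) {
    se <- st$se; C <- st$C; v <- st$v
    zv <- cross_z(v, ai, q)
    Azv <- (A_rr %*% zv)[, 1L]
    qf <- c(sum(zv * Azv), sum(zv^2), sum(v^2))
    S_zz <- (diag(D, q) - C * outer(D, D)) / se
    tr_T <- c(sum(A_rr * S_zz), sum(diag(S_zz)), (n - sum(diag(C) * D)) / se)
    S_xz <- (XZ - st$XZC %*% diag(D, q)) / se
    XZC2 <- st$XZC
    XT2X <- (XtX - 2 * XZC2 %*% t(XZ) + (XZC2 %*% diag(D, q)) %*% t(XZC2)) / se^2
    tr_P <- c(tr_T[1L] - sum(st$Sxx_inv * (S_xz %*% A_rr %*% t(S_xz))),
              tr_T[2L] - sum(st$Sxx_inv * tcrossprod(S_xz)),
              tr_T[3L] - sum(st$Sxx_inv * XT2X))
    score <- -0.5 * (tr_P - qf)
    # AI matrix: 0.5 * (Vdot_i P y)' P (Vdot_j P y)
    W <- cbind(Azv[ai], zv[ai], v)
    PW <- apply(W, 2L, function(w) {
      zw <- cross_z(w, ai, q)
      Czw <- (C %*% zw)[, 1L]
      Tw <- (w - Czw[ai]) / se
      XTw <- (crossprod(X, w)[, 1L] - (st$XZC %*% zw)[, 1L]) / se
      b <- (st$Sxx_inv %*% XTw)[, 1L]
      ZtXb <- (ZtX %*% b)[, 1L]
      Tw - ((X %*% b)[, 1L] - (C %*% ZtXb)[, 1L][ai]) / se
    })
    AI <- 0.5 * crossprod(W, PW)
    AI <- (AI + t(AI)) / 2
    list(score = score, AI = AI, tr_P = tr_P, qf = qf)
  }

  st <- eval_state(theta)
  traj <- data.frame(iter = 0L, sigma_a2 = theta[1L], sigma_p2 = theta[2L],
                     sigma_e2 = theta[3L], logL = st$logL)
  converged <- FALSE
  dv <- NULL
  for (it in seq_len(max_iter)) {
    dv <- derivs(st)
    em_step <- theta + theta^2 * (dv$qf - dv$tr_P) / c(q, q, n)
    delta <- tryCatch(solve(dv$AI, dv$score), error = function(e) NULL)
    cand <- NULL
    if (!is.null(delta)) {
      h <- 1
      for (halv in 0:10) {
        trial <- theta + h * delta
        if (all(trial >= lb)) { cand <- trial; break }
        h <- h / 2
      }
    }
    if (is.null(cand)) cand <- pmax(em_step, lb)
    st_new <- tryCatch(eval_state(cand), error = function(e) NULL)
    # fall back to EM if the AI proposal failed or lowered the likelihood
    if (is.null(st_new) || st_new$logL < st$logL - 1e-10) {
      cand2 <- pmax(em_step, lb)
      st2 <- tryCatch(eval_state(cand2), error = function(e) NULL)
      if (!is.null(st2) && (is.null(st_new) || st2$logL > st_new$logL)) {
        cand <- cand2; st_new <- st2
      }
    }
    if (is.null(st_new)) break
    d_logL <- st_new$logL - st$logL
    theta <- cand; st <- st_new
    traj <- rbind(traj, data.frame(iter = it, sigma_a2 = theta[1L],
                                   sigma_p2 = theta[2L], sigma_e2 = theta[3L],
                                   logL = st$logL))
    if (abs(d_logL) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("wgwas_reml_nonconvergence", "error", "condition"),
      list(message = paste0("AI-REML did not converge in ", max_iter,
                            " iterations for trait '", trait, "'"),
           call = sys.call(-1L), trajectory = traj))
    stop(cond)
  }
  dv <- derivs(st)
  AI_inv <- tryCatch(solve(dv$AI), error = function(e) matrix(NA_real_, 3, 3))
  tot <- sum(theta)
  h2 <- theta[1L] / tot
  re <- (theta[1L] + theta[2L]) / tot
  g_h2 <- c(tot - theta[1L], -theta[1L], -theta[1L]) / tot^2
  g_re <- c(theta[3L], theta[3L], -(theta[1L] + theta[2L])) / tot^2
  structure(list(
    sigma_a2 = theta[1L], sigma_p2 = theta[2L], sigma_e2 = theta[3L],
    h2 = h2, re = re,
    se = sqrt(pmax(diag(AI_inv), 0)),
    h2_se = sqrt(max(0, drop(t(g_h2) %*% AI_inv %*% g_h2))),
    re_se = sqrt(max(0, drop(t(g_re) %*% AI_inv %*% g_re))),
    loglik = st$logL, converged = TRUE, n_iter = max(traj$iter),
    trajectory = traj, trait = trait, animals = animals,
    n_records = n, n_animals = q), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Repeatability-model variance components (", x$trait, ")\n", sep = "")
  cat(sprintf("  sigma_a2 = %.4g (SE %.3g)\n", x$sigma_a2, x$se[1L]))
  cat(sprintf("  sigma_p2 = %.4g (SE %.3g)\n", x$sigma_p2, x$se[2L]))
  cat(sprintf("  sigma_e2 = %.4g (SE %.3g)\n", x$sigma_e2, x$se[3L]))
  cat(sprintf("  h2 = %.3f (SE %.3f)   repeatability = %.3f (SE %.3f)\n",
              x$h2, x$h2_se, x$re, x$re_se))
  cat(sprintf("  logL = %.4f after %d iterations (%d animals, %d records)\n",
              x$loglik, x$n_iter, x$n_animals, x$n_records))
  invisible(x)
}
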