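fake_vc <- function(sa, sp, se) {
  structure(list(sigma_a2 = sa, sigma_p2 = sp, sigma_e2 = se,
                 h2 = sa / (sa + sp + se), re = (sa + sp) / (sa + sp + se),
                 converged = TRUE), class = "variance_components")
}

test_that("tabular A matrix reproduces textbook relationships", {
  A <- build_A(pedigree_table(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d")))
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["d", "o"], 0.5)
  expect_equal(A["o", "o"], 1)
  # full sibs
  A <- build_A(pedigree_table(c("s", "d", "a", "b"),
                              c(NA, NA, "s", "s"), c(NA, NA, "d", "d")))
  expect_equal(A["a", "b"], 0.5)
  # offspring of a parent-offspring mating is inbred with diagonal 1.25
  A <- build_A(pedigree_table(c("s", "d", "o", "x"),
                              c(NA, NA, "s", "s"), c(NA, NA, "d", "o")))
  expect_equal(A["x", "x"], 1.25)
})

test_that("A equals the inheritance-vector enumeration oracle on all pedigrees up to 4 animals", {
  # enumerate every (sire, dam) assignment with parents preceding offspring
  for (n in 2:4) {
    choices <- lapply(seq_len(n), function(i) {
      expand.grid(s = 0:(i - 1L), d = 0:(i - 1L))
    })
    grid <- do.call(expand.grid, lapply(choices, function(ch) seq_len(nrow(ch))))
    for (r in seq_len(nrow(grid))) {
      sire <- integer(n); dam <- integer(n)
      for (i in seq_len(n)) {
        sire[i] <- choices[[i]]$s[grid[r, i]]
        dam[i] <- choices[[i]]$d[grid[r, i]]
      }
      ids <- paste0("p", seq_len(n))
      ped <- pedigree_table(ids, c(NA, ids)[sire + 1L], c(NA, ids)[dam + 1L])
      A <- unclass(build_A(ped))[ids, ids]
      expect_equal(A, oracle_A_enum(sire, dam), ignore_attr = TRUE,
                   tolerance = 1e-12,
                   label = sprintf("pedigree n=%d sire=%s dam=%s", n,
                                   paste(sire, collapse = ","),
                                   paste(dam, collapse = ",")))
    }
  }
})

test_that("A equals the enumeration oracle on random pedigrees of 5-8 animals", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    rp <- random_pedigree_idx(n, max_links = 12L)
    ids <- paste0("p", seq_len(n))
    ped <- pedigree_table(ids, c(NA, ids)[rp$sire + 1L], c(NA, ids)[rp$dam + 1L])
    A <- unclass(build_A(ped))[ids, ids]
    expect_equal(A, oracle_A_enum(rp$sire, rp$dam), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

sim_small_records <- function(seed, n_animals = 10, k = 2, sa = 4, sp = 2, se = 6) {
  set.seed(seed)
  ids <- paste0("an", seq_len(n_animals))
  ped <- pedigree_table(ids, NA, NA)
  a <- rnorm(n_animals, sd = sqrt(sa))
  p <- rnorm(n_animals, sd = sqrt(sp))
  df <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
    data.frame(animal = ids[i], date = as.Date("2023-01-01") + seq_len(k) * 7,
               year_season = rep(c("s1", "s2"), length.out = k),
               parity = "P1", age_months = 10 + runif(k, 0, 3),
               interval_days = c(NA, rep(7, k - 1)),
               y = 50 + a[i] + p[i] + rnorm(k, sd = sqrt(se)),
               stringsAsFactors = FALSE)
  }))
  list(ped = ped, df = phenotype_table(df))
}

test_that("REML maximum matches a dense grid search on a tiny dataset", {
  sim <- sim_small_records(301)
  A <- build_A(sim$ped)
  vc <- reml_repeatability(sim$df, A, "y")
  df <- as.data.frame(sim$df)
  animals <- sort(unique(df$animal))
  ai <- match(df$animal, animals)
  X <- cbind(1, as.numeric(df$year_season == "s2"), df$age_months)
  A_rr <- unclass(A)[animals, animals]
  # the fitted maximum dominates a coarse grid of the dense restricted likelihood
  vy <- var(df$y)
  grid <- expand.grid(sa = vy * seq(0.05, 0.95, by = 0.15),
                      sp = vy * seq(0.05, 0.95, by = 0.15),
                      se = vy * seq(0.05, 0.95, by = 0.15))
  ll_grid <- apply(grid, 1, function(th)
    dense_reml_ll(df$y, X, ai, A_rr, th[1], th[2], th[3]))
  ll_fit <- dense_reml_ll(df$y, X, ai, A_rr, vc$sigma_a2, vc$sigma_p2, vc$sigma_e2)
  expect_gte(ll_fit, max(ll_grid) - 1e-6)
  # and agrees with the internal likelihood value
  expect_equal(ll_fit, vc$loglik, tolerance = 1e-6)
})

test_that("REML is invariant to record order and to adding a constant", {
  sim <- sim_small_records(302, n_animals = 15, k = 3)
  A <- build_A(sim$ped)
  vc1 <- reml_repeatability(sim$df, A, "y")
  df2 <- as.data.frame(sim$df)
  df2 <- df2[sample(nrow(df2)), ]
  vc2 <- reml_repeatability(df2, A, "y")
  expect_equal(vc2$sigma_a2, vc1$sigma_a2, tolerance = 1e-5)
  expect_equal(vc2$sigma_e2, vc1$sigma_e2, tolerance = 1e-5)
  df3 <- as.data.frame(sim$df); df3$y <- df3$y + 100
  vc3 <- reml_repeatability(df3, A, "y")
  expect_equal(vc3$sigma_a2, vc1$sigma_a2, tolerance = 1e-5)
  expect_equal(vc3$h2, vc1$h2, tolerance = 1e-5)
})

test_that("REML finds essentially zero heritability when none was simulated", {
  # family structure is needed so sigma_a2 is identified (and estimated ~ 0)
  cfg <- sim_config(seed = 55, n_founders = 100, n_generations = 2, n_markers = 50,
                    n_chromosomes = 1, mean_records_per_animal = 5,
                    traits = list(y = trait_spec(50, 8, 0, 0.2, "continuous")))
  pop <- simulate_population(cfg)
  rec <- simulate_records(pop$pedigree, pop$truth, cfg)
  vc <- reml_repeatability(rec, build_A(pop$pedigree), "y")
  expect_lt(vc$h2, 0.05)
})

test_that("a singular fixed-effects design is rejected with the confounded columns named", {
  sim <- sim_small_records(303)
  df <- as.data.frame(sim$df)
  df$parity <- df$year_season   # perfectly confounded factors
  expect_error(reml_repeatability(df, build_A(sim$ped), "y"),
               "confounded|singular")
})

test_that("BLUP equals the dense V-inverse oracle, including reliabilities", {
  # 5 animals: 2 founder parents, 2 offspring with records, 1 unrecorded sib
  ped <- pedigree_table(c("s", "d", "o1", "o2", "o3"),
                        c(NA, NA, "s", "s", "s"), c(NA, NA, "d", "d", "d"))
  A <- build_A(ped)
  set.seed(99)
  df <- data.frame(animal = rep(c("s", "d", "o1", "o2"), each = 3),
                   date = as.Date("2023-01-01") + rep(1:3, 4) * 5,
                   year_season = "q1", parity = "P1",
                   age_months = 10, y = rnorm(12, 50, 3),
                   stringsAsFactors = FALSE)
  sa <- 4; sp <- 2; se <- 6
  bv <- solve_mme_blup(df, A, fake_vc(sa, sp, se), "y")
  # dense oracle: a_hat = sa * A[, rec] Z' P y over records
  rec_ids <- c("s", "d", "o1", "o2")
  ai <- match(df$animal, rec_ids)
  n <- nrow(df)
  Z <- matrix(0, n, 4); Z[cbind(seq_len(n), ai)] <- 1
  Afull <- unclass(A)
  V <- Z %*% ((sa * Afull[rec_ids, rec_ids]) + sp * diag(4)) %*% t(Z) + se * diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  CovAy <- sa * Afull[, rec_ids] %*% t(Z)
  a_hat <- CovAy %*% P %*% df$y
  pev <- sa * Afull - CovAy %*% P %*% t(CovAy)
  expect_equal(bv$ebv, unname(a_hat[bv$animal, 1]), tolerance = 1e-8)
  expect_equal(bv$rel, unname(1 - diag(pev)[bv$animal] / sa), tolerance = 1e-8)
  # the unrecorded full sib gets the parent-average EBV
  expect_equal(bv$ebv[bv$animal == "o3"],
               mean(bv$ebv[bv$animal %in% c("s", "d")]), tolerance = 1e-8)
})

test_that("EBVs shrink to zero and reliabilities vanish as sigma_a2 -> 0", {
  sim <- sim_small_records(304)
  A <- build_A(sim$ped)
  bv <- solve_mme_blup(sim$df, A, fake_vc(1e-7, 2, 6), "y")
  expect_lt(max(abs(bv$ebv)), 1e-3)
  expect_lt(max(bv$rel), 1e-3)
})

test_that("reliability strictly increases with an animal's record count", {
  rels <- sapply(c(1, 2, 4, 8), function(k) {
    others <- do.call(rbind, lapply(1:5, function(a)
      data.frame(animal = paste0("ref", a),
                 date = as.Date("2023-01-01") + 1:2 * 7,
                 year_season = "q1", parity = "P1", age_months = 10,
                 y = c(48, 52), stringsAsFactors = FALSE)))
    target <- data.frame(animal = "tgt", date = as.Date("2023-01-01") + seq_len(k) * 7,
                         year_season = "q1", parity = "P1", age_months = 10,
                         y = 50 + seq_len(k) %% 2, stringsAsFactors = FALSE)
    df <- rbind(others, target)
    ped <- pedigree_table(unique(df$animal), NA, NA)
    bv <- solve_mme_blup(df, build_A(ped), fake_vc(4, 2, 6), "y")
    bv$rel[bv$animal == "tgt"]
  })
  expect_true(all(diff(rels) > 0))
})

test_that("deregression reproduces the hand-derived case exactly", {
  ped <- pedigree_table(c("s", "d", "i"), c(NA, NA, "s"), c(NA, NA, "d"))
  bv <- data.frame(animal = c("s", "d", "i"), ebv = c(1.0, 0.6, 2.0),
                   rel = c(0.4, 0.4, 0.5), n_records = 5,
                   stringsAsFactors = FALSE)
  dr <- deregress(bv, ped, h2 = 0.25)
  i <- dr[dr$animal == "i", ]
  expect_equal(i$pa, 0.8)
  expect_equal(i$rel_pa, 0.2)
  expect_equal(i$de_i, 3)          # k = 3, 3 * 0.5 / 0.5
  expect_equal(i$de_pa, 0.75)      # 3 * 0.2 / 0.8
  expect_equal(i$r_i, 0.75)
  expect_equal(i$debv, 2.4)
})

test_that("deregression with unknown parents is the identity on EBVs", {
  ped <- pedigree_table(c("a", "b"), NA, NA)
  bv <- data.frame(animal = c("a", "b"), ebv = c(1.3, -0.7),
                   rel = c(0.6, 0.3), n_records = 5, stringsAsFactors = FALSE)
  dr <- deregress(bv, ped, h2 = 0.3)
  expect_equal(dr$rel_pa, c(0, 0))
  expect_equal(dr$de_pa, c(0, 0))
  expect_equal(dr$r_i, c(1, 1))
  expect_equal(dr$debv, dr$ebv)
  expect_error(deregress(transform(bv, rel = c(1, 0.3)), ped, 0.3), "REL")
})

test_that("DEBV minus PA keeps the sign of EBV minus PA whenever R_i > 0", {
  set.seed(41)
  ids <- c("s1", "d1", paste0("o", 1:10))
  ped <- pedigree_table(ids, c(NA, NA, rep("s1", 10)), c(NA, NA, rep("d1", 10)))
  bv <- data.frame(animal = ids, ebv = rnorm(12), rel = runif(12, 0.2, 0.8),
                   n_records = 5, stringsAsFactors = FALSE)
  dr <- deregress(bv, ped, h2 = 0.3)
  ok <- !dr$excluded
  expect_true(all(sign(dr$debv[ok] - dr$pa[ok]) == sign(dr$ebv[ok] - dr$pa[ok]) |
                    dr$ebv[ok] == dr$pa[ok]))
})

test_that("weights obey the closed form, its limits, and monotonicity", {
  mk <- function(rel_debv, rel_pa = 0) {
    data.frame(animal = "x", ebv = 1, rel = 0.5, n_records = 5, pa = 0,
               rel_pa = rel_pa, de_i = 1, de_pa = 0, r_i = 1, debv = 1,
               rel_debv = rel_debv, excluded = FALSE, stringsAsFactors = FALSE)
  }
  # Rel_Animal -> 1: weight -> (1 - h2)/c = 7 at h2 = 0.3, c = 0.1
  w1 <- compute_weights(mk(1 - 1e-9), h2 = 0.3, c = 0.1)
  expect_equal(w1$weight, 7, tolerance = 1e-6)
  # Rel_Animal -> 0: weight -> 0
  w0 <- compute_weights(mk(1e-9), h2 = 0.3, c = 0.1)
  expect_lt(w0$weight, 1e-6)
  # direct evaluation at Rel_Animal = 0.5 (rel_pa = 0 makes rel_animal = rel_debv)
  wm <- compute_weights(mk(0.5), h2 = 0.25, c = 0.1)
  expect_equal(wm$rel_animal, 0.5)
  expect_equal(wm$weight, 0.75 / (0.1 + 0.25), tolerance = 1e-12)
  # monotone in Rel_Animal for fixed h2, c
  rels <- seq(0.05, 0.95, by = 0.05)
  ws <- sapply(rels, function(r) compute_weights(mk(r), h2 = 0.3, c = 0.1)$weight)
  expect_true(all(diff(ws) > 0))
})
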