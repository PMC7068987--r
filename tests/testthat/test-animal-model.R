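test_that("heritability recomputes from reported variance components", {
  expect_equal(round(heritability_from_components(69807.7, 71990.1, 0.06), 2), 0.46)
  expect_equal(round(heritability_from_components(11.2, 30.5, 0.10), 2), 0.24)
  expect_equal(heritability_from_components(0, 30, 0.1), 0)
  expect_error(heritability_from_components(1, 1, 1), "c2")
  expect_error(heritability_from_components(-1, 1, 0), "non-negative")
})

# direct dense REML log-likelihood, written independently of the engine
reml_ll_direct <- function(theta, y, X, Bmats) {
  V <- Reduce(`+`, Map(`*`, theta, Bmats))
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
            drop(t(y) %*% P %*% y))
}

test_that("litter-free REML agrees with direct likelihood maximisation on small data", {
  set.seed(11)
  ped <- random_pedigree(12, p_known = 0.8)
  extra <- tibble::tibble(
    animal = sprintf("y%02d", 1:28),
    sire = sample(ped$animal, 28, replace = TRUE),
    dam = NA_character_
  )
  ped2 <- dplyr::bind_rows(ped, extra)
  A <- build_A(ped2)
  ids <- ped2$animal
  bv <- drop(t(chol(A + diag(1e-8, nrow(A)))) %*% rnorm(nrow(A))) * sqrt(2)
  pheno <- tibble::tibble(
    animal = ids,
    y = 10 + bv + rnorm(length(ids), 0, sqrt(3))
  )
  fit <- fit_univariate(pheno, A, "y", fixed = character(0),
                        covariate = NULL, litter = NULL)
  y <- pheno$y
  X <- matrix(1, length(y), 1)
  Bmats <- list(A[ids, ids], diag(length(y)))
  opt <- optim(c(1, 1), function(th) -reml_ll_direct(th, y, X, Bmats),
               method = "L-BFGS-B", lower = c(1e-6, 1e-6))
  expect_equal(unname(fit$components$estimate[fit$components$term == "animal"]),
               opt$par[1], tolerance = 1e-3)
  expect_equal(unname(fit$components$estimate[fit$components$term == "residual"]),
               opt$par[2], tolerance = 1e-3)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("a pure-noise phenotype yields near-zero heritability", {
  set.seed(22)
  cfg <- sim_config(label = "null", n_sires = 15, n_dams = 60, litter_size = 4,
                    generations = 2, n_markers = 300, n_chrom = 3,
                    traits = list(y = trait_config(0, 1e-4, 1e-4, 100)),
                    n_qtl = 1, qtl_shares = 1e-6, n_background = 50, seed = 12)
  st <- simulate_study(cfg)
  A <- build_A(st$ped)
  fit <- fit_univariate(st$pheno, A, "y")
  expect_lt(fit$h2, 2 * fit$h2_se + 0.02)
})

test_that("variance estimates are scale-equivariant and ratios internally consistent", {
  cfg <- sim_preset("demo", seed = 41)
  st <- simulate_study(cfg)
  A <- build_A(st$ped)
  fit1 <- fit_univariate(st$pheno, A, "va")
  ph2 <- dplyr::mutate(st$pheno, va = 10 * va)
  fit2 <- fit_univariate(ph2, A, "va")
  th1 <- setNames(fit1$components$estimate, fit1$components$term)
  th2 <- setNames(fit2$components$estimate, fit2$components$term)
  expect_equal(th2, 100 * th1, tolerance = 1e-3)
  expect_equal(fit1$h2, unname(th1["animal"] / sum(th1)), tolerance = 1e-12)
  expect_equal(fit1$c2, unname(th1["litter"] / sum(th1)), tolerance = 1e-12)
  expect_equal(fit2$h2, fit1$h2, tolerance = 1e-4)
})

test_that("REML recovers simulated heritability and litter effects on average", {
  h2_hat <- c2_hat <- h2_true <- c2_true <- numeric(12)
  for (r in seq_len(12)) {
    cfg <- sim_config(label = "rec", n_sires = 15, n_dams = 60, litter_size = 4,
                      generations = 2, n_markers = 400, n_chrom = 4,
                      traits = list(va = trait_config(1000, 69807.7, 9051, 71990.1)),
                      n_qtl = 3, qtl_shares = c(0.05, 0.05, 0.07),
                      n_background = 120, seed = 100 + r)
    st <- simulate_study(cfg)
    A <- build_A(st$ped)
    fit <- fit_univariate(st$pheno, A, "va")
    h2_hat[r] <- fit$h2; c2_hat[r] <- fit$c2
    h2_true[r] <- st$truth$realized$h2_realized
    c2_true[r] <- st$truth$realized$c2_realized
  }
  expect_lt(abs(mean(h2_hat - h2_true)), 2 * sd(h2_hat - h2_true) / sqrt(12))
  expect_lt(abs(mean(c2_hat - c2_true)), 2 * sd(c2_hat - c2_true) / sqrt(12) + 0.01)
})

test_that("bivariate REML recovers genetic correlations", {
  # strongly correlated pair
  cfg <- sim_config(label = "biv", n_sires = 15, n_dams = 60, litter_size = 4,
                    generations = 2, n_markers = 400, n_chrom = 4,
                    traits = list(
                      vh = trait_config(36, 27.1, 2, 20.1),
                      vw = trait_config(27, 10.8, 1.5, 22.6)
                    ),
                    cor_g = 0.9, cor_e = 0.5,
                    n_qtl = 2, qtl_shares = c(0.1, 0.1), n_background = 120,
                    seed = 77)
  st <- simulate_study(cfg)
  A <- build_A(st$ped)
  fit <- suppressWarnings(fit_bivariate(st$pheno, A, c("vh", "vw")))
  true_rg <- cor(st$truth$bv$vh, st$truth$bv$vw)
  expect_lt(abs(fit$r_g - true_rg), 0.25)
  expect_gt(fit$r_g, 0.4)
  expect_true(abs(fit$r_p) <= 1 && abs(fit$r_g) <= 1)
  g <- glance(fit)
  expect_true(g$converged)

  # an effectively duplicated trait pins both correlations near 1
  ph <- st$pheno
  set.seed(123)
  ph$vh2 <- ph$vh + rnorm(nrow(ph), 0, 2)
  fit_dup <- suppressWarnings(fit_bivariate(ph, A, c("vh", "vh2")))
  expect_gt(fit_dup$r_g, 0.9)
  expect_gt(fit_dup$r_p, 0.9)

  expect_error(fit_bivariate(dplyr::mutate(ph, cst = 1), A, c("vh", "cst")),
               "constant")
})

test_that("null genetic correlation is recovered within uncertainty", {
  cfg <- sim_config(label = "biv0", n_sires = 15, n_dams = 60, litter_size = 4,
                    generations = 2, n_markers = 400, n_chrom = 4,
                    traits = list(
                      t1 = trait_config(0, 30, 3, 30),
                      t2 = trait_config(0, 30, 3, 30)
                    ),
                    cor_g = 0, cor_e = 0,
                    n_qtl = 2, qtl_shares = c(0.02, 0.02), n_background = 150,
                    seed = 88)
  st <- simulate_study(cfg)
  A <- build_A(st$ped)
  fit <- suppressWarnings(fit_bivariate(st$pheno, A, c("t1", "t2")))
  expect_lt(abs(fit$r_g), 2 * fit$r_g_se + 0.1)
})
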