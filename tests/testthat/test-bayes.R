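# small shared fixture: QC'd genotypes + phenotype with a planted signal
bayes_fixture <- function(seed = 5, n_markers = 300, share = 0.3) {
  cfg <- sim_config(label = "bx", n_sires = 12, n_dams = 50, litter_size = 4,
                    generations = 2, n_markers = n_markers, n_chrom = 3,
                    traits = list(y = trait_config(0, 40, 0, 60)),
                    n_qtl = 1, qtl_shares = share, n_background = 80,
                    seed = seed)
  st <- simulate_study(cfg)
  g <- subset_genotypes(apply_genotype_qc(st$genotypes)$genotypes,
                        animals = st$pheno$animal)
  list(g = g, pheno = st$pheno, truth = st$truth)
}

test_that("pi = 1 keeps every marker out of the model", {
  fx <- bayes_fixture()
  cc <- chain_config("BayesC", pi = 1, n_iter = 200, n_burnin = 50, seed = 1,
                     var_a = 40, var_e = 60)
  fit <- fit_bayes(fx$g, fx$pheno, cc, "y")
  expect_true(all(fit$effects == 0))
  expect_true(all(fit$indicators == 0))
  expect_equal(unname(gebv_from_effects(fit, fx$g)), rep(0, nrow(fx$g$calls)))
})

test_that("identical seed and config give bit-identical retained draws", {
  fx <- bayes_fixture()
  cc <- chain_config("BayesB", pi = 0.95, n_iter = 300, n_burnin = 100,
                     seed = 99, var_a = 40, var_e = 60)
  f1 <- fit_bayes(fx$g, fx$pheno, cc, "y")
  f2 <- fit_bayes(fx$g, fx$pheno, cc, "y")
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$sigma2_e, f2$sigma2_e)
  expect_identical(f1$pi, f2$pi)
})

test_that("inclusion indicators and effects are consistent draw by draw", {
  fx <- bayes_fixture()
  cc <- chain_config("BayesC", pi = 0.9, n_iter = 400, n_burnin = 100, seed = 3,
                     var_a = 40, var_e = 60)
  fit <- fit_bayes(fx$g, fx$pheno, cc, "y")
  expect_true(all((fit$effects == 0) == (fit$indicators == 0)))
  expect_equal(fit$n_draws, 300)
  cc_thin <- chain_config("BayesC", pi = 0.9, n_iter = 400, n_burnin = 100,
                          thin = 3, seed = 3, var_a = 40, var_e = 60)
  expect_equal(fit_bayes(fx$g, fx$pheno, cc_thin, "y")$n_draws, 100)
})

test_that("a marker explaining much genetic variance attains top inclusion", {
  hits <- 0
  for (s in 1:5) {
    fx <- bayes_fixture(seed = 200 + s, share = 0.45)
    cc <- chain_config("BayesC", pi = 0.99, n_iter = 800, n_burnin = 200,
                       seed = s, var_a = 40, var_e = 60)
    fit <- fit_bayes(fx$g, fx$pheno, cc, "y")
    incl <- colMeans(fit$indicators)
    qtl <- fx$truth$qtl_markers[1]
    # accept markers in the QTL's own Mb window as equivalent tags
    w <- assign_windows(fx$g$map)
    top_w <- w$window_id[match(names(which.max(incl)), w$marker)]
    qtl_w <- w$window_id[match(qtl, w$marker)]
    if (identical(top_w, qtl_w)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("BayesCpi tracks the simulated sparsity", {
  # ~99% null markers
  fx <- bayes_fixture(seed = 17, n_markers = 400, share = 0.5)
  cc <- chain_config("BayesCpi", pi = 0.5, n_iter = 1000, n_burnin = 300,
                     seed = 7, var_a = 40, var_e = 60)
  # truth: 1 QTL + 80 background of 400 -> ~80% null; pi-hat should be high
  est <- estimate_pi(fx$g, fx$pheno, cc, "y")
  expect_gt(est$pi, 0.5)
  expect_lt(est$pi, 1)

  # pure noise: posterior pi stays prior-dominated and high
  ph <- fx$pheno
  set.seed(1); ph$y <- rnorm(nrow(ph), 0, 10)
  est0 <- estimate_pi(fx$g, ph, cc, "y")
  expect_gt(est0$pi, 0.5)

  # dense strong signal, n >> m: most markers matter
  cfgd <- sim_config(label = "dense", n_sires = 12, n_dams = 60, litter_size = 5,
                     generations = 2, n_markers = 40, n_chrom = 2,
                     traits = list(y = trait_config(0, 90, 0, 10)),
                     n_qtl = 2, qtl_shares = c(0.05, 0.05), n_background = 38,
                     seed = 23)
  std <- simulate_study(cfgd)
  gd <- subset_genotypes(apply_genotype_qc(std$genotypes)$genotypes,
                         animals = std$pheno$animal)
  ccd <- chain_config("BayesCpi", pi = 0.5, n_iter = 1500, n_burnin = 400,
                      seed = 8, var_a = 90, var_e = 10)
  estd <- estimate_pi(gd, std$pheno, ccd, "y")
  expect_lt(estd$pi, 0.5)
})

test_that("posterior residual variance recovers simulated noise", {
  fx <- bayes_fixture(seed = 31, share = 0.02)
  ph <- fx$pheno
  set.seed(2)
  ph$y <- rnorm(nrow(ph), 0, sqrt(50))
  cc <- chain_config("BayesC", pi = 0.99, n_iter = 1500, n_burnin = 500,
                     seed = 4, var_a = 1, var_e = 25)
  fit <- fit_bayes(fx$g, ph, cc, "y")
  # compare against the realised noise variance of this sample
  target <- var(ph$y)
  expect_lt(abs(mean(fit$sigma2_e) - target) / target, 0.10)
})

test_that("GEBVs are linear in marker subsets and consistent with the chain", {
  fx <- bayes_fixture(seed = 8)
  cc <- chain_config("BayesB", pi = 0.95, n_iter = 400, n_burnin = 100,
                     seed = 21, var_a = 40, var_e = 60)
  fit <- fit_bayes(fx$g, fx$pheno, cc, "y")
  all_m <- fit$markers
  gv_all <- gebv_from_effects(fit, fx$g)
  # posterior-mean GEBV equals the mean over per-draw GEBVs (linearity)
  gd <- giltvs:::gebv_draws(fit, fx$g)
  expect_equal(unname(gv_all), unname(rowMeans(gd)), tolerance = 1e-10)
  set.seed(3)
  s1 <- sample(all_m, 120)
  s2 <- setdiff(all_m, s1)
  gv1 <- gebv_from_effects(fit, fx$g, snp_set = s1, centers = fit$centers)
  gv2 <- gebv_from_effects(fit, fx$g, snp_set = s2, centers = fit$centers)
  expect_equal(gv1 + gv2, gv_all, tolerance = 1e-12)
  expect_error(gebv_from_effects(fit, fx$g, snp_set = character(0)), "empty")
  eff0 <- setNames(rep(0, length(all_m)), all_m)
  expect_equal(unname(gebv_from_effects(eff0, fx$g)), rep(0, nrow(fx$g$calls)))
})

test_that("BayesC0 posterior-mean GEBVs approach the ridge/GBLUP solution", {
  set.seed(1234)
  n <- 60; m <- 200
  p <- runif(m, 0.1, 0.5)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  g <- toy_geno(calls)
  Xc <- scale(calls, center = TRUE, scale = FALSE)
  beta <- rnorm(m, 0, sqrt(4 / m))
  y <- drop(Xc %*% beta) + rnorm(n, 0, 2)
  pheno <- tibble::tibble(animal = rownames(g$calls), y = y)
  var_a <- var(drop(Xc %*% beta)); var_e <- 4
  cc <- chain_config("BayesC0", n_iter = 2500, n_burnin = 500, seed = 6,
                     var_a = var_a, var_e = var_e)
  fit <- fit_bayes(g, pheno, cc, "y", fixed = character(0), covariate = NULL)
  gv <- gebv_from_effects(fit, g)
  # closed-form mixed-model ridge with the same variance ratio
  lambda <- var_e / (var_a / sum(2 * p * (1 - p)))
  alpha_hat <- solve(crossprod(Xc) + diag(lambda, m), crossprod(Xc, y - mean(y)))
  expect_gt(cor(gv, drop(Xc %*% alpha_hat)), 0.98)
})
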