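fold_fixture <- function(n_sires = 20, daughters = 6, seed = 1) {
  sires <- sprintf("s%02d", seq_len(n_sires))
  ped <- tibble::tibble(
    animal = sires, sire = NA_character_, dam = NA_character_
  )
  kids <- tibble::tibble(
    animal = sprintf("k%03d", seq_len(n_sires * daughters)),
    sire = rep(sires, each = daughters),
    dam = NA_character_
  )
  list(ped = dplyr::bind_rows(ped, kids),
       pheno = tibble::tibble(animal = kids$animal))
}

test_that("sire-family folds use every sire and never split a family", {
  fx <- fold_fixture()
  f <- make_folds(fx$pheno, fx$ped, n_folds = 4, sires_per_fold = 5, seed = 3)
  expect_equal(sort(unique(f$fold)), 1:4)
  expect_equal(nrow(f), nrow(fx$pheno))
  per_sire <- tapply(f$fold, f$sire, function(x) length(unique(x)))
  expect_true(all(per_sire == 1))

  f2 <- make_folds(fx$pheno, fx$ped, n_folds = 4, sires_per_fold = 5, seed = 3)
  expect_identical(f$fold, f2$fold)
  f3 <- make_folds(fx$pheno, fx$ped, n_folds = 4, sires_per_fold = 5, seed = 4)
  expect_false(identical(f$fold, f3$fold))

  # random family structures: partition property holds
  set.seed(10)
  for (r in 1:5) {
    ns <- sample(8:14, 1)
    fx2 <- fold_fixture(n_sires = ns, daughters = sample(2:5, 1))
    f <- suppressMessages(make_folds(fx2$pheno, fx2$ped, n_folds = 2,
                                     sires_per_fold = ns %/% 3, seed = r))
    expect_setequal(f$animal, fx2$pheno$animal)
    expect_true(all(tapply(f$fold, f$sire, function(x) length(unique(x))) == 1))
  }

  bad <- fx$pheno
  bad$animal[1] <- "orphan"
  ped2 <- dplyr::bind_rows(fx$ped, tibble::tibble(animal = "orphan",
                                                  sire = NA, dam = NA))
  expect_error(make_folds(bad, ped2, 4, 5, seed = 1), "unknown sire")
  expect_error(make_folds(fx$pheno, fx$ped, n_folds = 10, sires_per_fold = 5),
               "sires")
})

test_that("phenotype adjustment subtracts training fixed-effect solutions", {
  spec <- list(fixed = "line", levels = list(line = c("A", "B")),
               covariate = "bw", center = 100)
  fit <- list(fixed = list(
    coef = c(`(Intercept)` = 10, lineB = 2, bw = 0.5), spec = spec
  ))
  ph <- tibble::tibble(animal = c("x", "y", "z"),
                       line = c("A", "B", "B"),
                       bw = c(100, 102, 98), y = c(20, 25, 15))
  out <- adjust_phenotypes(ph, fit, "y")
  expect_equal(out$y_star, c(20 - 10, 25 - 13, 15 - 11))

  # zero fixed effects leave the phenotype unchanged
  fit0 <- list(fixed = list(coef = c(`(Intercept)` = 0, lineB = 0, bw = 0),
                            spec = spec))
  expect_equal(adjust_phenotypes(ph, fit0, "y")$y_star, ph$y)

  # unseen level is treated as baseline, with a warning
  ph2 <- dplyr::mutate(ph, line = c("A", "C", "B"))
  expect_warning(out2 <- adjust_phenotypes(ph2, fit, "y"), "Unseen")
  expect_equal(out2$y_star[2], 25 - 10 - 0.5 * 2)
})

test_that("GPA formulas follow the definition exactly", {
  expect_equal(gpa_single(c(1, 2, 3, 2), c(4, 4, 4, 4) + c(2, 4, 6, 4) * 0, # r undefined
                          h2 = 0.25), NA_real_) |> suppressWarnings()
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  expect_equal(gpa_single(x, y, h2 = 0.46), 1 / sqrt(0.46))
  set.seed(2)
  a <- rnorm(50); b <- 0.5 * scale(a)[, 1] + sqrt(0.75) * rnorm(50)
  expect_equal(gpa_single(a, b, 0.25), cor(a, b) / 0.5)

  folds <- tibble::tibble(r = c(0.4, 0.2), n = c(100, 50))
  expect_equal(gpa_cv(folds, 0.25)$gpa, (0.4 * 100 + 0.2 * 50) / 150 / 0.5,
               tolerance = 1e-12)
  expect_equal(gpa_cv(folds[2:1, ], 0.25)$gpa, gpa_cv(folds, 0.25)$gpa)
  expect_true(is.na(gpa_cv(folds[1, ], 0.25)$sd))

  # equal folds with equal r reduce to the single-set formula
  eq <- tibble::tibble(r = rep(0.3, 4), n = rep(25, 4))
  expect_equal(gpa_cv(eq, 0.36)$gpa, 0.3 / 0.6)
  expect_error(gpa_cv(tibble::tibble(r = 0.1, n = 2), 0.5), "at least 3")
})

test_that("SNP sets respect QTL boundaries and the exclusion flank", {
  map <- tibble::tibble(
    marker = sprintf("m%03d", 1:200),
    chrom = rep(c(2L, 9L), each = 100),
    pos = as.integer(rep(seq(5e5, by = 2e6, length.out = 100), 2))
  )
  regions <- tibble::tibble(chrom = 2L, start_mb = 154, end_mb = 157)
  sets <- build_snp_sets(regions, map, flank_mb = 3)
  lab <- sets$label
  expect_setequal(lab, c("ALL", "per-QTL:2:154-157", "QTL", "REST"))
  get <- function(l) sets$markers[[which(lab == l)]]
  inside <- map$marker[map$chrom == 2 & map$pos >= 154e6 & map$pos < 157e6]
  expect_setequal(get("per-QTL:2:154-157"), inside)
  expect_setequal(get("QTL"), inside)
  # REST excludes 151-160 Mb on chrom 2
  excluded <- map$marker[map$chrom == 2 & map$pos >= 151e6 & map$pos < 160e6]
  expect_length(intersect(get("REST"), excluded), 0)
  flank_only <- setdiff(excluded, inside)
  expect_setequal(c(get("QTL"), get("REST"), flank_only), get("ALL"))

  sets0 <- build_snp_sets(NULL, map)
  expect_setequal(sets0$markers[[which(sets0$label == "QTL")]], character(0))
  expect_setequal(sets0$markers[[which(sets0$label == "REST")]], map$marker)
  expect_warning(
    build_snp_sets(tibble::tibble(chrom = 2L, start_mb = 400, end_mb = 401), map),
    "no markers"
  )
})

test_that("prediction strategies produce coherent GPA tables", {
  # one small breed pair with a shared genome layout
  mk <- function(lab, seed) {
    cfg <- sim_config(label = lab, n_sires = 12, n_dams = 40, litter_size = 4,
                      generations = 2, n_markers = 300, n_chrom = 3,
                      traits = list(y = trait_config(0, 50, 5, 45)),
                      n_qtl = 1, qtl_shares = 0.4, n_background = 60,
                      seed = seed)
    st <- simulate_study(cfg)
    g <- subset_genotypes(apply_genotype_qc(st$genotypes)$genotypes,
                          animals = st$pheno$animal)
    list(genotypes = g, pheno = st$pheno, h2 = 0.5, ped = st$ped,
         truth = st$truth)
  }
  b1 <- mk("brA", 301); b2 <- mk("brB", 302)
  breed_data <- list(brA = b1[1:3], brB = b2[1:3])
  folds <- list(
    brA = make_folds(b1$pheno, b1$ped, n_folds = 3, sires_per_fold = 4, seed = 1),
    brB = make_folds(b2$pheno, b2$ped, n_folds = 3, sires_per_fold = 4, seed = 2)
  )
  cc <- chain_config("BayesB", pi = 0.99, n_iter = 600, n_burnin = 150,
                     seed = 5, var_a = 50, var_e = 50)

  wn <- run_strategy("within", breed_data["brA"], folds["brA"], cc, "y")
  expect_equal(wn$strategy, "within")
  expect_equal(nrow(wn$folds[[1]]), 3)
  expect_equal(wn$gpa,
               weighted.mean(wn$folds[[1]]$r, wn$folds[[1]]$n) / sqrt(0.5))

  bw <- run_strategy("between", breed_data, NULL, cc, "y")
  expect_equal(sort(bw$validation_breed), c("brA", "brB"))
  expect_true(all(is.na(bw$sd)))

  ml <- run_strategy("multi", breed_data, folds, cc, "y")
  expect_equal(sum(vapply(ml$folds, nrow, integer(1))), 6) # 3 + 3 folds
  expect_setequal(ml$validation_breed, c("brA", "brB"))
})

test_that("subset GEBVs feeding GPA sum exactly to the full-set GEBV", {
  cfg <- sim_config(label = "parts", n_sires = 10, n_dams = 30, litter_size = 4,
                    generations = 2, n_markers = 240, n_chrom = 3,
                    traits = list(y = trait_config(0, 50, 5, 45)),
                    n_qtl = 1, qtl_shares = 0.4, n_background = 50, seed = 9)
  st <- simulate_study(cfg)
  g <- subset_genotypes(apply_genotype_qc(st$genotypes)$genotypes,
                        animals = st$pheno$animal)
  cc <- chain_config("BayesB", pi = 0.98, n_iter = 500, n_burnin = 100,
                     seed = 2, var_a = 50, var_e = 45)
  fit <- fit_bayes(g, st$pheno, cc, "y")
  res <- window_results(fit, g)
  regions <- call_qtl(res, tgvm_min = 5)
  sets <- build_snp_sets(regions, g$map, flank_mb = 3)
  lab <- sets$label
  get <- function(l) intersect(sets$markers[[which(lab == l)]], fit$markers)
  flank_only <- setdiff(get("ALL"), c(get("QTL"), get("REST")))
  gv <- function(snp) {
    if (!length(snp)) return(rep(0, nrow(g$calls)))
    unname(gebv_from_effects(fit, g, snp_set = snp, centers = fit$centers))
  }
  expect_equal(gv(get("QTL")) + gv(get("REST")) + gv(flank_only),
               gv(get("ALL")), tolerance = 1e-12)
})
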