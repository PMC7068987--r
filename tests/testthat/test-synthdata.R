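test_that("pedigree simulation honours the mating design and is reproducible", {
  cfg <- sim_config(label = "p", n_sires = 5, n_dams = 20, generations = 1,
                    litter_size = 4, n_markers = 10, seed = 2)
  ped <- simulate_pedigree(cfg)
  off <- ped[ped$generation == 1, ]
  expect_equal(nrow(off), 80)
  expect_false(anyNA(off$sire))
  expect_false(anyNA(off$dam))
  expect_equal(length(unique(off$litter)), 20)
  expect_true(all(table(off$litter) == 4))

  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped, ped2)

  cfg3 <- sim_config(label = "p", n_sires = 8, n_dams = 25, generations = 3,
                     litter_size = 4, n_markers = 10, seed = 6)
  ped3 <- simulate_pedigree(cfg3)
  sorted <- sort_pedigree(ped3)       # errors on cycles/unknown parents
  expect_equal(nrow(sorted), nrow(ped3))
  idx <- match(ped3$animal, ped3$animal)
  pos <- setNames(seq_len(nrow(ped3)), ped3$animal)
  nonf <- !is.na(ped3$sire)
  expect_true(all(pos[ped3$sire[nonf]] < pos[ped3$animal[nonf]]))
})

test_that("gene-dropped genotypes show the expected familial and LD structure", {
  cfg <- sim_config(label = "g", n_sires = 30, n_dams = 90, generations = 1,
                    litter_size = 4, n_markers = 400, n_chrom = 2,
                    ld_rho = 0, maf_range = c(0.1, 0.5), seed = 4)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_equal(nrow(g$calls), nrow(ped))
  expect_true(all(g$calls %in% 0:2))

  # founder allele frequencies span the configured spectrum
  founders <- ped$animal[is.na(ped$sire)]
  p <- colMeans(g$calls[founders, ]) / 2
  expect_gt(mean(p > 0.05 & p < 0.95), 0.95)

  # with ld_rho = 0 adjacent founder markers are nearly uncorrelated
  cors <- sapply(seq_len(150), function(j) {
    suppressWarnings(cor(g$calls[founders, j], g$calls[founders, j + 1]))
  })
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.06)

  # full sibs share more alleles than unrelated pairs
  off <- ped[ped$generation == 1, ]
  fam <- split(off$animal, off$litter)
  sib_share <- mean(sapply(fam[1:30], function(a) {
    mean(2 - abs(g$calls[a[1], ] - g$calls[a[2], ]))
  }))
  unrel <- sapply(1:30, function(i) {
    a <- sample(founders, 2)
    mean(2 - abs(g$calls[a[1], ] - g$calls[a[2], ]))
  })
  expect_gt(sib_share, mean(unrel) + 0.05)

  # block LD appears when requested
  cfg_ld <- sim_config(label = "g", n_sires = 30, n_dams = 90, generations = 1,
                       litter_size = 4, n_markers = 400, n_chrom = 2,
                       ld_rho = 0.8, block_markers = 8,
                       maf_range = c(0.1, 0.5), seed = 4)
  g_ld <- simulate_genotypes(simulate_pedigree(cfg_ld), cfg_ld)
  cors_ld <- sapply(seq_len(150), function(j) {
    suppressWarnings(cor(g_ld$calls[founders, j], g_ld$calls[founders, j + 1]))
  })
  expect_gt(mean(cors_ld, na.rm = TRUE), 0.2)
})

test_that("phenotypes realise the configured variance structure", {
  # noise-only: phenotypic variance ~ residual variance
  cfg <- sim_config(label = "n", n_sires = 15, n_dams = 80, generations = 2,
                    litter_size = 5, n_markers = 200, n_chrom = 2,
                    traits = list(y = trait_config(0, 1e-6, 1e-6, 100)),
                    n_qtl = 1, qtl_shares = 0.5, n_background = 30, seed = 5)
  st <- simulate_study(cfg)
  expect_lt(abs(var(st$pheno$y - ave(st$pheno$y, st$pheno$line,
                                     st$pheno$cg)) / 100 - 1), 0.25)

  # realised components recompute from stored effects
  cfg2 <- sim_preset("yorkshire-like", n_markers = 500, seed = 8)
  st2 <- simulate_study(cfg2)
  r <- st2$truth$realized
  expect_equal(r$h2_realized,
               r$var_bv / (r$var_bv + r$var_litter + r$var_resid),
               tolerance = 1e-12)
  expect_lt(abs(r$h2_realized - 0.46), 0.12)
  expect_lt(abs(r$c2_realized - 0.06), 0.06)
  bv <- st2$truth$bv$va
  expect_equal(length(bv), nrow(st2$pheno))

  # window shares reconcile with the QTL table
  ws <- st2$truth$window_shares
  expect_equal(sum(ws$share), 1, tolerance = 1e-9)

  # determinism under a fixed seed
  st2b <- simulate_study(cfg2)
  expect_identical(st2$pheno, st2b$pheno)
  expect_identical(st2$genotypes$calls, st2b$genotypes$calls)
})

test_that("configured genetic correlations shape the simulated breeding values", {
  cfg <- sim_config(label = "c", n_sires = 20, n_dams = 100, generations = 2,
                    litter_size = 5, n_markers = 400, n_chrom = 3,
                    traits = list(
                      vh = trait_config(36, 27, 2, 20),
                      vw = trait_config(27, 11, 1.5, 22)
                    ),
                    cor_g = 0.9, cor_e = 0.5, n_qtl = 2,
                    qtl_shares = c(0.1, 0.1), n_background = 150,
                    derive_va = TRUE, seed = 19)
  st <- simulate_study(cfg)
  expect_true("va" %in% names(st$pheno))
  expect_equal(st$pheno$va, st$pheno$vh * st$pheno$vw)
  rg <- cor(st$truth$bv$vh, st$truth$bv$vw)
  expect_lt(abs(rg - 0.9), 0.12)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(qtl_shares = c(0.9, 0.9), n_qtl = 2), "sum")
  expect_error(sim_config(n_qtl = 2, qtl_shares = 0.1), "n_qtl")
  expect_error(sim_config(cor_g = 1.5), "Correlations")
  cfg <- sim_config(n_sires = 50, n_dams = 5, generations = 2, litter_size = 1)
  expect_error(simulate_pedigree(cfg), "too few")
})
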