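#' Trait settings for the simulator
#'
#' @param mean Trait mean in its measurement units.
#' @param var_a Additive genetic variance.
#' @param var_d Litter common-environment variance.
#' @param var_e Residual variance.
#' @return A list used inside [sim_config()].
#' @export
trait_config <- function(mean, var_a, var_d, var_e) {
  stopifnot(var_a >= 0, var_d >= 0, var_e > 0)
  list(mean = mean, var_a = var_a, var_d = var_d, var_e = var_e)
}

#' Simulation configuration for one breeding population
#'
#' Describes a closed purebred population with discrete generations: founder
#' sires and dams, random sire-dam matings producing litters, and a final
#' generation of phenotyped gilts. The genome has evenly spaced SNPs on
#' `n_chrom` autosomes; founder haplotypes draw each marker's allele through
#' a Gaussian copula so markers within a block of `block_markers` share a
#' latent ancestral variable with correlation `ld_rho` (block-level LD);
#' descendants are gene-dropped with 1 cM/Mb recombination. Genetic
#' architecture: `n_qtl` sparse QTL with fixed per-QTL shares of `var_a`
#' (scaled against the phenotyped cohort's realised dosage variances, so
#' planted shares are accurate), the remainder spread as a marker-based
#' polygenic background over `n_background` random SNPs
#' (`polygenic = "marker"`) or bred down the pedigree as a latent term with
#' parent-average plus Mendelian sampling (`polygenic = "pedigree"`).
#' Multi-trait effects share QTL (pleiotropy) and the polygenic correlation
#' is chosen so the total genetic correlation approximates `cor_g`.
#'
#' @param label Breed label.
#' @param n_sires,n_dams Founders (and parents sampled per generation).
#' @param generations Number of offspring generations; the last one is the
#'   all-female phenotyped cohort.
#' @param litter_size Gilts per litter (one litter per dam per generation).
#' @param n_chrom,chrom_length_mb,n_markers Genome layout.
#' @param maf_range Founder minor-allele-frequency range (uniform spectrum).
#' @param ld_rho,block_markers Founder LD block structure.
#' @param traits Named list of [trait_config()]s.
#' @param cor_g,cor_e Target genetic and residual correlations between
#'   traits (scalar, applied to all pairs).
#' @param n_qtl,qtl_shares,n_background,polygenic Genetic architecture (see
#'   above); `sum(qtl_shares) <= 1`.
#' @param n_lines,n_cg Numbers of line and contemporary-group levels.
#' @param line_sd_frac,cg_sd_frac Fixed-effect SDs as fractions of the
#'   phenotypic SD.
#' @param bw_mean,bw_sd,bw_beta_frac Body-weight covariate distribution
#'   (kg) and its regression slope as a fraction of phenotypic SD per
#'   covariate SD.
#' @param derive_va When traits `vh` and `vw` are simulated, add the
#'   product trait `va = vh * vw`.
#' @param seed Integer seed; all `simulate_*` calls derive their streams
#'   from it.
#' @return A `vs_sim_config` list.
#' @export
sim_config <- function(label = "demo",
                       n_sires = 25, n_dams = 120, generations = 3,
                       litter_size = 5,
                       n_chrom = 5, chrom_length_mb = 100, n_markers = 2000,
                       maf_range = c(0.05, 0.5), ld_rho = 0.7,
                       block_markers = 10,
                       traits = list(va = trait_config(1000, 69807.7, 9051, 71990.1)),
                       cor_g = 0.9, cor_e = 0.6,
                       n_qtl = 3, qtl_shares = rep(0.05, n_qtl),
                       n_background = 200,
                       polygenic = c("marker", "pedigree"),
                       n_lines = 2, n_cg = 5,
                       line_sd_frac = 0.25, cg_sd_frac = 0.25,
                       bw_mean = 120, bw_sd = 12, bw_beta_frac = 0.15,
                       derive_va = FALSE, seed = 1) {
  polygenic <- match.arg(polygenic)
  stopifnot(n_sires >= 1, n_dams >= 1, generations >= 1, litter_size >= 1)
  if (length(qtl_shares) != n_qtl) abort("`qtl_shares` must have `n_qtl` entries.")
  if (sum(qtl_shares) > 1 + 1e-12) abort("QTL shares of var_a must sum to <= 1.")
  if (abs(cor_g) > 1 || abs(cor_e) > 1) abort("Correlations must lie in [-1, 1].")
  if (n_markers < 1) abort("Need at least one marker.")
  structure(list(
    label = label, n_sires = n_sires, n_dams = n_dams,
    generations = generations, litter_size = litter_size,
    n_chrom = n_chrom, chrom_length_mb = chrom_length_mb,
    n_markers = n_markers, maf_range = maf_range, ld_rho = ld_rho,
    block_markers = block_markers, traits = traits,
    cor_g = cor_g, cor_e = cor_e,
    n_qtl = n_qtl, qtl_shares = qtl_shares, n_background = n_background,
    polygenic = polygenic, n_lines = n_lines, n_cg = n_cg,
    line_sd_frac = line_sd_frac, cg_sd_frac = cg_sd_frac,
    bw_mean = bw_mean, bw_sd = bw_sd, bw_beta_frac = bw_beta_frac,
    derive_va = derive_va, seed = seed
  ), class = "vs_sim_config")
}

#' Breed presets mirroring the study populations
#'
#' `"yorkshire-like"` (n ~ 700 gilts, VA variances 69,807.7 / 71,990.1 and
#' c2 = 0.06, few moderate QTL) and `"landrace-like"` (n ~ 475, VA
#' variances 21,953.3 / 89,166.2, c2 = 0.17, larger-effect QTL), both at
#' desk scale (2,000 markers on 5 chromosomes); `"demo"` is a small
#' smoke-test population.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_config()].
#' @return A `vs_sim_config`.
#' @export
sim_preset <- function(name = c("yorkshire-like", "landrace-like", "demo"),
                       ...) {
  name <- match.arg(name)
  args <- switch(
    name,
    "yorkshire-like" = list(
      label = "yorkshire", n_sires = 30, n_dams = 140, litter_size = 5,
      traits = list(va = trait_config(984.5, 69807.7, 9051.0, 71990.1)),
      n_qtl = 3, qtl_shares = c(0.05, 0.05, 0.07)
    ),
    "landrace-like" = list(
      label = "landrace", n_sires = 25, n_dams = 95, litter_size = 5,
      traits = list(va = trait_config(1014.7, 21953.3, 22758.3, 89166.2)),
      n_qtl = 4, qtl_shares = c(0.13, 0.14, 0.11, 0.05)
    ),
    "demo" = list(
      label = "demo", n_sires = 12, n_dams = 40, litter_size = 4,
      generations = 2, n_markers = 600, n_chrom = 3,
      traits = list(va = trait_config(1000, 60000, 9000, 70000)),
      n_qtl = 2, qtl_shares = c(0.15, 0.1), n_background = 100
    )
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# deterministic per-stage seed streams below 2^31 (double arithmetic to
# dodge 32-bit integer overflow)
stage_seed <- function(cfg, stage) {
  (as.numeric(cfg$seed) * 1009 + stage * 9973) %% 2147483647
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations; each generation samples `n_sires` sires and
#' `n_dams` dams from the previous one (founders for the first), mates each
#' dam to one randomly chosen sire, and records one litter of
#' `litter_size` offspring per dam. Intermediate generations have random
#' sexes; the final generation is the all-female phenotyped cohort.
#'
#' @param cfg A [sim_config()].
#' @return A tibble `animal`, `sire`, `dam`, `generation`, `sex`,
#'   `litter` (birth-litter ID, `NA` for founders), sorted parents-first.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "vs_sim_config"))
  set.seed(stage_seed(cfg, 1L))
  id <- function(prefix, i) sprintf("%s_%s%04d", cfg$label, prefix, i)
  founders_s <- id("S", seq_len(cfg$n_sires))
  founders_d <- id("D", seq_len(cfg$n_dams))
  ped <- tibble::tibble(
    animal = c(founders_s, founders_d),
    sire = NA_character_, dam = NA_character_,
    generation = 0L,
    sex = c(rep("M", cfg$n_sires), rep("F", cfg$n_dams)),
    litter = NA_character_
  )
  counter <- 0L
  for (g in seq_len(cfg$generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (length(males) < cfg$n_sires || length(females) < cfg$n_dams) {
      abort(sprintf(
        "Generation %d has too few candidate parents (%d males, %d females).",
        g - 1L, length(males), length(females)))
    }
    sires <- sample(males, cfg$n_sires)
    dams <- sample(females, cfg$n_dams)
    rows <- list()
    for (d in seq_along(dams)) {
      s <- sample(sires, 1)
      lit <- sprintf("%s_L%d_%03d", cfg$label, g, d)
      n_off <- cfg$litter_size
      counter_new <- counter + n_off
      offspring <- id("A", (counter + 1L):counter_new)
      counter <- counter_new
      sex <- if (g == cfg$generations) {
        rep("F", n_off)
      } else {
        sample(c("M", "F"), n_off, replace = TRUE)
      }
      rows[[d]] <- tibble::tibble(
        animal = offspring, sire = s, dam = dams[d],
        generation = g, sex = sex, litter = lit
      )
    }
    ped <- dplyr::bind_rows(ped, rows)
  }
  ped
}

#' Simulate SNP genotypes down a pedigree
#'
#' Founder haplotypes are drawn with a uniform MAF spectrum and block-level
#' LD (Gaussian copula, see [sim_config()]); non-founders are gene-dropped
#' with recombination probability `0.01 * gap_Mb` between adjacent markers
#' (1 cM/Mb).
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param cfg The same [sim_config()].
#' @return A [genotype_data()] covering every pedigree animal.
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "vs_sim_config"))
  set.seed(stage_seed(cfg, 2L))
  m_per_chrom <- rep(cfg$n_markers %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_markers %% cfg$n_chrom
  if (extra > 0) m_per_chrom[seq_len(extra)] <- m_per_chrom[seq_len(extra)] + 1L
  map <- dplyr::bind_rows(lapply(seq_len(cfg$n_chrom), function(cc) {
    mc <- m_per_chrom[cc]
    gap <- cfg$chrom_length_mb * 1e6 / mc
    tibble::tibble(
      marker = sprintf("snp_c%d_%05d", cc, seq_len(mc)),
      chrom = cc,
      pos = as.integer(round(gap / 2 + gap * (seq_len(mc) - 1)))
    )
  }))
  m <- nrow(map)
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(p)

  sp <- ped
  n <- nrow(sp)
  founder <- is.na(sp$sire) & is.na(sp$dam)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  rownames(H1) <- rownames(H2) <- sp$animal

  # founder haplotypes: block-latent Gaussian copula
  block <- ceiling(seq_len(m) / cfg$block_markers)
  # blocks never span chromosomes
  block <- as.integer(factor(paste(map$chrom, block)))
  n_blocks <- max(block)
  fi <- which(founder)
  for (h in 1:2) {
    tlat <- matrix(rnorm(length(fi) * n_blocks), length(fi), n_blocks)
    eps <- matrix(rnorm(length(fi) * m), length(fi), m)
    z <- sqrt(cfg$ld_rho) * tlat[, block, drop = FALSE] +
      sqrt(1 - cfg$ld_rho) * eps
    hap <- t(t(z) < thr) * 1L
    if (h == 1) H1[fi, ] <- hap else H2[fi, ] <- hap
  }

  chrom_idx <- split(seq_len(m), map$chrom)
  recomb <- lapply(chrom_idx, function(ix) {
    d_mb <- diff(map$pos[ix]) / 1e6
    pmin(0.5, 0.01 * d_mb)
  })
  meiosis <- function(h1, h2) {
    gam <- integer(m)
    for (cc in seq_along(chrom_idx)) {
      ix <- chrom_idx[[cc]]
      mc <- length(ix)
      switches <- c(sample(0:1, 1), runif(mc - 1) < recomb[[cc]])
      path <- cumsum(switches) %% 2
      gam[ix] <- ifelse(path == 0, h1[ix], h2[ix])
    }
    gam
  }
  idx <- setNames(seq_len(n), sp$animal)
  for (i in which(!founder)) {
    s <- idx[sp$sire[i]]
    d <- idx[sp$dam[i]]
    H1[i, ] <- meiosis(H1[s, ], H2[s, ])
    H2[i, ] <- meiosis(H1[d, ], H2[d, ])
  }
  calls <- H1 + H2
  storage.mode(calls) <- "double"
  colnames(calls) <- map$marker
  genotype_data(calls, map, NULL)
}

#' Simulate phenotypes with full ground truth
#'
#' Builds breeding values from the configured QTL architecture (plus the
#' marker or pedigree polygenic remainder), adds litter common-environment
#' effects shared within birth litter, line and contemporary-group fixed
#' effects, a body-weight covariate and residual noise:
#' `y = mu + line + cg + beta * BW + bv + litter + e`. Only the final
#' generation (the gilt cohort) is phenotyped. Multi-trait effects are
#' drawn with the configured genetic correlation; with `derive_va = TRUE`
#' and simulated `vh`/`vw`, the product trait `va` is added.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param g Genotypes from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A list with `pheno` (phenotype tibble for the cohort) and
#'   `truth` (true breeding values, litter effects, QTL table with marker
#'   IDs and per-trait effects, realised variance components/h2/c2, and
#'   realised per-window genetic-variance shares of the marker-based
#'   genetic part).
#' @export
simulate_phenotypes <- function(ped, g, cfg) {
  stopifnot(inherits(cfg, "vs_sim_config"), inherits(g, "vs_geno"))
  set.seed(stage_seed(cfg, 3L))
  traits <- names(cfg$traits)
  nt <- length(traits)
  cohort <- ped[ped$generation == max(ped$generation), ]
  nC <- nrow(cohort)
  M <- g$calls[cohort$animal, , drop = FALSE]

  w_qtl <- sum(cfg$qtl_shares)
  # QTL markers: prefer distinct 1-Mb windows and informative frequencies
  pcol <- colMeans(M) / 2
  wmap <- assign_windows(g$map)
  informative <- wmap$marker[pmin(pcol, 1 - pcol)[wmap$marker] >= 0.1]
  if (length(informative) < cfg$n_qtl) informative <- wmap$marker
  cand <- wmap[wmap$marker %in% informative, ]
  qtl_markers <- character(0)
  pool <- cand
  for (k in seq_len(cfg$n_qtl)) {
    pick <- pool[sample(nrow(pool), 1), ]
    qtl_markers <- c(qtl_markers, pick$marker)
    pool <- pool[pool$window_id != pick$window_id, ]
    if (!nrow(pool)) pool <- cand
  }
  # background polygenic markers (marker-based remainder)
  bg_markers <- character(0)
  if (cfg$polygenic == "marker" && w_qtl < 1) {
    bg_pool <- setdiff(colnames(M), qtl_markers)
    bg_markers <- sample(bg_pool, min(cfg$n_background, length(bg_pool)))
  }

  # correlation structure: QTL effects share signs across traits, so the
  # polygenic correlation is set to hit the total target cor_g
  R_g <- matrix(cfg$cor_g, nt, nt); diag(R_g) <- 1
  poly_share <- 1 - w_qtl
  rho_poly <- if (poly_share > 1e-8) {
    max(-1, min(1, (cfg$cor_g - w_qtl) / poly_share))
  } else {
    0
  }
  R_poly <- matrix(rho_poly, nt, nt); diag(R_poly) <- 1
  L_poly <- chol_psd(R_poly)

  bv <- matrix(0, nC, nt, dimnames = list(cohort$animal, traits))
  qtl_tab <- list()
  signs <- sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
  for (t in seq_len(nt)) {
    va_t <- cfg$traits[[t]]$var_a
    for (k in seq_len(cfg$n_qtl)) {
      x <- M[, qtl_markers[k]]
      vx <- var(x)
      a <- if (vx > 0) signs[k] * sqrt(cfg$qtl_shares[k] * va_t / vx) else 0
      bv[, t] <- bv[, t] + (x - mean(x)) * a
      qtl_tab[[length(qtl_tab) + 1]] <- tibble::tibble(
        marker = qtl_markers[k], trait = traits[t],
        effect = a, share = cfg$qtl_shares[k]
      )
    }
  }

  bg_tab <- list()
  if (length(bg_markers)) {
    z <- matrix(rnorm(length(bg_markers) * nt), length(bg_markers), nt) %*% L_poly
    Xb <- M[, bg_markers, drop = FALSE]
    vb <- apply(Xb, 2, var)
    ok <- vb > 0
    for (t in seq_len(nt)) {
      va_t <- cfg$traits[[t]]$var_a
      share_each <- poly_share / sum(ok)
      a <- numeric(length(bg_markers))
      # unit-variance correlated z keeps the cross-trait correlation at
      # rho_poly and the expected per-marker variance share at share_each
      a[ok] <- z[ok, t] * sqrt(share_each * va_t / vb[ok])
      bv[, t] <- bv[, t] + scale(Xb, center = TRUE, scale = FALSE) %*% a
      bg_tab[[length(bg_tab) + 1]] <- tibble::tibble(
        marker = bg_markers, trait = traits[t], effect = a,
        share = share_each
      )
    }
  } else if (poly_share > 1e-8) {
    # latent polygenic term bred down the pedigree
    fped <- inbreeding(ped)
    fvec <- setNames(fped$f, fped$animal)
    poly <- matrix(0, nrow(ped), nt, dimnames = list(ped$animal, traits))
    sd_t <- sqrt(vapply(cfg$traits, function(tc) tc$var_a, numeric(1)) * poly_share)
    founder <- is.na(ped$sire) & is.na(ped$dam)
    zf <- matrix(rnorm(sum(founder) * nt), sum(founder), nt) %*% L_poly
    poly[founder, ] <- sweep(zf, 2, sd_t, `*`)
    for (i in which(!founder)) {
      fbar <- mean(c(fvec[ped$sire[i]], fvec[ped$dam[i]]))
      ms_sd <- sd_t * sqrt(0.5 * (1 - fbar))
      zi <- drop(rnorm(nt) %*% L_poly)
      poly[i, ] <- 0.5 * (poly[ped$sire[i], ] + poly[ped$dam[i], ]) + zi * ms_sd
    }
    bv <- bv + poly[cohort$animal, , drop = FALSE]
  }

  # litter effects shared within birth litter, independent across traits
  litters <- unique(cohort$litter)
  lit_eff <- matrix(0, length(litters), nt, dimnames = list(litters, traits))
  for (t in seq_len(nt)) {
    lit_eff[, t] <- rnorm(length(litters), 0, sqrt(cfg$traits[[t]]$var_d))
  }

  # residuals with configured correlation
  R_e <- matrix(cfg$cor_e, nt, nt); diag(R_e) <- 1
  eres <- matrix(rnorm(nC * nt), nC, nt) %*% chol_psd(R_e)
  for (t in seq_len(nt)) eres[, t] <- eres[, t] * sqrt(cfg$traits[[t]]$var_e)

  # fixed structure
  line <- sample(sprintf("L%d", seq_len(cfg$n_lines)), nC, replace = TRUE)
  cg <- sample(sprintf("CG%d", seq_len(cfg$n_cg)), nC, replace = TRUE)
  bw <- rnorm(nC, cfg$bw_mean, cfg$bw_sd)
  pheno <- tibble::tibble(
    animal = cohort$animal, breed = cfg$label,
    line = line, cg = cg, litter = cohort$litter, bw = bw
  )
  for (t in seq_len(nt)) {
    tc <- cfg$traits[[t]]
    sd_p <- sqrt(tc$var_a + tc$var_d + tc$var_e)
    line_eff <- setNames(rnorm(cfg$n_lines, 0, cfg$line_sd_frac * sd_p),
                         sprintf("L%d", seq_len(cfg$n_lines)))
    cg_eff <- setNames(rnorm(cfg$n_cg, 0, cfg$cg_sd_frac * sd_p),
                       sprintf("CG%d", seq_len(cfg$n_cg)))
    beta <- cfg$bw_beta_frac * sd_p / cfg$bw_sd
    pheno[[traits[t]]] <- tc$mean + line_eff[line] + cg_eff[cg] +
      beta * (bw - cfg$bw_mean) + bv[, t] +
      lit_eff[cohort$litter, t] + eres[, t]
  }
  if (cfg$derive_va && all(c("vh", "vw") %in% traits)) {
    pheno <- derive_va(pheno)
  }

  # realised components among the cohort
  realized <- dplyr::bind_rows(lapply(seq_len(nt), function(t) {
    vb <- var(bv[, t])
    vl <- var(lit_eff[cohort$litter, t])
    ve <- var(eres[, t])
    tibble::tibble(
      trait = traits[t], var_bv = vb, var_litter = vl, var_resid = ve,
      h2_realized = vb / (vb + vl + ve),
      c2_realized = vl / (vb + vl + ve)
    )
  }))

  marker_tab <- dplyr::bind_rows(c(qtl_tab, bg_tab))
  window_shares <- NULL
  if (nrow(marker_tab)) {
    wm <- dplyr::left_join(marker_tab, wmap[, c("marker", "window_id")],
                           by = "marker")
    window_shares <- dplyr::bind_rows(lapply(traits, function(tr) {
      mt <- wm[wm$trait == tr, ]
      shares <- vapply(split(mt, mt$window_id), function(d) {
        u <- scale(M[, d$marker, drop = FALSE], center = TRUE, scale = FALSE) %*% d$effect
        var(drop(u))
      }, numeric(1))
      tibble::tibble(trait = tr, window_id = names(shares),
                     genvar = unname(shares),
                     share = unname(shares) / sum(shares))
    }))
  }

  truth <- list(
    bv = tibble::as_tibble(cbind(tibble::tibble(animal = cohort$animal),
                                 as.data.frame(bv))),
    litter_effects = tibble::as_tibble(cbind(tibble::tibble(litter = litters),
                                             as.data.frame(lit_eff))),
    qtl = marker_tab, qtl_markers = qtl_markers,
    realized = realized, window_shares = window_shares
  )
  list(pheno = pheno, truth = truth)
}

chol_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) abort("Correlation matrix is not PSD.")
  t(e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0))))
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()].
#'
#' @param cfg A [sim_config()].
#' @return A list `ped`, `genotypes`, `pheno`, `truth`.
#' @export
simulate_study <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, g, cfg)
  list(ped = ped, genotypes = g, pheno = ph$pheno, truth = ph$truth)
}
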