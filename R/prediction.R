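#' Sire-family cross-validation folds
#'
#' Folds are built from sire families so paternal half-sib groups are never
#' split: sires are shuffled by `seed`, grouped `sires_per_fold` at a time
#' into `n_folds` folds, and every daughter inherits her sire's fold.
#' Leftover sires' daughters are distributed to the currently smallest
#' folds (and logged via a message).
#'
#' @param pheno Phenotype tibble (`animal` column) of the animals to fold.
#' @param pedigree Pedigree data frame giving each animal's sire.
#' @param n_folds Number of folds.
#' @param sires_per_fold Sires grouped per fold (5 in the reference
#'   design).
#' @param seed Integer seed for the sire shuffle.
#' @return A `vs_folds` tibble: `animal`, `sire`, `fold` (integer).
#' @export
make_folds <- function(pheno, pedigree, n_folds, sires_per_fold = 5,
                       seed = 1) {
  pheno <- tibble::as_tibble(pheno)
  ped <- tibble::as_tibble(pedigree)
  sire <- ped$sire[match(pheno$animal, ped$animal)]
  no_sire <- pheno$animal[is.na(sire)]
  if (length(no_sire)) {
    abort(paste0("Animal(s) with unknown sire: ",
                 paste(head(no_sire, 5), collapse = ", ")))
  }
  sires <- unique(sire)
  if (n_folds * sires_per_fold > length(sires)) {
    abort(sprintf("Need %d sires for %d folds of %d; pedigree has %d.",
                  n_folds * sires_per_fold, n_folds, sires_per_fold,
                  length(sires)))
  }
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  shuffled <- withr_seed(sample(sires))
  fold_of_sire <- setNames(rep(NA_integer_, length(sires)), shuffled)
  core <- shuffled[seq_len(n_folds * sires_per_fold)]
  fold_of_sire[core] <- rep(seq_len(n_folds), each = sires_per_fold)
  leftovers <- shuffled[-seq_len(n_folds * sires_per_fold)]
  if (length(leftovers)) {
    inform(sprintf("%d leftover sire(s) assigned to the smallest folds.",
                   length(leftovers)))
    for (s in leftovers) {
      sizes <- vapply(seq_len(n_folds), function(f) {
        assigned <- names(fold_of_sire)[!is.na(fold_of_sire) & fold_of_sire == f]
        sum(sire %in% assigned)
      }, numeric(1))
      fold_of_sire[s] <- which.min(sizes)
    }
  }
  out <- tibble::tibble(
    animal = pheno$animal,
    sire = sire,
    fold = unname(fold_of_sire[sire])
  )
  attr(out, "n_folds") <- n_folds
  attr(out, "sires_per_fold") <- sires_per_fold
  attr(out, "seed") <- seed
  class(out) <- c("vs_folds", class(out))
  out
}

#' Adjust phenotypes for fixed effects
#'
#' `y* = y - (mu + line + CG + beta * BW)` using fixed-effect solutions
#' from a training fit; validation animals' own records never inform their
#' adjustment. Factor levels unseen in training are treated as baseline
#' (effect 0) with a warning.
#'
#' @param pheno Phenotype tibble for the animals to adjust.
#' @param fit A `vs_bayes_fit` (or `vs_varcomp`) carrying fixed-effect
#'   solutions and the training design information.
#' @param trait Trait column.
#' @return The tibble with an added `y_star` column.
#' @export
adjust_phenotypes <- function(pheno, fit, trait) {
  pheno <- tibble::as_tibble(pheno)
  fx <- fit$fixed
  if (is.null(fx)) abort("`fit` carries no fixed-effect solutions.")
  fitted_fx <- fixed_predict(pheno, fx$spec, fx$coef)
  dplyr::mutate(pheno, y_star = .data[[trait]] - fitted_fx)
}

#' Genomic prediction accuracy, single validation set
#'
#' `GPA = cor(GEBV, y*) / sqrt(h2)` with `h2` the trait heritability of the
#' validation breed (the between-breed formula). A GEBV with zero variance
#' makes the correlation undefined; `NA` is returned with a warning. Values
#' above 1 are possible (e.g. perfect correlation with `h2 < 1`).
#'
#' @param gebv,y_star Numeric vectors, matched by position.
#' @param h2 Validation-breed heritability, in (0, 1].
#' @return A single numeric GPA.
#' @export
gpa_single <- function(gebv, y_star, h2) {
  if (h2 <= 0 || h2 > 1) abort("`h2` must lie in (0, 1].")
  if (length(gebv) != length(y_star) || length(gebv) < 3) {
    abort("Need at least 3 matched GEBV/phenotype pairs.")
  }
  if (sd(gebv) == 0 || sd(y_star) == 0) {
    warn("Zero-variance GEBV or adjusted phenotype; GPA undefined.")
    return(NA_real_)
  }
  cor(gebv, y_star) / sqrt(h2)
}

#' Genomic prediction accuracy across cross-validation folds
#'
#' The within-/multi-breed formula: the fold correlations `r_i` are
#' averaged weighted by fold size `n_i`, then scaled,
#' `GPA = (sum n_i r_i / sum n_i) / sqrt(h2)`. The across-fold SD of
#' `r_i / sqrt(h2)` is returned alongside (NA with a single fold).
#'
#' @param fold_stats Tibble/data frame with columns `r` (per-fold
#'   correlation of GEBV with `y*`) and `n` (fold size, all `>= 3`).
#' @param h2 Validation-breed heritability.
#' @return A tibble with `gpa`, `sd`, `n_folds`.
#' @export
gpa_cv <- function(fold_stats, h2) {
  if (h2 <= 0 || h2 > 1) abort("`h2` must lie in (0, 1].")
  fs <- tibble::as_tibble(fold_stats)
  if (any(fs$n < 3)) abort("Every fold needs at least 3 animals.")
  if (any(abs(fs$r) > 1, na.rm = TRUE)) abort("Fold correlations must lie in [-1, 1].")
  gpa <- weighted.mean(fs$r, fs$n) / sqrt(h2)
  sdev <- if (nrow(fs) < 2) NA_real_ else sd(fs$r / sqrt(h2))
  tibble::tibble(gpa = gpa, sd = sdev, n_folds = nrow(fs))
}

#' Marker subsets induced by QTL regions
#'
#' Builds the marker sets used for QTL-subset prediction: one `per-QTL` set
#' per region (markers inside the region), their union (`QTL`), and `REST`
#' — all markers at least `flank_mb` Mb away from every region boundary,
#' excluding flanking markers in partial LD with the QTL. Training always
#' uses all markers; these sets restrict which effects enter the GEBV.
#'
#' @param qtl_regions Region tibble from [call_qtl()] (columns `chrom`,
#'   `start_mb`, `end_mb`).
#' @param map Marker map (or [genotype_data()]).
#' @param flank_mb Exclusion flank around each region for `REST`.
#' @return A tibble `label`, `n`, `markers` (list column). Regions
#'   containing no markers are kept with `n = 0` and flagged via a warning.
#' @export
build_snp_sets <- function(qtl_regions, map, flank_mb = 3) {
  if (inherits(map, "vs_geno")) map <- map$map
  map <- tibble::as_tibble(map)
  all_m <- as.character(map$marker)
  sets <- list(ALL = all_m)
  qtl <- character(0)
  in_flank <- rep(FALSE, nrow(map))
  if (!is.null(qtl_regions) && nrow(qtl_regions)) {
    for (i in seq_len(nrow(qtl_regions))) {
      r <- qtl_regions[i, ]
      inside <- map$chrom == r$chrom &
        map$pos >= r$start_mb * 1e6 & map$pos < r$end_mb * 1e6
      lab <- sprintf("per-QTL:%d:%g-%g", r$chrom, r$start_mb, r$end_mb)
      if (!any(inside)) warn(paste0("QTL region with no markers: ", lab))
      sets[[lab]] <- all_m[inside]
      qtl <- union(qtl, all_m[inside])
      flank <- map$chrom == r$chrom &
        map$pos >= (r$start_mb - flank_mb) * 1e6 &
        map$pos < (r$end_mb + flank_mb) * 1e6
      in_flank <- in_flank | flank
    }
  }
  sets$QTL <- qtl
  sets$REST <- all_m[!in_flank]
  tibble::tibble(
    label = names(sets),
    n = lengths(sets),
    markers = unname(sets)
  )
}

#' Run a genomic prediction strategy
#'
#' Three training/validation strategies over one or two breeds:
#' * `"within"`: per breed, sire-family k-fold cross-validation; train on
#'   k-1 folds, predict the held-out fold; GPA by the fold-weighted formula
#'   ([gpa_cv()]).
#' * `"between"`: train on the full other breed, validate on the whole
#'   target breed in a single split; GPA by [gpa_single()] (no across-fold
#'   SD).
#' * `"multi"`: folds are the union of the within-breed folds; training
#'   uses both breeds minus the validation fold; GPA aggregated per
#'   validation breed.
#'
#' All markers are used in training; `snp_sets` only restrict which
#' estimated effects enter the validation GEBV, so effects stay conditional
#' on the whole genome. Fixed effects for the `y*` adjustment come from
#' each training fit (never from validation records), validation dosages
#' are centered with training-set allele frequencies, and the heritability
#' in the denominator is always the validation breed's pedigree estimate.
#' Markers absent from (or monomorphic in) the training set contribute zero
#' effects. Between-breed runs intersect the breeds' post-QC marker sets.
#'
#' @param strategy `"within"`, `"between"` or `"multi"`.
#' @param breed_data Named list, one element per breed, each a list with
#'   `genotypes` (QC'd [genotype_data()]), `pheno` (phenotype tibble) and
#'   `h2` (the breed's pedigree heritability for `trait`).
#' @param folds Named list of [make_folds()] assignments per breed
#'   (required for `"within"` and `"multi"`).
#' @param cfg [chain_config()] for the training fits (BayesB with the
#'   BayesCpi-estimated `pi` in the reference flow).
#' @param trait Trait column.
#' @param snp_sets Optional [build_snp_sets()] tibble (or named list of
#'   marker vectors); default uses all markers (`ALL`).
#' @param fixed,covariate Fixed-effect specification passed to
#'   [fit_bayes()].
#' @return A `vs_gpa_result` tibble: `strategy`, `validation_breed`,
#'   `trait`, `snp_set`, `gpa`, `sd`, `folds` (list column of per-fold `r`
#'   and `n`).
#' @export
run_strategy <- function(strategy = c("within", "between", "multi"),
                         breed_data, folds = NULL, cfg, trait,
                         snp_sets = NULL, fixed = c("line", "cg"),
                         covariate = "bw") {
  strategy <- match.arg(strategy)
  stopifnot(is.list(breed_data), !is.null(names(breed_data)))
  sets <- normalise_snp_sets(snp_sets, breed_data)
  breeds <- names(breed_data)
  if (strategy %in% c("within", "multi") && is.null(folds)) {
    abort("`folds` are required for within/multi-breed strategies.")
  }

  results <- list()
  if (strategy == "within") {
    for (br in breeds) {
      bd <- breed_data[[br]]
      fl <- folds[[br]]
      per_fold <- run_cv_folds(
        train_sets = lapply(sort(unique(fl$fold)), function(f) {
          list(train = list(bd), val = bd,
               val_animals = fl$animal[fl$fold == f])
        }),
        cfg = cfg, trait = trait, sets = sets,
        fixed = fixed, covariate = covariate
      )
      results[[length(results) + 1]] <-
        summarise_gpa(per_fold, strategy, br, trait, bd$h2)
    }
  } else if (strategy == "between") {
    if (length(breeds) < 2) abort("Between-breed prediction needs two breeds.")
    for (br in breeds) {
      other <- setdiff(breeds, br)
      bd <- breed_data[[br]]
      per_fold <- run_cv_folds(
        train_sets = list(list(
          train = breed_data[other], val = bd, val_animals = bd$pheno$animal
        )),
        cfg = cfg, trait = trait, sets = sets,
        fixed = fixed, covariate = covariate
      )
      results[[length(results) + 1]] <-
        summarise_gpa(per_fold, strategy, br, trait, bd$h2, single = TRUE)
    }
  } else {
    units <- list()
    for (br in breeds) {
      fl <- folds[[br]]
      for (f in sort(unique(fl$fold))) {
        train <- lapply(breeds, function(b) {
          bd <- breed_data[[b]]
          keep <- if (b == br) setdiff(bd$pheno$animal, fl$animal[fl$fold == f]) else bd$pheno$animal
          list(genotypes = bd$genotypes,
               pheno = bd$pheno[bd$pheno$animal %in% keep, ])
        })
        units[[length(units) + 1]] <- list(
          train = train, val = breed_data[[br]],
          val_animals = fl$animal[fl$fold == f], breed = br
        )
      }
    }
    per_fold <- run_cv_folds(units, cfg, trait, sets, fixed, covariate)
    per_fold$breed <- vapply(units, `[[`, character(1), "breed")[per_fold$unit]
    for (br in breeds) {
      results[[length(results) + 1]] <- summarise_gpa(
        per_fold[per_fold$breed == br, ], strategy, br, trait,
        breed_data[[br]]$h2
      )
    }
  }
  out <- dplyr::bind_rows(results)
  class(out) <- c("vs_gpa_result", class(out))
  out
}

normalise_snp_sets <- function(snp_sets, breed_data) {
  if (is.null(snp_sets)) {
    all_m <- unique(unlist(lapply(breed_data, function(b) colnames(b$genotypes$calls))))
    return(list(ALL = all_m))
  }
  if (is.data.frame(snp_sets)) {
    setNames(snp_sets$markers, snp_sets$label)
  } else {
    snp_sets
  }
}

# Fit one chain per training unit and score every snp_set on its
# validation animals. Training pools the listed breeds over their common
# markers; validation GEBVs use training centers.
run_cv_folds <- function(train_sets, cfg, trait, sets, fixed, covariate) {
  out <- list()
  for (u in seq_along(train_sets)) {
    unit <- train_sets[[u]]
    train_pheno <- dplyr::bind_rows(lapply(unit$train, function(b) {
      b$pheno[!b$pheno$animal %in% unit$val_animals, , drop = FALSE]
    }))
    common <- Reduce(intersect, lapply(unit$train, function(b) colnames(b$genotypes$calls)))
    calls <- do.call(rbind, lapply(unit$train, function(b) {
      b$genotypes$calls[intersect(rownames(b$genotypes$calls), train_pheno$animal),
                        common, drop = FALSE]
    }))
    map1 <- unit$train[[1]]$genotypes$map
    gtrain <- genotype_data(calls, map1[map1$marker %in% common, ], NULL)
    fit <- fit_bayes(gtrain, train_pheno, cfg, trait,
                     fixed = fixed, covariate = covariate)
    val_pheno <- unit$val$pheno[unit$val$pheno$animal %in% unit$val_animals, ]
    gval <- subset_genotypes(unit$val$genotypes, animals = val_pheno$animal,
                             markers = intersect(common, colnames(unit$val$genotypes$calls)))
    adj <- suppressWarnings(adjust_phenotypes(val_pheno, fit, trait))
    eff <- colMeans(fit$effects)
    for (lab in names(sets)) {
      snp <- intersect(sets[[lab]], colnames(gval$calls))
      if (!length(snp)) next
      gv <- gebv_from_effects(eff, gval, snp_set = snp, centers = fit$centers)
      r <- if (sd(gv) == 0 || sd(adj$y_star) == 0) NA_real_ else cor(gv, adj$y_star)
      out[[length(out) + 1]] <- tibble::tibble(
        unit = u, snp_set = lab, r = r, n = nrow(val_pheno)
      )
    }
  }
  dplyr::bind_rows(out)
}

summarise_gpa <- function(per_fold, strategy, breed, trait, h2,
                          single = FALSE) {
  dplyr::bind_rows(lapply(split(per_fold, per_fold$snp_set), function(d) {
    if (single) {
      g <- gpa_single_from_r(d$r[1], h2)
      tibble::tibble(
        strategy = strategy, validation_breed = breed, trait = trait,
        snp_set = d$snp_set[1], gpa = g, sd = NA_real_,
        folds = list(d[, c("r", "n")])
      )
    } else {
      g <- gpa_cv(d[, c("r", "n")], h2)
      tibble::tibble(
        strategy = strategy, validation_breed = breed, trait = trait,
        snp_set = d$snp_set[1], gpa = g$gpa, sd = g$sd,
        folds = list(d[, c("r", "n")])
      )
    }
  }))
}

gpa_single_from_r <- function(r, h2) {
  if (is.na(r)) NA_real_ else r / sqrt(h2)
}

#' Bar chart of genomic prediction accuracies
#'
#' @param object A `vs_gpa_result`.
#' @param ... Unused.
#' @return A ggplot of GPA by SNP set and validation breed with SD error
#'   bars where available.
#' @export
autoplot.vs_gpa_result <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$snp_set, y = .data$gpa,
                                    fill = .data$validation_breed)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gpa - .data$sd, ymax = .data$gpa + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~ .data$strategy) +
    ggplot2::labs(x = "SNP set", y = "Genomic prediction accuracy",
                  fill = "Validation breed") +
    ggplot2::theme_minimal()
}
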