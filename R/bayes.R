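#' Configuration for a Bayes-alphabet Gibbs chain
#'
#' @param method One of `"BayesB"`, `"BayesC"`, `"BayesCpi"`, `"BayesC0"`.
#'   BayesB samples a per-marker effect variance, BayesC/BayesC0 share one,
#'   BayesCpi additionally samples the null-marker fraction `pi` from
#'   `Beta(#excluded + 1, #included + 1)`.
#' @param pi Prior fraction of SNPs with zero effect. Fixed for BayesB and
#'   BayesC, the starting value for BayesCpi, forced to 0 for BayesC0.
#' @param n_iter,n_burnin,thin Chain length, burn-in and thinning; the
#'   number of retained draws is `floor((n_iter - n_burnin) / thin)`.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   retained draws.
#' @param var_a,var_e Prior additive-genetic and residual variances,
#'   typically the pedigree REML estimates. The per-marker effect-variance
#'   scale is derived at fit time as
#'   `var_a / ((1 - pi) * sum(2 p_k (1 - p_k)))` over the analysed markers.
#' @param nu_a,nu_e Scaled-inverse-chi-squared degrees of freedom for the
#'   marker-effect and residual variances.
#' @return A `vs_chain_config` list.
#' @export
chain_config <- function(method = c("BayesB", "BayesC", "BayesCpi", "BayesC0"),
                         pi = 0.99, n_iter = 50000, n_burnin = 5000, thin = 1,
                         seed = NULL, var_a = NULL, var_e = NULL,
                         nu_a = 4.2, nu_e = 10) {
  method <- match.arg(method)
  if (method == "BayesC0") pi <- 0
  if (pi < 0 || pi > 1) abort("`pi` must lie in [0, 1].")
  if (n_burnin >= n_iter) abort("`n_burnin` must be smaller than `n_iter`.")
  if (thin < 1) abort("`thin` must be >= 1.")
  if (!is.null(var_a) && var_a <= 0) abort("`var_a` must be positive.")
  if (!is.null(var_e) && var_e <= 0) abort("`var_e` must be positive.")
  structure(list(
    method = method, pi = pi, n_iter = as.integer(n_iter),
    n_burnin = as.integer(n_burnin), thin = as.integer(thin),
    seed = seed, var_a = var_a, var_e = var_e, nu_a = nu_a, nu_e = nu_e
  ), class = "vs_chain_config")
}

method_code <- function(method) {
  match(method, c("BayesB", "BayesC", "BayesCpi", "BayesC0")) - 1L
}

#' Whole-genome regression by Gibbs sampling
#'
#' Fits `y = W b + sum_j x_j alpha_j delta_j + e` by single-site Gibbs
#' sampling under the prior named in `cfg`. `W` holds the intercept, the
#' line and contemporary-group factors and the centered body-weight
#' covariate (flat priors); marker dosages are centered by their
#' within-analysis-set means (or by `centers`, e.g. training frequencies
#' when refitting). The litter common-environment effect is deliberately
#' not part of this model. Marker inclusion is sampled from the
#' marginalised likelihood ratio against the point mass at zero; an
#' indicator of 0 implies an effect of exactly 0 within a draw.
#'
#' @param g A QC'd [genotype_data()] object.
#' @param pheno Phenotype tibble covering the animals of `g` (extra
#'   genotyped animals are allowed; phenotyped animals missing from `g` are
#'   an error).
#' @param cfg A [chain_config()].
#' @param trait Trait column to analyse.
#' @param fixed,covariate Fixed-effect factor columns and covariate column.
#' @param centers Optional named vector of dosage centering values (twice
#'   the allele frequency) per marker; defaults to the analysed animals'
#'   column means.
#' @return A `vs_bayes_fit` with retained draws of marker effects,
#'   inclusion indicators, fixed effects, variances and (BayesCpi) `pi`,
#'   plus the centering values and fixed-effect solutions needed for
#'   prediction.
#' @export
fit_bayes <- function(g, pheno, cfg, trait, fixed = c("line", "cg"),
                      covariate = "bw", centers = NULL) {
  stopifnot(inherits(g, "vs_geno"), inherits(cfg, "vs_chain_config"))
  pheno <- tibble::as_tibble(pheno)
  if (!trait %in% names(pheno)) abort(paste0("Trait column not found: ", trait))
  used_cols <- c("animal", trait, intersect(fixed, names(pheno)),
                 intersect(covariate, names(pheno)))
  dat <- pheno[complete.cases(pheno[, used_cols]), ]
  unmatched <- setdiff(dat$animal, rownames(g$calls))
  if (length(unmatched)) {
    abort(paste0("Phenotyped animal(s) without genotypes: ",
                 paste(head(unmatched, 5), collapse = ", ")))
  }
  M <- g$calls[dat$animal, , drop = FALSE]
  if (anyNA(M)) abort("Genotypes must be QC'd (no missing calls).")
  ctr <- centers %||% colMeans(M)
  if (is.null(names(ctr))) names(ctr) <- colnames(M)
  Xc <- sweep(M, 2, ctr[colnames(M)])

  spec <- fixed_spec(dat, fixed = fixed, covariate = covariate)
  W <- fixed_design(dat, spec)
  y <- dat[[trait]]

  var_e <- cfg$var_e %||% (var(y) / 2)
  var_a <- cfg$var_a %||% (var(y) / 2)
  sum2pq <- sum(2 * (ctr / 2) * (1 - ctr / 2))
  if (sum2pq <= 0) abort("All analysed markers are monomorphic.")
  s2_marker <- var_a / (max(1 - cfg$pi, 1 / ncol(M)) * sum2pq)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- bayes_gibbs_cpp(Xc, y, W, method_code(cfg$method), cfg$pi,
                         cfg$n_iter, cfg$n_burnin, cfg$thin,
                         cfg$nu_a, s2_marker, cfg$nu_e, var_e)
  colnames(res$effects) <- colnames(M)
  colnames(res$indicators) <- colnames(M)
  colnames(res$fixed) <- colnames(W)

  structure(list(
    method = cfg$method, config = cfg, trait = trait,
    animals = dat$animal, markers = colnames(M), centers = ctr,
    effects = res$effects, indicators = res$indicators,
    fixed_draws = res$fixed,
    sigma2_e = as.numeric(res$sigma2_e),
    sigma2_alpha = as.numeric(res$sigma2_alpha),
    pi = as.numeric(res$pi),
    n_draws = res$n_kept,
    fixed = list(coef = colMeans(res$fixed), spec = spec)
  ), class = "vs_bayes_fit")
}

#' @export
print.vs_bayes_fit <- function(x, ...) {
  cat(sprintf(
    "<%s fit> trait '%s': %d animals, %d markers, %d retained draws\n",
    x$method, x$trait, length(x$animals), length(x$markers), x$n_draws))
  cat(sprintf("posterior mean sigma2_e = %.4g; mean inclusion rate = %.4f\n",
              mean(x$sigma2_e), mean(x$indicators)))
  invisible(x)
}

#' @rdname fit_bayes
#' @param x A `vs_bayes_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per marker with posterior mean effect,
#'   inclusion frequency and the Mb window of the marker's position.
#' @export
tidy.vs_bayes_fit <- function(x, ...) {
  tibble::tibble(
    marker = x$markers,
    effect = colMeans(x$effects),
    inclusion = colMeans(x$indicators)
  )
}

#' @rdname fit_bayes
#' @export
glance.vs_bayes_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, trait = x$trait,
    n = length(x$animals), m = length(x$markers), n_draws = x$n_draws,
    sigma2_e = mean(x$sigma2_e), sigma2_alpha = mean(x$sigma2_alpha),
    pi = if (x$method == "BayesCpi") mean(x$pi) else x$config$pi
  )
}

#' Estimate the null-marker fraction with BayesCpi
#'
#' Runs a BayesCpi chain and returns the posterior mean of `pi` (the
#' fraction of SNPs with zero effect) after burn-in, for use as the fixed
#' `pi` of subsequent BayesB/BayesC analyses.
#'
#' @inheritParams fit_bayes
#' @return A list with `pi` (posterior mean), `chain` (retained draws) and
#'   `fit` (the full `vs_bayes_fit`).
#' @export
estimate_pi <- function(g, pheno, cfg, trait, fixed = c("line", "cg"),
                        covariate = "bw") {
  cfg$method <- "BayesCpi"
  fit <- fit_bayes(g, pheno, cfg, trait, fixed = fixed, covariate = covariate)
  list(pi = mean(fit$pi), chain = fit$pi, fit = fit)
}

#' Genomic breeding values from marker effects
#'
#' `GEBV_i = sum_{k in snp_set} (dosage_ik - center_k) * effect_k`. Dosages
#' are centered so subset GEBVs are additive: GEBVs over disjoint marker
#' sets sum to the GEBV over their union.
#'
#' @param effects Named vector of marker effects (e.g. posterior means), or
#'   a `vs_bayes_fit` whose posterior-mean effects and centers are used.
#' @param g [genotype_data()] for the animals to predict.
#' @param snp_set Character vector of marker IDs to use; default all
#'   markers shared between `effects` and `g`. Must be non-empty.
#' @param centers Named centering vector; defaults to the fit's training
#'   centers (when `effects` is a fit) or to `g`'s own column means.
#'   Markers of `snp_set` absent from `effects` get a zero effect.
#' @return A named numeric vector of GEBVs, one per animal of `g`.
#' @export
gebv_from_effects <- function(effects, g, snp_set = NULL, centers = NULL) {
  stopifnot(inherits(g, "vs_geno"))
  if (inherits(effects, "vs_bayes_fit")) {
    centers <- centers %||% effects$centers
    eff <- colMeans(effects$effects)
  } else {
    eff <- effects
    if (is.null(names(eff))) {
      if (length(eff) != ncol(g$calls)) {
        abort("Unnamed `effects` must match the markers of `g`.")
      }
      names(eff) <- colnames(g$calls)
    }
  }
  snp_set <- snp_set %||% intersect(names(eff), colnames(g$calls))
  if (!length(snp_set)) abort("`snp_set` is empty.")
  missing_m <- setdiff(snp_set, colnames(g$calls))
  if (length(missing_m)) {
    abort(paste0("snp_set marker(s) not in genotypes: ",
                 paste(head(missing_m, 5), collapse = ", ")))
  }
  M <- g$calls[, snp_set, drop = FALSE]
  ctr <- centers %||% colMeans(M)
  ctr <- ctr[snp_set]
  ctr[is.na(ctr)] <- 0
  ev <- setNames(rep(0, length(snp_set)), snp_set)
  common <- intersect(snp_set, names(eff))
  ev[common] <- eff[common]
  drop(sweep(M, 2, ctr) %*% ev)
}

# per-draw GEBV matrix (animals x draws) for a marker subset
gebv_draws <- function(fit, g, snp_set = NULL) {
  snp_set <- snp_set %||% fit$markers
  snp_set <- intersect(snp_set, colnames(g$calls))
  if (!length(snp_set)) abort("`snp_set` is empty.")
  Xc <- sweep(g$calls[, snp_set, drop = FALSE], 2,
              ifelse(is.na(fit$centers[snp_set]), 0, fit$centers[snp_set]))
  Xc %*% t(fit$effects[, snp_set, drop = FALSE])
}
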