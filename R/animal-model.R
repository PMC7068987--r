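#' Univariate animal model by AI-REML
#'
#' Fits the mixed model
#' `y = mu + line + contemporary group + beta * BW + a + d + e`
#' with `a ~ N(0, A * sigma2_a)` (additive genetic, pedigree relationship
#' matrix `A`), `d ~ N(0, I * sigma2_d)` (common litter environment) and
#' `e ~ N(0, I * sigma2_e)`, by average-information REML with an
#' EM-flavoured fallback when AI steps leave the parameter space. Standard
#' errors of the variance ratios `h2 = sigma2_a / sigma2_p` and
#' `c2 = sigma2_d / sigma2_p` (`sigma2_p` the sum of the three components)
#' are obtained by the delta method on the inverse average-information
#' matrix.
#'
#' With few litters the additive and litter components separate weakly; the
#' fit reports the sampling correlation of the two estimates so this can be
#' inspected.
#'
#' @param pheno Phenotype tibble; needs the trait column, the fixed-effect
#'   factors, the covariate and a `litter` column.
#' @param A Numerator relationship matrix from [build_A()] covering every
#'   phenotyped animal.
#' @param trait Name of the trait column (e.g. `"va"`).
#' @param fixed Character vector of fixed-effect factor columns.
#' @param covariate Name of the body-weight covariate column (centered
#'   internally), or `NULL`.
#' @param litter Name of the litter column, or `NULL` to omit the common
#'   litter effect.
#' @param max_iter,tol REML iteration controls (convergence on successive
#'   log-likelihood change).
#' @return A `vs_varcomp` object; see [tidy.vs_varcomp()] and
#'   [glance.vs_varcomp()].
#' @export
fit_univariate <- function(pheno, A, trait, fixed = c("line", "cg"),
                           covariate = "bw", litter = "litter",
                           max_iter = 200, tol = 1e-8) {
  pheno <- tibble::as_tibble(pheno)
  if (!trait %in% names(pheno)) abort(paste0("Trait column not found: ", trait))
  used_cols <- c("animal", trait, intersect(fixed, names(pheno)),
                 intersect(c(covariate, litter), names(pheno)))
  dat <- pheno[complete.cases(pheno[, used_cols]), ]
  if (nrow(dat) < 10) abort("Too few complete records to fit the animal model.")
  missing_a <- setdiff(dat$animal, rownames(A))
  if (length(missing_a)) {
    abort(paste0("Phenotyped animal(s) absent from A: ",
                 paste(head(missing_a, 5), collapse = ", ")))
  }
  y <- dat[[trait]]
  if (var(y) <= 0) abort("Trait is constant.")

  spec <- fixed_spec(dat, fixed = fixed, covariate = covariate)
  X <- fixed_design(dat, spec)

  Aq <- A[dat$animal, dat$animal]
  ev_min <- min(eigen(Aq, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) abort("Relationship matrix is not positive semi-definite.")
  Bmats <- list(animal = Aq)
  if (!is.null(litter) && litter %in% names(dat)) {
    Zl <- model.matrix(~ 0 + factor(dat[[litter]]))
    Bmats$litter <- tcrossprod(Zl)
  }
  Bmats$residual <- diag(nrow(dat))

  fit <- reml_engine(y, X, Bmats, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    abort(paste0("REML did not converge in ", max_iter, " iterations."),
          trace_loglik = fit$trace)
  }

  theta <- fit$theta
  Vth <- fit$vcov
  tot <- sum(theta)
  has_litter <- "litter" %in% names(theta)
  grad_ratio <- function(which) {
    g <- -theta[which] / tot^2
    g <- rep(g, length(theta))
    names(g) <- names(theta)
    g[which] <- (tot - theta[which]) / tot^2
    g
  }
  h2 <- unname(theta["animal"] / tot)
  gh <- grad_ratio("animal")
  h2_se <- sqrt(drop(t(gh) %*% Vth %*% gh))
  if (has_litter) {
    c2 <- unname(theta["litter"] / tot)
    gc <- grad_ratio("litter")
    c2_se <- sqrt(drop(t(gc) %*% Vth %*% gc))
    sep_cor <- Vth["animal", "litter"] /
      sqrt(Vth["animal", "animal"] * Vth["litter", "litter"])
  } else {
    c2 <- NA_real_; c2_se <- NA_real_; sep_cor <- NA_real_
  }

  structure(list(
    trait = trait,
    components = tibble::tibble(
      term = names(theta),
      estimate = unname(theta),
      std_error = sqrt(pmax(diag(Vth), 0)),
      at_boundary = unname(fit$at_boundary)
    ),
    h2 = h2, h2_se = h2_se, c2 = c2, c2_se = c2_se,
    separation_cor = sep_cor,
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations, n = nrow(dat),
    fixed = list(coef = fit$beta, spec = spec),
    vcov_theta = Vth
  ), class = "vs_varcomp")
}

#' @export
print.vs_varcomp <- function(x, ...) {
  cat(sprintf("<animal model REML fit> trait '%s', n = %d, logLik = %.3f\n",
              x$trait, x$n, x$loglik))
  print(x$components)
  cat(sprintf("h2 = %.3f (SE %.3f)", x$h2, x$h2_se))
  if (!is.na(x$c2)) cat(sprintf(", c2 = %.3f (SE %.3f)", x$c2, x$c2_se))
  cat("\n")
  invisible(x)
}

#' @rdname fit_univariate
#' @param x A `vs_varcomp` object.
#' @param ... Unused.
#' @export
tidy.vs_varcomp <- function(x, ...) x$components

#' @rdname fit_univariate
#' @export
glance.vs_varcomp <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, n = x$n,
    h2 = x$h2, h2_se = x$h2_se, c2 = x$c2, c2_se = x$c2_se,
    logLik = x$loglik, converged = x$converged, iterations = x$iterations
  )
}

#' Bivariate animal model by AI-REML
#'
#' Joint fit of two traits with unstructured 2x2 additive-genetic, litter
#' and residual (co)variance matrices, each constrained positive
#' semi-definite (a non-PSD iterate is projected to the nearest PSD matrix
#' with a warning via the engine's fallback path). Genetic correlation
#' `r_G = cov_a / sqrt(sigma2_a1 * sigma2_a2)`; phenotypic correlation from
#' the summed covariance components. Standard errors by the delta method.
#'
#' @inheritParams fit_univariate
#' @param traits Character vector of two trait column names.
#' @return A `vs_varcomp_biv` object with `tidy()`/`glance()` methods.
#' @export
fit_bivariate <- function(pheno, A, traits, fixed = c("line", "cg"),
                          covariate = "bw", litter = "litter",
                          max_iter = 500, tol = 1e-7) {
  stopifnot(length(traits) == 2)
  pheno <- tibble::as_tibble(pheno)
  blocks <- list()
  for (t in seq_along(traits)) {
    tr <- traits[t]
    if (!tr %in% names(pheno)) abort(paste0("Trait column not found: ", tr))
    used_cols <- c("animal", tr, intersect(fixed, names(pheno)),
                   intersect(c(covariate, litter), names(pheno)))
    dat <- pheno[complete.cases(pheno[, used_cols]), ]
    if (var(dat[[tr]]) <= 0) abort(paste0("Trait is constant: ", tr))
    blocks[[t]] <- dat
  }
  if (!length(intersect(blocks[[1]]$animal, blocks[[2]]$animal))) {
    abort("The two traits share no animals.")
  }
  animals <- unique(c(blocks[[1]]$animal, blocks[[2]]$animal))
  missing_a <- setdiff(animals, rownames(A))
  if (length(missing_a)) {
    abort(paste0("Phenotyped animal(s) absent from A: ",
                 paste(head(missing_a, 5), collapse = ", ")))
  }
  Aq <- A[animals, animals]
  litters <- unique(c(blocks[[1]][[litter]], blocks[[2]][[litter]]))

  y <- c(blocks[[1]][[traits[1]]], blocks[[2]][[traits[2]]])
  n1 <- nrow(blocks[[1]]); n2 <- nrow(blocks[[2]]); n <- n1 + n2
  # per-trait fixed-effect blocks
  spec1 <- fixed_spec(blocks[[1]], fixed = fixed, covariate = covariate)
  spec2 <- fixed_spec(blocks[[2]], fixed = fixed, covariate = covariate)
  X1 <- fixed_design(blocks[[1]], spec1)
  X2 <- fixed_design(blocks[[2]], spec2)
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))

  Za <- lapply(blocks, function(b) {
    Z <- matrix(0, nrow(b), length(animals))
    Z[cbind(seq_len(nrow(b)), match(b$animal, animals))] <- 1
    Z
  })
  Zd <- lapply(blocks, function(b) {
    Z <- matrix(0, nrow(b), length(litters))
    Z[cbind(seq_len(nrow(b)), match(b[[litter]], litters))] <- 1
    Z
  })
  block_B <- function(M11, M12, M22) {
    rbind(cbind(M11, M12), cbind(t(M12), M22))
  }
  comp_mats <- function(Z, K) {
    if (is.null(K)) {
      ZK1 <- Z[[1]]; ZK2 <- Z[[2]]
    } else {
      ZK1 <- Z[[1]] %*% K; ZK2 <- Z[[2]] %*% K
    }
    list(
      b11 = block_B(tcrossprod(ZK1, Z[[1]]), matrix(0, n1, n2), matrix(0, n2, n2)),
      b12 = block_B(matrix(0, n1, n1), tcrossprod(ZK1, Z[[2]]), matrix(0, n2, n2)),
      b22 = block_B(matrix(0, n1, n1), matrix(0, n1, n2), tcrossprod(ZK2, Z[[2]]))
    )
  }
  ga <- comp_mats(Za, Aq)
  gd <- comp_mats(Zd, NULL)
  Ze <- lapply(blocks, function(b) {
    Z <- matrix(0, nrow(b), length(animals))
    Z[cbind(seq_len(nrow(b)), match(b$animal, animals))] <- 1
    Z
  })
  ge <- comp_mats(Ze, NULL)
  # residual diagonal blocks are identities (one record per animal per trait)
  ge$b11 <- block_B(diag(n1), matrix(0, n1, n2), matrix(0, n2, n2))
  ge$b22 <- block_B(matrix(0, n1, n1), matrix(0, n1, n2), diag(n2))

  Bmats <- list(
    a11 = ga$b11, a12 = ga$b12, a22 = ga$b22,
    d11 = gd$b11, d12 = gd$b12, d22 = gd$b22,
    e11 = ge$b11, e12 = ge$b12, e22 = ge$b22
  )
  v1 <- var(blocks[[1]][[traits[1]]]); v2 <- var(blocks[[2]][[traits[2]]])
  init <- c(v1 / 3, 0, v2 / 3, v1 / 6, 0, v2 / 6, v1 / 2, 0, v2 / 2)
  lb <- 1e-8 * sqrt(v1 * v2)
  lower <- c(lb, -Inf, lb, lb, -Inf, lb, lb, -Inf, lb)
  psd_groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))

  fit <- reml_engine(y, X, Bmats, init = init, lower = lower,
                     psd_groups = psd_groups, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    abort(paste0("Bivariate REML did not converge in ", max_iter, " iterations."),
          trace_loglik = fit$trace)
  }
  if (fit$used_fallback) {
    warn("Non-PSD AI iterate encountered; projected to the nearest PSD matrix.")
  }

  th <- fit$theta
  Vth <- fit$vcov
  rg <- th["a12"] / sqrt(th["a11"] * th["a22"])
  grad_rg <- setNames(numeric(9), names(th))
  grad_rg["a12"] <- 1 / sqrt(th["a11"] * th["a22"])
  grad_rg["a11"] <- -0.5 * th["a12"] / (th["a11"]^1.5 * sqrt(th["a22"]))
  grad_rg["a22"] <- -0.5 * th["a12"] / (th["a22"]^1.5 * sqrt(th["a11"]))
  rg_se <- sqrt(drop(t(grad_rg) %*% Vth %*% grad_rg))

  p11 <- th["a11"] + th["d11"] + th["e11"]
  p22 <- th["a22"] + th["d22"] + th["e22"]
  p12 <- th["a12"] + th["d12"] + th["e12"]
  rp <- p12 / sqrt(p11 * p22)
  grad_rp <- setNames(numeric(9), names(th))
  for (cmp in c("a", "d", "e")) {
    grad_rp[paste0(cmp, "12")] <- 1 / sqrt(p11 * p22)
    grad_rp[paste0(cmp, "11")] <- -0.5 * p12 / (p11^1.5 * sqrt(p22))
    grad_rp[paste0(cmp, "22")] <- -0.5 * p12 / (p22^1.5 * sqrt(p11))
  }
  rp_se <- sqrt(drop(t(grad_rp) %*% Vth %*% grad_rp))

  structure(list(
    traits = traits,
    components = tibble::tibble(
      term = names(th), estimate = unname(th),
      std_error = sqrt(pmax(diag(Vth), 0))
    ),
    r_g = unname(rg), r_g_se = rg_se,
    r_p = unname(rp), r_p_se = rp_se,
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations, n = c(n1 = n1, n2 = n2),
    vcov_theta = Vth
  ), class = "vs_varcomp_biv")
}

#' @export
print.vs_varcomp_biv <- function(x, ...) {
  cat(sprintf("<bivariate animal model REML fit> traits %s/%s, n = %d + %d\n",
              x$traits[1], x$traits[2], x$n[1], x$n[2]))
  cat(sprintf("r_G = %.3f (SE %.3f), r_P = %.3f (SE %.3f)\n",
              x$r_g, x$r_g_se, x$r_p, x$r_p_se))
  invisible(x)
}

#' @rdname fit_bivariate
#' @param x A `vs_varcomp_biv` object.
#' @param ... Unused.
#' @export
tidy.vs_varcomp_biv <- function(x, ...) x$components

#' @rdname fit_bivariate
#' @export
glance.vs_varcomp_biv <- function(x, ...) {
  tibble::tibble(
    trait1 = x$traits[1], trait2 = x$traits[2],
    r_g = x$r_g, r_g_se = x$r_g_se, r_p = x$r_p, r_p_se = x$r_p_se,
    logLik = x$loglik, converged = x$converged
  )
}

#' Heritability from published variance components
#'
#' Reconstructs heritability from a reported additive variance, residual
#' variance and litter common-environment ratio: with
#' `sigma2_p = (sigma2_a + sigma2_e) / (1 - c2)` (so that
#' `c2 = sigma2_d / sigma2_p` is consistent with the reported ratio),
#' `h2 = sigma2_a / sigma2_p`. Vectorised over all arguments.
#'
#' @param sigma2_a Additive genetic variance (trait units squared).
#' @param sigma2_e Residual variance.
#' @param c2 Litter common-environment ratio, in `[0, 1)`.
#' @return Heritability `h2` on the observed scale.
#' @examples
#' heritability_from_components(69807.7, 71990.1, 0.06) # ~0.46
#' @export
heritability_from_components <- function(sigma2_a, sigma2_e, c2) {
  if (any(sigma2_a < 0) || any(sigma2_e < 0)) {
    abort("Variances must be non-negative.")
  }
  if (any(c2 < 0) || any(c2 >= 1)) {
    abort("`c2` must lie in [0, 1).")
  }
  sigma2_p <- (sigma2_a + sigma2_e) / (1 - c2)
  ifelse(sigma2_p == 0, 0, sigma2_a / sigma2_p)
}
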