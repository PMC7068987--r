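# Fixed-effect design construction shared by the REML fitter, the Bayes
# samplers and phenotype adjustment. Treatment coding with the training
# data's factor levels; the covariate is centered (numerical conditioning;
# centering does not change variance estimates). Unseen validation levels
# map to the baseline (all-zero dummies) with a warning, i.e. their level
# effect is treated as 0.

fixed_spec <- function(data, fixed = c("line", "cg"), covariate = "bw") {
  fixed <- intersect(fixed, names(data))
  levs <- lapply(fixed, function(f) sort(unique(as.character(data[[f]]))))
  names(levs) <- fixed
  center <- if (!is.null(covariate) && covariate %in% names(data)) {
    mean(data[[covariate]], na.rm = TRUE)
  } else {
    covariate <- NULL
    NULL
  }
  list(fixed = fixed, levels = levs, covariate = covariate, center = center)
}

fixed_design <- function(data, spec, warn_unseen = TRUE) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  for (f in spec$fixed) {
    x <- as.character(data[[f]])
    levs <- spec$levels[[f]]
    unseen <- setdiff(unique(x), levs)
    if (length(unseen) && warn_unseen) {
      warn(paste0("Unseen level(s) of `", f, "` treated as baseline: ",
                  paste(head(unseen, 5), collapse = ", ")))
    }
    for (l in levs[-1]) cols[[paste0(f, l)]] <- as.numeric(x == l)
  }
  if (!is.null(spec$covariate)) {
    cols[[spec$covariate]] <- data[[spec$covariate]] - spec$center
  }
  X <- do.call(cbind, cols)
  # drop aliased columns so the design is full rank
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  X
}

fixed_predict <- function(data, spec, coef, warn_unseen = TRUE) {
  X <- fixed_design(data, spec, warn_unseen = warn_unseen)
  common <- intersect(colnames(X), names(coef))
  drop(X[, common, drop = FALSE] %*% coef[common])
}
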