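#' Validate and topologically sort a pedigree
#'
#' Parents must precede offspring after sorting and no animal may be its own
#' ancestor. Unknown parents (`NA`) are founders with zero relationship to
#' everything born before them.
#'
#' @param ped Data frame with character columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent).
#' @return A tibble sorted so every parent precedes its offspring, with a
#'   `generation` column (founders = 0, otherwise 1 + max parental
#'   generation).
#' @export
sort_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  if (!all(c("animal", "sire", "dam") %in% names(ped))) {
    abort("Pedigree needs columns animal, sire, dam.")
  }
  if (nrow(ped) == 0) abort("Empty pedigree.")
  ped$animal <- as.character(ped$animal)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$animal)) {
    abort(paste0("Duplicate animal ID: ", ped$animal[duplicated(ped$animal)][1]))
  }
  unknown <- setdiff(c(ped$sire, ped$dam), c(ped$animal, NA))
  if (length(unknown)) {
    abort(paste0("Parent ID(s) not in pedigree: ", paste(head(unknown, 5), collapse = ", ")))
  }
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  gen <- rep(NA_integer_, n)
  ord <- integer(0)
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    ready <- which(remaining &
                     (si == 0L | !remaining[pmax(si, 1L)]) &
                     (di == 0L | !remaining[pmax(di, 1L)]))
    if (!length(ready)) {
      cyc <- ped$animal[remaining]
      abort(paste0("Pedigree cycle involving: ", paste(head(cyc, 10), collapse = ", ")))
    }
    g_par <- vapply(ready, function(i) {
      gp <- c(if (si[i] > 0) gen[si[i]], if (di[i] > 0) gen[di[i]])
      if (length(gp)) max(gp) + 1L else 0L
    }, integer(1))
    gen[ready] <- g_par
    ord <- c(ord, ready)
    remaining[ready] <- FALSE
  }
  out <- ped[ord, c("animal", "sire", "dam")]
  out$generation <- gen[ord]
  out
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular method: with animals sorted parents-first,
#' `a_ii = 1 + 0.5 * a_sd` and `a_ij = 0.5 * (a_js + a_jd)` for `j < i`,
#' an unknown parent contributing zero. The diagonal is `1 + F_i` with `F_i`
#' the inbreeding coefficient.
#'
#' @param ped Pedigree data frame (`animal`, `sire`, `dam`); sorted
#'   internally with [sort_pedigree()].
#' @return A symmetric positive semi-definite matrix with animal IDs as
#'   dimnames, rows/columns in the input animal order.
#' @export
build_A <- function(ped) {
  input_ids <- as.character(tibble::as_tibble(ped)$animal)
  sp <- sort_pedigree(ped)
  n <- nrow(sp)
  idx <- setNames(seq_len(n), sp$animal)
  si <- ifelse(is.na(sp$sire), 0L, idx[sp$sire])
  di <- ifelse(is.na(sp$dam), 0L, idx[sp$dam])
  A <- matrix(0, n, n, dimnames = list(sp$animal, sp$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    a_sd <- if (s > 0 && d > 0) A[s, d] else 0
    if (i > 1) {
      prev <- seq_len(i - 1)
      v <- numeric(i - 1)
      if (s > 0) v <- v + 0.5 * A[prev, s]
      if (d > 0) v <- v + 0.5 * A[prev, d]
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + 0.5 * a_sd
  }
  A[input_ids, input_ids]
}

#' Pedigree inbreeding coefficients
#'
#' `F_i = a_ii - 1` from the numerator relationship matrix.
#'
#' @param ped Pedigree data frame.
#' @return A tibble with columns `animal` and `f` in the input order.
#' @seealso [mean_inbreeding()] for the summary that excludes non-inbred
#'   animals.
#' @export
inbreeding <- function(ped) {
  A <- build_A(ped)
  tibble::tibble(animal = rownames(A), f = unname(diag(A) - 1))
}

#' Mean inbreeding over inbred animals
#'
#' The conventional herd summary: the mean of `F` over animals with `F > 0`.
#' When no animal is inbred the mean is undefined and 0 is returned with a
#' warning.
#'
#' @param ped Pedigree data frame.
#' @return A single numeric value.
#' @export
mean_inbreeding <- function(ped) {
  f <- inbreeding(ped)$f
  pos <- f[f > 0]
  if (!length(pos)) {
    warn("No inbred animals; mean inbreeding over inbred animals is undefined, returning 0.")
    return(0)
  }
  mean(pos)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum(p_k * (1 - p_k)))` where `W` is the dosage matrix
#' centered by twice the allele frequencies `p_k`. Frequencies default to
#' the analysed samples' own means, under which the mean off-diagonal
#' relationship is approximately zero.
#'
#' @param g A QC'd [genotype_data()] object (no missing calls, at least two
#'   segregating markers).
#' @param allele_freq Optional vector of allele frequencies (one per marker)
#'   to center and scale by, e.g. training-set frequencies.
#' @return A symmetric matrix with animal IDs as dimnames.
#' @export
build_G <- function(g, allele_freq = NULL) {
  stopifnot(inherits(g, "vs_geno"))
  M <- g$calls
  if (anyNA(M)) abort("Genotypes must be QC'd (no missing calls) before building G.")
  p <- allele_freq %||% (colMeans(M) / 2)
  if (length(p) != ncol(M)) abort("`allele_freq` must have one entry per marker.")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("All markers are monomorphic; G is undefined.")
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / denom
  (G + t(G)) / 2
}

#' Average relationships within and between cross-validation folds
#'
#' Summarises a relationship matrix (pedigree A or genomic G) at the fold
#' level: entry (f, f') is the mean relationship over pairs of animals with
#' one in each fold. Within-fold entries average off-diagonal pairs only
#' (relationships among distinct animals); the mean self-relationship of a
#' fold is reported separately in `mean_self`.
#'
#' @param R Square relationship matrix with animal IDs as dimnames.
#' @param folds Data frame with columns `animal` and `fold` partitioning the
#'   animals of `R`.
#' @return A tibble with columns `fold_a`, `fold_b`, `mean_rel`, `n_pairs`
#'   and `mean_self` (NA off the diagonal); within-fold rows for folds with
#'   fewer than two animals carry `mean_rel = NA` and a warning.
#' @export
fold_relationship_summary <- function(R, folds) {
  folds <- tibble::as_tibble(folds)
  if (!all(c("animal", "fold") %in% names(folds))) {
    abort("`folds` needs columns animal, fold.")
  }
  folds$animal <- as.character(folds$animal)
  if (!setequal(folds$animal, rownames(R)) || anyDuplicated(folds$animal)) {
    abort("`folds` must partition the animals of `R`.")
  }
  ids <- split(folds$animal, folds$fold)
  labs <- names(ids)
  res <- list()
  for (a in seq_along(labs)) {
    for (b in a:length(labs)) {
      ia <- ids[[a]]; ib <- ids[[b]]
      block <- R[ia, ib, drop = FALSE]
      if (a == b) {
        if (length(ia) < 2) {
          warn(sprintf("Fold '%s' has fewer than 2 animals; within-fold mean undefined.", labs[a]))
          mr <- NA_real_; np <- 0L
        } else {
          off <- block[lower.tri(block)]
          mr <- mean(off); np <- length(off)
        }
        ms <- mean(diag(block))
      } else {
        mr <- mean(block); np <- length(block); ms <- NA_real_
      }
      res[[length(res) + 1]] <- tibble::tibble(
        fold_a = labs[a], fold_b = labs[b],
        mean_rel = mr, n_pairs = np, mean_self = ms
      )
    }
  }
  dplyr::bind_rows(res)
}
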