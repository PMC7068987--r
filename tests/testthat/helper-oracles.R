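# Independent oracles used across tests. These deliberately avoid the
# package's own algorithms: kinship by Wright-style recursion, variances by
# brute-force algebra.

# Recursive kinship coefficients (Malecot); A = 2 * phi. Independent of the
# tabular method used by build_A().
kinship_oracle_A <- function(ped) {
  ped <- as.data.frame(ped)
  ids <- as.character(ped$animal)
  sire <- setNames(as.character(ped$sire), ids)
  dam <- setNames(as.character(ped$dam), ids)
  pos <- setNames(seq_along(ids), ids)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(sire[[i]], dam[[i]]))
    } else {
      # recurse through the younger animal
      if (pos[[i]] < pos[[j]]) { tmp <- i; i <- j; j <- tmp }
      0.5 * (phi(sire[[i]], j) + phi(dam[[i]], j))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in a:n) {
      A[a, b] <- A[b, a] <- 2 * phi(ids[a], ids[b])
    }
  }
  A
}

# random valid pedigree (parents precede offspring), n <= ~12
random_pedigree <- function(n, p_known = 0.7) {
  animal <- sprintf("x%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < p_known) {
      sire[i] <- sample(animal[seq_len(i - 1)], 1)
      rest <- setdiff(animal[seq_len(i - 1)], sire[i])
      if (length(rest) && runif(1) < 0.9) dam[i] <- sample(rest, 1)
    }
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam)
}

# minimal hand-built posterior container accepted by the window functions
fake_bayes_fit <- function(effects, indicators, g, animals = rownames(g$calls)) {
  structure(list(
    method = "BayesC", trait = "y",
    animals = animals, markers = colnames(g$calls),
    centers = colMeans(g$calls[animals, , drop = FALSE]),
    effects = effects, indicators = indicators,
    n_draws = nrow(effects),
    sigma2_e = rep(1, nrow(effects)), sigma2_alpha = rep(1, nrow(effects)),
    pi = rep(0.99, nrow(effects)),
    fixed = NULL
  ), class = "vs_bayes_fit")
}

# small genotype object with an evenly spaced map
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("m%03d", seq_len(m))
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("a%03d", seq_len(nrow(calls)))
  map <- tibble::tibble(
    marker = colnames(calls),
    chrom = chrom %||% rep(1L, m),
    pos = pos %||% as.integer(seq_len(m) * 1e5)
  )
  genotype_data(calls, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
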