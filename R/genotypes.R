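#' SNP genotype container
#'
#' Bundles a dosage matrix (animals x markers, allele counts in 0/1/2, real
#' values allowed after mean imputation, `NA` = missing) with a marker map
#' and, optionally, per-call quality scores (e.g. Illumina GenCall, in
#' \[0, 1\]). The map must be sorted by chromosome then base-pair position
#' and be parallel to the columns of `calls`.
#'
#' @param calls Numeric matrix with animal IDs as row names and marker IDs
#'   as column names.
#' @param map Data frame with columns `marker`, `chrom` (integer) and `pos`
#'   (base pairs, 1-based), one row per column of `calls`, in column order.
#' @param quality Optional numeric matrix of per-call quality scores with
#'   the same dimensions as `calls`.
#'
#' @return An object of class `vs_geno`: a list with elements `calls`,
#'   `map` (tibble) and `quality`.
#' @export
genotype_data <- function(calls, map, quality = NULL) {
  if (!is.matrix(calls) || !is.numeric(calls)) {
    abort("`calls` must be a numeric matrix (animals x markers).")
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` must carry animal IDs as rownames and marker IDs as colnames.")
  }
  if (anyDuplicated(rownames(calls))) abort("Duplicate animal IDs in `calls`.")
  if (anyDuplicated(colnames(calls))) abort("Duplicate marker IDs in `calls`.")
  map <- tibble::as_tibble(map)
  req <- c("marker", "chrom", "pos")
  if (!all(req %in% names(map))) {
    abort("`map` needs columns `marker`, `chrom`, `pos`.")
  }
  if (nrow(map) != ncol(calls) || !identical(as.character(map$marker), colnames(calls))) {
    abort("`map` must be parallel to the columns of `calls` (same markers, same order).")
  }
  if (any(map$pos < 0)) abort("Marker positions must be non-negative.")
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map)))) {
    abort("`map` must be sorted by (chrom, pos).")
  }
  rng <- range(calls, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 2) {
    abort("Dosages must lie in [0, 2].")
  }
  if (!is.null(quality)) {
    if (!identical(dim(quality), dim(calls))) {
      abort("`quality` must have the same dimensions as `calls`.")
    }
    if (any(quality < 0 | quality > 1, na.rm = TRUE)) {
      abort("Quality scores must lie in [0, 1].")
    }
  }
  structure(
    list(calls = calls, map = map, quality = quality),
    class = "vs_geno"
  )
}

#' @export
print.vs_geno <- function(x, ...) {
  cat(sprintf(
    "<vs_geno> %d animals x %d markers on %d chromosome(s); %d missing call(s)%s\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
    sum(is.na(x$calls)),
    if (is.null(x$quality)) "" else "; quality scores present"
  ))
  invisible(x)
}

#' @export
dim.vs_geno <- function(x) dim(x$calls)

n_animals <- function(g) nrow(g$calls)
n_markers <- function(g) ncol(g$calls)

#' Subset a genotype object
#'
#' @param g A [genotype_data()] object.
#' @param animals,markers Character vectors of IDs (or logical/integer
#'   indices) to keep; `NULL` keeps all.
#' @return A `vs_geno` with the selected rows/columns; marker order is kept
#'   map-sorted.
#' @export
subset_genotypes <- function(g, animals = NULL, markers = NULL) {
  stopifnot(inherits(g, "vs_geno"))
  ai <- if (is.null(animals)) seq_len(nrow(g$calls)) else animals
  mi <- if (is.null(markers)) seq_len(ncol(g$calls)) else markers
  if (is.character(ai)) {
    missing_a <- setdiff(ai, rownames(g$calls))
    if (length(missing_a)) abort(paste0("Unknown animal ID(s): ", paste(head(missing_a, 5), collapse = ", ")))
  }
  if (is.character(mi)) {
    missing_m <- setdiff(mi, colnames(g$calls))
    if (length(missing_m)) abort(paste0("Unknown marker ID(s): ", paste(head(missing_m, 5), collapse = ", ")))
  }
  calls <- g$calls[ai, mi, drop = FALSE]
  keep <- match(colnames(calls), g$map$marker)
  map <- g$map[keep, , drop = FALSE]
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  calls <- calls[, as.character(map$marker), drop = FALSE]
  quality <- if (is.null(g$quality)) NULL else g$quality[ai, mi, drop = FALSE][, as.character(map$marker), drop = FALSE]
  genotype_data(calls, map, quality)
}

#' Read SNP genotypes
#'
#' Two plain-text dialects are supported:
#' * `"ped"`: PLINK-1 text `.ped`/`.map` pair (white-space separated, two
#'   allele columns per marker, alleles A/C/G/T and `0` for missing). The
#'   dosage counts the lexicographically later of the two alleles observed
#'   at each marker, so an `A`/`C` marker yields the number of `C` alleles.
#' * `"dosage"`: a TSV with a header row `animal` followed by marker IDs and
#'   one row per animal of dosages (`NA` for missing), plus a PLINK `.map`
#'   sidecar.
#'
#' @param path For `"ped"`, the `.ped` file; for `"dosage"`, the TSV.
#' @param format `"ped"` or `"dosage"`.
#' @param map_path Path to the PLINK `.map` file (chromosome, marker ID,
#'   genetic distance, bp). Defaults to `path` with its extension replaced
#'   by `.map`.
#' @return A [genotype_data()] object.
#' @export
read_genotypes <- function(path, format = c("ped", "dosage"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  map_path <- map_path %||% sub("\\.[^.]*$", ".map", path)
  if (!file.exists(map_path)) abort(paste0("Map file not found: ", map_path))
  map_raw <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4) abort("Malformed .map: expected 4 columns (chrom, marker, cM, bp).")
  map <- tibble::tibble(
    marker = as.character(map_raw[[2]]),
    chrom = as.integer(map_raw[[1]]),
    pos = as.integer(map_raw[[4]])
  )
  if (format == "ped") {
    read_ped(path, map)
  } else {
    read_dosage_tsv(path, map)
  }
}

read_ped <- function(path, map) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- nrow(map)
  ids <- character(length(lines))
  calls <- matrix(NA_real_, length(lines), m)
  allele_tab <- vector("list", m)
  raw <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      abort(sprintf("Malformed .ped line %d: expected %d fields, found %d.",
                    i, 6 + 2 * m, length(f)))
    }
    ids[i] <- f[2]
    al <- f[-(1:6)]
    bad <- !al %in% c("A", "C", "G", "T", "0")
    if (any(bad)) {
      abort(sprintf("Malformed .ped line %d: invalid allele code '%s'.", i, al[which(bad)[1]]))
    }
    raw[[i]] <- al
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate animal ID in .ped: ", ids[duplicated(ids)][1]))
  }
  a1 <- do.call(rbind, lapply(raw, function(al) al[seq(1, 2 * m, by = 2)]))
  a2 <- do.call(rbind, lapply(raw, function(al) al[seq(2, 2 * m, by = 2)]))
  for (j in seq_len(m)) {
    obs <- setdiff(unique(c(a1[, j], a2[, j])), "0")
    if (length(obs) > 2) {
      abort(sprintf("Marker %s has more than two alleles.", map$marker[j]))
    }
    counted <- if (length(obs)) sort(obs)[length(obs)] else NA_character_
    miss <- a1[, j] == "0" | a2[, j] == "0"
    if (!is.na(counted)) {
      calls[, j] <- (a1[, j] == counted) + (a2[, j] == counted)
    } else {
      calls[, j] <- 0
    }
    calls[miss, j] <- NA_real_
  }
  rownames(calls) <- ids
  colnames(calls) <- map$marker
  o <- order(map$chrom, map$pos)
  genotype_data(calls[, o, drop = FALSE], map[o, ], NULL)
}

read_dosage_tsv <- function(path, map) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(dat)[1] != "animal") abort("Dosage TSV must start with an `animal` column.")
  ids <- as.character(dat[[1]])
  if (anyDuplicated(ids)) abort(paste0("Duplicate animal ID: ", ids[duplicated(ids)][1]))
  calls <- as.matrix(dat[, -1, drop = FALSE])
  mode(calls) <- "numeric"
  rownames(calls) <- ids
  common <- intersect(map$marker, colnames(calls))
  if (!setequal(colnames(calls), map$marker)) {
    abort("Dosage TSV markers do not match the map.")
  }
  o <- order(map$chrom, map$pos)
  map <- map[o, ]
  genotype_data(calls[, as.character(map$marker), drop = FALSE], map, NULL)
}

#' Write SNP genotypes
#'
#' Inverse of [read_genotypes()]. In `"ped"` format dosages 0/1/2 are coded
#' `A A` / `A C` / `C C` and missing calls `0 0`; real-valued (imputed)
#' dosages cannot be represented and raise an error. Quality scores are not
#' persisted by either dialect.
#'
#' @param g A [genotype_data()] object.
#' @param path Output `.ped` or `.tsv` file; the `.map` sidecar is written
#'   next to it.
#' @param format `"ped"` or `"dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("ped", "dosage")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "vs_geno"))
  map_path <- sub("\\.[^.]*$", ".map", path)
  map_out <- data.frame(g$map$chrom, g$map$marker, 0, g$map$pos)
  utils::write.table(map_out, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (format == "ped") {
    if (any(g$calls %% 1 != 0, na.rm = TRUE)) {
      abort("Real-valued dosages cannot be written as .ped; use format = 'dosage'.")
    }
    n <- nrow(g$calls)
    out <- character(n)
    code <- c("A A", "A C", "C C")
    for (i in seq_len(n)) {
      d <- g$calls[i, ]
      al <- ifelse(is.na(d), "0 0", code[d + 1])
      out[i] <- paste(c("FAM", rownames(g$calls)[i], "0", "0", "0", "-9", al),
                      collapse = " ")
    }
    writeLines(out, path)
  } else {
    dat <- data.frame(animal = rownames(g$calls), g$calls, check.names = FALSE)
    utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a pedigree file
#'
#' CSV with columns `animal,sire,dam`; `0`, empty or `NA` parent fields mark
#' unknown (founder) parents.
#'
#' @param path CSV file path.
#' @return A tibble with character columns `animal`, `sire`, `dam` (`NA` =
#'   unknown parent).
#' @export
read_pedigree <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("animal", "sire", "dam") %in% names(dat))) {
    abort("Pedigree CSV needs columns animal, sire, dam.")
  }
  clean <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  tibble::tibble(
    animal = trimws(dat$animal),
    sire = clean(dat$sire),
    dam = clean(dat$dam)
  )
}

#' Read a phenotype file
#'
#' CSV with named columns `animal, breed, line, cg, litter, bw, vh, vw`
#' and optionally `va`. Factors are read as character, measurements as
#' numeric.
#'
#' @param path CSV file path.
#' @return A tibble, one row per animal record.
#' @export
read_phenotypes <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal", "breed", "line", "cg", "litter", "bw", "vh", "vw")
  miss <- setdiff(req, names(dat))
  if (length(miss)) abort(paste0("Phenotype CSV missing column(s): ", paste(miss, collapse = ", ")))
  out <- tibble::as_tibble(dat)
  out$animal <- as.character(out$animal)
  out$line <- as.character(out$line)
  out$cg <- as.character(out$cg)
  out$litter <- as.character(out$litter)
  out
}
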