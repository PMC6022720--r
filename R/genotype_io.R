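# PED/MAP genotype input: parsing, haploid collapse of diploid-encoded mtDNA
# calls, and marker call-rate QC.

MITO_CHROM_CODES <- c("26", "MT", "M")

#' Read a PED/MAP genotype file pair
#'
#' Parses a whitespace-delimited MAP file (chrom, marker name, genetic
#' distance, bp position) and its companion PED file (FID, IID, PAT, MAT,
#' SEX, PHENO, then two allele tokens per MAP marker). mtDNA is haploid, so
#' the diploid-encoded allele pair of each call is collapsed with
#' [collapse_diploid()]: equal tokens give the allele, `0 0` gives missing,
#' and discordant non-zero pairs (heteroplasmy-like) give missing with a
#' warning.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return An object of class `mito_genotypes`: a list with `map` (data
#'   frame: `chrom`, `name`, `cm`, `position`), `fam` (data frame: `fid`,
#'   `iid`, `pat`, `mat`, `sex`, `pheno`), and `calls` (character matrix,
#'   samples x markers, `NA` = missing; columns in MAP order, named by
#'   marker).
#' @export
read_ped_map <- function(ped_path, map_path) {
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  map <- read_map(map_path)
  n_markers <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file '", ped_path, "' contains no samples",
                           call. = FALSE)
  expected <- 6L + 2L * n_markers

  fam <- vector("list", length(lines))
  calls <- matrix(NA_character_, nrow = length(lines), ncol = n_markers,
                  dimnames = list(NULL, map$name))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != expected) {
      stop("PED line ", i, ": found ", length(tok), " fields, expected ",
           expected, " (6 + 2 × ", n_markers, " markers)", call. = FALSE)
    }
    fam[[i]] <- tok[1:6]
    a1 <- toupper(tok[seq(7L, by = 2L, length.out = n_markers)])
    a2 <- toupper(tok[seq(8L, by = 2L, length.out = n_markers)])
    bad <- !(a1 %in% c("A", "C", "G", "T", "0")) |
           !(a2 %in% c("A", "C", "G", "T", "0"))
    if (any(bad)) {
      stop("PED line ", i, ": invalid allele token(s) at marker(s) ",
           paste(map$name[bad], collapse = ", "),
           " (alleles must be A/C/G/T or 0)", call. = FALSE)
    }
    disc <- a1 != a2 & a1 != "0" & a2 != "0"
    if (any(disc)) {
      warning("PED line ", i, " (sample ", tok[2], "): discordant allele ",
              "pair(s) treated as missing at ",
              paste(map$name[disc], collapse = ", "), call. = FALSE)
    }
    calls[i, ] <- collapse_diploid(a1, a2, warn = FALSE)
  }
  fam <- as.data.frame(do.call(rbind, fam), stringsAsFactors = FALSE)
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  key <- paste(fam$fid, fam$iid)
  if (anyDuplicated(key)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  rownames(calls) <- fam$iid

  structure(list(map = map, fam = fam, calls = calls),
            class = "mito_genotypes")
}

read_map <- function(map_path) {
  lines <- readLines(map_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("MAP file '", map_path, "' is empty",
                           call. = FALSE)
  rows <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(rows) != 4L)
  if (length(bad)) {
    stop("MAP line ", bad[1], ": found ", length(rows[[bad[1]]]),
         " fields, expected 4 (chrom, name, cM, bp)", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  pos <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(pos)) {
    stop("MAP line ", which(is.na(pos))[1], ": position '",
         m[which(is.na(pos))[1], 4], "' is not an integer", call. = FALSE)
  }
  data.frame(chrom = m[, 1], name = m[, 2],
             cm = suppressWarnings(as.numeric(m[, 3])), position = pos,
             stringsAsFactors = FALSE)
}

#' Collapse a diploid-encoded allele pair to a haploid mtDNA call
#'
#' @param allele1,allele2 Character vectors of allele tokens in
#'   `A`/`C`/`G`/`T`/`0` (case-insensitive; `0` = missing).
#' @param warn Warn on discordant non-zero pairs (default `TRUE`).
#' @return Character vector: the shared allele, or `NA` for `0 0` and for
#'   discordant pairs.
#' @export
collapse_diploid <- function(allele1, allele2, warn = TRUE) {
  a1 <- toupper(as.character(allele1))
  a2 <- toupper(as.character(allele2))
  valid <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% valid) || !all(a2 %in% valid)) {
    stop("invalid allele token(s): ",
         paste(unique(c(a1, a2)[!(c(a1, a2) %in% valid)]), collapse = ", "),
         call. = FALSE)
  }
  out <- ifelse(a1 == a2 & a1 != "0", a1, NA_character_)
  disc <- a1 != a2 & a1 != "0" & a2 != "0"
  if (warn && any(disc)) {
    warning(sum(disc), " discordant allele pair(s) treated as missing",
            call. = FALSE)
  }
  out
}

#' Filter markers by genotyping call rate
#'
#' A marker is retained iff its call rate — the fraction of samples with a
#' non-missing call — is greater than or equal to `threshold` (inclusive
#' boundary). Per-sample calls at retained markers are never altered.
#'
#' @param geno A `mito_genotypes` object.
#' @param threshold Minimum call rate in \[0, 1\]; default 0.90.
#' @return A list with `geno` (the filtered `mito_genotypes`), `dropped`
#'   (character vector of dropped marker names), and `call_rate` (named
#'   numeric vector over all input markers).
#' @export
filter_by_call_rate <- function(geno, threshold = 0.90) {
  stopifnot(inherits(geno, "mito_genotypes"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("'threshold' must be a single number in [0, 1]", call. = FALSE)
  }
  if (nrow(geno$calls) == 0L) {
    stop("cannot compute call rates from an empty sample set", call. = FALSE)
  }
  rate <- colMeans(!is.na(geno$calls))
  keep <- rate >= threshold
  dropped <- geno$map$name[!keep]
  geno$map <- geno$map[keep, , drop = FALSE]
  rownames(geno$map) <- NULL
  geno$calls <- geno$calls[, keep, drop = FALSE]
  list(geno = geno, dropped = dropped, call_rate = rate)
}

#' Write a `mito_genotypes` object as a PED/MAP file pair
#'
#' Haploid calls are emitted as homozygous diploid pairs (`A A`), missing
#' calls as `0 0`, per PED convention. Reading the files back with
#' [read_ped_map()] recovers the object exactly (round-trip identity).
#'
#' @param geno A `mito_genotypes` object.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_ped_map <- function(geno, ped_path, map_path) {
  stopifnot(inherits(geno, "mito_genotypes"))
  write_map_file(geno$map, map_path)
  a <- geno$calls
  a[is.na(a)] <- "0"
  write_ped_file(geno$fam, a, a, ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

write_map_file <- function(map, map_path) {
  writeLines(paste(map$chrom, map$name, map$cm, map$position, sep = "\t"),
             map_path)
}

write_ped_file <- function(fam, a1, a2, ped_path) {
  n_markers <- ncol(a1)
  geno_cols <- matrix(NA_character_, nrow = nrow(a1), ncol = 2L * n_markers)
  if (n_markers) {
    geno_cols[, seq(1L, by = 2L, length.out = n_markers)] <- a1
    geno_cols[, seq(2L, by = 2L, length.out = n_markers)] <- a2
  }
  lines <- vapply(seq_len(nrow(fam)), function(i) {
    paste(c(fam$fid[i], fam$iid[i], fam$pat[i], fam$mat[i], fam$sex[i],
            fam$pheno[i], geno_cols[i, ]), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
}

# Calls matrix keyed by rCRS position rather than marker name. Marker <->
# panel joining is by position (the coordinate contract); names are used
# only for reporting. Non-mitochondrial chromosome codes trigger a warning.
calls_by_position <- function(geno) {
  stopifnot(inherits(geno, "mito_genotypes"))
  non_mito <- !(toupper(geno$map$chrom) %in% MITO_CHROM_CODES)
  if (any(non_mito)) {
    warning("marker(s) with non-mitochondrial chromosome code used in ",
            "classification: ",
            paste(geno$map$name[non_mito], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(geno$map$position)) {
    stop("duplicate marker position(s) in MAP: ",
         paste(unique(geno$map$position[duplicated(geno$map$position)]),
               collapse = ", "), call. = FALSE)
  }
  calls <- geno$calls
  colnames(calls) <- as.character(geno$map$position)
  calls
}

#' @export
print.mito_genotypes <- function(x, ...) {
  cat("mtDNA panel genotypes:", nrow(x$calls), "samples x",
      nrow(x$map), "markers\n")
  cat("  missing calls:", sum(is.na(x$calls)), "of", length(x$calls), "\n")
  invisible(x)
}
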