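# Ground-truth-labelled synthetic panel genotypes: samples drawn down the
# haplogroup tree, with configurable missingness, discordant-call noise, and
# pedigree trios (children copy the maternal haplotype).

#' Perfect panel genotypes for one haplogroup
#'
#' Emits the cumulative required alleles for the label (descendant-override
#' semantics at reversion positions) and the panel's ancestral allele at
#' every other panel position; no call is missing. Classifying this vector
#' recovers exactly the label (closure property).
#'
#' @param tree A `haplogroup_tree`.
#' @param label Haplogroup label in the tree.
#' @return Named character vector of haploid calls over all panel positions.
#' @export
genotypes_for_haplogroup <- function(tree, label) {
  lookup_node(tree, label)
  calls <- tree$panel$ancestral
  names(calls) <- as.character(tree$panel$position)
  cum <- required_genotypes_cumulative(tree, label)
  calls[as.character(cum$position)] <- cum$allele
  calls
}

#' Simulate a ground-truth-labelled panel genotype dataset
#'
#' Haplogroups are drawn for each founder from `haplogroup_weights` (default:
#' uniform over the tree's terminal haplogroups), the corresponding perfect
#' genotype vectors are emitted, and noise is injected per call,
#' independently: with probability `missing_rate` a call becomes `0 0`; with
#' probability `discordant_rate` a surviving call becomes a discordant
#' diploid pair (heteroplasmy-like), which collapses to missing on read. The
#' first `3 * n_trios` samples form mother/father/child trios; the child
#' carries the mother's haplotype and haplogroup, mirroring matrilineal
#' inheritance, with PAT/MAT pedigree columns populated so founder filtering
#' is testable. An optional `knockout_markers` list of positions is set to
#' missing in every sample, emulating marker-correlated assay failure.
#'
#' @param tree A `haplogroup_tree`.
#' @param n_samples Number of samples.
#' @param haplogroup_weights Optional named non-negative weights over tree
#'   labels; sampling is proportional to weight.
#' @param missing_rate,discordant_rate Per-call noise probabilities in
#'   \[0, 1\].
#' @param n_trios Number of mother/father/child trios (requires
#'   `3 * n_trios <= n_samples`); remaining samples are unrelated founders.
#' @param knockout_markers Integer vector of rCRS positions forced missing in
#'   all samples.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `mito_simulation`: list with `geno` (a
#'   `mito_genotypes` of the collapsed haploid calls), `a1`/`a2` (the
#'   diploid-encoded allele token matrices actually written to PED), and
#'   `truth` (data frame `sample_id`, `haplogroup`).
#' @export
simulate_dataset <- function(tree, n_samples, haplogroup_weights = NULL,
                             missing_rate = 0, discordant_rate = 0,
                             n_trios = 0L, knockout_markers = integer(),
                             seed = 1L) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("'n_samples' must be a positive integer", call. = FALSE)
  }
  for (r in c(missing_rate, discordant_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop("noise rates must lie in [0, 1]", call. = FALSE)
    }
  }
  n_samples <- as.integer(n_samples)
  n_trios <- as.integer(n_trios)
  if (n_trios < 0 || 3L * n_trios > n_samples) {
    stop("'n_trios' requires 3 * n_trios <= n_samples", call. = FALSE)
  }

  labels <- names(haplogroup_weights)
  if (is.null(haplogroup_weights)) {
    labels <- terminal_haplogroups(tree)
    weights <- rep(1, length(labels))
  } else {
    weights <- as.numeric(haplogroup_weights)
    unknown <- setdiff(labels, tree$order)
    if (length(unknown)) {
      stop("unknown haplogroup label(s) in weights: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(weights < 0) || sum(weights) <= 0) {
      stop("haplogroup weights must be non-negative with positive sum",
           call. = FALSE)
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  positions <- tree$panel$position
  n_markers <- length(positions)

  fid <- iid <- pat <- mat <- sex <- truth_label <- character(n_samples)
  pheno <- rep("-9", n_samples)
  haplo <- matrix(NA_character_, n_samples, n_markers)

  draw <- function(n) {
    labels[sample.int(length(labels), n, replace = TRUE, prob = weights)]
  }

  i <- 1L
  for (t in seq_len(n_trios)) {
    fam <- sprintf("FAM%03d", t)
    ids <- sprintf("IND%04d", i:(i + 2L))
    mother <- draw(1L)
    father <- draw(1L)
    fid[i:(i + 2L)] <- fam
    iid[i:(i + 2L)] <- ids
    pat[i:(i + 2L)] <- c("0", "0", ids[2])
    mat[i:(i + 2L)] <- c("0", "0", ids[1])
    sex[i:(i + 2L)] <- c("2", "1", sample(c("1", "2"), 1L))
    truth_label[i:(i + 2L)] <- c(mother, father, mother)
    haplo[i, ] <- genotypes_for_haplogroup(tree, mother)
    haplo[i + 1L, ] <- genotypes_for_haplogroup(tree, father)
    haplo[i + 2L, ] <- haplo[i, ]  # child copies the maternal haplotype
    i <- i + 3L
  }
  if (i <= n_samples) {
    idx <- i:n_samples
    fid[idx] <- sprintf("FAM%03d", n_trios + seq_along(idx))
    iid[idx] <- sprintf("IND%04d", idx)
    pat[idx] <- "0"
    mat[idx] <- "0"
    sex[idx] <- sample(c("1", "2"), length(idx), replace = TRUE)
    truth_label[idx] <- draw(length(idx))
    for (k in idx) haplo[k, ] <- genotypes_for_haplogroup(tree, truth_label[k])
  }

  a1 <- a2 <- haplo
  miss <- matrix(stats::runif(n_samples * n_markers) < missing_rate,
                 n_samples, n_markers)
  if (length(knockout_markers)) {
    miss[, positions %in% as.integer(knockout_markers)] <- TRUE
  }
  disc <- !miss &
    matrix(stats::runif(n_samples * n_markers) < discordant_rate,
           n_samples, n_markers)
  a1[miss] <- "0"
  a2[miss] <- "0"
  if (any(disc)) {
    bases <- c("A", "C", "G", "T")
    cur <- a2[disc]
    a2[disc] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                       character(1))
  }

  calls <- haplo
  calls[miss | disc] <- NA_character_
  rownames(calls) <- iid
  map <- data.frame(chrom = "MT", name = tree$panel$name, cm = 0,
                    position = positions, stringsAsFactors = FALSE)
  colnames(calls) <- map$name
  fam <- data.frame(fid = fid, iid = iid, pat = pat, mat = mat, sex = sex,
                    pheno = pheno, stringsAsFactors = FALSE)
  geno <- structure(list(map = map, fam = fam, calls = calls),
                    class = "mito_genotypes")
  structure(
    list(geno = geno, a1 = a1, a2 = a2,
         truth = data.frame(sample_id = iid, haplogroup = truth_label,
                            stringsAsFactors = FALSE)),
    class = "mito_simulation"
  )
}

#' In-memory genotypes of a simulated dataset
#' @param sim A `mito_simulation`.
#' @return The `mito_genotypes` object (discordant pairs already collapsed to
#'   missing, matching what [read_ped_map()] recovers from the fixture).
#' @export
simulated_genotypes <- function(sim) {
  stopifnot(inherits(sim, "mito_simulation"))
  sim$geno
}

#' Write a simulated dataset as PED/MAP fixture files
#'
#' Emits the diploid-encoded pairs: haploid calls as homozygous `A A` pairs,
#' missing calls as `0 0`, injected discordant calls as mismatched pairs.
#' Reading the pair back with [read_ped_map()] yields genotypes identical to
#' [simulated_genotypes()].
#'
#' @param sim A `mito_simulation`.
#' @param ped_path,map_path Output PED and MAP paths.
#' @param truth_path Optional path for the two-column ground-truth CSV
#'   (`sample_id`, `haplogroup`).
#' @return Invisibly, a list of the written paths.
#' @export
write_fixture <- function(sim, ped_path, map_path, truth_path = NULL) {
  stopifnot(inherits(sim, "mito_simulation"))
  write_map_file(sim$geno$map, map_path)
  write_ped_file(sim$geno$fam, sim$a1, sim$a2, ped_path)
  if (!is.null(truth_path)) {
    utils::write.csv(sim$truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(ped = ped_path, map = map_path, truth = truth_path))
}

#' @export
print.mito_simulation <- function(x, ...) {
  cat("simulated mtDNA panel dataset:", nrow(x$geno$calls), "samples x",
      nrow(x$geno$map), "markers\n")
  tab <- sort(table(x$truth$haplogroup), decreasing = TRUE)
  cat("  truth haplogroups:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
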