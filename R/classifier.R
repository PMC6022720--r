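# Haplogroup assignment: recursive tree descent collecting satisfied nodes
# into an accumulator, then ranking by root-to-node path length.

#' Does a sample meet a single node's own genotype requirements?
#'
#' True iff, for every (position, allele) the node requires, the sample's
#' call at that position equals the required allele. A missing or mismatching
#' call at any required position fails the node: missingness is never treated
#' as evidence.
#'
#' @param tree A `haplogroup_tree`.
#' @param node_name Haplogroup label in the tree.
#' @param calls Named character vector of haploid calls; names are rCRS
#'   positions, values `A`/`C`/`G`/`T` or `NA` (missing).
#' @return Single logical.
#' @export
node_satisfied <- function(tree, node_name, calls) {
  node <- lookup_node(tree, node_name)
  req <- node$requires
  if (!nrow(req)) return(TRUE)
  obs <- unname(calls[as.character(req$position)])
  all(!is.na(obs) & toupper(obs) == req$allele)
}

#' Classify one sample's panel genotypes into a haplogroup
#'
#' Implements the two-step assignment. Step 1: the sample's genotypes are
#' passed into the root and carried down the tree; each node whose cumulative
#' genotype requirements (root-to-node, with descendant-overrides for
#' reversions) are fully met is added to an accumulator, and a subtree is
#' abandoned once some required position mismatches with no chance of a
#' reversion deeper down. Step 2: accumulated haplogroups are ranked by their
#' distance from the root and every haplogroup shallower than the deepest one
#' is dropped ([rank_accumulator()]). A longer path means more SNPs checked,
#' hence a more specific call. If nothing beyond the root is satisfied the
#' sample is `unclassified`.
#'
#' @inheritParams node_satisfied
#' @param sample_id Optional sample identifier carried into the result.
#' @return An object of class `haplo_call`: list with `sample_id`,
#'   `haplogroups` (character; empty when unclassified, >1 only on unresolved
#'   ties at maximal depth), `paths` (list of root-to-node label vectors, one
#'   per reported haplogroup), `status` (`"classified"` or
#'   `"unclassified"`), `accumulator` (all satisfied labels, visit order),
#'   and `missing_required` (panel positions that are missing in the sample
#'   and appear in some node requirement — the diagnostic for failure
#'   analysis).
#' @export
classify_sample <- function(tree, calls, sample_id = NA_character_) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  calls <- normalize_calls(tree, calls)

  acc <- character()
  walk <- function(name, eff_pos, eff_allele) {
    node <- tree$nodes[[name]]
    req <- node$requires
    for (j in seq_len(nrow(req))) {
      k <- match(req$position[j], eff_pos)
      if (is.na(k)) {
        eff_pos <- c(eff_pos, req$position[j])
        eff_allele <- c(eff_allele, req$allele[j])
      } else {
        eff_allele[k] <- req$allele[j]  # reversion: descendant wins
      }
    }
    obs <- unname(calls[as.character(eff_pos)])
    bad <- eff_pos[is.na(obs) | obs != eff_allele]
    if (!length(bad)) acc <<- c(acc, name)
    for (ch in node$children) {
      # descend only where every mismatched position could still be
      # overridden (required again) somewhere in the child's subtree
      if (!length(bad) || all(bad %in% tree$subtree_positions[[ch]])) {
        walk(ch, eff_pos, eff_allele)
      }
    }
  }
  walk(tree$root, integer(), character())

  top <- rank_accumulator(tree, acc)
  top <- setdiff(top, tree$root)
  miss <- intersect(tree$all_required_positions,
                    as.integer(names(calls)[is.na(calls)]))
  structure(
    list(sample_id = sample_id,
         haplogroups = top,
         paths = lapply(top, function(h) path_to_root(tree, h)),
         status = if (length(top)) "classified" else "unclassified",
         accumulator = acc,
         missing_required = miss),
    class = "haplo_call"
  )
}

# Restrict calls to the panel's usable (non-blacklisted) positions,
# uppercase, and pad positions absent from the data with NA.
normalize_calls <- function(tree, calls) {
  if (is.null(names(calls))) {
    stop("'calls' must be a named vector (names = rCRS positions)",
         call. = FALSE)
  }
  usable <- tree$panel$position[!tree$panel$blacklisted]
  out <- rep(NA_character_, length(usable))
  names(out) <- as.character(usable)
  hit <- intersect(names(out), names(calls))
  out[hit] <- toupper(as.character(calls[hit]))
  out[!(out %in% c("A", "C", "G", "T"))] <- NA_character_
  out
}

#' Rank accumulated haplogroups by distance from the root
#'
#' Keeps exactly the labels whose depth equals the maximum depth among the
#' accumulated labels; everything with a shorter root-to-node path is
#' dropped. Output order is deterministic (tree-definition order).
#'
#' @param tree A `haplogroup_tree`.
#' @param accumulated Character vector of labels present in the tree.
#' @return Character vector of maximal-depth labels.
#' @export
rank_accumulator <- function(tree, accumulated) {
  if (!length(accumulated)) return(character())
  unknown <- setdiff(accumulated, tree$order)
  if (length(unknown)) {
    stop("unknown haplogroup label(s) in accumulator: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  depths <- tree$depth[accumulated]
  top <- accumulated[depths == max(depths)]
  top[order(match(top, tree$order))]
}

#' Classify every sample of a dataset
#'
#' Batch wrapper around [classify_sample()]: one result row per sample, in
#' input order. QC-blacklisted panel markers are excluded from
#' classification regardless of their observed call rate.
#'
#' @param tree A `haplogroup_tree`.
#' @param geno A `mito_genotypes` object ([read_ped_map()],
#'   [simulated_genotypes()]), or a character matrix of haploid calls
#'   (samples x positions, columns named by rCRS position, `NA` = missing).
#' @return Data frame with one row per sample: `sample_id`, `haplogroup`
#'   (`;`-joined on ties, `""` when unclassified), `path` (root-to-node
#'   labels joined by `" -> "`), `status`, `n_missing_required`.
#' @export
classify_dataset <- function(tree, geno) {
  if (inherits(geno, "mito_genotypes")) {
    calls <- calls_by_position(geno)
  } else if (is.matrix(geno)) {
    calls <- geno
  } else {
    stop("'geno' must be a mito_genotypes object or a calls matrix",
         call. = FALSE)
  }
  ids <- rownames(calls)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(calls)))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    res <- classify_sample(tree, calls[i, ], sample_id = ids[i])
    data.frame(
      sample_id = ids[i],
      haplogroup = paste(res$haplogroups, collapse = ";"),
      path = paste(vapply(res$paths, paste, character(1), collapse = " -> "),
                   collapse = ";"),
      status = res$status,
      n_missing_required = length(res$missing_required),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(), haplogroup = character(),
               path = character(), status = character(),
               n_missing_required = integer(), stringsAsFactors = FALSE)
  }
  message("classified ", sum(out$status == "classified"), " of ", nrow(out),
          " samples (", sum(out$status == "unclassified"), " unclassified)")
  out
}

#' @export
print.haplo_call <- function(x, ...) {
  cat("sample:", x$sample_id, "\n")
  if (x$status == "classified") {
    cat("haplogroup:", paste(x$haplogroups, collapse = ";"), "\n")
    for (p in x$paths) cat("path:", paste(p, collapse = " -> "), "\n")
  } else {
    cat("haplogroup: unclassified\n")
  }
  if (length(x$missing_required)) {
    cat("missing required positions:",
        paste(x$missing_required, collapse = ", "), "\n")
  }
  invisible(x)
}
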