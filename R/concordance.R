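# Pairwise comparison of haplogroup call sets (unclassified exclusion,
# finer-resolution equivalence) and founder-only frequency summaries.

EXCLUDED_LABELS <- c("unclassified", "unknown")

#' Are two haplogroup labels concordant?
#'
#' Labels are concordant when they name the same haplogroup, even if one
#' method resolved it more finely: `A2` vs `A2x` is concordant. Three rules
#' apply in order: (1) equality after normalization (case-insensitive,
#' trimmed); (2) when both labels are nodes of the reduced tree, concordance
#' iff one lies on the other's root-to-node path (handles `JT` vs `J`,
#' `L3` vs `L3e`); (3) a string fallback for labels outside the tree: the
#' longer label must start with the shorter one AND the first extra
#' character must continue the letter/number alternation of haplogroup
#' nomenclature (so `A2`/`A2x` match but `H`/`HV` do not).
#'
#' @param label_a,label_b Non-empty haplogroup labels; neither may be
#'   `"unclassified"` (callers exclude those first).
#' @param tree A `haplogroup_tree` used for the path rule.
#' @return Single logical; symmetric in the two labels.
#' @export
is_concordant <- function(label_a, label_b, tree) {
  a <- normalize_label(label_a)
  b <- normalize_label(label_b)
  if (!nzchar(a) || !nzchar(b)) {
    stop("haplogroup labels must be non-empty", call. = FALSE)
  }
  if (a == b) return(TRUE)

  tree_labels <- toupper(tree$order)
  ia <- match(a, tree_labels)
  ib <- match(b, tree_labels)
  if (!is.na(ia) && !is.na(ib)) {
    na <- tree$order[ia]
    nb <- tree$order[ib]
    return(na %in% path_to_root(tree, nb) || nb %in% path_to_root(tree, na))
  }

  label_extends(a, b) || label_extends(b, a)
}

normalize_label <- function(x) toupper(trimws(as.character(x)))

# "A2X" extends "A2": prefix match plus the first extra character switching
# character class (digit after letter, letter after digit), per the
# alternating letter/number haplogroup nomenclature. Prevents "H" from
# matching "HV".
label_extends <- function(longer, shorter) {
  nl <- nchar(longer)
  ns <- nchar(shorter)
  if (nl <= ns || substr(longer, 1L, ns) != shorter) return(FALSE)
  last <- substr(shorter, ns, ns)
  nxt <- substr(longer, ns + 1L, ns + 1L)
  is_digit <- function(ch) grepl("^[0-9]$", ch)
  is_digit(last) != is_digit(nxt)
}

#' Concordance between two haplogroup call sets
#'
#' Samples present in both call sets are compared with [is_concordant()].
#' Any shared sample labelled `unclassified` (or `unknown`) in either call
#' set is removed from the calculation first and counted in
#' `n_excluded_unclassified`.
#'
#' @param a,b Call sets: named character vectors (names = sample ids) or
#'   two-column data frames (`sample_id`, `haplogroup`), e.g. from
#'   [read_callset()].
#' @param tree A `haplogroup_tree`.
#' @return An object of class `concordance_report`: list with `n_shared`,
#'   `n_excluded_unclassified`, `n_compared`, `n_concordant`,
#'   `percent_concordant` (= 100 * n_concordant / n_compared), and
#'   `discordant` (data frame `sample_id`, `label_a`, `label_b`).
#' @export
concordance_table <- function(a, b, tree) {
  a <- as_callset(a)
  b <- as_callset(b)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) {
    stop("the two call sets share no sample ids", call. = FALSE)
  }
  la <- a[shared]
  lb <- b[shared]
  excluded <- is.na(la) | is.na(lb) |
    tolower(trimws(la)) %in% EXCLUDED_LABELS |
    tolower(trimws(lb)) %in% EXCLUDED_LABELS
  cmp <- shared[!excluded]
  if (!length(cmp)) {
    stop("no comparable samples: every shared sample is unclassified",
         call. = FALSE)
  }
  conc <- vapply(cmp, function(s) is_concordant(la[[s]], lb[[s]], tree),
                 logical(1))
  structure(
    list(n_shared = length(shared),
         n_excluded_unclassified = sum(excluded),
         n_compared = length(cmp),
         n_concordant = sum(conc),
         percent_concordant = 100 * sum(conc) / length(cmp),
         discordant = data.frame(sample_id = cmp[!conc],
                                 label_a = unname(la[cmp[!conc]]),
                                 label_b = unname(lb[cmp[!conc]]),
                                 stringsAsFactors = FALSE)),
    class = "concordance_report"
  )
}

as_callset <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      stop("a call set data frame needs columns sample_id and haplogroup",
           call. = FALSE)
    }
    out <- as.character(x[[2]])
    names(out) <- as.character(x[[1]])
    return(out)
  }
  if (is.null(names(x))) {
    stop("a call set vector must be named by sample id", call. = FALSE)
  }
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Read a haplogroup call-set CSV
#'
#' Two columns with header: `sample_id`, `haplogroup`. External tools may
#' emit labels outside the reduced tree (e.g. `A2x`); they are kept verbatim.
#'
#' @param path CSV path.
#' @param source Optional source name attached as an attribute.
#' @return Named character vector of haplogroup labels.
#' @export
read_callset <- function(path, source = path) {
  if (!file.exists(path)) stop("call-set file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- as_callset(df)
  attr(out, "source") <- source
  out
}

#' Haplogroup and lineage frequency distributions
#'
#' Frequencies of assigned haplogroups over a classified dataset, and their
#' aggregation into continental lineages via the tree's per-node lineage
#' tags. mtDNA is matrilineal, so offspring carry their mother's haplogroup;
#' with `founders_only = TRUE` (the default) any sample whose maternal id
#' matches another sample's individual id within the same family is excluded
#' so that each maternal lineage is counted once. Unclassified samples are
#' excluded from the denominator. Ties (multi-label calls) contribute their
#' first, tree-order label.
#'
#' @param results Classification data frame from [classify_dataset()].
#' @param fam Pedigree data frame (`fid`, `iid`, `pat`, `mat`, ...), e.g.
#'   `geno$fam`.
#' @param tree A `haplogroup_tree`.
#' @param founders_only Exclude offspring (default `TRUE`). When all
#'   pedigree parent columns are `"0"` this is a no-op.
#' @return List with `haplogroup` (data frame `haplogroup`, `lineage`,
#'   `count`, `frequency`) and `lineage` (data frame `lineage`, `count`,
#'   `frequency`); each `frequency` column sums to 1 when non-empty.
#' @export
haplogroup_frequencies <- function(results, fam, tree, founders_only = TRUE) {
  if (!all(results$sample_id %in% fam$iid)) {
    stop("results contain sample ids absent from the pedigree", call. = FALSE)
  }
  keep <- results
  if (founders_only) {
    offspring <- vapply(seq_len(nrow(fam)), function(i) {
      fam$mat[i] != "0" &&
        any(fam$iid == fam$mat[i] & fam$fid == fam$fid[i])
    }, logical(1))
    if (!any(offspring) && all(fam$mat == "0") && all(fam$pat == "0")) {
      # nothing to do, but say so: pedigree carries no parent links
      message("founders_only: pedigree has no parent links; keeping all samples")
    }
    keep <- keep[!(keep$sample_id %in% fam$iid[offspring]), , drop = FALSE]
  }
  keep <- keep[keep$status == "classified" & nzchar(keep$haplogroup), ,
               drop = FALSE]
  if (!nrow(keep)) {
    warning("no classified samples; frequency distributions are empty",
            call. = FALSE)
    empty_h <- data.frame(haplogroup = character(), lineage = character(),
                          count = integer(), frequency = numeric(),
                          stringsAsFactors = FALSE)
    empty_l <- data.frame(lineage = character(), count = integer(),
                          frequency = numeric(), stringsAsFactors = FALSE)
    return(list(haplogroup = empty_h, lineage = empty_l))
  }
  label <- vapply(strsplit(keep$haplogroup, ";", fixed = TRUE), `[[`,
                  character(1), 1L)
  tab <- table(label)
  hg <- data.frame(haplogroup = names(tab),
                   count = as.integer(tab),
                   stringsAsFactors = FALSE)
  hg$lineage <- vapply(hg$haplogroup, function(h) {
    node <- tree$nodes[[h]]
    if (is.null(node)) NA_character_ else node$lineage
  }, character(1))
  hg$frequency <- hg$count / sum(hg$count)
  hg <- hg[order(match(hg$haplogroup, tree$order)),
           c("haplogroup", "lineage", "count", "frequency")]
  rownames(hg) <- NULL

  ltab <- tapply(hg$count, hg$lineage, sum)
  lin <- data.frame(lineage = names(ltab), count = as.integer(ltab),
                    stringsAsFactors = FALSE)
  lin$frequency <- lin$count / sum(lin$count)
  lin <- lin[order(-lin$count), ]
  rownames(lin) <- NULL
  list(haplogroup = hg, lineage = lin)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("haplogroup call-set concordance\n")
  cat("  shared samples:        ", x$n_shared, "\n")
  cat("  excluded unclassified: ", x$n_excluded_unclassified, "\n")
  cat("  compared:              ", x$n_compared, "\n")
  cat("  concordant:            ", x$n_concordant, "\n")
  cat(sprintf("  percent concordant:     %.1f\n", x$percent_concordant))
  if (nrow(x$discordant)) {
    cat("  discordant pairs:\n")
    for (i in seq_len(nrow(x$discordant))) {
      cat("    ", x$discordant$sample_id[i], ": ",
          x$discordant$label_a[i], " vs ", x$discordant$label_b[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}
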