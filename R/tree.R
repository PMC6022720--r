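# Reduced mitochondrial phylogeny and SNP panel: loading, validation,
# traversal. Positions are 1-based rCRS coordinates throughout.

RCRS_LENGTH <- 16569L

#' Load a haplogroup tree and SNP panel from a JSON configuration
#'
#' Reads a single JSON document holding the marker panel (`panel` array) and
#' the reduced phylogeny (`nodes` array), cross-references the two, and
#' validates the result. Every haplogroup node carries the set of
#' (position, allele) genotypes a sample must possess to belong to it;
#' back-mutations ("reversions", e.g. at rCRS position 10398) are encoded as
#' ordinary requirements that contradict an ancestor's requirement at the
#' same position, with descendant-overrides semantics.
#'
#' @param path Path to the JSON tree/panel configuration.
#' @param expected_nodes Optional integer; if given, validation fails unless
#'   the tree holds exactly this many non-root haplogroup nodes.
#' @return An object of class `haplogroup_tree`: a list with elements
#'   `panel` (data frame: `name`, `position`, `ancestral`, `derived`,
#'   `blacklisted`), `nodes` (named list of node records), `root` (root node
#'   name), and `order` (node names in definition order).
#' @seealso [default_tree()], [write_tree()], [path_to_root()],
#'   [required_genotypes_cumulative()]
#' @examples
#' tr <- default_tree()
#' tr
#' path_to_root(tr, "H")
#' @export
load_tree <- function(path, expected_nodes = NULL) {
  if (!file.exists(path)) {
    stop("tree configuration file not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse tree configuration '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(doc) || is.null(doc$panel) || is.null(doc$nodes)) {
    stop("tree configuration must contain 'panel' and 'nodes' arrays",
         call. = FALSE)
  }

  panel <- parse_panel(doc$panel)
  nodes <- parse_nodes(doc$nodes)

  tree <- structure(
    list(panel = panel, nodes = nodes$nodes, root = nodes$root,
         order = nodes$order),
    class = "haplogroup_tree"
  )
  validate_tree(tree, expected_nodes = expected_nodes)
}

parse_panel <- function(records) {
  if (length(records) == 0L) {
    return(data.frame(name = character(), position = integer(),
                      ancestral = character(), derived = character(),
                      blacklisted = logical(), stringsAsFactors = FALSE))
  }
  one <- function(i) {
    r <- records[[i]]
    for (f in c("name", "position", "ancestral", "derived")) {
      if (is.null(r[[f]])) {
        stop("panel record ", i, " is missing field '", f, "'", call. = FALSE)
      }
    }
    data.frame(name = as.character(r$name),
               position = as.integer(r$position),
               ancestral = toupper(as.character(r$ancestral)),
               derived = toupper(as.character(r$derived)),
               blacklisted = isTRUE(r$blacklist),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(records), one))
}

parse_nodes <- function(records) {
  if (length(records) == 0L) stop("tree has no nodes", call. = FALSE)
  nodes <- list()
  order <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$name)) {
      stop("node record ", i, " is missing field 'name'", call. = FALSE)
    }
    name <- as.character(r$name)
    if (!is.null(nodes[[name]])) {
      stop("duplicate node name '", name, "'", call. = FALSE)
    }
    req <- r$requires
    requires <- if (length(req)) {
      data.frame(
        position = vapply(req, function(q) as.integer(q$position), integer(1)),
        allele = vapply(req, function(q) toupper(as.character(q$allele)),
                        character(1)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(position = integer(), allele = character(),
                 stringsAsFactors = FALSE)
    }
    parent <- if (is.null(r$parent)) NA_character_ else as.character(r$parent)
    lineage <- if (is.null(r$lineage)) NA_character_ else as.character(r$lineage)
    nodes[[name]] <- list(name = name, parent = parent, lineage = lineage,
                          requires = requires, children = character())
    order[i] <- name
  }
  root <- NULL
  for (name in order) {
    p <- nodes[[name]]$parent
    if (is.na(p)) {
      if (!is.null(root)) {
        stop("multiple root nodes: '", root, "' and '", name, "'",
             call. = FALSE)
      }
      root <- name
    } else {
      if (is.null(nodes[[p]])) {
        stop("node '", name, "' references unknown parent '", p, "'",
             call. = FALSE)
      }
      nodes[[p]]$children <- c(nodes[[p]]$children, name)
    }
  }
  if (is.null(root)) stop("tree has no root node (all nodes have parents)",
                          call. = FALSE)
  list(nodes = nodes, root = root, order = order)
}

validate_tree <- function(tree, expected_nodes = NULL) {
  panel <- tree$panel
  if (anyDuplicated(panel$position)) {
    stop("panel positions are not unique: ",
         paste(unique(panel$position[duplicated(panel$position)]),
               collapse = ", "), call. = FALSE)
  }
  bad_pos <- panel$position < 1L | panel$position > RCRS_LENGTH
  if (any(bad_pos)) {
    stop("panel positions outside the rCRS [1, ", RCRS_LENGTH, "]: ",
         paste(panel$position[bad_pos], collapse = ", "), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  ok_alleles <- panel$ancestral %in% bases & panel$derived %in% bases &
    panel$ancestral != panel$derived
  if (!all(ok_alleles)) {
    stop("invalid ancestral/derived alleles for panel marker(s): ",
         paste(panel$name[!ok_alleles], collapse = ", "), call. = FALSE)
  }

  # every node reachable from the root by parent links, and acyclic
  for (name in tree$order) {
    seen <- character()
    cur <- name
    while (!is.na(cur)) {
      if (cur %in% seen) {
        stop("cycle in parent links involving node '", cur, "'",
             call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- tree$nodes[[cur]]$parent
    }
    if (seen[length(seen)] != tree$root) {
      stop("node '", name, "' is not connected to the root", call. = FALSE)
    }
  }

  # node requirements must point at non-blacklisted panel positions and use
  # one of the marker's two alleles
  usable <- panel$position[!panel$blacklisted]
  for (name in tree$order) {
    req <- tree$nodes[[name]]$requires
    if (!nrow(req)) next
    missing_pos <- setdiff(req$position, panel$position)
    if (length(missing_pos)) {
      stop("node '", name, "' requires position(s) absent from the panel: ",
           paste(missing_pos, collapse = ", "), call. = FALSE)
    }
    black <- setdiff(req$position, usable)
    if (length(black)) {
      stop("node '", name, "' requires QC-blacklisted position(s): ",
           paste(black, collapse = ", "), call. = FALSE)
    }
    idx <- match(req$position, panel$position)
    legal <- req$allele == panel$ancestral[idx] | req$allele == panel$derived[idx]
    if (!all(legal)) {
      stop("node '", name, "' requires allele(s) that are neither the ",
           "ancestral nor the derived state: position ",
           paste(req$position[!legal], collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(req$position)) {
      stop("node '", name, "' lists the same position twice", call. = FALSE)
    }
  }

  n_hg <- length(tree$order) - 1L  # root (MRCA) is not a haplogroup
  if (!is.null(expected_nodes) && n_hg != expected_nodes) {
    stop("tree holds ", n_hg, " haplogroup nodes; expected ",
         expected_nodes, call. = FALSE)
  }

  tree <- index_tree(tree)
  lint_tree(tree)
  tree
}

# Precompute depths and, per node, the set of positions required anywhere in
# its subtree (node included). The subtree sets drive reversion-aware pruning
# during classification: a mismatch at a position can only be overridden
# deeper in the tree if some descendant requires that position again.
index_tree <- function(tree) {
  depth <- integer(length(tree$order))
  names(depth) <- tree$order
  for (name in tree$order) {
    d <- 0L
    cur <- tree$nodes[[name]]$parent
    while (!is.na(cur)) {
      d <- d + 1L
      cur <- tree$nodes[[cur]]$parent
    }
    depth[[name]] <- d
  }
  subtree <- list()
  for (name in tree$order[order(depth, decreasing = TRUE)]) {
    node <- tree$nodes[[name]]
    pos <- node$requires$position
    for (ch in node$children) pos <- union(pos, subtree[[ch]])
    subtree[[name]] <- as.integer(pos)
  }
  tree$depth <- depth
  tree$subtree_positions <- subtree
  tree$all_required_positions <-
    sort(unique(unlist(lapply(tree$nodes, function(n) n$requires$position),
                       use.names = FALSE)))
  tree
}

# Sibling nodes with identical cumulative requirement sets could never be
# separated by classification; warn (tree lint), do not fail.
lint_tree <- function(tree) {
  for (name in tree$order) {
    children <- tree$nodes[[name]]$children
    if (length(children) < 2L) next
    sets <- vapply(children, function(ch) {
      cum <- required_genotypes_cumulative(tree, ch)
      paste(cum$position, cum$allele, sep = ":", collapse = ";")
    }, character(1))
    if (anyDuplicated(sets)) {
      dup <- children[sets %in% sets[duplicated(sets)]]
      warning("sibling nodes with identical cumulative requirements: ",
              paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  invisible(tree)
}

#' The packaged default haplogroup tree
#'
#' Loads the tree and panel shipped with the package: a curated reduction of
#' the human mtDNA phylogeny to 46 common European, African, and Native
#' American/Asian haplogroups, keyed on a 63-marker mitochondrial SNP panel.
#' Two hypervariable/NumtS-prone markers (MT16189, MT9540) are carried in the
#' panel but blacklisted: they take no part in any node definition and are
#' excluded from classification.
#'
#' @return A validated `haplogroup_tree` with 46 haplogroup nodes.
#' @export
default_tree <- function() {
  path <- system.file("extdata", "haplogroup_tree.json", package = "mitohaplo",
                      mustWork = TRUE)
  load_tree(path, expected_nodes = 46L)
}

#' Serialize a haplogroup tree back to its JSON configuration format
#'
#' Inverse of [load_tree()]: writing the default tree and re-loading it
#' yields an identical structure (round-trip property).
#'
#' @param tree A `haplogroup_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  panel <- lapply(seq_len(nrow(tree$panel)), function(i) {
    r <- tree$panel[i, ]
    list(name = r$name, position = r$position, ancestral = r$ancestral,
         derived = r$derived, blacklist = r$blacklisted)
  })
  nodes <- lapply(tree$order, function(name) {
    node <- tree$nodes[[name]]
    req <- node$requires
    list(
      name = node$name,
      parent = if (is.na(node$parent)) NULL else node$parent,
      lineage = node$lineage,
      requires = lapply(seq_len(nrow(req)), function(j) {
        list(position = req$position[j], allele = req$allele[j])
      })
    )
  })
  jsonlite::write_json(list(panel = panel, nodes = nodes), path,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Path from the root to a haplogroup node
#'
#' @param tree A `haplogroup_tree`.
#' @param node_name Haplogroup label present in the tree.
#' @return Character vector of node names, root first, `node_name` last; its
#'   length minus one is the node's depth.
#' @export
path_to_root <- function(tree, node_name) {
  node <- lookup_node(tree, node_name)
  path <- character()
  cur <- node$name
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$nodes[[cur]]$parent
  }
  path
}

lookup_node <- function(tree, node_name) {
  node <- tree$nodes[[node_name]]
  if (is.null(node)) {
    stop("unknown haplogroup label '", node_name, "'", call. = FALSE)
  }
  node
}

#' Cumulative required genotypes along the root-to-node path
#'
#' Union of the `requires` lists of every node on the path from the root down
#' to `node_name`. Where an ancestor and a descendant require different
#' alleles at the same position — the encoding of a reversion, e.g. the
#' 10398A back-mutation — the descendant's allele wins.
#'
#' @inheritParams path_to_root
#' @return Data frame with columns `position` and `allele`, one row per
#'   position, in first-required order along the path.
#' @export
required_genotypes_cumulative <- function(tree, node_name) {
  path <- path_to_root(tree, node_name)
  pos <- integer()
  allele <- character()
  for (name in path) {
    req <- tree$nodes[[name]]$requires
    for (j in seq_len(nrow(req))) {
      k <- match(req$position[j], pos)
      if (is.na(k)) {
        pos <- c(pos, req$position[j])
        allele <- c(allele, req$allele[j])
      } else {
        allele[k] <- req$allele[j]  # descendant override (reversion)
      }
    }
  }
  data.frame(position = pos, allele = allele, stringsAsFactors = FALSE)
}

#' Depth of a node (root has depth 0)
#' @inheritParams path_to_root
#' @return Integer depth.
#' @export
node_depth <- function(tree, node_name) {
  lookup_node(tree, node_name)
  tree$depth[[node_name]]
}

#' Terminal (leaf) haplogroup labels of a tree
#' @param tree A `haplogroup_tree`.
#' @return Character vector of labels with no children, in definition order.
#' @export
terminal_haplogroups <- function(tree) {
  tree$order[vapply(tree$order,
                    function(n) length(tree$nodes[[n]]$children) == 0L,
                    logical(1))]
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("Reduced mitochondrial haplogroup tree\n")
  cat("  root:            ", x$root, "\n", sep = "")
  cat("  haplogroup nodes:", length(x$order) - 1L, "\n")
  cat("  panel markers:   ", nrow(x$panel),
      " (", sum(x$panel$blacklisted), " QC-blacklisted)\n", sep = "")
  lin <- table(vapply(x$nodes[setdiff(x$order, x$root)],
                      function(n) n$lineage, character(1)))
  cat("  lineages:        ",
      paste(names(lin), lin, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
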