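# Independent brute-force classification oracle: evaluates the cumulative
# requirement set of EVERY node independently (no tree descent, no pruning,
# none of the package's traversal helpers) and keeps the maximal-depth
# satisfied nodes. Used to cross-check the recursive accumulator.

oracle_depth <- function(tree, name) {
  d <- 0L
  cur <- tree$nodes[[name]]$parent
  while (!is.na(cur)) {
    d <- d + 1L
    cur <- tree$nodes[[cur]]$parent
  }
  d
}

# cumulative requirements by direct parent-chain walk; descendant overrides
oracle_cumulative <- function(tree, name) {
  chain <- character()
  cur <- name
  while (!is.na(cur)) {
    chain <- c(cur, chain)  # root first
    cur <- tree$nodes[[cur]]$parent
  }
  req <- character()  # named by position, value = allele
  for (n in chain) {
    r <- tree$nodes[[n]]$requires
    for (j in seq_len(nrow(r))) req[[as.character(r$position[j])]] <- r$allele[j]
  }
  req
}

oracle_classify <- function(tree, calls) {
  labels <- setdiff(tree$order, tree$root)
  sat <- labels[vapply(labels, function(l) {
    req <- oracle_cumulative(tree, l)
    obs <- calls[names(req)]
    all(!is.na(obs) & obs == req)
  }, logical(1))]
  if (!length(sat)) return(character())
  depths <- vapply(sat, function(l) oracle_depth(tree, l), integer(1))
  top <- sat[depths == max(depths)]
  top[order(match(top, tree$order))]
}
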