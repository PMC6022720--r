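test_that("packaged tree has the documented structure", {
  tr <- default_tree()
  expect_s3_class(tr, "haplogroup_tree")
  expect_identical(length(tr$order) - 1L, 46L)  # root not counted
  expect_identical(nrow(tr$panel), 63L)
  expect_setequal(tr$panel$name[tr$panel$blacklisted],
                  c("MT16189", "MT9540"))

  # every haplogroup and panel marker the method is documented to cover
  named_nodes <- c("L0", "L1", "L2", "L3", "L3b", "L3d", "L3e", "M", "N",
                   "Y", "A", "A2", "B", "C", "D", "E", "H", "JT", "U", "K",
                   "X")
  expect_true(all(named_nodes %in% tr$order))
  named_snps <- c("MT1736", "MT2092", "MT3552", "MT4883", "MT9042",
                  "MT9347", "MT5442", "MT10115", "MT10398", "MT10400",
                  "MT11177", "MT11251", "MT11719", "MT12007", "MT12308",
                  "MT12705", "MT13368", "MT14766", "MT15452", "MT16189",
                  "MT9540")
  expect_true(all(named_snps %in% tr$panel$name))

  # blacklisted markers take no part in any node definition
  black <- tr$panel$position[tr$panel$blacklisted]
  expect_length(intersect(black, tr$all_required_positions), 0L)
})

test_that("a single-root, empty-panel config is a valid 1-node tree", {
  tr <- load_tree(toy_config(panel = list(),
                             nodes = list(toy_node("ROOT"))))
  expect_identical(tr$root, "ROOT")
  expect_identical(path_to_root(tr, "ROOT"), "ROOT")
})

test_that("malformed configurations are rejected with informative errors", {
  # required position absent from panel (and beyond the rCRS)
  expect_error(
    load_tree(toy_config(
      panel = list(toy_snp(100, "A", "G")),
      nodes = list(toy_node("ROOT"),
                   toy_node("X", "ROOT", list(req(99999, "G")))))),
    "99999")
  # cycle via mutual parents
  expect_error(
    load_tree(toy_config(
      panel = list(),
      nodes = list(toy_node("A1", parent = "B1"),
                   toy_node("B1", parent = "A1")))),
    "cycle|root")
  # unknown parent
  expect_error(
    load_tree(toy_config(
      panel = list(),
      nodes = list(toy_node("ROOT"), toy_node("A1", parent = "GHOST")))),
    "GHOST")
  # duplicate node names
  expect_error(
    load_tree(toy_config(
      panel = list(),
      nodes = list(toy_node("ROOT"), toy_node("A1", "ROOT"),
                   toy_node("A1", "ROOT")))),
    "duplicate")
  # two roots
  expect_error(
    load_tree(toy_config(panel = list(),
                         nodes = list(toy_node("R1"), toy_node("R2")))),
    "root")
  # blacklisted marker used in a node definition
  expect_error(
    load_tree(toy_config(
      panel = list(toy_snp(100, "A", "G", blacklist = TRUE)),
      nodes = list(toy_node("ROOT"),
                   toy_node("X", "ROOT", list(req(100, "G")))))),
    "blacklist")
  # node count mismatch
  expect_error(
    load_tree(toy_config(panel = list(),
                         nodes = list(toy_node("ROOT"))),
              expected_nodes = 46L),
    "expected 46")
})

test_that("path_to_root is consistent for every node of the default tree", {
  tr <- default_tree()
  for (name in tr$order) {
    p <- path_to_root(tr, name)
    expect_identical(p[1], tr$root)
    expect_identical(p[length(p)], name)
    expect_identical(length(p) - 1L, node_depth(tr, name))
    parent <- tr$nodes[[name]]$parent
    if (!is.na(parent)) {
      expect_identical(node_depth(tr, name), node_depth(tr, parent) + 1L)
    } else {
      expect_identical(node_depth(tr, name), 0L)
    }
  }
  expect_error(path_to_root(tr, "NOPE"), "unknown")
})

test_that("cumulative requirements apply descendant-override reversions", {
  tr <- default_tree()
  # root: no requirements of its own
  expect_identical(nrow(required_genotypes_cumulative(tr, tr$root)), 0L)

  # N reverts 10398 to the ancestral A over its ancestor's derived G
  anc <- required_genotypes_cumulative(tr, tr$nodes[["N"]]$parent)
  expect_identical(anc$allele[anc$position == 10398], "G")
  cum_n <- required_genotypes_cumulative(tr, "N")
  expect_identical(cum_n$allele[cum_n$position == 10398], "A")

  # J reverts back to the derived G below N
  cum_j <- required_genotypes_cumulative(tr, "J")
  expect_identical(cum_j$allele[cum_j$position == 10398], "G")

  # union with override is never longer than naive concatenation
  for (name in tr$order) {
    naive <- sum(vapply(path_to_root(tr, name),
                        function(n) nrow(tr$nodes[[n]]$requires),
                        integer(1)))
    cum <- required_genotypes_cumulative(tr, name)
    expect_lte(nrow(cum), naive)
    expect_false(anyDuplicated(cum$position) > 0)
  }
})

test_that("load -> serialize -> load round-trips the default tree", {
  tr <- default_tree()
  path <- tempfile(fileext = ".json")
  write_tree(tr, path)
  tr2 <- load_tree(path, expected_nodes = 46L)
  expect_identical(tr2$order, tr$order)
  expect_identical(tr2$root, tr$root)
  expect_equal(tr2$panel, tr$panel)
  for (name in tr$order) {
    expect_identical(tr2$nodes[[name]]$parent, tr$nodes[[name]]$parent)
    expect_identical(tr2$nodes[[name]]$lineage, tr$nodes[[name]]$lineage)
    expect_equal(tr2$nodes[[name]]$requires, tr$nodes[[name]]$requires)
  }
})

test_that("sibling nodes with identical cumulative requirements raise a lint warning", {
  expect_warning(
    load_tree(toy_config(
      panel = list(toy_snp(100, "A", "G")),
      nodes = list(toy_node("ROOT"),
                   toy_node("TWIN1", "ROOT", list(req(100, "G"))),
                   toy_node("TWIN2", "ROOT", list(req(100, "G")))))),
    "identical cumulative")
  # the default tree is lint-clean
  expect_silent(default_tree())
})
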