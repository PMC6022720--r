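# Programmatic fixtures: toy tree configurations written as temp JSON, and
# small PED/MAP files built in code.

toy_config <- function(panel, nodes) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(panel = panel, nodes = nodes), path,
                       auto_unbox = TRUE, null = "null")
  path
}

toy_snp <- function(position, ancestral, derived, blacklist = FALSE) {
  list(name = paste0("MT", position), position = position,
       ancestral = ancestral, derived = derived, blacklist = blacklist)
}

toy_node <- function(name, parent = NULL, requires = list(),
                     lineage = "European") {
  list(name = name, parent = parent, lineage = lineage, requires = requires)
}

req <- function(position, allele) list(position = position, allele = allele)

# 5-node toy tree: ROOT -> P -> {Q1, Q2}; Q1 -> R1. Q1 and Q2 are depth-2
# siblings with disjoint requirements; useful for tie and ranking tests.
toy_tree <- function() {
  load_tree(toy_config(
    panel = list(toy_snp(100, "A", "G"), toy_snp(200, "C", "T"),
                 toy_snp(300, "G", "A"), toy_snp(400, "T", "C")),
    nodes = list(
      toy_node("ROOT"),
      toy_node("P", "ROOT", list(req(100, "G"))),
      toy_node("Q1", "P", list(req(200, "T"))),
      toy_node("Q2", "P", list(req(300, "A"))),
      toy_node("R1", "Q1", list(req(400, "C")))
    )
  ))
}

write_ped_lines <- function(lines) {
  path <- tempfile(fileext = ".ped")
  writeLines(lines, path)
  path
}

write_map_lines <- function(lines) {
  path <- tempfile(fileext = ".map")
  writeLines(lines, path)
  path
}
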