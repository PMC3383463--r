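# Shared fixtures: the packaged maps/tree are loaded once, and random
# character/tree generators used by the property tests live here.

xmaps <- xen_painting_maps()
xanalysis <- xmaps[setdiff(names(xmaps), "AEKALT")]
xtree <- xen_tree()
xmatrix <- build_character_matrix(xanalysis, policy = "missing",
                                  contains = "7/10")

random_rooted_tree <- function(n_tips) {
  phy <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy
}

random_binary_states <- function(tips, p_present = 0.4, p_missing = 0.1) {
  s <- ifelse(runif(length(tips)) < p_missing, NA_integer_,
              as.integer(runif(length(tips)) < p_present))
  setNames(s, tips)
}

random_count_states <- function(tips, max_count = 3, p_missing = 0.1) {
  s <- ifelse(runif(length(tips)) < p_missing, NA_integer_,
              sample.int(max_count, length(tips), replace = TRUE))
  setNames(as.integer(s), tips)
}

# empty-override configuration for simulated data
sim_infer_config <- function(outgroup = "ANC") {
  list(
    policy = "missing", outgroup = outgroup, contains = character(),
    overrides = xen_overrides()[0, ],
    assignments = xen_block_assignments()[0, ]
  )
}

# attach an outgroup tip carrying the ancestor's map below the root
with_outgroup_tree <- function(tree, og = "ANC") {
  nwk <- ape::write.tree(tree)
  read_tree(paste0("(", og, ":1,", sub(";$", "", nwk), ":1)TreeRoot;"))
}

ancestor_as_map <- function(sim, taxon = "ANC") {
  m <- karyoanc:::simstate_to_map(
    sim$node_karyotypes[[karyoanc:::node_names(sim$config$tree)[
      karyoanc:::root_of(sim$config$tree)]]], taxon)
  m
}
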