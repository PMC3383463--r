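# Small helpers over ape's phylo representation. Internal nodes are addressed
# by their Newick labels; unlabeled internals get "node<N>" names.

node_names <- function(phy) {
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  lab[!nzchar(lab)] <- paste0("node", which(!nzchar(lab)) + length(phy$tip.label))
  c(phy$tip.label, lab)
}

node_number <- function(phy, name) {
  idx <- match(name, node_names(phy))
  if (is.na(idx)) abort(paste0("unknown tree node: ", name))
  idx
}

children_of <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  kids
}

parent_of <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

root_of <- function(phy) {
  setdiff(unique(phy$edge[, 1]), phy$edge[, 2])[1]
}

postorder_nodes <- function(phy) {
  # children before parents, by depth-first walk from the root
  kids <- children_of(phy)
  out <- integer(0)
  visit <- function(v) {
    for (k in kids[[v]]) visit(k)
    out <<- c(out, v)
  }
  visit(root_of(phy))
  out
}

clade_tip_labels <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(phy$tip.label[node])
  kids <- children_of(phy)
  tips <- character(0)
  visit <- function(v) {
    if (v <= n_tip) tips <<- c(tips, phy$tip.label[v]) else for (k in kids[[v]]) visit(k)
  }
  visit(node)
  tips
}
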