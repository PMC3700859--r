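#' @title Mutation-labelled clade genealogies
#'
#' @description
#' A `clade_tree` is a rooted genealogy whose edges carry explicit mutation
#' labels in branch notation (`"x"` = variant gained, `"@x"` = variant
#' reverted), the computational counterpart of a hand-drawn mtDNA cladogram.
#' Nodes are either *observed* (one per sampled haplotype; attached by a
#' zero-mutation edge when their sequence equals an inferred ancestral
#' state) or *inferred* ancestral states. Every node stores its full
#' rCRS-relative variant set, and the class invariant is that replaying edge
#' labels from the root reproduces each node's state exactly.
#'
#' @name clade_tree
NULL

new_clade_tree <- function(nodes, states, edges, edge_labels, root,
                           validate = TRUE) {
  tree <- structure(list(nodes = nodes, states = states, edges = edges,
                         edge_labels = edge_labels, root = root),
                    class = "clade_tree")
  if (validate) validate_clade_tree(tree)
  tree
}

apply_edge_labels <- function(state, labels) {
  losses <- strip_back(labels[is_back(labels)])
  gains <- labels[!is_back(labels)]
  sort_labels(union(setdiff(state, losses), gains))
}

sort_labels <- function(labels) {
  labels <- as.character(labels)
  labels[order(variant_site(labels), labels)]
}

validate_clade_tree <- function(tree) {
  n <- nrow(tree$nodes)
  stopifnot(length(tree$states) == n,
            nrow(tree$edges) == length(tree$edge_labels))
  if (nrow(tree$edges) != n - 1L) stop("clade tree is not a tree")
  seen <- rep(FALSE, n)
  seen[tree$root] <- TRUE
  kids <- tree_children(tree)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    for (i in which(tree$edges$parent == v)) {
      ch <- tree$edges$child[i]
      if (seen[ch]) stop("cycle in clade tree")
      seen[ch] <- TRUE
      expect <- apply_edge_labels(tree$states[[v]], tree$edge_labels[[i]])
      if (!identical(sort_labels(tree$states[[ch]]), expect)) {
        stop("replay failure: state of node ", ch,
             " does not follow from its parent edge labels")
      }
      stack <- c(stack, ch)
    }
  }
  if (!all(seen)) stop("disconnected node(s) in clade tree")
  invisible(tree)
}

tree_children <- function(tree) {
  split(tree$edges$child, factor(tree$edges$parent,
                                 levels = seq_len(nrow(tree$nodes))))
}

#' @export
print.clade_tree <- function(x, ...) {
  n_obs <- sum(x$nodes$observed)
  cat("<clade_tree> ", n_obs, " sampled haplotypes, ",
      nrow(x$nodes) - n_obs, " inferred nodes, parsimony length ",
      parsimony_length(x), "\n", sep = "")
  invisible(x)
}

#' Total mutation count of a clade tree
#' @param tree a `clade_tree`.
#' @return Integer: the sum of edge mutation labels (the parsimony length).
#' @export
parsimony_length <- function(tree) {
  sum(lengths(tree$edge_labels))
}

#' Observed samples of a clade tree
#' @param tree a `clade_tree`.
#' @return Data frame `sample_id`, `node`.
#' @export
tree_samples <- function(tree) {
  obs <- which(tree$nodes$observed)
  data.frame(sample_id = tree$nodes$sample_id[obs], node = obs,
             stringsAsFactors = FALSE)
}

node_by_name <- function(tree, name) {
  id <- which(tree$nodes$name == name)
  if (!length(id)) stop("no node named ", sQuote(name), " in tree")
  id[1]
}

parent_edge <- function(tree, id) {
  which(tree$edges$child == id)
}

#' Mutation distance from every node to a reference node
#'
#' Counts edge labels along the unique tree path. The reference node must be
#' an ancestor of (or equal to) each node for genealogical use; distances
#' are path mutation counts either way.
#'
#' @param tree a `clade_tree`.
#' @param reference node id.
#' @return Integer vector indexed by node id.
#' @export
mutation_depths <- function(tree, reference = tree$root) {
  n <- nrow(tree$nodes)
  depth <- rep(NA_integer_, n)
  depth[reference] <- 0L
  # walk down from reference
  repeat {
    advanced <- FALSE
    for (i in seq_len(nrow(tree$edges))) {
      p <- tree$edges$parent[i]; ch <- tree$edges$child[i]
      w <- length(tree$edge_labels[[i]])
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + w; advanced <- TRUE
      } else if (!is.na(depth[ch]) && is.na(depth[p])) {
        depth[p] <- depth[ch] + w; advanced <- TRUE
      }
    }
    if (!advanced) break
  }
  depth
}

subtree_nodes <- function(tree, id) {
  out <- id
  stack <- id
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ch <- tree$edges$child[tree$edges$parent == v]
    out <- c(out, ch); stack <- c(stack, ch)
  }
  out
}

#' The most recent common ancestor node of the sampled haplotypes
#'
#' Walks down from the tree root past any unsampled single-child chain (a
#' stem retained from rooting on the haplogroup's ancestral motif); the MRCA
#' is the first node that is observed or branches.
#'
#' @param tree a `clade_tree`.
#' @return Node id.
#' @export
mrca_node <- function(tree) {
  v <- tree$root
  repeat {
    ch <- tree$edges$child[tree$edges$parent == v]
    if (tree$nodes$observed[v] || length(ch) != 1L) return(v)
    v <- ch
  }
}

#' Graft an ancestral stem above the root of a clade tree
#'
#' Adds a new root (the haplogroup's parent node in the motif tree, i.e. the
#' splitting node towards the closest sister lineage) joined to the current
#' root by an edge carrying the stem mutations.
#'
#' @param tree a `clade_tree`.
#' @param stem_labels character vector of stem mutation tokens (the clade's
#'   defining variants).
#' @param parent_name name for the new root node.
#' @param clade_name optional (re)name for the old root (the clade MRCA).
#' @return The extended `clade_tree`.
#' @export
with_stem <- function(tree, stem_labels, parent_name = "split_node",
                      clade_name = NULL) {
  stem_labels <- sort_labels(stem_labels)
  old_root <- tree$root
  if (!is.null(clade_name)) tree$nodes$name[old_root] <- clade_name
  losses <- stem_labels[!is_back(stem_labels)]
  gains <- strip_back(stem_labels[is_back(stem_labels)])
  parent_state <- sort_labels(union(setdiff(tree$states[[old_root]], losses),
                                    gains))
  tree$nodes <- rbind(tree$nodes,
                      data.frame(name = parent_name, observed = FALSE,
                                 sample_id = NA_character_,
                                 stringsAsFactors = FALSE))
  new_id <- nrow(tree$nodes)
  tree$states[[new_id]] <- parent_state
  tree$edges <- rbind(tree$edges,
                      data.frame(parent = new_id, child = old_root))
  tree$edge_labels[[nrow(tree$edges)]] <- stem_labels
  tree$root <- new_id
  validate_clade_tree(tree)
  tree
}

#' Extract a named clade: members, MRCA and stem length
#'
#' @param tree a `clade_tree` whose internal nodes carry haplogroup names.
#' @param node_name name of the clade's MRCA node.
#' @return List with `members` (sample ids below the node), `root` (node
#'   id), and `stem_length` (mutation count on the edge joining the node to
#'   its parent, the splitting node).
#' @export
extract_clade <- function(tree, node_name) {
  id <- node_by_name(tree, node_name)
  if (id == tree$root) stop("node ", sQuote(node_name),
                            " is the tree root: stem undefined")
  sub <- subtree_nodes(tree, id)
  members <- tree$nodes$sample_id[intersect(sub, which(tree$nodes$observed))]
  stem <- length(tree$edge_labels[[parent_edge(tree, id)]])
  list(members = members, root = id, stem_length = stem)
}

#' Flag recurrent mutations across a set of phylogenies
#'
#' A site is recurrent when variants at it label more than one edge across
#' the supplied phylogeny context (the whole regional tree, in practice);
#' such sites are conventionally underlined in published cladograms. Back
#' mutations (`@`) at a site count as hits of the same site.
#'
#' @param tree the `clade_tree` whose edges are to be flagged.
#' @param context list of `clade_tree`s defining the comparison set
#'   (defaults to `tree` alone).
#' @return `tree` with an added `edge_recurrent` list (per edge, a logical
#'   vector aligned with its labels) and attribute `"recurrent_sites"`.
#' @export
annotate_recurrence <- function(tree, context = list(tree)) {
  hits <- integer(0)
  for (tr in context) {
    for (labs in tr$edge_labels) {
      for (site in unique(variant_site(labs))) {
        hits[as.character(site)] <- sum(hits[as.character(site)], 1L,
                                        na.rm = TRUE)
      }
    }
  }
  recurrent_sites <- as.integer(names(hits)[hits > 1L])
  tree$edge_recurrent <- lapply(tree$edge_labels, function(labs) {
    variant_site(labs) %in% recurrent_sites
  })
  attr(tree, "recurrent_sites") <- sort(recurrent_sites)
  tree
}
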