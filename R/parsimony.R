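#' Reconstruct a clade genealogy by maximum parsimony
#'
#' Builds a minimum-length mutation-labelled tree for a set of masked
#' haplotypes, rooted at the clade's ancestral state (the haplogroup motif,
#' not a midpoint). Each distinct variant label is one binary character.
#'
#' The search is exact: when the characters are pairwise compatible the
#' perfect phylogeny is constructed directly (it attains the minimum, one
#' change per character); otherwise an exhaustive branch-and-bound search
#' over topologies ([phangorn::bab()]) is run for up to 12 distinct
#' haplotypes, with a parsimony-ratchet heuristic above that. Ancestral
#' states are assigned by a deterministic Fitch pass anchored at the root
#' motif, and ties among equally parsimonious trees are broken by fewest
#' recurrent sites, then by the lexicographic order of sorted edge labels.
#'
#' @param haplotypes list of masked [haplotype()] objects.
#' @param root_motif character vector: the clade's ancestral variant set
#'   (rCRS-relative), from the haplogroup motif tree.
#' @param reference reference sequence for token canonicalization.
#' @param method `"auto"` (exact up to 12 distinct haplotypes), `"exact"`,
#'   or `"heuristic"`.
#' @param root_name name given to the root node.
#' @return A [clade_tree]; the root state equals the canonicalized
#'   `root_motif`, every sampled haplotype is an observed node, and
#'   replaying edge labels from the root reproduces each observed variant
#'   set (enforced on construction).
#' @export
build_mp_tree <- function(haplotypes, root_motif = character(),
                          reference = synthetic_rcrs(),
                          method = c("auto", "exact", "heuristic"),
                          root_name = "MRCA") {
  method <- match.arg(method)
  stopifnot(length(haplotypes) >= 1L)
  ids <- vapply(haplotypes, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  root_motif <- canonical_variants(root_motif, reference)

  present <- lapply(haplotypes, function(h) h$variants[!is_back(h$variants)])
  reverted <- lapply(haplotypes, function(h) {
    strip_back(h$variants[is_back(h$variants)])
  })
  chars <- sort_labels(unique(c(root_motif, unlist(present), unlist(reverted))))
  z <- chars %in% root_motif                       # root state per character
  M <- do.call(rbind, lapply(present, function(p) chars %in% p))
  Y <- M != matrix(z, nrow(M), length(chars), byrow = TRUE)  # recoded: root 0
  variable <- colSums(Y) > 0L
  # coverage gaps at informative sites are not representable as binary states
  for (i in seq_along(haplotypes)) {
    pos <- variant_site(chars[variable])
    if (length(pos) && !all(position_covered(pos, haplotypes[[i]]$coverage_ranges))) {
      stop("sample ", ids[i], " has a coverage gap at informative site(s); ",
           "restrict the analysis to shared coverage")
    }
  }
  Yv <- Y[, variable, drop = FALSE]
  vchars <- chars[variable]
  vz <- z[variable]

  key <- apply(Yv, 1L, paste, collapse = "")
  ukey <- sort(unique(key))
  U <- Yv[match(ukey, key), , drop = FALSE]        # unique states x chars
  attach_state <- match(key, ukey)                 # sample -> unique state

  if (ncol(U) == 0L || is_laminar(U)) {
    skeleton <- perfect_phylogeny(U, vchars, vz)
  } else {
    skeleton <- mp_search(U, vchars, vz, method)
  }
  assemble_clade_tree(skeleton, attach_state, ids, root_motif, chars, z,
                      variable, root_name)
}

# carrier sets pairwise nested or disjoint?
is_laminar <- function(U) {
  m <- ncol(U)
  if (m < 2L) return(TRUE)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      ab <- sum(U[, a] & U[, b])
      if (ab > 0L && ab < sum(U[, a]) && ab < sum(U[, b])) return(FALSE)
    }
  }
  TRUE
}

# Both construction routes return a "skeleton": a rooted tree over recoded
# states; node 1 is the root (all-zero state). Fields: states (list of
# logical vectors over vchars), edges (parent, child), state_node (unique
# state index -> node id).
perfect_phylogeny <- function(U, vchars, vz) {
  u <- nrow(U); m <- ncol(U)
  states <- list(rep(FALSE, m))
  edges <- data.frame(parent = integer(), child = integer())
  state_node <- integer(u)
  if (m == 0L) {
    state_node[] <- 1L
    return(list(states = states, edges = edges, state_node = state_node))
  }
  ckey <- apply(U, 2L, paste, collapse = "")
  bundle_id <- match(ckey, unique(ckey))
  bundles <- lapply(unique(ckey), function(k) which(ckey == k))
  sizes <- vapply(bundles, function(b) sum(U[, b[1]]), 0L)
  ord <- order(-sizes, vapply(bundles, function(b) vchars[b[1]], ""))
  bundles <- bundles[ord]; sizes <- sizes[ord]
  node_of_bundle <- integer(length(bundles))
  for (bi in seq_along(bundles)) {
    carriers <- U[, bundles[[bi]][1]]
    # parent: smallest strict superset among earlier (larger) bundles
    parent_node <- 1L
    best <- Inf
    for (bj in seq_len(bi - 1L)) {
      sup <- U[, bundles[[bj]][1]]
      if (all(carriers <= sup) && sizes[bj] > sizes[bi] && sizes[bj] < best) {
        best <- sizes[bj]; parent_node <- node_of_bundle[bj]
      }
    }
    st <- states[[parent_node]]
    st[bundles[[bi]]] <- TRUE
    states[[length(states) + 1L]] <- st
    node_of_bundle[bi] <- length(states)
    edges <- rbind(edges, data.frame(parent = parent_node,
                                     child = node_of_bundle[bi]))
  }
  for (s in seq_len(u)) {
    inb <- which(vapply(bundles, function(b) U[s, b[1]], TRUE))
    state_node[s] <- if (length(inb)) {
      node_of_bundle[inb[which.min(sizes[inb])]]
    } else 1L
  }
  list(states = states, edges = edges, state_node = state_node)
}

mp_search <- function(U, vchars, vz, method) {
  u <- nrow(U)
  taxa <- c("__ROOT__", paste0("S", seq_len(u)))
  mat <- rbind(rep(0L, ncol(U)), U * 1L)
  rownames(mat) <- taxa
  storage.mode(mat) <- "character"
  pd <- phangorn::phyDat(mat, type = "USER", levels = c("0", "1"))
  exact <- method == "exact" || (method == "auto" && u <= 12L)
  trees <- if (exact) {
    phangorn::bab(pd, trace = 0)
  } else {
    phangorn::pratchet(pd, trace = 0)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  best <- NULL
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]     # [[ restores compressed multiPhylo tip labels
    tr <- ape::root(tr, outgroup = "__ROOT__", resolve.root = TRUE)
    lab <- fitch_label(tr, U)
    sc <- list(length = lab$length, n_recurrent = lab$n_recurrent,
               canon = lab$canon)
    if (is.null(best) || better_mp(sc, best$sc)) best <- list(sc = sc, lab = lab)
  }
  best$lab$skeleton
}

better_mp <- function(a, b) {
  if (a$length != b$length) return(a$length < b$length)
  if (a$n_recurrent != b$n_recurrent) return(a$n_recurrent < b$n_recurrent)
  a$canon < b$canon
}

# Deterministic Fitch pass on a rooted phylo whose tips are __ROOT__ (the
# all-zero ancestral state) and S<i> (unique states, rows of U). Returns the
# skeleton plus tie-break statistics.
fitch_label <- function(phy, U) {
  m <- ncol(U)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  low <- matrix(FALSE, nnode, m)    # 0 in Fitch set
  high <- matrix(FALSE, nnode, m)   # 1 in Fitch set
  tipstate <- matrix(FALSE, ntip, m)
  for (i in seq_len(ntip)) {
    nm <- phy$tip.label[i]
    tipstate[i, ] <- if (nm == "__ROOT__") rep(FALSE, m) else
      U[as.integer(sub("^S", "", nm)), ]
  }
  low[seq_len(ntip), ] <- !tipstate
  high[seq_len(ntip), ] <- tipstate
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    # accumulate children into parents pairwise (binary trees from bab)
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (!any(low[p, ] | high[p, ])) {   # first child seen
      low[p, ] <- low[ch, ]; high[p, ] <- high[ch, ]
    } else {
      il <- low[p, ] & low[ch, ]; ih <- high[p, ] & high[ch, ]
      un <- !(il | ih)
      low[p, ] <- ifelse(un, low[p, ] | low[ch, ], il)
      high[p, ] <- ifelse(un, high[p, ] | high[ch, ], ih)
    }
  }
  rootn <- ntip + 1L
  state <- matrix(NA, nnode, m)
  state[rootn, ] <- FALSE           # anchored at the ancestral motif
  pre <- rev(seq_len(nrow(po$edge)))
  for (k in pre) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    s <- state[p, ]
    ok0 <- low[ch, ]; ok1 <- high[ch, ]
    keep <- (s & ok1) | (!s & ok0)    # parent state is in the Fitch set
    state[ch, ] <- ifelse(keep, s, ok1)
  }
  # build skeleton: nodes = phylo nodes except the __ROOT__ tip
  root_tip <- match("__ROOT__", phy$tip.label)
  keep_nodes <- setdiff(seq_len(nnode), root_tip)
  remap <- integer(nnode)
  remap[rootn] <- 1L
  remap[setdiff(keep_nodes, rootn)] <-
    seq_along(setdiff(keep_nodes, rootn)) + 1L
  states <- vector("list", length(keep_nodes))
  for (v in keep_nodes) states[[remap[v]]] <- state[v, ]
  edges <- data.frame(parent = integer(), child = integer())
  changes_per_char <- integer(m)
  canon_parts <- character(0)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    if (ch == root_tip) next
    edges <- rbind(edges, data.frame(parent = remap[p], child = remap[ch]))
    diffc <- which(state[p, ] != state[ch, ])
    changes_per_char[diffc] <- changes_per_char[diffc] + 1L
    canon_parts <- c(canon_parts, paste(diffc, collapse = ","))
  }
  state_node <- integer(nrow(U))
  for (i in seq_len(ntip)) {
    nm <- phy$tip.label[i]
    if (nm != "__ROOT__") state_node[as.integer(sub("^S", "", nm))] <- remap[i]
  }
  list(skeleton = list(states = states, edges = edges,
                       state_node = state_node),
       length = sum(changes_per_char),
       n_recurrent = sum(changes_per_char > 1L),
       canon = paste(sort(canon_parts), collapse = ";"))
}

# Turn a recoded skeleton into a clade_tree in original (rCRS-relative)
# label space, attaching every sample as an observed node.
assemble_clade_tree <- function(skeleton, attach_state, ids, root_motif,
                                chars, z, variable, root_name) {
  vchars <- chars[variable]; vz <- z[variable]
  constant_state <- chars[z & !variable]
  # original-space state: label present iff (root has it) xor (recoded flip)
  orig_state <- function(y) sort_labels(c(constant_state, vchars[xor(vz, y)]))

  n_skel <- length(skeleton$states)
  nodes <- data.frame(name = c(root_name, rep("", n_skel - 1L)),
                      observed = FALSE, sample_id = NA_character_,
                      stringsAsFactors = FALSE)
  states <- lapply(skeleton$states, orig_state)
  edges <- skeleton$edges
  edge_labels <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    yp <- skeleton$states[[edges$parent[i]]]
    yc <- skeleton$states[[edges$child[i]]]
    diffc <- which(yp != yc)
    # gained in original space if child's original state carries the label
    lab <- ifelse(xor(vz[diffc], yc[diffc]), vchars[diffc],
                  paste0("@", vchars[diffc]))
    edge_labels[[i]] <- sort_labels(lab)
  }
  for (s in seq_along(ids)) {
    host <- skeleton$state_node[attach_state[s]]
    nodes <- rbind(nodes, data.frame(name = ids[s], observed = TRUE,
                                     sample_id = ids[s],
                                     stringsAsFactors = FALSE))
    id <- nrow(nodes)
    states[[id]] <- states[[host]]
    edges <- rbind(edges, data.frame(parent = host, child = id))
    edge_labels[[nrow(edges)]] <- character(0)
  }
  new_clade_tree(nodes, states, edges, edge_labels, root = 1L)
}
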