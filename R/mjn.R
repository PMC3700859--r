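#' Build a median-joining haplotype network
#'
#' Implements the median-joining construction used to verify intraspecific
#' mtDNA genealogies: start from the minimum spanning network (all links
#' that occur in some minimum spanning tree, with tolerance `epsilon`),
#' repeatedly add median (consensus) vectors of linked triplets — candidate
#' unsampled ancestral states — and finally discard obsolete median nodes.
#' On homoplasy-free data the result collapses to the unique most
#' parsimonious tree.
#'
#' Haplotypes are encoded as binary presence vectors over variant labels,
#' with distances counted as label differences (Hamming). The construction
#' is deterministic: candidate medians are processed in a fixed lexicographic
#' order, independent of input order.
#'
#' @param haplotypes list of masked [haplotype()] objects.
#' @param epsilon non-negative integer weight tolerance (0 reproduces the
#'   strict minimum spanning network before median addition).
#' @param reference reference sequence for canonicalization.
#' @return An object of class `mj_network`: `nodes` (data frame with `id`,
#'   `sampled`, `sample_ids`), `states` (variant-label sets per node),
#'   `edges` (data frame `from`, `to`) and `edge_labels` (differing variants
#'   per edge).
#' @export
build_mj_network <- function(haplotypes, epsilon = 0L,
                             reference = synthetic_rcrs()) {
  stopifnot(length(haplotypes) >= 1L, epsilon >= 0L)
  present <- lapply(haplotypes, function(h) h$variants[!is_back(h$variants)])
  ids <- vapply(haplotypes, `[[`, "", "sample_id")
  chars <- sort_labels(unique(unlist(present)))
  M <- do.call(rbind, lapply(present, function(p) chars %in% p))
  if (is.null(M)) M <- matrix(FALSE, length(haplotypes), 0L)
  key <- apply(M, 1L, paste, collapse = "")
  ukey <- sort(unique(key))
  S <- M[match(ukey, key), , drop = FALSE]         # distinct sampled states
  sample_of <- split(ids, match(key, ukey))

  repeat {
    links <- msn_links(S, epsilon)
    med <- candidate_medians(S, links, nrow_sampled = length(ukey),
                             epsilon = epsilon)
    if (is.null(med)) break
    S <- rbind(S, med)
  }
  # prune obsolete medians: unsampled nodes of degree <= 2 in the final MSN
  repeat {
    links <- msn_links(S, epsilon)
    deg <- tabulate(c(links$from, links$to), nbins = nrow(S))
    sampled <- seq_len(nrow(S)) <= length(ukey)
    drop <- which(!sampled & deg <= 2L)
    if (!length(drop)) break
    S <- S[-drop[1L], , drop = FALSE]
  }
  links <- msn_links(S, epsilon)
  n_samp <- length(ukey)
  states <- lapply(seq_len(nrow(S)), function(i) sort_labels(chars[S[i, ]]))
  edge_labels <- lapply(seq_len(nrow(links)), function(k) {
    sort_labels(chars[xor(S[links$from[k], ], S[links$to[k], ])])
  })
  nodes <- data.frame(id = seq_len(nrow(S)),
                      sampled = seq_len(nrow(S)) <= n_samp,
                      stringsAsFactors = FALSE)
  nodes$sample_ids <- c(lapply(seq_len(n_samp), function(i) sample_of[[i]]),
                        rep(list(character(0)), nrow(S) - n_samp))
  structure(list(nodes = nodes, states = states, edges = links,
                 edge_labels = edge_labels, epsilon = epsilon,
                 chars = chars),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat("<mj_network> ", sum(x$nodes$sampled), " sampled + ",
      sum(!x$nodes$sampled), " median nodes, ", nrow(x$edges),
      " links (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

# Minimum spanning network over binary state rows: a link (u,v) of weight w
# is feasible iff u and v lie in different connected components of the graph
# using only links of weight < w - epsilon.
msn_links <- function(S, epsilon = 0L) {
  n <- nrow(S)
  if (n == 1L) return(data.frame(from = integer(), to = integer()))
  D <- as.matrix(stats::dist(S * 1L, method = "manhattan"))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(length(w))
  i <- 1L
  while (i <= length(w)) {
    level <- which(w >= w[i] & w < w[i] + 1)   # this weight level
    # components from links of weight < w[i] - epsilon are already merged
    for (k in level) {
      keep[k] <- find(pairs[k, 1]) != find(pairs[k, 2])
    }
    # merge all links up to and including weights <= w[i] - ... for the next
    # level, links of weight < w_next - epsilon must be merged; merging by
    # levels: after processing level w, merge links with weight <= w - epsilon
    nxt <- if (max(level) < length(w)) w[max(level) + 1L] else Inf
    to_merge <- which(w < nxt - epsilon)
    for (k in to_merge) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
    i <- max(level) + 1L
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
}

# Majority-consensus medians of linked triplets. Returns one batch of new
# median rows (those with minimal connection cost, ties included), or NULL.
candidate_medians <- function(S, links, nrow_sampled, epsilon = 0L) {
  n <- nrow(S)
  if (!nrow(links) || n < 3L) return(NULL)
  adj <- matrix(FALSE, n, n)
  adj[cbind(links$from, links$to)] <- TRUE
  adj <- adj | t(adj)
  existing <- apply(S, 1L, paste, collapse = "")
  cand <- list(); cost <- numeric(0)
  for (u in seq_len(n - 2L)) {
    for (v in (u + 1L):(n - 1L)) {
      for (wn in (v + 1L):n) {
        nlink <- adj[u, v] + adj[u, wn] + adj[v, wn]
        if (nlink < 2L) next
        med <- (S[u, ] + S[v, ] + S[wn, ]) >= 2L
        mkey <- paste(med, collapse = "")
        if (mkey %in% existing || mkey %in% names(cand)) next
        cand[[mkey]] <- med
        cost[mkey] <- sum(xor(med, S[u, ])) + sum(xor(med, S[v, ])) +
          sum(xor(med, S[wn, ]))
      }
    }
  }
  if (!length(cand)) return(NULL)
  keep <- names(cand)[cost <= min(cost) + epsilon]
  do.call(rbind, unname(cand[sort(keep)]))
}

#' Compare a median-joining network with a clade tree
#'
#' Canonicalizes both to sets of undirected links between variant-set
#' states and tests equality — the check that the parsimony reconstruction
#' and the median-joining verification agree, up to rooting. On the tree
#' side, zero-length sample attachments are merged into their state node,
#' unsampled pendant nodes (e.g. a grafted stem ancestor) are dropped, and
#' unsampled degree-2 Steiner points — which the median-joining
#' construction never materializes — are spliced out.
#'
#' @param net an [build_mj_network()] result.
#' @param tree a [clade_tree].
#' @return `TRUE`/`FALSE`.
#' @export
network_matches_tree <- function(net, tree) {
  state_key <- function(labels) paste(labels, collapse = "|")
  net_edges <- vapply(seq_len(nrow(net$edges)), function(k) {
    a <- state_key(net$states[[net$edges$from[k]]])
    b <- state_key(net$states[[net$edges$to[k]]])
    paste(sort(c(a, b)), collapse = " -- ")
  }, "")

  # canonicalize the tree as an undirected state graph
  obs_states <- unique(vapply(which(tree$nodes$observed), function(v) {
    state_key(tree$states[[v]])
  }, ""))
  ed <- data.frame(
    a = vapply(tree$edges$parent, function(v) state_key(tree$states[[v]]), ""),
    b = vapply(tree$edges$child, function(v) state_key(tree$states[[v]]), ""),
    stringsAsFactors = FALSE)
  ed <- ed[ed$a != ed$b, , drop = FALSE]       # merge 0-length attachments
  repeat {
    nodes <- unique(c(ed$a, ed$b))
    deg <- table(factor(c(ed$a, ed$b), levels = nodes))
    unsampled <- setdiff(nodes, obs_states)
    pendant <- intersect(names(deg)[deg == 1L], unsampled)
    if (length(pendant)) {
      ed <- ed[!(ed$a %in% pendant | ed$b %in% pendant), , drop = FALSE]
      next
    }
    steiner <- intersect(names(deg)[deg == 2L], unsampled)
    if (!length(steiner)) break
    s <- steiner[1]
    hit <- which(ed$a == s | ed$b == s)
    others <- c(ed$a[hit], ed$b[hit])
    others <- others[others != s]
    ed <- ed[-hit, , drop = FALSE]
    ed <- rbind(ed, data.frame(a = others[1], b = others[2],
                               stringsAsFactors = FALSE))
  }
  tree_edges <- vapply(seq_len(nrow(ed)), function(k) {
    paste(sort(c(ed$a[k], ed$b[k])), collapse = " -- ")
  }, "")
  setequal(net_edges, tree_edges)
}
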