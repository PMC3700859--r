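#' Write a clade tree as Newick with mutation labels
#'
#' Serializes through [ape::write.tree()]: branch lengths carry the edge
#' mutation counts and each node label carries the node name plus the
#' incoming edge's mutation tokens (`name#tok1|tok2`, spaces encoded as
#' `_`); the root label carries the root's full variant state instead, so
#' the tree replays exactly on reading.
#'
#' @param tree a [clade_tree] with at least two sampled haplotypes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clade_tree_newick <- function(tree, path) {
  kids <- split(tree$edges$child, tree$edges$parent)
  is_leaf <- !(seq_len(nrow(tree$nodes)) %in% tree$edges$parent)
  tips <- which(is_leaf)
  internals <- c(tree$root, setdiff(which(!is_leaf), tree$root))
  if (length(tips) < 2L) stop("newick export needs at least two leaves")
  remap <- integer(nrow(tree$nodes))
  remap[tips] <- seq_along(tips)
  remap[internals] <- length(tips) + seq_along(internals)
  enc <- function(id) {
    payload <- if (id == tree$root) {
      paste(tree$states[[id]], collapse = "|")
    } else {
      paste(tree$edge_labels[[parent_edge(tree, id)]], collapse = "|")
    }
    # reversible escaping: literal underscores first, then spaces
    s <- paste0(tree$nodes$name[id], "#", payload)
    gsub(" ", "_", gsub("_", "%5F", s))
  }
  phy <- list(edge = cbind(remap[tree$edges$parent], remap[tree$edges$child]),
              edge.length = lengths(tree$edge_labels),
              tip.label = vapply(tips, enc, ""),
              node.label = vapply(internals, enc, ""),
              Nnode = length(internals))
  storage.mode(phy$edge) <- "integer"
  class(phy) <- "phylo"
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a mutation-labelled clade tree from Newick
#'
#' Inverse of [write_clade_tree_newick()].
#'
#' @param path Newick file.
#' @return A [clade_tree].
#' @export
read_clade_tree_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file ", path)
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  labels <- c(phy$tip.label, phy$node.label)
  dec <- function(s) {
    s <- gsub("%5F", "_", gsub("_", " ", s))
    parts <- strsplit(s, "#", fixed = TRUE)[[1]]
    toks <- if (length(parts) > 1L && nzchar(parts[2])) {
      strsplit(parts[2], "|", fixed = TRUE)[[1]]
    } else character(0)
    list(name = parts[1], tokens = toks)
  }
  decoded <- lapply(labels, dec)
  root <- ntip + 1L
  nodes <- data.frame(name = vapply(decoded, `[[`, "", "name"),
                      observed = c(rep(TRUE, ntip), rep(FALSE, phy$Nnode)),
                      sample_id = c(vapply(decoded[seq_len(ntip)], `[[`, "",
                                           "name"),
                                    rep(NA_character_, phy$Nnode)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2])
  edge_labels <- lapply(seq_len(nrow(edges)), function(k) {
    decoded[[edges$child[k]]]$tokens
  })
  states <- vector("list", n)
  states[[root]] <- sort_labels(decoded[[root]]$tokens)
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]; ch <- edges$child[k]
      if (!is.null(states[[p]]) && is.null(states[[ch]])) {
        states[[ch]] <- apply_edge_labels(states[[p]], edge_labels[[k]])
        done <- FALSE
      }
    }
    if (done) break
  }
  new_clade_tree(nodes, states, edges, edge_labels, root = root)
}

#' Export a median-joining network as an edge-list text file
#'
#' Tab-separated: `from`, `to` (node ids), `from_type`/`to_type`
#' (`sampled`/`median`), `labels` (space-separated variant tokens on the
#' link), plus `from_samples`/`to_samples` (comma-joined sample ids).
#'
#' @param net an [build_mj_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  type <- ifelse(net$nodes$sampled, "sampled", "median")
  smp <- vapply(net$nodes$sample_ids, paste, "", collapse = ",")
  df <- data.frame(from = net$edges$from, to = net$edges$to,
                   from_type = type[net$edges$from],
                   to_type = type[net$edges$to],
                   labels = vapply(net$edge_labels, paste, "",
                                   collapse = " "),
                   from_samples = smp[net$edges$from],
                   to_samples = smp[net$edges$to],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a median-joining network as GraphML
#'
#' Requires the igraph package.
#'
#' @inheritParams write_network_edgelist
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               labels = vapply(net$edge_labels, paste, "", collapse = " ")),
    directed = FALSE,
    vertices = data.frame(
      name = net$nodes$id,
      sampled = net$nodes$sampled,
      samples = vapply(net$nodes$sample_ids, paste, "", collapse = ",")))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a population frequency table (Table S4 style CSV)
#'
#' Columns: `population_id`, `latitude`, `longitude`, `n`, and optionally
#' `count` (carriers of the target haplogroup). Malformed rows are reported
#' with their line number.
#'
#' @param path CSV file.
#' @return Data frame, with `frequency = count/n` added when counts are
#'   present.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population_id", "latitude", "longitude", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("population table ", path, " lacks column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in c("latitude", "longitude", "n", intersect("count", names(df)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop("population table ", path, ": non-numeric ", col,
           " at data line(s) ", paste(bad, collapse = ", "))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("count" %in% names(df)) {
    if (any(df$count > df$n)) stop("count exceeds n in ", path)
    df$frequency <- ifelse(df$n > 0, df$count / df$n, 0)
  }
  df
}
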