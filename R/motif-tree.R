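#' Load a haplogroup motif tree from an indented text file
#'
#' The format mirrors how Phylotree-style haplogroup trees are written down:
#' one node per line, depth given by two-space (or tab) indentation, then the
#' haplogroup name followed by its defining variant tokens relative to the
#' parent node. The first line is the root — the reference-anchored node
#' (H2a2a1 for an rCRS-rooted tree) — and carries no defining variants.
#' A defining token prefixed `@` undoes a variant acquired higher up the
#' path (a back mutation on the haplogroup's stem).
#'
#' @param path motif file.
#' @param reference reference sequence for token parsing.
#' @return An object of class `motif_tree`.
#' @export
load_motif_tree <- function(path, reference = synthetic_rcrs()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("motif file ", path, " is empty")
  indent <- nchar(sub("\\S.*$", "", gsub("\t", "  ", lines)))
  depth <- indent %/% 2L
  name <- character(); parent <- character(); defining <- list()
  stack <- character(0)   # names at each depth
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nm <- f[1]
    toks <- tokenize_variants(f[-1])
    d <- depth[i]
    if (nm %in% name) stop("duplicate haplogroup name ", sQuote(nm))
    if (i == 1L) {
      if (d != 0L) stop("first motif line must be the unindented root")
      if (length(toks)) stop("root node must carry no defining variants")
    } else {
      if (d == 0L) stop("line ", i, ": second root ", sQuote(nm))
      if (d > length(stack)) {
        stop("line ", i, ": node ", sQuote(nm),
             " indented below a parent that has not been listed yet")
      }
      if (!length(toks)) {
        stop("non-root node ", sQuote(nm), " has no defining variants")
      }
    }
    name <- c(name, nm)
    parent <- c(parent, if (d == 0L) NA_character_ else stack[d])
    defining[[nm]] <- canonical_variants(toks, reference)
    stack <- c(stack[seq_len(d)], nm)
  }
  structure(list(nodes = data.frame(name = name, parent = parent,
                                    depth = depth, stringsAsFactors = FALSE),
                 defining = defining),
            class = "motif_tree")
}

#' @export
print.motif_tree <- function(x, ...) {
  cat("<motif_tree> ", nrow(x$nodes), " haplogroups, root ",
      sQuote(x$nodes$name[1]), "\n", sep = "")
  invisible(x)
}

#' Root-to-node path of a motif tree
#'
#' @param tree a [load_motif_tree()] tree.
#' @param name haplogroup name.
#' @return Character vector of node names from the root down to `name`.
#' @export
motif_path <- function(tree, name) {
  if (!name %in% tree$nodes$name) stop("unknown haplogroup ", sQuote(name))
  path <- character(0)
  while (!is.na(name)) {
    path <- c(name, path)
    name <- tree$nodes$parent[match(name, tree$nodes$name)]
  }
  path
}

#' Full motif of a haplogroup node
#'
#' Accumulates defining variants along the root path, applying `@`-prefixed
#' back mutations (a site reverted on a stem drops out of the cumulative
#' motif; a later re-gain re-enters it).
#'
#' @inheritParams motif_path
#' @return Character vector of canonical variant labels.
#' @export
full_motif <- function(tree, name) {
  motif <- character(0)
  for (nd in motif_path(tree, name)) {
    toks <- tree$defining[[nd]]
    backs <- toks[is_back(toks)]
    motif <- setdiff(motif, strip_back(backs))
    motif <- union(motif, toks[!is_back(toks)])
  }
  motif[order(variant_site(motif), motif)]
}

#' Number of defining variants on a haplogroup's stem
#'
#' The mutation count on the branch joining a haplogroup to its parent in
#' the motif tree — the stem length used for splitting-age dating.
#'
#' @inheritParams motif_path
#' @return Integer.
#' @export
motif_stem_length <- function(tree, name) {
  if (name == tree$nodes$name[1]) stop("root node has no stem")
  length(tree$defining[[name]])
}
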