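#' Assign a haplotype to a haplogroup by motif matching
#'
#' Walks every node of the motif tree and scores the haplotype against the
#' node's full (root-path) motif restricted to the haplotype's declared
#' coverage: `matched` defining variants present, `missed` expected but
#' absent, `extra_private` haplotype variants the path does not explain.
#' The winner is the node maximizing `matched - missed`; ties go to the
#' deeper node, then to fewer `extra_private`, then to the lexicographically
#' smaller name. A back-mutated token in the query (`"@150"`) counts as
#' absence of that defining variant — a haplotype can still reach a deep
#' node through the rest of its motif, which is exactly how V-lineage
#' haplotypes that reverted the np 150 hotspot are handled.
#'
#' @param hap a masked [haplotype()].
#' @param tree a [load_motif_tree()] motif tree.
#' @return A one-row data frame (class `mt_classification`) with columns
#'   `haplotype_id`, `best_node`, `matched`, `missed`, `extra_private`.
#' @export
classify <- function(hap, tree) {
  stopifnot(inherits(hap, "mt_haplotype"), inherits(tree, "motif_tree"))
  if (!nrow(tree$nodes)) stop("empty motif tree")
  present <- hap$variants[!is_back(hap$variants)]
  reverted <- strip_back(hap$variants[is_back(hap$variants)])
  ranges <- hap$coverage_ranges

  best <- NULL
  for (nm in tree$nodes$name) {
    motif <- full_motif(tree, nm)
    motif_cov <- motif[position_covered(variant_site(motif), ranges)]
    matched <- sum(motif_cov %in% present)
    missed <- length(motif_cov) - matched
    extra <- sum(!(present %in% motif_cov))
    depth <- tree$nodes$depth[match(nm, tree$nodes$name)]
    cand <- list(name = nm, score = matched - missed, depth = depth,
                 matched = matched, missed = missed, extra = extra)
    if (is.null(best) || better_classification(cand, best)) best <- cand
  }
  structure(data.frame(haplotype_id = hap$sample_id, best_node = best$name,
                       matched = best$matched, missed = best$missed,
                       extra_private = best$extra, stringsAsFactors = FALSE),
            class = c("mt_classification", "data.frame"))
}

better_classification <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$depth != b$depth) return(a$depth > b$depth)
  if (a$extra != b$extra) return(a$extra < b$extra)
  a$name < b$name
}

#' Classify a list of haplotypes
#'
#' @param haps list of [haplotype()] objects.
#' @inheritParams classify
#' @return Data frame, one row per haplotype.
#' @export
classify_panel <- function(haps, tree) {
  do.call(rbind, lapply(haps, classify, tree = tree))
}

#' Type a single diagnostic site
#'
#' Reports the state of one position relative to the reference — the
#' coding-region typing used to confirm V-lineage membership at np 7765 when
#' control-region motifs are uninformative.
#'
#' @param hap a [haplotype()].
#' @param position rCRS position.
#' @return `"present"` (a derived, non-reverted variant at the site),
#'   `"absent"` (reference state, including back-mutated sites), or
#'   `"no_coverage"`.
#' @export
type_diagnostic <- function(hap, position) {
  check_pos(position)
  if (!position_covered(position, hap$coverage_ranges)) return("no_coverage")
  at_site <- hap$variants[variant_site(hap$variants) == position]
  at_site <- at_site[!is_back(at_site)]
  if (length(at_site)) "present" else "absent"
}

#' Search a haplotype panel for carriers of a motif
#'
#' Finds every panel haplotype whose covered variants contain the full query
#' motif. Haplotypes whose declared coverage misses any query position are
#' excluded as uninformative rather than counted as non-carriers.
#'
#' @param query_motif character vector of variant tokens.
#' @param panel list of [haplotype()] objects with population labels.
#' @param reference reference sequence for canonicalization.
#' @return List with `matches` (data frame `sample_id`, `population`) and
#'   `counts` (per population: informative sample count `n`, carrier count
#'   `hits`, and `frequency`).
#' @export
search_haplotype_panel <- function(query_motif, panel,
                                   reference = synthetic_rcrs()) {
  query <- canonical_variants(query_motif, reference)
  qpos <- variant_site(query)
  status <- vapply(panel, function(h) {
    if (!all(position_covered(qpos, h$coverage_ranges))) return(NA)
    all(query %in% h$variants[!is_back(h$variants)])
  }, NA)
  informative <- !is.na(status)
  pops <- vapply(panel, `[[`, "", "population")
  matches <- data.frame(
    sample_id = vapply(panel[which(status %in% TRUE)], `[[`, "", "sample_id"),
    population = pops[which(status %in% TRUE)],
    stringsAsFactors = FALSE)
  tab_n <- table(pops[informative])
  tab_h <- table(factor(pops[status %in% TRUE], levels = names(tab_n)))
  counts <- data.frame(population = names(tab_n),
                       n = as.integer(tab_n), hits = as.integer(tab_h),
                       stringsAsFactors = FALSE)
  counts$frequency <- ifelse(counts$n > 0, counts$hits / counts$n, 0)
  list(matches = matches, counts = counts)
}
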