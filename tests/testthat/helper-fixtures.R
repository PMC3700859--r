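# Shared fixtures and independent oracles.

fixture_path <- function(name) {
  system.file("extdata", name, package = "mtphylo", mustWork = TRUE)
}

load_fixture_motif <- function() {
  load_motif_tree(fixture_path("motif_tree_synthetic.txt"))
}

load_fixture_clades <- function(masked = TRUE) {
  haps <- read_haplotype_table(fixture_path("clades_synthetic_mitogenomes.tsv"))
  if (masked) lapply(haps, apply_mask) else haps
}

clade_members <- function(haps, prefix) {
  haps[startsWith(vapply(haps, `[[`, "", "sample_id"), prefix)]
}

# Independent Saillard-error oracle: explicit edge-list enumeration with its
# own reachability walk (no reuse of the package's subtree helpers).
oracle_sigma <- function(tree, reference) {
  edges <- tree$edges
  obs <- which(tree$nodes$observed)
  reach <- function(start) {     # nodes at or below `start`
    out <- start
    repeat {
      add <- edges$child[edges$parent %in% out & !(edges$child %in% out)]
      if (!length(add)) break
      out <- c(out, add)
    }
    out
  }
  below <- reach(reference)
  n <- length(obs)
  s2 <- 0
  for (k in seq_len(nrow(edges))) {
    if (!(edges$parent[k] %in% below)) next
    n_e <- length(intersect(reach(edges$child[k]), obs))
    s2 <- s2 + (n_e / n)^2 * length(tree$edge_labels[[k]])
  }
  sqrt(s2)
}

# Brute-force position-by-position diff of two equal-length ungapped
# sequences (substitutions only).
oracle_seq_diff <- function(sample, reference) {
  s <- strsplit(sample, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  stopifnot(length(s) == length(r))
  pos <- which(s != r)
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(pos, function(p) {
    if (identical(s[p], unname(partner[r[p]]))) as.character(p)
    else paste0(p, s[p])
  }, "")
}

# Exhaustive per-haplotype subset scan for motif carriers.
oracle_panel_hits <- function(query, panel) {
  hits <- character(0)
  for (h in panel) {
    qpos <- as.integer(sub("^@?([0-9]+).*$", "\\1", query))
    covered <- all(vapply(qpos, function(p) {
      any(p >= h$coverage_ranges[, 1] & p <= h$coverage_ranges[, 2])
    }, TRUE))
    if (!covered) next
    nonback <- h$variants[!startsWith(h$variants, "@")]
    if (all(query %in% nonback)) hits <- c(hits, h$sample_id)
  }
  hits
}
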