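#' Configuration for the synthetic-genealogy generator
#'
#' The generator emulates the clade structure seen in regional mtDNA
#' phylogenies: a founder node from which 7–12 sampled haplotypes descend,
#' Poisson-distributed mutations on branches, a short (2–3 mutation) stem
#' branch to the closest sister lineage, and optional recurrent hits at
#' hypermutable sites.
#'
#' @param n_samples number of sampled haplotypes.
#' @param topology `"star"` (founder radiation), `"coalescent"` (random
#'   coalescent genealogy), or `"fixed_tree"` (replay a supplied branch
#'   table).
#' @param mutation_rate expected mutations per root-to-tip lineage.
#' @param stem_length integer mutation count of the stem to the sister
#'   lineage (0 = no stem).
#' @param hotspot_recurrence_prob probability that a mutation event re-hits
#'   an already-mutated site (creating recurrence/back mutation) instead of
#'   a fresh one.
#' @param seed integer; fully determines the output.
#' @param root_motif ancestral variant set of the clade founder
#'   (rCRS-relative labels).
#' @param tree for `topology = "fixed_tree"`: data frame `parent`, `child`,
#'   `n_mut` describing branches of a rooted tree with node 1 as root;
#'   leaves are nodes that never appear as parents.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 10L,
                              topology = c("star", "coalescent", "fixed_tree"),
                              mutation_rate = 1.5, stem_length = 2L,
                              hotspot_recurrence_prob = 0,
                              seed = 1L, root_motif = character(),
                              tree = NULL) {
  topology <- match.arg(topology)
  stopifnot(n_samples >= 1L, mutation_rate >= 0, stem_length >= 0,
            hotspot_recurrence_prob >= 0, hotspot_recurrence_prob <= 1)
  if (topology == "fixed_tree" && is.null(tree)) {
    stop("fixed_tree topology needs a branch table in `tree`")
  }
  structure(list(n_samples = as.integer(n_samples), topology = topology,
                 mutation_rate = mutation_rate,
                 stem_length = as.integer(stem_length),
                 hotspot_recurrence_prob = hotspot_recurrence_prob,
                 seed = as.integer(seed), root_motif = root_motif,
                 tree = tree),
            class = "simulation_config")
}

with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a clade genealogy and its sampled haplotypes
#'
#' Places Poisson-distributed mutation events on the branches of the chosen
#' genealogy. Each event hits a fresh, uniformly chosen unused position
#' (finite sites), except with probability `hotspot_recurrence_prob`, when
#' it re-hits an already-mutated site: a re-hit on a site currently derived
#' reverts it (a back mutation), otherwise it recreates the variant (a
#' recurrence). Positions under the default hotspot mask are never used for
#' fresh mutations, so masking leaves simulated signal intact.
#'
#' @param config a [simulation_config()].
#' @return List with `true_tree` (the generating [clade_tree], stem grafted
#'   when `stem_length > 0`), `haplotypes` (list of [haplotype()]),
#'   and `truth` (`rho`, `sigma`, `stem_length`, `mutation_rate` of the
#'   generating process).
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng_seed(config$seed, simulate_clade_impl(config))
}

simulate_clade_impl <- function(config) {
  n <- config$n_samples
  branches <- switch(config$topology,
    star = data.frame(parent = rep(1L, n), child = seq_len(n) + 1L,
                      mean_mut = config$mutation_rate),
    coalescent = coalescent_branches(n, config$mutation_rate),
    fixed_tree = {
      tr <- config$tree
      data.frame(parent = tr$parent, child = tr$child, mean_mut = NA,
                 n_mut = tr$n_mut)
    })
  masked <- mask_positions(hotspot_mask())
  used <- integer(0)
  root_state <- canonical_variants(config$root_motif)
  n_nodes <- max(branches$parent, branches$child)
  states <- vector("list", n_nodes)
  states[[1L]] <- root_state
  edge_labels <- vector("list", nrow(branches))
  # parents listed before children in all three constructions
  ord <- order(branches$parent)
  for (k in ord) {
    p <- branches$parent[k]; ch <- branches$child[k]
    n_mut <- if (config$topology == "fixed_tree") branches$n_mut[k] else
      stats::rpois(1L, branches$mean_mut[k])
    state <- states[[p]]
    labs <- character(0)
    for (e in seq_len(n_mut)) {
      rehit <- length(used) > 0 &&
        stats::runif(1) < config$hotspot_recurrence_prob
      if (rehit) {
        site <- used[sample.int(length(used), 1L)]
      } else {
        repeat {
          site <- sample.int(16569L, 1L)
          if (!(site %in% masked) && !(site %in% used)) break
        }
        used <- c(used, site)
      }
      lab <- as.character(site)
      if (lab %in% state) state <- setdiff(state, lab)
      else state <- union(state, lab)
      labs <- c(labs, lab)
    }
    # net out sites hit an even number of times on this branch (invisible)
    odd <- names(which(table(labs) %% 2L == 1L))
    net <- ifelse(odd %in% states[[p]], paste0("@", odd), odd)
    states[[ch]] <- sort_labels(state)
    edge_labels[[k]] <- sort_labels(net)
  }
  leaves <- setdiff(seq_len(n_nodes), branches$parent)
  nodes <- data.frame(name = c("MRCA", rep("", n_nodes - 1L)),
                      observed = FALSE, sample_id = NA_character_,
                      stringsAsFactors = FALSE)
  nodes$observed[leaves] <- TRUE
  nodes$sample_id[leaves] <- paste0("S", seq_along(leaves))
  nodes$name[leaves] <- nodes$sample_id[leaves]
  tree <- new_clade_tree(nodes, states,
                         branches[, c("parent", "child")],
                         edge_labels, root = 1L)
  if (config$stem_length > 0L) {
    stem <- character(0)
    for (s in seq_len(config$stem_length)) {
      repeat {
        site <- sample.int(16569L, 1L)
        if (!(site %in% masked) && !(site %in% used)) break
      }
      used <- c(used, site)
      stem <- c(stem, as.character(site))
    }
    # the stem variants are part of every clade state, gained on the stem
    tree$states <- lapply(tree$states, function(s) sort_labels(c(s, stem)))
    tree <- with_stem(tree, stem, parent_name = "split_node")
  }
  haps <- lapply(which(tree$nodes$observed), function(v) {
    haplotype(tree$nodes$sample_id[v], variants = tree$states[[v]],
              population = "sim", coverage = "complete_genome")
  })
  mrca <- mrca_node(tree)
  list(true_tree = tree, haplotypes = haps,
       truth = list(rho = rho_statistic(tree, mrca),
                    sigma = sigma_rho(tree, mrca),
                    stem_length = config$stem_length,
                    mutation_rate = config$mutation_rate))
}

coalescent_branches <- function(n, rate) {
  if (n == 1L) {
    return(data.frame(parent = 1L, child = 2L, mean_mut = rate))
  }
  phy <- ape::rcoal(n)
  depth <- max(ape::node.depth.edgelength(phy))
  # breadth-first renumbering so the root is 1 and parents precede children
  ntip <- length(phy$tip.label)
  old_root <- ntip + 1L
  remap <- integer(ntip + phy$Nnode)
  remap[old_root] <- 1L
  nxt <- 2L
  queue <- old_root
  edges <- phy$edge
  out <- data.frame(parent = integer(), child = integer(),
                    mean_mut = numeric())
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (k in which(edges[, 1] == v)) {
      ch <- edges[k, 2]
      remap[ch] <- nxt; nxt <- nxt + 1L
      out <- rbind(out, data.frame(parent = remap[v], child = remap[ch],
                                   mean_mut = rate * phy$edge.length[k] / depth))
      queue <- c(queue, ch)
    }
  }
  out
}

mask_positions <- function(mask) {
  c(mask$positions, unlist(lapply(mask$intervals, function(iv) iv[1]:iv[2])))
}

#' Simulate a population panel with a planted frequency cline
#'
#' Generates control-region haplotype panels for a set of populations whose
#' carrier frequency of a target motif follows a planted spatial pattern —
#' by default a peak that decays with distance, emulating a regionally
#' confined founder lineage. Carrier counts are planted exactly
#' (`round(frequency * n)`), so tabulated frequencies are recoverable to
#' rounding.
#'
#' @param populations data frame `population_id`, `latitude`, `longitude`,
#'   `n`; defaults to a 5 x 5 grid of 24 survey populations plus a distal
#'   one.
#' @param target_motif variant labels defining the surveyed lineage.
#' @param peak `c(longitude, latitude)` of the planted frequency peak.
#' @param peak_frequency frequency at the peak.
#' @param decay e-folding distance (degrees) of the planted peak.
#' @param seed integer seed.
#' @return List with `panel` (list of [haplotype()]), `populations` (the
#'   input plus planted `count` and `frequency` columns), and `truth`
#'   (`peak`, `peak_frequency`).
#' @export
simulate_population_panel <- function(populations = NULL,
                                      target_motif = c("16270", "16189"),
                                      peak = c(-1.5, 43.0),
                                      peak_frequency = 0.17,
                                      decay = 1.2, seed = 1L) {
  if (is.null(populations)) {
    g <- expand.grid(longitude = seq(-4, 0, length.out = 5),
                     latitude = seq(42, 44, length.out = 5))
    populations <- data.frame(population_id = paste0("P", seq_len(nrow(g))),
                              latitude = g$latitude, longitude = g$longitude,
                              n = 100L, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("population_id", "latitude", "longitude", "n") %in%
                  names(populations)))
  with_rng_seed(seed, {
    d2 <- (populations$longitude - peak[1])^2 +
      (populations$latitude - peak[2])^2
    freq <- peak_frequency * exp(-d2 / (2 * decay^2))
    count <- as.integer(round(freq * populations$n))
    target <- canonical_variants(target_motif)
    background <- c("16126", "16069")    # a distinct non-target motif
    panel <- list()
    for (i in seq_len(nrow(populations))) {
      for (j in seq_len(populations$n[i])) {
        carrier <- j <= count[i]
        extra_pool <- setdiff(16024:16365, c(variant_site(target), 16182,
                                             16183, variant_site(background)))
        extra <- if (stats::runif(1) < 0.3) {
          as.character(sample(extra_pool, 1L))
        } else character(0)
        vars <- if (carrier) c(target, extra) else c(background, extra)
        panel[[length(panel) + 1L]] <-
          haplotype(sprintf("%s_%03d", populations$population_id[i], j),
                    variants = vars,
                    population = populations$population_id[i],
                    coverage = "control_region")
      }
    }
    populations$count <- count
    populations$frequency <- count / populations$n
    list(panel = panel, populations = populations,
         truth = list(peak = peak, peak_frequency = peak_frequency))
  })
}
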