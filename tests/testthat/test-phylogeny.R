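test_that("two haplotypes sharing one variant give the textbook 2-taxon tree", {
  haps <- list(haplotype("A", c("1000", "2000")),
               haplotype("B", c("1000")))
  tr <- build_mp_tree(haps)
  expect_equal(parsimony_length(tr), 2L)
  # shared variant below the root, private variant on the deeper branch
  depths <- mutation_depths(tr, tr$root)
  smp <- tree_samples(tr)
  expect_equal(depths[smp$node[smp$sample_id == "A"]], 2L)
  expect_equal(depths[smp$node[smp$sample_id == "B"]], 1L)
})

test_that("perfect-phylogeny simulations are reconstructed exactly", {
  for (seed in 1:10) {
    cfg <- simulation_config(n_samples = 10, topology = "coalescent",
                             mutation_rate = 1.8, seed = seed,
                             stem_length = 0)
    sim <- simulate_clade(cfg)
    tr <- build_mp_tree(sim$haplotypes)
    expect_equal(parsimony_length(tr), parsimony_length(sim$true_tree))
    expect_equal(rho_statistic(tr), sim$truth$rho)
    expect_equal(sigma_rho(tr), sim$truth$sigma)
  }
})

test_that("sampled haplotypes replay exactly from the root (conservation)", {
  haps <- clade_members(load_fixture_clades(), "U5b1f")
  motif <- load_fixture_motif()
  tr <- build_mp_tree(haps, root_motif = full_motif(motif, "U5b1f"))
  smp <- tree_samples(tr)
  for (k in seq_len(nrow(smp))) {
    h <- haps[[match(smp$sample_id[k], vapply(haps, `[[`, "", "sample_id"))]]
    expect_setequal(tr$states[[smp$node[k]]],
                    h$variants[!startsWith(h$variants, "@")])
  }
})

test_that("parsimony length never exceeds the generating tree's length", {
  for (seed in 1:15) {
    cfg <- simulation_config(n_samples = 8, topology = "star",
                             mutation_rate = 2,
                             hotspot_recurrence_prob = 0.25, seed = seed,
                             stem_length = 0)
    sim <- simulate_clade(cfg)
    tr <- build_mp_tree(sim$haplotypes)
    expect_lte(parsimony_length(tr), parsimony_length(sim$true_tree))
  }
})

test_that("exact search length agrees with the branch-and-bound oracle", {
  # dual route: our tree length vs phangorn's parsimony score of the same
  # data under its own search
  for (seed in c(3, 42)) {
    cfg <- simulation_config(n_samples = 7, topology = "star",
                             mutation_rate = 2,
                             hotspot_recurrence_prob = 0.3, seed = seed,
                             stem_length = 0)
    sim <- simulate_clade(cfg)
    tr <- build_mp_tree(sim$haplotypes)

    vars <- lapply(sim$haplotypes, `[[`, "variants")
    chars <- sort(unique(unlist(vars)))
    mat <- rbind(`__anc__` = rep("0", length(chars)),
                 do.call(rbind, lapply(vars, function(v) {
                   as.character(as.integer(chars %in% v))
                 })))
    rownames(mat)[-1] <- paste0("H", seq_along(vars))
    pd <- phangorn::phyDat(mat, type = "USER", levels = c("0", "1"))
    found <- phangorn::bab(pd, trace = 0)
    first <- if (inherits(found, "phylo")) found else found[[1]]
    oracle <- phangorn::parsimony(first, pd)
    expect_equal(parsimony_length(tr), oracle)
  }
})

test_that("fixed-tree replay recovers the planted 5-leaf genealogy", {
  branches <- data.frame(parent = c(1, 1, 2, 2, 3, 3, 7, 7),
                         child = c(2, 3, 4, 5, 6, 7, 8, 9),
                         n_mut = c(2, 1, 1, 1, 1, 1, 1, 1))
  cfg <- simulation_config(n_samples = 5, topology = "fixed_tree",
                           tree = branches, seed = 9, stem_length = 0)
  sim <- simulate_clade(cfg)
  tr <- build_mp_tree(sim$haplotypes)
  expect_equal(parsimony_length(tr), sum(branches$n_mut))
  expect_equal(rho_statistic(tr), sim$truth$rho)
  net <- build_mj_network(sim$haplotypes)
  expect_true(network_matches_tree(net, tr))
})

test_that("clade extraction reports members and stem lengths", {
  motif <- load_fixture_motif()
  haps <- load_fixture_clades()
  for (case in list(list("U5b1f", 3L, 12L), list("V22", 2L, 9L),
                    list("J1c5c1", 3L, 7L))) {
    hg <- case[[1]]
    members <- clade_members(haps, hg)
    tr <- build_mp_tree(members, root_motif = full_motif(motif, hg))
    tr <- with_stem(tr, motif$defining[[hg]], parent_name = "sister_anc",
                    clade_name = hg)
    ext <- extract_clade(tr, hg)
    expect_equal(ext$stem_length, case[[2]])
    expect_length(ext$members, case[[3]])
    expect_error(extract_clade(tr, "sister_anc"), "root")
  }
})

test_that("simulated clades with planted stems recover the stem length", {
  cfg <- simulation_config(n_samples = 6, topology = "star",
                           mutation_rate = 1, seed = 77, stem_length = 5L)
  sim <- simulate_clade(cfg)
  tree <- sim$true_tree
  tree$nodes$name[mrca_node(tree)] <- "clade"
  expect_equal(extract_clade(tree, "clade")$stem_length, 5L)
})

test_that("recurrence flags mark exactly the multiply-hit sites", {
  # one recurrence planted by hand across two subtrees
  t1 <- build_mp_tree(list(haplotype("A", c("1000", "2000")),
                           haplotype("B", c("1000", "3000"))))
  t2 <- build_mp_tree(list(haplotype("C", c("5000", "2000")),
                           haplotype("D", c("5000"))))
  ann <- annotate_recurrence(t1, context = list(t1, t2))
  expect_equal(attr(ann, "recurrent_sites"), 2000L)
  flagged <- unlist(lapply(seq_along(ann$edge_labels), function(k) {
    ann$edge_labels[[k]][ann$edge_recurrent[[k]]]
  }))
  expect_equal(unique(flagged), "2000")

  # single-edge variants are never flagged
  solo <- annotate_recurrence(t1, context = list(t1))
  expect_equal(length(attr(solo, "recurrent_sites")), 0L)

  # simulator-planted recurrences are recovered
  cfg <- simulation_config(n_samples = 10, topology = "star",
                           mutation_rate = 3,
                           hotspot_recurrence_prob = 0.4, seed = 1,
                           stem_length = 0)
  sim <- simulate_clade(cfg)
  counts <- table(sub("^@", "",
                      unlist(sim$true_tree$edge_labels)))
  planted <- sort(as.integer(names(counts)[counts > 1]))
  ann2 <- annotate_recurrence(sim$true_tree)
  expect_equal(attr(ann2, "recurrent_sites"), planted)
})

test_that("trivial median-joining cases match the textbook expectations", {
  # two haplotypes, one difference: a single link, no medians
  net <- build_mj_network(list(haplotype("A", "1000"),
                               haplotype("B", character(0))))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sum(!net$nodes$sampled), 0L)

  # three haplotypes pairwise differing at 3 sites: one degree-3 median
  net3 <- build_mj_network(list(haplotype("A", "1000"),
                                haplotype("B", "2000"),
                                haplotype("C", "3000")))
  med <- which(!net3$nodes$sampled)
  expect_length(med, 1L)
  deg <- table(c(net3$edges$from, net3$edges$to))
  expect_equal(unname(deg[as.character(med)]), 3L)
  # the median is the empty (ancestral) state here
  expect_equal(net3$states[[med]], character(0))
})

test_that("the epsilon=0 network contains a minimum spanning network", {
  haps <- clade_members(load_fixture_clades(), "V22")
  net <- build_mj_network(haps, epsilon = 0L)
  # every sampled haplotype is a node
  ids <- unlist(net$nodes$sample_ids)
  expect_setequal(ids, vapply(haps, `[[`, "", "sample_id"))
  # edge labels equal the state difference of their endpoints
  for (k in seq_len(nrow(net$edges))) {
    a <- net$states[[net$edges$from[k]]]
    b <- net$states[[net$edges$to[k]]]
    expect_setequal(net$edge_labels[[k]],
                    union(setdiff(a, b), setdiff(b, a)))
  }
  # connectivity
  n <- nrow(net$nodes)
  reach <- 1L
  repeat {
    nxt <- unique(c(reach,
                    net$edges$to[net$edges$from %in% reach],
                    net$edges$from[net$edges$to %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_length(reach, n)
})

test_that("newick export with edge labels round-trips", {
  motif <- load_fixture_motif()
  haps <- clade_members(load_fixture_clades(), "J1c5c1")
  tr <- build_mp_tree(haps, root_motif = full_motif(motif, "J1c5c1"))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_clade_tree_newick(tr, path)
  back <- read_clade_tree_newick(path)
  expect_equal(rho_statistic(back), rho_statistic(tr))
  expect_equal(sigma_rho(back), sigma_rho(tr))
  expect_setequal(tree_samples(back)$sample_id, tree_samples(tr)$sample_id)
  expect_setequal(back$states[[back$root]], tr$states[[tr$root]])
})
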