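test_that("motif trees load, validate, and expose cumulative motifs", {
  motif <- load_fixture_motif()
  expect_s3_class(motif, "motif_tree")
  expect_true(all(c("U5b1f", "J1c5c1", "V22", "H2a2a1") %in%
                    motif$nodes$name))

  # full motif equals the union of defining variants along the root path,
  # checked by brute-force path enumeration
  for (nm in motif$nodes$name) {
    path <- character(0)
    cur <- nm
    while (!is.na(cur)) {
      path <- c(cur, path)
      cur <- motif$nodes$parent[match(cur, motif$nodes$name)]
    }
    expected <- unique(unlist(motif$defining[path]))
    expected <- expected[!startsWith(expected, "@")]
    expect_setequal(full_motif(motif, nm), expected)
  }

  expect_equal(motif_stem_length(motif, "U5b1f"), 3L)
  expect_equal(motif_stem_length(motif, "J1c5c1"), 3L)
  expect_equal(motif_stem_length(motif, "V22"), 2L)
})

test_that("malformed motif files are rejected", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("root", "    orphan 73"), p)    # depth jumps past a parent
  expect_error(load_motif_tree(p), "has not been listed")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("root", "  A 73", "  A 150"), p2)
  expect_error(load_motif_tree(p2), "duplicate")
  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("root", "  A"), p3)
  expect_error(load_motif_tree(p3), "no defining variants")
})

test_that("the reference haplotype classifies to the rCRS-anchored node", {
  motif <- load_fixture_motif()
  cls <- classify(haplotype("ref", character(0)), motif)
  expect_equal(cls$best_node, "H2a2a1")
  expect_equal(cls$missed, 0L)
})

test_that("HV0 haplotypes with the np 7765 transition reach V22", {
  motif <- load_fixture_motif()
  h <- haplotype("x", c("16298", "4580", "150", "7765"))
  expect_equal(classify(h, motif)$best_node, "V22")
})

test_that("a back-mutated np 150 hotspot still classifies into the V branch", {
  motif <- load_fixture_motif()
  h <- haplotype("bm", c("16298", "4580", "@150", "7765", "15671"))
  cls <- classify(h, motif)
  expect_equal(cls$best_node, "V22")
  expect_equal(cls$missed, 1L)   # the reverted 150
  expect_equal(cls$extra_private, 0L)
})

test_that("classification is deterministic and order-invariant", {
  motif <- load_fixture_motif()
  vars <- c("16270", "16192", "11467", "12308", "150", "14182")
  a <- classify(haplotype("a", vars), motif)
  b <- classify(haplotype("b", rev(vars)), motif)
  expect_equal(a$best_node, b$best_node)
  expect_equal(a$matched, b$matched)
})

test_that("matched + missed equals the covered motif size", {
  motif <- load_fixture_motif()
  h <- haplotype("cr", c("16270", "16192"), coverage = "control_region")
  cls <- classify(h, motif)
  m <- full_motif(motif, cls$best_node)
  pos <- as.integer(sub("^@?([0-9]+).*$", "\\1", m))
  covered <- sum(pos >= 16024 | pos <= 576)
  expect_equal(cls$matched + cls$missed, covered)
})

test_that("simulated haplotypes classify back to their generating node", {
  motif <- load_fixture_motif()
  nodes <- setdiff(motif$nodes$name, "H2a2a1")
  taken <- unique(unlist(lapply(motif$nodes$name,
                                function(n) full_motif(motif, n))))
  pool <- setdiff(600:16000,
                  as.integer(sub("[ACGT]?$", "", taken)))
  set.seed(101)
  correct <- 0L
  for (i in 1:100) {
    nm <- sample(nodes, 1)
    privates <- as.character(sample(pool, sample(0:2, 1)))
    h <- haplotype(paste0("sim", i), c(full_motif(motif, nm), privates))
    if (classify(h, motif)$best_node == nm) correct <- correct + 1L
  }
  expect_gte(correct, 99L)
})

test_that("diagnostic-site typing distinguishes present/absent/no_coverage", {
  v22 <- haplotype("v", c("16298", "4580", "150", "7765", "15671"))
  expect_equal(type_diagnostic(v22, 7765), "present")
  expect_equal(type_diagnostic(haplotype("r", character(0)), 7765), "absent")
  cr <- haplotype("cr", "16270", coverage = "control_region")
  expect_equal(type_diagnostic(cr, 7765), "no_coverage")
  expect_error(type_diagnostic(v22, 20000), "outside")
  # a back-mutated site types as absent
  bm <- haplotype("bm", c("@150", "4580"))
  expect_equal(type_diagnostic(bm, 150), "absent")
})

test_that("panel search matches the exhaustive scan oracle", {
  motif <- load_fixture_motif()
  u5 <- full_motif(motif, "U5")
  # constructed panel: 3 carriers among 20
  set.seed(5)
  panel <- c(
    lapply(1:3, function(i) {
      haplotype(paste0("carrier", i), c(u5, as.character(6000 + i)),
                population = c("A", "A", "B")[i])
    }),
    lapply(4:20, function(i) {
      haplotype(paste0("other", i), c("16126", "16069"),
                population = sample(c("A", "B"), 1))
    }))
  res <- search_haplotype_panel(u5, panel)
  expect_equal(nrow(res$matches), 3L)
  expect_setequal(res$matches$sample_id, oracle_panel_hits(u5, panel))
  expect_equal(sum(res$counts$hits), 3L)

  # coverage rule: a query site off-coverage excludes, not counts absent
  cr_only <- haplotype("cr", c("16270", "16192"),
                       population = "C", coverage = "control_region")
  res2 <- search_haplotype_panel(u5, c(panel, list(cr_only)))
  expect_false("C" %in% res2$counts$population)

  # random panels vs oracle
  for (rep in 1:5) {
    q <- as.character(sample(700:5000, 2))
    rnd <- lapply(1:15, function(i) {
      haplotype(paste0("r", rep, "_", i),
                unique(as.character(sample(700:5000, 4))),
                population = "P")
    })
    got <- search_haplotype_panel(q, rnd)$matches$sample_id
    expect_setequal(got, oracle_panel_hits(canonical_variants(q), rnd))
  }
})

test_that("the bundled synthetic clades classify to their haplogroups", {
  motif <- load_fixture_motif()
  cls <- classify_panel(load_fixture_clades(), motif)
  expect_equal(as.integer(table(cls$best_node)[c("J1c5c1", "U5b1f", "V22")]),
               c(7L, 12L, 9L))
  expect_true(all(startsWith(cls$haplotype_id, cls$best_node)))
})
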