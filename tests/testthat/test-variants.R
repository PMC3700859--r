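test_that("variant tokens parse to the right kind and round-trip", {
  ref <- synthetic_rcrs()

  v <- parse_variant("7765")
  expect_equal(v$position, 7765L)
  expect_equal(v$kind, "transition")
  expect_false(v$back_mutation)

  v <- parse_variant("@150")
  expect_true(v$back_mutation)
  expect_equal(v$kind, "transition")
  expect_equal(v$label, "@150")

  # reference carries T at 152: suffix A is a purine<->pyrimidine change
  expect_equal(substr(ref, 152, 152), "T")
  v <- parse_variant("152A")
  expect_equal(v$kind, "transversion")
  expect_equal(v$derived_base, "A")

  # explicit transition suffix canonicalizes to the bare form
  expect_equal(parse_variant("152C")$label, "152")

  cases <- c("7765", "@150", "152A", "309.1C", "523 del", "@16192")
  for (tok in cases) {
    expect_identical(format_variant(parse_variant(tok)), tok)
  }
  # alternative deletion spellings collapse to the canonical one
  expect_equal(parse_variant("523del")$label, "523 del")
  expect_equal(parse_variant("523d")$label, "523 del")
})

test_that("malformed tokens are rejected", {
  expect_error(parse_variant("xyz"), "malformed")
  expect_error(parse_variant("16570"), "outside")
  expect_error(parse_variant("0"), "outside")
  ref <- synthetic_rcrs()
  refbase <- substr(ref, 100, 100)
  expect_error(parse_variant(paste0("100", refbase)), "reference base")
})

test_that("space-separated token strings tokenize with two-word deletions", {
  df <- parse_variants("73 523 del 309.1C")
  expect_equal(df$label, c("73", "309.1C", "523 del"))
  expect_equal(df$kind, c("transition", "insertion", "deletion"))
})

test_that("hotspot masking removes exactly the masked classes", {
  h <- haplotype("s", c("16519", "16270"))
  m <- apply_mask(h)
  expect_equal(m$variants, "16270")
  expect_equal(attr(m, "n_masked"), 1L)

  h0 <- haplotype("empty", character(0))
  expect_equal(apply_mask(h0)$variants, character(0))

  h2 <- haplotype("s2", c("16182", "16183", "309.1C", "523 del", "73"))
  expect_equal(apply_mask(h2)$variants, "73")

  # idempotence, and untouched outside the mask
  mm <- apply_mask(apply_mask(h2))
  expect_equal(mm$variants, apply_mask(h2)$variants)
  # input untouched
  expect_equal(h2$variants,
               canonical_variants(c("16182", "16183", "309.1C", "523 del",
                                    "73")))
})

test_that("length-heteroplasmy tokens are masked wherever they fall", {
  # a poly-C insertion far from any masked interval
  h <- haplotype("s", c("16193.2C", "73"))
  expect_equal(apply_mask(h)$variants, "73")
  relaxed <- hotspot_mask(exclude_length_heteroplasmy = FALSE)
  expect_true("16193.2C" %in% apply_mask(h, relaxed)$variants)
})

test_that("mask config files round-trip the default mask", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# default-equivalent mask", "position 16182",
               "position 16183", "position 16519", "interval 303 315",
               "interval 522 524", "length_heteroplasmy true"), path)
  m <- read_mask_config(path)
  expect_equal(m$positions, hotspot_mask()$positions)
  expect_equal(m$intervals, hotspot_mask()$intervals)
  expect_error(read_mask_config({
    p2 <- withr::local_tempfile(fileext = ".txt")
    writeLines("frobnicate 1", p2); p2
  }), "unknown mask directive")
})

test_that("variant calling recovers exactly the introduced differences", {
  ref <- synthetic_rcrs()

  # identity over the control region
  expect_equal(call_variants(ref, ref, range = rbind(c(16024, 16365))),
               character(0))

  s <- ref
  substr(s, 16270, 16270) <- "T"    # reference has C: a transition
  expect_equal(call_variants(s, ref), "16270")

  # random 5-substitution mutants vs the brute-force diff oracle
  set.seed(11)
  for (rep in 1:10) {
    pos <- sample(1000:16000, 5)
    s <- ref
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    expect_setequal(call_variants(s, ref), oracle_seq_diff(s, ref))
  }

  expect_error(call_variants(gsub("A", "X", ref), ref), "non-nucleotide")
})

test_that("mutate_sequence and call_variants are mutual inverses", {
  ref <- synthetic_rcrs()
  set.seed(23)
  masked_pos <- c(16182, 16183, 16519, 303:315, 522:524)
  for (rep in 1:5) {
    pos <- sample(setdiff(600:16000, masked_pos), 6)
    labels <- canonical_variants(c(as.character(pos[1:4]),
                                   paste0(pos[5], ".1A"),
                                   paste(pos[6], "del")))
    aln <- mutate_sequence(labels, ref)
    called <- call_variants(aln$sample, aln$reference, align = FALSE)
    expect_setequal(called, labels)
  }
})

test_that("haplotype invariants are enforced", {
  expect_error(haplotype("d", c("73", "73")), "duplicate")
  expect_error(haplotype("c", "7765", coverage = "control_region"),
               "outside declared coverage")
  # two insertions at one position are distinct events, not duplicates
  expect_silent(haplotype("i", c("309.1C", "309.2C")))
  h <- haplotype("cr", c("16270", "73"), coverage = "control_region")
  expect_equal(h$coverage, "control_region")
})

test_that("haplotype tables round-trip losslessly", {
  haps <- load_fixture_clades(masked = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(haps, path)
  back <- read_haplotype_table(path)
  expect_equal(back, haps)
  # malformed table: missing columns
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", p2)
  expect_error(read_haplotype_table(p2), "lacks column")
})
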