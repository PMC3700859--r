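make_classifications <- function(pops, carriers, others, hg = "U5b1f") {
  do.call(rbind, lapply(seq_along(pops), function(i) {
    n <- carriers[i] + others[i]
    if (n == 0) return(NULL)
    data.frame(haplotype_id = sprintf("%s_%d", pops[i], seq_len(n)),
               best_node = c(rep(hg, carriers[i]), rep("H2a2a1", others[i])),
               population = pops[i], stringsAsFactors = FALSE)
  }))
}

test_that("per-population frequencies are exact counts over n", {
  pops <- data.frame(population_id = c("A", "B"), latitude = c(43, 43.5),
                     longitude = c(-2, -1), stringsAsFactors = FALSE)
  cls <- make_classifications(c("A", "B"), carriers = c(3L, 0L),
                              others = c(17L, 10L))
  tab <- tabulate_frequencies(cls, pops, "U5b1f")
  expect_equal(tab$frequency[tab$population_id == "A"], 0.15)
  expect_equal(tab$frequency[tab$population_id == "B"], 0)
  expect_equal(tab$count[tab$population_id == "total"], 3L)
})

test_that("the pooled row uses pooled counts, not the mean of ratios", {
  pops <- data.frame(population_id = c("peak", "absent"),
                     latitude = c(43.1, 43.2), longitude = c(-1.7, -4.0),
                     stringsAsFactors = FALSE)
  # 17% of 100 at the peak, 0 of 10 elsewhere: pooled = 17/110, not 8.5%
  cls <- make_classifications(c("peak", "absent"), carriers = c(17L, 0L),
                              others = c(83L, 10L))
  tab <- tabulate_frequencies(cls, pops, "U5b1f")
  total <- tab[tab$population_id == "total", ]
  expect_equal(total$frequency, 17 / 110)
  expect_false(isTRUE(all.equal(total$frequency,
                                mean(c(0.17, 0)))))
})

test_that("nested subclades count as carriers; unknown populations error", {
  pops <- data.frame(population_id = "A", latitude = 43, longitude = -2)
  cls <- data.frame(haplotype_id = c("x", "y"),
                    best_node = c("U5b1f", "U5b1f1a"),
                    population = "A", stringsAsFactors = FALSE)
  tab <- tabulate_frequencies(cls, pops, "U5b1f", total = FALSE)
  expect_equal(tab$count, 2L)
  cls$population[2] <- "nowhere"
  expect_error(tabulate_frequencies(cls, pops, "U5b1f"), "without metadata")
})

test_that("kriging is exact at data points and respects [0,1] clipping", {
  pops <- read_population_csv(fixture_path("populations_u5b1f_synthetic.csv"))
  surf <- interpolate_surface(pops, list(nx = 30, ny = 30))
  at <- as.matrix(pops[, c("longitude", "latitude")])
  pred <- interpolate_points(surf, at = at)
  expect_equal(pred, pops$frequency, tolerance = 1e-9)
  expect_true(all(surf$values >= 0 & surf$values <= 1))
  # constant data give a constant surface
  const <- pops; const$frequency <- 0.2
  sc <- interpolate_surface(const, list(nx = 10, ny = 10))
  expect_equal(range(sc$values), c(0.2, 0.2), tolerance = 1e-9)
})

test_that("a linear north-south cline interpolates monotonically", {
  set.seed(4)
  pts <- expand.grid(longitude = seq(-3, -1, by = 0.5),
                     latitude = seq(42, 44, by = 0.5))
  pts$frequency <- (pts$latitude - 42) / 2 * 0.2    # 0 at 42N, 0.2 at 44N
  pts$population_id <- paste0("p", seq_len(nrow(pts)))
  surf <- interpolate_surface(pts, list(nx = 9, ny = 21))
  mid <- surf$values[5, ]    # a single longitude column, south to north
  expect_true(all(diff(mid) > -1e-6))
  # IDW is exact at the data but shows the usual bullseye flats between
  # points, so only the endpoint values are asserted for it
  idw <- interpolate_surface(pts, list(nx = 9, ny = 21), method = "idw")
  expect_equal(idw$values[5, 1], 0, tolerance = 1e-9)
  expect_equal(idw$values[5, 21], 0.2, tolerance = 1e-9)
})

test_that("kriging and IDW agree within 0.05 on a dense regular fixture", {
  pts <- expand.grid(longitude = seq(-3, -1, by = 0.25),
                     latitude = seq(42.5, 43.5, by = 0.25))
  pts$frequency <- 0.1 + 0.05 * sin(pts$longitude * 2) *
    cos(pts$latitude * 3)
  pts$population_id <- paste0("p", seq_len(nrow(pts)))
  k <- interpolate_surface(pts, list(nx = 25, ny = 25), method = "kriging")
  i <- interpolate_surface(pts, list(nx = 25, ny = 25), method = "idw")
  expect_lt(max(abs(k$values - i$values)), 0.05)
})

test_that("degenerate interpolation inputs raise clean errors", {
  pts <- data.frame(population_id = c("a", "b", "c"),
                    longitude = c(-2, -1, 0), latitude = c(43, 43, 43),
                    frequency = c(0.1, 0.2, 0.3))
  expect_error(interpolate_surface(pts), "collinear")
  dup <- data.frame(population_id = c("a", "b"),
                    longitude = c(-2, -2), latitude = c(43, 43),
                    frequency = c(0.1, 0.2))
  expect_error(interpolate_surface(dup, method = "idw"), "conflicting")
  expect_error(interpolate_surface(pts[1:2, ], method = "kriging"),
               "at least 3")
})

test_that("ASCII grid export writes a well-formed header and full matrix", {
  pops <- read_population_csv(fixture_path("populations_u5b1f_synthetic.csv"))
  surf <- interpolate_surface(pops, list(nx = 12, ny = 8))
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(surf, path)
  lines <- readLines(path)
  expect_match(lines[1], "^ncols 12$")
  expect_match(lines[2], "^nrows 8$")
  expect_length(lines, 6 + 8)
  first_row <- as.numeric(strsplit(lines[7], " ")[[1]])
  expect_length(first_row, 12)
  # top line of the grid is the northernmost row
  expect_equal(first_row, unname(surf$values[, 8]), tolerance = 1e-6)
})
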