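test_that("a straight line gives two nodes and one edge of full length", {
  m <- matrix(FALSE, 60, 20); m[6:55, 10] <- TRUE
  g <- build_graph(m, c(6, 10))
  expect_equal(nrow(g$nodes), 2L)
  expect_length(g$edges, 1L)
  expect_equal(g$edges[[1]]$length_px, 49)
  expect_setequal(g$nodes$kind, c("origin", "tip"))
})

test_that("a T-shape yields one junction, three tips and three edges", {
  m <- t_skeleton()
  g <- build_graph(m, c(10, 40))
  kinds <- table(g$nodes$kind)
  expect_equal(unname(kinds["origin"]), 1)
  expect_length(g$edges, 3L)
  # degree scan: exactly one junction cluster
  expect_equal(sum(g$nodes$kind == "branch"), 1L)
})

test_that("cycles are permitted and satisfy the Euler formula", {
  m <- matrix(FALSE, 30, 30)
  m[10, 10:20] <- TRUE; m[20, 10:20] <- TRUE
  m[10:20, 10] <- TRUE; m[10:20, 20] <- TRUE
  m[5:10, 10] <- TRUE    # handle so the origin is a tip
  g <- build_graph(m, c(5, 10))
  cyclomatic <- length(g$edges) - nrow(g$nodes) + 1L
  expect_equal(cyclomatic, 1L)
})

test_that("graph construction is deterministic", {
  set.seed(11)
  gen <- generate_sequence(one_plant_config(
    n_frames = 10L,
    laterals = list(list(frame = 2L, pos_mm = 0.8, angle = 45,
                         growth = growth_linear(0.5)))))
  m <- gen$seq$frames[[10]] %in% c(1L, 2L)
  dim(m) <- dim(gen$seq$frames[[10]])
  s <- prune_spurs(skeletonize(m), 5L)
  g1 <- build_graph(s, c(13, 60))
  g2 <- build_graph(s, c(13, 60))
  expect_identical(g1, g2)
})

test_that("an origin far from the skeleton is rejected with the distance", {
  m <- matrix(FALSE, 30, 30); m[10:20, 15] <- TRUE
  expect_error(build_graph(m, c(1, 1)), "px")
})

test_that("sum of edge lengths matches an independent pixel-path total", {
  m <- t_skeleton()
  g <- build_graph(m, c(10, 40))
  total <- sum(vapply(g$edges, `[[`, numeric(1), "length_px"))
  # independent count: per pixel-pair steps over the whole skeleton
  indep <- sum(vapply(g$edges, function(e) {
    d <- diff(e$path)
    sum(sqrt(d[, 1]^2 + d[, 2]^2))
  }, numeric(1)))
  expect_lt(abs(total - indep) / indep, 0.005)
})

test_that("axis classification: bare path is all main, T splits main/lateral", {
  m <- matrix(FALSE, 60, 20); m[6:55, 10] <- TRUE
  ax <- classify_axes(build_graph(m, c(6, 10)))
  expect_length(ax$laterals, 0L)
  expect_equal(ax$main$length_px, 49)

  axt <- classify_axes(build_graph(t_skeleton(), c(10, 40)))
  # vertical (59 px) beats origin->junction->horizontal-end (20 + 30)
  expect_equal(length(axt$laterals), 1L)
  expect_equal(axt$main$length_px, 59, tolerance = 1e-6)
  expect_equal(axt$laterals[[1]]$length_px, 30, tolerance = 0.05)
  expect_lte(abs(axt$laterals[[1]]$base_rc[1] - 30), 1)
})

test_that("a lateral looping back to the main root stays one lateral and
          leaves the main-root length unchanged", {
  base <- matrix(FALSE, 60, 40)
  base[5:55, 15] <- TRUE
  ax0 <- classify_axes(build_graph(base, c(5, 15)))
  m <- base
  # lateral leaving at row 20, arcing right and reconnecting at row 48
  for (k in 0:9) m[20 + k, 15 + k] <- TRUE
  m[30:39, 24] <- TRUE
  for (k in 1:9) m[39 + k, 24 - k] <- TRUE
  ax <- classify_axes(build_graph(m, c(5, 15)))
  expect_equal(length(ax$laterals), 1L)
  expect_true(ax$laterals[[1]]$has_loop)
  expect_gt(length(ax$loop_edges), 0L)
  expect_equal(ax$main$length_px, ax0$main$length_px, tolerance = 0.05)
})

test_that("lateral matching is stable, mints fresh ids, and resolves
          nearby bases optimally", {
  set.seed(12)
  lat2 <- list(list(frame = 2L, pos_mm = 0.6, angle = 45,
                    growth = growth_linear(0.5)),
               list(frame = 2L, pos_mm = 1.4, angle = -40,
                    growth = growth_linear(0.5)))
  gen <- generate_sequence(one_plant_config(n_frames = 12L, laterals = lat2))
  get_axes <- function(t) {
    m <- gen$seq$frames[[t]] %in% c(1L, 2L)
    dim(m) <- dim(gen$seq$frames[[t]])
    classify_axes(build_graph(prune_spurs(skeletonize(m), 5L), c(13, 60)))
  }
  a10 <- get_axes(10L); a11 <- get_axes(11L)
  mp <- match_laterals(a10, a11, max_shift = 15)
  expect_equal(mp$prev, seq_along(a10$laterals))  # identity mapping

  # one new lateral appears: old ids preserved, fresh NA for the new one
  empty <- structure(list(laterals = list()), class = "axis_labeling")
  mp0 <- match_laterals(empty, a11)
  expect_true(all(is.na(mp0$prev)))

  # two bases 4 px apart, gate 10: assignment minimizes total base distance
  fake <- function(arcs, tips) {
    structure(list(laterals = lapply(seq_along(arcs), function(i)
      list(base_arc_px = arcs[i], tip_rc = tips[[i]], id = i))),
      class = "axis_labeling")
  }
  prev <- fake(c(10, 14), list(c(20, 20), c(24, 24)))
  cur <- fake(c(11, 15), list(c(21, 20), c(25, 24)))
  mp2 <- match_laterals(prev, cur, max_shift = 10)
  # brute force over both assignments: {1->1, 2->2} total 2 beats crossing 8
  expect_equal(mp2$prev, c(1L, 2L))
})
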