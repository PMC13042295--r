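test_that("empty configuration yields background-only frames and empty truth", {
  cfg <- synth_config(canvas = c(40L, 40L), n_frames = 3L, plants = list(),
                      rng_seed = 1L)
  gen <- generate_sequence(cfg)
  expect_length(gen$seq$frames, 3L)
  expect_true(all(vapply(gen$seq$frames, function(f) all(f == 0L),
                         logical(1))))
  expect_equal(nrow(gen$truth), 0L)
})

test_that("rendered main-root arc length tracks the analytic growth function", {
  # 1 mm/h at 15-min frames: frame 9 sits at t = 2 h, so truth MR = 2 mm
  gen <- generate_sequence(one_plant_config(n_frames = 9L))
  tr <- gen$truth
  mr <- tr[tr$structure == "main", ]
  expect_equal(mr$length_mm, pmax(0, (mr$frame - 1) * 0.25))
  # rendered class-1 pixel extent vs truth, every frame (2 px * scale band)
  for (t in seq_len(9L)) {
    px <- which(gen$seq$frames[[t]] == 1L, arr.ind = TRUE)
    rendered_mm <- (diff(range(px[, 1])) ) * 0.04
    expect_lt(abs(rendered_mm - mr$length_mm[mr$frame == t]), 2 * 0.04 + 0.08)
  }
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- one_plant_config(droplet_rate = 0.3, seed = 123L)
  g1 <- generate_sequence(cfg)
  g2 <- generate_sequence(cfg)
  expect_identical(g1$seq$frames, g2$seq$frames)
  expect_identical(g1$truth, g2$truth)
})

test_that("plant pixel sets are non-shrinking before artifact injection", {
  gen <- generate_sequence(one_plant_config(n_frames = 12L))
  prev <- gen$seq$frames[[1]] > 0L
  for (t in 2:12) {
    cur <- gen$seq$frames[[t]] > 0L
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("ground-truth lengths are non-decreasing and angles stay in range", {
  lat <- list(list(frame = 2L, pos_mm = 0.6, angle = 50,
                   growth = growth_linear(0.6)))
  gen <- generate_sequence(one_plant_config(n_frames = 20L, laterals = lat))
  tr <- gen$truth
  for (s in split(tr, interaction(tr$structure, tr$lateral_id, drop = TRUE))) {
    expect_true(all(diff(s$length_mm) >= -1e-9))
  }
  ang <- tr$theta_bt[!is.na(tr$theta_bt)]
  expect_true(all(ang >= 0 & ang <= 180))
})

test_that("droplet artifacts last exactly one frame", {
  cfg <- one_plant_config(n_frames = 40L, droplet_rate = 0.5, seed = 5L)
  gen <- generate_sequence(cfg)
  dr <- gen$artifacts[gen$artifacts$type == "droplet", ]
  expect_gt(nrow(dr), 0L)
  for (k in seq_len(nrow(dr))) {
    t <- dr$frame[k]; r <- dr$row[k]; c <- dr$col[k]
    if (t <= 1L || t >= 40L) next
    # skip droplets adjacent in time and space (they can overlap at this
    # high artifact rate)
    if (any(dr$frame %in% c(t - 1L, t + 1L) & abs(dr$row - r) <= 16 &
              abs(dr$col - c) <= 16 & dr$frame != t)) next
    # droplet-only pixels are class 1 at t and gone at t+1; they must have
    # been background at t-1 (one-frame lifetime)
    rr <- max(1, r - 6):min(nrow(gen$seq$frames[[t]]), r + 6)
    cc <- max(1, c - 6):min(ncol(gen$seq$frames[[t]]), c + 6)
    f_prev <- gen$seq$frames[[t - 1L]][rr, cc]
    f_cur <- gen$seq$frames[[t]][rr, cc]
    f_next <- gen$seq$frames[[t + 1L]][rr, cc]
    droplet_px <- f_cur == 1L & f_next == 0L
    if (any(droplet_px)) expect_true(all(f_prev[droplet_px] == 0L))
  }
})

test_that("plants overlapping at the first frame are rejected", {
  sp1 <- plant_spec(seed_rc = c(20L, 20L), main_growth = growth_linear(0.5))
  sp2 <- plant_spec(seed_rc = c(20L, 23L), main_growth = growth_linear(0.5))
  cfg <- synth_config(canvas = c(60L, 60L), n_frames = 3L,
                      plants = list(sp1, sp2), rng_seed = 1L)
  expect_error(generate_sequence(cfg), "overlap")
})

test_that("render_frame: a straight vertical axis gives one component and a
          lateral touches it", {
  st <- list(px = cbind(10:59, rep(20L, 50L)), class_id = 1L, width = 3L)
  m <- render_frame(list(st), c(80L, 40L))
  lab <- EBImage::bwlabel(EBImage::Image((m == 1L) * 1))
  expect_equal(max(lab), 1)
  # lateral at 45 degrees from (30, 21)
  lat <- list(px = cbind(30:45, 21L + 0:15), class_id = 2L, width = 2L)
  m2 <- render_frame(list(st, lat), c(80L, 40L))
  p1 <- which(m2 == 1L, arr.ind = TRUE)
  p2 <- which(m2 == 2L, arr.ind = TRUE)
  # at least one 8-adjacent pair across the two classes
  d <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  expect_lte(min(d), 2)
})
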