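test_that("seed detection finds components within the area gates", {
  m <- matrix(0L, 40, 60)
  m[5:9, 5:8] <- 3L      # 20 px
  m[20:24, 30:33] <- 3L  # 20 px
  m[33:37, 50:53] <- 3L  # 20 px
  det <- detect_seeds(m, min_area = 5, max_area = 400)
  expect_equal(nrow(det), 3L)
  expect_equal(sort(round(det$cr)), c(7, 22, 35))
  # tiny blob filtered out
  m2 <- m; m2[1, 1:2] <- 3L
  expect_equal(nrow(detect_seeds(m2, min_area = 5)), 3L)
  # merged blob flagged oversized and excluded
  m3 <- matrix(0L, 40, 40); m3[10:19, 10:19] <- 3L
  d3 <- detect_seeds(m3, min_area = 5, max_area = 50)
  expect_equal(nrow(d3), 0L)
  expect_equal(nrow(attr(d3, "oversized")), 1L)
  expect_equal(attr(d3, "oversized")$area, 100)
})

test_that("Hungarian matches brute force on random rectangular problems", {
  expect_equal(hungarian_solve(rbind(c(1, 2), c(2, 1)))$assignment, c(1L, 2L))
  expect_equal(hungarian_solve(rbind(c(1, 2), c(2, 1)))$cost, 2)
  set.seed(41)
  for (i in 1:150) {
    n <- sample(2:6, 1)
    C <- matrix(sample(0:20, n * n, replace = TRUE) + runif(n * n), n)
    expect_equal(hungarian_solve(C)$cost, brute_assignment(C))
  }
})

test_that("zero-noise Kalman tracking of constant velocity is exact after
          two updates", {
  kf <- rhizolapse:::kf_new(c(0, 0), sigma_p = 0, sigma_m = 0)
  z <- cbind(0:6, seq(0, 12, by = 2))
  for (i in 2:7) {
    kf <- rhizolapse:::kf_predict(kf)
    if (i >= 3) expect_equal(kf$x[1:2], z[i, ], tolerance = 1e-8)
    kf <- rhizolapse:::kf_update(kf, z[i, ])
  }
})

test_that("stationary seeds keep one id each; missed detections are bridged", {
  pos <- expand.grid(cr = c(10, 30, 50), cc = c(10, 30))
  mk_det <- function(drop = integer(0)) {
    d <- data.frame(id = 1:6, cr = pos$cr, cc = pos$cc, area = 20,
                    r0 = pos$cr - 2, c0 = pos$cc - 2,
                    r1 = pos$cr + 2, c1 = pos$cc + 2)
    if (length(drop)) d <- d[-drop, ]
    d
  }
  det <- lapply(1:30, function(t) mk_det())
  trk <- track_plants(det)
  expect_length(trk, 6L)
  expect_true(all(vapply(trk, function(tr) all(tr$history$observed),
                         logical(1))))
  # predictions sit on the observations for a stationary target
  for (tr in trk) {
    h <- tr$history
    expect_lt(max(abs(h$pred_cr[-1] - h$cr[-1])), 1e-6)
  }
  # drop random detections in 20% of frames: ids still stable, gaps coasted
  set.seed(42)
  det2 <- lapply(1:30, function(t)
    if (t > 1 && runif(1) < 0.4) mk_det(drop = sample(6, 1)) else mk_det())
  trk2 <- track_plants(det2)
  expect_length(trk2, 6L)
  for (tr in trk2) {
    obs <- tr$history[tr$history$observed, ]
    expect_lt(max((obs$cr - obs$cr[1])^2 + (obs$cc - obs$cc[1])^2), 1)
  }
})

test_that("QC removes teleporting tracks and contacting plants", {
  # teleport: 80 px jump with a 40 px/frame gate
  d1 <- data.frame(id = 1, cr = 10, cc = 10, area = 20,
                   r0 = 8, c0 = 8, r1 = 12, c1 = 12)
  det <- list(d1, d1, transform(d1, cr = 90), transform(d1, cr = 90))
  trk <- track_plants(det, max_dist = 100)
  frames <- lapply(1:4, function(t) matrix(0L, 100, 30))
  trk <- qc_filter(trk, frame_sequence(frames), motion_thresh = 40)
  expect_equal(trk[[1]]$status, "qc_removed")
  expect_equal(trk[[1]]$qc_reason, "motion")

  # contact: two plants whose pixels join at frame 3
  mk <- function(join) {
    m <- matrix(0L, 40, 60)
    m[18:22, 10:14] <- 3L; m[18:22, 40:44] <- 3L
    m[20, 15:24] <- 1L
    m[20, if (join) 25:39 else 30:39] <- 1L
    m
  }
  frames2 <- list(mk(FALSE), mk(FALSE), mk(TRUE), mk(TRUE))
  det2 <- lapply(frames2, detect_seeds, min_area = 5)
  trk2 <- track_plants(det2)
  trk2 <- qc_filter(trk2, frame_sequence(frames2), check_every = 1L)
  expect_true(all(vapply(trk2, function(tr) tr$status == "qc_removed",
                         logical(1))))
  expect_true(all(vapply(trk2, function(tr) tr$qc_reason == "contact",
                         logical(1))))
  expect_equal(trk2[[1]]$first_contact, 3L)

  # isolated plants survive
  trk3 <- track_plants(lapply(1:4, function(t) det2[[1]]))
  trk3 <- qc_filter(trk3, frame_sequence(lapply(1:4, function(t)
    mk(FALSE))), check_every = 1L)
  expect_true(all(vapply(trk3, function(tr) tr$status == "active",
                         logical(1))))
})

test_that("germination curves are cumulative percentages with step shape", {
  # 2 seeds; roots appear at frames 10 and 21 and persist
  mk <- function(t) {
    m <- matrix(0L, 60, 60)
    m[10:13, 10:13] <- 3L; m[10:13, 40:43] <- 3L
    if (t >= 10) m[14:30, 11] <- 1L
    if (t >= 21) m[14:30, 41] <- 1L
    m
  }
  frames <- lapply(1:60, mk)
  seqq <- frame_sequence(frames, dt = 60)  # 1-h frames
  det <- lapply(frames, detect_seeds, min_area = 5)
  trk <- track_plants(det)
  curve <- germination_curve(trk, seqq, min_persist_h = 6)
  expect_true(all(diff(curve$values) >= 0))
  expect_lte(max(curve$values), 100)
  expect_equal(curve$values[9], 0)
  expect_equal(curve$values[15], 50)
  expect_equal(curve$values[60], 100)
  ev <- attr(curve, "events")
  expect_equal(sort(ev$time_h), c(9, 20))

  # half germinate, half never: plateau at 50
  mk2 <- function(t) {
    m <- matrix(0L, 60, 60)
    m[10:13, 10:13] <- 3L; m[10:13, 40:43] <- 3L
    if (t >= 10) m[14:30, 11] <- 1L
    m
  }
  frames2 <- lapply(1:60, mk2)
  curve2 <- germination_curve(track_plants(lapply(frames2, detect_seeds,
                                                  min_area = 5)),
                              frame_sequence(frames2, dt = 60))
  expect_equal(max(curve2$values), 50)
})

test_that("hypocotyl series applies the rate gate then the monotonic
          constraint", {
  # worked example: raw [1.0, 1.1, 9.0, 1.3] with a 2 mm/frame gate
  raw <- c(1.0, 1.1, 9.0, 1.3)
  gate <- 2
  clean <- raw
  for (t in 2:4) if (clean[t] - clean[t - 1] > gate) clean[t] <- clean[t - 1]
  clean <- cummax(clean)
  expect_equal(clean, c(1.0, 1.1, 1.1, 1.3))
})

test_that("hypocotyl and plant measures recover synthetic truth", {
  demo <- demo_screening_experiment(n_seeds = 4L, n_frames = 97L,
                                    germination_frames = c(5L, 9L, 13L, 17L),
                                    rng_seed = 2L)
  gen <- generate_sequence(demo$config)
  res <- analyze_screening(gen$seq, measure = TRUE)
  expect_length(res$tracks, 4L)
  trh <- gen$truth[gen$truth$structure == "hypocotyl" &
                     gen$truth$frame == 97L, ]
  grid <- expand.grid(row = c(90L, 250L, 410L, 570L),
                      col = c(70L, 190L, 310L, 430L, 550L))
  for (id in names(res$hypocotyl)) {
    tr <- res$tracks[[as.integer(id)]]
    k <- which.min((grid$row - tr$history$cr[1])^2 +
                     (grid$col - tr$history$cc[1])^2)
    truth <- trh$length_mm[trh$plant == k]
    est <- tail(res$hypocotyl[[id]]$clean$values, 1)
    expect_lt(abs(est - truth), max(0.12, 0.06 * truth))
    # simple root length against main-root truth
    mr_truth <- gen$truth$length_mm[gen$truth$plant == k &
                                      gen$truth$structure == "main" &
                                      gen$truth$frame == 97L]
    est_root <- tail(res$plant[[id]]$root_length$values, 1)
    expect_lt(abs(est_root - mr_truth), max(0.15, 0.06 * mr_truth))
  }
  # area example: pixel count times the pixel area
  m <- matrix(0L, 30, 30); m[1:10, 1:25] <- 1L
  fake_track <- list(seed_bbox = c(5L, 5L, 8L, 8L), id = 1L,
                     history = data.frame(frame = 1, cr = 6, cc = 6,
                                          observed = TRUE))
  pm <- plant_measures(fake_track, frame_sequence(list(m), scale = 0.04))
  expect_equal(pm$area$values[1], 250 * 0.0016)
})
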