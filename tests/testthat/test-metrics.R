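test_that("base-tip angle matches its closed form", {
  expect_equal(base_tip_angle(c(0, 0), c(0, 100)), 0)
  expect_equal(base_tip_angle(c(0, 0), c(100, 100)), 45)
  expect_equal(base_tip_angle(c(0, 0), c(50, 86.60)), 30, tolerance = 0.01 / 30)
  expect_equal(base_tip_angle(c(0, 0), c(0, -10)), 180)
  expect_error(base_tip_angle(c(3, 3), c(3, 3)), "undefined")
})

test_that("emergence angle walks the path to the requested arc length", {
  scale <- 0.04
  # straight down: 0 degrees
  p_down <- cbind(10:90, rep(20, 81))
  expect_equal(emergence_angle(p_down, 2, scale), 0)
  # 2 mm at 45 degrees then vertical: theta_e = 45, base-tip angle < 45
  n45 <- 36   # 36 diagonal steps ~ 36*sqrt(2) px ~ 2.04 mm
  p <- rbind(cbind(10 + 0:n45, 20 + 0:n45),
             cbind(10 + n45 + 1:250, rep(20 + n45, 250)))
  te <- emergence_angle(p, 2, scale)
  expect_equal(te, 45, tolerance = 0.02)
  tb <- base_tip_angle(c(p[1, 2], p[1, 1]), c(p[nrow(p), 2], p[nrow(p), 1]))
  expect_lt(tb, 45)
  # d beyond the total path length: measurement deferred (missing value)
  expect_true(is.na(emergence_angle(p, 100, scale)))
  # for a straight path, theta_e at increasing d converges on theta_bt
  pl <- cbind(10 + 0:80, 20 + 0:80)
  tbl <- base_tip_angle(c(pl[1, 2], pl[1, 1]), c(pl[81, 2], pl[81, 1]))
  expect_equal(emergence_angle(pl, 4.5, scale), tbl, tolerance = 1e-6)
  # path of 1.5 mm with d = 2 mm: missing value
  short <- cbind(10:(10 + 37), rep(5, 38))
  expect_true(is.na(emergence_angle(short, 2, scale)))
})

test_that("architecture metrics follow the trait-table arithmetic", {
  fake_axes <- structure(list(
    main = list(length_px = 20 / 0.04, path = cbind(1:10, 5)),
    laterals = lapply(1:4, function(i)
      list(id = i, length_px = 2.5 / 0.04, base_rc = c(i * 10, 5),
           tip_rc = c(i * 10 + 5, 10), path = cbind(1:5, 5),
           base_arc_px = i * 10))
  ), class = "axis_labeling")
  m <- architecture_metrics(fake_axes, scale = 0.04)
  expect_equal(m$mr_mm, 20)
  expect_equal(m$lr_mm, 10)
  expect_equal(m$tr_mm, 30)
  expect_equal(m$n_lr, 4)
  expect_equal(m$density_lr_cm, 2)          # 10 * 4 / 20
  expect_equal(m$main_over_total, 2 / 3, tolerance = 1e-3)

  # no laterals: ratio 1, LR length 0
  fake0 <- structure(list(main = fake_axes$main, laterals = list()),
                     class = "axis_labeling")
  m0 <- architecture_metrics(fake0, 0.04)
  expect_equal(m0$lr_mm, 0)
  expect_equal(m0$main_over_total, 1)

  # zero-length main root: density and ratio undefined, not zero
  fakez <- structure(list(main = list(length_px = 0), laterals = list()),
                     class = "axis_labeling")
  mz <- architecture_metrics(fakez, 0.04)
  expect_true(is.na(mz$density_lr_cm))
  expect_true(is.na(mz$main_over_total))
})

test_that("convex hull metrics: square, collinear and brute-force oracle", {
  scale <- 1
  # 4 corners of a 10x10 square (in px = mm at scale 1)
  px <- rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10))
  h <- convex_hull_metrics(px, scale, total_root_length_mm = 50)
  expect_equal(h$area_mm2, 100)
  expect_equal(h$aspect, 1)
  expect_equal(h$width_mm, 10)
  expect_equal(h$density_mm_mm2, 0.5)

  # collinear: zero area, missing density
  pc <- cbind(1:10, 1:10)
  hc <- convex_hull_metrics(pc, scale, 5)
  expect_equal(hc$area_mm2, 0)
  expect_true(is.na(hc$density_mm_mm2))

  # random cloud vs exhaustive extreme-point oracle
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    pts <- cbind(runif(n, 0, 20), runif(n, 0, 20))
    h2 <- convex_hull_metrics(pts, scale, 1)
    expect_equal(h2$area_mm2, brute_hull_area(pts[, 2], pts[, 1]),
                 tolerance = 1e-9)
  }
})

test_that("growth speed is the finite-difference derivative at midpoints", {
  s <- trait_series(c(0, 1, 2), c(0, 1, 2), trait = "len", units = "mm")
  g <- growth_speed(s)
  expect_equal(g$values, c(1, 1))
  expect_equal(g$time_h, c(0.5, 1.5))

  s2 <- trait_series(0:5, rep(3, 6))
  expect_equal(growth_speed(s2)$values, rep(0, 5))

  # quadratic L = t^2 sampled at 0.25 h: midpoint speeds equal 2 * t_mid
  tt <- seq(0, 4, by = 0.25)
  g3 <- growth_speed(trait_series(tt, tt^2))
  expect_equal(g3$values, 2 * g3$time_h)
})

test_that("detrending removes constants and slow ramps", {
  tt <- seq(0, 48, by = 0.25)
  expect_equal(detrend_series(trait_series(tt, rep(5, length(tt))))$values,
               rep(0, length(tt)))
  ramp <- detrend_series(trait_series(tt, 0.3 * tt), window_h = 12)
  interior <- ramp$values[50:(length(tt) - 50)]
  expect_lt(max(abs(interior)), 1e-9)
})

test_that("the spectrum localizes planted rhythms", {
  dt <- 0.25
  tt <- seq(0, 144 - dt, by = dt)
  s24 <- trait_series(tt, sin(2 * pi * tt / 24))
  sp <- fourier_spectrum(s24)
  expect_equal(sp$period[which.max(sp$amplitude)], 24)
  expect_equal(amplitude_at_period(sp, 24), 1, tolerance = 0.05)

  flat <- fourier_spectrum(trait_series(tt, rep(2, length(tt))))
  expect_lt(max(flat$amplitude), 1e-9)

  s2 <- trait_series(tt, sin(2 * pi * tt / 24) + 0.5 * sin(2 * pi * tt / 12))
  sp2 <- fourier_spectrum(s2)
  top2 <- sp2$period[order(-sp2$amplitude)[1:2]]
  expect_setequal(top2, c(24, 12))

  expect_error(fourier_spectrum(trait_series(c(0, 1, 3, 7), 1:4)),
               "uniform")
})

test_that("monotonic growth enforcement is a running maximum", {
  expect_equal(enforce_monotonic(trait_series(1:3, c(3, 2, 5)))$values,
               c(3, 3, 5))
  expect_equal(enforce_monotonic(trait_series(1:3, c(5, 4, 3)))$values,
               c(5, 5, 5))
  nd <- trait_series(1:4, c(1, 2, 2, 7))
  expect_equal(enforce_monotonic(nd)$values, nd$values)
  # idempotent
  once <- enforce_monotonic(trait_series(1:5, c(2, 1, 4, 3, 3)))
  expect_equal(enforce_monotonic(once)$values, once$values)
})

test_that("persistence validation applies the strict 6-h rule", {
  dt <- 15
  expect_false(temporal_validation(rep(TRUE, 17), dt))   # 4 h
  expect_true(temporal_validation(rep(TRUE, 29), dt))    # 7 h
  expect_false(temporal_validation(rep(TRUE, 25), dt))   # exactly 6 h
  expect_false(temporal_validation(rep(FALSE, 40), dt))
  # split runs do not accumulate
  v <- c(rep(TRUE, 20), FALSE, rep(TRUE, 20))
  expect_false(temporal_validation(v, dt))
})

test_that("Mann-Whitney: exact enumeration for small n, approx otherwise", {
  r <- mann_whitney_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(mann_whitney_compare(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_compare(c(1, 2), c(3, 4))$p, 1 / 3,
               tolerance = 1e-12)
  # no-tie small samples agree with wilcox.test exact p
  set.seed(30)
  for (rep in 1:10) {
    a <- sample(seq(1, 100), 5); b <- sample(seq(101, 200), 6) + 0.5
    ours <- mann_whitney_compare(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$U, unname(ref$statistic))
  }
  expect_error(mann_whitney_compare(numeric(0), 1:3), "non-empty")
})

test_that("group comparison over time reports BH-adjusted q values", {
  set.seed(31)
  mk <- function(shift) lapply(1:6, function(i)
    trait_series(0:10, (0:10) * 0.5 + shift + rnorm(11, 0, 0.01)))
  tab <- compare_groups_over_time(mk(0), mk(3), at_h = c(2, 5, 8))
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_true(all(tab$p < 0.05))
})
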