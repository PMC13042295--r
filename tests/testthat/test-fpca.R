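tg <- seq(0, 48, length.out = 25)
u <- tg / 48
# Legendre-style functions, orthonormal under the unit-domain inner product
phi1 <- sqrt(3) * (2 * u - 1)
phi2 <- sqrt(5) * (6 * u^2 - 6 * u + 1)

test_that("rank-1 curve families load entirely on PC1, proportional to t", {
  curves <- lapply(1:8, function(i) trait_series(tg, (1 + 0.3 * i) * tg))
  mod <- fit_fpca(curves, monomial_basis(4, c(0, 48)))
  expect_equal(mod$ratios[1], 1, tolerance = 1e-9)
  expect_lt(sum(mod$ratios[-1]), 1e-9)
  # PC1 evaluated on the grid is proportional to t
  v <- rhizolapse:::fpca_component_fun(mod, 1, tg)
  expect_gt(abs(cor(v, tg)), 1 - 1e-9)
})

test_that("identical curves give a degenerate model with no components", {
  curves <- lapply(1:5, function(i) trait_series(tg, 3 + 0.5 * tg))
  mod <- fit_fpca(curves)
  expect_true(mod$degenerate)
  expect_equal(ncol(mod$components), 0L)
})

test_that("planted orthogonal modes with 4:1 score variance give
          0.8 / 0.2 ratios", {
  n <- 40
  a <- rep(c(2, 2, -2, -2), n / 4)
  b <- rep(c(1, -1, 1, -1), n / 4)
  curves <- lapply(1:n, function(i)
    trait_series(tg, 5 + 0.1 * tg + a[i] * phi1 + b[i] * phi2))
  mod <- fit_fpca(curves, monomial_basis(4, c(0, 48)), n_components = 2)
  expect_equal(mod$ratios[1], 0.8, tolerance = 0.02 / 0.8)
  expect_equal(mod$ratios[2], 0.2, tolerance = 0.02 / 0.2)
  # components are orthonormal under the Gram inner product
  W <- rhizolapse:::basis_gram(mod$basis)
  G <- t(mod$components) %*% W %*% mod$components
  expect_equal(G, diag(2), tolerance = 1e-6)
  # full spectrum sums to one
  expect_equal(sum(mod$ratios), 1, tolerance = 1e-9)
})

test_that("quantile reconstructions bracket the mean where the component
          is non-zero", {
  set.seed(60)
  n <- 50
  a <- rnorm(n, 0, 2)
  curves <- lapply(1:n, function(i) trait_series(tg, 5 + 0.1 * tg + a[i] * phi1))
  mod <- fit_fpca(curves, monomial_basis(4, c(0, 48)), n_components = 1)
  rec <- reconstruct_quantiles(mod, 1, c(0.05, 0.5, 0.95))
  mu <- rhizolapse:::fpca_mean_fun(mod, mod$grid)
  phi <- rhizolapse:::fpca_component_fun(mod, 1, mod$grid)
  lo <- rec$value[rec$quantile == 0.05]
  hi <- rec$value[rec$quantile == 0.95]
  mid <- rec$value[rec$quantile == 0.5]
  nz <- abs(phi) > 0.05
  expect_true(all((pmin(lo, hi) <= mu + 1e-9)[nz]))
  expect_true(all((pmax(lo, hi) >= mu - 1e-9)[nz]))
  # the 0.95 reconstruction is exactly mean + q95(score) * phi
  q95 <- quantile(mod$scores[, 1], 0.95, names = FALSE)
  expect_equal(rec$value[rec$quantile == 0.95], mu + q95 * phi,
               tolerance = 1e-9)
  # median of a near-symmetric score distribution stays near the mean
  expect_lt(max(abs(mid - mu)), 0.2 * max(abs(phi)) * sd(a))
})

test_that("score comparison flags only truly shifted components", {
  n <- 16
  a <- rep(c(2, -2), n / 2)
  grp <- rep(c("wt", "mut"), each = n / 2)
  shift <- ifelse(grp == "mut", 3, 0)
  curves <- lapply(1:n, function(i)
    trait_series(tg, 5 + a[i] * phi1 + shift[i] * phi2))
  mod <- fit_fpca(curves, monomial_basis(4, c(0, 48)), n_components = 2)
  tab <- compare_scores(mod, grp)
  expect_equal(nrow(tab), 2L)
  # the shifted mode is by far the most significant; the unshifted mode,
  # whose group score multisets coincide up to rounding, is not
  p_by_comp <- tab$p[order(tab$component)]
  expect_equal(which.min(p_by_comp), 2L)
  expect_lt(p_by_comp[2], 0.01)
  expect_gt(p_by_comp[1], 0.05)
  expect_error(compare_scores(mod, rep("one", n)), "two groups")
  expect_error(compare_scores(mod, c("a", rep("b", n - 1))), "at least two")
})

test_that("affine time reparameterization leaves the ratios unchanged", {
  n <- 24
  set.seed(61)
  a <- rnorm(n); b <- rnorm(n, 0, 0.5)
  mk <- function(times) lapply(1:n, function(i) {
    uu <- (times - min(times)) / diff(range(times))
    trait_series(times, 2 + a[i] * sqrt(3) * (2 * uu - 1) +
                   b[i] * sqrt(5) * (6 * uu^2 - 6 * uu + 1))
  })
  m1 <- fit_fpca(mk(tg), n_components = 3)
  m2 <- fit_fpca(mk(10 + 3 * tg), n_components = 3)
  expect_equal(m1$ratios, m2$ratios, tolerance = 1e-8)
})

test_that("curves with too few samples are rejected with a diagnostic", {
  short <- c(lapply(1:3, function(i) trait_series(tg, tg * i)),
             list(trait_series(c(0, 24, 48), c(0, 1, 2))))
  expect_error(fit_fpca(short, monomial_basis(4, c(0, 48))),
               "fewer samples")
})
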