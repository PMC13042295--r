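# Functional principal component analysis of trait trajectories.
#
# Curves are projected onto a monomial basis by least squares; the
# eigen-decomposition of the coefficient covariance under the basis Gram
# inner product yields orthonormal component functions ranked by explained
# variance. Internally the time domain is rescaled to [0, 1], which
# conditions the monomial Gram matrix (a Hilbert matrix) and makes the
# decomposition invariant to affine time reparameterization.

#' Monomial functional basis
#'
#' Basis functions `1, u, u^2, ..., u^degree` of the unit-rescaled time
#' `u = (t - t_min) / (t_max - t_min)`.
#'
#' @param degree Polynomial degree (default 4; five coefficients capture
#'   sigmoidal growth).
#' @param domain `c(t_min, t_max)` in hours.
#' @return A `functional_basis` object.
#' @export
monomial_basis <- function(degree = 4L, domain) {
  stopifnot(degree >= 1L, length(domain) == 2L, domain[2] > domain[1])
  structure(list(kind = "monomial", degree = as.integer(degree),
                 domain = as.numeric(domain)),
            class = "functional_basis")
}

# Design matrix of the basis at times t (hours).
basis_eval <- function(basis, t) {
  u <- (t - basis$domain[1]) / diff(basis$domain)
  outer(u, 0:basis$degree, `^`)
}

# Gram matrix of inner products over the unit domain: a Hilbert matrix.
basis_gram <- function(basis) {
  p <- basis$degree + 1L
  outer(seq_len(p), seq_len(p), function(i, j) 1 / (i + j - 1))
}

#' Fit functional PCA to a collection of curves
#'
#' Each curve is aligned to a common grid by linear interpolation, projected
#' onto the basis by least squares, and the centred coefficient covariance is
#' eigen-decomposed under the basis Gram inner product. Components are
#' orthonormal functions ranked by explained variance ratio; the sign of
#' each is fixed so that its value at the end of the domain is non-negative.
#' Collections with (numerically) zero total variance are flagged degenerate
#' and carry no components.
#'
#' @param curves List of `trait_series` sharing a common time domain.
#' @param basis A [monomial_basis()]; default degree 4 over the common
#'   domain.
#' @param n_components Number of components to keep; default the smallest
#'   number reaching 95 percent cumulative explained variance.
#' @return An `fpca_model`: `basis`, `mean_coef`, `components` (columns =
#'   orthonormal coefficient vectors), `ratios` (explained variance ratios,
#'   descending, full spectrum), `scores` (curve x component), `grid`,
#'   `degenerate`.
#' @export
fit_fpca <- function(curves, basis = NULL, n_components = NULL) {
  stopifnot(length(curves) >= 3L)
  t0 <- max(vapply(curves, function(s) min(s$time_h), numeric(1)))
  t1 <- min(vapply(curves, function(s) max(s$time_h), numeric(1)))
  if (t1 <= t0) stop("curves have no common time domain")
  if (is.null(basis)) basis <- monomial_basis(4L, c(t0, t1))
  p <- basis$degree + 1L
  n_grid <- max(vapply(curves, function(s) length(s$time_h), integer(1)))
  n_grid <- max(n_grid, 2L * p)
  grid <- seq(t0, t1, length.out = n_grid)
  short <- vapply(curves, function(s) length(s$values) < p, logical(1))
  if (any(short))
    stop(sprintf("%d curve(s) have fewer samples than basis coefficients",
                 sum(short)))
  B <- basis_eval(basis, grid)
  Y <- vapply(curves, function(s) approx(s$time_h, s$values, grid)$y,
              numeric(n_grid))
  C <- t(qr.coef(qr(B), Y))            # n_curves x p coefficient matrix
  mean_coef <- colMeans(C)
  Cc <- sweep(C, 2, mean_coef)
  W <- basis_gram(basis)
  eW <- eigen(W, symmetric = TRUE)
  Wh <- eW$vectors %*% diag(sqrt(pmax(eW$values, 0))) %*% t(eW$vectors)
  Whi <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-300))) %*%
    t(eW$vectors)
  Sigma <- crossprod(Cc) / (nrow(C) - 1)
  M <- Wh %*% Sigma %*% Wh
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(eM$values, 0)
  total <- sum(lam)
  curve_scale <- mean(colMeans(Y^2))
  degenerate <- total <= 1e-12 * max(curve_scale, 1e-300)
  if (degenerate) {
    return(structure(list(
      basis = basis, mean_coef = mean_coef,
      components = matrix(0, p, 0), ratios = numeric(0),
      scores = matrix(0, nrow(C), 0), grid = grid, degenerate = TRUE
    ), class = "fpca_model"))
  }
  ratios <- lam / total
  comp <- Whi %*% eM$vectors             # coefficient vectors, W-orthonormal
  # sign convention: component value at the domain end is non-negative
  endval <- as.numeric(basis_eval(basis, basis$domain[2]) %*% comp)
  flip <- ifelse(abs(endval) > 1e-12, sign(endval), 1)
  comp <- sweep(comp, 2, flip, `*`)
  scores <- Cc %*% W %*% comp
  if (is.null(n_components))
    n_components <- which(cumsum(ratios) >= 0.95)[1]
  n_components <- min(n_components, ncol(comp))
  structure(list(
    basis = basis, mean_coef = mean_coef,
    components = comp[, seq_len(n_components), drop = FALSE],
    ratios = ratios, scores = scores[, seq_len(n_components), drop = FALSE],
    grid = grid, degenerate = FALSE
  ), class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  if (x$degenerate) {
    cat("<fpca_model> degenerate (zero total variance), no components\n")
  } else {
    cat(sprintf("<fpca_model> %d components; explained variance: %s\n",
                ncol(x$components),
                paste(sprintf("%.3f", x$ratios[seq_len(min(4, length(x$ratios)))]),
                      collapse = ", ")))
  }
  invisible(x)
}

# Evaluate mean or component functions on a time grid.
fpca_mean_fun <- function(model, t) {
  as.numeric(basis_eval(model$basis, t) %*% model$mean_coef)
}

fpca_component_fun <- function(model, k, t) {
  as.numeric(basis_eval(model$basis, t) %*% model$components[, k])
}

#' Quantile-based trajectory reconstructions
#'
#' Reconstructs `mean(t) + q * phi_k(t)` where `q` is the requested quantile
#' of the component-k scores: an intuitive picture of how that mode bends
#' the developmental trajectory across the population.
#'
#' @param model An `fpca_model`.
#' @param component Component index (default 1).
#' @param quantiles Score quantiles to draw (default
#'   `c(0.05, 0.25, 0.5, 0.75, 0.95)`).
#' @param grid Time grid (default the model grid).
#' @return Data frame `time_h`, `quantile`, `value`.
#' @export
reconstruct_quantiles <- function(model, component = 1L,
                                  quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                  grid = NULL) {
  if (model$degenerate) stop("degenerate model has no components")
  if (component > ncol(model$components)) stop("component out of range")
  if (is.null(grid)) grid <- model$grid
  mu <- fpca_mean_fun(model, grid)
  phi <- fpca_component_fun(model, component, grid)
  qs <- quantile(model$scores[, component], probs = quantiles, names = FALSE,
                 type = 7)
  do.call(rbind, lapply(seq_along(quantiles), function(i) {
    data.frame(time_h = grid, quantile = quantiles[i],
               value = mu + qs[i] * phi)
  }))
}

#' Compare FPCA scores between experimental groups
#'
#' Per component, a two-sided Mann-Whitney test between every pair of
#' groups, with Benjamini-Hochberg adjustment across components within each
#' group pair.
#'
#' @param model An `fpca_model`.
#' @param groups Factor/character vector of group labels, one per curve.
#' @return Data frame `component`, `group_a`, `group_b`, `U`, `p`, `q`.
#' @export
compare_scores <- function(model, groups) {
  if (model$degenerate) stop("degenerate model has no scores")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(model$scores))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two curves")
  gl <- names(tab)
  pairs <- utils::combn(gl, 2)
  out <- list()
  for (pr in seq_len(ncol(pairs))) {
    ga <- pairs[1, pr]; gb <- pairs[2, pr]
    rows <- lapply(seq_len(ncol(model$scores)), function(k) {
      mw <- mann_whitney_compare(model$scores[groups == ga, k],
                                 model$scores[groups == gb, k])
      data.frame(component = k, group_a = ga, group_b = gb,
                 U = mw$U, p = mw$p)
    })
    df <- do.call(rbind, rows)
    df$q <- p.adjust(df$p, method = "BH")
    out[[pr]] <- df
  }
  do.call(rbind, out)
}
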