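# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# vertical bar mask (width px wide, from row r0 to r1, centred on col)
bar_mask <- function(nr, nc, r0, r1, col, width = 3L) {
  m <- matrix(FALSE, nr, nc)
  h <- (width - 1L) %/% 2L
  m[r0:r1, (col - h):(col + h)] <- TRUE
  m
}

# 1-px T skeleton: vertical r0..r1 at col, horizontal at row rj, col..c2
t_skeleton <- function(nr = 80L, nc = 80L, r0 = 10L, r1 = 69L, col = 40L,
                       rj = 30L, c2 = 70L) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, col] <- TRUE
  m[rj, col:c2] <- TRUE
  m
}

# one-plant synthetic config: straight main root at 1 mm/h, optional lateral
one_plant_config <- function(n_frames = 9L, laterals = list(), seed = 7L,
                             droplet_rate = 0, canvas = c(200L, 120L)) {
  sp <- plant_spec(seed_rc = c(10L, 60L), germination_frame = 1L,
                   main_growth = growth_linear(1),
                   laterals = laterals)
  synth_config(canvas = canvas, n_frames = n_frames, plants = list(sp),
               scale = 0.04, dt = 15, droplet_rate = droplet_rate,
               rng_seed = seed)
}

# brute-force minimal assignment cost over all permutations (n <= 7)
brute_assignment <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(C[cbind(seq_len(n), p)]))
  best
}

# O(n^3) convex hull area oracle: max over all triangle fans is wrong in
# general, so sum signed areas of the hull polygon found by exhaustive
# extreme-point test: a point is on the hull iff it is not strictly inside
# any triangle of three other points.
brute_hull_area <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 60)
  inside <- function(px, py, ax, ay, bx, by, cx, cy) {
    d1 <- (px - bx) * (ay - by) - (ax - bx) * (py - by)
    d2 <- (px - cx) * (by - cy) - (bx - cx) * (py - cy)
    d3 <- (px - ax) * (cy - ay) - (cx - ax) * (py - ay)
    neg <- (d1 < -1e-12) || (d2 < -1e-12) || (d3 < -1e-12)
    pos <- (d1 > 1e-12) || (d2 > 1e-12) || (d3 > 1e-12)
    !(neg && pos)
  }
  on_hull <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    combs <- combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]; b <- combs[2, k]; c <- combs[3, k]
      if (inside(x[p], y[p], x[a], y[a], x[b], y[b], x[c], y[c])) {
        on_hull[p] <- FALSE
        break
      }
    }
  }
  hx <- x[on_hull]; hy <- y[on_hull]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]; hy <- hy[o]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}
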