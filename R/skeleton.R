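# Skeletonization, spur pruning, and skeleton quality scores.

#' Skeletonize a binary mask
#'
#' Homotopy-preserving thinning (Zhang-Suen style, two sub-iterations to a
#' fixpoint) producing a 1-px-wide, 8-connected medial representation.
#' Idempotent: re-skeletonizing returns the same pixel set.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(m)) return(m)
  cpp_thin(m)
}

# Walk from a tip pixel through degree-2 pixels to the nearest junction (or
# the other end of a bare path). Returns the walked chain (junction excluded)
# and whether the path is bare (junction-free).
walk_spur <- function(idx_tip, skel, deg, nr) {
  chain <- idx_tip
  prev <- 0L
  cur <- idx_tip
  repeat {
    nb <- skel_neighbors(cur, skel)
    nb <- setdiff(nb, c(prev, chain))
    if (length(nb) == 0L) return(list(chain = chain, bare = TRUE))
    j <- nb[deg[nb] >= 3L]
    if (length(j)) return(list(chain = chain, bare = FALSE))
    if (length(nb) > 1L)  # meeting zone without a marked junction: be safe
      return(list(chain = chain, bare = FALSE))
    nxt <- nb[1]
    if (deg[nxt] <= 1L) return(list(chain = c(chain, nxt), bare = TRUE))
    prev <- cur; cur <- nxt
    chain <- c(chain, cur)
  }
}

# Linear indices of the 8 neighbours of linear index i in an nr x (n/nr) grid.
neighbor_indices <- function(i, nr, n) {
  r <- (i - 1L) %% nr + 1L
  c <- (i - 1L) %/% nr + 1L
  nc <- n %/% nr
  # fixed order: N, NE, E, SE, S, SW, W, NW
  drs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dcs <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  rr <- r + drs; cc <- c + dcs
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  rr[ok] + (cc[ok] - 1L) * nr
}

# Foreground neighbours of a skeleton pixel under reduced 8-adjacency
# (matching cpp_neighbor_degree): orthogonal always, diagonal only when
# neither shared orthogonal pixel is foreground. Fixed visit order
# N, NE, E, SE, S, SW, W, NW for determinism.
skel_neighbors <- function(i, skel) {
  nr <- nrow(skel); ncol_ <- ncol(skel)
  r <- (i - 1L) %% nr + 1L
  c <- (i - 1L) %/% nr + 1L
  drs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dcs <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  out <- integer(8L); k <- 0L
  for (j in 1:8) {
    rr <- r + drs[j]; cc <- c + dcs[j]
    if (rr < 1L || rr > nr || cc < 1L || cc > ncol_) next
    if (!skel[rr, cc]) next
    if (drs[j] != 0L && dcs[j] != 0L &&
        (skel[r + drs[j], c] || skel[r, c + dcs[j]]))
      next
    k <- k + 1L
    out[k] <- rr + (cc - 1L) * nr
  }
  out[seq_len(k)]
}

#' Prune short skeleton spurs
#'
#' Removes every junction-to-tip branch whose pixel count (tip inclusive,
#' junction exclusive) is below `min_len`, iterating until no spur remains.
#' Bare paths without junctions are never touched, so overall connectivity is
#' preserved.
#'
#' @param skel Logical skeleton matrix.
#' @param min_len Minimum branch length in pixels to be preserved
#'   (default 5, about 0.2 mm at 0.04 mm/px).
#' @return Pruned logical skeleton.
#' @export
prune_spurs <- function(skel, min_len = 5L) {
  stopifnot(min_len >= 1L)
  nr <- nrow(skel); n <- length(skel)
  repeat {
    deg <- cpp_neighbor_degree(skel)
    tips <- which(deg == 1L)
    if (length(tips) == 0L) return(skel)
    removed <- FALSE
    for (tp in tips) {
      if (!skel[tp]) next  # may already be gone this round
      w <- walk_spur(tp, skel, deg, nr)
      if (isTRUE(w$bare)) next
      if (length(w$chain) < min_len) {
        skel[w$chain] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(skel)
    # re-thin to dissolve 1-px nubs left at junction zones by the removal
    skel <- cpp_thin(skel)
  }
}

#' Completeness and correctness of an extracted skeleton
#'
#' Completeness is the fraction of reference pixels lying within `tol` of a
#' predicted pixel (missing structure lowers it); correctness is the fraction
#' of predicted pixels within `tol` of a reference pixel (spurious structure
#' lowers it). Both are in `[0, 1]`.
#'
#' @param pred,truth Logical skeleton matrices on the same canvas.
#' @param tol Pixel tolerance (Euclidean; default 0 = exact overlap).
#' @return List with `completeness` and `correctness`. When `truth` is empty
#'   completeness is `NA` and the result carries attribute
#'   `undefined = TRUE`.
#' @export
skeleton_scores <- function(pred, truth, tol = 0) {
  stopifnot(all(dim(pred) == dim(truth)))
  p <- matrix(as.logical(pred), nrow(pred), ncol(pred))
  t_ <- matrix(as.logical(truth), nrow(truth), ncol(truth))
  if (!any(t_)) {
    res <- list(completeness = NA_real_,
                correctness = if (any(p)) 0 else NA_real_)
    attr(res, "undefined") <- TRUE
    return(res)
  }
  dist_to <- function(target) {
    # distance of every pixel to the nearest TRUE pixel of `target`
    if (!any(target)) return(matrix(Inf, nrow(target), ncol(target)))
    img <- EBImage::Image(1 - target * 1)
    matrix(as.numeric(EBImage::distmap(img)), nrow(target), ncol(target))
  }
  comp <- mean(dist_to(p)[t_] <= tol + 1e-9)
  corr <- if (!any(p)) NA_real_ else mean(dist_to(t_)[p] <= tol + 1e-9)
  list(completeness = comp, correctness = corr)
}
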