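# Root graph construction from skeletons and main/lateral axis
# classification.
#
# Skeleton pixels with exactly two 8-neighbours form edge chains; all other
# pixels (tips and junction zones) are clustered into nodes. The graph is
# traversed depth-first from the user-provided origin with a fixed
# neighbour-visit order (N, NE, E, SE, S, SW, W, NW) so construction is
# fully deterministic. Cycles are permitted and recorded.

# Flood-fill clustering of a set of skeleton pixel indices under the
# reduced skeleton adjacency.
cluster_pixels <- function(idx, skel) {
  if (length(idx) == 0L)
    return(list(cluster = integer(0), n = 0L))
  cl <- rep(0L, length(idx))
  pos <- integer(length(skel))
  pos[idx] <- seq_along(idx)
  nxt <- 0L
  for (i in seq_along(idx)) {
    if (cl[i] != 0L) next
    nxt <- nxt + 1L
    queue <- idx[i]; cl[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in skel_neighbors(cur, skel)) {
        j <- pos[nb]
        if (j > 0L && cl[j] == 0L) { cl[j] <- nxt; queue <- c(queue, nb) }
      }
    }
  }
  list(cluster = cl, n = nxt)
}

#' Build a root graph from a skeleton
#'
#' Nodes are maximal clusters of skeleton pixels whose 8-neighbour count
#' differs from 2 (tips and junction zones), plus the origin pixel; edges are
#' the maximal junction-free pixel chains between them. Edge lengths use the
#' geodesic pixel metric (axial step 1, diagonal step sqrt(2)). A depth-first
#' search from the origin assigns a deterministic traversal order; cycles are
#' allowed.
#'
#' @param skel Logical skeleton matrix.
#' @param origin `c(row, col)` starting position of the root; must lie within
#'   10 px of a skeleton pixel.
#' @return A `root_graph`: list with `nodes` (data frame `id`, `row`, `col`,
#'   `kind`, `dfs_order`), `edges` (list of `from`, `to`, `path` pixel
#'   matrix, `length_px`), `adj` (incident edge ids per node), `origin`
#'   (node id) and `dim`.
#' @export
build_graph <- function(skel, origin) {
  nr <- nrow(skel); n <- length(skel)
  px <- which(skel)
  if (length(px) == 0L) stop("empty skeleton")
  prow <- (px - 1L) %% nr + 1L
  pcol <- (px - 1L) %/% nr + 1L
  d2 <- (prow - origin[1])^2 + (pcol - origin[2])^2
  if (min(d2) > 100)
    stop(sprintf("origin is %.1f px from the nearest skeleton pixel (max 10)",
                 sqrt(min(d2))))
  origin_px <- px[which.min(d2)]

  deg <- cpp_neighbor_degree(skel)
  node_px <- px[deg[px] != 2L]
  node_px <- sort(unique(c(node_px, origin_px)))
  cl <- cluster_pixels(node_px, skel)
  node_of <- integer(n)  # pixel linear index -> node id (0 = chain pixel)
  node_of[node_px] <- cl$cluster

  # node positions: cluster pixel nearest the cluster centroid
  nodes <- do.call(rbind, lapply(seq_len(cl$n), function(k) {
    pp <- node_px[cl$cluster == k]
    rr <- (pp - 1L) %% nr + 1L; cc <- (pp - 1L) %/% nr + 1L
    ctr <- c(mean(rr), mean(cc))
    i <- order((rr - ctr[1])^2 + (cc - ctr[2])^2, pp)[1]
    data.frame(id = k, row = rr[i], col = cc[i])
  }))

  edges <- list()
  chain_used <- logical(n)
  direct_seen <- character(0)
  for (k in seq_len(cl$n)) {
    members <- node_px[cl$cluster == k]
    for (p0 in members) {
      for (nb in skel_neighbors(p0, skel)) {
        if (node_of[nb] != 0L) {
          if (node_of[nb] == k) next  # intra-cluster adjacency
          key <- paste(min(p0, nb), max(p0, nb))
          if (key %in% direct_seen) next
          direct_seen <- c(direct_seen, key)
          path <- rbind(c((p0 - 1L) %% nr + 1L, (p0 - 1L) %/% nr + 1L),
                        c((nb - 1L) %% nr + 1L, (nb - 1L) %/% nr + 1L))
          edges[[length(edges) + 1L]] <-
            list(from = k, to = node_of[nb], path = path,
                 length_px = path_arc_px(path))
        } else {
          if (chain_used[nb]) next
          chain <- nb; prev <- p0; cur <- nb
          repeat {
            nxt <- skel_neighbors(cur, skel)
            nxt <- setdiff(nxt, c(prev, chain))
            # keep cycles closable, but don't re-hit the start pixel while
            # still inside its junction wedge
            if (length(chain) < 3L) nxt <- setdiff(nxt, p0)
            if (length(nxt) == 0L) break
            hit <- nxt[node_of[nxt] != 0L]
            if (length(hit)) { chain <- c(chain, hit[1]); break }
            prev <- cur; cur <- nxt[1]
            chain <- c(chain, cur)
          }
          end_px <- chain[length(chain)]
          end_node <- node_of[end_px]
          if (end_node == 0L) {
            # chain dead-ends without a node pixel (shouldn't happen after
            # degree analysis) — treat terminal chain pixel as a tip node
            next
          }
          chain_used[setdiff(chain, node_px)] <- TRUE
          pix <- c(p0, chain)
          path <- cbind((pix - 1L) %% nr + 1L, (pix - 1L) %/% nr + 1L)
          edges[[length(edges) + 1L]] <-
            list(from = k, to = end_node, path = path,
                 length_px = path_arc_px(path))
        }
      }
    }
  }

  adj <- vector("list", cl$n)
  for (e in seq_along(edges)) {
    ed <- edges[[e]]
    adj[[ed$from]] <- c(adj[[ed$from]], e)
    if (ed$to != ed$from) adj[[ed$to]] <- c(adj[[ed$to]], e)
  }
  n_inc <- vapply(seq_len(cl$n), function(k) {
    sum(vapply(edges, function(ed)
      (ed$from == k) + (ed$to == k), numeric(1)))
  }, numeric(1))
  origin_id <- node_of[origin_px]
  nodes$kind <- ifelse(seq_len(cl$n) == origin_id, "origin",
                       ifelse(n_inc <= 1L, "tip", "branch"))

  # deterministic DFS from origin
  dfs_order <- rep(NA_integer_, cl$n)
  stack <- origin_id; cnt <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (!is.na(dfs_order[v])) next
    cnt <- cnt + 1L; dfs_order[v] <- cnt
    for (e in rev(adj[[v]])) {
      ed <- edges[[e]]
      w <- if (ed$from == v) ed$to else ed$from
      if (is.na(dfs_order[w])) stack <- c(stack, w)
    }
  }
  nodes$dfs_order <- dfs_order

  structure(list(nodes = nodes, edges = edges, adj = adj,
                 origin = origin_id, dim = dim(skel)),
            class = "root_graph")
}

#' @export
print.root_graph <- function(x, ...) {
  cat(sprintf("<root_graph> %d nodes, %d edges, origin node %d\n",
              nrow(x$nodes), length(x$edges), x$origin))
  invisible(x)
}

# Dijkstra over graph nodes; returns dist and predecessor edge per node.
graph_geodesics <- function(graph) {
  nv <- nrow(graph$nodes)
  dist <- rep(Inf, nv); dist[graph$origin] <- 0
  pred_edge <- rep(NA_integer_, nv)
  done <- rep(FALSE, nv)
  for (it in seq_len(nv)) {
    v <- which(!done & dist < Inf)
    if (!length(v)) break
    v <- v[which.min(dist[v])]
    done[v] <- TRUE
    for (e in graph$adj[[v]]) {
      ed <- graph$edges[[e]]
      w <- if (ed$from == v) ed$to else ed$from
      if (dist[v] + ed$length_px < dist[w] - 1e-12) {
        dist[w] <- dist[v] + ed$length_px
        pred_edge[w] <- e
      }
    }
  }
  list(dist = dist, pred_edge = pred_edge)
}

# Orient an edge's pixel path so it starts at node `from_id`.
orient_path <- function(edge, from_id, nodes) {
  p <- edge$path
  start <- c(nodes$row[edge$from], nodes$col[edge$from])
  if (edge$from == from_id) return(p)
  p[rev(seq_len(nrow(p))), , drop = FALSE]
}

#' Classify main and lateral root axes
#'
#' The main root is taken as the geodesic (shortest in-graph path) from the
#' origin to the tip with the greatest geodesic depth, with ties broken by
#' the lowest tip (greatest image row) then smallest column; in an acyclic
#' graph this is exactly the longest origin-to-tip path, and in the presence
#' of loops it keeps the main axis on the direct route rather than detouring
#' through a reconnecting lateral. All non-main edges are grouped into
#' laterals rooted where they leave the main path; a lateral that reconnects
#' to the main root (a loop) keeps its loop edges and its reconnection point
#' is not treated as a new lateral base.
#'
#' @param graph A `root_graph`.
#' @return An `axis_labeling`: list with `main` (`edges`, `nodes`, `path`
#'   pixel matrix, `length_px`, `tip_node`), `laterals` (each with `id`,
#'   `base_node`, `base_rc`, `base_arc_px`, `tip_rc`, `path`, `length_px`,
#'   `n_edges`, `has_loop`) and `loop_edges`.
#' @export
classify_axes <- function(graph) {
  nv <- nrow(graph$nodes)
  empty <- list(main = list(edges = integer(0), nodes = graph$origin,
                            path = cbind(graph$nodes$row[graph$origin],
                                         graph$nodes$col[graph$origin]),
                            length_px = 0, tip_node = graph$origin),
                laterals = list(), loop_edges = integer(0))
  class(empty) <- "axis_labeling"
  if (length(graph$edges) == 0L) return(empty)

  geo <- graph_geodesics(graph)
  tips <- which(graph$nodes$kind == "tip" & is.finite(geo$dist))
  if (length(tips) == 0L)
    tips <- setdiff(which(is.finite(geo$dist)), graph$origin)
  if (length(tips) == 0L) return(empty)
  ord <- order(-geo$dist[tips], -graph$nodes$row[tips], graph$nodes$col[tips])
  main_tip <- tips[ord[1]]

  # walk predecessors back to the origin
  main_edges <- integer(0); main_nodes <- main_tip
  v <- main_tip
  while (v != graph$origin) {
    e <- geo$pred_edge[v]
    main_edges <- c(e, main_edges)
    ed <- graph$edges[[e]]
    v <- if (ed$to == v) ed$from else ed$to
    main_nodes <- c(v, main_nodes)
  }

  # ordered pixel path and arc positions of main nodes; junction clusters
  # may leave a small gap between consecutive edge endpoints, which counts
  # its Euclidean distance in the arc length
  main_path <- NULL
  node_arc <- setNames(numeric(length(main_nodes)), main_nodes)
  for (i in seq_along(main_edges)) {
    ed <- graph$edges[[main_edges[i]]]
    p <- orient_path(ed, main_nodes[i], graph$nodes)
    if (!is.null(main_path) &&
        all(p[1, ] == main_path[nrow(main_path), ]))
      p <- p[-1, , drop = FALSE]
    main_path <- rbind(main_path, p)
    node_arc[as.character(main_nodes[i + 1])] <- path_arc_px(main_path)
  }
  main_len <- path_smooth_arc_px(main_path)

  # group non-main edges into lateral components (connected through
  # non-main nodes only, so two laterals sharing a junction stay distinct)
  non_main <- setdiff(seq_along(graph$edges), main_edges)
  loop_edges <- integer(0)
  laterals <- list()
  if (length(non_main)) {
    on_main <- seq_len(nv) %in% main_nodes
    parent <- seq_along(non_main)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    node2edges <- list()
    for (j in seq_along(non_main)) {
      ed <- graph$edges[[non_main[j]]]
      for (u in unique(c(ed$from, ed$to))) {
        if (on_main[u]) next
        key <- as.character(u)
        node2edges[[key]] <- c(node2edges[[key]], j)
      }
    }
    for (grp in node2edges) {
      for (j in grp[-1]) {
        a <- find(grp[1]); b <- find(j)
        if (a != b) parent[b] <- a
      }
    }
    comp <- vapply(seq_along(non_main), find, integer(1))
    for (cid in unique(comp)) {
      eids <- non_main[comp == cid]
      enodes <- unique(unlist(lapply(graph$edges[eids],
                                     function(ed) c(ed$from, ed$to))))
      attach <- enodes[on_main[enodes]]
      if (length(attach) == 0L) next  # disconnected fragment; ignore
      base <- attach[order(node_arc[as.character(attach)],
                           graph$nodes$row[attach])][1]
      # independent cycles this component adds once grafted onto the main
      # path: edges minus the new (non-main) nodes they introduce
      cyc <- length(eids) - sum(!on_main[enodes])
      has_loop <- length(attach) >= 2L || cyc >= 1L
      if (has_loop) {
        # loop edges: those beyond a spanning tree from the base
        loop_edges <- c(loop_edges, utils::tail(eids, max(0L, cyc)))
      }
      lp <- longest_path_from(graph, eids, base)
      laterals[[length(laterals) + 1L]] <- list(
        base_node = base,
        base_rc = c(graph$nodes$row[base], graph$nodes$col[base]),
        base_arc_px = unname(node_arc[as.character(base)]),
        tip_rc = lp$tip_rc, path = lp$path,
        length_px = sum(vapply(graph$edges[eids], function(ed)
          path_smooth_arc_px(ed$path), numeric(1))),
        n_edges = length(eids), has_loop = has_loop
      )
    }
    if (length(laterals)) {
      o <- order(vapply(laterals, `[[`, numeric(1), "base_arc_px"),
                 vapply(laterals, function(l) l$tip_rc[2], numeric(1)))
      laterals <- laterals[o]
      for (i in seq_along(laterals)) laterals[[i]]$id <- i
    }
  }

  structure(list(
    main = list(edges = main_edges, nodes = main_nodes, path = main_path,
                length_px = main_len, tip_node = main_tip,
                node_arc = node_arc),
    laterals = laterals, loop_edges = loop_edges,
    origin = graph$origin, dim = graph$dim
  ), class = "axis_labeling")
}

# Longest simple path from `base` using only the given edges; DFS
# enumeration (components are small). Returns the pixel path and tip.
longest_path_from <- function(graph, eids, base) {
  best <- list(len = -1, edges = integer(0), nodes = base)
  rec <- function(v, used, len, eseq, nseq) {
    improved <- FALSE
    for (e in eids) {
      if (used[match(e, eids)]) next
      ed <- graph$edges[[e]]
      if (ed$from != v && ed$to != v) next
      w <- if (ed$from == v) ed$to else ed$from
      if (w %in% nseq && w != v) next  # node-simple (allow self-loop end)
      used2 <- used; used2[match(e, eids)] <- TRUE
      rec(w, used2, len + ed$length_px, c(eseq, e), c(nseq, w))
      improved <- TRUE
    }
    if (!improved && len > best$len)
      best <<- list(len = len, edges = eseq, nodes = nseq)
  }
  rec(base, rep(FALSE, length(eids)), 0, integer(0), base)
  path <- NULL
  if (length(best$edges)) {
    for (i in seq_along(best$edges)) {
      ed <- graph$edges[[best$edges[i]]]
      p <- orient_path(ed, best$nodes[i], graph$nodes)
      if (!is.null(path) && all(p[1, ] == path[nrow(path), ]))
        p <- p[-1, , drop = FALSE]
      path <- rbind(path, p)
    }
  } else {
    path <- cbind(graph$nodes$row[base], graph$nodes$col[base])
  }
  tip_node <- best$nodes[length(best$nodes)]
  list(path = path, tip_rc = path[nrow(path), ],
       tip_node = tip_node, length = max(best$len, 0))
}

#' Match lateral identities between consecutive frames
#'
#' Laterals are matched by the proximity of their base points measured as arc
#' length along the main path (nearest first, at most `max_shift` px apart);
#' ties are broken by the smaller tip displacement. Assignment is solved
#' optimally with the Hungarian algorithm. Unmatched current laterals are
#' reported with `prev = NA` so the caller can mint fresh ids; ids are never
#' reused.
#'
#' @param prev,cur `axis_labeling` objects from consecutive frames of the
#'   same plant.
#' @param max_shift Maximum allowed base shift, arc-length px (default 15).
#' @return Data frame with one row per current lateral: `cur` (index in
#'   `cur$laterals`) and `prev` (matching index in `prev$laterals` or `NA`).
#' @export
match_laterals <- function(prev, cur, max_shift = 15) {
  np <- length(prev$laterals); ncur <- length(cur$laterals)
  if (ncur == 0L) return(data.frame(cur = integer(0), prev = integer(0)))
  if (np == 0L) return(data.frame(cur = seq_len(ncur), prev = NA_integer_))
  big <- 1e9
  cost <- matrix(big, np, ncur)
  for (i in seq_len(np)) for (j in seq_len(ncur)) {
    d <- abs(prev$laterals[[i]]$base_arc_px - cur$laterals[[j]]$base_arc_px)
    if (d <= max_shift) {
      tipd <- sqrt(sum((prev$laterals[[i]]$tip_rc -
                          cur$laterals[[j]]$tip_rc)^2))
      cost[i, j] <- d + 1e-6 * tipd
    }
  }
  sol <- hungarian_solve(cost)
  prev_of <- rep(NA_integer_, ncur)
  for (i in seq_len(np)) {
    j <- sol$assignment[i]
    if (!is.na(j) && j <= ncur && cost[i, j] < big) prev_of[j] <- i
  }
  data.frame(cur = seq_len(ncur), prev = prev_of)
}
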