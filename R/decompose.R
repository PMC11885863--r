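# Per-frame decomposition of a skeleton graph into one main root (MR)
# polyline and a set of lateral-root (LR) observations.

# mean absolute angular deviation (deg) of chain steps from gravity (+row)
chain_gravity_dev <- function(chain) {
  if (nrow(chain) < 2) return(0)
  d <- chain[-1, , drop = FALSE] - chain[-nrow(chain), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  mean(rad2deg(acos(clip(d[, 1] / len, -1, 1))))
}

# direction (unit, row/col) of a chain near one of its ends, pointing away
# from that end into the chain when `outward`, or into the node when not
chain_dir <- function(chain, at_start, window = 6) {
  n <- nrow(chain)
  if (at_start) v <- chain[min(window, n), ] - chain[1, ]
  else v <- chain[n, ] - chain[max(1, n - window + 1), ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(0, 0) else v / nv
}

# Minimal-turning paths from the root to every node (Dijkstra on directed
# half-edges). Root systems cross themselves in 2-D projection; at a
# crossing junction the main root continues nearly straight while a detour
# onto another root needs sharp turns, so routing by accumulated turning
# angle (with a small length regularizer) follows the true root through
# cycles where plain shortest-path routing would cut corners.
min_turn_paths <- function(sg, eps_per_mm = 1e-3) {
  nE <- length(sg$edges)
  if (nE == 0) return(NULL)
  # state = directed edge: s = 2*e-1 traverses from->to, s = 2*e is to->from
  st_edge <- rep(seq_len(nE), each = 2)
  st_fwd <- rep(c(TRUE, FALSE), nE)
  arrive <- ifelse(st_fwd,
                   vapply(sg$edges, `[[`, numeric(1), "to")[st_edge],
                   vapply(sg$edges, `[[`, numeric(1), "from")[st_edge])
  depart <- ifelse(st_fwd,
                   vapply(sg$edges, `[[`, numeric(1), "from")[st_edge],
                   vapply(sg$edges, `[[`, numeric(1), "to")[st_edge])
  lens <- vapply(sg$edges, `[[`, numeric(1), "length_mm")[st_edge]
  # unit directions: out_dir = leaving the depart node; in_dir = arriving
  out_dir <- matrix(0, 2 * nE, 2)
  in_dir <- matrix(0, 2 * nE, 2)
  for (e in seq_len(nE)) {
    ch <- sg$edges[[e]]$chain
    d_start <- chain_dir(ch, at_start = TRUE)
    d_end <- chain_dir(ch, at_start = FALSE)
    out_dir[2 * e - 1, ] <- d_start;  in_dir[2 * e - 1, ] <- d_end
    out_dir[2 * e, ] <- -d_end;       in_dir[2 * e, ] <- -d_start
  }
  nS <- 2 * nE
  cost <- rep(Inf, nS)
  pred <- rep(NA_integer_, nS)
  done <- rep(FALSE, nS)
  start <- which(depart == sg$root & st_edge %in%
                   which(vapply(sg$edges, function(e) e$from != e$to,
                                logical(1))))
  cost[start] <- eps_per_mm * lens[start]
  repeat {
    masked <- ifelse(done, Inf, cost)
    u <- which.min(masked)
    if (!is.finite(masked[u])) break
    done[u] <- TRUE
    n <- arrive[u]
    nxt <- which(depart == n & st_edge != st_edge[u] & !done)
    if (length(nxt) > 0) {
      turn <- acos(clip(in_dir[u, 1] * out_dir[nxt, 1] +
                          in_dir[u, 2] * out_dir[nxt, 2], -1, 1))
      newc <- cost[u] + turn + eps_per_mm * lens[nxt]
      upd <- newc < cost[nxt]
      cost[nxt[upd]] <- newc[upd]
      pred[nxt[upd]] <- u
    }
  }
  list(cost = cost, pred = pred, arrive = arrive, st_edge = st_edge,
       st_fwd = st_fwd, lens = lens)
}

# reconstruct the edge path (with orientation) of the best state arriving
# at node v; returns NULL if unreachable
mtp_path_to <- function(mtp, v) {
  cand <- which(mtp$arrive == v & is.finite(mtp$cost))
  if (length(cand) == 0) return(NULL)
  s <- cand[which.min(mtp$cost[cand])]
  eids <- integer(0); fwd <- logical(0)
  while (!is.na(s)) {
    eids <- c(mtp$st_edge[s], eids)
    fwd <- c(mtp$st_fwd[s], fwd)
    s <- mtp$pred[s]
  }
  list(eids = eids, fwd = fwd)
}

#' Extract the main root from a skeleton graph
#'
#' The MR is the root-to-endpoint path maximizing arc length, with exact
#' ties broken in favour of the candidate deviating least, on average, from
#' the gravity vector. Paths are routed by minimal accumulated turning at
#' junctions, so that where roots cross in the 2-D projection (producing
#' cycles in the skeleton graph) the MR continues straight through the
#' crossing instead of cutting onto another root. The returned chain is
#' ordered seed to tip.
#'
#' @param sg A [skeletonize_mask()] result.
#' @return Object of class `mr_polyline`: `chain` (pixel matrix row/col,
#'   seed to tip), `length_mm`, `node_ids` (vertex sequence), `px_mm`.
#' @export
extract_main_root <- function(sg) {
  stopifnot(inherits(sg, "skeleton_graph"))
  ep <- sg$nodes$id[sg$nodes$kind == "endpoint" & sg$nodes$id != sg$root]
  if (length(ep) == 0)
    stop("extract_main_root: skeleton has no endpoint path")
  mtp <- min_turn_paths(sg)
  paths <- lapply(ep, function(v) mtp_path_to(mtp, v))
  ok <- !vapply(paths, is.null, logical(1))
  ep <- ep[ok]; paths <- paths[ok]
  if (length(ep) == 0) stop("extract_main_root: no endpoint reachable")
  lens <- vapply(paths, function(p)
    sum(vapply(sg$edges[p$eids], `[[`, numeric(1), "length_mm")), numeric(1))
  lmax <- max(lens)
  cand <- which(lens >= lmax - 1e-9 * max(1, lmax))
  chains <- lapply(cand, function(i) {
    ch <- NULL
    for (j in seq_along(paths[[i]]$eids)) {
      e <- sg$edges[[paths[[i]]$eids[j]]]
      cc <- e$chain
      if (!paths[[i]]$fwd[j]) cc <- cc[nrow(cc):1, , drop = FALSE]
      ch <- if (is.null(ch)) cc else rbind(ch, cc[-1, , drop = FALSE])
    }
    ch
  })
  pick <- if (length(cand) == 1) 1 else
    which.min(vapply(chains, chain_gravity_dev, numeric(1)))
  i <- cand[pick]
  chain <- chains[[pick]]
  # vertex sequence along the picked path
  e1 <- sg$edges[[paths[[i]]$eids[1]]]
  vpath <- if (paths[[i]]$fwd[1]) e1$from else e1$to
  for (j in seq_along(paths[[i]]$eids)) {
    e <- sg$edges[[paths[[i]]$eids[j]]]
    vpath <- c(vpath, if (paths[[i]]$fwd[j]) e$to else e$from)
  }
  structure(list(chain = chain, node_ids = vpath,
                 edge_idx = paths[[i]]$eids,
                 length_mm = chain_steps_px(chain) * sg$px_mm,
                 px_mm = sg$px_mm),
            class = "mr_polyline")
}

#' @export
print.mr_polyline <- function(x, ...) {
  cat(sprintf("mr_polyline: %.2f mm, %d px\n", x$length_mm, nrow(x$chain)))
  invisible(x)
}

#' Extract lateral-root observations hanging off the main root
#'
#' Every maximal subtree attached to the MR chain becomes one LR whose
#' polyline is the longest base-to-endpoint path within the subtree. LRs
#' shorter than `min_lr_len_mm` are discarded. Results are ordered by base
#' arc position along the MR.
#'
#' @param sg A `skeleton_graph`.
#' @param mr The matching [extract_main_root()] result.
#' @param min_lr_len_mm Minimum reported LR length (default 0.5 mm).
#' @return List of `lr_observation`: `base_px` (row, col), `base_arc_on_mr_mm`,
#'   `chain` (pixel matrix base to tip), `length_mm`.
#' @export
extract_lateral_roots <- function(sg, mr, min_lr_len_mm = 0.5) {
  stopifnot(inherits(sg, "skeleton_graph"), inherits(mr, "mr_polyline"))
  if (length(sg$edges) == 0) return(list())
  mr_nodes <- mr$node_ids
  g <- sg$graph
  drop <- which(igraph::edge_attr(g, "eid") %in% mr$edge_idx)
  g2 <- igraph::delete_edges(g, drop)
  comp <- igraph::components(g2)$membership
  mr_ca <- cum_arc(mr$chain) * sg$px_mm      # arc position of each MR pixel
  # arc position of each MR node
  node_arc <- vapply(mr_nodes, function(v) {
    px <- c(sg$nodes$row[v], sg$nodes$col[v])
    i <- which(mr$chain[, 1] == px[1] & mr$chain[, 2] == px[2])[1]
    mr_ca[i]
  }, numeric(1))

  out <- list()
  for (cid in unique(comp)) {
    verts <- which(comp == cid)
    on_mr <- intersect(verts, mr_nodes)
    if (length(on_mr) == 0 || length(verts) == 1) next
    base <- if (length(on_mr) == 1) on_mr else {
      # rasterization cycle touching >1 MR node: anchor at the basal-most
      on_mr[which.min(node_arc[match(on_mr, mr_nodes)])]
    }
    sub <- igraph::induced_subgraph(g2, verts)
    sub_base <- which(verts == base)
    dd <- igraph::distances(sub, v = sub_base)[1, ]
    tip <- which.max(dd)
    if (!is.finite(dd[tip]) || dd[tip] <= 0) next
    sp <- igraph::shortest_paths(sub, from = sub_base, to = tip,
                                 output = "both")
    vpath <- verts[as.integer(sp$vpath[[1]])]
    # map subgraph epath back to full-graph edge list entries
    eids <- vapply(seq_len(length(vpath) - 1), function(i) {
      e <- igraph::get_edge_ids(g2, c(vpath[i], vpath[i + 1]))
      igraph::edge_attr(g2, "eid", e[e > 0][1])
    }, numeric(1))
    chain <- NULL
    for (i in seq_along(eids)) {
      e <- sg$edges[[eids[i]]]
      ch <- e$chain
      if (e$from != vpath[i]) ch <- ch[nrow(ch):1, , drop = FALSE]
      chain <- if (is.null(chain)) ch else rbind(chain, ch[-1, , drop = FALSE])
    }
    len <- chain_steps_px(chain) * sg$px_mm
    if (len < min_lr_len_mm) next
    out[[length(out) + 1]] <-
      structure(list(base_px = c(sg$nodes$row[base], sg$nodes$col[base]),
                     base_arc_on_mr_mm = node_arc[match(base, mr_nodes)],
                     chain = chain, length_mm = len),
                class = "lr_observation")
  }
  out[order(vapply(out, `[[`, numeric(1), "base_arc_on_mr_mm"))]
}

# extend a polyline's tip along its final direction
extend_tip <- function(p, by_mm, window_mm = 0.2) {
  n <- nrow(p)
  if (n < 2 || by_mm <= 0) return(p)
  L <- arc_length(p)
  u <- p[n, ] - point_at_arc(p, max(0, L - window_mm))
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(p)
  rbind(p, p[n, ] + by_mm * u / nu)
}

# Sub-pixel refinement of an LR's attachment point. Thinning displaces the
# Y-junction branch point from the true MR-LR crossing by up to about the
# stroke width, *along the LR*, so raw chain lengths systematically
# undershoot. The true attachment is recovered by extrapolating the LR's
# initial direction backwards onto the local MR axis (fitted basal of the
# junction, outside the distorted zone) and prepending the intersection.
refine_lr_base <- function(lr_mm, mr_mm, base_arc_mm,
                           max_back_mm = 0.5, fit_window_mm = 0.5,
                           fit_skip_mm = 0.15) {
  if (nrow(lr_mm) < 2) return(list(poly = lr_mm, base_arc = base_arc_mm))
  lr_len <- arc_length(lr_mm)
  # direction of the LR just beyond the junction-distorted zone
  s0 <- min(fit_skip_mm, lr_len / 4)
  s1 <- min(s0 + fit_window_mm, lr_len)
  u <- point_at_arc(lr_mm, s1) - point_at_arc(lr_mm, s0)
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(list(poly = lr_mm, base_arc = base_arc_mm))
  u <- u / nu
  # local MR axis basal of the junction, skipping the distorted zone
  mr_ca <- cum_arc(mr_mm)
  hi_arc <- base_arc_mm - 0.1
  lo_arc <- base_arc_mm - 0.1 - 2 * fit_window_mm
  if (hi_arc <= 0.05) return(list(poly = lr_mm, base_arc = base_arc_mm))
  lo_arc <- max(lo_arc, 0)
  A <- point_at_arc(mr_mm, lo_arc)
  B <- point_at_arc(mr_mm, hi_arc)
  v <- B - A
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(list(poly = lr_mm, base_arc = base_arc_mm))
  v <- v / nv
  # solve lr_base - t*u = B + s*v  for (t, s)
  M <- cbind(-u, -v)
  if (abs(det(M)) < 1e-6) return(list(poly = lr_mm, base_arc = base_arc_mm))
  ts <- solve(M, as.numeric(B - lr_mm[1, ]))
  t_back <- ts[1]
  if (!is.finite(t_back) || t_back <= 0 || t_back > max_back_mm)
    return(list(poly = lr_mm, base_arc = base_arc_mm))
  p_true <- lr_mm[1, ] - t_back * u
  list(poly = rbind(p_true, lr_mm),
       base_arc = max(0, hi_arc + ts[2]))
}

#' Decompose one mask frame into MR and LR observations
#'
#' Convenience wrapper: skeletonize, extract the MR, extract LRs, and attach
#' smoothed mm polylines ready for angle and length measurement.
#'
#' @param frame A [mask_frame()].
#' @param prune_len_mm,seed_attach_radius_px Passed to [skeletonize_mask()].
#' @param min_lr_len_mm Passed to [extract_lateral_roots()].
#' @param smooth_window Moving-average window (vertices) applied to pixel
#'   chains before mm conversion; reduces staircase jitter. Set below 3 to
#'   disable.
#' @param refine_base If `TRUE` (default), correct each LR's attachment
#'   point for the junction displacement introduced by thinning by
#'   extrapolating the LR's initial direction back onto the local MR axis.
#' @param tip_extend_px Additional LR tip extension in pixels along the
#'   final direction. The skeletonizer already re-anchors eroded endpoints
#'   to the mask boundary, so the default is 0; a positive value is only
#'   useful for masks whose segmentation systematically undershoots tips.
#' @return Object of class `root_system_frame`: timestamp, plant id, px_mm,
#'   `mr` (list: chain, mm polyline, length_mm) and `lrs` (list with base
#'   pixel, base arc on MR, mm polyline, length_mm each).
#' @export
root_system_frame <- function(frame, prune_len_mm = 0.3,
                              seed_attach_radius_px = 20,
                              min_lr_len_mm = 0.5, smooth_window = 5,
                              refine_base = TRUE, tip_extend_px = 0) {
  sg <- skeletonize_mask(frame, prune_len_mm, seed_attach_radius_px)
  mr <- extract_main_root(sg)
  lrs <- extract_lateral_roots(sg, mr, min_lr_len_mm)
  mr_mm <- chain_to_mm(mr$chain, sg$px_mm, smooth_window)
  lr_list <- lapply(lrs, function(l) {
    mm <- chain_to_mm(l$chain, sg$px_mm, smooth_window)
    arc <- l$base_arc_on_mr_mm
    if (refine_base) {
      rb <- refine_lr_base(mm, mr_mm, arc)
      mm <- rb$poly
      arc <- rb$base_arc
    }
    if (tip_extend_px > 0) mm <- extend_tip(mm, tip_extend_px * sg$px_mm)
    list(base_px = l$base_px, base_arc_on_mr_mm = arc,
         poly_mm = mm, length_mm = arc_length(mm))
  })
  structure(list(timestamp_h = frame$timestamp_h, plant_id = frame$plant_id,
                 px_mm = frame$px_mm,
                 mr = list(chain = mr$chain, poly_mm = mr_mm,
                           length_mm = arc_length(mr_mm)),
                 lrs = lr_list),
            class = "root_system_frame")
}

# Build root_system_frame objects directly from simulator ground truth
# (exact geometry, no rasterization); used for tracker and statistics
# validation where pixel noise must be absent.
#' Ground-truth frames without rendering
#'
#' Converts a [simulate_root_system()] result into per-frame decompositions
#' identical in shape to [root_system_frame()] output, using the exact
#' polylines (no rasterization). `px_mm` controls the nominal pixel grid
#' used for base-pixel coordinates.
#'
#' @param gt A `ground_truth_series`.
#' @param px_mm Nominal scale for pixel coordinates (default 0.04).
#' @param frames Frame indices (default all).
#' @param min_lr_len_mm LRs shorter than this are omitted from a frame,
#'   mirroring the mask pipeline's detection floor.
#' @param plant_id Identifier.
#' @return List of `root_system_frame` objects.
#' @export
gt_frames <- function(gt, px_mm = 0.04, frames = NULL, min_lr_len_mm = 0.5,
                      plant_id = "sim") {
  stopifnot(inherits(gt, "ground_truth_series"))
  if (is.null(frames)) frames <- seq_along(gt$times)
  lapply(frames, function(k) {
    lrs <- list()
    for (lr in gt$lrs) {
      len <- gt_lr_len_at(gt, lr, k)
      if (len < min_lr_len_mm) next
      poly <- gt_lr_at(lr, k)
      lrs[[length(lrs) + 1]] <-
        list(base_px = round(c(lr$base_mm[2], lr$base_mm[1]) / px_mm) + 1,
             base_arc_on_mr_mm = lr$base_arc_mm,
             poly_mm = poly, length_mm = arc_length(poly),
             gt_id = lr$id)
    }
    ord <- order(vapply(lrs, `[[`, numeric(1), "base_arc_on_mr_mm"))
    mrp <- gt_mr_at(gt, k)
    structure(list(timestamp_h = gt$times[k], plant_id = plant_id,
                   px_mm = px_mm,
                   mr = list(chain = NULL, poly_mm = mrp,
                             length_mm = arc_length(mrp)),
                   lrs = lrs[ord]),
              class = "root_system_frame")
  })
}

#' @export
print.root_system_frame <- function(x, ...) {
  cat(sprintf("root_system_frame %s t=%.2fh: MR %.2f mm, %d LRs\n",
              x$plant_id, x$timestamp_h, x$mr$length_mm, length(x$lrs)))
  invisible(x)
}
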