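# Skeleton graphs: thin a binary mask to a 1-px skeleton and organize it as
# a rooted graph of junction/endpoint nodes joined by 8-connected pixel
# chains, with arc lengths in mm.

# 8-neighbour offsets, fixed order (N, NE, E, SE, S, SW, W, NW)
NB8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
             dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# number of skeleton neighbours of every pixel (matrix of same size)
neighbor_counts <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sk
  cnt <- matrix(0L, nr, nc)
  for (k in seq_len(8)) {
    cnt <- cnt + pad[(2:(nr + 1)) + NB8[k, 1], (2:(nc + 1)) + NB8[k, 2]]
  }
  cnt
}

# connected-component labels of foreground pixels (8-connectivity);
# returns an integer matrix (0 = background)
label_components <- function(mask) {
  fg <- which(mask == 1L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0) return(lab)
  nr <- nrow(mask)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[fg] <- seq_along(fg)
  rc <- arrayInd(fg, dim(mask))
  edges <- list()
  for (k in c(3, 4, 5, 6)) {   # E, SE, S, SW: half the directions, no dupes
    rr <- rc[, 1] + NB8[k, 1]; cc <- rc[, 2] + NB8[k, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(mask)
    ok[ok] <- mask[cbind(rr[ok], cc[ok])] == 1L
    if (any(ok))
      edges[[length(edges) + 1]] <-
        cbind(id[fg[ok]], id[cbind(rr[ok], cc[ok])])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else
      matrix(integer(0), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp[seq_along(fg)]
  lab
}

# arc length of a pixel chain in pixel units (unit + sqrt(2) steps)
chain_steps_px <- function(chain) {
  if (nrow(chain) < 2) return(0)
  d <- abs(chain[-1, , drop = FALSE] - chain[-nrow(chain), , drop = FALSE])
  sum(ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1))
}

# Build node/edge structure from a thinned skeleton matrix.
build_skel_graph <- function(sk, px_mm) {
  nr <- nrow(sk); nc <- ncol(sk)
  deg <- neighbor_counts(sk)
  is_node <- sk == 1L & deg != 2L
  if (!any(is_node) && any(sk == 1L)) {
    # pure cycle: designate an arbitrary pixel as a node
    first <- which(sk == 1L)[1]
    is_node[first] <- TRUE
  }
  node_px <- which(is_node, arr.ind = TRUE)
  if (is.null(dim(node_px))) node_px <- matrix(node_px, ncol = 2)
  nid <- matrix(0L, nr, nc)
  nid[is_node] <- seq_len(nrow(node_px))
  kind <- character(nrow(node_px))
  for (i in seq_len(nrow(node_px)))
    kind[i] <- if (deg[node_px[i, 1], node_px[i, 2]] >= 3) "junction"
               else "endpoint"

  sk_at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc &&
    sk[r, c] == 1L

  edges <- list()
  seen <- new.env(hash = TRUE)
  for (i in seq_len(nrow(node_px))) {
    r0 <- node_px[i, 1]; c0 <- node_px[i, 2]
    for (k in seq_len(8)) {
      r1 <- r0 + NB8[k, 1]; c1 <- c0 + NB8[k, 2]
      if (!sk_at(r1, c1)) next
      chain <- matrix(c(r0, c0, r1, c1), ncol = 2, byrow = TRUE)
      prev <- c(r0, c0); cur <- c(r1, c1)
      while (deg[cur[1], cur[2]] == 2L) {
        nxt <- NULL
        for (j in seq_len(8)) {
          r2 <- cur[1] + NB8[j, 1]; c2 <- cur[2] + NB8[j, 2]
          if (sk_at(r2, c2) && !(r2 == prev[1] && c2 == prev[2])) {
            nxt <- c(r2, c2); break
          }
        }
        if (is.null(nxt)) break        # defensive; deg==2 guarantees a next
        chain <- rbind(chain, nxt)
        prev <- cur; cur <- nxt
        if (cur[1] == r0 && cur[2] == c0) break   # closed loop
      }
      to <- nid[cur[1], cur[2]]
      if (to == 0L) next               # loop back into a chain; skip
      key_fwd <- paste(c(t(chain)), collapse = ",")
      key_rev <- paste(c(t(chain[nrow(chain):1, , drop = FALSE])),
                       collapse = ",")
      key <- if (key_fwd < key_rev) key_fwd else key_rev
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      edges[[length(edges) + 1]] <-
        list(from = i, to = to, chain = chain,
             length_mm = chain_steps_px(chain) * px_mm)
    }
  }
  nodes <- data.frame(id = seq_len(nrow(node_px)),
                      row = node_px[, 1], col = node_px[, 2], kind = kind,
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

# Iteratively delete spur chains (< prune_len_mm, endpoint-terminated,
# junction-rooted) from the skeleton matrix; returns the cleaned matrix.
# Spurs whose free end lies near `protect_px` (the seed point) are kept:
# the short seed-side stub left when a lateral emerges right at the seed
# must survive, or the root node and the top of the MR are lost.
prune_spurs <- function(sk, px_mm, prune_len_mm, protect_px = NULL,
                        protect_radius_px = 20) {
  repeat {
    gr <- build_skel_graph(sk, px_mm)
    if (length(gr$edges) <= 1) return(sk)
    kinds <- gr$nodes$kind
    protected <- function(node) {
      if (is.null(protect_px)) return(FALSE)
      sqrt((gr$nodes$row[node] - protect_px[1])^2 +
             (gr$nodes$col[node] - protect_px[2])^2) <= protect_radius_px
    }
    pruned <- FALSE
    for (e in gr$edges) {
      kf <- kinds[e$from]; kt <- kinds[e$to]
      if (e$length_mm >= prune_len_mm) next
      if (kf == "endpoint" && kt == "junction" && !protected(e$from)) {
        drop <- e$chain[-nrow(e$chain), , drop = FALSE]
      } else if (kt == "endpoint" && kf == "junction" && !protected(e$to)) {
        drop <- e$chain[-1, , drop = FALSE]
      } else next
      sk[drop] <- 0L
      pruned <- TRUE
    }
    # collapse sub-threshold cycles (thinning turns small bumps into tiny
    # parallel chains): of two edges joining the same node pair, drop the
    # interior of the longer one when it is below the pruning threshold
    keys <- vapply(gr$edges, function(e)
      paste(sort(c(e$from, e$to)), collapse = "-"), character(1))
    for (k in unique(keys[duplicated(keys)])) {
      par_idx <- which(keys == k)
      lens <- vapply(gr$edges[par_idx], `[[`, numeric(1), "length_mm")
      for (i in par_idx[order(lens)][-1]) {
        e <- gr$edges[[i]]
        if (e$length_mm >= prune_len_mm || nrow(e$chain) <= 2) next
        sk[e$chain[-c(1, nrow(e$chain)), , drop = FALSE]] <- 0L
        pruned <- TRUE
      }
    }
    if (!pruned) return(sk)
  }
}

# Extend every endpoint chain along its local tangent while the next pixel
# still lies on the original (unthinned) component: homotopic thinning
# retracts open line ends by a few pixels, and anchoring them back to the
# mask boundary restores the measurable root length.
anchor_endpoints <- function(sk, comp, max_steps = 12) {
  gr <- build_skel_graph(sk, 1)
  for (i in which(gr$nodes$kind == "endpoint")) {
    inc <- Filter(function(e) e$from == i || e$to == i, gr$edges)
    if (length(inc) != 1) next
    ch <- inc[[1]]$chain
    if (inc[[1]]$to == i) ch <- ch else ch <- ch[nrow(ch):1, , drop = FALSE]
    n <- nrow(ch)
    if (n < 2) next
    v <- ch[n, ] - ch[max(1, n - 5), ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    v <- v / nv
    pos <- ch[n, ]
    for (s in seq_len(max_steps)) {
      nxt <- round(ch[n, ] + v * s)
      if (nxt[1] < 1 || nxt[1] > nrow(comp) ||
          nxt[2] < 1 || nxt[2] > ncol(comp)) break
      if (comp[nxt[1], nxt[2]] != 1L) break
      if (sk[nxt[1], nxt[2]] == 1L) break
      sk[nxt[1], nxt[2]] <- 1L
      pos <- nxt
    }
  }
  sk
}

#' Skeletonize a mask frame into a rooted skeleton graph
#'
#' Selects the connected component at (or nearest) the seed point, thins it
#' to a 1-pixel-wide skeleton by homotopic (Guo-Hall) thinning, prunes short
#' spurs, and organizes the result as a graph whose nodes are endpoints and
#' junctions and whose edges are ordered 8-connected pixel chains with arc
#' lengths in mm. The root node is the node nearest the seed point.
#'
#' @param frame A [mask_frame()].
#' @param prune_len_mm Spurs shorter than this are removed (default 0.3 mm).
#' @param seed_attach_radius_px Maximum seed-to-foreground distance before
#'   an error is raised (default 20 px).
#' @return Object of class `skeleton_graph`: `nodes` (data.frame id/row/col/
#'   kind), `edges` (list of from/to/chain/length_mm), `root` (node id),
#'   `graph` (igraph, edge attributes `weight` = mm and `eid` = edge index),
#'   `skel` (skeleton matrix, cropped to the foreground bounding box whose
#'   top-left corner is `crop_offset`), plus calibration and identity
#'   fields. Node and chain coordinates are in full-image pixels.
#' @export
skeletonize_mask <- function(frame, prune_len_mm = 0.3,
                             seed_attach_radius_px = 20) {
  stopifnot(inherits(frame, "mask_frame"))
  mask <- frame$mask
  if (sum(mask) == 0) stop("skeletonize_mask: no foreground in mask")
  lab <- label_components(mask)
  sp <- round(frame$seed_point)
  comp_at_seed <- if (sp[1] >= 1 && sp[1] <= nrow(mask) &&
                      sp[2] >= 1 && sp[2] <= ncol(mask)) lab[sp[1], sp[2]]
                  else 0L
  if (comp_at_seed == 0L) {
    fg <- which(mask == 1L, arr.ind = TRUE)
    d2 <- (fg[, 1] - sp[1])^2 + (fg[, 2] - sp[2])^2
    if (min(d2) > seed_attach_radius_px^2)
      stop("skeletonize_mask: seed point farther than ",
           seed_attach_radius_px, " px from any foreground")
    comp_at_seed <- lab[fg[which.min(d2), , drop = FALSE]]
  }
  if (max(lab) > 1)
    warning("skeletonize_mask: ignoring ", max(lab) - 1,
            " foreground component(s) away from the seed")
  comp <- (lab == comp_at_seed) + 0L
  # work on the foreground bounding box: thinning cost scales with canvas
  # area while the plant usually occupies a small, growing part of it
  fg <- which(comp == 1L, arr.ind = TRUE)
  r0 <- max(1L, min(fg[, 1]) - 2L); r1 <- min(nrow(comp), max(fg[, 1]) + 2L)
  c0 <- max(1L, min(fg[, 2]) - 2L); c1 <- min(ncol(comp), max(fg[, 2]) + 2L)
  comp <- comp[r0:r1, c0:c1, drop = FALSE]
  sp_c <- c(sp[1] - r0 + 1, sp[2] - c0 + 1)
  sk <- .thin_cpp(comp)
  sk <- prune_spurs(sk, frame$px_mm, prune_len_mm, protect_px = sp_c,
                    protect_radius_px = seed_attach_radius_px)
  sk <- anchor_endpoints(sk, comp)
  gr <- build_skel_graph(sk, frame$px_mm)
  # report node and chain coordinates in full-image pixels
  off <- c(r0 - 1L, c0 - 1L)
  gr$nodes$row <- gr$nodes$row + off[1]
  gr$nodes$col <- gr$nodes$col + off[2]
  gr$edges <- lapply(gr$edges, function(e) {
    e$chain[, 1] <- e$chain[, 1] + off[1]
    e$chain[, 2] <- e$chain[, 2] + off[2]
    e
  })
  # The root must sit at the seed. When a lateral emerges right at the
  # seed the seed pixel is a chain-interior point (a V apex of degree 2),
  # so the nearest *node* can be far down the plant and the MR top would
  # be absorbed into the lateral's chain: split the containing chain at
  # the skeleton pixel nearest the seed and make it a node of kind
  # "seed" whenever that pixel is closer than any existing node.
  skel_px <- which(sk == 1L, arr.ind = TRUE)
  skel_px <- cbind(skel_px[, 1] + off[1], skel_px[, 2] + off[2])
  near_px <- skel_px[which.min((skel_px[, 1] - sp[1])^2 +
                                 (skel_px[, 2] - sp[2])^2), ]
  d2 <- (gr$nodes$row - sp[1])^2 + (gr$nodes$col - sp[2])^2
  d2_px <- sum((near_px - sp)^2)
  if (d2_px < min(d2) - 1e-9) {
    split_done <- FALSE
    for (ei in seq_along(gr$edges)) {
      e <- gr$edges[[ei]]
      hit <- which(e$chain[, 1] == near_px[1] & e$chain[, 2] == near_px[2])
      hit <- hit[hit > 1 & hit < nrow(e$chain)]
      if (length(hit) == 0) next
      i <- hit[1]
      new_id <- nrow(gr$nodes) + 1L
      gr$nodes <- rbind(gr$nodes,
                        data.frame(id = new_id, row = near_px[1],
                                   col = near_px[2], kind = "seed"))
      c1 <- e$chain[1:i, , drop = FALSE]
      c2 <- e$chain[i:nrow(e$chain), , drop = FALSE]
      gr$edges[[ei]] <- list(from = e$from, to = new_id, chain = c1,
                             length_mm = chain_steps_px(c1) * frame$px_mm)
      gr$edges[[length(gr$edges) + 1]] <-
        list(from = new_id, to = e$to, chain = c2,
             length_mm = chain_steps_px(c2) * frame$px_mm)
      split_done <- TRUE
      break
    }
    if (split_done) d2 <- c(d2, 0)
  }
  root <- gr$nodes$id[which.min(d2)]
  g <- igraph::make_empty_graph(n = nrow(gr$nodes), directed = FALSE)
  if (length(gr$edges)) {
    el <- do.call(rbind, lapply(gr$edges, function(e) c(e$from, e$to)))
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- vapply(gr$edges, `[[`, numeric(1), "length_mm")
    igraph::E(g)$eid <- seq_along(gr$edges)
  }
  structure(list(nodes = gr$nodes, edges = gr$edges, root = root, graph = g,
                 skel = sk, crop_offset = off, px_mm = frame$px_mm,
                 timestamp_h = frame$timestamp_h, plant_id = frame$plant_id,
                 seed_point = frame$seed_point),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph %s t=%.2fh: %d nodes, %d chains, %.2f mm total\n",
              x$plant_id, x$timestamp_h, nrow(x$nodes), length(x$edges),
              sum(vapply(x$edges, `[[`, numeric(1), "length_mm"))))
  invisible(x)
}

# TRUE if no 2x2 foreground block exists (1-px-wide invariant)
skeleton_is_thin <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  if (nr < 2 || nc < 2) return(TRUE)
  blk <- sk[-nr, -nc] + sk[-nr, -1] + sk[-1, -nc] + sk[-1, -1]
  !any(blk == 4L)
}
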