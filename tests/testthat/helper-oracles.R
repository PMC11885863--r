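# Independent oracles and small constructors shared across the test files.

# Brute-force convex hull, O(n^3): a pair (i, j) is a hull edge iff every
# other point lies (weakly) on one side of the line through i and j.
# Returns the hull vertex cycle in counter-clockwise order.
brute_hull <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  verts <- integer(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- pts[j, ] - pts[i, ]
      cr <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
      cr <- cr[-c(i, j)]
      if (all(cr <= 1e-12) || all(cr >= -1e-12))
        verts <- union(verts, c(i, j))
    }
  }
  hull <- pts[verts, , drop = FALSE]
  ctr <- colMeans(hull)
  hull[order(atan2(hull[, 2] - ctr[2], hull[, 1] - ctr[1])), , drop = FALSE]
}

shoelace <- function(p) {
  n <- nrow(p); i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n1+n2, n1) group labelings (midranks, so ties are handled too).
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

# mask with a vertical bar (inclusive pixel ranges)
bar_mask <- function(nrow_, ncol_, rows, cols) {
  m <- matrix(0L, nrow_, ncol_)
  m[rows, cols] <- 1L
  m
}

# hand-made skeleton_graph from chains (list of integer (row, col)
# matrices); nodes are inferred from chain endpoints
make_sg <- function(chains, root_px, px_mm = 0.1) {
  ends <- do.call(rbind, lapply(chains, function(ch)
    rbind(ch[1, ], ch[nrow(ch), ])))
  nodes <- unique(ends)
  nid <- function(px) which(nodes[, 1] == px[1] & nodes[, 2] == px[2])
  edges <- lapply(chains, function(ch)
    list(from = nid(ch[1, ]), to = nid(ch[nrow(ch), ]), chain = ch,
         length_mm = roottrack:::chain_steps_px(ch) * px_mm))
  deg <- tabulate(unlist(lapply(edges, function(e) c(e$from, e$to))),
                  nbins = nrow(nodes))
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  el <- do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- vapply(edges, `[[`, numeric(1), "length_mm")
  igraph::E(g)$eid <- seq_along(edges)
  structure(list(
    nodes = data.frame(id = seq_len(nrow(nodes)), row = nodes[, 1],
                       col = nodes[, 2],
                       kind = ifelse(deg >= 3, "junction", "endpoint")),
    edges = edges, root = nid(root_px), graph = g, skel = NULL,
    px_mm = px_mm, timestamp_h = 0, plant_id = "test",
    seed_point = root_px), class = "skeleton_graph")
}

# straight pixel chain between two pixels (one of the 8 principal
# directions only)
px_chain <- function(from, to) {
  n <- max(abs(to - from)) + 1
  cbind(round(seq(from[1], to[1], length.out = n)),
        round(seq(from[2], to[2], length.out = n)))
}

# fake root_system_frame holding given LR observations (for tracker tests)
fake_frame <- function(t_h, lrs) {
  structure(list(timestamp_h = t_h, plant_id = "test", px_mm = 0.1,
                 mr = list(chain = NULL, poly_mm = NULL, length_mm = 10),
                 lrs = lrs), class = "root_system_frame")
}

fake_lr <- function(base_px, arc, len = 1, gt_id = NULL) {
  poly <- rbind(c(0, 0), c(len / sqrt(2), len / sqrt(2)))
  c(list(base_px = base_px, base_arc_on_mr_mm = arc, poly_mm = poly,
         length_mm = len),
    if (!is.null(gt_id)) list(gt_id = gt_id))
}
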