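# Polyline geometry helpers shared by the simulator, the skeleton
# decomposition and the angle estimators.

#' Arc length of a polyline
#'
#' @param p Numeric matrix with two columns (x, y); one vertex per row.
#' @return Total length (sum of segment lengths), 0 for fewer than 2 rows.
#' @export
arc_length <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# cumulative arc length at each vertex (first = 0)
cum_arc <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))))
}

#' Point at a given arc length along a polyline
#'
#' Walks the polyline from its first vertex and returns the point at arc
#' length `s`, linearly interpolating within the containing segment.
#'
#' @param p Polyline matrix (x, y).
#' @param s Arc length from the first vertex; must satisfy
#'   `0 <= s <= arc_length(p)`.
#' @return Length-2 numeric vector (x, y).
#' @export
point_at_arc <- function(p, s) {
  p <- as.matrix(p)
  stopifnot(nrow(p) >= 2, is.finite(s), s >= 0)
  ca <- cum_arc(p)
  if (s > ca[length(ca)] + 1e-12)
    stop("arc length ", s, " exceeds polyline length ", ca[length(ca)])
  s <- min(s, ca[length(ca)])
  i <- findInterval(s, ca, rightmost.closed = TRUE)
  i <- min(i, nrow(p) - 1)
  seg <- ca[i + 1] - ca[i]
  f <- if (seg > 0) (s - ca[i]) / seg else 0
  p[i, ] + f * (p[i + 1, ] - p[i, ])
}

#' Moving-average smoothing of a polyline
#'
#' Replaces interior vertices by a centred moving average of width `window`;
#' the two endpoints are kept fixed so that base and tip positions are
#' unaffected. Used to suppress the staircase jitter of rasterized skeleton
#' chains, which otherwise inflates arc-length estimates by several percent.
#'
#' @param p Polyline matrix.
#' @param window Odd integer window width; values below 3 return `p`
#'   unchanged.
#' @return Smoothed polyline of the same dimensions.
#' @export
smooth_polyline <- function(p, window = 5) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3 || window < 3) return(p)
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  if (window %% 2 == 0) window <- window - 1
  k <- rep(1 / window, window)
  q <- p
  for (j in 1:2) {
    f <- stats::filter(p[, j], k)
    ok <- !is.na(f)
    q[ok, j] <- f[ok]
  }
  q[1, ] <- p[1, ]
  q[n, ] <- p[n, ]
  # near-endpoint vertices not covered by the full window: shrink the window
  h <- (window - 1) / 2
  if (h >= 2) {
    for (i in 2:h) {
      w <- 2 * (i - 1) + 1
      q[i, ] <- colMeans(p[1:(2 * i - 1), , drop = FALSE])
      q[n - i + 1, ] <- colMeans(p[(n - 2 * i + 2):n, , drop = FALSE])
    }
  }
  q
}

# pixel chain (row, col) -> mm polyline (x, y), y increasing with row
chain_to_mm <- function(chain, px_mm, smooth_window = 5) {
  chain <- as.matrix(chain)
  mm <- cbind(x = (chain[, 2] - 1) * px_mm, y = (chain[, 1] - 1) * px_mm)
  smooth_polyline(mm, smooth_window)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# direction unit vector (x, y) for an angle from gravity (+y), signed
# side: +1 bends toward +x, -1 toward -x
dir_from_gravity <- function(theta_deg, side = 1) {
  th <- deg2rad(theta_deg)
  cbind(side * sin(th), cos(th))
}
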