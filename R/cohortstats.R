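# Cohort-level genotype comparison: per-hour Mann-Whitney rank-sum tests
# with a both-lines significance flag, and superposition count maps.

#' Mann-Whitney rank-sum test
#'
#' Computes the U statistic from midranks and a two-sided p-value: exact
#' (by complete enumeration of the rank-sum distribution) when the combined
#' sample size is at most 12 and no ties are present, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples (each non-empty).
#' @return List: `U` (statistic of `a`), `p` (two-sided), `exact` (logical).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("mann_whitney: empty sample")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- (n1 + n2) <= 12 && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(U = U, p = p, exact = exact)
}

#' Time-resolved cohort comparison
#'
#' For each feature and hour, tests every treatment group against the
#' control with [mann_whitney()] and flags per-line significance at
#' `alpha`; the `both_lines` flag is true for a feature-hour when every
#' treatment line is individually significant (the "**" convention). No
#' multiple-testing correction is applied by default; `fdr = TRUE` adds
#' Benjamini-Hochberg-adjusted p-values per feature across hours and bases
#' the flags on them.
#'
#' @param table Tidy feature table: columns `plant_id`, `group`, `hour`,
#'   plus one numeric column per feature.
#' @param control Group id of the control line.
#' @param features Feature columns to test (default: all numeric except
#'   `hour`).
#' @param alpha Per-test significance level (default 0.05).
#' @param min_n Minimum group size per hour; smaller comparisons are
#'   skipped with a warning (default 3).
#' @param fdr Apply step-up FDR per feature across hours.
#' @return Tibble: feature, hour, group, n_control, n_group, U, p
#'   (and p_adj when `fdr`), significant, both_lines.
#' @export
timeseries_compare <- function(table, control, features = NULL,
                               alpha = 0.05, min_n = 3, fdr = FALSE) {
  stopifnot(all(c("plant_id", "group", "hour") %in% names(table)))
  if (!control %in% table$group)
    stop("timeseries_compare: control group not present")
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        "hour")
  treat <- setdiff(unique(table$group), control)
  rows <- list()
  n_skipped <- 0
  for (f in features) {
    for (h in sort(unique(table$hour))) {
      at <- table[table$hour == h, , drop = FALSE]
      ctrl <- at[[f]][at$group == control]
      ctrl <- ctrl[is.finite(ctrl)]
      for (g in treat) {
        x <- at[[f]][at$group == g]
        x <- x[is.finite(x)]
        if (length(ctrl) < min_n || length(x) < min_n) {
          n_skipped <- n_skipped + 1
          next
        }
        mw <- mann_whitney(x, ctrl)
        rows[[length(rows) + 1]] <-
          tibble::tibble(feature = f, hour = h, group = g,
                         n_control = length(ctrl), n_group = length(x),
                         U = mw$U, p = mw$p)
      }
    }
  }
  if (n_skipped > 0)
    warning("timeseries_compare: skipped ", n_skipped,
            " comparison(s) with group n < ", min_n)
  if (length(rows) == 0)
    return(tibble::tibble(feature = character(0), hour = numeric(0),
                          group = character(0), n_control = integer(0),
                          n_group = integer(0), U = numeric(0),
                          p = numeric(0), significant = logical(0),
                          both_lines = logical(0)))
  out <- do.call(rbind, rows)
  if (fdr) {
    out$p_adj <- NA_real_
    for (f in unique(out$feature)) {
      i <- out$feature == f
      out$p_adj[i] <- stats::p.adjust(out$p[i], method = "BH")
    }
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  key <- paste(out$feature, out$hour)
  full <- vapply(split(out, key), function(d)
    nrow(d) == length(treat) && all(d$significant), logical(1))
  out$both_lines <- unname(full[key])
  out
}

#' Superposition count map of a cohort
#'
#' For each plant, rotates the final segmentation about the MR start so the
#' start-to-end chord points straight down, translates the MR start to a
#' common reference pixel, resamples to a binary image (nearest neighbour,
#' so masks stay binary), and sums across plants: the value of a pixel is
#' the number of plants whose root occupies it.
#'
#' @param plants List with one entry per plant: `mask` (binary matrix),
#'   `mr_start`, `mr_end` (pixels, row/col). Plants with `mr_start ==
#'   mr_end` are excluded with a warning.
#' @param canvas_hw Optional canvas (rows, cols); auto-sized by default.
#' @param ref_px Optional reference pixel (row, col) for the MR start.
#' @return Object of class `superposition_map`: `counts` (integer matrix),
#'   `ref_px`, `n_plants`.
#' @export
superposition_map <- function(plants, canvas_hw = NULL, ref_px = NULL) {
  plants <- lapply(plants, function(p) {
    p$mr_start <- unname(as.numeric(p$mr_start))
    p$mr_end <- unname(as.numeric(p$mr_end))
    p
  })
  keep <- vapply(plants, function(p)
    !all(p$mr_start == p$mr_end), logical(1))
  if (any(!keep))
    warning("superposition_map: excluded ", sum(!keep),
            " plant(s) with degenerate MR chord")
  plants <- plants[keep]
  if (length(plants) == 0) stop("superposition_map: no usable plants")

  # rotation taking the start->end chord to +row (straight down)
  rot <- lapply(plants, function(p) {
    v <- p$mr_end - p$mr_start
    phi <- atan2(v[2], v[1])        # angle of chord from +row axis
    c(cos = cos(-phi), sin = sin(-phi))
  })
  # forward-rotate mask corners to size the canvas
  if (is.null(canvas_hw) || is.null(ref_px)) {
    ext <- t(vapply(seq_along(plants), function(i) {
      p <- plants[[i]]; R <- rot[[i]]
      fg <- which(p$mask == 1L, arr.ind = TRUE)
      rb <- if (nrow(fg)) range(fg[, 1]) else c(1, 1)
      cb <- if (nrow(fg)) range(fg[, 2]) else c(1, 1)
      corners <- rbind(c(rb[1], cb[1]), c(rb[1], cb[2]),
                       c(rb[2], cb[1]), c(rb[2], cb[2]))
      d <- sweep(corners, 2, p$mr_start)
      rr <- R["cos"] * d[, 1] - R["sin"] * d[, 2]
      cc <- R["sin"] * d[, 1] + R["cos"] * d[, 2]
      c(min(rr), max(rr), min(cc), max(cc))
    }, numeric(4)))
    if (is.null(ref_px))
      ref_px <- c(1 - floor(min(ext[, 1])) + 1, 1 - floor(min(ext[, 3])) + 1)
    if (is.null(canvas_hw))
      canvas_hw <- c(ceiling(max(ext[, 2])) + ref_px[1] + 1,
                     ceiling(max(ext[, 4])) + ref_px[2] + 1)
  }
  counts <- matrix(0L, canvas_hw[1], canvas_hw[2])
  tgt <- as.matrix(expand.grid(r = seq_len(canvas_hw[1]),
                               c = seq_len(canvas_hw[2])))
  for (i in seq_along(plants)) {
    p <- plants[[i]]; R <- rot[[i]]
    # inverse map: canvas pixel -> source pixel (rotate by +phi)
    dr <- tgt[, 1] - ref_px[1]; dc <- tgt[, 2] - ref_px[2]
    sr <- R["cos"] * dr + R["sin"] * dc + p$mr_start[1]
    sc <- -R["sin"] * dr + R["cos"] * dc + p$mr_start[2]
    sr <- round(sr); sc <- round(sc)
    ok <- sr >= 1 & sr <= nrow(p$mask) & sc >= 1 & sc <= ncol(p$mask)
    hit <- ok
    hit[ok] <- p$mask[cbind(sr[ok], sc[ok])] == 1L
    counts[tgt[hit, , drop = FALSE]] <- counts[tgt[hit, , drop = FALSE]] + 1L
  }
  structure(list(counts = counts, ref_px = ref_px,
                 n_plants = length(plants)),
            class = "superposition_map")
}

#' @export
print.superposition_map <- function(x, ...) {
  cat(sprintf("superposition_map: %d plants, %dx%d px, max overlap %d\n",
              x$n_plants, nrow(x$counts), ncol(x$counts), max(x$counts)))
  invisible(x)
}

#' Write a superposition map as a 16-bit PNG
#'
#' @param map A `superposition_map`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_superposition_png <- function(map, path) {
  png::writePNG(map$counts / 65535, path)
  invisible(path)
}
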