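#' Delaunay triangulation of 2-D points (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation. Sufficient for electrode
#' montages (tens of points); exactly co-circular quadruples - common in
#' left/right symmetric montages - are broken by a deterministic,
#' vanishingly small perturbation so the result is reproducible.
#'
#' @param px,py point coordinates.
#' @return Integer matrix, one triangle per row (vertex indices).
#' @export
delaunay_triangulate <- function(px, py) {
  n <- length(px)
  .assert(length(py) == n, "px, py length mismatch")
  .assert(n >= 3, "need at least 3 points")
  scale <- max(max(px) - min(px), max(py) - min(py), .Machine$double.eps)
  # deterministic symmetry-breaking jitter (~1e-9 of the bounding box)
  i <- seq_len(n)
  px <- px + scale * 1e-9 * (((i * 37) %% 101) / 101 - 0.5)
  py <- py + scale * 1e-9 * (((i * 59) %% 103) / 103 - 0.5)

  cx <- mean(range(px)); cy <- mean(range(py))
  d <- 20 * scale
  P <- rbind(cbind(px, py),
             c(cx - 2 * d, cy - d), c(cx + 2 * d, cy - d), c(cx, cy + 2 * d))
  s1 <- n + 1; s2 <- n + 2; s3 <- n + 3

  tris <- list(c(s1, s2, s3))
  for (p in seq_len(n)) {
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      bad[t] <- .in_circumcircle(P[tris[[t]][1], ], P[tris[[t]][2], ],
                                 P[tris[[t]][3], ], P[p, ])
    }
    # polygon boundary = edges of bad triangles that occur exactly once
    edges <- matrix(integer(0), ncol = 2)
    for (t in which(bad)) {
      v <- tris[[t]]
      edges <- rbind(edges,
                     sort(v[c(1, 2)]), sort(v[c(2, 3)]), sort(v[c(1, 3)]))
    }
    if (nrow(edges) > 0) {
      key <- paste(edges[, 1], edges[, 2])
      keep <- key %in% names(which(table(key) == 1))
      edges <- edges[keep, , drop = FALSE]
    }
    tris <- tris[!bad]
    for (e in seq_len(nrow(edges))) {
      tris[[length(tris) + 1]] <- c(edges[e, 1], edges[e, 2], p)
    }
  }
  out <- do.call(rbind, tris)
  out <- out[apply(out, 1, function(v) all(v <= n)), , drop = FALSE]
  out
}

# TRUE if point d lies strictly inside the circumcircle of triangle abc
.in_circumcircle <- function(a, b, c, d) {
  # normalize orientation so the incircle determinant sign is meaningful
  orient <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (orient < 0) { tmp <- b; b <- c; c <- tmp }
  ax <- a[1] - d[1]; ay <- a[2] - d[2]
  bx <- b[1] - d[1]; by <- b[2] - d[2]
  cx <- c[1] - d[1]; cy <- c[2] - d[2]
  det <- (ax * ax + ay * ay) * (bx * cy - cx * by) -
         (bx * bx + by * by) * (ax * cy - cx * ay) +
         (cx * cx + cy * cy) * (ax * by - bx * ay)
  det > 0
}
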