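# Independent oracles used by the tests: gift-wrapping convex hull and a
# rotational-scan minimal enclosing triangle, both deliberately unrelated
# to the package's own algorithms.

# gift-wrapping (Jarvis march) hull, CCW vertex order
oracle_hull <- function(pts) {
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  idx <- start
  repeat {
    cur <- idx[length(idx)]
    cand <- setdiff(seq_len(n), cur)
    best <- cand[1]
    for (j in cand[-1]) {
      cr <- (pts[best, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[best, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cr < 0 || (cr == 0 &&
          sum((pts[j, ] - pts[cur, ])^2) > sum((pts[best, ] - pts[cur, ])^2)))
        best <- j
    }
    if (best == start) break
    idx <- c(idx, best)
    if (length(idx) > n) stop("gift wrapping failed")
  }
  pts[idx, , drop = FALSE]
}

oracle_polygon_area <- function(v) {
  n <- nrow(v); j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Minimal enclosing triangle by dense rotational scan: for each hull edge
# taken as the flush side (a known optimality property), scan the outward
# normal angles of the two remaining support lines on a grid, then zoom.
oracle_min_triangle_area <- function(pts) {
  hull <- oracle_hull(as.matrix(pts))
  support <- function(theta) {
    u <- rbind(cos(theta), sin(theta))
    apply(hull %*% u, 2, max)
  }
  # vectorised area of triangles bounded by support lines at angles
  # (a0, a1, a2); Inf when the normals do not positively span the plane
  tri_area <- function(a0, c0, a1, a2) {
    c1 <- support(a1); c2 <- support(a2)
    inter <- function(aa, ca, ab, cb) {
      det <- sin(ab - aa)
      cbind((ca * sin(ab) - cb * sin(aa)) / det,
            (cos(aa) * cb - cos(ab) * ca) / det)
    }
    v01 <- inter(a0, c0, a1, c1)
    v02 <- inter(a0, c0, a2, c2)
    v12 <- inter(a1, c1, a2, c2)
    area <- abs((v02[, 1] - v01[, 1]) * (v12[, 2] - v01[, 2]) -
                (v02[, 2] - v01[, 2]) * (v12[, 1] - v01[, 1])) / 2
    d1 <- (a1 - a0) %% (2 * pi); d2 <- (a2 - a0) %% (2 * pi)
    ok <- d1 < d2 & d1 < pi & (d2 - d1) < pi & (2 * pi - d2) < pi &
      abs(sin(a1 - a0)) > 1e-9 & abs(sin(a2 - a0)) > 1e-9 &
      abs(sin(a2 - a1)) > 1e-9
    area[!ok | !is.finite(area)] <- Inf
    area
  }
  h <- nrow(hull)
  best <- Inf
  for (e in seq_len(h)) {
    i2 <- if (e == h) 1L else e + 1L
    d <- hull[i2, ] - hull[e, ]
    a0 <- atan2(-d[1], d[2])      # outward normal of a CCW edge... sign checked below
    if (cos(a0) * hull[e, 1] + sin(a0) * hull[e, 2] < max(hull %*% c(cos(a0), sin(a0))) - 1e-12)
      a0 <- a0 + pi
    c0 <- max(hull %*% c(cos(a0), sin(a0)))
    # coarse grid over normal offsets (d1, d2) from the flush normal,
    # then zoom refinement from each of the best coarse cells (the area
    # surface has several local basins per flush edge)
    m0 <- 90
    g1 <- seq(0, 2 * pi, length.out = m0)
    grid0 <- expand.grid(d1 = g1, d2 = g1)
    ar0 <- tri_area(a0, c0, a0 + grid0$d1, a0 + grid0$d2)
    starts <- order(ar0)[seq_len(min(8, sum(is.finite(ar0))))]
    step0 <- 2 * pi / (m0 - 1)
    for (k0 in starts) {
      if (!is.finite(ar0[k0])) next
      lo1 <- grid0$d1[k0] - 1.5 * step0; hi1 <- grid0$d1[k0] + 1.5 * step0
      lo2 <- grid0$d2[k0] - 1.5 * step0; hi2 <- grid0$d2[k0] + 1.5 * step0
      if (ar0[k0] < best) best <- ar0[k0]
      m <- 25
      for (round in 1:10) {
        gg1 <- seq(lo1, hi1, length.out = m)
        gg2 <- seq(lo2, hi2, length.out = m)
        grid <- expand.grid(d1 = gg1, d2 = gg2)
        ar <- tri_area(a0, c0, a0 + grid$d1, a0 + grid$d2)
        k <- which.min(ar)
        if (!is.finite(ar[k])) break
        if (ar[k] < best) best <- ar[k]
        step1 <- (hi1 - lo1) / (m - 1); step2 <- (hi2 - lo2) / (m - 1)
        lo1 <- grid$d1[k] - 1.5 * step1; hi1 <- grid$d1[k] + 1.5 * step1
        lo2 <- grid$d2[k] - 1.5 * step2; hi2 <- grid$d2[k] + 1.5 * step2
      }
    }
  }
  best
}

# hand-rolled Welch two-sample t-test p-value
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# ages of the internal nodes of an ultrametric tree (for picking cut times)
node_ages_for_test <- function(tree) ape::branching.times(tree)

# order a vector's values, dropping names, for multiset comparisons
msort <- function(v) unname(sort(v))
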