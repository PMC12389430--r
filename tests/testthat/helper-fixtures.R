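# fixtures built in code; all randomness goes through explicit seeds

# stand with guaranteed minimum spacing: jittered lattice
jitteredGridStand <- function(n = 20, plotSize = 25, jitter = 1,
                              speciesPool = 5, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  sp <- plotSize / side
  g <- expand.grid(x = (seq_len(side) - 0.5) * sp,
                   y = (seq_len(side) - 0.5) * sp)[seq_len(n), ]
  dbh <- 5 + rexp(n, 0.08)
  ForestStand(data.frame(
    tree_id = seq_len(n),
    species = sprintf("sp%02d", sample.int(speciesPool, n, replace = TRUE)),
    x = g$x + runif(n, -jitter, jitter),
    y = g$y + runif(n, -jitter, jitter),
    dbh = dbh, height = pmax(1.3 * dbh^0.6, 3),
    stringsAsFactors = FALSE), plotSize)
}

# hand-placed stand for oracle checks
smallStand <- function(df, plotSize = 25) ForestStand(df, plotSize)

# independent point-in-convex-polygon oracle (half-plane signs)
convexContains <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  # inside iff all edge cross products share one sign (zero = on boundary)
  pos <- rep(FALSE, length(px)); neg <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    pos <- pos | cr > eps
    neg <- neg | cr < -eps
  }
  !(pos & neg)
}

# brute-force circumcircle-empty check for a triangulation
delaunayPropertyHolds <- function(xy, tri, tol = 1e-9) {
  for (t in seq_len(nrow(tri))) {
    a <- xy[tri[t, 1], ]; b <- xy[tri[t, 2], ]; c <- xy[tri[t, 3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(FALSE)
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    others <- setdiff(seq_len(nrow(xy)), tri[t, ])
    d2 <- (xy[others, 1] - ux)^2 + (xy[others, 2] - uy)^2
    if (any(d2 < r2 * (1 - tol) - tol)) return(FALSE)
  }
  TRUE
}
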