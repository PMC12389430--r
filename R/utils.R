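# internal helpers shared across modules

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (caller-controlled RNG).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Chunked brute-force k-nearest-neighbour search in the horizontal plane
# (or any d-dim coordinate matrix). Returns list(idx, dist): n x k matrices,
# neighbours of each query row among the rows of `ref`, excluding an exact
# self-match when `self` gives the ref index of each query. Ties in distance
# are broken by ascending ref index.
.knn <- function(query, ref, k, self = NULL, chunk = 512L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  n <- nrow(query); m <- nrow(ref)
  avail <- if (is.null(self)) m else m - 1L
  if (k > avail)
    stop("k must not exceed the number of available reference points")
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  ref2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    nr <- e - s + 1L
    if (!is.null(self)) {
      sl <- self[s:e]
      d2[cbind(seq_len(nr), sl)] <- Inf
    }
    # k passes of max.col: each pass pulls the next-nearest neighbour
    # (ties resolved to the lowest reference index)
    rows <- seq_len(nr)
    for (j in seq_len(k)) {
      jm <- max.col(-d2, ties.method = "first")
      idx[s:e, j] <- jm
      dst[s:e, j] <- sqrt(d2[cbind(rows, jm)])
      d2[cbind(rows, jm)] <- Inf
    }
  }
  list(idx = idx, dist = dst)
}

# Azimuth in degrees from point (x0, y0) to (x1, y1): 0 = +y (north),
# clockwise positive, range [0, 360).
.azimuth <- function(x0, y0, x1, y1) {
  a <- atan2(x1 - x0, y1 - y0) * 180 / pi
  (a + 360) %% 360
}

.romanLabels <- function(n) as.character(utils::as.roman(seq_len(n)))
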