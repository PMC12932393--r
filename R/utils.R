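#' Logit and inverse-logit
#'
#' Beta values live in (0,1); all additive simulation and several transforms
#' operate on the logit scale.
#'
#' @param p Numeric vector in (0,1).
#' @return `logit()` returns log(p/(1-p)); `expit()` its inverse.
#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @param x Numeric vector.
#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same samples, corrected for chance.
#' Labels may be any atomic type; NA pairs are dropped.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Optimal one-to-one matching maximizing the trace of a score matrix.
# Exhaustive over permutations of the smaller dimension; intended for
# cluster-label matching where k <= 8.
best_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  transposed <- nr > nc
  if (transposed) score <- t(score)
  nr <- nrow(score); nc <- ncol(score)
  if (nr > 8) stop("assignment matching supports at most 8 clusters per side")
  perms <- permutations(nc)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    cols <- perms[i, seq_len(nr)]
    val <- sum(score[cbind(seq_len(nr), cols)])
    if (val > best_val + 1e-12) { best_val <- val; best <- cols }
  }
  # match[i] = column matched to row i (of the original orientation)
  if (transposed) {
    out <- rep(NA_integer_, nc)
    out[best] <- seq_len(nr)
    out
  } else best
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# Point-in-polygon with boundary points counted inside.
# poly: matrix with 2 columns (vertices in order); pts: n x 2 matrix.
# Handles degenerate (collinear / single-point) polygons as zero-width sets.
points_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- matrix(as.numeric(poly), ncol = 2)
  nv <- nrow(poly)
  scale <- max(1, abs(range(poly)))
  eps <- tol * scale
  on_segment <- function(p, a, b) {
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) > eps * max(1, sqrt(sum((b - a)^2)))) return(FALSE)
    p[1] >= min(a[1], b[1]) - eps && p[1] <= max(a[1], b[1]) + eps &&
      p[2] >= min(a[2], b[2]) - eps && p[2] <= max(a[2], b[2]) + eps
  }
  apply(pts, 1, function(p) {
    if (nv == 1) return(all(abs(p - poly[1, ]) <= eps))
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      if (on_segment(p, poly[i, ], poly[j, ])) return(TRUE)
    }
    if (nv < 3) return(FALSE)
    inside <- FALSE
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > p[2]) != (yj > p[2])) {
        xint <- poly[i, 1] + (p[2] - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
        if (p[1] < xint) inside <- !inside
      }
    }
    inside
  })
}

# Derive a child RNG seed from a base seed and a stream counter, kept within
# 32-bit integer range.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435761 + stream * 97) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a > b, stable.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}
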