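# Independent oracles kept deliberately separate from the package's own
# algorithms: a hand-built codon-table walk, a pairwise-enumeration run
# finder, and a brute-force convex hull.

# Standard nuclear genetic code, laid out in the classic TCAG order.
ORACLE_CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

# Walk a CDS codon by codon; returns the amino-acid string incl. stops.
oracle_translate <- function(s) {
  n <- nchar(s) %/% 3L
  paste(ORACLE_CODON_TABLE[substring(s, 3L * seq_len(n) - 2L,
                                     3L * seq_len(n))], collapse = "")
}

# Maximal valid run intervals by exhaustive pairwise enumeration: a segment
# [i, j] is valid iff both ends cosegregate, it holds >= min_run
# cosegregating calls and no internal stretch of > max_mismatch successive
# mismatches; report the valid segments contained in no larger valid one.
oracle_runs <- function(coseg, min_run = 3L, max_mismatch = 2L) {
  n <- length(coseg)
  if (n == 0L) return(cbind(i = integer(0), j = integer(0)))
  f <- integer(n)                       # mismatch-run length ending at k
  for (k in seq_len(n)) f[k] <- if (coseg[k]) 0L else
    (if (k > 1L) f[k - 1L] else 0L) + 1L
  cumC <- cumsum(coseg)
  cumG <- cumsum(f > max_mismatch)
  iM <- matrix(seq_len(n), n, n)
  jM <- t(iM)
  nC <- outer(c(0L, cumC[-n]), cumC, function(a, b) b - a)  # C count in [i,j]
  badIn <- outer(cumG, cumG, function(a, b) b - a) > 0L     # k in (i, j]
  valid <- outer(coseg, coseg, "&") & jM >= iM & nC >= min_run & !badIn
  if (!any(valid)) return(cbind(i = integer(0), j = integer(0)))
  # containment count: number of valid segments with i2 <= i and j2 >= j
  cnt <- apply(apply(valid, 2L, cumsum), 1L, function(r) rev(cumsum(rev(r))))
  cnt <- t(cnt)                         # cnt[i, j]
  maximal <- which(valid & cnt == 1L, arr.ind = TRUE)
  maximal <- maximal[order(maximal[, 1L]), , drop = FALSE]
  cbind(i = maximal[, 1L], j = maximal[, 2L])
}

# Brute-force convex hull area: a vertex is extreme iff it lies strictly
# inside no triangle of other vertices; hull area by shoelace on the
# extreme points sorted around the centroid.
oracle_hull_area <- function(x, y) {
  n <- length(x)
  in_triangle <- function(px, py, ax, ay, bx, by, cx, cy) {
    d1 <- (px - bx) * (ay - by) - (ax - bx) * (py - by)
    d2 <- (px - cx) * (by - cy) - (bx - cx) * (py - cy)
    d3 <- (px - ax) * (cy - ay) - (cx - ax) * (py - ay)
    neg <- d1 < 0 | d2 < 0 | d3 < 0
    pos <- d1 > 0 | d2 > 0 | d3 > 0
    !(neg && pos)
  }
  extreme <- rep(TRUE, n)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    for (tri in utils::combn(others, 3L, simplify = FALSE)) {
      if (in_triangle(x[v], y[v], x[tri[1]], y[tri[1]],
                      x[tri[2]], y[tri[2]], x[tri[3]], y[tri[3]])) {
        # strict interior only: skip if v coincides with a triangle vertex
        if (!any(x[tri] == x[v] & y[tri] == y[v])) {
          extreme[v] <- FALSE
          break
        }
      }
    }
  }
  hx <- x[extreme]; hy <- y[extreme]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]; hy <- hy[o]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Regular polygon approximating an ellipse with semi-axes a, b.
ellipse_poly <- function(a, b, n = 512L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = a * cos(t), y = b * sin(t))
}
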