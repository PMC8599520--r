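# Brute-force oracles: direct evaluation of the set definitions of erosion
# and dilation (with the reflected element) at every translation, and small
# random binary images / structuring elements to drive them.

oracle_offsets <- function(se, anchor = NULL) {
  if (is.null(anchor)) anchor <- c((ncol(se) - 1) %/% 2, (nrow(se) - 1) %/% 2)
  idx <- which(se == 1, arr.ind = TRUE)
  cbind(ox = idx[, 2] - 1 - anchor[1], oy = idx[, 1] - 1 - anchor[2])
}

oracle_erode <- function(a, se) {
  off <- oracle_offsets(se)
  h <- nrow(a); w <- ncol(a)
  out <- matrix(0L, h, w)
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    qx <- x - off[, "ox"]; qy <- y - off[, "oy"]
    inb <- qx >= 0 & qx < w & qy >= 0 & qy < h
    out[y + 1, x + 1] <- as.integer(all(inb) && all(a[cbind(qy + 1, qx + 1)] == 1))
  }
  out
}

oracle_dilate <- function(a, se) {
  off <- oracle_offsets(se)
  h <- nrow(a); w <- ncol(a)
  out <- matrix(0L, h, w)
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    qx <- x - off[, "ox"]; qy <- y - off[, "oy"]
    inb <- qx >= 0 & qx < w & qy >= 0 & qy < h
    out[y + 1, x + 1] <-
      as.integer(any(a[cbind(qy[inb] + 1, qx[inb] + 1)] == 1))
  }
  out
}

random_binary <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

random_se <- function() {
  repeat {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    se <- matrix(as.integer(stats::runif(n * m) < 0.6), n, m)
    if (sum(se) >= 1) break
  }
  attr(se, "anchor") <- c((m - 1) %/% 2, (n - 1) %/% 2)
  se
}

# shoelace area of an (n x 2) polygon
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
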