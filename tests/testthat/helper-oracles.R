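# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package kernels.

# Sliding-window masked mean by explicit triple loop over window offsets.
oracle_masked_pool <- function(vol, mask, r) {
  d <- dim(vol)
  sums <- array(0, d)
  cnts <- array(0, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        ii <- max(1, i - r[1]):min(d[1], i + r[1])
        jj <- max(1, j - r[2]):min(d[2], j + r[2])
        kk <- max(1, k - r[3]):min(d[3], k + r[3])
        m <- mask[ii, jj, kk]
        sums[i, j, k] <- sum(vol[ii, jj, kk] * m)
        cnts[i, j, k] <- sum(m)
      }
  list(mean = ifelse(cnts > 0, sums / cnts, NA), count = cnts)
}

# Exhaustive Otsu: every one of the 255 interior bin edges is scored by
# the between-class variance computed directly from the raw values.
oracle_otsu <- function(values, bins = 256) {
  # class means computed from the binned representation (the histogram is
  # part of the method's definition), variance maximised by direct search;
  # plateaus of equal variance resolve to their midpoint
  edges <- seq(min(values), max(values), length.out = bins + 1)
  idx <- pmin(bins, pmax(1L, findInterval(values, edges,
                                          rightmost.closed = TRUE)))
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  binned <- mids[idx]
  n <- length(values)
  cand <- edges[2:bins]
  sb <- vapply(seq_along(cand), function(ci) {
    lo <- idx <= ci
    n0 <- sum(lo)
    if (n0 == 0 || n0 == n) return(-Inf)
    w0 <- n0 / n
    w0 * (1 - w0) * (mean(binned[lo]) - mean(binned[!lo]))^2
  }, numeric(1))
  best <- max(sb)
  mean(cand[sb >= best - 1e-12 * max(best, 1)])
}

# Union-find connected components.
oracle_label_cc <- function(mask, connectivity) {
  d <- dim(mask)
  n <- prod(d)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  idx <- which(mask != 0, arr.ind = TRUE)
  lin <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
      if (ii >= 1 && jj >= 1 && kk >= 1 && ii <= d[1] && jj <= d[2] &&
          kk <= d[3] && mask[ii, jj, kk] != 0)
        union(lin(i, j, k), lin(ii, jj, kk))
    }
  }
  roots <- vapply(which(mask != 0), find, numeric(1))
  labels <- array(0L, d)
  labels[which(mask != 0)] <- as.integer(factor(roots))
  labels
}

# Largest component as a mask (ties: smallest minimum linear index).
oracle_largest_cc <- function(mask, connectivity) {
  labels <- oracle_label_cc(mask, connectivity)
  if (all(labels == 0)) return(array(0L, dim(mask)))
  sizes <- table(labels[labels > 0])
  mx <- max(sizes)
  tied <- as.integer(names(sizes)[sizes == mx])
  first_idx <- vapply(tied, function(l) min(which(labels == l)), numeric(1))
  best <- tied[which.min(first_idx)]
  array(as.integer(labels == best), dim(mask))
}

# Direct 3D Sobel gradient magnitude via kernel convolution at one voxel.
oracle_sobel_at <- function(vol, i, j, k) {
  d1 <- c(-1, 0, 1)
  s1 <- c(1, 2, 1)
  at <- function(ii, jj, kk) {
    d <- dim(vol)
    if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
      return(0)
    vol[ii, jj, kk]
  }
  g <- c(0, 0, 0)
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    v <- at(i + a, j + b, k + cc)
    g[1] <- g[1] + d1[a + 2] * s1[b + 2] * s1[cc + 2] * v
    g[2] <- g[2] + s1[a + 2] * d1[b + 2] * s1[cc + 2] * v
    g[3] <- g[3] + s1[a + 2] * s1[b + 2] * d1[cc + 2] * v
  }
  sqrt(sum(g^2))
}
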