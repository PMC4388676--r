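cul3_tokens <- strsplit("NSGLSFEELYRNAYTMVLHK", "")[[1]]

make_cul3_helix <- function() make_helix(cul3_tokens, start = 49)

# brute-force span enumerator for fragment-count checks
brute_spans <- function(first, last, cuts) {
  starts <- c(first, cuts + 1L)
  ends <- c(cuts, last)
  out <- list()
  for (a in starts) for (b in ends) if (a <= b) out[[length(out) + 1]] <- c(a, b)
  out
}

# numeric rigid-superposition oracle: optimize Euler angles on centered sets
oracle_rmsd <- function(A, B, restarts = 30) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  obj <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    R <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  best <- Inf
  for (i in seq_len(restarts)) {
    set.seed(i)
    r <- stats::optim(stats::runif(3, -pi, pi), obj)
    best <- min(best, r$value)
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_r)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
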