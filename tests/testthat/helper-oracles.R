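# Independent brute-force oracles. These deliberately avoid the package's
# BFS/Brandes/rotation code paths: distances and shortest-path counts come
# from adjacency-matrix powers, betweenness from the sigma-product identity,
# clustering from explicit neighbor-pair enumeration, and the rotation group
# from BFS closure over two hand-written 90-degree generators.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  pw <- diag(n)
  for (L in seq_len(n)) {
    pw <- pw %*% a
    newly <- is.infinite(d) & pw > 0
    d[newly] <- L
    diag(d) <- 0
  }
  d
}

# number of shortest i-j paths: walks of length dist(i,j) are exactly the
# shortest paths (any shorter connection would shorten the distance)
oracle_sigma <- function(a, d) {
  n <- nrow(a)
  sig <- matrix(0, n, n)
  pws <- list(diag(n))
  for (L in seq_len(n)) pws[[L + 1]] <- pws[[L]] %*% a
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) sig[i, j] <- pws[[d[i, j] + 1]][i, j]
  }
  sig
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sig <- oracle_sigma(a, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
      if (s == v || t == v || is.infinite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  bc
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (x in seq_len(k - 1)) for (y in seq.int(x + 1, k))
      if (a[nb[x], nb[y]] > 0) links <- links + 1
    2 * links / (k * (k - 1))
  }, double(1))
}

oracle_lp <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  if (!any(is.finite(off))) return(NA_real_)
  mean(off[is.finite(off)])
}

oracle_eglob <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  mean(1 / off)
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# --- rotation oracle: closure of two 90-degree generators -------------------

# coordinate maps on {-1,0,1}^3, raster order (x fastest): rotation about the
# x axis (y,z) -> (-z,y), and about the z axis (x,y) -> (-y,x)
oracle_rotations <- function() {
  coords <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  key <- function(m) (m[, 1] + 1) + 3 * (m[, 2] + 1) + 9 * (m[, 3] + 1) + 1
  perm_of <- function(f) {
    newc <- t(apply(coords, 1, f))
    p <- integer(27)
    p[key(newc)] <- 1:27
    p
  }
  gx <- perm_of(function(c) c(c[1], -c[3], c[2]))
  gz <- perm_of(function(c) c(-c[2], c[1], c[3]))
  seen <- list(`1` = 1:27)
  keyp <- function(p) paste(p, collapse = ",")
  elems <- list(1:27)
  names(elems) <- keyp(1:27)
  frontier <- list(1:27)
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) for (g in list(gx, gz)) {
      q <- p[g] # compose permutations
      k <- keyp(q)
      if (is.null(elems[[k]])) {
        elems[[k]] <- q
        nxt[[length(nxt) + 1]] <- q
      }
    }
    frontier <- nxt
  }
  elems
}

# Pearson correlation from its definitional sums (no cor())
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_cube_similarity <- function(a, b) {
  best <- -Inf
  for (p in oracle_rotations()) {
    r <- oracle_pearson(a, b[p])
    if (r > best) best <- r
  }
  best
}

# small synthetic design used across tests
tiny_design <- function(...) {
  synthetic_design(grid_shape = c(12, 12, 12), n_roi = 4, n_low = 4,
                   n_high = 4, noise_sd = 0.05, seed = 11, ...)
}
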