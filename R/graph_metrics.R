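## Global and nodal measures on binary undirected networks, implemented from
## scratch (breadth-first search, Brandes dependency accumulation, matrix
## triangle counting) so they can be cross-checked against independent
## oracles. Disconnected graphs are handled with the reachable-pair
## convention: characteristic path length averages over reachable ordered
## pairs and reports the unreachable fraction; global efficiency treats
## 1/infinity as 0 natively.

.net_adj <- function(net) {
  if (inherits(net, "binary_network")) return(net$adjacency * 1)
  mn_assert(is.matrix(net) && nrow(net) == ncol(net),
            "expected a binary_network or square adjacency matrix")
  a <- (net != 0) * 1
  a <- 1 * ((a + t(a)) > 0)
  diag(a) <- 0
  a
}

.adj_list <- function(a) apply(a > 0, 1, which, simplify = FALSE)

#' Nodal degree centrality
#'
#' The number of edges incident to each node (row sums of the adjacency).
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return integer vector of per-node degrees.
#' @export
node_degree <- function(net) {
  a <- .net_adj(net)
  as.integer(rowSums(a))
}

#' Nodal clustering coefficient
#'
#' Per node: `2 * triangles / (k * (k - 1))`, i.e. the fraction of a node's
#' neighbor pairs that are themselves connected; 0 for degree < 2.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return numeric vector of per-node clustering coefficients in `[0, 1]`.
#' @export
node_clustering <- function(net) {
  a <- .net_adj(net)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2 # triangles through each node
  cp <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  as.numeric(cp)
}

## BFS distances from one source; Inf where unreachable.
.bfs_dist <- function(adjl, s, n) {
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- unique(unlist(adjl[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

#' All-pairs shortest-path distance matrix
#'
#' Breadth-first search from every node; `Inf` marks unreachable pairs.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return an n x n numeric matrix of hop distances, zero diagonal.
#' @export
distance_matrix <- function(net) {
  a <- .net_adj(net)
  n <- nrow(a)
  adjl <- .adj_list(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) d[s, ] <- .bfs_dist(adjl, s, n)
  d
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered reachable pairs (i != j), plus the
#' fraction of unreachable ordered pairs. With no reachable pairs at all the
#' path length is undefined and returned as `NA`.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return list with `LP`, `unreachable_frac`, and the `distances` matrix.
#' @export
char_path_length <- function(net) {
  d <- distance_matrix(net)
  n <- nrow(d)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  LP <- if (any(reach)) mean(off[reach]) else NA_real_
  list(LP = LP, unreachable_frac = mean(!reach), distances = d)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance, with
#' `1/Inf = 0`, so disconnection is handled natively.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  d <- distance_matrix(net)
  off <- d[row(d) != col(d)]
  if (!length(off)) return(0)
  mean(1 / off)
}

#' Nodal betweenness centrality (Brandes accumulation)
#'
#' For each node `v`, the sum over pairs `(s, t)` (s != t != v) of the
#' fraction of shortest s-t paths passing through `v`. Unnormalized,
#' unordered-pair convention (each pair counted once), computed with the
#' standard breadth-first dependency-accumulation algorithm.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return numeric vector of per-node betweenness values.
#' @export
node_betweenness <- function(net) {
  a <- .net_adj(net)
  n <- nrow(a)
  adjl <- .adj_list(a)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adjl[[v]]) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in adjl[[w]]) {
        if (dist[v] == dist[w] - 1L)
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2 # each unordered pair was counted from both endpoints
}

#' Degree-preserving edge rewiring (double edge swaps)
#'
#' Repeatedly picks two edges (a,b) and (c,d) and swaps them to (a,d), (c,b)
#' when this creates neither self-loops nor duplicate edges, preserving every
#' node's degree. Used to build null networks for small-worldness. Consumes
#' the caller's RNG stream (seed externally via `set.seed`).
#'
#' @param net a `binary_network` or adjacency matrix.
#' @param n_attempts number of attempted swaps; default `10 * n_edges`.
#' @return adjacency matrix of the rewired network.
#' @export
rewire_preserving_degree <- function(net, n_attempts = NULL) {
  a <- .net_adj(net)
  p <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  m <- nrow(p)
  if (m < 2) return(a)
  if (is.null(n_attempts)) n_attempts <- 10L * m
  edges <- p # m x 2, i < j
  for (it in seq_len(n_attempts)) {
    ij <- sample.int(m, 2)
    e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
    ## randomly orient the second edge
    if (runif(1) < 0.5) e2 <- rev(e2)
    na <- sort(c(e1[1], e2[2])); nb <- sort(c(e2[1], e1[2]))
    if (na[1] == na[2] || nb[1] == nb[2]) next # self-loop
    if (a[na[1], na[2]] > 0 || a[nb[1], nb[2]] > 0) next # duplicate
    a[e1[1], e1[2]] <- a[e1[2], e1[1]] <- 0
    a[e2[1], e2[2]] <- a[e2[2], e2[1]] <- 0
    a[na[1], na[2]] <- a[na[2], na[1]] <- 1
    a[nb[1], nb[2]] <- a[nb[2], nb[1]] <- 1
    edges[ij[1], ] <- na
    edges[ij[2], ] <- nb
  }
  a
}

#' Small-worldness against degree-preserving null networks
#'
#' `SW = (CP / CP_null) / (LP / LP_null)` where `CP` is the mean clustering
#' coefficient, `LP` the characteristic path length (reachable-pair
#' convention), and the null values are means over `n_null` rewired networks
#' ([rewire_preserving_degree()]). When rewiring cannot change the graph
#' (e.g. a complete graph) the null equals the original and SW = 1.
#'
#' @param net a `binary_network` or adjacency matrix with at least one edge.
#' @param n_null number of null networks (default 20).
#' @param seed integer seed for the rewiring stream.
#' @param n_attempts swap attempts per null network; default `10 * n_edges`.
#' @return list with `SW`, `CP`, `LP`, `CP_null`, `LP_null`, and the null
#'   samples (`null_CP`, `null_LP`) for diagnostics.
#' @export
small_worldness <- function(net, n_null = 20, seed = 1, n_attempts = NULL) {
  a <- .net_adj(net)
  mn_assert(sum(a) > 0, "small_worldness needs at least one edge")
  mn_assert(n_null >= 1, "n_null must be >= 1")
  CP <- mean(node_clustering(a))
  LP <- char_path_length(a)$LP
  null_CP <- numeric(n_null)
  null_LP <- numeric(n_null)
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      r <- rewire_preserving_degree(a, n_attempts = n_attempts)
      null_CP[b] <- mean(node_clustering(r))
      null_LP[b] <- char_path_length(r)$LP
    }
  })
  CP_null <- mean(null_CP)
  LP_null <- mean(null_LP)
  ## CP > 0 with a triangle-free null makes the ratio unbounded; SW is then
  ## not estimable at this density and reported as NA rather than Inf
  ratio_cp <- if (CP_null == 0) { if (CP == 0) 1 else NA_real_ } else
    CP / CP_null
  ratio_lp <- if (is.na(LP) || is.na(LP_null)) NA_real_ else LP / LP_null
  SW <- if (is.na(ratio_lp) || ratio_lp == 0) NA_real_ else ratio_cp / ratio_lp
  list(SW = SW, CP = CP, LP = LP, CP_null = CP_null, LP_null = LP_null,
       null_CP = null_CP, null_LP = null_LP, n_null = n_null, seed = seed)
}

#' All global and nodal graph measures of a binary network
#'
#' Bundles degree, clustering, betweenness, characteristic path length,
#' global efficiency and small-worldness into one record.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @param n_null null networks for small-worldness (default 20).
#' @param seed seed for the small-world null stream.
#' @return a list of class `graph_metrics` with fields `DC`, `CP`, `BC`
#'   (nodal vectors), `mean_DC`, `mean_CP`, `LP`, `unreachable_frac`,
#'   `E_glob`, `SW`, `n_edges`, `null_spec`.
#' @export
graph_metrics <- function(net, n_null = 20, seed = 1) {
  a <- .net_adj(net)
  dc <- node_degree(a)
  cp <- node_clustering(a)
  bc <- node_betweenness(a)
  pl <- char_path_length(a)
  eg <- global_efficiency(a)
  sw <- if (sum(a) > 0) small_worldness(a, n_null = n_null, seed = seed)
        else list(SW = NA_real_)
  structure(list(DC = dc, CP = cp, BC = bc,
                 mean_DC = mean(dc), mean_CP = mean(cp),
                 LP = pl$LP, unreachable_frac = pl$unreachable_frac,
                 E_glob = eg, SW = sw$SW, n_edges = sum(a) / 2,
                 null_spec = list(n_null = n_null, seed = seed)),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(
    "<graph_metrics> n=%d edges=%d mean_DC=%.3f mean_CP=%.3f LP=%s E_glob=%.3f SW=%s\n",
    length(x$DC), x$n_edges, x$mean_DC, x$mean_CP,
    ifelse(is.na(x$LP), "NA", sprintf("%.3f", x$LP)), x$E_glob,
    ifelse(is.na(x$SW), "NA", sprintf("%.3f", x$SW))))
  invisible(x)
}
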