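# Brute-force graph-metric oracles, independent of the package's topology
# code: all-pairs BFS with explicit shortest-path counting, and hand-rolled
# k-core peeling. Only suitable for small graphs.

oracle_topology <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  n <- length(nodes)
  adj <- setNames(vector("list", n), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- vapply(adj, length, integer(1))

  # BFS from each source: distances, shortest-path counts, predecessors
  bfs <- function(src) {
    dist <- setNames(rep(Inf, n), nodes)
    sigma <- setNames(rep(0, n), nodes)
    preds <- setNames(vector("list", n), nodes)
    order_visited <- character()
    dist[src] <- 0; sigma[src] <- 1
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    list(dist = dist, sigma = sigma, preds = preds, order = order_visited)
  }

  btw <- setNames(rep(0, n), nodes)
  dists <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (src in nodes) {
    r <- bfs(src)
    dists[src, ] <- r$dist[nodes]
    # dependency accumulation (pair-counted twice over sources; halve later)
    delta <- setNames(rep(0, n), nodes)
    for (w in rev(r$order)) {
      for (v in r$preds[[w]]) {
        delta[v] <- delta[v] + (r$sigma[v] / r$sigma[w]) * (1 + delta[w])
      }
      if (w != src) btw[w] <- btw[w] + delta[w]
    }
  }
  btw <- btw / 2  # undirected: each unordered pair counted once

  clo <- vapply(nodes, function(v) {
    finite <- is.finite(dists[v, ])
    r <- sum(finite)
    if (r <= 1L) return(0)
    ((r - 1) / sum(dists[v, finite])) * ((r - 1) / (n - 1))
  }, numeric(1))

  # k-core by iterative peeling
  kcore <- setNames(rep(0L, n), nodes)
  alive <- setNames(rep(TRUE, n), nodes)
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      cur_deg <- vapply(nodes, function(v) {
        if (!alive[v]) return(-1L)
        sum(alive[adj[[v]]])
      }, integer(1))
      drop <- names(cur_deg)[alive & cur_deg < k]
      if (!length(drop)) break
      kcore[drop] <- k - 1L
      alive[drop] <- FALSE
    }
  }

  data.frame(gene_id = nodes, degree = unname(deg), betweenness = unname(btw),
             closeness = unname(clo), kcoreness = unname(kcore),
             stringsAsFactors = FALSE)
}

random_small_graph <- function(n_nodes, p = 0.35) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      combined_score = sample(150:999, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# universe and count those overlapping the K-set by at least k.
oracle_hypergeom <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  universe <- seq_len(N)
  special <- seq_len(K)
  draws <- combn(universe, n)
  hits <- colSums(matrix(draws %in% special, nrow = n))
  mean(hits >= k)
}
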