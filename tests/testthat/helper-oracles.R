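# Independent brute-force oracles.  Everything here works from first
# principles (explicit enumeration, textbook formulas) and never calls the
# package's own code paths or igraph, so it can stand as the second route
# in equivalence tests.

# upper tail of the hypergeometric by direct combinatorial summation
oracle_hyper_tail <- function(x, n, M, N) {
  ks <- x:min(n, M)
  if (x > min(n, M)) return(0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# symmetric weight matrix from an edge-list data frame over given nodes
oracle_adjacency <- function(edges, nodes) {
  a <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a[edges$gene_a[i], edges$gene_b[i]] <- edges$weight[i]
    a[edges$gene_b[i], edges$gene_a[i]] <- edges$weight[i]
  }
  a
}

# path strength by explicit outset-mediator-end triple loop
oracle_ps <- function(net, part, pair) {
  nodes <- net$nodes
  a <- oracle_adjacency(net$edges, nodes)
  mod <- setNames(rep("unassigned", length(nodes)), nodes)
  mod[part$gene[part$gene %in% nodes]] <-
    part$module[part$gene %in% nodes]
  gx <- nodes[mod == pair[1]]
  gy <- nodes[mod == pair[2]]
  mids <- nodes[!(mod %in% pair)]
  total <- 0
  for (m in mids) {
    wm <- sum(a[m, ])
    if (wm == 0) next
    for (o in gx) for (e in gy) {
      total <- total + (a[m, o] / wm) * (a[m, e] / wm)
    }
  }
  total
}

# consistency score by per-gene term evaluation
oracle_ct <- function(net, part, pair) {
  nodes <- sort(unique(c(net$nodes, part$gene)))
  a <- oracle_adjacency(net$edges, nodes)
  mod <- setNames(rep("unassigned", length(nodes)), nodes)
  mod[part$gene] <- part$module
  cc <- length(nodes)
  s_x <- sum(mod == pair[1])
  s_y <- sum(mod == pair[2])
  total <- 0
  for (i in nodes) {
    if (mod[i] %in% pair) next
    cl <- sum(a[i, ] > 0)
    if (cl == 0) next
    w <- sum(a[i, ])
    cmx <- sum(a[i, mod == pair[1]] > 0)
    cmy <- sum(a[i, mod == pair[2]] > 0)
    centered <- min(cmx - (s_x / cc) * cl, cmy - (s_y / cc) * cl)
    total <- total + centered * (cmx * cmy / cl) * w
  }
  total
}

# all-pairs unweighted shortest paths by Floyd-Warshall
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# all shortest paths between two vertices by exhaustive simple-path search
oracle_all_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  best <- list()
  best_len <- Inf
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1
      if (len < best_len) {
        best_len <<- len
        best <<- list(path)
      } else if (len == best_len) {
        best[[length(best) + 1]] <<- path
      }
      return()
    }
    if (length(path) - 1 >= best_len) return()
    for (u in seq_len(n)) {
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  list(paths = best, length = best_len)
}

# normalized vertex betweenness from the enumerated shortest paths
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- setNames(rep(0, n), rownames(adj))
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    sp <- oracle_all_shortest_paths(adj, s, t)
    if (!is.finite(sp$length) || length(sp$paths) == 0) next
    sigma <- length(sp$paths)
    through <- rep(0, n)
    for (p in sp$paths) {
      inner <- setdiff(p, c(s, t))
      through[inner] <- through[inner] + 1
    }
    b <- b + through / sigma
  }
  b / ((n - 1) * (n - 2) / 2)
}

# all eight map summary statistics from the weight matrix
oracle_topo <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj > 0)
  n_edges <- sum(adj > 0) / 2
  d <- oracle_distances(adj)
  fin <- is.finite(d) & d > 0
  btw <- oracle_betweenness(adj)
  local_cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb] > 0) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  list(
    avg_degree = mean(deg),
    density = 2 * n_edges / (n * (n - 1)),
    characteristic_path_length = if (any(fin)) mean(d[fin]) else NA_real_,
    diameter = if (any(fin)) max(d[fin]) else NA_real_,
    avg_betweenness = mean(btw),
    cluster_coefficient = mean(local_cc),
    centrality = if (n >= 3) sum(max(deg) - deg) / ((n - 1) * (n - 2))
                 else NA_real_,
    avg_weight = mean(adj[upper.tri(adj) & adj > 0])
  )
}

# closed-form simple linear regression for fit cross-checks
oracle_lsq <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  pred <- a * x + b
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, r2 = r2)
}
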