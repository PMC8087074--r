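# Small deterministic fixtures shared across test files.

edge_df <- function(a, b, w) data.frame(gene_a = a, gene_b = b, weight = w)

# two 3-gene modules, four cross edges with weights summing to 1.0
bipartite_fixture <- function() {
  list(
    net = gene_network(edge_df(
      a = c("a1", "a1", "a2", "a3", "a1", "b1"),
      b = c("b1", "b2", "b2", "b3", "a2", "b2"),
      w = c(0.1, 0.2, 0.3, 0.4, 0.9, 0.8)
    )),
    part = module_partition(data.frame(
      gene = c("a1", "a2", "a3", "b1", "b2", "b3"),
      module = rep(c("A", "B"), each = 3)
    ))
  )
}

# seven genes, two mediators outside the pair
mediator_fixture <- function() {
  list(
    net = gene_network(edge_df(
      a = c("o1", "o2", "m1", "m1", "m2", "m2", "o1"),
      b = c("m1", "m2", "e1", "e2", "e1", "x1", "e1"),
      w = c(0.5, 0.4, 0.5, 0.3, 0.6, 0.2, 0.15)
    )),
    part = module_partition(data.frame(
      gene = c("o1", "o2", "e1", "e2", "m1", "m2", "x1"),
      module = c("O", "O", "E", "E", "Mid", "Mid", "Mid")
    ))
  )
}

# random connected-ish weighted map on n modules
random_map <- function(seed, n = 8, p = 0.45) {
  withr::with_seed(seed, {
    labels <- sprintf("m%02d", seq_len(n))
    cmb <- utils::combn(labels, 2)
    keep <- runif(ncol(cmb)) < p
    if (sum(keep) < n - 1) keep[sample(which(!keep), n - 1 - sum(keep))] <- TRUE
    modular_map(data.frame(module_x = cmb[1, keep], module_y = cmb[2, keep],
                           imcc = round(runif(sum(keep), 0.05, 1), 3)),
                modules = labels)
  })
}

map_adjacency <- function(map) {
  a <- matrix(0, length(map$modules), length(map$modules),
              dimnames = list(map$modules, map$modules))
  for (i in seq_len(nrow(map$edges))) {
    a[map$edges$module_x[i], map$edges$module_y[i]] <- map$edges$imcc[i]
    a[map$edges$module_y[i], map$edges$module_x[i]] <- map$edges$imcc[i]
  }
  a
}

# small random gene network + partition for parameter oracles
random_condition <- function(seed, n_modules = 3, size = 3, n_bg = 2,
                             p_intra = 0.8, p_cross = 0.35) {
  withr::with_seed(seed, {
    mods <- LETTERS[seq_len(n_modules)]
    part <- data.frame(
      gene = sprintf("g%02d", seq_len(n_modules * size + n_bg)),
      module = c(rep(mods, each = size), rep("unassigned", n_bg))
    )
    genes <- part$gene
    cmb <- utils::combn(genes, 2)
    same <- part$module[match(cmb[1, ], genes)] ==
      part$module[match(cmb[2, ], genes)]
    keep <- ifelse(same, runif(ncol(cmb)) < p_intra,
                   runif(ncol(cmb)) < p_cross)
    edges <- edge_df(cmb[1, keep], cmb[2, keep],
                     round(runif(sum(keep), 0.05, 1), 3))
    list(net = gene_network(edges, nodes = genes),
         part = module_partition(part))
  })
}

clique_map <- function(n, w = 0.5) {
  labels <- sprintf("m%02d", seq_len(n))
  cmb <- utils::combn(labels, 2)
  modular_map(data.frame(module_x = cmb[1, ], module_y = cmb[2, ],
                         imcc = w))
}

star_map <- function(n, w = 0.5) {
  labels <- sprintf("m%02d", seq_len(n))
  modular_map(data.frame(module_x = labels[1], module_y = labels[-1],
                         imcc = w))
}
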