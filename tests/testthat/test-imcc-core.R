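test_that("sum of cross-module weights matches explicit enumeration", {
  # single cross edge
  net1 <- gene_network(edge_df("a", "b", 0.5))
  part1 <- module_partition(data.frame(gene = c("a", "b"),
                                       module = c("A", "B")))
  expect_equal(sum_of_weights(net1, part1, c("A", "B")), 0.5)

  # no cross edges at all
  net0 <- gene_network(edge_df(c("a1", "b1"), c("a2", "b2"), c(0.5, 0.4)))
  part0 <- module_partition(data.frame(gene = c("a1", "a2", "b1", "b2"),
                                       module = c("A", "A", "B", "B")))
  expect_equal(sum_of_weights(net0, part0, c("A", "B")), 0)

  # bipartite fixture: cross weights 0.1 + 0.2 + 0.3 + 0.4; intra ignored
  fx <- bipartite_fixture()
  expect_equal(sum_of_weights(fx$net, fx$part, c("A", "B")), 1.0)
  expect_equal(sum_of_weights(fx$net, fx$part, c("B", "A")), 1.0)
  expect_error(sum_of_weights(fx$net, fx$part, c("A", "Z")),
               "unknown module")
})

test_that("hypergeometric upper tail equals the combinatorial sum", {
  expect_equal(hypergeom_upper_tail(0, 5, 3, 10), 1.0)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  # monotone in x (tail nesting)
  expect_gte(hypergeom_upper_tail(1, 4, 5, 12),
             hypergeom_upper_tail(2, 4, 5, 12))
  # exhaustive small-population equivalence with the enumeration oracle
  for (seed in 1:20) {
    withr::with_seed(seed, {
      N <- sample(5:30, 1)
      M <- sample(0:N, 1)
      n <- sample(1:N, 1)
      x <- sample(0:n, 1)
    })
    expect_equal(hypergeom_upper_tail(x, n, M, N),
                 oracle_hyper_tail(x, n, M, N), tolerance = 1e-10,
                 label = sprintf("tail seed %d", seed))
  }
  expect_error(hypergeom_upper_tail(3, 2, 2, 4), "exceed")
})

test_that("path strength matches the triple-loop oracle", {
  # one mediator with two equal-weight neighbours: (1/2) * (1/2)
  net <- gene_network(edge_df(c("o", "m"), c("m", "e"), c(0.4, 0.4)))
  part <- module_partition(data.frame(gene = c("o", "e", "m"),
                                      module = c("X", "Y", "unassigned")))
  expect_equal(path_strength(net, part, c("X", "Y")), 0.25)

  # no external mediator
  net2 <- gene_network(edge_df("o", "e", 0.7))
  part2 <- module_partition(data.frame(gene = c("o", "e"),
                                       module = c("X", "Y")))
  expect_equal(path_strength(net2, part2, c("X", "Y")), 0)

  fx <- mediator_fixture()
  expect_equal(path_strength(fx$net, fx$part, c("O", "E")),
               oracle_ps(fx$net, fx$part, c("O", "E")), tolerance = 1e-12)

  for (seed in 1:20) {
    rc <- random_condition(seed)
    got <- path_strength(rc$net, rc$part, c("A", "B"))
    want <- oracle_ps(rc$net, rc$part, c("A", "B"))
    expect_equal(got, want, tolerance = 1e-10,
                 label = sprintf("PS seed %d", seed))
    # symmetry and per-mediator bound
    expect_equal(path_strength(rc$net, rc$part, c("B", "A")), got,
                 tolerance = 1e-12)
    expect_gte(got, 0)
  }
})

test_that("consistency score matches per-gene term evaluation", {
  # empty cross structure: every external gene lacks a link to one module
  net <- gene_network(edge_df(c("a1", "b1"), c("a2", "b2"), c(0.5, 0.4)))
  part <- module_partition(data.frame(gene = c("a1", "a2", "b1", "b2"),
                                      module = c("A", "A", "B", "B")))
  expect_equal(consistency_score(net, part, c("A", "B")), 0)

  for (seed in 1:20) {
    rc <- random_condition(seed)
    expect_equal(consistency_score(rc$net, rc$part, c("A", "C")),
                 oracle_ct(rc$net, rc$part, c("A", "C")), tolerance = 1e-9,
                 label = sprintf("CT seed %d", seed))
  }
})

test_that("normalization and integration arithmetic", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(5), 0)
  v <- withr::with_seed(8, runif(20))
  expect_equal(order(minmax_normalize(v)), order(v))

  expect_equal(integrate_imcc1(0.6, 0.2, rho = 1), 0.4)
  expect_equal(integrate_imcc1(1, 0, rho = 10), 10 / 11)
  grid <- c(1/10, 1/8, 1/4, 1/2, 1, 2, 4, 8, 10)
  for (r in grid) {
    expect_true(is.finite(integrate_imcc1(0.3, 0.7, r)))
  }
  expect_equal(integrate_imcc2(0.3, 0.2), 0.5)
  expect_equal(integrate_imcc2(0.9, 0), 0.9)
})

test_that("screening flags equal brute-force recounts on a condition", {
  d <- planted_design(module_sizes = rep(6, 6), mediator_pool = 10,
                      n_coordinated = 10, seed = 14)
  sim <- make_modular_network(d)
  sc <- score_condition(sim$network, sim$partition)
  cfg <- screening_config()

  # recompute both hypergeometric screens from the stored counts with the
  # enumeration oracle
  m_edges <- sum(sc$x_edges)
  n_possible <- sum(sc$n_pairs)
  m_med <- sum(sc$x_mediators)
  n_cand <- sum(sc$n_candidates)
  for (i in seq_len(nrow(sc))) {
    expect_equal(sc$p_sw[i],
                 oracle_hyper_tail(sc$x_edges[i], sc$n_pairs[i],
                                   m_edges, n_possible), tolerance = 1e-9)
    expect_equal(sc$p_ps[i],
                 oracle_hyper_tail(sc$x_mediators[i], sc$n_candidates[i],
                                   m_med, n_cand), tolerance = 1e-9)
  }
  expect_identical(sc$sw_valid, sc$p_sw < cfg$p_cutoff)
  expect_identical(sc$ps_valid, sc$p_ps < cfg$p_cutoff)
  expect_identical(sc$ct_valid, sc$ct > cfg$ct_cutoff)
})

test_that("CT cutoff is a strict inequality at the boundary", {
  d <- planted_design(module_sizes = rep(5, 4), mediator_pool = 4,
                      n_coordinated = 4, seed = 3)
  sim <- make_modular_network(d)
  sc <- score_condition(sim$network, sim$partition)
  # set the cutoff exactly at an observed CT: that pair must NOT be valid
  boundary <- max(sc$ct)
  sc2 <- score_condition(sim$network, sim$partition,
                         screening_config(ct_cutoff = boundary))
  expect_false(any(sc2$ct_valid[sc2$ct == boundary]))
  sc3 <- score_condition(sim$network, sim$partition,
                         screening_config(ct_cutoff = boundary - 1e-9))
  expect_true(any(sc3$ct_valid[sc3$ct == boundary]))
})

test_that("per-condition pipeline: pair universe, symmetry, ordering", {
  d <- planted_design(seed = 11)
  sim <- make_modular_network(d)
  sc <- score_condition(sim$network, sim$partition)

  # pair universe = module pairs with at least one cross edge (recount)
  ed <- sim$network$edges
  mod <- setNames(sim$partition$module, sim$partition$gene)
  ma <- mod[ed$gene_a]; mb <- mod[ed$gene_b]
  cross <- ma != mb & ma != "unassigned" & mb != "unassigned"
  want_pairs <- unique(paste(pmin(ma, mb)[cross], pmax(ma, mb)[cross]))
  expect_setequal(paste(sc$module_x, sc$module_y), want_pairs)

  # canonical pair order and final table ordering
  expect_true(all(sc$module_x < sc$module_y))
  fin <- compute_imcc(sc)
  expect_true(all(diff(fin$imcc) <= 1e-12))
  expect_true(all(!is.na(fin$imcc)))
  expect_equal(fin$imcc, fin$sw_norm + fin$ct_norm, tolerance = 1e-12)

  # final score ranks identically to the weighted integration at rho = 1
  expect_equal(order(-fin$imcc), order(-fin$imcc1))

  # adding an inter-module edge never decreases SW
  extra <- rbind(ed, data.frame(
    gene_a = sim$partition$gene[sim$partition$module == sc$module_x[1]][1],
    gene_b = sim$partition$gene[sim$partition$module == sc$module_y[1]][2],
    weight = 0.5))
  extra <- extra[!duplicated(paste(pmin(extra$gene_a, extra$gene_b),
                                   pmax(extra$gene_a, extra$gene_b))), ]
  net2 <- gene_network(extra, nodes = sim$network$nodes)
  sc2 <- score_condition(net2, sim$partition)
  key <- paste(sc$module_x, sc$module_y)
  key2 <- paste(sc2$module_x, sc2$module_y)
  common <- intersect(key, key2)
  expect_true(all(sc2$sw[match(common, key2)] >=
                    sc$sw[match(common, key)] - 1e-12))
})

test_that("ranking is invariant to affine rescaling of raw SW", {
  d <- planted_design(seed = 23)
  sim <- make_modular_network(d)
  sc <- score_condition(sim$network, sim$partition)
  fin <- compute_imcc(sc)
  expect_gte(nrow(fin), 3)
  # min-max removes scale: rescaling valid SW values affinely leaves
  # sw_norm unchanged
  sw <- sc$sw[sc$sw_valid]
  expect_equal(minmax_normalize(3.7 * sw + 2), minmax_normalize(sw),
               tolerance = 1e-12)
})

test_that("planted coordination strengths are recovered by IMCC", {
  d <- planted_design(seed = 11)  # 15 planted pairs over 20 modules
  sim <- make_modular_network(d)
  sc <- score_condition(sim$network, sim$partition)
  fin <- compute_imcc(sc)
  j <- dplyr::left_join(sim$ground_truth,
                        fin[, c("module_x", "module_y", "imcc")],
                        by = c("module_x", "module_y"))
  j$imcc[is.na(j$imcc)] <- 0
  expect_gte(nrow(j), 10)
  expect_gte(cor(j$strength, j$imcc, method = "spearman"), 0.8)
})
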