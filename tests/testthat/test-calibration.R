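test_that("Jaccard similarity basics and symmetry", {
  expect_equal(jaccard_similarity(letters[1:5], letters[1:5]), 1.0)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0.0)
  expect_true(is.na(jaccard_similarity(character(), character())))
  a <- c("p1", "p2", "p3"); b <- c("p2", "p4")
  expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
  expect_true(jaccard_similarity(a, b) >= 0 && jaccard_similarity(a, b) <= 1)
})

test_that("curve fitting recovers exact relations and reduces to lm", {
  x <- seq(0.5, 10, length.out = 25)
  f <- fit_curve(x, 2 * log(x) + 1, "logarithmic")
  expect_equal(unname(f$coefficients["a"]), 2, tolerance = 1e-10)
  expect_equal(unname(f$coefficients["b"]), 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1.0, tolerance = 1e-12)

  # logarithmic fit is exactly the linear fit on (ln x, y)
  y <- withr::with_seed(2, 1.5 * log(x) + 0.3 + rnorm(25, sd = 0.2))
  f2 <- fit_curve(x, y, "logarithmic")
  ref <- oracle_lsq(log(x), y)
  expect_equal(unname(f2$coefficients["a"]), ref$a, tolerance = 1e-10)
  expect_equal(unname(f2$coefficients["b"]), ref$b, tolerance = 1e-10)
  expect_equal(f2$r_squared, ref$r2, tolerance = 1e-10)

  # constant response has no explained variance
  expect_equal(fit_curve(x, rep(2, 25), "linear")$r_squared, 0)

  # power and exponential fit on their linearized scales
  fp <- fit_curve(x, 3 * x^1.7, "power")
  expect_equal(unname(fp$coefficients["a"]), 1.7, tolerance = 1e-8)
  expect_equal(unname(fp$coefficients["b"]), 3, tolerance = 1e-8)
  fe <- fit_curve(x, 0.5 * exp(0.4 * x), "exponential")
  expect_equal(unname(fe$coefficients["a"]), 0.4, tolerance = 1e-8)
  expect_error(fit_curve(c(-1, 1, 2), c(1, 2, 3), "logarithmic"),
               "positive x")

  td <- tidy(f)
  expect_identical(td$term, c("a", "b"))
  expect_identical(glance(f)$model, "logarithmic")
})

test_that("outlier removal drops exactly the injected gross outlier", {
  x <- seq(1, 20)
  y <- 2 * log(x) + withr::with_seed(5, rnorm(20, sd = 0.05))
  clean <- remove_outliers(x, y, "logarithmic")
  expect_identical(clean$removed, 0L)

  y_bad <- y
  y_bad[7] <- y[7] + 25
  dirty <- remove_outliers(x, y_bad, "logarithmic")
  expect_identical(dirty$removed, 1L)
  expect_false(x[7] %in% dirty$x)

  # refit after removal never has larger residual error
  ss <- function(x, y) sum(resid(lm(y ~ log(x)))^2)
  expect_lte(ss(dirty$x, dirty$y), ss(x, y_bad))

  # refusal when removal would leave fewer than 3 points
  few <- remove_outliers(c(1, 2, 3), c(1, 2, 90), "linear")
  expect_identical(few$removed, 0L)
  expect_identical(length(few$x), 3L)
})

test_that("rho scan recovers the planted weighting and is deterministic", {
  # plant JS proportional to ln of the equally weighted integration
  withr::with_seed(31, {
    n <- 40
    sw_norm <- runif(n)
    ct_norm <- runif(n)
  })
  labels <- sprintf("m%02d", seq_len(2 * 40))
  tab <- tibble::tibble(
    module_x = labels[seq(1, 79, by = 2)],
    module_y = labels[seq(2, 80, by = 2)],
    sw = sw_norm, ps = 0, ct = ct_norm,
    sw_norm = sw_norm, ct_norm = ct_norm,
    sw_valid = TRUE, ps_valid = FALSE, ct_valid = TRUE,
    imcc2 = NA_real_
  )
  v <- 0.5 * sw_norm + 0.5 * ct_norm
  js <- tibble::tibble(module_x = tab$module_x, module_y = tab$module_y,
                       js = 0.2 * log(v) + 0.8)
  scan <- scan_rho(tab, js)
  expect_equal(scan$best_rho, 1)
  expect_identical(nrow(scan$results), 9L)
  expect_true(all(c(1/10, 10) %in% scan$results$rho))
  # the planted relation fits perfectly at rho = 1
  expect_equal(glance(scan)$r.squared, 1, tolerance = 1e-10)
  scan2 <- scan_rho(tab, js)
  expect_identical(tidy(scan), tidy(scan2))

  expect_equal(scan_rho(tab, js, grid = 1)$best_rho, 1)
})

test_that("integration comparison reports all three fits and a winner", {
  withr::with_seed(7, {
    n <- 40
    sw_norm <- runif(n)
    ct_norm <- runif(n)
  })
  labels <- sprintf("m%02d", seq_len(2 * 40))
  v <- 0.5 * sw_norm + 0.5 * ct_norm
  tab <- tibble::tibble(
    module_x = labels[seq(1, 79, by = 2)],
    module_y = labels[seq(2, 80, by = 2)],
    sw = sw_norm + 0.01, ps = 0.01, ct = ct_norm,
    sw_norm = sw_norm, ct_norm = ct_norm,
    sw_valid = TRUE, ps_valid = TRUE, ct_valid = TRUE,
    imcc2 = sw_norm + 0.02
  )
  js <- tibble::tibble(module_x = tab$module_x, module_y = tab$module_y,
                       js = 0.2 * log(v) + 0.8)
  rep <- compare_integrations(tab, js)
  expect_identical(rep$score, c("sw", "imcc1", "imcc2"))
  expect_true(all(rep$available))
  # data were planted to favour the combined score
  expect_identical(attr(rep, "winner"), "imcc1")
  expect_gt(rep$r_squared[rep$score == "imcc1"],
            rep$r_squared[rep$score == "sw"])

  # degenerate CT: the combined score collapses onto SW, identical fits
  tab2 <- tab
  tab2$ct_norm <- tab2$sw_norm
  tab2$sw <- tab2$sw_norm
  js2 <- js
  js2$js <- 0.2 * log(tab2$sw_norm) + 0.8
  rep2 <- compare_integrations(tab2, js2)
  expect_equal(rep2$r_squared[rep2$score == "sw"],
               rep2$r_squared[rep2$score == "imcc1"], tolerance = 1e-9)
})

test_that("inter-module average shortest path equals BFS enumeration", {
  # two singleton modules joined by one edge
  net <- gene_network(edge_df("a", "b", 0.9))
  part <- module_partition(data.frame(gene = c("a", "b"),
                                      module = c("A", "B")))
  expect_equal(as.numeric(imasp(net, part, c("A", "B"))), 1.0)

  # chain a - b - c with modules {a}, {c}
  chain <- gene_network(edge_df(c("a", "b"), c("b", "c"), c(0.5, 0.5)))
  part3 <- module_partition(data.frame(gene = c("a", "b", "c"),
                                       module = c("A", "mid", "C")))
  expect_equal(as.numeric(imasp(chain, part3, c("A", "C"))), 2.0)

  # random fixtures against the Floyd-Warshall oracle
  for (seed in 1:10) {
    rc <- random_condition(seed, n_modules = 3, size = 3, n_bg = 3,
                           p_cross = 0.25)
    d <- oracle_distances(oracle_adjacency(rc$net$edges, rc$net$nodes))
    gx <- rc$part$gene[rc$part$module == "A"]
    gy <- rc$part$gene[rc$part$module == "B"]
    sub <- d[gx, gy, drop = FALSE]
    want <- if (any(is.finite(sub))) mean(sub[is.finite(sub)]) else NA_real_
    expect_equal(as.numeric(imasp(rc$net, rc$part, c("A", "B"))), want,
                 tolerance = 1e-12, label = sprintf("imasp seed %d", seed))
  }

  # adding an edge never increases the distance
  base <- random_condition(17, n_modules = 2, size = 4, n_bg = 2,
                           p_cross = 0.2)
  v0 <- as.numeric(imasp(base$net, base$part, c("A", "B")))
  gx <- base$part$gene[base$part$module == "A"]
  gy <- base$part$gene[base$part$module == "B"]
  aug <- rbind(base$net$edges,
               data.frame(gene_a = gx[1], gene_b = gy[4], weight = 0.5))
  aug <- aug[!duplicated(paste(pmin(aug$gene_a, aug$gene_b),
                               pmax(aug$gene_a, aug$gene_b))), ]
  v1 <- as.numeric(imasp(gene_network(aug, nodes = base$net$nodes),
                         base$part, c("A", "B")))
  expect_lte(v1, v0 + 1e-12)
})

test_that("generated annotations make similarity track planted strength", {
  d <- planted_design(module_sizes = rep(8, 12), mediator_pool = 10,
                      coordination = tibble::tibble(
                        module_x = sprintf("M%02d", seq(1, 11, by = 2)),
                        module_y = sprintf("M%02d", seq(2, 12, by = 2)),
                        strength = seq(0.05, 1, length.out = 6)),
                      seed = 9)
  sim <- make_modular_network(d)
  ann <- make_annotations(sim$partition, d$coordination, seed = 9)
  js <- pair_jaccard(ann, d$coordination[, c("module_x", "module_y")])
  expect_gt(cor(js$js, d$coordination$strength, method = "spearman"), 0.9)
})
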