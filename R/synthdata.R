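# Synthetic co-expression networks with planted inter-module coordination.
#
# The generator emulates the shape of a thresholded weighted co-expression
# network over a few hundred genes: dense high-weight intra-module blocks,
# cross-module edges whose number and weight scale with a planted
# coordination strength, and a pool of background ("unassigned") mediator
# genes wired to both members of coordinated pairs so that indirect
# connectivity (PS, CT) tracks the same planted strength.  Every output is
# a deterministic function of the design's seed.

#' Describe a planted-coordination design
#'
#' @param module_sizes Integer vector of module sizes; if `NULL`,
#'   `n_genes - mediator_pool` genes are split near-evenly over
#'   `n_modules` modules.
#' @param n_modules,n_genes Used only when `module_sizes` is `NULL`
#'   (defaults 20 modules over 374 genes, the scale of a focused disease
#'   panel).
#' @param mediator_pool Number of background genes available as path
#'   mediators (default 30).
#' @param intra_weight Range of intra-module edge weights (default
#'   0.6--0.95: tight co-expression blocks).
#' @param coordination Tibble `module_x`, `module_y`, `strength` in
#'   `[0, 1]`; if `NULL`, `n_coordinated` pairs are drawn at random with
#'   strengths spread evenly on (0, 1].
#' @param n_coordinated Number of planted pairs when `coordination` is
#'   `NULL` (default 15).
#' @param mediator_count Optional integer vector (parallel to
#'   `coordination` rows); defaults to `round(6 * strength)` mediators per
#'   pair.
#' @param cross_frac Fraction of a pair's possible cross edges realized at
#'   strength 1 (default 0.25).
#' @param seed Integer seed; fully determines every generated object.
#' @return A `planted_design` list.
#' @export
planted_design <- function(module_sizes = NULL, n_modules = 20,
                           n_genes = 374, mediator_pool = 30,
                           intra_weight = c(0.6, 0.95),
                           coordination = NULL, n_coordinated = 15,
                           mediator_count = NULL, cross_frac = 0.25,
                           seed = 1) {
  stopifnot(length(intra_weight) == 2, intra_weight[1] > 0,
            intra_weight[2] <= 1, intra_weight[1] <= intra_weight[2],
            cross_frac > 0, cross_frac <= 1)
  if (is.null(module_sizes)) {
    avail <- n_genes - mediator_pool
    if (avail < 2 * n_modules) abort("too few genes for that many modules")
    base <- avail %/% n_modules
    module_sizes <- rep(base, n_modules)
    extra <- avail - base * n_modules
    if (extra > 0) module_sizes[seq_len(extra)] <- base + 1
  }
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 2)) abort("module sizes must be >= 2")
  labels <- sprintf("M%02d", seq_along(module_sizes))
  if (is.null(coordination)) {
    coordination <- withr::with_seed(seed, {
      cmb <- utils::combn(labels, 2)
      k <- min(n_coordinated, ncol(cmb))
      pick <- sample(ncol(cmb), k)
      tibble(module_x = cmb[1, pick], module_y = cmb[2, pick],
             strength = sample(seq(0.05, 1, length.out = k)))
    })
  } else {
    coordination <- as_tibble(as.data.frame(coordination))[, 1:3]
    names(coordination) <- c("module_x", "module_y", "strength")
    cp <- canonical_pair(as.character(coordination$module_x),
                         as.character(coordination$module_y))
    coordination$module_x <- cp$x
    coordination$module_y <- cp$y
    bad <- setdiff(c(coordination$module_x, coordination$module_y), labels)
    if (length(bad) > 0) abort(sprintf("unknown module '%s'", bad[1]))
    if (any(coordination$strength < 0 | coordination$strength > 1)) {
      abort("strengths must lie in [0, 1]")
    }
  }
  if (is.null(mediator_count)) {
    mediator_count <- as.integer(round(6 * coordination$strength))
  }
  stopifnot(length(mediator_count) == nrow(coordination))
  structure(list(module_sizes = setNames(module_sizes, labels),
                 mediator_pool = as.integer(mediator_pool),
                 intra_weight = intra_weight,
                 coordination = coordination,
                 mediator_count = as.integer(mediator_count),
                 cross_frac = cross_frac, seed = as.integer(seed)),
            class = "planted_design")
}

design_partition <- function(design) {
  labels <- names(design$module_sizes)
  genes_assigned <- sprintf("g%04d", seq_len(sum(design$module_sizes)))
  part <- tibble(gene = genes_assigned,
                 module = rep(labels, design$module_sizes))
  pool <- if (design$mediator_pool > 0) {
    tibble(gene = sprintf("b%04d", seq_len(design$mediator_pool)),
           module = UNASSIGNED_LABEL)
  } else tibble(gene = character(), module = character())
  module_partition(dplyr::bind_rows(part, pool))
}

#' Generate a network with planted inter-module coordination
#'
#' Builds dense intra-module blocks, cross-module edges whose count and
#' weight scale with each pair's planted strength, and background mediator
#' genes wired to both modules of coordinated pairs.  Pairs with strength
#' zero receive no cross edges.
#'
#' @param design A [planted_design()].
#' @return List with `network` ([gene_network()]), `partition`
#'   ([module_partition()]; mediator genes carry the reserved background
#'   label) and `ground_truth` (tibble `module_x`, `module_y`, `strength`,
#'   `n_mediators`).
#' @examples
#' d <- planted_design(module_sizes = c(5, 5, 5), mediator_pool = 4,
#'                     coordination = data.frame(module_x = "M01",
#'                       module_y = "M02", strength = 1), seed = 7)
#' sim <- make_modular_network(d)
#' sim$ground_truth
#' @export
make_modular_network <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  part <- design_partition(design)
  withr::with_seed(design$seed, {
    genes_of <- split(part$gene, part$module)
    pool <- genes_of[[UNASSIGNED_LABEL]] %||% character()
    edges <- list()
    for (m in names(design$module_sizes)) {
      gs <- genes_of[[m]]
      cmb <- utils::combn(gs, 2)
      edges[[length(edges) + 1]] <- tibble(
        gene_a = cmb[1, ], gene_b = cmb[2, ],
        weight = runif(ncol(cmb), design$intra_weight[1],
                       design$intra_weight[2])
      )
    }
    co <- design$coordination
    for (i in seq_len(nrow(co))) {
      s <- co$strength[i]
      if (s <= 0) next
      gx <- genes_of[[co$module_x[i]]]
      gy <- genes_of[[co$module_y[i]]]
      all_cross <- expand.grid(gene_a = gx, gene_b = gy,
                               stringsAsFactors = FALSE)
      n_cross <- max(1L, round(s * design$cross_frac * nrow(all_cross)))
      pick <- sample(nrow(all_cross), n_cross)
      edges[[length(edges) + 1]] <- tibble(
        gene_a = all_cross$gene_a[pick],
        gene_b = all_cross$gene_b[pick],
        weight = pmin(1, runif(n_cross, 0.05 + 0.4 * s, 0.15 + 0.6 * s))
      )
      k <- design$mediator_count[i]
      if (k > 0 && length(pool) > 0) {
        meds <- sample(pool, min(k, length(pool)))
        for (m in meds) {
          ox <- sample(gx, min(4, length(gx)))
          oy <- sample(gy, min(4, length(gy)))
          edges[[length(edges) + 1]] <- tibble(
            gene_a = m, gene_b = c(ox, oy),
            weight = pmin(1, runif(length(ox) + length(oy),
                                   0.25 + 0.3 * s, 0.45 + 0.4 * s))
          )
        }
      }
    }
    # background genes also co-express weakly with single modules, so the
    # candidate-mediator universe is wider than the realized mediators
    if (length(pool) > 0) {
      for (b in pool) {
        m <- sample(names(design$module_sizes), 1)
        targets <- sample(genes_of[[m]], min(2, length(genes_of[[m]])))
        edges[[length(edges) + 1]] <- tibble(
          gene_a = b, gene_b = targets,
          weight = runif(length(targets), 0.1, 0.3)
        )
      }
    }
    ed <- dplyr::bind_rows(edges)
    # a mediator serving several pairs can duplicate an edge; keep the first
    cp <- canonical_pair(ed$gene_a, ed$gene_b)
    ed$gene_a <- cp$x
    ed$gene_b <- cp$y
    ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b, sep = "\r")), ]
    net <- gene_network(ed, nodes = part$gene, weight_floor = 0.02)
    gt <- co
    gt$n_mediators <- design$mediator_count
    list(network = net, partition = part, ground_truth = gt)
  })
}

#' Generate block-correlated expression data for a design
#'
#' Each module gets a latent sample profile; its genes are that profile
#' plus Gaussian noise, so the soft-threshold adjacency recovers the
#' module blocks.  Background genes are independent noise.
#'
#' @param design A [planted_design()].
#' @param n_samples Number of samples (default 50).
#' @param noise_sd Gene-level noise standard deviation around the module
#'   profile (default 0.5; 0 gives within-module `|r| = 1`).
#' @param seed Seed (defaults to the design seed).
#' @return Numeric matrix genes x samples, gene ids as rownames.
#' @export
make_expression <- function(design, n_samples = 50, noise_sd = 0.5,
                            seed = design$seed) {
  stopifnot(inherits(design, "planted_design"), n_samples >= 3,
            noise_sd >= 0)
  part <- design_partition(design)
  withr::with_seed(seed, {
    mods <- module_labels(part)
    latent <- matrix(rnorm(length(mods) * n_samples), length(mods),
                     n_samples, dimnames = list(mods, NULL))
    expr <- matrix(0, nrow(part), n_samples,
                   dimnames = list(part$gene, sprintf("s%03d",
                                                      seq_len(n_samples))))
    for (i in seq_len(nrow(part))) {
      base <- if (part$module[i] == UNASSIGNED_LABEL) {
        rnorm(n_samples)
      } else {
        latent[part$module[i], ]
      }
      expr[i, ] <- base + noise_sd * rnorm(n_samples)
    }
    expr
  })
}

#' Generate module annotations whose sharing tracks planted coordination
#'
#' Each module draws `n_per_module` category labels from a common pool;
#' then, walking the planted pairs from strongest to weakest, the second
#' module's set is edited so the pair shares about
#' `round(strength * n_per_module)` categories.  Annotation similarity
#' (Jaccard) therefore increases with planted strength.
#'
#' @param part A [module_partition()].
#' @param coordination Tibble `module_x`, `module_y`, `strength`.
#' @param base_categories Size of the category pool (default 60).
#' @param n_per_module Categories per module (default 8).
#' @param seed Integer seed.
#' @return An [annotation_table()].
#' @export
make_annotations <- function(part, coordination, base_categories = 60,
                             n_per_module = 8, seed = 1) {
  part <- as_module_partition(part)
  mods <- module_labels(part)
  pool <- sprintf("cat%03d", seq_len(base_categories))
  co <- as_tibble(as.data.frame(coordination))[, 1:3]
  names(co) <- c("module_x", "module_y", "strength")
  withr::with_seed(seed, {
    sets <- lapply(setNames(mods, mods),
                   function(m) sample(pool, n_per_module))
    co <- dplyr::arrange(co, dplyr::desc(.data$strength))
    for (i in seq_len(nrow(co))) {
      x <- co$module_x[i]; y <- co$module_y[i]
      target <- round(co$strength[i] * n_per_module)
      shared <- intersect(sets[[x]], sets[[y]])
      need <- target - length(shared)
      if (need > 0) {
        give <- setdiff(sets[[x]], sets[[y]])[seq_len(min(need,
          length(setdiff(sets[[x]], sets[[y]]))))]
        drop <- setdiff(sets[[y]], sets[[x]])
        drop <- drop[seq_len(min(length(give), length(drop)))]
        sets[[y]] <- union(setdiff(sets[[y]], drop), give)
      }
    }
    annotation_table(tibble(
      module = rep(names(sets), lengths(sets)),
      category = unlist(sets, use.names = FALSE)
    ))
  })
}

#' Rewire a synthetic condition toward aggregation or dispersion
#'
#' `aggregate` mode adds cross-module edges so the module map densifies
#' toward a clique-like structure; `disperse` mode removes a fraction of
#' cross edges, strengthens the survivors, and scatters the genes of a
#' designated module pair over several landing modules.  Intensity 0 is
#' the identity.
#'
#' @param net A [gene_network()].
#' @param part A [module_partition()].
#' @param mode `"aggregate"` or `"disperse"`.
#' @param intensity Rewiring intensity in `[0, 1]`.
#' @param seed Integer seed.
#' @param pmp For `disperse`: the module pair to scatter (defaults to the
#'   pair with the most cross edges).
#' @param n_landing For `disperse`: number of landing modules (default
#'   scales with intensity up to the number of other modules).
#' @return List with `network`, `partition` and `ground_truth` (for
#'   `disperse`: the landing table `gene`, `module`, plus `n_landing`).
#' @export
rewire_condition <- function(net, part, mode = c("aggregate", "disperse"),
                             intensity = 0.5, seed = 1, pmp = NULL,
                             n_landing = NULL) {
  mode <- match.arg(mode)
  stopifnot(intensity >= 0, intensity <= 1)
  net <- as_gene_network(net)
  part <- as_module_partition(part)
  if (intensity == 0) {
    return(list(network = net, partition = part, ground_truth = NULL))
  }
  mod <- setNames(part$module, part$gene)
  genes_of <- split(part$gene, part$module)
  mods <- module_labels(part)
  withr::with_seed(seed, {
    if (mode == "aggregate") {
      cmb <- utils::combn(mods, 2)
      new_edges <- list()
      existing <- paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")
      for (j in seq_len(ncol(cmb))) {
        gx <- genes_of[[cmb[1, j]]]
        gy <- genes_of[[cmb[2, j]]]
        all_cross <- expand.grid(a = gx, b = gy, stringsAsFactors = FALSE)
        cp <- canonical_pair(all_cross$a, all_cross$b)
        key <- paste(cp$x, cp$y, sep = "\r")
        free <- which(!(key %in% existing))
        n_add <- min(length(free),
                     max(1L, round(intensity * 0.15 * nrow(all_cross))))
        if (n_add == 0) next
        pick <- free[sample(length(free), n_add)]
        new_edges[[length(new_edges) + 1]] <- tibble(
          gene_a = cp$x[pick], gene_b = cp$y[pick],
          weight = runif(n_add, 0.15, 0.15 + 0.5 * intensity)
        )
      }
      ed <- dplyr::bind_rows(c(list(net$edges), new_edges))
      list(network = gene_network(ed, nodes = net$nodes,
                                  weight_floor = net$weight_floor),
           partition = part,
           ground_truth = list(mode = "aggregate", intensity = intensity))
    } else {
      ed <- net$edges
      ma <- mod[ed$gene_a]
      mb <- mod[ed$gene_b]
      cross <- which(!is.na(ma) & !is.na(mb) & ma != mb &
                       ma != UNASSIGNED_LABEL & mb != UNASSIGNED_LABEL)
      drop <- if (length(cross) > 0) {
        cross[sample(length(cross),
                     round(intensity * 0.6 * length(cross)))]
      } else integer()
      if (length(drop) > 0) ed <- ed[-drop, ]
      # widen surviving paths
      ed$weight <- pmin(1, ed$weight * (1 + 0.5 * intensity))
      if (is.null(pmp)) {
        cross_tab <- tibble(x = pmin(ma, mb)[cross], y = pmax(ma, mb)[cross]) |>
          dplyr::count(.data$x, .data$y, sort = TRUE)
        if (nrow(cross_tab) == 0) abort("no cross edges; cannot pick a pair")
        pmp <- c(cross_tab$x[1], cross_tab$y[1])
      }
      pmp_genes <- part$gene[part$module %in% pmp]
      others <- setdiff(mods, pmp)
      if (!is.null(n_landing) && n_landing > length(pmp_genes)) {
        abort("more landing modules than pair genes")
      }
      if (is.null(n_landing)) {
        n_landing <- max(2L, min(length(others), length(pmp_genes),
                                 round(2 + intensity * (length(others) - 2))))
      }
      n_landing <- as.integer(n_landing)
      if (n_landing > length(others)) {
        abort("not enough landing modules")
      }
      landing <- sort(sample(others, n_landing))
      # every landing module receives at least one gene
      assign_to <- sample(c(landing,
                            sample(landing, length(pmp_genes) - n_landing,
                                   replace = TRUE)))
      mod2 <- mod
      mod2[pmp_genes] <- assign_to
      part2 <- module_partition(tibble(gene = names(mod2),
                                       module = unname(mod2)))
      gt <- list(mode = "disperse", intensity = intensity, pmp = pmp,
                 n_landing = n_landing,
                 landing = tibble(gene = pmp_genes, module = assign_to))
      list(network = gene_network(ed, nodes = net$nodes,
                                  weight_floor = net$weight_floor),
           partition = part2, ground_truth = gt)
    }
  })
}

#' Write a design's ground truth beside generated data
#'
#' @param ground_truth Tibble as returned in `make_modular_network()$ground_truth`.
#' @param path Output TSV.
#' @export
write_ground_truth <- function(ground_truth, path) {
  readr::write_tsv(as_tibble(ground_truth), path, progress = FALSE)
  invisible(ground_truth)
}
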