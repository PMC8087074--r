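# Inter-module coordination parameters (SW, PS, CT), their screening, and
# integration into the IMCC score.
#
# Direct inter-module connectivity is the sum of cross-module edge weights
# (SW).  Indirect connectivity is carried by genes outside a module pair:
# the path strength (PS) sums, over outset-mediator-end paths, the product
# of the mediator's weighted probabilities of choosing each endpoint; the
# consistency score (CT) contrasts each external gene's observed links into
# the two modules with its null expectation, scaled by the gene's weighted
# degree.  SW and PS are screened by hypergeometric upper tails, CT by a
# fixed cutoff, and the surviving normalized SW and CT are summed into the
# final IMCC.

#' Screening and integration settings
#'
#' @param p_cutoff Hypergeometric p-value below which SW (or PS) counts as
#'   a valid measurement (default 0.05).
#' @param ct_cutoff Consistency-score cutoff; CT is valid when strictly
#'   greater (default 10).
#' @param rho Weighting ratio alpha/beta between normalized SW and CT in
#'   the weighted integration (default 1, the calibrated optimum).
#' @return A list with class `screening_config`.
#' @export
screening_config <- function(p_cutoff = 0.05, ct_cutoff = 10, rho = 1) {
  stopifnot(p_cutoff > 0, p_cutoff < 1, ct_cutoff >= 0, rho > 0)
  structure(list(p_cutoff = p_cutoff, ct_cutoff = ct_cutoff, rho = rho),
            class = "screening_config")
}

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `x` marked items when `n` items are
#' drawn without replacement from `N` items of which `M` are marked:
#' `sum_{k = x..n} C(M,k) C(N-M, n-k) / C(N,n)`, evaluated in log space by
#' `stats::phyper` and clamped to the support.
#'
#' @param x Observed count (0 <= x <= n).
#' @param n Number drawn.
#' @param M Marked items in the population.
#' @param N Population size.
#' @return Upper-tail probability; 1 when `x = 0`.
#' @examples
#' hypergeom_upper_tail(2, 2, 2, 4)  # 1/6
#' @export
hypergeom_upper_tail <- function(x, n, M, N) {
  stopifnot(length(x) == length(n) | length(n) == 1)
  if (any(x < 0 | n < 0 | M < 0 | N < 0)) abort("counts must be non-negative")
  if (any(x > n)) abort("x cannot exceed n")
  if (any(n > N) || any(M > N)) abort("draw / marked count exceeds population")
  p <- stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

canonical_pair <- function(a, b) {
  list(x = pmin(a, b), y = pmax(a, b))
}

# Assemble everything the pair parameters need: per-gene module assignment
# over the network's node set (genes absent from the partition are
# background), gene x module link-count and link-weight matrices, degrees.
condition_context <- function(net, part) {
  net <- as_gene_network(net)
  part <- as_module_partition(part)
  stray <- setdiff(part$gene, net$nodes)
  if (length(stray) > 0) {
    warn(sprintf("%d partition gene(s) absent from the network (isolated)",
                 length(stray)))
  }
  nodes <- sort(unique(c(net$nodes, part$gene)))
  mod <- setNames(rep(UNASSIGNED_LABEL, length(nodes)), nodes)
  mod[part$gene] <- part$module
  mods <- sort(unique(mod))
  ed <- net$edges
  long <- tibble(
    gene = c(ed$gene_a, ed$gene_b),
    other = c(ed$gene_b, ed$gene_a),
    weight = rep(ed$weight, 2)
  )
  long$other_mod <- mod[long$other]
  gi <- match(long$gene, nodes)
  mi <- match(long$other_mod, mods)
  cm <- matrix(0, length(nodes), length(mods),
               dimnames = list(nodes, mods))
  aw <- cm
  idx <- cbind(gi, mi)
  # accumulate counts and weights per (gene, module of neighbor)
  for (k in seq_len(nrow(idx))) {
    cm[idx[k, 1], idx[k, 2]] <- cm[idx[k, 1], idx[k, 2]] + 1
    aw[idx[k, 1], idx[k, 2]] <- aw[idx[k, 1], idx[k, 2]] + long$weight[k]
  }
  list(net = net, part = part, nodes = nodes, module_of = mod,
       modules = setdiff(mods, UNASSIGNED_LABEL),
       cm = cm, aw = aw,
       degree = rowSums(cm), strength = rowSums(aw),
       n_genes = length(nodes))
}

check_pair <- function(ctx, pair) {
  pair <- as.character(pair)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must be two distinct module labels")
  }
  missing <- setdiff(pair, ctx$modules)
  if (length(missing) > 0) {
    abort(sprintf("unknown module label: '%s'", missing[1]))
  }
  sort(pair)
}

#' Sum of cross-module edge weights (direct connectivity)
#'
#' Adds up the adjacency weights of every edge with one endpoint in each
#' of the two modules.
#'
#' @param net A [gene_network()] (or edge-list data frame).
#' @param part A [module_partition()].
#' @param pair Character vector of two distinct module labels.
#' @return Non-negative scalar; 0 when the modules share no edge.
#' @export
sum_of_weights <- function(net, part, pair) {
  ctx <- condition_context(net, part)
  pair <- check_pair(ctx, pair)
  ed <- ctx$net$edges
  ma <- ctx$module_of[ed$gene_a]
  mb <- ctx$module_of[ed$gene_b]
  sel <- (ma == pair[1] & mb == pair[2]) | (ma == pair[2] & mb == pair[1])
  sum(ed$weight[sel])
}

#' Path strength of a module pair (indirect connectivity via paths)
#'
#' Sums, over all three-node paths outset--mediator--end with the outset in
#' one module, the end in the other, and the mediator outside both, the
#' product of the mediator's weighted probabilities of choosing the outset
#' and the end (each probability is the edge weight over the mediator's
#' total incident weight).
#'
#' @inheritParams sum_of_weights
#' @return Non-negative scalar; 0 when no mediator exists.
#' @export
path_strength <- function(net, part, pair) {
  ctx <- condition_context(net, part)
  pair <- check_pair(ctx, pair)
  ps_from_context(ctx, pair[1], pair[2])$ps
}

ps_from_context <- function(ctx, x, y) {
  outside <- !(ctx$module_of %in% c(x, y))
  ax <- ctx$aw[, x]
  ay <- ctx$aw[, y]
  med <- outside & ctx$cm[, x] > 0 & ctx$cm[, y] > 0
  cand <- outside & (ctx$cm[, x] > 0 | ctx$cm[, y] > 0)
  w <- ctx$strength
  ps <- sum((ax[med] * ay[med]) / w[med]^2)
  list(ps = ps, n_mediators = sum(med), n_candidates = sum(cand))
}

#' Consistency score of a module pair (shared-partner connectivity)
#'
#' For every gene outside both modules, contrasts its observed link counts
#' into each module with the null expectation proportional to its degree
#' (module size over network size times degree), takes the smaller of the
#' two centered counts, and scales by the product of the two link counts
#' over the gene's degree and by the gene's weighted degree; the score is
#' the sum over genes.  Genes linked to only one (or neither) module
#' contribute zero through the multiplicative link-count factor.
#'
#' @inheritParams sum_of_weights
#' @return Real scalar (can be negative when shared partners are weaker
#'   than expected).
#' @export
consistency_score <- function(net, part, pair) {
  ctx <- condition_context(net, part)
  pair <- check_pair(ctx, pair)
  ct_from_context(ctx, pair[1], pair[2])
}

ct_from_context <- function(ctx, x, y) {
  sizes <- table(factor(ctx$module_of, levels = unique(ctx$module_of)))
  s_x <- sum(ctx$module_of == x)
  s_y <- sum(ctx$module_of == y)
  cc <- ctx$n_genes
  keep <- !(ctx$module_of %in% c(x, y)) & ctx$degree > 0
  if (!any(keep)) return(0)
  cmx <- ctx$cm[keep, x]
  cmy <- ctx$cm[keep, y]
  cl <- ctx$degree[keep]
  w <- ctx$strength[keep]
  centered <- pmin(cmx - (s_x / cc) * cl, cmy - (s_y / cc) * cl)
  sum(centered * (cmx * cmy / cl) * w)
}

#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros so the
#' degenerate case stays defined.
#'
#' @param values Numeric vector (length >= 1; NAs propagate).
#' @return Vector of the same length in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) abort("nothing to normalize")
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(rng[1])) return(rep(NA_real_, length(values)))
  if (rng[1] == rng[2]) return(ifelse(is.na(values), NA_real_, 0))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Weighted integration of normalized SW and CT
#'
#' With weighting ratio `rho = alpha / beta` and `alpha + beta = 1`,
#' returns `alpha * sw_norm + beta * ct_norm`.
#'
#' @param sw_norm,ct_norm Normalized direct / shared-partner connectivity
#'   in `[0, 1]`.
#' @param rho Positive weighting ratio.
#' @return The weighted sum.
#' @examples
#' integrate_imcc1(0.6, 0.2, rho = 1)  # 0.4
#' @export
integrate_imcc1 <- function(sw_norm, ct_norm, rho = 1) {
  stopifnot(rho > 0)
  alpha <- rho / (1 + rho)
  beta <- 1 / (1 + rho)
  alpha * sw_norm + beta * ct_norm
}

#' Unweighted integration of SW and PS
#'
#' Both parameters live on the edge-weight scale, so they are summed
#' without normalization.
#'
#' @param sw,ps Direct connectivity and path strength.
#' @return `sw + ps`.
#' @export
integrate_imcc2 <- function(sw, ps) sw + ps

#' Score every module pair of one condition
#'
#' End-to-end pipeline for a single condition: computes SW, PS and CT for
#' every module pair joined by at least one edge, screens SW and PS with
#' hypergeometric upper tails (edge-based and node-based parameterizations)
#' and CT with the fixed cutoff, min-max-normalizes the valid SW and CT
#' values, and integrates them into the weighted score (`imcc1`), the
#' same-dimension score (`imcc2 = sw + ps`, where both screens pass) and
#' the final score (`imcc = sw_norm + ct_norm`, where both screens pass).
#'
#' The SW screen asks whether a pair's observed cross-edge count `x` is
#' enriched among its `|M_x||M_y|` possible cross pairs relative to the
#' condition-wide totals (all observed inter-module edges out of all
#' possible cross-module gene pairs over the scored universe).  The PS
#' screen does the same with mediator genes: observed mediators out of the
#' external genes adjacent to at least one of the two modules, against the
#' condition-wide mediator totals.
#'
#' @inheritParams sum_of_weights
#' @param config A [screening_config()].
#' @return A tibble of class `imcc_scores`, one row per scored pair, with
#'   columns `module_x`, `module_y`, `sw`, `p_sw`, `ps`, `p_ps`, `ct`,
#'   `sw_norm`, `ct_norm`, `imcc1`, `imcc2`, `imcc`, `sw_valid`,
#'   `ps_valid`, `ct_valid` (plus the screening counts), sorted by
#'   descending `imcc` with NA-score rows last.
#' @export
score_condition <- function(net, part, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  ctx <- condition_context(net, part)
  ed <- ctx$net$edges
  ma <- unname(ctx$module_of[ed$gene_a])
  mb <- unname(ctx$module_of[ed$gene_b])
  cross <- ma != mb & ma != UNASSIGNED_LABEL & mb != UNASSIGNED_LABEL
  if (!any(cross)) {
    res <- empty_scores()
    attr(res, "config") <- config
    return(res)
  }
  cp <- canonical_pair(ma[cross], mb[cross])
  tab <- tibble(module_x = cp$x, module_y = cp$y,
                weight = ed$weight[cross]) |>
    dplyr::group_by(.data$module_x, .data$module_y) |>
    dplyr::summarise(sw = sum(.data$weight), x_edges = dplyr::n(),
                     .groups = "drop")
  sizes <- module_sizes(ctx$part)
  # genes of a module that are actually in this network's universe
  in_net <- table(factor(ctx$module_of, levels = names(sizes)))
  tab$n_pairs <- as.integer(in_net[tab$module_x] * in_net[tab$module_y])
  ps_parts <- purrr::map2(tab$module_x, tab$module_y,
                          function(x, y) ps_from_context(ctx, x, y))
  tab$ps <- purrr::map_dbl(ps_parts, "ps")
  tab$x_mediators <- purrr::map_dbl(ps_parts, "n_mediators")
  tab$n_candidates <- purrr::map_dbl(ps_parts, "n_candidates")
  tab$ct <- purrr::map2_dbl(tab$module_x, tab$module_y,
                            function(x, y) ct_from_context(ctx, x, y))
  # condition-wide totals over the scored universe
  m_edges <- sum(tab$x_edges)
  n_possible <- sum(tab$n_pairs)
  m_med <- sum(tab$x_mediators)
  n_cand <- sum(tab$n_candidates)
  tab$p_sw <- hypergeom_upper_tail(tab$x_edges, tab$n_pairs,
                                   m_edges, n_possible)
  tab$p_ps <- hypergeom_upper_tail(tab$x_mediators, tab$n_candidates,
                                   m_med, n_cand)
  tab$sw_valid <- tab$p_sw < config$p_cutoff
  tab$ps_valid <- tab$p_ps < config$p_cutoff
  tab$ct_valid <- tab$ct > config$ct_cutoff
  # normalization over the screened-valid values of each parameter
  tab$sw_norm <- NA_real_
  tab$ct_norm <- NA_real_
  if (any(tab$sw_valid)) {
    tab$sw_norm[tab$sw_valid] <- minmax_normalize(tab$sw[tab$sw_valid])
  }
  if (any(tab$ct_valid)) {
    tab$ct_norm[tab$ct_valid] <- minmax_normalize(tab$ct[tab$ct_valid])
  }
  both <- tab$sw_valid & tab$ct_valid
  tab$imcc1 <- ifelse(both,
                      integrate_imcc1(tab$sw_norm, tab$ct_norm, config$rho),
                      NA_real_)
  tab$imcc2 <- ifelse(tab$sw_valid & tab$ps_valid,
                      integrate_imcc2(tab$sw, tab$ps), NA_real_)
  tab$imcc <- ifelse(both, tab$sw_norm + tab$ct_norm, NA_real_)
  tab <- tab |>
    dplyr::select("module_x", "module_y", "sw", "p_sw", "ps", "p_ps", "ct",
                  "sw_norm", "ct_norm", "imcc1", "imcc2", "imcc",
                  "sw_valid", "ps_valid", "ct_valid",
                  "x_edges", "n_pairs", "x_mediators", "n_candidates") |>
    dplyr::arrange(dplyr::desc(!is.na(.data$imcc)), dplyr::desc(.data$imcc),
                   dplyr::desc(.data$sw), .data$module_x, .data$module_y)
  class(tab) <- c("imcc_scores", class(tab))
  attr(tab, "config") <- config
  tab
}

empty_scores <- function() {
  tab <- tibble(
    module_x = character(), module_y = character(), sw = numeric(),
    p_sw = numeric(), ps = numeric(), p_ps = numeric(), ct = numeric(),
    sw_norm = numeric(), ct_norm = numeric(), imcc1 = numeric(),
    imcc2 = numeric(), imcc = numeric(), sw_valid = logical(),
    ps_valid = logical(), ct_valid = logical(), x_edges = integer(),
    n_pairs = integer(), x_mediators = numeric(), n_candidates = numeric()
  )
  class(tab) <- c("imcc_scores", class(tab))
  tab
}

#' Final IMCC table of a condition
#'
#' Keeps the pairs whose SW and CT screens both passed, i.e. the pairs
#' with a final score, sorted by descending IMCC (ties broken by raw SW,
#' then by pair label).
#'
#' @param scores An `imcc_scores` table from [score_condition()].
#' @return Tibble with `module_x`, `module_y`, `imcc` and the underlying
#'   parameters.
#' @export
compute_imcc <- function(scores) {
  scores |>
    dplyr::filter(!is.na(.data$imcc)) |>
    dplyr::arrange(dplyr::desc(.data$imcc), dplyr::desc(.data$sw),
                   .data$module_x, .data$module_y) |>
    as_tibble()
}

#' Write a scored pair table as TSV
#'
#' Stable column order: pair labels, raw parameters with p-values,
#' normalized values, integrated scores, validity flags.
#'
#' @param scores An `imcc_scores` table.
#' @param path Output file.
#' @export
write_scores <- function(scores, path) {
  out <- scores |>
    dplyr::select("module_x", "module_y", "sw", "p_sw", "ps", "p_ps", "ct",
                  "sw_norm", "ct_norm", "imcc1", "imcc2", "imcc",
                  "sw_valid", "ps_valid", "ct_valid") |>
    as_tibble()
  readr::write_tsv(out, path, progress = FALSE)
  invisible(scores)
}

#' @export
glance.imcc_scores <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    frac_sw_valid = if (nrow(x)) mean(x$sw_valid) else NA_real_,
    frac_ps_valid = if (nrow(x)) mean(x$ps_valid) else NA_real_,
    frac_ct_valid = if (nrow(x)) mean(x$ct_valid) else NA_real_,
    n_final = sum(!is.na(x$imcc))
  )
}
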