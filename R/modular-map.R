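# Module-level map and global rewiring statistics: topology summaries,
# score-distribution shifts, principal component projection, architecture
# distance.

#' Build the module-level map from scored pairs
#'
#' One node per module of the partition (isolated modules allowed), one
#' edge per pair with a final IMCC score greater than zero.
#'
#' @param scores An `imcc_scores` table (or any data frame with
#'   `module_x`, `module_y`, `imcc`).
#' @param part Optional [module_partition()] supplying the node set;
#'   defaults to the modules appearing in `scores`.
#' @return A [modular_map()].
#' @export
build_map <- function(scores, part = NULL) {
  ed <- as_tibble(scores)[, c("module_x", "module_y", "imcc")]
  ed <- dplyr::filter(ed, !is.na(.data$imcc), .data$imcc > 0)
  modules <- if (is.null(part)) NULL else module_labels(part)
  modular_map(ed, modules = modules)
}

freeman_centralization <- function(deg) {
  n <- length(deg)
  if (n < 3) return(NA_real_)
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Topological summary of a modular map
#'
#' Eight whole-map statistics: mean unweighted degree; density
#' `2E / (n(n-1))`; characteristic path length (mean unweighted shortest
#' path over connected node pairs) and diameter (the maximum); mean
#' normalized node betweenness; mean local clustering coefficient (genes
#' with fewer than two neighbours count zero); Freeman degree
#' centralization `sum(k_max - k_i) / ((n-1)(n-2))`; and mean edge IMCC.
#' Centralization is `NA` with a message for maps of fewer than 3 modules.
#'
#' @param map A [modular_map()].
#' @param centralization One of `"degree"` (default) or `"betweenness"`.
#' @return One-row tibble with columns `avg_degree`, `density`,
#'   `characteristic_path_length`, `diameter`, `avg_betweenness`,
#'   `cluster_coefficient`, `centrality`, `avg_weight`.
#' @export
topo_summary <- function(map, centralization = c("degree", "betweenness")) {
  centralization <- match.arg(centralization)
  if (length(map$modules) == 0) abort("empty modular map")
  g <- as_igraph(map)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  d <- igraph::distances(g, weights = NA)
  finite <- is.finite(d) & d > 0
  cpl <- if (any(finite)) mean(d[finite]) else NA_real_
  diam <- if (any(finite)) max(d[finite]) else NA_real_
  btw <- if (n >= 3) {
    igraph::betweenness(g, weights = NA, normalized = TRUE)
  } else rep(0, n)
  cc_local <- igraph::transitivity(g, type = "localundirected", weights = NA)
  cc_local[is.nan(cc_local)] <- 0
  centr <- if (n < 3) {
    inform("centralization undefined for maps with fewer than 3 modules")
    NA_real_
  } else if (centralization == "degree") {
    freeman_centralization(deg)
  } else {
    # betweenness centralization, normalized by the star's maximum
    b <- btw
    sum(max(b) - b) / (n - 1)
  }
  tibble(
    avg_degree = mean(deg),
    density = if (n >= 2) 2 * igraph::ecount(g) / (n * (n - 1)) else NA_real_,
    characteristic_path_length = cpl,
    diameter = diam,
    avg_betweenness = mean(btw),
    cluster_coefficient = mean(cc_local),
    centrality = centr,
    avg_weight = if (nrow(map$edges)) mean(map$edges$imcc) else NA_real_
  )
}

#' Signed percent change
#'
#' `100 * (after - before) / before`, reported to one decimal place.
#'
#' @param before,after Numeric scalars or vectors (`before != 0`).
#' @return Signed percentage, rounded to one decimal.
#' @examples
#' percent_change(0.271, 0.858)  # +216.6
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) abort("percent change undefined for before = 0")
  round(100 * (after - before) / before, 1)
}

#' Quartile bin edges on the -log2 score scale
#'
#' Convenience for [bin_distribution()]: the quartiles of `-log2(values)`
#' of a reference condition.
#'
#' @param imcc_values Positive scores of the reference condition.
#' @return Three increasing edges.
#' @export
quartile_edges <- function(imcc_values) {
  if (any(imcc_values <= 0)) abort("scores must be positive for -log2")
  unname(stats::quantile(-log2(imcc_values), probs = c(0.25, 0.5, 0.75)))
}

#' Bin IMCC scores into four intervals on the -log2 scale
#'
#' Scores are transformed to `-log2(IMCC)` and counted into the
#' right-closed intervals `(-Inf, e1]`, `(e1, e2]`, `(e2, e3]`,
#' `(e3, Inf)`; a value sitting exactly on an edge falls into the lower
#' bin.  Edges default to the quartiles of the transformed values
#' themselves; pass a reference condition's [quartile_edges()] (or
#' explicit published edges) to compare conditions on a common grid.
#'
#' @param imcc_values Positive scores.
#' @param edges Three increasing bin edges on the `-log2` scale.
#' @return An `imcc_profile`: tibble with `bin` (factor), `lower`,
#'   `upper`, `count`, `relative`; the edges are kept as an attribute.
#' @export
bin_distribution <- function(imcc_values, edges = NULL) {
  if (length(imcc_values) == 0) abort("no scores to bin")
  if (any(imcc_values <= 0)) abort("scores must be positive for -log2")
  v <- -log2(imcc_values)
  edges <- edges %||% quartile_edges(imcc_values)
  if (length(edges) != 3 || is.unsorted(edges, strictly = FALSE)) {
    abort("`edges` must be three non-decreasing reals")
  }
  breaks <- c(-Inf, edges, Inf)
  # explicit comparison instead of cut(): duplicate edges (degenerate
  # quartiles) then simply leave middle bins empty
  idx <- 1L + (v > edges[1]) + (v > edges[2]) + (v > edges[3])
  counts <- vapply(1:4, function(b) sum(idx == b), integer(1))
  labels <- make.unique(sprintf("(%s, %s]", format(breaks[1:4], digits = 4),
                                format(breaks[2:5], digits = 4)))
  out <- tibble(
    bin = factor(labels, levels = labels),
    lower = breaks[1:4],
    upper = breaks[2:5],
    count = counts,
    relative = counts / length(v)
  )
  class(out) <- c("imcc_profile", class(out))
  attr(out, "edges") <- edges
  out
}

#' Chi-square test for rewiring between two score distributions
#'
#' Compares the binned score counts of two conditions with a 2 x 4
#' contingency chi-square test (no continuity correction).  Bins whose
#' expected count falls below 1 are merged with their neighbour first
#' (with a message).
#'
#' @param profile_a,profile_b `imcc_profile` objects on the same edges.
#' @return Tibble with `statistic`, `df`, `p_value`, `bins_used`.
#' @export
rewiring_test <- function(profile_a, profile_b) {
  ea <- attr(profile_a, "edges")
  eb <- attr(profile_b, "edges")
  if (!is.null(ea) && !is.null(eb) && !isTRUE(all.equal(ea, eb))) {
    abort("profiles binned on different edges")
  }
  m <- rbind(profile_a$count, profile_b$count)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  # merge bins whose expected count under independence is < 1
  repeat {
    if (ncol(m) < 2) break
    exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
    low <- which(apply(exp_counts, 2, min) < 1)
    if (length(low) == 0) break
    j <- low[1]
    nb <- if (j == ncol(m)) j - 1 else j + 1
    inform(sprintf("merging low-expectation bin %d into bin %d", j, nb))
    m[, nb] <- m[, nb] + m[, j]
    m <- m[, -j, drop = FALSE]
  }
  if (ncol(m) < 2) {
    return(tibble(statistic = 0, df = 0L, p_value = 1, bins_used = ncol(m)))
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ht$statistic),
         df = as.integer(ht$parameter),
         p_value = if (unname(ht$statistic) == 0) 1 else unname(ht$p.value),
         bins_used = ncol(m))
}

#' Principal component projection of per-condition score distributions
#'
#' Treats each bin's relative frequency as a variable and each condition
#' as an observation; centered, unscaled PCA; the first two component
#' scores are returned with a fixed sign convention (the largest-magnitude
#' loading of each component is made positive).
#'
#' @param profiles Named list of `imcc_profile` objects (or a conditions x
#'   bins numeric matrix of relative frequencies).
#' @return Tibble `condition`, `pc1`, `pc2`; loadings in the `rotation`
#'   attribute.
#' @export
pca_profiles <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.matrix(profiles)) {
    if (is.null(names(profiles))) abort("profiles must be named")
    m <- do.call(rbind, lapply(profiles, function(p) p$relative))
    rownames(m) <- names(profiles)
  } else {
    m <- as.matrix(profiles)
  }
  if (nrow(m) < 2) abort("need at least two conditions")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- tibble(
    condition = rownames(m) %||% as.character(seq_len(nrow(m))),
    pc1 = unname(scores[, 1]),
    pc2 = if (k >= 2) unname(scores[, 2]) else 0
  )
  attr(out, "rotation") <- rot
  out
}

#' Architecture distance between conditions
#'
#' Min-max normalizes mean edge weight, density and centralization across
#' conditions and reports each condition's Euclidean distance to the
#' reference in that unit 3-space (0 for the reference itself; at most
#' sqrt(3)).
#'
#' @param summaries Data frame with one row per condition: a `condition`
#'   column plus `avg_weight`, `density`, `centrality` (e.g. stacked
#'   [topo_summary()] rows).
#' @param reference Condition label to measure from.
#' @return Tibble `condition`, `distance`.
#' @export
architecture_distance <- function(summaries, reference) {
  summaries <- as_tibble(summaries)
  need <- c("condition", "avg_weight", "density", "centrality")
  if (!all(need %in% names(summaries))) {
    abort("summaries need columns condition, avg_weight, density, centrality")
  }
  if (!reference %in% summaries$condition) {
    abort(sprintf("reference condition '%s' not present", reference))
  }
  m <- sapply(c("avg_weight", "density", "centrality"),
              function(cl) minmax_normalize(summaries[[cl]]))
  m <- matrix(m, ncol = 3)
  ref <- m[summaries$condition == reference, , drop = FALSE][1, ]
  tibble(
    condition = summaries$condition,
    distance = sqrt(rowSums((m - matrix(ref, nrow(m), 3, byrow = TRUE))^2))
  )
}

#' Export a modular map edge list as TSV
#'
#' @param map A [modular_map()].
#' @param path Output file.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map$edges, path, progress = FALSE)
  invisible(map)
}
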