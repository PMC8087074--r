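# Connector-module detection (three criteria + consensus), pathological
# module pair identification, and dissociation of the pair across
# conditions.

#' Connector modules by betweenness centrality
#'
#' Ranks modules by normalized betweenness in the unweighted modular map
#' and keeps the top fraction (ceiling; modules tied with the last
#' included rank are all included, with a message).
#'
#' @param map A [modular_map()].
#' @param top_fraction Fraction of modules to keep (default 0.10).
#' @return Character vector of module labels.
#' @export
betweenness_connectors <- function(map, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  g <- as_igraph(map)
  n <- igraph::vcount(g)
  if (n == 0) return(character())
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  k <- ceiling(top_fraction * n)
  ord <- order(-btw, names(btw))
  cut_val <- btw[ord][k]
  tol <- 1e-12
  sel <- names(btw)[btw > cut_val + tol]
  tied <- setdiff(names(btw)[abs(btw - cut_val) <= tol], sel)
  if (length(sel) + length(tied) > k) {
    inform(sprintf("%d modules tied at the betweenness cut; all included",
                   length(tied)))
  }
  sort(c(sel, tied))
}

#' Connector modules by path-length/density perturbation (VRCD)
#'
#' Deletes each module in turn and measures the relative change of the
#' map's characteristic path length (`delta_s`) and density (`delta_t`);
#' the response ratio is `eta = delta_s / delta_t`.  Modules whose `eta`
#' exceeds twice the mean `eta` are connectors.  Modules with an undefined
#' ratio (density unchanged, as when deleting any node of a clique) are
#' excluded from the mean; if no ratio is defined, or all defined ratios
#' are equal, no connector is called — a clique-like map has no
#' distinguished bridge.  A deletion that leaves no connected module pair
#' at all destroys every channel: such a module is reported with an
#' infinite ratio and is always a connector.
#'
#' @param map A [modular_map()] with at least 3 modules.
#' @param multiplier Cutoff multiple of the mean ratio (default 2).
#' @return List with `eta` (tibble `module`, `delta_s`, `delta_t`, `eta`)
#'   and `connectors` (character vector).
#' @export
vrcd <- function(map, multiplier = 2) {
  g <- as_igraph(map)
  n <- igraph::vcount(g)
  if (n < 3) abort("VRCD needs at least 3 modules")
  cpl_of <- function(gr) {
    d <- igraph::distances(gr, weights = NA)
    fin <- is.finite(d) & d > 0
    if (any(fin)) mean(d[fin]) else NA_real_
  }
  dens_of <- function(gr) {
    nn <- igraph::vcount(gr)
    if (nn < 2) return(NA_real_)
    2 * igraph::ecount(gr) / (nn * (nn - 1))
  }
  cpl_o <- cpl_of(g)
  d_o <- dens_of(g)
  if (is.na(cpl_o) || is.na(d_o) || d_o == 0) {
    abort("map has no paths; VRCD undefined")
  }
  mods <- igraph::V(g)$name
  rows <- purrr::map(mods, function(m) {
    gr <- igraph::delete_vertices(g, m)
    cpl_a <- cpl_of(gr)
    d_a <- dens_of(gr)
    # a deletion that leaves no connected pair destroys all communication:
    # infinite path-length inflation, connector by definition
    delta_s <- if (is.na(cpl_a)) Inf else (cpl_a - cpl_o) / cpl_o
    delta_t <- if (is.na(d_a)) NA_real_ else (d_a - d_o) / d_o
    eta <- if (is.infinite(delta_s)) {
      Inf
    } else if (is.na(delta_t) || delta_t == 0) {
      NA_real_
    } else delta_s / delta_t
    tibble(module = m, delta_s = delta_s, delta_t = delta_t, eta = eta)
  }) |> dplyr::bind_rows()
  finite <- rows$eta[is.finite(rows$eta)]
  by_cut <- if (length(finite) == 0 || diff(range(finite)) < 1e-12) {
    # clique-like map: every (defined) response equal, no distinguished
    # bridge
    character()
  } else {
    cutoff <- multiplier * mean(finite)
    rows$module[is.finite(rows$eta) & rows$eta > cutoff]
  }
  disconnectors <- rows$module[is.infinite(rows$eta)]
  list(eta = rows, connectors = sort(unique(c(by_cut, disconnectors))))
}

#' Connector modules by edge-weight distribution
#'
#' Modules incident to at least one map edge with weight strictly above
#' the cutoff.
#'
#' @param map A [modular_map()].
#' @param cutoff Edge-weight cutoff (default 0.1).
#' @return Character vector of module labels.
#' @export
weight_connectors <- function(map, cutoff = 0.1) {
  ed <- map$edges[map$edges$imcc > cutoff, ]
  sort(unique(c(ed$module_x, ed$module_y)))
}

#' Consensus connectors and the pathological module pair
#'
#' The consensus is the three-way intersection of the betweenness, VRCD
#' and edge-weight connector sets; the pathological module pair (PMP) is
#' the consensus pair joined by the strongest map edge.  When fewer than
#' two consensus modules share an edge the PMP is reported as absent
#' rather than forced.
#'
#' @param map A [modular_map()].
#' @param top_fraction,multiplier,cutoff Passed to the three detectors.
#' @return A `connector_report`: list with the three method sets,
#'   `consensus`, `pmp` (two labels or `NULL`), `pmp_imcc`, and the VRCD
#'   `eta` table.
#' @export
detect_connectors <- function(map, top_fraction = 0.10, multiplier = 2,
                              cutoff = 0.1) {
  by_b <- betweenness_connectors(map, top_fraction)
  v <- vrcd(map, multiplier)
  by_w <- weight_connectors(map, cutoff)
  consensus_and_pmp(map, by_b, v$connectors, by_w, eta = v$eta)
}

#' @rdname detect_connectors
#' @param by_betweenness,by_vrcd,by_weight Connector sets from the three
#'   methods.
#' @param eta Optional VRCD `eta` table carried into the report.
#' @export
consensus_and_pmp <- function(map, by_betweenness, by_vrcd, by_weight,
                              eta = NULL) {
  consensus <- sort(Reduce(intersect,
                           list(by_betweenness, by_vrcd, by_weight)))
  ed <- map$edges[map$edges$module_x %in% consensus &
                    map$edges$module_y %in% consensus, ]
  pmp <- NULL
  pmp_imcc <- NA_real_
  if (nrow(ed) > 0) {
    ed <- dplyr::arrange(ed, dplyr::desc(.data$imcc), .data$module_x,
                         .data$module_y)
    pmp <- c(ed$module_x[1], ed$module_y[1])
    pmp_imcc <- ed$imcc[1]
  }
  structure(list(by_betweenness = by_betweenness, by_vrcd = by_vrcd,
                 by_weight = by_weight, consensus = consensus, pmp = pmp,
                 pmp_imcc = pmp_imcc, eta = eta),
            class = "connector_report")
}

#' @export
print.connector_report <- function(x, ...) {
  cat("<connector_report>\n")
  cat("  betweenness:", paste(x$by_betweenness, collapse = ", "), "\n")
  cat("  VRCD:       ", paste(x$by_vrcd, collapse = ", "), "\n")
  cat("  edge weight:", paste(x$by_weight, collapse = ", "), "\n")
  cat("  consensus:  ", paste(x$consensus, collapse = ", "), "\n")
  if (is.null(x$pmp)) {
    cat("  PMP: none\n")
  } else {
    cat(sprintf("  PMP: %s -- %s (IMCC %.4g)\n", x$pmp[1], x$pmp[2],
                x$pmp_imcc))
  }
  invisible(x)
}

#' @export
tidy.connector_report <- function(x, ...) {
  mods <- sort(unique(c(x$by_betweenness, x$by_vrcd, x$by_weight)))
  tibble(
    module = mods,
    by_betweenness = mods %in% x$by_betweenness,
    by_vrcd = mods %in% x$by_vrcd,
    by_weight = mods %in% x$by_weight,
    consensus = mods %in% x$consensus,
    in_pmp = mods %in% (x$pmp %||% character())
  )
}

#' Dissociation rate of a module pair across conditions
#'
#' `DR = (n_B / n_A) * (N_A / N_B)`: the growth in the number of modules
#' hosting the pair's genes, corrected by the total module counts of the
#' two states.
#'
#' @param n_A Modules forming the pair in the initial state (2 for a pair).
#' @param n_B Modules the pair's genes occupy in the succeeding state.
#' @param N_A,N_B Total module counts of the initial and succeeding states.
#' @return Positive scalar.
#' @examples
#' dissociation_rate(2, 15, 48, 23)  # 15.65...
#' @export
dissociation_rate <- function(n_A, n_B, N_A, N_B) {
  if (any(c(n_A, n_B, N_A, N_B) < 1)) abort("all counts must be >= 1")
  (n_B / n_A) * (N_A / N_B)
}

#' Trace a module pair's genes into another condition's partition
#'
#' Collects the genes of the pair in the reference partition, looks each
#' up in the other condition's partition, and reports how many distinct
#' modules they land in (`n_B`), the landing fractions, and the
#' dissociation rate (with `N_A`, `N_B` the two partitions' module
#' counts).  Genes absent from the other partition are tallied under the
#' reserved label `"lost"` and excluded from `n_B` and the fractions.
#'
#' @param part_ref Reference-condition [module_partition()] containing the
#'   pair.
#' @param part_other The other condition's partition.
#' @param pmp Character vector of the two reference module labels.
#' @return A `dissociation_result`: list with counts `n_A`, `n_B`, `N_A`,
#'   `N_B`, `dr`, tibble `dispersion` (`module`, `n_genes`, `fraction`),
#'   and `n_lost`.
#' @export
trace_pmp <- function(part_ref, part_other, pmp) {
  part_ref <- as_module_partition(part_ref)
  part_other <- as_module_partition(part_other)
  pmp <- as.character(pmp)
  if (length(pmp) != 2 || pmp[1] == pmp[2]) {
    abort("`pmp` must be two distinct module labels")
  }
  missing <- setdiff(pmp, unique(part_ref$module))
  if (length(missing) > 0) {
    abort(sprintf("module '%s' absent from reference partition", missing[1]))
  }
  genes <- part_ref$gene[part_ref$module %in% pmp]
  lookup <- setNames(part_other$module, part_other$gene)
  landed <- unname(lookup[genes])
  n_lost <- sum(is.na(landed))
  if (n_lost > 0) {
    inform(sprintf("%d gene(s) absent from the other partition ('lost')",
                   n_lost))
  }
  landed <- landed[!is.na(landed)]
  if (length(landed) == 0) abort("no pair gene present in the other partition")
  disp <- tibble(module = landed) |>
    dplyr::count(.data$module, name = "n_genes") |>
    dplyr::mutate(fraction = .data$n_genes / sum(.data$n_genes)) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$module)
  n_A <- 2L
  n_B <- nrow(disp)
  N_A <- length(module_labels(part_ref, include_unassigned = FALSE))
  N_B <- length(module_labels(part_other, include_unassigned = FALSE))
  structure(list(n_A = n_A, n_B = n_B, N_A = N_A, N_B = N_B,
                 dr = dissociation_rate(n_A, n_B, N_A, N_B),
                 dispersion = disp, n_lost = n_lost),
            class = "dissociation_result")
}

#' @export
print.dissociation_result <- function(x, ...) {
  cat(sprintf("<dissociation_result> n_A = %d, n_B = %d, N_A = %d, N_B = %d, DR = %.2f\n",
              x$n_A, x$n_B, x$N_A, x$N_B, x$dr))
  print(head(x$dispersion, 5))
  invisible(x)
}

#' @export
tidy.dissociation_result <- function(x, ...) x$dispersion

#' @export
glance.dissociation_result <- function(x, ...) {
  tibble(n_A = x$n_A, n_B = x$n_B, N_A = x$N_A, N_B = x$N_B, dr = x$dr,
         n_lost = x$n_lost)
}
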