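# S3 containers for the gene-level network, the module partition and the
# module-level annotation table.  All are thin wrappers around tibbles so
# they compose with dplyr; the wrappers exist to enforce the invariants
# (symmetry, weight range, disjoint module assignment) once, at the door.

#' Reserved module label for genes outside every scored module
#'
#' Genes carrying this label still belong to the network (they count in the
#' consistency-score gene universe and may act as path mediators) but their
#' "module" is never scored as a member of a module pair.
#'
#' @export
UNASSIGNED_LABEL <- "unassigned"

#' Construct a weighted gene co-expression network
#'
#' A network is an undirected, simple, weighted graph over genes, stored as
#' a canonical edge list (each unordered pair once, `gene_a < gene_b`).
#' Weights are soft-threshold adjacencies in `(0, 1]`; edges below
#' `weight_floor` are rejected because the network is defined as the graph
#' that survives the adjacency cutoff.  Isolated genes are kept in the node
#' set: they still count in the gene universe of the consistency score.
#'
#' @param edges A data frame whose first three columns are interpreted as
#'   gene, gene, weight (canonical names `gene_a`, `gene_b`, `weight`).
#' @param nodes Optional character vector of gene ids; the node set is the
#'   union of `nodes` and all edge endpoints.
#' @param weight_floor Minimum admissible adjacency (default 0.02, the
#'   usual cutoff applied when thresholding a soft-power adjacency).
#' @return A `gene_network` object: a list with tibble `$edges`, character
#'   `$nodes` (sorted) and scalar `$weight_floor`.
#' @examples
#' net <- gene_network(data.frame(a = "g1", b = "g2", w = 0.5))
#' net$edges
#' @export
gene_network <- function(edges, nodes = NULL, weight_floor = 0.02) {
  stopifnot(is.numeric(weight_floor), length(weight_floor) == 1,
            weight_floor >= 0, weight_floor < 1)
  edges <- as_tibble(as.data.frame(edges))
  if (ncol(edges) < 3) {
    abort("`edges` needs at least three columns: gene, gene, weight.")
  }
  edges <- edges[, 1:3]
  names(edges) <- c("gene_a", "gene_b", "weight")
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  if (!is.numeric(edges$weight)) abort("edge weights must be numeric")
  if (anyNA(edges)) abort("edge list contains missing values")
  if (any(edges$gene_a == edges$gene_b)) abort("self-loops are not allowed")
  bad <- edges$weight <= 0 | edges$weight > 1
  if (any(bad)) {
    abort(sprintf("weight out of range (0, 1]: %s",
                  paste(head(edges$weight[bad], 3), collapse = ", ")))
  }
  if (any(edges$weight < weight_floor)) {
    abort(sprintf("edge weight below weight_floor = %g", weight_floor))
  }
  # canonical unordered representation, one row per pair
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    w_by_key <- split(edges$weight, key)
    conflict <- vapply(w_by_key[dup], function(w) length(unique(w)) > 1,
                       logical(1))
    if (any(conflict)) {
      abort("duplicate edge with conflicting weights")
    }
    edges <- edges[!duplicated(key), ]
  }
  nodes <- sort(unique(c(as.character(nodes %||% character()),
                         edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = nodes, weight_floor = weight_floor),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges (weight floor %g)\n",
              length(x$nodes), nrow(x$edges), x$weight_floor))
  print(head(x$edges, 5))
  invisible(x)
}

as_gene_network <- function(x, weight_floor = 0.02) {
  if (inherits(x, "gene_network")) return(x)
  gene_network(x, weight_floor = weight_floor)
}

#' Convert a gene network or modular map to an igraph graph
#'
#' @param x A `gene_network` or `modular_map`.
#' @return An undirected `igraph` graph with a `weight` edge attribute;
#'   isolated nodes are preserved.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.gene_network <- function(x) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes)
  g
}

#' @export
as_igraph.modular_map <- function(x) {
  ed <- x$edges
  names(ed) <- c("from", "to", "weight")
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = x$modules)
}

#' Construct a module partition
#'
#' Each gene belongs to exactly one module.  The reserved label
#' [UNASSIGNED_LABEL] may be used for background genes; it is excluded from
#' every pair-scoring step but its genes remain in the network universe.
#'
#' @param assignment Data frame whose first two columns are gene id and
#'   module label.
#' @return A `module_partition`: a tibble with columns `gene`, `module`,
#'   class-tagged.
#' @examples
#' part <- module_partition(data.frame(gene = c("g1", "g2"),
#'                                     module = c("blue", "brown")))
#' module_labels(part)
#' @export
module_partition <- function(assignment) {
  assignment <- as_tibble(as.data.frame(assignment))
  if (ncol(assignment) < 2) abort("partition needs columns gene, module")
  assignment <- assignment[, 1:2]
  names(assignment) <- c("gene", "module")
  assignment$gene <- as.character(assignment$gene)
  assignment$module <- as.character(assignment$module)
  if (anyNA(assignment)) abort("partition contains missing values")
  if (any(!nzchar(assignment$module))) abort("empty module label")
  if (anyDuplicated(assignment$gene)) {
    dup <- assignment$gene[duplicated(assignment$gene)][1]
    abort(sprintf("gene assigned to more than one module: '%s'", dup))
  }
  assignment <- dplyr::arrange(assignment, .data$gene)
  class(assignment) <- c("module_partition", class(assignment))
  assignment
}

as_module_partition <- function(x) {
  if (inherits(x, "module_partition")) return(x)
  module_partition(x)
}

#' Module labels of a partition
#'
#' @param part A `module_partition` (or coercible data frame).
#' @param include_unassigned Keep the reserved background label?
#' @return Sorted character vector of module labels.
#' @export
module_labels <- function(part, include_unassigned = FALSE) {
  part <- as_module_partition(part)
  labs <- sort(unique(part$module))
  if (!include_unassigned) labs <- setdiff(labs, UNASSIGNED_LABEL)
  labs
}

#' Module sizes of a partition
#'
#' @inheritParams module_labels
#' @return Named integer vector, one entry per (non-background) module.
#' @export
module_sizes <- function(part, include_unassigned = FALSE) {
  part <- as_module_partition(part)
  tab <- table(part$module)
  sizes <- setNames(as.integer(tab), names(tab))
  if (!include_unassigned) {
    sizes <- sizes[setdiff(names(sizes), UNASSIGNED_LABEL)]
  }
  sizes[order(names(sizes))]
}

#' Construct a module-level map
#'
#' Nodes are module labels; edges carry the final IMCC of the module pair.
#' Built from a scored pair table by [build_map()], or directly for tests.
#'
#' @param edges Data frame with columns module, module, imcc (weights > 0).
#' @param modules Optional label vector; node set is the union with edge
#'   endpoints (isolated modules allowed).
#' @return A `modular_map`: list with tibble `$edges` (`module_x`,
#'   `module_y`, `imcc`, canonical order) and character `$modules`.
#' @export
modular_map <- function(edges, modules = NULL) {
  edges <- as_tibble(as.data.frame(edges))
  if (ncol(edges) < 3) abort("map edges need columns module, module, weight")
  edges <- edges[, 1:3]
  names(edges) <- c("module_x", "module_y", "imcc")
  edges$module_x <- as.character(edges$module_x)
  edges$module_y <- as.character(edges$module_y)
  if (any(edges$module_x == edges$module_y)) abort("self-loop module pair")
  if (any(edges$imcc <= 0)) abort("map edge weights must be positive")
  flip <- edges$module_x > edges$module_y
  tmp <- edges$module_x[flip]
  edges$module_x[flip] <- edges$module_y[flip]
  edges$module_y[flip] <- tmp
  edges <- dplyr::arrange(edges, .data$module_x, .data$module_y)
  if (anyDuplicated(paste(edges$module_x, edges$module_y))) {
    abort("duplicate module pair in map")
  }
  modules <- sort(unique(c(as.character(modules %||% character()),
                           edges$module_x, edges$module_y)))
  structure(list(edges = edges, modules = modules), class = "modular_map")
}

#' @export
print.modular_map <- function(x, ...) {
  cat(sprintf("<modular_map> %d modules, %d scored pairs\n",
              length(x$modules), nrow(x$edges)))
  print(head(x$edges, 5))
  invisible(x)
}

#' Construct a module annotation table
#'
#' Long table mapping modules to functional category labels (for example
#' enriched pathway identifiers); the per-module category sets drive the
#' Jaccard-similarity calibration.
#'
#' @param annotations Data frame whose first two columns are module label
#'   and category label.
#' @return A tibble with columns `module`, `category`, deduplicated.
#' @export
annotation_table <- function(annotations) {
  annotations <- as_tibble(as.data.frame(annotations))
  if (ncol(annotations) < 2) abort("annotations need columns module, category")
  annotations <- annotations[, 1:2]
  names(annotations) <- c("module", "category")
  annotations$module <- as.character(annotations$module)
  annotations$category <- as.character(annotations$category)
  if (anyNA(annotations)) abort("annotations contain missing values")
  dplyr::distinct(dplyr::arrange(annotations, .data$module, .data$category))
}

# per-gene degree / weighted degree (strength), including isolated genes
node_strengths <- function(net) {
  net <- as_gene_network(net)
  long <- tibble(
    gene = c(net$edges$gene_a, net$edges$gene_b),
    weight = rep(net$edges$weight, 2)
  )
  agg <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(degree = dplyr::n(), strength = sum(.data$weight),
                     .groups = "drop")
  tibble(gene = net$nodes) |>
    dplyr::left_join(agg, by = "gene") |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0L),
                  strength = dplyr::coalesce(.data$strength, 0))
}
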