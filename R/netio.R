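# Readers/writers for the TSV dialects and construction of the
# soft-threshold adjacency from an expression matrix.

#' Read a gene expression matrix
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column.  Missing or non-numeric cells and duplicate gene ids are
#' refused rather than repaired: the correlation step downstream assumes a
#' complete matrix.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), comment = "#", progress = FALSE)
  if (ncol(df) < 2) abort("expression table has no sample columns")
  genes <- as.character(df[[1]])
  if (anyNA(genes) || any(!nzchar(genes))) abort("missing gene id")
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene id: '%s'", genes[duplicated(genes)][1]))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(raw)) abort("missing expression values are not accepted")
  mat <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = dimnames(raw)))
  if (anyNA(mat)) abort("non-numeric expression value")
  if (ncol(mat) < 3) abort("need at least 3 samples for correlation")
  rownames(mat) <- genes
  mat
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr))) abort("`expr` needs gene ids as rownames")
  if (anyDuplicated(rownames(expr))) abort("duplicate gene id")
  if (anyNA(expr)) abort("missing expression values are not accepted")
  if (ncol(expr) < 3) abort("need at least 3 samples for correlation")
  invisible(expr)
}

#' Build a soft-threshold co-expression adjacency
#'
#' The adjacency between genes i and j is `|cor(x_i, x_j)|^power`
#' (unsigned Pearson correlation raised to the soft-threshold power); pairs
#' below `weight_floor` are dropped, but every gene stays in the node set,
#' isolated if need be.
#'
#' @param expr Numeric matrix, genes x samples, gene ids as rownames.
#' @param power Soft-threshold exponent (positive integer-ish scalar).
#' @param weight_floor Adjacency cutoff below which edges are discarded
#'   (default 0.02).
#' @return A [gene_network()].
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
#' build_adjacency(expr, power = 6)
#' @export
build_adjacency <- function(expr, power, weight_floor = 0.02) {
  check_expression(expr)
  stopifnot(is.numeric(power), length(power) == 1, power >= 1)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("constant expression for gene '%s': correlation undefined",
                  rownames(expr)[sds == 0][1]))
  }
  a <- abs(stats::cor(t(expr)))^power
  genes <- rownames(expr)
  idx <- which(upper.tri(a) & a >= weight_floor, arr.ind = TRUE)
  edges <- tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    weight = pmin(a[idx], 1)
  )
  gene_network(edges, nodes = genes, weight_floor = weight_floor)
}

# scale-free fit index: equal-count binning of connectivity, regression of
# log10(frequency) on log10(mean connectivity)
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  n_bins <- min(n_bins, length(unique(k)))
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mean_k) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  summary(fit)$r.squared
}

#' Choose a soft-threshold power by scale-free fit
#'
#' For each candidate power the thresholded adjacency is built and the
#' scale-free topology fit index computed: connectivities (sums of
#' adjacency per gene) are grouped into ten equal-count bins and
#' log10(frequency) regressed on log10(mean connectivity); the index is
#' that regression's R-squared.  The smallest candidate reaching
#' `r2_target` wins; if none does, the candidate with the maximal index.
#'
#' @inheritParams build_adjacency
#' @param candidates Candidate powers (non-empty numeric vector).
#' @param r2_target Fit index considered "scale-free enough" (default 0.8).
#' @return The selected power (scalar from `candidates`).
#' @export
pick_soft_power <- function(expr, candidates = 1:20, weight_floor = 0.02,
                            r2_target = 0.8) {
  check_expression(expr)
  if (length(candidates) == 0) abort("no candidate powers")
  candidates <- sort(unique(candidates))
  if (length(candidates) == 1) return(candidates)
  r2 <- vapply(candidates, function(p) {
    net <- build_adjacency(expr, power = p, weight_floor = weight_floor)
    st <- node_strengths(net)
    scale_free_r2(st$strength)
  }, numeric(1))
  if (all(is.na(r2))) abort("scale-free fit undefined for every candidate")
  hit <- which(!is.na(r2) & r2 >= r2_target)
  if (length(hit) > 0) return(candidates[hit[1]])
  candidates[which.max(r2)]
}

#' Read / write a weighted edge list
#'
#' Three tab-separated columns `gene_a  gene_b  weight`, header row,
#' leading `#` lines ignored.  Writing then reading reproduces the network
#' exactly (edge lists are kept in canonical sorted order).
#'
#' @param path File path.
#' @param weight_floor Cutoff recorded on the returned network.
#' @return `read_network()` a [gene_network()]; `write_network()` the input,
#'   invisibly.
#' @export
read_network <- function(path, weight_floor = 0.02) {
  df <- readr::read_tsv(path, col_types = "ccd", comment = "#",
                        progress = FALSE)
  gene_network(df, weight_floor = weight_floor)
}

#' @rdname read_network
#' @param net A [gene_network()].
#' @export
write_network <- function(net, path) {
  net <- as_gene_network(net)
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(net)
}

#' Read / write a module partition
#'
#' Two tab-separated columns `gene  module`.  Empty module labels are an
#' error; genes absent from a network are allowed (isolated genes).
#'
#' @param path File path.
#' @return `read_partition()` a [module_partition()].
#' @export
read_partition <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", comment = "#",
                        progress = FALSE)
  module_partition(df)
}

#' @rdname read_partition
#' @param part A [module_partition()].
#' @export
write_partition <- function(part, path) {
  part <- as_module_partition(part)
  readr::write_tsv(tibble(gene = part$gene, module = part$module), path,
                   progress = FALSE)
  invisible(part)
}

#' Read / write a module annotation table
#'
#' Two tab-separated columns `module  category`.
#'
#' @param path File path.
#' @return `read_annotations()` a tibble (see [annotation_table()]).
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", comment = "#",
                        progress = FALSE)
  annotation_table(df)
}

#' @rdname read_annotations
#' @param ann An annotation table.
#' @export
write_annotations <- function(ann, path) {
  ann <- annotation_table(ann)
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(ann)
}

#' Export a network or modular map to GraphML
#'
#' @param x A [gene_network()] or [modular_map()].
#' @param path Output file.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(x)
}
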