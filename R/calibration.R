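# Calibration of the integration weighting against functional-annotation
# similarity, and topological verification via the inter-module average
# shortest path.

#' Jaccard similarity of two category sets
#'
#' `|A intersect B| / |A union B|`.  If both sets are empty the similarity
#' is undefined and `NA` is returned (such pairs are skipped in fits).
#'
#' @param a,b Character vectors of category labels (duplicates ignored).
#' @return Scalar in `[0, 1]`, or `NA` for two empty sets.
#' @examples
#' jaccard_similarity(letters[1:8], letters[3:13])  # 6 shared of 11 -> 0.54545
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

#' Jaccard similarity for every module pair of an annotation table
#'
#' @param ann An [annotation_table()] (module, category).
#' @param pairs Optional tibble/data frame with columns `module_x`,
#'   `module_y`; defaults to all unordered pairs of annotated modules.
#' @return Tibble `module_x`, `module_y`, `js` (NA when both sets empty).
#' @export
pair_jaccard <- function(ann, pairs = NULL) {
  ann <- annotation_table(ann)
  sets <- split(ann$category, ann$module)
  if (is.null(pairs)) {
    mods <- sort(names(sets))
    if (length(mods) < 2) abort("need at least two annotated modules")
    cmb <- utils::combn(mods, 2)
    pairs <- tibble(module_x = cmb[1, ], module_y = cmb[2, ])
  } else {
    pairs <- as_tibble(as.data.frame(pairs))[, 1:2]
    names(pairs) <- c("module_x", "module_y")
  }
  pairs$js <- purrr::map2_dbl(pairs$module_x, pairs$module_y, function(x, y) {
    jaccard_similarity(sets[[x]] %||% character(), sets[[y]] %||% character())
  })
  pairs
}

model_names <- c("linear", "logarithmic", "power", "exponential")

# transform a model to its linearized regression scales
model_transform <- function(x, y, model) {
  switch(model,
    linear = list(xs = x, ys = y),
    logarithmic = {
      if (any(x <= 0)) abort("logarithmic model needs positive x")
      list(xs = log(x), ys = y)
    },
    power = {
      if (any(x <= 0)) abort("power model needs positive x")
      if (any(y <= 0)) abort("power model needs positive y")
      list(xs = log(x), ys = log(y))
    },
    exponential = {
      if (any(y <= 0)) abort("exponential model needs positive y")
      list(xs = x, ys = log(y))
    },
    abort(sprintf("unknown model '%s'", model))
  )
}

#' Fit one of the standard curve-estimation models
#'
#' Least-squares fit of `linear` (y = a x + b), `logarithmic`
#' (y = a ln x + b), `power` (y = b x^a, fitted log-log) or `exponential`
#' (y = b e^(a x), fitted semi-log).  The coefficient of determination is
#' reported on the scale on which the model is linear, as classical curve
#' estimation does.
#'
#' @param x,y Numeric vectors (>= 3 points; positivity as the model
#'   requires).
#' @param model One of `"linear"`, `"logarithmic"`, `"power"`,
#'   `"exponential"`.
#' @param outliers_removed Bookkeeping count carried into the result.
#' @return An `imcc_fit` object; see [tidy()][generics::tidy] /
#'   [glance()][generics::glance] methods.
#' @examples
#' x <- 1:20
#' fit_curve(x, 2 * log(x) + 1, "logarithmic")
#' @export
fit_curve <- function(x, y, model = "logarithmic", outliers_removed = 0L) {
  model <- match.arg(model, model_names)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 points to fit")
  if (length(unique(x)) < 2) abort("degenerate x: all values equal")
  tr <- model_transform(x, y, model)
  fit <- stats::lm(ys ~ xs, data = tr)
  # summary.lm warns on an exactly collinear (planted) relation; the fit
  # itself is what we report
  sm <- suppressWarnings(summary(fit))
  # a constant response has no explainable variance
  r_squared <- if (stats::var(tr$ys) == 0) 0 else sm$r.squared
  co <- coef(fit)
  coefficients <- switch(model,
    linear = c(a = unname(co[2]), b = unname(co[1])),
    logarithmic = c(a = unname(co[2]), b = unname(co[1])),
    power = c(a = unname(co[2]), b = unname(exp(co[1]))),
    exponential = c(a = unname(co[2]), b = unname(exp(co[1])))
  )
  structure(list(model_name = model, coefficients = coefficients,
                 r_squared = r_squared, n_points = length(x),
                 outliers_removed = as.integer(outliers_removed),
                 lm_fit = fit, data = tibble(x = x, y = y)),
            class = "imcc_fit")
}

#' @export
print.imcc_fit <- function(x, ...) {
  cat(sprintf("<imcc_fit> %s model: a = %.4g, b = %.4g, R^2 = %.3f (n = %d%s)\n",
              x$model_name, x$coefficients["a"], x$coefficients["b"],
              x$r_squared, x$n_points,
              if (x$outliers_removed > 0)
                sprintf(", %d outliers removed", x$outliers_removed) else ""))
  invisible(x)
}

#' @export
tidy.imcc_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.imcc_fit <- function(x, ...) {
  tibble(model = x$model_name, r.squared = x$r_squared,
         n_points = x$n_points, outliers_removed = x$outliers_removed)
}

#' Remove gross outliers before a curve fit
#'
#' One pass: fit the requested model, compute externally studentized
#' residuals on the linearized scale, and drop points whose absolute value
#' exceeds `threshold`.  If removal would leave fewer than 3 points the
#' data are returned untouched.
#'
#' @inheritParams fit_curve
#' @param threshold Studentized-residual cutoff (default 3).
#' @return List with `x`, `y`, `removed` (count).
#' @export
remove_outliers <- function(x, y, model = "logarithmic", threshold = 3) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) return(list(x = x, y = y, removed = 0L))
  tr <- model_transform(x, y, model)
  fit <- stats::lm(ys ~ xs, data = tr)
  rs <- suppressWarnings(stats::rstudent(fit))
  out <- is.finite(rs) & abs(rs) > threshold
  if (!any(out) || (length(x) - sum(out)) < 3) {
    return(list(x = x, y = y, removed = 0L))
  }
  list(x = x[!out], y = y[!out], removed = sum(out))
}

# join annotation similarity onto a scored pair table
scores_with_js <- function(scores, ann) {
  js <- if (is.data.frame(ann) && "js" %in% names(ann)) {
    tab <- as_tibble(ann)
    cp <- canonical_pair(as.character(tab$module_x),
                         as.character(tab$module_y))
    tibble(module_x = cp$x, module_y = cp$y, js = tab$js)
  } else {
    pair_jaccard(ann, pairs = scores[, c("module_x", "module_y")])
  }
  dplyr::inner_join(as_tibble(scores), js, by = c("module_x", "module_y")) |>
    dplyr::filter(!is.na(.data$js))
}

fit_with_outlier_rule <- function(x, y, model) {
  cleaned <- remove_outliers(x, y, model = model)
  fit_curve(cleaned$x, cleaned$y, model = model,
            outliers_removed = cleaned$removed)
}

#' Scan the weighting ratio against annotation similarity
#'
#' For each candidate ratio `rho`, recomputes the weighted integration of
#' normalized SW and CT over the pairs where both screens passed, fits the
#' logarithmic model of annotation Jaccard similarity on the integrated
#' score (after the outlier rule), and records the coefficient of
#' determination.  The best ratio maximizes that R-squared; ties go to the
#' ratio closest to 1.
#'
#' @param scores An `imcc_scores` table from [score_condition()].
#' @param ann Either an [annotation_table()] or a precomputed tibble
#'   `module_x`, `module_y`, `js`.
#' @param grid Candidate ratios (default the standard 9-point grid
#'   1/10 ... 10).
#' @return A `rho_scan` object: `$best_rho` plus a per-rho result tibble;
#'   `tidy()` returns the profile, `glance()` the winner.
#' @export
scan_rho <- function(scores, ann,
                     grid = c(1/10, 1/8, 1/4, 1/2, 1, 2, 4, 8, 10)) {
  if (length(grid) == 0) abort("empty rho grid")
  df <- scores_with_js(scores, ann) |>
    dplyr::filter(!is.na(.data$sw_norm), !is.na(.data$ct_norm))
  results <- purrr::map(grid, function(rho) {
    v <- integrate_imcc1(df$sw_norm, df$ct_norm, rho)
    ok <- v > 0
    if (sum(ok) < 3) {
      return(tibble(rho = rho, r_squared = NA_real_, n_points = sum(ok),
                    outliers_removed = NA_integer_))
    }
    fit <- fit_with_outlier_rule(v[ok], df$js[ok], "logarithmic")
    tibble(rho = rho, r_squared = fit$r_squared, n_points = fit$n_points,
           outliers_removed = fit$outliers_removed)
  }) |> dplyr::bind_rows()
  if (all(is.na(results$r_squared))) {
    abort("too few annotated pairs with positive integrated scores")
  }
  best_r2 <- max(results$r_squared, na.rm = TRUE)
  cand <- results$rho[!is.na(results$r_squared) &
                        abs(results$r_squared - best_r2) < 1e-12]
  best_rho <- cand[which.min(abs(log(cand)))]
  structure(list(best_rho = best_rho, results = results),
            class = "rho_scan")
}

#' @export
print.rho_scan <- function(x, ...) {
  cat(sprintf("<rho_scan> best rho = %g\n", x$best_rho))
  print(x$results)
  invisible(x)
}

#' @export
tidy.rho_scan <- function(x, ...) x$results

#' @export
glance.rho_scan <- function(x, ...) {
  best <- x$results[which(x$results$rho == x$best_rho), ]
  tibble(best_rho = x$best_rho, r.squared = best$r_squared[1],
         n_points = best$n_points[1])
}

#' Compare integration schemes against annotation similarity
#'
#' Fits annotation Jaccard similarity against raw SW, against the weighted
#' integration at the best ratio from [scan_rho()], and against the
#' unweighted SW + PS integration, all with the same model family and
#' outlier rule, and reports the three coefficients of determination and
#' the winner.
#'
#' @inheritParams scan_rho
#' @param model Model family for all three fits (default logarithmic).
#' @return Tibble with one row per score (`sw`, `imcc1`, `imcc2`):
#'   `rho` (NA unless applicable), `r_squared`, `n_points`,
#'   `outliers_removed`, `available`; the winning score name is in the
#'   `winner` attribute.
#' @export
compare_integrations <- function(scores, ann, model = "logarithmic",
                                 grid = c(1/10, 1/8, 1/4, 1/2, 1, 2, 4, 8, 10)) {
  df <- scores_with_js(scores, ann)
  safe_fit <- function(x, y) {
    tryCatch({
      ok <- is.finite(x) & x > 0 & !is.na(y)
      fit <- fit_with_outlier_rule(x[ok], y[ok], model)
      tibble(r_squared = fit$r_squared, n_points = fit$n_points,
             outliers_removed = fit$outliers_removed, available = TRUE)
    }, error = function(e) {
      tibble(r_squared = NA_real_, n_points = NA_integer_,
             outliers_removed = NA_integer_, available = FALSE)
    })
  }
  sw_row <- safe_fit(df$sw[df$sw_valid], df$js[df$sw_valid])
  scan <- tryCatch(scan_rho(scores, ann, grid = grid), error = function(e) NULL)
  best_rho <- if (is.null(scan)) NA_real_ else scan$best_rho
  imcc1_row <- if (is.null(scan)) {
    tibble(r_squared = NA_real_, n_points = NA_integer_,
           outliers_removed = NA_integer_, available = FALSE)
  } else {
    both <- !is.na(df$sw_norm) & !is.na(df$ct_norm)
    safe_fit(integrate_imcc1(df$sw_norm[both], df$ct_norm[both], best_rho),
             df$js[both])
  }
  ok2 <- !is.na(df$imcc2)
  imcc2_row <- safe_fit(df$imcc2[ok2], df$js[ok2])
  report <- dplyr::bind_rows(sw = sw_row, imcc1 = imcc1_row,
                             imcc2 = imcc2_row, .id = "score")
  report$rho <- c(NA_real_, best_rho, NA_real_)
  report <- report[, c("score", "rho", "r_squared", "n_points",
                       "outliers_removed", "available")]
  avail <- report[report$available & !is.na(report$r_squared), ]
  attr(report, "winner") <- if (nrow(avail)) {
    avail$score[which.max(avail$r_squared)]
  } else NA_character_
  report
}

#' Inter-module average shortest path
#'
#' Mean shortest-path length in the gene network between every gene of one
#' module and every gene of the other.  Hop counts by default (the network
#' is a thresholded adjacency); with `weighted = TRUE` edge lengths are
#' `1/weight`.  Unreachable gene pairs are excluded from the mean and
#' counted in the `n_unreachable` attribute; all-unreachable returns `NA`.
#'
#' @inheritParams sum_of_weights
#' @param weighted Use `1/weight` edge lengths instead of hops?
#' @return Scalar mean distance with attribute `n_unreachable`.
#' @export
imasp <- function(net, part, pair, weighted = FALSE) {
  net <- as_gene_network(net)
  part <- as_module_partition(part)
  pair <- as.character(pair)
  missing <- setdiff(pair, unique(part$module))
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must be two distinct module labels")
  }
  if (length(missing) > 0) abort(sprintf("unknown module '%s'", missing[1]))
  g <- as_igraph(net)
  gx <- intersect(part$gene[part$module == pair[1]], net$nodes)
  gy <- intersect(part$gene[part$module == pair[2]], net$nodes)
  if (length(gx) == 0 || length(gy) == 0) {
    res <- NA_real_
    attr(res, "n_unreachable") <- NA_integer_
    return(res)
  }
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  d <- igraph::distances(g, v = gx, to = gy, weights = w)
  finite <- is.finite(d)
  res <- if (any(finite)) mean(d[finite]) else NA_real_
  attr(res, "n_unreachable") <- sum(!finite)
  res
}
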