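#' Binary transcript-detection calls
#'
#' A gene is called detected in a cell when its count reaches `min_count`
#' (default 1: presence of any captured transcript).
#'
#' @param x a [count_matrix()] or genes x cells matrix.
#' @param min_count detection threshold, >= 1.
#' @return A logical genes x cells matrix of the same dimensions.
#' @export
detect <- function(x, min_count = 1) {
  x <- as_count_input(x)
  if (min_count < 1) stop("min_count must be >= 1")
  m <- as.matrix(x$counts) >= min_count
  dimnames(m) <- dimnames(x$counts)
  m
}

#' Per-gene detection fractions
#'
#' The fraction of cells in which each gene is detected: the marginal
#' frequencies `p`, `q`, ... entering the independence prediction.
#'
#' @param detected logical genes x cells matrix from [detect()].
#' @return Named numeric vector in `[0, 1]` with attribute `n_cells`.
#' @export
detection_fractions <- function(detected) {
  if (is.null(dim(detected)) || !is.logical(detected))
    stop("`detected` must be a logical genes x cells matrix")
  if (ncol(detected) == 0L) stop("no cells: detection fractions undefined")
  f <- rowMeans(detected)
  attr(f, "n_cells") <- ncol(detected)
  f
}

#' Venn partition of detection patterns
#'
#' Splits the cell population into the `2^k` disjoint detection patterns of
#' `k` genes (including the none-detected region) and reports the fraction
#' of cells in each. Region names concatenate the detected genes with
#' `"&"`; the empty pattern is `"none"`. Fractions sum to 1 exactly.
#'
#' @param detected logical genes x cells matrix.
#' @param genes two or three gene names present in `detected`.
#' @return A list of class `venn_partition` with elements `genes`,
#'   `fractions` (named, length `2^k`), `counts`, `n_cells`.
#' @examples
#' det <- rbind(A = c(TRUE, TRUE, FALSE, FALSE),
#'              B = c(FALSE, TRUE, FALSE, TRUE))
#' colnames(det) <- paste0("c", 1:4)
#' venn_partition(det, c("A", "B"))
#' @export
venn_partition <- function(detected, genes) {
  if (length(genes) < 2L || length(genes) > 3L)
    stop("`genes` must name two or three genes")
  missing <- setdiff(genes, rownames(detected))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  n <- ncol(detected)
  if (n == 0L) stop("no cells")
  sub <- detected[genes, , drop = FALSE]
  k <- length(genes)
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), k))[, k:1, drop = FALSE]
  labels <- apply(pat, 1L, function(row) {
    if (!any(row)) "none" else paste(genes[as.logical(row)], collapse = "&")
  })
  # integer code of each cell's detection pattern, most significant = gene 1
  code <- as.integer(2L^((k - 1L):0L) %*% sub)
  pat_code <- as.integer(as.matrix(pat) %*% 2L^((k - 1L):0L))
  counts <- vapply(pat_code, function(p) sum(code == p), integer(1))
  names(counts) <- labels
  structure(list(genes = genes, fractions = counts / n, counts = counts,
                 n_cells = n),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, digits = 1, ...) {
  cat(sprintf("Detection partition of %s over %d cells\n",
              paste(x$genes, collapse = ", "), x$n_cells))
  pct <- formatC(100 * x$fractions, format = "f", digits = digits)
  for (i in seq_along(pct))
    cat(sprintf("  %-20s %6s%%\n", names(x$fractions)[i], pct[i]))
  invisible(x)
}

#' Independence-predicted coexpression frequency
#'
#' Under stochastic independent expression, genes detected in fractions
#' `p` and `q` of the population are predicted to be co-detected in a
#' fraction `p * q` (for a triple, `p * q * r`).
#'
#' @param profile named detection-fraction vector from
#'   [detection_fractions()].
#' @param genes two or more gene names in `profile`.
#' @return The product of the marginal detection fractions.
#' @export
predicted_coexpression <- function(profile, genes) {
  missing <- setdiff(genes, names(profile))
  if (length(missing))
    stop("gene(s) not in profile: ", paste(missing, collapse = ", "))
  prod(profile[genes])
}

#' Through-origin least-squares regression
#'
#' Fits `y = b x` constrained through the origin: `b = sum(x y) / sum(x^2)`.
#' The goodness of fit is the uncentered R-squared,
#' `1 - sum((y - b x)^2) / sum(y^2)`, the standard convention for a
#' no-intercept fit (the centred convention can exceed 1 or lose meaning
#' without an intercept); `r_squared = "correlation"` instead returns the
#' squared Pearson correlation of `x` and `y`.
#'
#' @param x predictor values (e.g. predicted coexpression frequencies).
#' @param y response values (e.g. observed frequencies).
#' @param r_squared `"uncentered"` (default) or `"correlation"`.
#' @return A list of class `origin_fit` with `slope`, `r.squared`,
#'   `fitted`, `residuals`, `x`, `y`, `n`.
#' @examples
#' fit_through_origin(c(1, 2), c(2, 3))  # slope 1.6
#' @export
fit_through_origin <- function(x, y, r_squared = c("uncentered", "correlation")) {
  r_squared <- match.arg(r_squared)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two points")
  if (all(x == 0)) stop("slope undefined: predictor is identically zero")
  slope <- sum(x * y) / sum(x^2)
  fitted <- slope * x
  res <- y - fitted
  r2 <- if (r_squared == "uncentered") {
    if (all(y == 0)) NA_real_ else 1 - sum(res^2) / sum(y^2)
  } else stats::cor(x, y)^2
  structure(list(slope = slope, r.squared = r2, fitted = fitted,
                 residuals = res, x = x, y = y, n = length(x),
                 r_squared_convention = r_squared),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("Through-origin fit: y = %.4g x  (R^2 = %.4g, n = %d)\n",
              x$slope, x$r.squared, x$n))
  invisible(x)
}

all_pairs <- function(genes) {
  cmb <- combn(genes, 2L)
  data.frame(gene1 = cmb[1L, ], gene2 = cmb[2L, ], stringsAsFactors = FALSE)
}

#' Fit the stochastic-independence model of coexpression
#'
#' The central estimator of the package. For a set of genes in a single-cell
#' count matrix it computes per-gene detection fractions, the observed
#' co-detection frequency of every gene pair, and the independence
#' prediction (the product of the two marginal fractions), then fits a
#' through-origin regression of observed on predicted frequencies. Under
#' stochastic, mutually independent expression with homogeneous read depth
#' the slope is 1; heterogeneous per-cell depth inflates observed
#' coexpression above the product of marginals (detection of *both* genes
#' is favoured in deeply read cells), pushing the slope above 1.
#'
#' @param x a [count_matrix()] or genes x cells matrix.
#' @param genes genes to analyse (default: all rows). May also be a list of
#'   character vectors (gene panels); pairs are then formed within each
#'   panel and de-duplicated, as when combining several published panels.
#' @param min_count detection threshold passed to [detect()].
#' @param r_squared R-squared convention, see [fit_through_origin()].
#' @return An object of class `coexpr_fit` with components `profile`
#'   (detection fractions), `pairs` (data frame with `gene1`, `gene2`,
#'   `observed`, `predicted`), `fit` (the [fit_through_origin()] result),
#'   `n_cells`, `min_count`, `line`, `call`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @examples
#' sim <- simulate_sc_counts(sc_sim_params(
#'   2000, paste0("g", 1:5), expr_prob = seq(0.1, 0.5, 0.1),
#'   depth_sigma = 0, seed = 1))
#' fit <- coexpr_independence(sim)
#' coef(fit)
#' @export
coexpr_independence <- function(x, genes = NULL, min_count = 1,
                                r_squared = c("uncentered", "correlation")) {
  cl <- match.call()
  x <- as_count_input(x)
  det <- detect(x, min_count = min_count)
  if (is.null(genes)) genes <- rownames(det)
  panels <- if (is.list(genes)) genes else list(genes)
  allg <- unique(unlist(panels))
  missing <- setdiff(allg, rownames(det))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(allg) < 2L) stop("need at least two genes")
  pairs <- unique(do.call(rbind, lapply(panels, function(p) {
    if (length(p) < 2L) return(NULL)
    all_pairs(sort(p))
  })))
  profile <- detection_fractions(det[allg, , drop = FALSE])
  obs <- mapply(function(a, b) mean(det[a, ] & det[b, ]),
                pairs$gene1, pairs$gene2)
  pred <- profile[pairs$gene1] * profile[pairs$gene2]
  pairs$observed <- as.numeric(obs)
  pairs$predicted <- as.numeric(pred)
  rownames(pairs) <- NULL
  fit <- fit_through_origin(pairs$predicted, pairs$observed,
                            r_squared = match.arg(r_squared))
  structure(list(profile = profile, pairs = pairs, fit = fit,
                 n_cells = ncol(det), min_count = min_count,
                 line = x$line, call = cl),
            class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, ...) {
  cat("Stochastic-independence coexpression fit\n")
  if (!is.null(x$line)) cat(sprintf("  line: %s\n", x$line))
  cat(sprintf("  %d genes, %d pairs, %d cells (detection: count >= %d)\n",
              length(x$profile), nrow(x$pairs), x$n_cells, x$min_count))
  cat(sprintf("  observed = %.3f x predicted (through origin), R^2 = %.3f\n",
              x$fit$slope, x$fit$r.squared))
  invisible(x)
}

#' @export
coef.coexpr_fit <- function(object, ...) {
  c(slope = object$fit$slope)
}

#' @export
residuals.coexpr_fit <- function(object, ...) {
  setNames(object$fit$residuals,
           paste(object$pairs$gene1, object$pairs$gene2, sep = ":"))
}

#' Predict co-detection frequencies from a coexpression fit
#'
#' With `newdata` a data frame containing gene pairs (columns `gene1`,
#' `gene2`) or a numeric vector of independence-predicted frequencies,
#' returns the model prediction `slope * p * q`.
#'
#' @param object a `coexpr_fit`.
#' @param newdata pairs data frame or numeric predictor; default: the
#'   fitted pairs.
#' @param ... unused.
#' @export
predict.coexpr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$fitted)
  if (is.numeric(newdata)) return(object$fit$slope * newdata)
  stopifnot(all(c("gene1", "gene2") %in% names(newdata)))
  p <- object$profile
  object$fit$slope * as.numeric(p[newdata$gene1] * p[newdata$gene2])
}

#' @export
summary.coexpr_fit <- function(object, ...) {
  out <- object
  out$pairs$fitted <- object$fit$fitted
  out$pairs$residual <- object$fit$residuals
  class(out) <- "summary.coexpr_fit"
  out
}

#' @export
print.summary.coexpr_fit <- function(x, digits = 4, ...) {
  print.coexpr_fit(x)
  cat("\nDetection fractions:\n")
  print(round(x$profile, digits))
  cat("\nPairs (observed vs predicted):\n")
  print(format(x$pairs, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.coexpr_fit <- function(x, ...) {
  plot.default(x$pairs$predicted, x$pairs$observed,
               xlab = "predicted coexpression (p x q)",
               ylab = "observed coexpression",
               main = sprintf("y = %.3f x, R^2 = %.3f",
                              x$fit$slope, x$fit$r.squared), ...)
  abline(0, x$fit$slope)
  abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate detection matrices under the fitted independence null
#'
#' Parametric resampling: draws binary detection matrices in which each
#' gene is detected independently with its fitted marginal fraction. Useful
#' for calibrating the null distribution of the through-origin slope.
#'
#' @param object a `coexpr_fit`.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of logical genes x cells matrices.
#' @export
simulate.coexpr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(object$profile)
  n <- object$n_cells
  replicate(nsim, {
    m <- matrix(rbinom(length(genes) * n, 1L,
                       rep(object$profile, times = n)) == 1L,
                nrow = length(genes),
                dimnames = list(genes, sprintf("cell%05d", seq_len(n))))
    m
  }, simplify = FALSE)
}

#' Depth-stratified coexpression inflation diagnostic
#'
#' Splits cells into read-depth quantile strata (default quartiles) and
#' recomputes, within each stratum, the observed co-detection frequency of
#' every pair and the through-origin slope of observed against
#' within-stratum predicted frequencies. If depth heterogeneity is what
#' lifts the pooled slope above 1, the within-stratum slopes stay near 1
#' while per-pair coexpression rises monotonically with depth.
#'
#' @param x a [count_matrix()] (per-cell depth metadata used when present,
#'   else column totals) or genes x cells matrix.
#' @param genes genes or gene panels as in [coexpr_independence()].
#' @param strata number of depth quantile strata (default 4).
#' @param min_count detection threshold.
#' @return A list of class `depth_strata`: `observed` (pairs x strata
#'   matrix), `predicted` (pairs x strata), `slopes` (per-stratum
#'   through-origin slopes), `pooled_slope`, `monotone` (logical per pair:
#'   nondecreasing observed coexpression across strata),
#'   `top_ge_bottom` (logical per pair), `n_per_stratum`.
#' @export
depth_inflation <- function(x, genes = NULL, strata = 4, min_count = 1) {
  x <- as_count_input(x)
  depth <- cell_depth(x)
  n <- length(depth)
  if (n < strata) stop("fewer cells than strata")
  det <- detect(x, min_count = min_count)
  if (is.null(genes)) genes <- rownames(det)
  panels <- if (is.list(genes)) genes else list(genes)
  allg <- unique(unlist(panels))
  pairs <- unique(do.call(rbind, lapply(panels, function(p)
    if (length(p) >= 2L) all_pairs(sort(p)) else NULL)))
  # quantile strata by depth rank; ties broken by cell order for stability
  stratum <- cut(rank(depth, ties.method = "first"),
                 breaks = seq(0, n, length.out = strata + 1),
                 labels = FALSE, include.lowest = TRUE)
  pair_lab <- paste(pairs$gene1, pairs$gene2, sep = ":")
  obs <- pred <- matrix(NA_real_, nrow = nrow(pairs), ncol = strata,
                        dimnames = list(pair_lab, paste0("Q", seq_len(strata))))
  slopes <- numeric(strata)
  for (s in seq_len(strata)) {
    idx <- stratum == s
    dsub <- det[allg, idx, drop = FALSE]
    p <- rowMeans(dsub)
    obs[, s] <- mapply(function(a, b) mean(dsub[a, ] & dsub[b, ]),
                       pairs$gene1, pairs$gene2)
    pred[, s] <- p[pairs$gene1] * p[pairs$gene2]
    slopes[s] <- fit_through_origin(pred[, s], obs[, s])$slope
  }
  pooled <- coexpr_independence(x, genes = genes, min_count = min_count)
  monotone <- apply(obs, 1L, function(v) all(diff(v) >= 0))
  structure(list(observed = obs, predicted = pred, slopes = slopes,
                 pooled_slope = unname(coef(pooled)), monotone = monotone,
                 top_ge_bottom = obs[, strata] >= obs[, 1L],
                 n_per_stratum = tabulate(stratum, strata)),
            class = "depth_strata")
}

#' @export
print.depth_strata <- function(x, ...) {
  k <- length(x$slopes)
  cat(sprintf("Depth-stratified coexpression (%d strata, %d pairs)\n",
              k, nrow(x$observed)))
  cat(sprintf("  within-stratum slopes: %s\n",
              paste(sprintf("%.3f", x$slopes), collapse = ", ")))
  cat(sprintf("  pooled slope: %.3f\n", x$pooled_slope))
  cat(sprintf("  pairs with nondecreasing coexpression across strata: %d/%d\n",
              sum(x$monotone), length(x$monotone)))
  invisible(x)
}
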