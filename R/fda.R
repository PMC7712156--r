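#' Fit a two-class Fisher discriminant model
#'
#' Finds the unit weight vector `W` maximizing the separation ratio
#' `J(W) = (W' S_B W) / (W' S_W W)`, where `S_B` is the class-size-weighted
#' between-class scatter `sum_k n_k (xbar_k - xbar)(xbar_k - xbar)'` and
#' `S_W` the class-size-weighted within-class scatter
#' `sum_k n_k sum_{i in k} (x_i - xbar_k)(x_i - xbar_k)'`.  For two classes
#' the maximizer is the closed form `W proportional to
#' S_W^{-1} (xbar_pos - xbar_neg)`, equal (up to scale) to the leading
#' generalized eigenvector of `(S_B, S_W)`.  `W` is normalized to unit
#' Euclidean norm and oriented so the positive class (by default `"ASD"`)
#' has the larger mean score.
#'
#' If `S_W` is numerically singular a ridge `eps * I` with
#' `eps = 1e-8 * trace(S_W) / k` is added once; if it is still singular an
#' error is raised.
#'
#' @param X numeric sample-by-feature matrix (k features).
#' @param labels two-class vector aligned with the rows of `X`.
#' @param positive label of the class oriented to higher scores (default
#'   `"ASD"`; if absent, the first label level).
#' @return An object of class `fda_model`: `metabolites` (feature names),
#'   unit `W`, class means `xbar_k`, global mean `xbar`, scatter matrices
#'   `S_B` and `S_W`, separation `J`, and `positive`.
#' @export
fit_fda <- function(X, labels, positive = "ASD") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("degenerate labels: need exactly two classes")
  if (!positive %in% cls) positive <- cls[1L]
  negative <- setdiff(cls, positive)
  n_k <- c(sum(labels == positive), sum(labels == negative))
  if (any(n_k < 2L)) stop("degenerate labels: need >= 2 samples per class")
  k <- ncol(X)
  mu_pos <- colMeans(X[labels == positive, , drop = FALSE])
  mu_neg <- colMeans(X[labels == negative, , drop = FALSE])
  mu <- colMeans(X)
  d <- mu_pos - mu_neg
  if (max(abs(d)) == 0) stop("degenerate separation: identical class means")
  S_B <- n_k[1L] * tcrossprod(mu_pos - mu) + n_k[2L] * tcrossprod(mu_neg - mu)
  C_pos <- X[labels == positive, , drop = FALSE] -
    matrix(mu_pos, n_k[1L], k, byrow = TRUE)
  C_neg <- X[labels == negative, , drop = FALSE] -
    matrix(mu_neg, n_k[2L], k, byrow = TRUE)
  S_W <- n_k[1L] * crossprod(C_pos) + n_k[2L] * crossprod(C_neg)
  W <- tryCatch(solve(S_W, d), error = function(e) NULL)
  if (is.null(W)) {
    ridge <- 1e-8 * sum(diag(S_W)) / k
    W <- tryCatch(solve(S_W + diag(ridge, k), d), error = function(e) NULL)
    if (is.null(W)) stop("singular within-class scatter")
  }
  W <- W / sqrt(sum(W^2))
  if (sum(W * d) < 0) W <- -W   # positive class on the high-score side
  J <- drop(crossprod(W, S_B %*% W) / crossprod(W, S_W %*% W))
  structure(list(metabolites = colnames(X), W = drop(W),
                 xbar_k = rbind(positive = mu_pos, negative = mu_neg),
                 xbar = mu, S_B = S_B, S_W = S_W, J = J,
                 positive = positive, negative = negative),
            class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat("<fda_model> k = ", length(x$W), " (",
      paste(x$metabolites, collapse = ", "), "), J = ",
      format(x$J, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Project samples onto the discriminant axis
#'
#' Discriminant score of sample i is `W' x_i` (no centering offset, so
#' thresholds derived from training scores apply directly).
#'
#' @param model an [fit_fda()] model.
#' @param X numeric matrix whose columns match `model$metabolites` (checked
#'   by name when column names are present).
#' @return Numeric vector of scores.
#' @export
fda_project <- function(model, X) {
  stopifnot(inherits(model, "fda_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$W))
    stop("feature misalignment: expected ", length(model$W), " columns")
  if (!is.null(colnames(X)) && !is.null(model$metabolites) &&
      !identical(colnames(X), model$metabolites))
    stop("feature misalignment: column order does not match the model")
  drop(X %*% model$W)
}

#' @export
predict.fda_model <- function(object, newdata, ...) fda_project(object, newdata)

#' Gaussian kernel density of discriminant scores
#'
#' Smooths a set of scores with a Gaussian kernel using Silverman's
#' rule-of-thumb bandwidth.  The PDF is the kernel mixture and the CDF its
#' analytic integral (a mean of Gaussian CDFs), so no grid approximation is
#' involved.
#'
#' @param scores numeric vector with at least two distinct values.
#' @param bw optional bandwidth override.
#' @return An object of class `score_density`: functions `pdf` and `cdf`,
#'   the `bandwidth`, and the source `scores`.
#' @export
fit_kde <- function(scores, bw = NULL) {
  scores <- scores[!is.na(scores)]
  if (length(unique(scores)) < 2L)
    stop("degenerate scores: need at least 2 distinct values")
  h <- bw %||% bw.nrd0(scores)
  structure(list(
    pdf = function(x) vapply(x, function(q) mean(dnorm(q, scores, h)),
                             numeric(1)),
    cdf = function(x) vapply(x, function(q) mean(pnorm(q, scores, h)),
                             numeric(1)),
    bandwidth = h, scores = scores), class = "score_density")
}

#' @export
print.score_density <- function(x, ...) {
  cat("<score_density> n = ", length(x$scores), ", bandwidth = ",
      format(x$bandwidth, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Classification threshold at a target Type II error
#'
#' Inverts the smoothed CDF of the positive-class (treated-cohort) score
#' density by monotone bisection: the returned threshold `t` satisfies
#' `CDF(t) = beta` to within 1e-6, so classifying `score >= t` as positive
#' incurs Type II (false negative) error `beta` on the smoothed density.
#'
#' @param density a [fit_kde()] density of positive-class scores.
#' @param beta target Type II error in (0, 1).
#' @param tol bisection tolerance on the CDF scale (default 1e-6).
#' @return An object of class `threshold_spec` with elements `beta` and
#'   `threshold`.
#' @export
threshold_at_beta <- function(density, beta, tol = 1e-6) {
  stopifnot(inherits(density, "score_density"), beta > 0, beta < 1)
  h <- density$bandwidth
  lo <- min(density$scores) - 10 * h
  hi <- max(density$scores) + 10 * h
  while (density$cdf(lo) > beta) lo <- lo - 10 * h
  while (density$cdf(hi) < beta) hi <- hi + 10 * h
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- density$cdf(mid)
    if (abs(fm - beta) < tol) break
    if (fm < beta) lo <- mid else hi <- mid
  }
  structure(list(beta = beta, threshold = mid), class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec> beta = ", x$beta, ", threshold = ",
      format(x$threshold, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Export a density on a grid
#'
#' Evaluates the PDF and CDF on an equally spaced grid spanning the score
#' range plus five bandwidths on each side, for plotting or TSV export.
#'
#' @param density a [fit_kde()] density.
#' @param n grid size (default 512).
#' @return Data frame with columns `score`, `pdf`, `cdf`.
#' @export
density_grid <- function(density, n = 512L) {
  stopifnot(inherits(density, "score_density"))
  h <- density$bandwidth
  x <- seq(min(density$scores) - 5 * h, max(density$scores) + 5 * h,
           length.out = n)
  data.frame(score = x, pdf = density$pdf(x), cdf = density$cdf(x))
}

#' Serialize a fitted model, thresholds and bandwidth to JSON
#'
#' @param model an [fit_fda()] model.
#' @param thresholds optional list of `threshold_spec` objects.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_fda_model <- function(model, path, thresholds = NULL) {
  obj <- list(metabolites = model$metabolites, W = model$W, J = model$J,
              positive = model$positive)
  if (!is.null(thresholds))
    obj$thresholds <- lapply(thresholds, function(t)
      list(beta = t$beta, threshold = t$threshold))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
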