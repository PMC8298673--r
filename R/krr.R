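## Kernel ridge regression machinery.
##
## One shared kernel serves all distance targets: training solves
## (K + lambda I) alpha = Y once for the whole N x T target block (a single
## symmetric factorization), so adding targets is free.  Hyperparameters
## (kernel family, sigma, lambda) are shared across targets and chosen by
## grid search with nested fivefold cross-validation.

KERNEL_FAMILIES <- c("laplacian", "gaussian")

## pairwise distances between row sets; "l1" or squared "l2sq"
.cross_dist <- function(Xa, Xb, type) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb)) stop("feature dimension mismatch")
  if (type == "l1") {
    D <- matrix(0, nrow(Xa), nrow(Xb))
    for (k in seq_len(ncol(Xa)))
      D <- D + abs(outer(Xa[, k], Xb[, k], "-"))
    D
  } else {
    D <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * tcrossprod(Xa, Xb)
    pmax(D, 0)
  }
}

.dist_type <- function(family) if (family == "laplacian") "l1" else "l2sq"

.kernel_from_dist <- function(D, family, sigma) {
  if (family == "laplacian") exp(-D / sigma) else exp(-D / (2 * sigma^2))
}

#' Kernel matrix between two feature sets
#'
#' Laplacian kernel \eqn{\exp(-\lVert x_i - x_j\rVert_1 / \sigma)} or
#' Gaussian kernel \eqn{\exp(-\lVert x_i - x_j\rVert_2^2 / 2\sigma^2)}.
#'
#' @param Xa,Xb Feature matrices (rows = samples).
#' @param family \code{"laplacian"} or \code{"gaussian"}.
#' @param sigma Kernel width (> 0).
#' @return \code{nrow(Xa)} x \code{nrow(Xb)} matrix with entries in (0, 1].
#' @export
kernel_matrix <- function(Xa, Xb, family = c("laplacian", "gaussian"),
                          sigma) {
  family <- match.arg(family)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (!all(is.finite(as.matrix(Xa))) || !all(is.finite(as.matrix(Xb))))
    stop("non-finite feature values")
  .kernel_from_dist(.cross_dist(Xa, Xb, .dist_type(family)), family, sigma)
}

## solve (K + (lam + jitter) I) A = Y by Cholesky, escalating jitter
## 1e-10 -> 1e-6 if the factorization fails
.chol_solve <- function(K, lam, Y) {
  for (jit in c(0, 10^seq(-10, -6))) {
    R <- tryCatch(chol(K + diag(lam + jit, nrow(K))),
                  error = function(e) NULL)
    if (!is.null(R))
      return(backsolve(R, backsolve(R, Y, transpose = TRUE)))
  }
  stop("kernel matrix factorization failed even with jitter up to 1e-6")
}

#' Fit a multi-output kernel ridge regression model
#'
#' Solves \eqn{\alpha = (K + \lambda I)^{-1} Y} once for all target columns
#' via a Cholesky factorization (with documented jitter escalation on
#' failure).
#'
#' @param X N x d training feature matrix.
#' @param Y N x T target matrix (or length-N vector).
#' @param family Kernel family.
#' @param sigma Kernel width.
#' @param lam Regularization strength (>= 0).
#' @param target_names Optional names for the T targets.
#' @return Object of class \code{kernel_model}.
#' @export
krr_fit <- function(X, Y, family = c("laplacian", "gaussian"), sigma, lam,
                    target_names = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (lam < 0) stop("lam must be nonnegative")
  K <- kernel_matrix(X, X, family, sigma)
  alpha <- .chol_solve(K, lam, Y)
  if (is.null(target_names)) target_names <- colnames(Y)
  structure(list(kernel_family = family, sigma = sigma, lam = lam,
                 training_features = X, coefficients = alpha,
                 target_names = target_names),
            class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("<kernel_model> %s kernel, sigma=%.4g, lambda=%.3g, N=%d, T=%d\n",
              x$kernel_family, x$sigma, x$lam, nrow(x$training_features),
              ncol(x$coefficients)))
  invisible(x)
}

#' Predict targets for query features
#'
#' @param model A \code{kernel_model}.
#' @param X_query Query feature matrix (rows = queries).
#' @return Queries x T matrix of predictions.
#' @export
krr_predict <- function(model, X_query) {
  Xq <- as.matrix(X_query)
  if (ncol(Xq) != ncol(model$training_features))
    stop("query feature dimension ", ncol(Xq), " does not match training (",
         ncol(model$training_features), ")")
  Kq <- kernel_matrix(Xq, model$training_features, model$kernel_family,
                      model$sigma)
  P <- Kq %*% model$coefficients
  colnames(P) <- model$target_names
  P
}

#' Hyperparameter grid
#'
#' @param sigma_values Kernel widths; NULL means a data-driven grid of 13
#'   log-spaced factors in [0.05, 20] times the median nonzero pairwise
#'   feature distance (computed per kernel family at search time).
#' @param lambda_values Regularization strengths (default decades 1e-10 to
#'   1e-3).
#' @param kernel_families Subset of \code{c("laplacian", "gaussian")}.
#' @return Object of class \code{hyper_grid}.
#' @export
hyper_grid <- function(sigma_values = NULL,
                       lambda_values = 10^seq(-10, -3),
                       kernel_families = c("laplacian", "gaussian")) {
  kernel_families <- match.arg(kernel_families, KERNEL_FAMILIES,
                               several.ok = TRUE)
  if (length(lambda_values) == 0L) stop("empty lambda grid")
  structure(list(sigma_values = sigma_values,
                 lambda_values = lambda_values,
                 kernel_families = kernel_families),
            class = "hyper_grid")
}

## resolve data-driven sigma values for one family
.sigma_grid <- function(grid, D) {
  if (!is.null(grid$sigma_values)) return(grid$sigma_values)
  med <- stats::median(D[upper.tri(D)][D[upper.tri(D)] > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  med * exp(seq(log(0.05), log(20), length.out = 13))
}

.make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

## mean CV MAE of one (family, sigma, lambda) given a precomputed full
## distance matrix; folds is an integer fold-id vector
.cv_score <- function(D, Y, folds, family, sigma, lam) {
  errs <- vapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    K <- .kernel_from_dist(D[tr, tr, drop = FALSE], family, sigma)
    a <- tryCatch(.chol_solve(K, lam, Y[tr, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(a)) return(NA_real_)
    P <- .kernel_from_dist(D[te, tr, drop = FALSE], family, sigma) %*% a
    mean(abs(P - Y[te, , drop = FALSE]))
  }, numeric(1))
  mean(errs)
}

#' Grid search with nested fivefold cross-validation
#'
#' Inner folds choose the (kernel family, sigma, lambda) triple minimizing
#' the mean MAE over all targets; outer folds report an unbiased MAE for the
#' winning triple.  One shared triple serves all targets.  The final model is
#' refit on all data with the hyperparameters that win most inner contests
#' (ties broken by mean inner score).
#'
#' @param X Feature matrix (N >= 25).
#' @param Y Target matrix.
#' @param grid A \code{\link{hyper_grid}}.
#' @param k_outer,k_inner Fold counts (default 5).
#' @param seed Integer seed driving all fold assignments.
#' @return List with \code{best} (family, sigma, lambda), \code{outer_mae}
#'   (per outer fold), \code{cv_table} (all combos with mean inner MAE) and
#'   \code{model} (final refit \code{kernel_model}).
#' @export
nested_cv_search <- function(X, Y, grid = hyper_grid(), k_outer = 5,
                             k_inner = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 25) stop("nested CV needs N >= 25 (got ", n, ")")
  Dfull <- lapply(stats::setNames(nm = grid$kernel_families), function(fam)
    .cross_dist(X, X, .dist_type(fam)))
  combos <- do.call(rbind, lapply(grid$kernel_families, function(fam) {
    expand.grid(family = fam, sigma = .sigma_grid(grid, Dfull[[fam]]),
                lambda = grid$lambda_values, stringsAsFactors = FALSE)
  }))

  .with_seed(seed, function() {
    outer_folds <- .make_folds(n, k_outer)
    inner_scores <- matrix(NA_real_, nrow(combos), k_outer)
    outer_mae <- numeric(k_outer)
    winners <- integer(k_outer)
    for (f in seq_len(k_outer)) {
      tr <- which(outer_folds != f); te <- which(outer_folds == f)
      inner_folds <- .make_folds(length(tr), k_inner)
      for (ci in seq_len(nrow(combos))) {
        fam <- combos$family[ci]
        inner_scores[ci, f] <- .cv_score(
          Dfull[[fam]][tr, tr, drop = FALSE], Y[tr, , drop = FALSE],
          inner_folds, fam, combos$sigma[ci], combos$lambda[ci])
      }
      if (all(is.na(inner_scores[, f])))
        stop("hyperparameter grid exhausted: all inner CV scores are NaN")
      w <- which.min(inner_scores[, f])
      winners[f] <- w
      fam <- combos$family[w]
      K <- .kernel_from_dist(Dfull[[fam]][tr, tr, drop = FALSE], fam,
                             combos$sigma[w])
      a <- .chol_solve(K, combos$lambda[w], Y[tr, , drop = FALSE])
      P <- .kernel_from_dist(Dfull[[fam]][te, tr, drop = FALSE], fam,
                             combos$sigma[w]) %*% a
      outer_mae[f] <- mean(abs(P - Y[te, , drop = FALSE]))
    }
    ## overall winner: most inner wins, ties by mean inner score
    tab <- table(winners)
    top <- as.integer(names(tab)[tab == max(tab)])
    mean_score <- rowMeans(inner_scores)
    best_i <- top[which.min(mean_score[top])]
    best <- list(family = combos$family[best_i],
                 sigma = combos$sigma[best_i],
                 lambda = combos$lambda[best_i])
    model <- krr_fit(X, Y, best$family, best$sigma, best$lambda,
                     target_names = colnames(Y))
    cv_table <- cbind(combos, mean_inner_mae = mean_score)
    list(best = best, outer_mae = outer_mae, cv_table = cv_table,
         model = model)
  })
}

## plain k-fold CV selection (used where the nested protocol would be
## disproportionate, e.g. inside learning curves); same scoring machinery
.cv_select <- function(X, Y, grid = hyper_grid(), k = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Dfull <- lapply(stats::setNames(nm = grid$kernel_families), function(fam)
    .cross_dist(X, X, .dist_type(fam)))
  combos <- do.call(rbind, lapply(grid$kernel_families, function(fam) {
    expand.grid(family = fam, sigma = .sigma_grid(grid, Dfull[[fam]]),
                lambda = grid$lambda_values, stringsAsFactors = FALSE)
  }))
  .with_seed(seed, function() {
    folds <- .make_folds(nrow(X), k)
    scores <- vapply(seq_len(nrow(combos)), function(ci)
      .cv_score(Dfull[[combos$family[ci]]], Y, folds, combos$family[ci],
                combos$sigma[ci], combos$lambda[ci]), numeric(1))
    w <- which.min(scores)
    list(family = combos$family[w], sigma = combos$sigma[w],
         lambda = combos$lambda[w], score = scores[w])
  })
}

#' Learning curve of test MAE versus training-set size
#'
#' Holds out a fixed seeded test set, then for each requested size draws
#' repeated random training subsets from the remaining pool, fits, and
#' records the distance MAE on the held-out set.
#'
#' @param X,Y Features and targets.
#' @param train_sizes Increasing vector of training-set sizes.
#' @param n_repeats Random subsets per size (default 5).
#' @param seed Integer seed for the split and every subset draw.
#' @param test_size Held-out test count (default 20\% of N).
#' @param hyper Optional list(family, sigma, lambda); if NULL, selected once
#'   on the full training pool by fivefold CV.
#' @param grid \code{\link{hyper_grid}} used when \code{hyper} is NULL.
#' @return data.frame with one row per size: \code{n_train},
#'   \code{mae_mean}, \code{mae_sd}, \code{mae_se}, plus per-repeat MAEs in
#'   attribute \code{"repeats"}.
#' @export
learning_curve <- function(X, Y, train_sizes, n_repeats = 5, seed = 1,
                           test_size = NULL, hyper = NULL,
                           grid = hyper_grid()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(test_size)) test_size <- max(1L, round(0.2 * n))
  if (max(train_sizes) + test_size > n)
    stop("max train size + test size exceeds available data (", n, ")")
  .with_seed(seed, function() {
    test_idx <- sample.int(n, test_size)
    pool <- setdiff(seq_len(n), test_idx)
    if (is.null(hyper))
      hyper <- .cv_select(X[pool, , drop = FALSE], Y[pool, , drop = FALSE],
                          grid = grid, k = 5,
                          seed = sample.int(2^31 - 1, 1))
    reps <- matrix(NA_real_, length(train_sizes), n_repeats)
    for (si in seq_along(train_sizes)) {
      for (ri in seq_len(n_repeats)) {
        tr <- sample(pool, train_sizes[si])
        m <- krr_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     hyper$family, hyper$sigma, hyper$lambda)
        P <- krr_predict(m, X[test_idx, , drop = FALSE])
        reps[si, ri] <- mean(abs(P - Y[test_idx, , drop = FALSE]))
      }
    }
    out <- data.frame(n_train = train_sizes,
                      mae_mean = rowMeans(reps),
                      mae_sd = apply(reps, 1, stats::sd),
                      mae_se = apply(reps, 1, stats::sd) / sqrt(n_repeats))
    attr(out, "repeats") <- reps
    attr(out, "hyper") <- hyper
    out
  })
}
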