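## Penalized least squares for rERP estimation.  The objective is
##   || X b - Y ||^2 + lambda || L b ||^2
## whose unique minimizer solves (X'X + lambda L'L) b = X'Y.  L is the
## scaled first difference (rows 1/2 * (e_j - e_{j+1})) restricted within
## component blocks so unrelated waveforms are never smoothed together.
## A "literal" mode using lambda*L instead of lambda*L'L in the normal
## equations is kept for audit; it does not minimize the stated objective
## and is off by default.

#' First-derivative (smoothness) penalty operator
#'
#' Within each block of `b` consecutive columns, contributes `b - 1` rows
#' of the form `0.5 * (e_j - e_{j+1})`; no row couples adjacent blocks.
#'
#' @param p total number of predictors.
#' @param block_boundaries 0-based column indices where blocks start
#'   (default: one block).
#' @return sparse `(p - n_blocks) x p` matrix.
#' @export
make_first_derivative_operator <- function(p, block_boundaries = 0L) {
  p <- check_count(p, "p", min = 2L)
  block_boundaries <- sort(unique(as.integer(block_boundaries)))
  if (block_boundaries[1] != 0L) stop_invalid("first block must start at column 0")
  starts <- block_boundaries + 1L
  ends <- c(block_boundaries[-1], p)
  ii <- list(); jj <- list(); xx <- list(); row0 <- 0L
  for (k in seq_along(starts)) {
    b <- ends[k] - starts[k] + 1L
    if (b < 2L) next            # width-1 block contributes no rows
    r <- row0 + seq_len(b - 1L)
    j <- starts[k] + seq_len(b - 1L) - 1L
    ii[[length(ii) + 1L]] <- c(r, r)
    jj[[length(jj) + 1L]] <- c(j, j + 1L)
    xx[[length(xx) + 1L]] <- c(rep(0.5, b - 1L), rep(-0.5, b - 1L))
    row0 <- row0 + b - 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(row0, p))
}

## block boundaries (0-based) of a design's component blocks
design_block_boundaries <- function(columns) {
  comp <- columns$component
  c(0L, which(comp[-1] != comp[-length(comp)]))
}

## Solve (X'X + lambda * P) B = X'Y for all channels at once.
## XtX, XtY precomputed; falls back to the pseudoinverse when singular.
solve_normal <- function(XtX, XtY, P, lambda) {
  A <- as.matrix(XtX) + lambda * as.matrix(P)
  B <- as.matrix(XtY)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(backsolve(ch, backsolve(ch, B, transpose = TRUE)))
  warning("normal equations singular; using minimum-norm (pseudoinverse) solution",
          call. = FALSE)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% B) / sv$d[pos])
}

#' Fit the rERP model
#'
#' Estimates per-channel coefficient vectors by Tikhonov-penalized least
#' squares on the assembled design.
#'
#' @param design a `rerp_design` from [assemble_design()].
#' @param lambda regularization weight (>= 0); 0 gives ordinary least
#'   squares (minimum-norm if rank deficient, with a warning).
#' @param L penalty operator; defaults to the blockwise first-derivative
#'   operator over the design's component blocks.
#' @param literal if `TRUE`, reproduce the normal-equation variant
#'   `(X'X + lambda L)^{-1} X'Y` (audit mode; not the objective's minimizer).
#' @return a `rerp_fit`: `beta` (channels x predictors), `fitted`,
#'   `residual` (channels x retained samples), `columns`, `lambda`.
#' @export
fit_rerp <- function(design, lambda = 0,
                     L = make_first_derivative_operator(
                       ncol(design$X), design_block_boundaries(design$columns)),
                     literal = FALSE) {
  stopifnot(inherits(design, "rerp_design"))
  check_scalar_number(lambda, "lambda", nonnegative = TRUE)
  X <- design$X
  Y <- design$Y
  if (!all(is.finite(Y))) stop_invalid("Y contains non-finite values")
  XtX <- Matrix::crossprod(X)
  XtY <- Matrix::crossprod(X, t(Y))
  P <- if (literal) L else Matrix::crossprod(L)
  if (literal && nrow(L) != ncol(L))
    stop_invalid("literal mode needs a square penalty; pad L or use the default")
  beta <- t(solve_normal(XtX, XtY, P, lambda))
  rownames(beta) <- design$channel_labels
  fitted <- as.matrix(Matrix::tcrossprod(beta, X))
  structure(list(beta = beta, fitted = fitted, residual = Y - fitted,
                 columns = design$columns, lambda = lambda,
                 channel_labels = design$channel_labels),
            class = "rerp_fit")
}

#' @export
print.rerp_fit <- function(x, ...) {
  cat(sprintf("<rerp_fit> %d channels, %d predictors, lambda = %g\n",
              nrow(x$beta), ncol(x$beta), x$lambda))
  invisible(x)
}

#' Extract an estimated waveform from a fit
#'
#' @param fit a `rerp_fit`.
#' @param component component name (`"cue"`, `"response"`, `"scaled"`, ...).
#' @return channels x points matrix with an `axis` attribute: lag in ms for
#'   fixed components, elapsed fraction for the scaled component.
#' @export
get_waveform <- function(fit, component) {
  idx <- which(fit$columns$component == component)
  if (length(idx) == 0L) stop_invalid("no component named '%s' in fit", component)
  w <- fit$beta[, idx, drop = FALSE]
  attr(w, "axis") <- if (component == "scaled")
    fit$columns$elapsed_fraction[idx] else fit$columns$lag_ms[idx]
  w
}

#' The nine-candidate regularization grid
#' @return numeric vector `c(0.001, 0.01, 0, 1, 10, 100, 1000, 1e4, 1e5)`.
#' @export
default_lambda_grid <- function() c(0.001, 0.01, 0, 1, 10, 100, 1000, 1e4, 1e5)

#' Choose lambda by k-fold cross-validation at one channel
#'
#' Retained samples are split into `k` contiguous blocks (respecting
#' temporal autocorrelation; set `contiguous = FALSE` for a seeded random
#' partition).  For each fold and candidate, the model is fit on the other
#' folds and the mean squared residual recorded at the held-out block; the
#' chosen lambda minimizes the across-fold mean, ties broken toward the
#' larger candidate.
#'
#' @param design a `rerp_design`.
#' @param channel channel index or label whose error is minimized.
#' @param grid candidate lambdas, default [default_lambda_grid()].
#' @param k number of folds (default 10).
#' @param contiguous contiguous temporal folds (default) or random.
#' @param literal passed to the solver.
#' @param seed used only when `contiguous = FALSE`.
#' @return a `cv_report`: `grid`, `fold_mse` (folds x grid),
#'   `chosen_lambda`, `fold_assignment`.
#' @export
cross_validate_lambda <- function(design, channel = 1L,
                                  grid = default_lambda_grid(), k = 10L,
                                  contiguous = TRUE, literal = FALSE,
                                  seed = NULL) {
  stopifnot(inherits(design, "rerp_design"))
  k <- check_count(k, "k", min = 2L)
  if (length(grid) == 0L) stop_invalid("empty lambda grid")
  if (is.character(channel)) channel <- match(channel, design$channel_labels)
  n <- nrow(design$X)
  y <- design$Y[channel, ]
  fold <- if (contiguous) {
    as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample(rep_len(seq_len(k), n))
  }
  L <- make_first_derivative_operator(ncol(design$X),
                                      design_block_boundaries(design$columns))
  P <- if (literal) L else Matrix::crossprod(L)

  ## per-fold Gram pieces so each train system is a cheap subtraction
  XtX_f <- vector("list", k); Xty_f <- vector("list", k)
  for (f in seq_len(k)) {
    Xf <- design$X[fold == f, , drop = FALSE]
    XtX_f[[f]] <- Matrix::crossprod(Xf)
    Xty_f[[f]] <- Matrix::crossprod(Xf, y[fold == f])
  }
  XtX <- Reduce(`+`, XtX_f)
  Xty <- Reduce(`+`, Xty_f)

  fold_mse <- matrix(NA_real_, k, length(grid),
                     dimnames = list(NULL, as.character(grid)))
  Pd <- as.matrix(P)
  for (f in seq_len(k)) {
    test <- fold == f
    Xf <- design$X[test, , drop = FALSE]
    if (sum(Matrix::rowSums(abs(Xf)) > 0) == 0L) next  # fold with no active rows
    A <- as.matrix(XtX - XtX_f[[f]])
    b <- as.matrix(Xty - Xty_f[[f]])
    for (g in seq_along(grid)) {
      beta <- solve_normal(A, b, Pd, grid[g])
      fold_mse[f, g] <- mean((y[test] - as.numeric(Xf %*% beta))^2)
    }
  }
  mean_mse <- colMeans(fold_mse, na.rm = TRUE)
  ## ties broken toward the larger candidate
  minimizers <- which(mean_mse == min(mean_mse))
  chosen <- grid[minimizers[which.max(grid[minimizers])]]
  structure(list(grid = grid, fold_mse = fold_mse, chosen_lambda = chosen,
                 fold_assignment = fold, channel = channel),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- colMeans(x$fold_mse, na.rm = TRUE)
  cat("<cv_report> mean MSE by lambda:\n")
  print(round(m, 4))
  cat(sprintf("chosen lambda: %g\n", x$chosen_lambda))
  invisible(x)
}

#' Compare the full model with a fixed-components-only model
#'
#' Mean squared residual over the samples where fixed regressors are
#' active (and over all channels), for two fits estimated on identical
#' rows.
#'
#' @param fit_full,fit_fixed_only `rerp_fit`s on the same rows.
#' @param active logical mask over retained rows (see
#'   [fixed_active_mask()]).
#' @return list `mse_full`, `mse_fixed_only`, `difference`
#'   (full minus fixed-only), `n_samples`.
#' @export
compare_models <- function(fit_full, fit_fixed_only, active) {
  if (ncol(fit_full$residual) != ncol(fit_fixed_only$residual))
    stop_invalid("fits were not estimated on identical rows")
  if (!any(active)) stop_invalid("empty active mask")
  mse <- function(fit) mean(fit$residual[, active, drop = FALSE]^2)
  m1 <- mse(fit_full); m2 <- mse(fit_fixed_only)
  list(mse_full = m1, mse_fixed_only = m2, difference = m1 - m2,
       n_samples = sum(active))
}
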