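## Method-validation quantities: VIF collinearity profiles, unmixed
## (fixed-only / scaled-only) reconstructions, and the temporal-scaling
## index.

#' Variance inflation factors of a design
#'
#' For each column `j`, `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from
#' regressing the (internally centered) column on all other columns with
#' an intercept.  Computed from the inverse correlation matrix when the
#' design is well conditioned, falling back to column-by-column least
#' squares otherwise.  Columns that are constant, or perfectly predicted
#' by the rest (`R2 >= 1 - 1e-12`), are reported as `Inf`.
#'
#' @param X design matrix (dense or sparse) or a `rerp_design`.
#' @param flag_level convention for reporting a high-VIF fraction
#'   (default 10).
#' @return a `vif_profile`: `vif` per column, column metadata when
#'   available, and `frac_above` at `flag_level`.
#' @export
compute_vif <- function(X, flag_level = 10) {
  columns <- NULL
  if (inherits(X, "rerp_design")) { columns <- X$columns; X <- X$X }
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop_invalid("VIF needs at least 2 columns")
  sds <- apply(X, 2, stats::sd)
  vif <- rep(Inf, p)
  est <- sds > 0
  Z <- scale(X[, est, drop = FALSE])   # center + unit variance
  R <- crossprod(Z) / (nrow(X) - 1)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(is.finite(diag(inv))) && min(diag(inv)) > 0) {
    vif[est] <- diag(inv)
  } else {
    ## near-singular: per-column R2 via least squares on the others
    cols <- which(est)
    for (jj in seq_along(cols)) {
      y <- Z[, jj]
      others <- Z[, -jj, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, others), y)
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      vif[cols[jj]] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  vif[est & vif > 1e12] <- Inf
  structure(list(vif = vif, columns = columns,
                 frac_above = mean(vif >= flag_level),
                 flag_level = flag_level),
            class = "vif_profile")
}

#' @export
print.vif_profile <- function(x, ...) {
  cat(sprintf("<vif_profile> %d predictors; median VIF %.2f; %.1f%% >= %g\n",
              length(x$vif), stats::median(x$vif[is.finite(x$vif)]),
              100 * x$frac_above, x$flag_level))
  invisible(x)
}

#' Fixed-only and scaled-only reconstructions
#'
#' Recombines the residual with either the scaled-time contribution or the
#' fixed-time contributions:
#' `scaled_only = X_scaled b_scaled + residual`,
#' `fixed_only  = X_fixed  b_fixed  + residual`.
#' By construction `fixed_only + scaled_only - residual` equals the
#' original (masked) recording.
#'
#' @param design the `rerp_design` the fit was estimated on.
#' @param fit the corresponding `rerp_fit`.
#' @return an `unmixed_datasets` list: `fixed_only` and `scaled_only`
#'   (channels x retained-samples matrices), `residual`, `row_index`.
#' @export
reconstruct_unmixed <- function(design, fit) {
  if (!identical(dim(fit$residual), dim(design$Y)))
    stop_invalid("fit does not match the design's retained rows")
  scaled_cols <- which(fit$columns$component == "scaled")
  fixed_cols <- which(fit$columns$component != "scaled")
  if (length(scaled_cols) == 0L || length(fixed_cols) == 0L)
    stop_invalid("design must contain both fixed and scaled blocks")
  contrib <- function(cols)
    as.matrix(Matrix::tcrossprod(fit$beta[, cols, drop = FALSE],
                                 design$X[, cols, drop = FALSE]))
  structure(list(fixed_only = contrib(fixed_cols) + fit$residual,
                 scaled_only = contrib(scaled_cols) + fit$residual,
                 residual = fit$residual,
                 row_index = design$row_index,
                 channel_labels = design$channel_labels),
            class = "unmixed_datasets")
}

#' Stretch ragged interval epochs to a common length and average
#'
#' Each per-trial channels x duration epoch is resampled with the box
#' kernel to `common_length` points, then averaged within condition
#' (stretch first, then average).
#'
#' @param intervals output of [interval_epochs()].
#' @param common_length target number of points (e.g. the longest
#'   condition's duration in samples).
#' @return named list per condition: channels x `common_length` mean
#'   matrix with a `duration_samples` attribute (mean original duration).
#' @export
stretch_and_average <- function(intervals, common_length) {
  common_length <- check_count(common_length, "common_length", min = 2L)
  conds <- unique(intervals$meta$condition)
  out <- list()
  for (cond in conds) {
    sel <- which(intervals$meta$condition == cond)
    acc <- 0
    for (i in sel) {
      ep <- intervals$epochs[[i]]
      R <- resize_box(ncol(ep), common_length)
      acc <- acc + t(as.matrix(R %*% t(ep)))
    }
    m <- acc / length(sel)
    attr(m, "duration_samples") <- mean(intervals$meta$duration_samples[sel])
    out[[cond]] <- m
  }
  out
}

#' Temporal-scaling index
#'
#' Quantifies post-stretch similarity between condition-average waveforms.
#' Every condition mean is resampled (box kernel) to `common_length`; for
#' each shorter condition, a simple linear regression (intercept + slope)
#' predicts the longest condition's waveform from the stretched shorter
#' one, and `R2 = 1 - SS_res / SS_tot` is recorded; the index is the mean
#' of these coefficients.  An index of 1 means the waveforms are exact
#' time-scaled copies.
#'
#' @param waveforms named list of per-condition numeric vectors (or
#'   single-channel matrices), each carrying a `duration_samples`
#'   attribute or accompanied by `durations`.
#' @param common_length points to compare at; defaults to the longest
#'   condition's length.
#' @param durations optional named durations overriding the attributes.
#' @return a `scaling_index_result`: `index`, `per_pair` R2 values,
#'   `common_length`, `longest`.
#' @export
scaling_index <- function(waveforms, common_length = NULL, durations = NULL) {
  if (length(waveforms) < 2L) stop_invalid("need >= 2 conditions")
  vecs <- lapply(waveforms, function(w) {
    if (is.matrix(w)) as.numeric(w[1, ]) else as.numeric(w)
  })
  if (is.null(durations)) {
    durations <- vapply(waveforms, function(w)
      attr(w, "duration_samples") %||% length(w), numeric(1))
  }
  if (is.null(common_length)) common_length <- length(vecs[[which.max(durations)]])
  stretch <- function(v) as.numeric(resize_box(length(v), common_length) %*% v)
  longest <- names(vecs)[which.max(durations)]
  target <- stretch(vecs[[longest]])
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot == 0) {
    warning("zero-variance target waveform; scaling index undefined", call. = FALSE)
    return(structure(list(index = NA_real_, per_pair = numeric(0),
                          common_length = common_length, longest = longest),
                     class = "scaling_index_result"))
  }
  per_pair <- c()
  for (nm in setdiff(names(vecs), longest)) {
    x <- stretch(vecs[[nm]])
    fit <- stats::lm.fit(cbind(1, x), target)
    per_pair[nm] <- 1 - sum(fit$residuals^2) / ss_tot
  }
  structure(list(index = mean(per_pair), per_pair = per_pair,
                 common_length = common_length, longest = longest),
            class = "scaling_index_result")
}

#' @export
print.scaling_index_result <- function(x, ...) {
  cat(sprintf("<scaling_index> %.4f (target: %s; pairs: %s)\n", x$index,
              x$longest,
              paste(sprintf("%s=%.3f", names(x$per_pair), x$per_pair),
                    collapse = ", ")))
  invisible(x)
}

#' Scaling index of an unmixed dataset variant
#'
#' Convenience wrapper: rebuilds a [continuous_recording()] from one
#' variant of [reconstruct_unmixed()] (gaps from masked samples are filled
#' by the variant's values on retained samples only), extracts interval
#' epochs, stretches to the longest condition and computes the index at
#' one channel.
#'
#' @param unmixed an `unmixed_datasets`.
#' @param variant `"fixed_only"` or `"scaled_only"`.
#' @param events event table (samples must index the original recording).
#' @param fs sampling rate.
#' @param n_original original recording length in samples.
#' @param channel channel index used for the index.
#' @return a `scaling_index_result`.
#' @export
scaling_index_of_variant <- function(unmixed, variant, events, fs, n_original,
                                     channel = 1L) {
  stopifnot(inherits(unmixed, "unmixed_datasets"))
  mat <- matrix(0, nrow(unmixed[[variant]]), n_original)
  mat[, unmixed$row_index] <- unmixed[[variant]]
  rec <- continuous_recording(mat, fs, unmixed$channel_labels)
  iv <- interval_epochs(rec, events)
  common <- max(iv$meta$duration_samples)
  means <- stretch_and_average(iv, common)
  means1 <- lapply(means, function(m) {
    v <- m[channel, ]
    attr(v, "duration_samples") <- attr(m, "duration_samples")
    v
  })
  scaling_index(means1, common_length = common)
}
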