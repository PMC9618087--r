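#' Box (area-averaging) resampling operator
#'
#' Builds the piecewise-constant resampling matrix that stretches or
#' compresses a length-`basis_len` series to `target_len` points.  Entry
#' `(d, j)` is the fractional overlap of target bin `d` -- the interval
#' `[d/target_len, (d+1)/target_len)` on the unit interval -- with basis bin
#' `j`, normalized so that every row sums to 1.  Multiplying a basis-length
#' vector by the operator yields its area-averaged ("box" kernel)
#' resampling; amplitudes are preserved, not integrals, so a constant
#' series stays constant at any target length.
#'
#' This operator is what gives the scaled-time regressor its variable
#' temporal support: one shared basis of `n_points` columns is mapped onto
#' each trial's own cue-to-response duration.
#'
#' @param basis_len number of points in the source grid (columns).
#' @param target_len number of points in the destination grid (rows).
#' @param sparse return a `Matrix::sparseMatrix` (default) or a base matrix.
#' @return a `target_len x basis_len` matrix with unit row sums.
#' @examples
#' resize_box(2, 4, sparse = FALSE)   # each basis bin duplicated
#' resize_box(5, 5, sparse = FALSE)   # identity
#' @export
resize_box <- function(basis_len, target_len, sparse = TRUE) {
  basis_len <- check_count(basis_len, "basis_len", min = 1L)
  target_len <- check_count(target_len, "target_len", min = 1L)

  ## overlap of [d, d+1) * basis_len / target_len with integer basis bins
  lo <- (seq_len(target_len) - 1L) * basis_len / target_len
  hi <- seq_len(target_len) * basis_len / target_len
  first <- floor(lo)
  last <- pmin(ceiling(hi) - 1, basis_len - 1)

  counts <- as.integer(last - first + 1)
  rows <- rep.int(seq_len(target_len), counts)
  cols <- sequence(counts, from = as.integer(first) + 1L)
  w <- pmin(hi[rows], cols) - pmax(lo[rows], cols - 1)
  keep <- w > 1e-15
  width <- basis_len / target_len
  M <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = w[keep] / width,
                            dims = c(target_len, basis_len))
  if (sparse) M else as.matrix(M)
}
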