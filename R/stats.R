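## Inference machinery for scaled-time waveforms: single-sample t maps,
## spatiotemporal cluster-based sign-flip permutation testing, paired t
## with Cohen's d, PCA latency analysis, and one-way repeated-measures
## ANOVA with partial / generalized eta squared.

#' Single-sample t map
#'
#' t statistic against zero at every electrode x point cell.
#'
#' @param waveforms participants x electrodes x points array (electrode
#'   dimnames recommended).
#' @param alpha two-sided cell-level alpha for the critical threshold.
#' @return a `tmap`: `t` (electrodes x points; `Inf` where the
#'   across-participant SD is zero but the mean is not), `df`,
#'   `critical_t`, `zero_variance` flag matrix.
#' @export
one_sample_tmap <- function(waveforms, alpha = 0.05) {
  d <- dim(waveforms)
  if (length(d) != 3L || d[1] < 3L)
    stop_invalid("waveforms must be participants x electrodes x points with >= 3 participants")
  n <- d[1]
  flat <- matrix(waveforms, nrow = n)          # n x (E*P)
  m <- colMeans(flat)
  v <- (colSums(flat^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  tm <- matrix(t, d[2], d[3], dimnames = list(dimnames(waveforms)[[2]], NULL))
  structure(list(t = tm, df = n - 1,
                 critical_t = stats::qt(1 - alpha / 2, n - 1),
                 zero_variance = matrix(se == 0, d[2], d[3])),
            class = "tmap")
}

#' Read an electrode neighbor graph
#'
#' Plain-text adjacency list, one line per electrode:
#' `Cz: C3 C4 FCz CPz`.  The graph is symmetrized (an edge listed on
#' either side counts).
#'
#' @param path file path; default is the packaged 10-20 montage template.
#' @return named list of neighbor character vectors.
#' @export
read_neighbor_graph <- function(path = system.file("extdata", "neighbors_1020.txt",
                                                   package = "scalerp")) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  parts <- strsplit(lines, ":")
  g <- stats::setNames(
    lapply(parts, function(p) strsplit(trimws(p[2]), "\\s+")[[1]]),
    trimws(vapply(parts, `[[`, "", 1)))
  ## symmetrize
  for (e in names(g)) for (nb in g[[e]]) {
    if (!nb %in% names(g)) g[[nb]] <- character(0)
    if (!e %in% g[[nb]]) g[[nb]] <- c(g[[nb]], e)
  }
  g
}

## spatial cluster per electrode: the electrode plus its graph neighbors
## restricted to the analysis set
spatial_clusters <- function(electrodes, graph) {
  lapply(stats::setNames(electrodes, electrodes), function(e) {
    nbs <- graph[[e]] %||% character(0)
    unique(c(e, intersect(nbs, electrodes)))
  })
}

## temporal clusters of a spatial set: maximal runs where the rule holds;
## returns data.frame(start, end, mass); mass = spatial mean of summed |t|
temporal_clusters <- function(absT, members, crit, rule = "all") {
  sub <- absT[members, , drop = FALSE]
  nm <- length(members)
  hits <- .colSums(sub > crit, nm, ncol(sub))
  exceeds <- if (rule == "all") hits == nm else hits > 0
  if (!any(exceeds)) return(NULL)
  r <- rle(exceeds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cs <- c(0, cumsum(.colSums(sub, nm, ncol(sub))))
  data.frame(start = starts[runs], end = ends[runs],
             mass = (cs[ends[runs] + 1L] - cs[starts[runs]]) / nm)
}

## fast path for the permutation loop: only the maximum mass is needed
max_cluster_mass <- function(absT, members, crit, rule = "all") {
  sub <- absT[members, , drop = FALSE]
  nm <- length(members)
  hits <- .colSums(sub > crit, nm, ncol(sub))
  exceeds <- if (rule == "all") hits == nm else hits > 0
  if (!any(exceeds)) return(0)
  r <- rle(exceeds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cs <- c(0, cumsum(.colSums(sub, nm, ncol(sub))))
  max((cs[ends[runs] + 1L] - cs[starts[runs]]) / nm)
}

#' Spatiotemporal cluster-based sign-flip permutation test
#'
#' For each electrode, the spatial cluster is the electrode with its graph
#' neighbors.  A temporal cluster is a maximal run of points where the
#' |t| of every electrode of the spatial cluster exceeds the cell-level
#' critical value (`rule = "all"`, the default; `rule = "any"` relaxes
#' this to at least one electrode).  Cluster mass is the spatial mean of
#' the per-electrode sum of |t| within the run.  The null flips the sign
#' of each participant's entire waveform with a fair coin and records, per
#' spatial cluster and permutation, the maximum cluster mass (0 when no
#' cluster forms).  Family-wise control follows the max-statistic
#' convention: an observed cluster is significant when its mass exceeds
#' the `1 - alpha_cluster` quantile of the per-permutation maximum over
#' all spatial clusters; reported p values use the add-one convention
#' `(#(null >= obs) + 1) / (n_perm + 1)` against that same global null.
#' The per-spatial-cluster null maxima are returned for audit.
#'
#' @param waveforms participants x electrodes x points array with
#'   electrode dimnames.
#' @param graph neighbor graph (named list), e.g. [read_neighbor_graph()].
#' @param alpha_cell cell-level threshold alpha (default 0.05).
#' @param n_perm number of permutations (default 1000).
#' @param alpha_cluster cluster-level alpha (default 0.05).
#' @param seed RNG seed for the sign flips.
#' @param rule `"all"` (default) or `"any"`.
#' @return a `cluster_result`: `clusters` data.frame (electrode set,
#'   extent as fraction of the interval, mass, p, significant),
#'   `null_max_mass` (n_perm x spatial clusters), `critical_t`, `n_perm`.
#' @export
cluster_permutation_test <- function(waveforms, graph, alpha_cell = 0.05,
                                     n_perm = 1000, alpha_cluster = 0.05,
                                     seed = 1L, rule = c("all", "any")) {
  rule <- match.arg(rule)
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  d <- dim(waveforms)
  n <- d[1]; n_pts <- d[3]
  electrodes <- dimnames(waveforms)[[2]]
  if (is.null(electrodes)) stop_invalid("waveforms needs electrode dimnames")
  missing_el <- setdiff(electrodes, names(graph))
  if (length(missing_el) > 0)
    stop_invalid("graph lacks electrode(s): %s", paste(missing_el, collapse = ", "))

  tm <- one_sample_tmap(waveforms, alpha = alpha_cell)
  crit <- tm$critical_t
  clusters <- spatial_clusters(electrodes, graph)

  obs <- list()
  for (e in electrodes) {
    tc <- temporal_clusters(abs(tm$t), clusters[[e]], crit, rule)
    if (!is.null(tc)) {
      tc$seed_electrode <- e
      obs[[e]] <- tc
    }
  }

  ## vectorized permutation t maps: sign flips leave per-cell sums of
  ## squares untouched, so only the means change
  set.seed(seed)
  flat <- matrix(waveforms, nrow = n)                      # n x cells
  ssq <- colSums(flat^2)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Mp <- (S %*% flat) / n                                   # n_perm x cells
  Vp <- sweep(-n * Mp^2, 2, ssq, `+`) / (n - 1)
  Vp[Vp < 0] <- 0
  Tp <- abs(Mp) / sqrt(Vp / n)
  Tp[!is.finite(Tp)] <- 0

  ## identical spatial clusters (same member set) share one null
  member_key <- vapply(clusters, function(m) paste(sort(m), collapse = "|"), "")
  uniq <- !duplicated(member_key)
  null_max <- matrix(0, n_perm, length(electrodes),
                     dimnames = list(NULL, electrodes))
  member_idx <- lapply(clusters, function(m) match(m, electrodes))
  for (b in seq_len(n_perm)) {
    absT <- matrix(Tp[b, ], d[2], n_pts)
    for (e in electrodes[uniq])
      null_max[b, e] <- max_cluster_mass(absT, member_idx[[e]], crit, rule)
  }
  null_max <- null_max[, match(member_key, member_key[uniq]), drop = FALSE]
  colnames(null_max) <- electrodes

  ## family-wise control: the reference null is the per-permutation maximum
  ## over all spatial clusters (max-statistic convention)
  null_global <- apply(null_max, 1, max)
  qcrit <- stats::quantile(null_global, 1 - alpha_cluster, type = 1,
                           names = FALSE)
  rows <- list()
  for (e in names(obs)) {
    for (i in seq_len(nrow(obs[[e]]))) {
      m <- obs[[e]]$mass[i]
      rows[[length(rows) + 1L]] <- data.frame(
        seed_electrode = e,
        electrodes = paste(clusters[[e]], collapse = ","),
        start_frac = (obs[[e]]$start[i] - 1) / n_pts,
        end_frac = obs[[e]]$end[i] / n_pts,
        mass = m,
        p = (sum(null_global >= m) + 1) / (n_perm + 1),
        significant = m > qcrit)
    }
  }
  structure(list(clusters = if (length(rows)) do.call(rbind, rows) else NULL,
                 null_max_mass = null_max, null_global = null_global,
                 critical_t = crit,
                 n_perm = n_perm, alpha_cell = alpha_cell,
                 alpha_cluster = alpha_cluster, rule = rule, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  if (is.null(x$clusters)) {
    cat("<cluster_result> no clusters found\n")
  } else {
    cat(sprintf("<cluster_result> %d temporal cluster(s), %d significant (alpha = %g, n_perm = %d)\n",
                nrow(x$clusters), sum(x$clusters$significant),
                x$alpha_cluster, x$n_perm))
    sig <- x$clusters[x$clusters$significant, , drop = FALSE]
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig)))
        cat(sprintf("  %s: %.0f-%.0f%% of interval, mass %.1f, p = %.4g\n",
                    sig$seed_electrode[i], 100 * sig$start_frac[i],
                    100 * sig$end_frac[i], sig$mass[i], sig$p[i]))
    }
  }
  invisible(x)
}

#' Paired t test with Cohen's d
#'
#' Differences `d_i = a_i - b_i`; `t = mean(d) / (sd(d) / sqrt(n))`;
#' `Cohen's d = mean(d) / sd(d)` (SD with the `n - 1` denominator);
#' two-sided p from the t distribution.
#'
#' @param a,b per-participant paired values.
#' @return an `effect_sizes` list: `t`, `df`, `p`, `cohens_d`,
#'   `mean_diff`, `sd_diff`.
#' @export
paired_t_cohens_d <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop_invalid("a and b must be paired vectors of length >= 2")
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d); n <- length(d)
  if (sdd == 0) {
    warning("zero-variance differences; t and d undefined", call. = FALSE)
    return(structure(list(t = NA_real_, df = n - 1, p = NA_real_,
                          cohens_d = NA_real_, mean_diff = md, sd_diff = 0),
                     class = "effect_sizes"))
  }
  t <- md / (sdd / sqrt(n))
  structure(list(t = t, df = n - 1,
                 p = 2 * stats::pt(-abs(t), n - 1),
                 cohens_d = md / sdd, mean_diff = md, sd_diff = sdd),
            class = "effect_sizes")
}

#' Group response times into equal-sized bins
#'
#' @param rt per-trial response times.
#' @param n_bins number of bins (default 3: early / on time / late).
#' @return factor of bin labels, ordered from fastest to slowest.
#' @export
rt_bins <- function(rt, n_bins = 3L) {
  labels <- if (n_bins == 3L) c("early", "on_time", "late")
            else paste0("bin", seq_len(n_bins))
  qs <- stats::quantile(rt, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  cut(rt, breaks = qs, labels = labels, right = TRUE)
}

#' PCA latency analysis
#'
#' Observations are the per-(response-time bin, electrode) mean waveforms;
#' rows are mean-centered and decomposed by SVD.  Sign conventions: PC1 is
#' oriented to have a positive inner product with the grand-mean waveform,
#' PC2 to correlate positively with the forward-difference temporal
#' derivative of PC1 (so a latency shift maps to a reproducible score
#' direction).  PC2 scores are per-bin means (over electrodes) of the row
#' projections onto PC2.
#'
#' @param waveforms bins x electrodes x time array of mean waveforms.
#' @return a `pca_latency_result`: `pc1`, `pc2` (time courses),
#'   `variance_explained`, `pc2_scores` (per bin), `scores`
#'   (rows x components).
#' @export
pca_latency <- function(waveforms) {
  d <- dim(waveforms)
  if (length(d) != 3L || d[1] < 2L)
    stop_invalid("waveforms must be bins x electrodes x time with >= 2 bins")
  n_bins <- d[1]; n_el <- d[2]; n_t <- d[3]
  ## rows ordered bin-major: (bin1,el1), (bin1,el2), ...
  M <- do.call(rbind, lapply(seq_len(n_bins), function(b)
    matrix(waveforms[b, , ], nrow = n_el)))
  grand <- colMeans(M)
  Mc <- M - rowMeans(M)                       # row mean-centering
  sv <- svd(Mc)
  if (sum(sv$d > max(sv$d) * 1e-10) < 2L) {
    warning("rank < 2; PC2 undefined", call. = FALSE)
  }
  pc1 <- sv$v[, 1]; pc2 <- sv$v[, 2]
  s1 <- if (sum(pc1 * grand) < 0) -1 else 1
  pc1 <- s1 * pc1
  dpc1 <- diff(pc1)
  s2 <- if (stats::cor(pc2[-length(pc2)], dpc1) < 0) -1 else 1
  pc2 <- s2 * pc2
  scores <- Mc %*% cbind(pc1, pc2)
  ve <- sv$d^2 / sum(sv$d^2)
  bin_of_row <- rep(seq_len(n_bins), each = n_el)
  pc2_scores <- tapply(scores[, 2], bin_of_row, mean)
  names(pc2_scores) <- dimnames(waveforms)[[1]] %||% paste0("bin", seq_len(n_bins))
  structure(list(pc1 = pc1, pc2 = pc2,
                 variance_explained = ve,
                 pc2_scores = pc2_scores, scores = scores,
                 centered = Mc, components = sv$v,
                 singular_values = sv$d),
            class = "pca_latency_result")
}

#' One-way repeated-measures ANOVA
#'
#' Decomposes a complete participants x bins table into the bin effect
#' (`ss_effect`), between-subject variation (`ss_subjects`) and the
#' residual (`ss_error`); `F = (ss_effect / df_effect) /
#' (ss_error / df_error)`.  Effect sizes:
#' `eta_p^2 = ss_effect / (ss_effect + ss_error)` and
#' `eta_g^2 = ss_effect / (ss_effect + ss_subjects + ss_error)`.
#'
#' @param scores participants x bins numeric matrix, no missing cells.
#' @return an `anova_result` with `F`, `df_effect`, `df_error`, `p`,
#'   the three sums of squares, `eta_p_sq`, `eta_g_sq`.
#' @export
rm_anova <- function(scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop_invalid("missing cells are not allowed")
  n <- nrow(scores); q <- ncol(scores)
  if (n < 3L || q < 2L) stop_invalid("need >= 3 participants and >= 2 bins")
  grand <- mean(scores)
  col_m <- colMeans(scores); row_m <- rowMeans(scores)
  ss_q <- n * sum((col_m - grand)^2)
  ss_s <- q * sum((row_m - grand)^2)
  ss_tot <- sum((scores - grand)^2)
  ss_sq <- max(ss_tot - ss_q - ss_s, 0)
  df_e <- q - 1; df_r <- (q - 1) * (n - 1)
  F <- if (ss_q <= 0) 0 else (ss_q / df_e) / (ss_sq / df_r)
  structure(list(F = F, df_effect = df_e, df_error = df_r,
                 p = stats::pf(F, df_e, df_r, lower.tail = FALSE),
                 ss_effect = ss_q, ss_subjects = ss_s, ss_error = ss_sq,
                 eta_p_sq = if (ss_q <= 0) 0 else ss_q / (ss_q + ss_sq),
                 eta_g_sq = if (ss_q <= 0) 0 else ss_q / (ss_q + ss_s + ss_sq)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d,%d) = %.3f, p = %.4g, eta_p^2 = %.3f, eta_g^2 = %.3f\n",
              x$df_effect, x$df_error, x$F, x$p, x$eta_p_sq, x$eta_g_sq))
  invisible(x)
}
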