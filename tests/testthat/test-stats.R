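test_that("one-sample t map: formula, symmetry, degenerate cells", {
  set.seed(70)
  w <- array(rnorm(10 * 3 * 20), dim = c(10, 3, 20))
  tm <- one_sample_tmap(w, alpha = 0.05)
  expect_equal(tm$df, 9)
  expect_equal(tm$critical_t, qt(0.975, 9))
  # cell-wise agreement with t.test
  for (cell in list(c(1, 1), c(3, 17))) {
    expect_equal(tm$t[cell[1], cell[2]],
                 unname(t.test(w[, cell[1], cell[2]])$statistic),
                 tolerance = 1e-12)
  }
  # sign flip of every participant negates t exactly
  tm_neg <- one_sample_tmap(-w)
  expect_equal(tm_neg$t, -tm$t, tolerance = 1e-12)

  # identical nonzero constant across participants: infinite t, flagged
  wc <- array(2, dim = c(5, 2, 4))
  tmc <- one_sample_tmap(wc)
  expect_true(all(is.infinite(tmc$t)))
  expect_true(all(tmc$zero_variance))
})

test_that("t map null calibration: |t| > critical at roughly the alpha rate", {
  set.seed(71)
  w <- array(rnorm(20 * 8 * 250), dim = c(20, 8, 250))
  tm <- one_sample_tmap(w, alpha = 0.05)
  frac <- mean(abs(tm$t) > tm$critical_t)
  n_cells <- 8 * 250
  ci <- qbinom(c(0.005, 0.995), n_cells, 0.05) / n_cells
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("cluster permutation: empty data, injected effect, conventions", {
  labels <- paste0("E", 1:4)
  g <- toy_graph(labels)

  # all-zero data: no clusters
  w0 <- array(0, dim = c(8, 4, 30), dimnames = list(NULL, labels, NULL))
  r0 <- cluster_permutation_test(w0, g, n_perm = 100, seed = 1)
  expect_null(r0$clusters)

  # strong common effect on points 10..20 of all electrodes: detected,
  # significant, extent matches
  set.seed(72)
  w <- array(rnorm(12 * 4 * 30, sd = 0.5), dim = c(12, 4, 30),
             dimnames = list(NULL, labels, NULL))
  w[, , 10:20] <- w[, , 10:20] + 2
  r <- cluster_permutation_test(w, g, n_perm = 200, seed = 2)
  expect_false(is.null(r$clusters))
  expect_true(any(r$clusters$significant))
  top <- r$clusters[which.max(r$clusters$mass), ]
  expect_lte(top$start_frac, 10 / 30)
  expect_gte(top$end_frac, 20 / 30)
  # add-one p values live in (0, 1]
  expect_true(all(r$clusters$p > 0 & r$clusters$p <= 1))
  expect_equal(min(r$clusters$p), 1 / 201, tolerance = 1e-12)

  # raising the threshold never enlarges a temporal cluster
  r_hi <- cluster_permutation_test(w, g, alpha_cell = 0.001, n_perm = 200,
                                   seed = 2)
  if (!is.null(r_hi$clusters)) {
    for (e in unique(r_hi$clusters$seed_electrode)) {
      lo <- r$clusters[r$clusters$seed_electrode == e, ]
      hi <- r_hi$clusters[r_hi$clusters$seed_electrode == e, ]
      expect_lte(sum(hi$end_frac - hi$start_frac),
                 sum(lo$end_frac - lo$start_frac) + 1e-12)
    }
  }

  # "all" rule is stricter than "any"
  r_any <- cluster_permutation_test(w, g, n_perm = 200, seed = 2, rule = "any")
  expect_gte(sum(r_any$clusters$end_frac - r_any$clusters$start_frac),
             sum(r$clusters$end_frac - r$clusters$start_frac) - 1e-12)
})

test_that("neighbor graph fixture parses and is symmetric", {
  g <- read_neighbor_graph()
  expect_true("FCz" %in% names(g))
  for (e in names(g)) for (nb in g[[e]]) {
    expect_true(e %in% g[[nb]])
  }
})

test_that("paired t and Cohen's d match the hand oracle", {
  # a = b: everything zero
  expect_warning(r0 <- paired_t_cohens_d(c(1, 2, 3), c(1, 2, 3) + 0),
                 "zero-variance")
  expect_true(is.na(r0$t) || r0$t == 0)   # sd 0 -> flagged

  # frozen four-value oracle: d = (1, 2, 3, 4)
  a <- c(2, 4, 6, 8); b <- c(1, 2, 3, 4)
  r <- paired_t_cohens_d(a, b)
  sd_d <- sd(c(1, 2, 3, 4))               # 1.2909944..., n - 1 denominator
  expect_equal(r$mean_diff, 2.5)
  expect_equal(r$sd_diff, sd_d, tolerance = 1e-12)
  expect_equal(r$t, 2.5 / (sd_d / 2), tolerance = 1e-12)
  expect_equal(r$cohens_d, 2.5 / sd_d, tolerance = 1e-12)
  expect_equal(r$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)

  # antisymmetry
  rs <- paired_t_cohens_d(b, a)
  expect_equal(rs$t, -r$t)
  expect_equal(rs$cohens_d, -r$cohens_d)
})

test_that("PCA latency: shifted bump family and sign conventions", {
  n_t <- 200
  t_ax <- seq_len(n_t)
  bump <- function(shift) exp(-((t_ax - 100 - shift)^2) / (2 * 15^2))
  shifts <- c(-8, 0, 8)
  n_el <- 5
  w <- array(0, dim = c(3, n_el, n_t),
             dimnames = list(c("early", "on_time", "late"), paste0("E", 1:5),
                             NULL))
  set.seed(73)
  for (b in 1:3) for (e in 1:n_el)
    w[b, e, ] <- (0.8 + 0.4 * e / n_el) * bump(shifts[b])
  res <- pca_latency(w)

  # PC1 tracks the mean bump, PC2 its temporal derivative
  grand <- colMeans(matrix(w, ncol = n_t))
  expect_gt(cor(res$pc1, grand - mean(grand)), 0.95)
  d1 <- diff(res$pc1)
  expect_gt(abs(cor(res$pc2[-n_t], d1)), 0.9)
  expect_gt(cor(res$pc2[-n_t], d1), 0)     # sign convention

  # scores strictly monotone in the latency shift
  expect_true(all(diff(res$pc2_scores) > 0) || all(diff(res$pc2_scores) < 0))

  # orthonormal components; variance explained sums to 1 and is sorted
  expect_equal(sum(res$pc1^2), 1, tolerance = 1e-12)
  expect_equal(sum(res$pc1 * res$pc2), 0, tolerance = 1e-12)
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(res$variance_explained) <= 1e-12))

  # reconstruction: centered rows = scores %*% components
  recon <- res$scores %*% t(cbind(res$pc1, res$pc2))
  expect_lt(max(abs(res$centered - res$centered %*%
                      tcrossprod(res$components))), 1e-10)

  # identical bins: equal PC2 scores
  w_eq <- w; for (b in 1:3) w_eq[b, , ] <- w[2, , ]
  res_eq <- suppressWarnings(pca_latency(w_eq))
  expect_lt(max(abs(diff(res_eq$pc2_scores))), 1e-8)
})

test_that("repeated-measures ANOVA matches the brute-force decomposition", {
  # identical columns: no bin effect
  s0 <- matrix(rnorm(12), 4, 3)
  s0[, 2] <- s0[, 1]; s0[, 3] <- s0[, 1]
  r0 <- rm_anova(s0)
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_equal(r0$eta_p_sq, 0, tolerance = 1e-12)
  expect_equal(r0$eta_g_sq, 0, tolerance = 1e-12)

  # 4 x 3 toy table against an explicit cell-loop oracle
  set.seed(74)
  s <- matrix(rnorm(12, mean = rep(c(0, 1, 2), each = 4)), 4, 3)
  r <- rm_anova(s)
  grand <- mean(s)
  ss_q <- ss_s <- ss_tot <- 0
  for (j in 1:3) ss_q <- ss_q + 4 * (mean(s[, j]) - grand)^2
  for (i in 1:4) ss_s <- ss_s + 3 * (mean(s[i, ]) - grand)^2
  for (i in 1:4) for (j in 1:3) ss_tot <- ss_tot + (s[i, j] - grand)^2
  ss_sq <- ss_tot - ss_q - ss_s
  expect_equal(r$ss_effect, ss_q, tolerance = 1e-10)
  expect_equal(r$ss_subjects, ss_s, tolerance = 1e-10)
  expect_equal(r$ss_error, ss_sq, tolerance = 1e-10)
  expect_equal(r$F, (ss_q / 2) / (ss_sq / 6), tolerance = 1e-10)
  expect_equal(r$eta_p_sq, ss_q / (ss_q + ss_sq), tolerance = 1e-10)
  expect_equal(r$eta_g_sq, ss_q / (ss_q + ss_s + ss_sq), tolerance = 1e-10)
  # and against aov's stratified decomposition
  df <- data.frame(y = as.numeric(s),
                   subj = factor(rep(1:4, 3)), bin = factor(rep(1:3, each = 4)))
  av <- summary(aov(y ~ bin + Error(subj), data = df))
  expect_equal(r$F, av[["Error: Within"]][[1]]$`F value`[1], tolerance = 1e-8)

  # adding a per-participant constant moves SS_S only
  s_shift <- s + c(10, -5, 3, 7)
  r_shift <- rm_anova(s_shift)
  expect_equal(r_shift$F, r$F, tolerance = 1e-10)
  expect_equal(r_shift$eta_p_sq, r$eta_p_sq, tolerance = 1e-10)
  expect_gt(r_shift$ss_subjects, r$ss_subjects)
  expect_lt(r_shift$eta_g_sq, r$eta_g_sq)

  # SS identity on random tables
  for (seed in 75:77) {
    set.seed(seed)
    sr <- matrix(rnorm(8 * 4), 8, 4)
    rr <- rm_anova(sr)
    expect_equal(rr$ss_effect + rr$ss_subjects + rr$ss_error,
                 sum((sr - mean(sr))^2), tolerance = 1e-9)
  }

  expect_error(rm_anova(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)), "missing")
})

test_that("rt_bins groups into equal-sized labelled bins", {
  rt <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  b <- rt_bins(rt, 3)
  expect_equal(as.character(b),
               rep(c("early", "on_time", "late"), each = 2))
})
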