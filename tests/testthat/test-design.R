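test_that("resize_box matches brute-force overlap integrals and contracts", {
  # equal grids: identity
  expect_equal(resize_box(7, 7, sparse = FALSE), diag(7))

  # 2 -> 4: each basis bin duplicated (frozen from overlap of [0,1/2),[1/2,1)
  # against quarter bins)
  expect_equal(resize_box(2, 4, sparse = FALSE),
               rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))

  # brute-force oracle: numerical overlap integrals on a fine grid
  brute <- function(b, t, grid = 720720) {
    u <- (seq_len(grid) - 0.5) / grid
    bb <- pmin(floor(u * b), b - 1) + 1
    tb <- pmin(floor(u * t), t - 1) + 1
    M <- matrix(0, t, b)
    for (g in seq_len(grid)) M[tb[g], bb[g]] <- M[tb[g], bb[g]] + 1
    M / rowSums(M)
  }
  for (dims in list(c(3, 5), c(5, 3), c(4, 9))) {
    expect_equal(resize_box(dims[1], dims[2], sparse = FALSE),
                 brute(dims[1], dims[2]), tolerance = 1e-9)
  }

  # row sums are 1 for arbitrary sizes
  set.seed(1)
  for (i in 1:20) {
    b <- sample(1:80, 1); t <- sample(1:80, 1)
    expect_equal(Matrix::rowSums(resize_box(b, t)), rep(1, t),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # up-down round trip approaches identity for ratio >= 4 on a smooth curve
  tmpl <- sin(seq(0, pi, length.out = 50))
  up <- resize_box(50, 200); down <- resize_box(200, 50)
  back <- as.numeric(down %*% (up %*% tmpl))
  expect_lt(max(abs(back - tmpl)) / max(abs(tmpl)), 0.02)

  expect_error(resize_box(0, 4), "basis_len")
})

test_that("fixed block: column counts, stick placement, linearity, edges", {
  fs <- 200
  ev <- data.frame(type = "cue", sample = 1000L, trial_id = 1L)
  blk <- build_fixed_block(ev, fixed_window("cue", -200, 800), 2000L, fs)
  expect_equal(ncol(blk$X), 200L)  # 1000 ms at 200 Hz
  expect_equal(blk$columns$lag_ms[1], -200)

  # each row has at most one nonzero for an isolated event, value 1
  expect_true(all(Matrix::rowSums(blk$X != 0) <= 1))
  expect_equal(unique(blk$X@x), 1)
  # stick at event_sample + lag
  expect_equal(which(blk$X[, 1] == 1), 1000L - 40L + 1L)  # 0-based 960

  # two coincident events sum to 2x the single-event block
  ev2 <- rbind(ev, ev)
  blk2 <- build_fixed_block(ev2, fixed_window("cue", -200, 800), 2000L, fs)
  expect_equal(as.matrix(blk2$X), 2 * as.matrix(blk$X))

  # window truncated at the edge: out-of-range entries dropped, rows flagged
  ev_edge <- data.frame(type = "cue", sample = 10L, trial_id = 1L)
  blk_e <- build_fixed_block(ev_edge, fixed_window("cue", -200, 800), 2000L, fs)
  expect_gt(length(blk_e$edge_rows), 0)
  expect_equal(sum(blk_e$X), 200 - 30)  # 30 pre-event lags fall off the start
})

test_that("design of concatenated event tables equals sum of designs", {
  fs <- 100
  e1 <- toy_events(cues = c(100, 300))
  e2 <- toy_events(cues = c(500, 700))
  e2$trial_id <- e2$trial_id + 2L
  w <- fixed_window("cue", -100, 300)
  b1 <- build_fixed_block(e1, w, 1200L, fs)
  b2 <- build_fixed_block(e2, w, 1200L, fs)
  b12 <- build_fixed_block(rbind(e1, e2), w, 1200L, fs)
  expect_equal(as.matrix(b12$X), as.matrix(b1$X + b2$X))
})

test_that("scaled block stretches one shared basis per trial", {
  ev <- toy_events(cues = c(100, 400), D = c(50, 90))
  blk <- build_scaled_block(ev, scaled_spec(50), 1000L)
  expect_equal(ncol(blk$X), 50L)
  # trial with D = n_points: identity rows
  expect_equal(as.matrix(blk$X[101:150, ]), diag(50), ignore_attr = TRUE)
  # different-duration trial feeds the same columns (elapsed fraction axis)
  expect_equal(as.numeric(Matrix::colSums(blk$X[401:490, ] != 0) > 0),
               rep(1, 50))
  expect_equal(blk$columns$elapsed_fraction, (seq_len(50) - 0.5) / 50)

  # missing partner names the trial
  bad <- ev[-2, ]
  expect_error(build_scaled_block(bad, scaled_spec(50), 1000L), "trial 1")
})

test_that("artifact flagging is a shared peak-to-peak moving-window mask", {
  fs <- 100
  flat <- continuous_recording(matrix(0, 2, 1000), fs)
  expect_true(all(flag_artifact_samples(flat, 150, 2000, 1000)$keep))

  # a 200 uV square pulse on one channel flags every overlapping window
  x <- matrix(0, 2, 1000); x[1, 501:520] <- 200
  rec <- continuous_recording(x, fs)
  m <- flag_artifact_samples(rec, 150, 2000, 1000)
  expect_false(any(m$keep[401:620]))      # windows overlapping the pulse
  expect_equal(unique(m$reasons[!m$keep]), "artifact")

  # peak-to-peak below threshold: nothing flagged
  x2 <- matrix(seq(0, 140, length.out = 1000), 1, 1000)
  expect_true(all(flag_artifact_samples(continuous_recording(x2, fs),
                                        150, 2000, 1000)$keep))
})

test_that("response-time exclusion masks interval samples and drops events", {
  ev <- toy_events(D = c(60, 80, 100))       # RTs 0.6, 0.8, 1.0 s
  m <- sample_mask(1500L)

  res <- exclude_response_trials(ev, m, 0.2, 5)
  expect_equal(res$events, ev)
  expect_true(all(res$mask$keep))

  ev$response_time_s[ev$trial_id == 1] <- 0.1
  res2 <- exclude_response_trials(ev, m, 0.2, 5)
  expect_false(1 %in% res2$events$trial_id)
  expect_false(any(res2$mask$keep[101:161]))       # trial 1 interval masked
  expect_true(all(res2$mask$keep[500:1500]))

  res3 <- exclude_response_trials(ev, m, 0, Inf)
  expect_equal(res3$events, ev)
})

test_that("assembly bookkeeping: masked rows removed from X and Y alike", {
  sim <- simulate_dataset(small_sim_config(seed = 5), small_shapes(),
                          n_channels = 2)
  n <- ncol(sim$recording$data)
  blocks <- list(
    build_fixed_block(sim$events, small_windows$cue, n, 100),
    build_scaled_block(sim$events, scaled_spec(40), n))

  d_all <- assemble_design(blocks, sim$recording)
  expect_equal(nrow(d_all$X), n)
  expect_equal(ncol(d_all$Y), n)

  m <- sample_mask(n)
  drop <- seq(1, n, by = 4)
  m$keep[drop] <- FALSE
  d <- assemble_design(blocks, sim$recording, m)
  expect_equal(nrow(d$X), n - length(drop))
  expect_equal(ncol(d$Y), nrow(d$X))
  expect_equal(d$row_index, setdiff(seq_len(n), drop))
  expect_false(anyDuplicated(d$row_index) > 0)

  expect_error(assemble_design(blocks, sim$recording, m, max_columns = 10),
               "fewer points")
})

test_that("production-task defaults give 200 + 200 fixed and 330 scaled columns", {
  sim <- simulate_dataset(sim_config(trials_per_condition = 2, seed = 1),
                          n_channels = 1)
  n <- ncol(sim$recording$data)
  blocks <- list(
    build_fixed_block(sim$events, fixed_window("cue", -200, 800), n, 200),
    build_fixed_block(sim$events, fixed_window("response", -800, 200), n, 200),
    build_scaled_block(sim$events, scaled_spec(330), n))
  d <- assemble_design(blocks, sim$recording)
  expect_equal(as.integer(table(d$columns$component)[c("cue", "response", "scaled")]),
               c(200L, 200L, 330L))
})
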