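test_that("stimulus means are uniformly spaced between the anchors", {
  expect_equal(stimulus_means(3), c(2.7, 6.2, 9.8)) # 6.25 rounds half-even
  expect_equal(stimulus_means(10),
               round(seq(2.7, 9.8, length.out = 10), 1))
  means <- stimulus_means(6)
  expect_equal(means[1], 2.7)
  expect_equal(means[6], 9.8)
  expect_error(stimulus_means(1), "at least 2")
})

test_that("the confusion matrix is the exact discretized-Gaussian channel", {
  # noiseless: point masses on the rounded means
  p0 <- confusion_matrix(channel_spec(sigma = 0), c(2.7, 9.8))
  expect_equal(p0[1, ], c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(p0[2, ], c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), ignore_attr = TRUE)

  # rows are probability distributions, tails folded into the ends
  for (s in c(0.3, 1, 2.5)) {
    p <- confusion_matrix(channel_spec(sigma = s), stimulus_means(10))
    expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(p >= 0))
  }

  # a mean halfway between two categories splits them symmetrically
  p <- confusion_matrix(channel_spec(sigma = 1), 5.5)
  expect_equal(p[1, 5], p[1, 6], tolerance = 1e-12)

  # cell probabilities match the Gaussian interval closed form
  p1 <- confusion_matrix(channel_spec(sigma = 1), 5)
  expect_equal(p1[1, 5], pnorm(5.5, 5, 1) - pnorm(4.5, 5, 1),
               tolerance = 1e-12)
  expect_equal(p1[1, 1], pnorm(1.5, 5, 1), tolerance = 1e-12)

  expect_error(channel_spec(sigma = -1), "sigma")
  expect_error(confusion_matrix(channel_spec(sigma = 1), 10.5), "scale")
})

test_that("the analytic block information rate has the right limits", {
  expect_equal(theoretical_block_mi(channel_spec(sigma = 0), c(2, 5, 8)),
               log2(3))
  # indistinguishable stimuli share a rounded mean: nothing is transmitted
  expect_equal(theoretical_block_mi(channel_spec(sigma = 0), c(5.2, 5.4)), 0)
  # regression constant: 10 uniformly spaced means on 2.7-9.8 at sigma = 1,
  # computed once by direct summation over the 10 x 10 joint distribution
  expect_equal(theoretical_block_mi(channel_spec(sigma = 1),
                                    stimulus_means(10)),
               1.2026596108, tolerance = 1e-9)
  # convergence: information vanishes as noise swamps the scale
  expect_lt(theoretical_block_mi(channel_spec(sigma = 25),
                                 stimulus_means(10)), 0.02)
})

test_that("sigma calibration hits the requested plateau and is monotone", {
  sigma <- calibrate_sigma(2.3)
  expect_equal(theoretical_block_mi(channel_spec(sigma = sigma),
                                    stimulus_means(10)),
               2.3, tolerance = 1e-6)
  # the channel_spec default is this calibrated value
  expect_equal(channel_spec()$sigma, sigma, tolerance = 1e-6)
  expect_gt(calibrate_sigma(1.5), sigma)
  expect_error(calibrate_sigma(5), "not attainable")
})

test_that("simulated datasets honor the experimental design", {
  ds <- simulate_dataset(seed = 21)
  # 50 participants x (15 + 20 + 30 + 50) trials
  expect_equal(nrow(ds), 5750L)
  counts <- table(ds$participant)
  expect_true(all(counts == 115L))
  per_block <- dplyr::count(tibble::as_tibble(ds), block,
                            name = "trials")
  expect_equal(sort(per_block$trials), sort(c(15L, 20L, 30L, 50L)) * 50L)
  # every participant-block-stimulus cell has exactly 5 repetitions
  reps <- dplyr::count(tibble::as_tibble(ds), participant, block, stimulus)
  expect_true(all(reps$n == 5L))
  expect_true(all(ds$rating >= 1 & ds$rating <= 10))
})

test_that("generation is deterministic in the seed", {
  a <- simulate_dataset(seed = 22)
  b <- simulate_dataset(seed = 22)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  # byte-identical CSV
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_ratings(a, fa); write_ratings(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- simulate_dataset(seed = 23)
  expect_false(identical(a$rating, c$rating))
})

test_that("no stimulus is ever shown twice in a row", {
  ds <- simulate_dataset(experiment_design(participants = 10),
                         channel_spec(), seed = 24)
  # rows are emitted in presentation order within each participant-block
  by_block <- split(ds$stimulus, paste(ds$participant, ds$block))
  for (order in by_block) {
    expect_false(any(order[-1] == order[-length(order)]))
  }
})

test_that("a noiseless channel reproduces its rounded means exactly", {
  design <- experiment_design(anchors = c(1, 10), participants = 2)
  ds <- simulate_dataset(design, channel_spec(sigma = 0), seed = 25)
  truth <- attr(ds, "design_means")
  joined <- dplyr::left_join(tibble::as_tibble(ds), truth,
                             by = c("block", "stimulus"))
  expect_equal(joined$rating, round(joined$true_mean), ignore_attr = TRUE)
})

test_that("default anchors collide at k = 10 when noiseless, as the rounding predicts", {
  # rounded means (3,4,4,5,6,7,7,8,9,10) have 8 distinct values, so a
  # noiseless rater transmits the entropy of the collided input, not log2(10)
  rounded <- round(stimulus_means(10))
  expect_equal(length(unique(rounded)), 8L)
  h_collided <- entropy_brute_force(as.vector(table(rounded)) / 10)
  expect_equal(theoretical_block_mi(channel_spec(sigma = 0),
                                    stimulus_means(10)),
               h_collided, tolerance = 1e-12)
})

test_that("per-participant offsets shift means without breaking validity", {
  ds <- simulate_dataset(experiment_design(participants = 6),
                         channel_spec(sigma = 0.3, participant_sd = 1),
                         seed = 26)
  expect_equal(nrow(ds), 6L * 115L)
  expect_true(all(ds$rating >= 1 & ds$rating <= 10))
  # offsets create real across-participant differences in mean rating
  m <- tapply(ds$rating, ds$participant, mean)
  expect_gt(max(m) - min(m), 0.3)
})
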