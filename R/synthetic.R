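# Synthetic rater-channel generator.
#
# Emulates the rating experiment's structure: each participant rates the
# stimuli of several blocks repeatedly on a bounded integer scale. A
# simulated rater draws each rating from a Gaussian centered on the
# stimulus's true mean, rounds it to the nearest scale category and clamps it
# at the scale ends. A single noise parameter sigma then controls the
# channel's information rate, which makes every stage of the analysis
# pipeline testable against analytic ground truth.

#' Experiment design for simulated rating blocks
#'
#' Defaults reproduce the reference design: 50 participants complete four
#' blocks of 3, 4, 6 and 10 distinct stimuli, each stimulus rated 5 times on
#' a 1-10 scale (so 15, 20, 30 or 50 trials per block). Every block contains
#' both anchor stimuli (true means 2.7 and 9.8, the extremes of the stimulus
#' pool), and the remaining true means are uniformly spaced between the
#' anchors, rounded to one decimal to match the anchors' granularity.
#'
#' @param block_sizes Integer vector of distinct-stimulus counts, all >= 2.
#' @param repetitions Ratings per stimulus per block.
#' @param scale_min,scale_max Integer bounds of the rating scale.
#' @param anchors Length-2 numeric: the extreme true means present in every
#'   block.
#' @param participants Number of simulated participants.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(block_sizes = c(3L, 4L, 6L, 10L),
                              repetitions = 5L,
                              scale_min = 1L, scale_max = 10L,
                              anchors = c(2.7, 9.8),
                              participants = 50L) {
  if (any(block_sizes < 2L)) stop("block sizes must be >= 2", call. = FALSE)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  anchors <- sort(as.numeric(anchors))
  if (length(anchors) != 2L || anchors[1] < scale_min || anchors[2] > scale_max) {
    stop("anchors must be two means within the rating scale", call. = FALSE)
  }
  if (participants < 1L) stop("need at least one participant", call. = FALSE)
  structure(list(block_sizes = as.integer(block_sizes),
                 repetitions = as.integer(repetitions),
                 scale_min = as.integer(scale_min),
                 scale_max = as.integer(scale_max),
                 anchors = anchors,
                 participants = as.integer(participants)),
            class = "experiment_design")
}

#' True stimulus means for a block
#'
#' `n_stimuli` means uniformly spaced between the two anchors (both anchors
#' always included), rounded to `digits` decimals.
#'
#' @param n_stimuli Number of stimuli in the block (>= 2).
#' @param anchors Length-2 numeric range of means.
#' @param digits Decimal places the means are rounded to (default 1).
#' @return Numeric vector of length `n_stimuli`.
#' @export
stimulus_means <- function(n_stimuli, anchors = c(2.7, 9.8), digits = 1) {
  if (n_stimuli < 2L) stop("a block needs at least 2 stimuli", call. = FALSE)
  round(seq(anchors[1], anchors[2], length.out = n_stimuli), digits)
}

#' Specification of a simulated rater channel
#'
#' A rater's response to a stimulus with true mean `mu` is
#' `clamp(round(mu + e))` with `e ~ Normal(0, sigma)`, rounding to the
#' nearest integer category and clamping to the scale ends. With `sigma = 0`
#' and distinct rounded means the channel is deterministic.
#' `participant_sd > 0` additionally shifts each simulated participant's
#' means by a persistent Normal(0, `participant_sd`) offset (a lenient or
#' strict rater), clamped back into the scale.
#'
#' The default `sigma` is calibrated (see [calibrate_sigma()]) so that the
#' uniform-input information rate of the 10-stimulus default block is 2.3
#' bits — a noise level representative of a rater whose transmitted
#' information plateaus near the one-dimensional judgment benchmark.
#'
#' @param sigma Rating noise standard deviation, in scale units (>= 0).
#' @param participant_sd Across-participant mean-offset SD (default 0).
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(sigma = 0.30610046, participant_sd = 0) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (participant_sd < 0) stop("participant_sd must be >= 0", call. = FALSE)
  structure(list(noise = "gaussian", sigma = as.numeric(sigma),
                 participant_sd = as.numeric(participant_sd)),
            class = "channel_spec")
}

#' Exact confusion matrix of a rater channel
#'
#' Row `s` gives the probability of each integer rating category for the
#' stimulus with true mean `stimulus_means[s]`: the Gaussian probability of
#' the interval `[k - 0.5, k + 0.5)` around category `k`, with the tails
#' folded into the end categories (clamping). With `sigma = 0` each row is a
#' point mass on the rounded mean.
#'
#' @param channel A `channel_spec`.
#' @param stimulus_means Numeric true means, all within the scale.
#' @param scale Integer vector of rating categories (default `1:10`).
#' @return A row-stochastic matrix, stimuli x rating categories.
#' @export
confusion_matrix <- function(channel, stimulus_means, scale = 1:10) {
  stopifnot(inherits(channel, "channel_spec"))
  scale <- as.integer(scale)
  if (any(stimulus_means < scale[1] | stimulus_means > scale[length(scale)])) {
    stop("stimulus means must lie within the rating scale", call. = FALSE)
  }
  k <- length(scale)
  lower <- scale - 0.5
  upper <- scale + 0.5
  lower[1] <- -Inf      # tails fold into the end categories
  upper[k] <- Inf
  rows <- lapply(stimulus_means, function(mu) {
    if (channel$sigma == 0) {
      p <- numeric(k)
      cat_idx <- match(pmin(pmax(round(mu), scale[1]), scale[k]), scale)
      p[cat_idx] <- 1
      p
    } else {
      stats::pnorm(upper, mean = mu, sd = channel$sigma) -
        stats::pnorm(lower, mean = mu, sd = channel$sigma)
    }
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(stimulus = seq_along(stimulus_means), rating = scale)
  out
}

#' Analytic information rate of a simulated block
#'
#' The mutual information, under uniform stimulus presentation, of the
#' block's exact confusion matrix: the value the empirical pipeline should
#' approach as repetitions and participants grow, under the idealization
#' that each stimulus's input category equals its rounded true mean. Stimuli
#' whose rounded means collide transmit no information about each other, so
#' with `sigma = 0` the value is `log2(#distinct rounded means)`.
#'
#' @inheritParams confusion_matrix
#' @return Mutual information in bits.
#' @export
theoretical_block_mi <- function(channel, stimulus_means, scale = 1:10) {
  mi_uniform_input(confusion_matrix(channel, stimulus_means, scale))
}

#' Calibrate channel noise to a target information plateau
#'
#' Finds `sigma` such that [theoretical_block_mi()] of the design's largest
#' block equals `target_bits`, by monotone root finding. The information rate
#' decreases strictly in `sigma`, so the solution is unique when it exists.
#'
#' @param target_bits Desired information rate of the largest block, in bits.
#' @param design An `experiment_design`.
#' @param interval Search interval for `sigma`.
#' @return The calibrated `sigma`.
#' @export
calibrate_sigma <- function(target_bits = 2.3, design = experiment_design(),
                            interval = c(0.02, 5)) {
  means <- stimulus_means(max(design$block_sizes), design$anchors)
  scale <- seq.int(design$scale_min, design$scale_max)
  f <- function(s) {
    theoretical_block_mi(channel_spec(sigma = s), means, scale) - target_bits
  }
  if (f(interval[1]) < 0 || f(interval[2]) > 0) {
    stop("target_bits is not attainable within the sigma interval",
         call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-9)$root
}

# trial order: seeded shuffle redrawn until no stimulus repeats consecutively
no_consecutive_order <- function(stimulus_ids, repetitions,
                                 max_tries = 10000L) {
  trials <- rep(stimulus_ids, each = repetitions)
  if (length(unique(stimulus_ids)) == 1L) {
    stop("cannot avoid consecutive repeats with a single stimulus",
         call. = FALSE)
  }
  for (i in seq_len(max_tries)) {
    ord <- sample(trials)
    if (!any(ord[-1] == ord[-length(ord)])) return(ord)
  }
  stop("failed to draw a no-consecutive-repeat trial order", call. = FALSE)
}

#' Simulate a complete rating dataset
#'
#' Draws one rating per participant x block x stimulus x repetition from the
#' channel's confusion-matrix rows. Within each block the trial order is a
#' seeded shuffle redrawn until no stimulus appears twice in a row, and
#' block order is shuffled per participant. The master seed deterministically
#' spawns one sub-seed per participant, so identical
#' (design, channel, seed) triples reproduce the dataset exactly.
#'
#' @param design An `experiment_design`.
#' @param channel A `channel_spec`.
#' @param seed Integer master seed.
#' @return A `rating_dataset` tibble with one row per trial; blocks are
#'   labeled `b<k>` for the block of `k` stimuli and stimuli `b<k>_s<j>` in
#'   order of increasing true mean. True means are attached as attribute
#'   `design_means` (a tibble with `block`, `stimulus`, `true_mean`).
#' @export
simulate_dataset <- function(design = experiment_design(),
                             channel = channel_spec(),
                             seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(channel, "channel_spec"))
  scale <- seq.int(design$scale_min, design$scale_max)
  block_ids <- paste0("b", design$block_sizes)
  block_means <- lapply(design$block_sizes, stimulus_means,
                        anchors = design$anchors)
  names(block_means) <- block_ids

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, design$participants)

  one_participant <- function(p) {
    set.seed(sub_seeds[p])
    offset <- if (channel$participant_sd > 0) {
      stats::rnorm(1, 0, channel$participant_sd)
    } else 0
    rows <- lapply(sample(seq_along(block_ids)), function(b) {
      bid <- block_ids[b]
      means <- pmin(pmax(block_means[[bid]] + offset, design$scale_min),
                    design$scale_max)
      conf <- confusion_matrix(channel_spec(sigma = channel$sigma),
                               means, scale)
      stim_ids <- paste0(bid, "_s", seq_along(means))
      ord <- no_consecutive_order(seq_along(means), design$repetitions)
      ratings <- vapply(ord, function(s) {
        sample(scale, 1L, prob = conf[s, ])
      }, integer(1))
      rep_idx <- stats::ave(ord, ord, FUN = seq_along)
      tibble::tibble(participant = sprintf("p%02d", p),
                     block = bid,
                     stimulus = stim_ids[ord],
                     repetition = as.integer(rep_idx),
                     rating = ratings)
    })
    dplyr::bind_rows(rows)
  }

  data <- dplyr::bind_rows(lapply(seq_len(design$participants),
                                  one_participant))
  out <- rating_dataset(data, scale_min = design$scale_min,
                        scale_max = design$scale_max)
  attr(out, "design_means") <- tibble::tibble(
    block = rep(block_ids, design$block_sizes),
    stimulus = unlist(lapply(block_ids, function(bid) {
      paste0(bid, "_s", seq_along(block_means[[bid]]))
    })),
    true_mean = unlist(block_means))
  out
}
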