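# From repeated ratings to the mutual-information-vs-source-entropy curve.
#
# The rater is treated as a channel: the "input" presented on a trial is the
# stimulus's rounded mean rating for that participant in that block (its
# personal ground-truth category), the "output" is the individual rating.
# Mutual information between input and output, estimated per participant and
# block, traces how transmitted information grows with source entropy
# log2(number of stimuli).

#' Round a vector of ratings to its integer input category
#'
#' The input category of a stimulus is the arithmetic mean of its repeated
#' ratings within one block, rounded to the nearest integer. Halves round to
#' even by default (the convention of R's `round()`); with five repetitions a
#' mean can never land exactly on a half-integer, so the tie rule only
#' matters for four-rating means as produced by the leave-one-out variant.
#'
#' @param ratings Integer ratings of one stimulus within one block.
#' @param rounding `"half_even"` (default) or `"half_up"`.
#' @return A single integer category; always within the range of `ratings`.
#' @examples
#' rounded_mean_input(c(2, 3, 3, 4, 5)) # mean 3.4 -> 3
#' rounded_mean_input(c(4, 4, 5, 5))    # mean 4.5 -> 4 (half to even)
#' @export
rounded_mean_input <- function(ratings, rounding = c("half_even", "half_up")) {
  if (length(ratings) == 0L) stop("no ratings to average", call. = FALSE)
  rounding <- match.arg(rounding)
  m <- mean(ratings)
  as.integer(if (rounding == "half_even") round(m) else floor(m + 0.5))
}

#' Leave-one-out input categories for a vector of ratings
#'
#' The plug-in input category contains the rating it is paired with (the mean
#' includes it), which can inflate mutual information. The leave-one-out
#' variant pairs rating `i` with the rounded mean of the *other* ratings of
#' the same stimulus in the same block, removing that self-dependence.
#'
#' @inheritParams rounded_mean_input
#' @return Integer vector the same length as `ratings`; element `i` is the
#'   rounded mean of `ratings[-i]`.
#' @examples
#' loo_inputs(c(2, 3, 3, 4, 5)) # c(4, 4, 4, 3, 3)
#' @export
loo_inputs <- function(ratings, rounding = c("half_even", "half_up")) {
  if (length(ratings) < 2L) {
    stop("leave-one-out needs at least 2 ratings", call. = FALSE)
  }
  rounding <- match.arg(rounding)
  vapply(seq_along(ratings),
         function(i) rounded_mean_input(ratings[-i], rounding = rounding),
         integer(1))
}

# (input, output) pairs for one participant-block; one pair per rating.
block_pairs <- function(block_data, mode, rounding) {
  split_ratings <- split(block_data$rating, block_data$stimulus)
  inputs <- integer(0)
  outputs <- integer(0)
  for (ratings in split_ratings) {
    inp <- if (mode == "loo") {
      loo_inputs(ratings, rounding = rounding)
    } else {
      rep(rounded_mean_input(ratings, rounding = rounding), length(ratings))
    }
    inputs <- c(inputs, inp)
    outputs <- c(outputs, ratings)
  }
  list(inputs = inputs, outputs = outputs)
}

check_block_complete <- function(block_data, repetitions = NULL) {
  counts <- table(block_data$stimulus)
  designed <- repetitions %||% max(counts)
  short <- counts[counts != designed]
  if (length(short) > 0L) {
    stop("incomplete block: stimulus(es) with fewer than ", designed,
         " repetitions: ",
         paste0(names(short), " (", as.integer(short), ")", collapse = ", "),
         call. = FALSE)
  }
  invisible(designed)
}

#' Mutual information of one participant's ratings in one block
#'
#' Builds one (input, output) pair per individual rating — the input is the
#' stimulus's rounded mean rating in that block (`mode = "plugin"`), or the
#' rounded mean of the other repetitions (`mode = "loo"`) — then estimates
#' mutual information from the contingency table of the pairs over the full
#' declared scale. Input categories are always computed within the block
#' only, never across blocks.
#'
#' @param block_data Data frame of one participant's ratings in one block;
#'   needs columns `stimulus` and `rating`.
#' @param mode `"plugin"` (input = rounded mean of all repetitions) or
#'   `"loo"` (leave-one-out input).
#' @param scale Integer vector of rating categories (default `1:10`).
#' @param estimator `"plugin"` for the raw plug-in estimate (default) or
#'   `"miller_madow"` for the bias-corrected diagnostic.
#' @param repetitions Designed number of repetitions per stimulus; inferred
#'   as the maximum observed count when `NULL`. Blocks where any stimulus has
#'   fewer repetitions raise an error naming the offending stimuli.
#' @inheritParams rounded_mean_input
#' @return Mutual information in bits.
#' @export
participant_block_mi <- function(block_data,
                                 mode = c("plugin", "loo"),
                                 scale = 1:10,
                                 estimator = c("plugin", "miller_madow"),
                                 rounding = c("half_even", "half_up"),
                                 repetitions = NULL) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  rounding <- match.arg(rounding)
  check_block_complete(block_data, repetitions)
  pairs <- block_pairs(block_data, mode = mode, rounding = rounding)
  tab <- contingency_from_pairs(pairs$inputs, pairs$outputs, scale = scale)
  if (estimator == "miller_madow") miller_madow_bits(tab)
  else mutual_information_bits(tab)
}

#' Mutual information curve across block sizes
#'
#' For every distinct block size (number of distinct stimuli in a block),
#' computes each participant's per-block mutual information and summarizes it
#' across participants. The source entropy of a block of `k` equally
#' presented stimuli is `log2(k)`; plotting mean transmitted information
#' against source entropy traces the curve whose plateau is the channel
#' capacity of the rater.
#'
#' Participants with any incomplete block are dropped entirely, with a
#' warning. With `pooled = TRUE`, all participants' (input, output) pairs for
#' a block size are pooled into a single contingency table instead; the
#' returned `mi_sd_bits` is then `NA` (there is no across-participant spread
#' for a pooled estimate).
#'
#' @param dataset A `rating_dataset` (see [rating_dataset()]) or a data frame
#'   with columns `participant`, `block`, `stimulus`, `repetition`, `rating`.
#' @param pooled Pool pairs across participants before estimating, instead of
#'   averaging per-participant estimates.
#' @inheritParams participant_block_mi
#' @return A tibble of class `mi_curve`, ordered by source entropy, with
#'   columns `n_stimuli`, `source_entropy_bits`, `mi_mean_bits`, `mi_sd_bits`
#'   and `n_participants`.
#' @export
aggregate_curve <- function(dataset,
                            mode = c("plugin", "loo"),
                            pooled = FALSE,
                            scale = NULL,
                            estimator = c("plugin", "miller_madow"),
                            rounding = c("half_even", "half_up"),
                            repetitions = NULL) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  rounding <- match.arg(rounding)
  scale <- scale %||% rating_scale(dataset)
  data <- tibble::as_tibble(as.data.frame(dataset))

  reps <- repetitions %||% max(table(paste(data$participant, data$block,
                                           data$stimulus, sep = "\r")))
  # a participant is usable only if every one of their blocks is complete
  complete <- data |>
    dplyr::count(.data$participant, .data$block, .data$stimulus) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(ok = all(.data$n == reps), .groups = "drop")
  dropped <- complete$participant[!complete$ok]
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped),
            " participant(s) with incomplete blocks: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...", call. = FALSE)
    data <- data[!data$participant %in% dropped, , drop = FALSE]
  }
  if (nrow(data) == 0L) {
    stop("no complete participants in the dataset", call. = FALSE)
  }

  per_block <- data |>
    dplyr::group_by(.data$participant, .data$block) |>
    dplyr::summarise(n_stimuli = dplyr::n_distinct(.data$stimulus),
                     pairs = list(block_pairs(
                       dplyr::pick(dplyr::everything()),
                       mode = mode, rounding = rounding)),
                     .groups = "drop")

  estimate <- function(inputs, outputs) {
    tab <- contingency_from_pairs(inputs, outputs, scale = scale)
    if (estimator == "miller_madow") miller_madow_bits(tab)
    else mutual_information_bits(tab)
  }

  if (pooled) {
    curve <- per_block |>
      dplyr::group_by(.data$n_stimuli) |>
      dplyr::summarise(
        mi_mean_bits = estimate(
          unlist(lapply(.data$pairs, `[[`, "inputs")),
          unlist(lapply(.data$pairs, `[[`, "outputs"))),
        mi_sd_bits = NA_real_,
        n_participants = dplyr::n_distinct(.data$participant),
        .groups = "drop")
  } else {
    curve <- per_block |>
      dplyr::mutate(mi_bits = vapply(
        .data$pairs, function(p) estimate(p$inputs, p$outputs), numeric(1))) |>
      dplyr::group_by(.data$n_stimuli) |>
      dplyr::summarise(mi_mean_bits = mean(.data$mi_bits),
                       mi_sd_bits = if (dplyr::n() > 1) {
                         stats::sd(.data$mi_bits)
                       } else 0,
                       n_participants = dplyr::n(),
                       .groups = "drop")
  }

  curve <- curve |>
    dplyr::mutate(source_entropy_bits = log2(.data$n_stimuli)) |>
    dplyr::select("n_stimuli", "source_entropy_bits", "mi_mean_bits",
                  "mi_sd_bits", "n_participants") |>
    dplyr::arrange(.data$source_entropy_bits)
  class(curve) <- c("mi_curve", class(curve))
  curve
}

#' Write a mutual-information curve as CSV
#'
#' @param curve An `mi_curve` from [aggregate_curve()].
#' @param path Output CSV path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
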