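# Long-format rating data: validation and CSV input/output.
# One row per observed rating, with columns
#   participant, block, stimulus, repetition, rating.

RATING_COLUMNS <- c("participant", "block", "stimulus", "repetition", "rating")

#' Validate a long-format rating dataset
#'
#' Checks a data frame of individual ratings — one row per
#' participant x block x stimulus x repetition — against the declared rating
#' scale and marks it as a rating dataset. Ratings must be integers within
#' the scale, and the (participant, block, stimulus, repetition) coordinates
#' must be unique. Completeness (every stimulus rated the designed number of
#' times) is enforced later, when per-block mutual information is computed,
#' so partially collected data can still be loaded and inspected.
#'
#' @param data Data frame with columns `participant`, `block`, `stimulus`,
#'   `repetition`, `rating`.
#' @param scale_min,scale_max Integer bounds of the rating scale (defaults 1
#'   and 10).
#' @return A tibble of class `rating_dataset` with attributes `scale_min` and
#'   `scale_max`.
#' @export
rating_dataset <- function(data, scale_min = 1L, scale_max = 10L) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(RATING_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("rating dataset is empty", call. = FALSE)
  if (any(data$rating != round(data$rating))) {
    stop("non-integer ratings found", call. = FALSE)
  }
  out_of_scale <- data$rating < scale_min | data$rating > scale_max
  if (any(out_of_scale)) {
    stop(sum(out_of_scale), " rating(s) outside the scale [",
         scale_min, ", ", scale_max, "]", call. = FALSE)
  }
  if (any(data$repetition < 1 | data$repetition != round(data$repetition))) {
    stop("repetition indices must be integers >= 1", call. = FALSE)
  }
  key <- paste(data$participant, data$block, data$stimulus, data$repetition,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant, block, stimulus, repetition) rows",
         call. = FALSE)
  }
  data$rating <- as.integer(data$rating)
  data$repetition <- as.integer(data$repetition)
  structure(data,
            scale_min = as.integer(scale_min),
            scale_max = as.integer(scale_max),
            class = c("rating_dataset",
                      setdiff(class(data), "rating_dataset")))
}

rating_scale <- function(dataset, scale_min = NULL, scale_max = NULL) {
  lo <- scale_min %||% attr(dataset, "scale_min") %||% 1L
  hi <- scale_max %||% attr(dataset, "scale_max") %||% 10L
  seq.int(as.integer(lo), as.integer(hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a rating dataset as CSV
#'
#' The CSV dialect is UTF-8, comma-separated, with the header row
#' `participant,block,stimulus,repetition,rating` and one rating per row.
#'
#' @param path Path of the CSV file.
#' @inheritParams rating_dataset
#' @return `read_ratings()` returns a validated `rating_dataset`;
#'   `write_ratings()` invisibly returns `path`.
#' @export
read_ratings <- function(path, scale_min = 1L, scale_max = 10L) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  rating_dataset(data, scale_min = scale_min, scale_max = scale_max)
}

#' @rdname read_ratings
#' @param dataset A `rating_dataset` (or compatible data frame).
#' @export
write_ratings <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[RATING_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Map a seven-point rating onto a ten-point scale
#'
#' Linear map `1 + 9 * (x - 1) / 6` preserving both endpoints, used to place
#' reference mean ratings collected on a 1-7 scale onto the 1-10 scale before
#' selecting or comparing stimuli.
#'
#' @param x Numeric rating(s) in `[1, 7]`.
#' @return Rating(s) in `[1, 10]`; the midpoint 4 maps to 5.5.
#' @export
sevenpoint_to_tenpoint <- function(x) {
  x <- as.numeric(x)
  if (any(x < 1 | x > 7)) {
    stop("seven-point ratings must lie in [1, 7]", call. = FALSE)
  }
  1 + 9 * (x - 1) / 6
}

#' Pearson correlation between two sets of per-stimulus mean ratings
#'
#' Validates stimulus selection by correlating mean ratings from the sample
#' at hand against reference (e.g. crowd-sourced) means for the same stimuli.
#'
#' @param means_a,means_b Equal-length numeric vectors (length >= 3) with
#'   nonzero variance.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_validate <- function(means_a, means_b) {
  if (length(means_a) != length(means_b)) {
    stop("mean vectors must have equal length", call. = FALSE)
  }
  if (length(means_a) < 3L) {
    stop("need at least 3 stimuli to correlate", call. = FALSE)
  }
  if (stats::sd(means_a) == 0 || stats::sd(means_b) == 0) {
    stop("zero variance in one of the mean vectors", call. = FALSE)
  }
  stats::cor(means_a, means_b, method = "pearson")
}
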