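# Discrete entropy and mutual information on contingency tables, in bits.
# All quantities use log base 2 throughout; 0 * log(0) is taken as 0 by
# continuity, so empty cells and empty categories contribute nothing.

.PROB_TOL <- 1e-9

#' Contingency table of paired category labels
#'
#' Builds the joint count table of (input, output) label pairs over a declared
#' category scale. The table always spans the full declared scale on both
#' axes, retaining all-zero rows and columns, so that table shapes are stable
#' across participants and blocks; empty categories do not change the plug-in
#' mutual information. Set `drop_empty = TRUE` to restrict the table to the
#' categories actually observed (this matters only for estimators that count
#' categories, not for plug-in mutual information).
#'
#' @param inputs,outputs Parallel vectors of integer category labels; element
#'   `i` of each forms one (input, output) pair.
#' @param scale Ordered vector of integer category labels defining the rating
#'   scale, e.g. `1:10`. Both axes use this scale.
#' @param drop_empty If `TRUE`, drop categories with zero marginal count from
#'   both axes after tabulation.
#' @return A `contingency_table`: an integer matrix of counts with the input
#'   categories as rows and output categories as columns, carrying the
#'   category labels in its `dimnames` and the total count in attribute `n`.
#' @examples
#' tab <- contingency_from_pairs(c(1, 2), c(1, 2), scale = 1:2)
#' mutual_information_bits(tab) # 1 bit: noiseless binary channel
#' @export
contingency_from_pairs <- function(inputs, outputs, scale, drop_empty = FALSE) {
  if (length(inputs) == 0L || length(outputs) == 0L) {
    stop("cannot build a contingency table from zero pairs", call. = FALSE)
  }
  if (length(inputs) != length(outputs)) {
    stop("`inputs` and `outputs` must have the same length", call. = FALSE)
  }
  scale <- as.integer(scale)
  bad <- setdiff(unique(c(inputs, outputs)), scale)
  if (length(bad) > 0L) {
    stop("label(s) outside the declared scale: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fx <- factor(as.integer(inputs), levels = scale)
  fy <- factor(as.integer(outputs), levels = scale)
  counts <- table(fx, fy)
  counts <- matrix(as.integer(counts), nrow = length(scale),
                   dimnames = list(input = scale, output = scale))
  if (drop_empty) {
    counts <- counts[rowSums(counts) > 0L, colSums(counts) > 0L, drop = FALSE]
  }
  new_contingency_table(counts)
}

#' @rdname contingency_from_pairs
#' @param counts A non-negative integer matrix of joint counts (inputs in
#'   rows, outputs in columns).
#' @export
as_contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative cell counts", call. = FALSE)
  if (any(counts != round(counts))) stop("non-integer cell counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  if (is.null(colnames(counts))) colnames(counts) <- seq_len(ncol(counts))
  new_contingency_table(counts)
}

new_contingency_table <- function(counts) {
  structure(counts, n = sum(counts), class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> ", nrow(x), "x", ncol(x),
      " categories, n = ", attr(x, "n"), "\n", sep = "")
  print(unclass(structure(x, n = NULL)), ...)
  invisible(x)
}

check_table <- function(table) {
  counts <- unclass(as.matrix(table))
  if (any(counts < 0)) stop("negative cell counts", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("contingency table has total count 0", call. = FALSE)
  counts
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' `H = -sum(p * log2(p))` with `0 * log2(0) = 0`. One bit is the information
#' needed to decide between two equally likely alternatives: a uniform source
#' over four categories has entropy 2 bits, over six categories about 2.6
#' bits, over 150 categories about 7.2 bits.
#'
#' @param probs Non-negative probabilities summing to 1 (within `1e-9`).
#' @return Entropy in bits, between 0 and `log2(length(probs))`.
#' @examples
#' entropy_bits(rep(1 / 6, 6)) # 2.585 bits
#' @export
entropy_bits <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) == 0L) stop("empty distribution", call. = FALSE)
  if (any(probs < 0)) {
    stop("invalid distribution: negative probabilities", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > .PROB_TOL) {
    stop("invalid distribution: probabilities sum to ", format(sum(probs)),
         ", not 1", call. = FALSE)
  }
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

#' Plug-in mutual information of a contingency table, in bits
#'
#' Substitutes empirical cell frequencies for probabilities in
#' `I(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`, where `p(x,y)` is the
#' joint cell frequency and `p(x)`, `p(y)` are the marginals. Zero cells
#' contribute nothing. The estimator is upward-biased in small samples; see
#' [miller_madow_bits()] for a first-order correction.
#'
#' @param table A `contingency_table` or a non-negative count matrix with
#'   total count at least 1.
#' @return Mutual information in bits; always in
#'   `[0, min(H(rows), H(columns))]` and invariant under transposition.
#' @examples
#' mutual_information_bits(matrix(c(5, 0, 0, 5), 2)) # 1 bit
#' mutual_information_bits(matrix(1, 2, 2))          # 0 bits (independence)
#' @export
mutual_information_bits <- function(table) {
  counts <- check_table(table)
  p <- counts / sum(counts)
  px <- rowSums(p)
  py <- colSums(p)
  prod_marg <- outer(px, py)
  pos <- p > 0
  # max(0, .) guards the tiny negative values floating-point cancellation can
  # leave on exactly independent tables
  max(0, sum(p[pos] * log2(p[pos] / prod_marg[pos])))
}

#' Miller-Madow corrected mutual information, in bits
#'
#' Plug-in mutual information minus the first-order small-sample bias term
#' `(Kx - 1) (Ky - 1) / (2 n ln 2)`, where `Kx` and `Ky` are the numbers of
#' input and output categories with nonzero marginal counts (occupied
#' categories, not the declared scale size, which would over-correct sparse
#' tables). The result is clipped at 0. Intended as a bias diagnostic
#' alongside the plug-in estimate for small tables such as a single block's
#' 15-50 rating pairs.
#'
#' @inheritParams mutual_information_bits
#' @return Bias-corrected mutual information in bits, never negative.
#' @export
miller_madow_bits <- function(table) {
  counts <- check_table(table)
  kx <- sum(rowSums(counts) > 0)
  ky <- sum(colSums(counts) > 0)
  bias <- (kx - 1) * (ky - 1) / (2 * sum(counts) * log(2))
  max(0, mutual_information_bits(table) - bias)
}

#' Mutual information of a channel under a uniform input, in bits
#'
#' Given a row-stochastic confusion matrix (one row per input symbol, one
#' column per output category), computes the mutual information transmitted
#' when the inputs are presented equally often. This is the information rate
#' of the uniform-input channel, the analytic ground truth against which
#' empirical estimates from simulated raters are validated. (It is not the
#' full channel capacity, which would maximize over input distributions.)
#'
#' @param confusion Matrix with non-negative entries whose rows each sum to 1
#'   within `1e-9`.
#' @return Mutual information in bits.
#' @examples
#' bsc <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
#' mi_uniform_input(bsc) # 1 - H2(0.1), about 0.531 bits
#' @export
mi_uniform_input <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("negative channel probabilities", call. = FALSE)
  bad <- which(abs(rowSums(confusion) - 1) > .PROB_TOL)
  if (length(bad) > 0L) {
    stop("confusion matrix row(s) not summing to 1: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  k <- nrow(confusion)
  joint <- confusion / k
  py <- colSums(joint)
  prod_marg <- outer(rep(1 / k, k), py)
  pos <- joint > 0
  max(0, sum(joint[pos] * log2(joint[pos] / prod_marg[pos])))
}
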