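entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Gain ratio of a continuous attribute
#'
#' Ranks an attribute by the C4.5-style gain ratio of its single best
#' binary split: candidate thresholds are the midpoints between
#' consecutive distinct sorted values; the split maximizing information
#' gain is chosen, and the returned rank is that split's information gain
#' divided by its intrinsic (split) information, both in bits. Following
#' C4.5's treatment of continuous attributes, the best gain must clear
#' the threshold-selection penalty `log2(candidates)/n` to count at all —
#' without this gate, the maximum over thousands of candidate thresholds
#' of a pure-noise attribute lands on chance fluctuations (often at
#' unbalanced cuts whose tiny intrinsic information inflates the ratio).
#' Constant attributes, and attributes whose best split carries no
#' significant information, rank 0.
#'
#' The rank depends only on the ordering of the values, so it is
#' invariant to any monotone rescaling of the attribute.
#'
#' @param values Numeric vector of attribute measurements (one per sample).
#' @param labels Class labels (coerced to factor), same length as `values`.
#' @return Non-negative gain-ratio rank (0 when no informative split exists).
#' @examples
#' gain_ratio(c(1, 2, 3, 4), c("A", "A", "B", "B")) # 1
#' @export
gain_ratio <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  if (length(values) != length(labels)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  if (length(values) < 2) stop("need at least 2 samples", call. = FALSE)
  if (nlevels(labels) < 2) {
    stop("need at least 2 classes present in labels", call. = FALSE)
  }
  n <- length(values)
  ord <- order(values)
  sv <- values[ord]
  sl <- as.integer(labels)[ord]
  cuts <- which(diff(sv) > 0) # split after position i
  if (length(cuts) == 0) return(0) # constant attribute
  k <- nlevels(labels)
  # cumulative class counts up to each sorted position
  cum <- vapply(seq_len(k), function(c) cumsum(sl == c), numeric(n))
  total <- cum[n, ]
  h_total <- entropy_bits(total)
  nl <- cuts
  nr <- n - nl
  left <- cum[cuts, , drop = FALSE]
  right <- matrix(total, nrow = length(cuts), ncol = k, byrow = TRUE) - left
  h_left <- apply(left, 1, entropy_bits)
  h_right <- apply(right, 1, entropy_bits)
  ig <- h_total - (nl / n) * h_left - (nr / n) * h_right
  best <- which.max(ig)
  # C4.5 continuous-attribute gate: the chosen threshold is one of
  # length(cuts) candidates, so the gain must exceed log2(cuts)/n
  if (ig[best] <= log2(length(cuts)) / n) return(0)
  ii <- entropy_bits(c(nl[best], nr[best]))
  if (ii == 0) return(0)
  unname(ig[best] / ii)
}

#' Gain-ratio attribute weights
#'
#' Ranks every attribute once by [gain_ratio()] and normalizes the ranks
#' into weights summing to 1. The table is computed a single time at the
#' start of a run and then guides mutation (which replaces the
#' lowest-weight terminal) and recombination (which moves the
#' highest-weight-sum gene). If every rank is 0 (e.g. an all-constant
#' matrix) uniform weights are used with a warning.
#'
#' @param data Data frame or matrix of expression values, samples in rows
#'   and attributes in columns. Non-numeric columns (e.g. sample IDs or
#'   the label column) are dropped.
#' @param labels Class labels, one per sample, or the name of a column of
#'   `data` holding them.
#' @return A tibble with columns `attribute`, `rank`, `weight`, sorted by
#'   descending weight (ties stable by attribute ID).
#' @examples
#' sim <- simulate_expression(n_samples = 30, n_attributes = 20,
#'                            n_informative = 2, seed = 1)
#' head(compute_weights(sim$data, "class"))
#' @export
compute_weights <- function(data, labels) {
  if (is.character(labels) && length(labels) == 1 && labels %in% colnames(data)) {
    lab <- data[[labels]]
    data <- data[, setdiff(colnames(data), labels), drop = FALSE]
  } else {
    lab <- labels
  }
  lab <- droplevels(as.factor(lab))
  x <- as.data.frame(data)
  numeric_cols <- vapply(x, is.numeric, logical(1))
  x <- x[, numeric_cols, drop = FALSE]
  if (ncol(x) == 0) stop("no numeric attribute columns in data", call. = FALSE)
  if (min(table(lab)) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  ranks <- vapply(x, gain_ratio, numeric(1), labels = lab)
  m <- length(ranks)
  if (all(ranks == 0)) {
    warning("all gain-ratio ranks are zero; falling back to uniform weights",
            call. = FALSE)
    weights <- rep(1 / m, m)
  } else {
    weights <- ranks / sum(ranks)
  }
  out <- tibble::tibble(attribute = colnames(x), rank = unname(ranks),
                        weight = unname(weights))
  # descending weight; ties broken deterministically by attribute ID
  out[order(-out$weight, out$attribute), ]
}
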