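#' Gene tail length
#'
#' The tail of a GEP gene must hold enough terminals to close every tree
#' the head can open: `t = h*(n - 1) + 1`, where `n` is the maximum arity
#' of the function set.
#'
#' @param h Head length (>= 1).
#' @param n Maximum function arity (>= 1).
#' @return Integer tail length.
#' @examples
#' tail_length(3, 2) # 4
#' @export
tail_length <- function(h, n) {
  if (h < 1 || n < 1) stop("h and n must be positive", call. = FALSE)
  as.integer(h) * (as.integer(n) - 1L) + 1L
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Per-generation head size
#'
#' Sizes chromosomes so that a generation of `CH` chromosomes covers the
#' current terminal set of size `T` about twice (`L * CH = 2T` with
#' `N = 2` genes per chromosome), giving
#' `h = max(h_min, round((T/CH - 1)/n))`, rounding half away from zero.
#' The clamp `h_min` keeps genes informative once the terminal set has
#' shrunk far below `CH`.
#'
#' @param T Current terminal-set size.
#' @param CH Chromosomes per generation.
#' @param n Maximum function arity.
#' @param h_min Minimum head size (default 3).
#' @return Integer head size, always `>= h_min`.
#' @examples
#' head_size(2200, 150) # 7
#' head_size(5, 150)    # 3 (clamped)
#' @export
head_size <- function(T, CH, n = 2L, h_min = 3L) {
  if (T < 1 || CH < 1 || n < 1 || h_min < 1) {
    stop("all sizing inputs must be positive", call. = FALSE)
  }
  h <- round_half_away((T / CH - 1) / n)
  as.integer(max(h_min, h))
}

#' Chromosome length
#'
#' `L = N * (h + t)` with `t` from [tail_length()].
#'
#' @inheritParams tail_length
#' @param N Genes per chromosome.
#' @return Integer chromosome length.
#' @examples
#' chromosome_length(3, 2, 1) # 7
#' @export
chromosome_length <- function(h, n, N) {
  if (N < 1) stop("N must be positive", call. = FALSE)
  as.integer(N) * (as.integer(h) + tail_length(h, n))
}
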