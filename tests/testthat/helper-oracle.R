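# Independent brute-force karva decoder: an explicit FIFO queue walks the
# open child slots one node at a time, consuming gene positions strictly
# left to right. Deliberately written with mutable node records rather
# than the arithmetic offset scheme used by the package.
oracle_decode <- function(gene, functions = dgs_functions()) {
  symbols <- c(gene$head, gene$tail)
  arity <- function(s) {
    if (s %in% names(functions)) unname(functions[[match(s, names(functions))]]) else 0L
  }
  nodes <- list(list(symbol = symbols[1], kids = integer()))
  queue <- if (arity(symbols[1]) > 0) 1L else integer()
  pos <- 1L
  while (length(queue) > 0) {
    parent <- queue[1]
    queue <- queue[-1]
    for (j in seq_len(arity(nodes[[parent]]$symbol))) {
      pos <- pos + 1L
      nodes[[pos]] <- list(symbol = symbols[pos], kids = integer())
      nodes[[parent]]$kids <- c(nodes[[parent]]$kids, pos)
      if (arity(symbols[pos]) > 0) queue <- c(queue, pos)
    }
  }
  to_nested <- function(i) {
    list(symbol = nodes[[i]]$symbol,
         children = lapply(nodes[[i]]$kids, to_nested))
  }
  list(root = to_nested(1L), expressed_length = pos)
}

# A tiny two-class dataset with one perfectly separating attribute
# (margin far above the noise) plus pure-noise attributes.
separable_data <- function(n = 40, n_noise = 3, seed = 42) {
  withr::with_seed(seed, {
    y <- factor(rep(c("a", "b"), each = n / 2))
    x <- data.frame(sep = ifelse(y == "b", 10, -10) + rnorm(n, sd = 0.1))
    for (i in seq_len(n_noise)) x[[paste0("noise", i)]] <- rnorm(n)
    x$class <- y
    tibble::as_tibble(x)
  })
}

# Shared slow fixtures for the acceptance suite: ten seeded selection
# runs on the planted-informative synthetic conditions, computed once.
.acceptance_cache <- new.env(parent = emptyenv())

recovery_runs <- function() {
  if (!is.null(.acceptance_cache$recovery)) return(.acceptance_cache$recovery)
  runs <- lapply(1:10, function(seed) {
    sim <- simulate_expression(n_samples = 60, n_attributes = 500,
                               n_informative = 5, effect_size = 2,
                               noise_sd = 1, class_balance = 0.5,
                               seed = seed)
    fit <- dgs_run(sim$data, config = dgs_config(CH = 100, N = 2, r = 0.2,
                                                 seed = seed))
    list(sim = sim, fit = fit)
  })
  .acceptance_cache$recovery <- runs
  runs
}
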