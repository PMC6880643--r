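toy_weights <- function(ids, w = NULL) {
  if (is.null(w)) w <- rev(seq_along(ids)) / sum(seq_along(ids))
  out <- tibble::tibble(attribute = ids, rank = w * 100, weight = w / sum(w))
  out[order(-out$weight, out$attribute), ]
}

test_that("initial populations have the documented shape", {
  ts13 <- paste0("a", 1:13)
  cfg <- dgs_config(CH = 10, N = 1, seed = 1)
  set.seed(1)
  pop <- init_population(ts13, cfg)
  expect_length(pop, 10L)
  for (e in pop) {
    expect_length(e$chromosome$genes, 1L)
    g <- e$chromosome$genes[[1]]
    expect_length(c(g$head, g$tail), 7L) # h = 3 clamp, n = 2
    expect_identical(validate_chromosome(e$chromosome, ts13), character())
    expect_null(e$fitness)
  }

  # a single-attribute terminal set can only select that attribute
  set.seed(2)
  pop1 <- init_population("a9", dgs_config(CH = 5, N = 2))
  for (e in pop1) {
    expect_identical(expressed_terminals(e$chromosome), "a9")
  }

  # determinism
  set.seed(3); p1 <- init_population(ts13, cfg)
  set.seed(3); p2 <- init_population(ts13, cfg)
  expect_identical(p1, p2)
})

test_that("ranking is by fitness, then smaller subsets, then stable", {
  mk <- function(f, s, tag) {
    list(chromosome = tag, fitness = list(AC = f, s = s, f = f))
  }
  pop <- list(mk(0.7, 2, "a"), mk(0.9, 4, "b"), mk(0.8, 1, "c"))
  expect_identical(vapply(rank_population(pop), `[[`, "", "chromosome"),
                   c("b", "c", "a"))
  tied <- list(mk(0.9, 4, "big"), mk(0.9, 2, "small"))
  expect_identical(vapply(rank_population(tied), `[[`, "", "chromosome"),
                   c("small", "big"))
  sorted <- list(mk(0.9, 1, "x"), mk(0.8, 1, "y"), mk(0.7, 1, "z"))
  expect_identical(rank_population(sorted), sorted)
})

test_that("terminal-set extraction unions the top half and never grows", {
  ts <- paste0("a", 1:13)
  w <- toy_weights(ts)
  set.seed(4)
  ok <- vapply(1:20, function(i) {
    pop <- init_population(ts, dgs_config(CH = 10, N = 1))
    pop <- lapply(pop, function(e) {
      s <- length(expressed_terminals(e$chromosome))
      e$fitness <- list(AC = runif(1), s = s, f = runif(1))
      e
    })
    pop <- rank_population(pop)
    nxt <- extract_terminal_set(pop, w, 0.5)
    manual <- unique(unlist(lapply(pop[1:5], function(e)
      expressed_terminals(e$chromosome))))
    length(nxt) <= length(ts) && all(nxt %in% ts) &&
      !anyDuplicated(nxt) &&
      identical(nxt, w$attribute[w$attribute %in% nxt]) &&
      setequal(nxt, manual)
  }, logical(1))
  expect_true(all(ok))

  # identical chromosomes: the set is that chromosome's terminal support
  ch <- new_chromosome(list(new_gene(c("+", "a2", "a3"),
                                     c("a5", "a7", "a2", "a2"))))
  pop_same <- lapply(1:6, function(i)
    list(chromosome = ch, fitness = list(AC = 0.5, s = 3, f = 0.5)))
  # expressed region is (+ a2 a3); the tail is never reached
  expect_setequal(extract_terminal_set(pop_same, w, 0.5),
                  c("a2", "a3"))
  expect_setequal(extract_terminal_set(pop_same, w, 0.5,
                                       expressed_only = FALSE),
                  c("a2", "a3", "a5", "a7"))
})

test_that("mutation always replaces the weakest expressed terminal lawfully", {
  ts <- paste0("a", 1:10)
  w <- toy_weights(ts) # a1 strongest ... a10 weakest
  wl <- stats::setNames(w$weight, w$attribute)
  fs <- dgs_functions()
  # expressed terminals of one gene, with duplicates, via the decoder
  expressed_syms <- function(g) {
    leaves <- function(n) {
      if (length(n$children) == 0) n$symbol
      else unlist(lapply(n$children, leaves))
    }
    leaves(decode_gene(g, fs)$root)
  }
  set.seed(5)
  n_changed <- 0L
  valid <- rule_ok <- TRUE
  for (i in 1:10000) {
    ch <- random_chromosome(ts, fs, h = 3L, n_genes = 2L)
    out <- mutate_chromosome(ch, w, ts, fs)
    valid <- valid && length(validate_chromosome(out, ts, fs)) == 0L

    before <- unlist(lapply(ch$genes, function(g) c(g$head, g$tail)))
    after <- unlist(lapply(out$genes, function(g) c(g$head, g$tail)))
    diff_pos <- which(before != after)
    expr_terms <- unlist(lapply(ch$genes, expressed_syms))
    expr_terms <- expr_terms[!expr_terms %in% names(fs)]
    w_min <- min(wl[expr_terms])
    if (length(diff_pos) == 1L) {
      n_changed <- n_changed + 1L
      repl <- after[diff_pos]
      rule_ok <- rule_ok &&
        # the replaced symbol was a minimum-weight expressed terminal ...
        isTRUE(all.equal(unname(wl[before[diff_pos]]), w_min)) &&
        # ... and the replacement is a function or strictly stronger
        (repl %in% names(fs) || wl[repl] > wl[before[diff_pos]])
    } else {
      # untouched only in the degenerate no-stronger-terminal case,
      # which requires the weakest expressed terminal to sit in a tail
      rule_ok <- rule_ok && length(diff_pos) == 0L &&
        isTRUE(all.equal(w_min, min(wl[ts])))
    }
  }
  expect_true(valid)
  expect_true(rule_ok)
  expect_gt(n_changed, 9000)
})

test_that("mutation leaves the chromosome alone when nothing is stronger", {
  ts <- c("a1", "a2")
  w <- toy_weights(ts, c(0.5, 0.5))
  # weakest terminal sits in the tail and no strictly higher weight exists
  ch <- new_chromosome(list(new_gene(c("+", "a1", "a2"),
                                     c("a1", "a2", "a1", "a2"))))
  set.seed(6)
  out <- mutate_chromosome(ch, w, ts)
  # head replacement by a function is allowed; the tail branch must not move
  expect_identical(out$genes[[1]]$tail, ch$genes[[1]]$tail)
})

test_that("recombination only accepts strictly improving children", {
  ts <- paste0("a", 1:8)
  w <- toy_weights(ts)
  fs <- dgs_functions()
  # toy evaluator: fitness rewards the total weight of expressed terminals
  wl <- stats::setNames(w$weight, w$attribute)
  evaluator <- function(ch) {
    sel <- expressed_terminals(ch, fs)
    f <- sum(wl[sel])
    list(AC = f, s = length(sel), f = f)
  }
  set.seed(7)
  accepted <- 0L
  strict <- TRUE
  for (i in 1:1000) {
    a <- random_chromosome(ts, fs, h = 3L, n_genes = 2L)
    b <- random_chromosome(ts, fs, h = 3L, n_genes = 2L)
    pa <- list(chromosome = a, fitness = evaluator(a))
    pb <- list(chromosome = b, fitness = evaluator(b))
    out <- recombine(pa, pb, w, evaluator, fs)
    if (!identical(out, list(pa, pb))) {
      accepted <- accepted + 1L
      strict <- strict &&
        out[[1]]$fitness$f > max(pa$fitness$f, pb$fitness$f)
    }
  }
  expect_true(strict)
  expect_gt(accepted, 50) # the operator does fire

  # identical parents can never strictly improve
  a <- random_chromosome(ts, fs, h = 3L, n_genes = 2L)
  pa <- list(chromosome = a, fitness = evaluator(a))
  expect_identical(recombine(pa, pa, w, evaluator, fs), list(pa, pa))
})

test_that("a small run terminates, logs, and reproduces bit-identically", {
  sim <- simulate_expression(n_samples = 30, n_attributes = 40,
                             n_informative = 3, effect_size = 2.5, seed = 9)
  cfg <- dgs_config(CH = 20, N = 2, max_generations = 12, seed = 9)
  fit1 <- dgs_run(sim$data, config = cfg)
  fit2 <- dgs_run(sim$data, config = cfg)
  expect_identical(fit1$selected, fit2$selected)
  expect_identical(fit1$log, fit2$log)

  expect_s3_class(fit1$log, "tbl_df")
  expect_named(fit1$log, c("generation", "T", "h", "best_f", "best_AC",
                           "best_s"))
  expect_true(all(diff(fit1$log$T) <= 0))
  expect_lte(nrow(fit1$log), 12L)
  expect_true(fit1$termination %in% c("stagnation", "max_generations"))
  expect_gt(length(fit1$selected), 0)
  expect_true(all(fit1$selected %in% colnames(sim$data)))
  expect_equal(fit1$best$s, length(fit1$selected))

  # elitism of the report: nothing in the final generation beats it
  expect_gte(fit1$best$f, max(0, fit1$log$best_f[nrow(fit1$log)] - 1e-9))
})

test_that("degenerate inputs fail fast before the loop", {
  const <- tibble::tibble(sample_id = paste0("s", 1:8),
                          class = factor(rep(c("A", "B"), 4)),
                          g1 = rep(1, 8), g2 = rep(2, 8))
  expect_error(dgs_run(const), "constant")

  one_class <- simulate_expression(n_samples = 12, n_attributes = 5,
                                   n_informative = 1, seed = 1)$data
  one_class$class <- factor(rep("A", 12))
  expect_error(dgs_run(one_class), "2 classes")

  lonely <- simulate_expression(n_samples = 12, n_attributes = 5,
                                n_informative = 1, seed = 2)$data
  lonely$class <- factor(c("B", rep("A", 11)))
  expect_error(dgs_run(lonely), "at least 2 samples")
})
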