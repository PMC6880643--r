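write_lines <- function(lines, name) {
  path <- withr::local_tempfile(fileext = paste0("-", name),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a toy CSV with a label column loads as a tidy dataset", {
  p <- write_lines(c("id,g1,g2,grp",
                     "s1,1.5,2.0,A",
                     "s2,0.5,1.0,B",
                     "s3,2.5,3.0,A"), "toy.csv")
  d <- read_expression(p, label_col = "grp")
  expect_named(d, c("sample_id", "class", "g1", "g2"))
  expect_equal(nrow(d), 3)
  expect_s3_class(d$class, "factor")
  expect_equal(d$g1, c(1.5, 0.5, 2.5))
})

test_that("transposed input with the orientation flag loads identically", {
  p_rows <- write_lines(c("id,g1,g2",
                          "s1,1.5,2.0",
                          "s2,0.5,1.0",
                          "s3,2.5,3.0"), "rows.csv")
  p_cols <- write_lines(c("probe,s1,s2,s3",
                          "g1,1.5,0.5,2.5",
                          "g2,2.0,1.0,3.0"), "cols.csv")
  p_lab <- write_lines(c("sample,grp", "s1,A", "s2,B", "s3,A"), "lab.csv")
  a <- read_expression(p_rows, labels = p_lab)
  b <- read_expression(p_cols, orientation = "attributes_in_rows",
                       labels = p_lab)
  expect_equal(a, b)
})

test_that("label and cell problems raise descriptive errors", {
  p <- write_lines(c("id,g1", "s1,1", "s2,2", "s3,3"), "d.csv")
  p_lab <- write_lines(c("sample,grp", "s1,A", "s3,B"), "short.csv")
  expect_error(read_expression(p, labels = p_lab), "s2")

  p_dup <- write_lines(c("id,g1", "s1,1", "s1,2", "s3,3"), "dup.csv")
  expect_error(read_expression(p_dup, label_col = "g1"), "duplicate")

  p_txt <- write_lines(c("id,g1,grp", "s1,1,A", "s2,oops,B", "s3,3,A"),
                       "txt.csv")
  expect_error(read_expression(p_txt, label_col = "grp"), "non-numeric")

  expect_error(read_expression(p, label_col = "missing"), "not found")
  expect_error(read_expression(file.path(tempdir(), "nope.csv"),
                               label_col = "x"), "not found")
})

test_that("sparse missing values are mean-imputed, heavy ones rejected", {
  vals <- c(sprintf("s%02d,%d,A", 1:10, 1:10),
            sprintf("s%02d,%d,B", 11:29, 11:29), "s30,,B")
  p <- write_lines(c("id,g1,grp", vals), "na.csv")
  expect_message(d <- read_expression(p, label_col = "grp"), "mean-imputed")
  expect_equal(d$g1[30], mean(1:29))

  heavy <- c("id,g1,grp", "s1,,A", "s2,,A", "s3,3,B", "s4,4,B")
  p2 <- write_lines(heavy, "na2.csv")
  expect_error(read_expression(p2, label_col = "grp"), "missing values")
})

test_that("write-then-read reproduces a dataset to full precision", {
  sim <- simulate_expression(n_samples = 12, n_attributes = 8,
                             n_informative = 2, seed = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_expression(sim$data, p)
  back <- read_expression(p, label_col = "class")
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(sim$data[, -(1:2)]))
  expect_equal(as.character(back$class), as.character(sim$data$class))
})

test_that("the generator is deterministic and correctly shaped", {
  s1 <- simulate_expression(seed = 4)
  s2 <- simulate_expression(seed = 4)
  expect_identical(s1, s2)
  expect_equal(dim(s1$data), c(60, 502))
  expect_length(s1$informative, 5)
  expect_true(all(s1$informative %in% colnames(s1$data)))
  # roughly balanced classes
  expect_gt(min(table(s1$data$class)), 15)

  # planting an explicit informative set gives a ground-truth replicate
  rep <- simulate_expression(informative = s1$informative, seed = 99)
  expect_identical(rep$informative, s1$informative)
  expect_error(simulate_expression(informative = "nope", seed = 1),
               "informative IDs")
  expect_error(simulate_expression(n_attributes = 3, n_informative = 4),
               "exceed")
})

test_that("planted effects shift class means by delta in noise units", {
  sim <- simulate_expression(n_samples = 4000, n_attributes = 20,
                             n_informative = 3, effect_size = 2,
                             noise_sd = 1.5, seed = 6)
  x <- sim$data
  case <- x$class == "case"
  for (a in sim$informative) {
    expect_equal(mean(x[[a]][case]) - mean(x[[a]][!case]), 3,
                 tolerance = 0.1)
  }
  bg <- setdiff(colnames(x)[-(1:2)], sim$informative)
  # background moments: mean 0 and sd = noise_sd within 3 standard errors
  for (a in bg[1:4]) {
    expect_lt(abs(mean(x[[a]])), 3 * 1.5 / sqrt(4000))
    expect_equal(stats::sd(x[[a]]), 1.5, tolerance = 0.1)
  }
})

test_that("a zero effect size leaves 'informative' attributes null", {
  t_inf <- c(); t_bg <- c()
  for (seed in 1:10) {
    sim <- simulate_expression(n_samples = 200, n_attributes = 50,
                               n_informative = 5, effect_size = 0,
                               seed = seed)
    x <- sim$data
    case <- x$class == "case"
    tstat <- vapply(colnames(x)[-(1:2)], function(a) {
      unname(stats::t.test(x[[a]][case], x[[a]][!case])$statistic)
    }, numeric(1))
    t_inf <- c(t_inf, tstat[sim$informative])
    t_bg <- c(t_bg, tstat[setdiff(names(tstat), sim$informative)])
  }
  expect_gt(suppressWarnings(stats::ks.test(t_inf, t_bg)$p.value), 0.01)
})

test_that("strong effects push every planted attribute into the top ranks", {
  sim <- simulate_expression(n_samples = 200, n_attributes = 500,
                             n_informative = 5, effect_size = 3, seed = 7)
  w <- compute_weights(sim$data, "class")
  bg_ranks <- w$rank[!w$attribute %in% sim$informative]
  cutoff <- stats::quantile(bg_ranks, 0.99)
  expect_true(all(w$rank[w$attribute %in% sim$informative] > cutoff))
})

test_that("run results are written as deterministic plain-text reports", {
  sim <- simulate_expression(n_samples = 24, n_attributes = 20,
                             n_informative = 2, effect_size = 2.5, seed = 8)
  fit <- dgs_run(sim$data, config = dgs_config(CH = 10, max_generations = 5,
                                               seed = 8))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  paths <- write_dgs_result(fit, out1)
  expect_true(all(file.exists(paths)))

  sel <- readr::read_tsv(file.path(out1, "selected_attributes.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(sel), fit$best$s)
  expect_named(sel, c("rank", "attribute", "weight"))

  summ <- readr::read_tsv(file.path(out1, "run_summary.tsv"),
                          show_col_types = FALSE)
  expect_true(all(c("best_accuracy", "termination", "generations", "seed")
                  %in% summ$key))
  expect_gte(as.integer(summ$value[summ$key == "generations"]), 1L)

  log <- readr::read_tsv(file.path(out1, "generation_log.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(log), nrow(fit$log))

  # byte-identical re-write
  write_dgs_result(fit, out2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
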