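sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a delimited expression matrix
#'
#' Loads a comma- or tab-delimited text matrix (delimiter sniffed from
#' the header line) whose first column holds IDs, and returns a tidy
#' tibble with one row per sample: a `sample_id` column, a `class`
#' column, and one numeric column per attribute. GEO-style exports with
#' probes in rows are transposed on load via
#' `orientation = "attributes_in_rows"`.
#'
#' Labels come either from a column of the matrix itself (`label_col`,
#' samples-in-rows orientation only) or from a separate two-column
#' delimited file `labels` (sample ID, class); every sample must be
#' labelled. Isolated missing values (at most 5% per attribute) are
#' mean-imputed with a message; attributes missing more than that, or
#' non-numeric cells, raise errors.
#'
#' @param path Path to the matrix file.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"attributes_in_rows"`.
#' @param labels Optional path to a two-column label file.
#' @param label_col Optional name of the label column inside the matrix.
#' @return A tibble: `sample_id`, `class` (factor), then attribute
#'   columns.
#' @export
read_expression <- function(path, orientation = c("samples_in_rows",
                                                  "attributes_in_rows"),
                            labels = NULL, label_col = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  id_col <- colnames(raw)[1]
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate IDs in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  if (orientation == "attributes_in_rows") {
    if (!is.null(label_col)) {
      stop("label_col applies only to samples_in_rows matrices; ",
           "use a label file for attributes_in_rows input", call. = FALSE)
    }
    mat_cols <- raw[, -1, drop = FALSE]
    sample_ids <- colnames(mat_cols)
    mat <- t(as.matrix(mat_cols))
    colnames(mat) <- ids
    rownames(mat) <- sample_ids
    df <- tibble::as_tibble(mat, .name_repair = "minimal")
    df <- tibble::add_column(df, sample_id = sample_ids, .before = 1)
  } else {
    df <- raw
    colnames(df)[1] <- "sample_id"
    df$sample_id <- ids
  }

  class_vec <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% colnames(df)) {
      stop("label column '", label_col, "' not found", call. = FALSE)
    }
    class_vec <- as.character(df[[label_col]])
    df <- df[, setdiff(colnames(df), label_col), drop = FALSE]
  } else if (!is.null(labels)) {
    if (!file.exists(labels)) {
      stop("label file not found: ", labels, call. = FALSE)
    }
    lab <- readr::read_delim(labels, delim = sniff_delim(labels),
                             col_types = readr::cols(.default = "c"),
                             show_col_types = FALSE, progress = FALSE)
    if (ncol(lab) < 2) stop("label file needs two columns", call. = FALSE)
    key <- as.character(lab[[1]])
    unmatched <- setdiff(df$sample_id, key)
    if (length(unmatched) > 0) {
      stop("no label for sample ID(s): ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    }
    class_vec <- as.character(lab[[2]])[match(df$sample_id, key)]
  } else {
    stop("provide labels via label_col or a label file", call. = FALSE)
  }

  attr_cols <- setdiff(colnames(df), "sample_id")
  for (a in attr_cols) {
    v <- df[[a]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (sum(is.na(v2)) > sum(is.na(v) | v == "")) {
        stop("non-numeric cells in attribute '", a, "'", call. = FALSE)
      }
      v <- v2
    }
    miss <- is.na(v)
    if (any(miss)) {
      if (mean(miss) > 0.05) {
        stop("attribute '", a, "' has ", round(100 * mean(miss), 1),
             "% missing values (limit 5%)", call. = FALSE)
      }
      v[miss] <- mean(v, na.rm = TRUE)
      message("mean-imputed ", sum(miss), " missing value(s) in '", a, "'")
    }
    df[[a]] <- v
  }
  if (length(unique(class_vec)) < 2) {
    stop("labels must contain at least 2 classes", call. = FALSE)
  }
  tibble::add_column(tibble::as_tibble(df), class = factor(class_vec),
                     .after = "sample_id")
}

#' Synthetic microarray-like dataset with planted informative genes
#'
#' Emulates the shape of a two-class expression study: thousands of
#' continuous attributes, few samples, and a small planted set of
#' class-informative attributes among pure noise. Background attributes
#' are `Normal(0, noise_sd^2)` independent of class; the planted
#' attributes get a `+effect_size * noise_sd` mean shift in the second
#' class. Class labels are drawn independently per sample with
#' probability `class_balance` for the second class.
#'
#' The defaults match the synthetic study conditions used throughout the
#' package tests: 60 samples, 500 attributes, 5 informative attributes
#' shifted by two noise standard deviations.
#'
#' @param n_samples,n_attributes,n_informative Dataset dimensions.
#' @param effect_size Class-mean shift in units of `noise_sd`.
#' @param noise_sd Attribute noise standard deviation.
#' @param class_balance Probability of the positive class.
#' @param informative Optional character vector of attribute IDs to plant
#'   the effect in (must be valid generated IDs); by default a random set
#'   of `n_informative` attributes is chosen. Supplying the IDs of a
#'   previous simulation yields an independent replicate with the same
#'   ground truth.
#' @param seed Integer seed (deterministic output for a given seed).
#' @return A list: `data` (tibble with `sample_id`, `class`, attribute
#'   columns `g0001`...) and `informative` (character vector of planted
#'   attribute IDs).
#' @examples
#' sim <- simulate_expression(seed = 1)
#' dim(sim$data)
#' sim$informative
#' @export
simulate_expression <- function(n_samples = 60L, n_attributes = 500L,
                                n_informative = 5L, effect_size = 2,
                                noise_sd = 1, class_balance = 0.5,
                                informative = NULL, seed = NULL) {
  if (n_informative > n_attributes) {
    stop("n_informative must not exceed n_attributes", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  build <- function() {
    ids <- sprintf("g%04d", seq_len(n_attributes))
    if (is.null(informative)) {
      informative <- sort(sample(ids, n_informative))
    } else {
      if (!all(informative %in% ids)) {
        stop("informative IDs must be among the generated attribute IDs",
             call. = FALSE)
      }
      informative <- sort(informative)
    }
    y <- stats::rbinom(n_samples, 1L, class_balance)
    mat <- matrix(stats::rnorm(n_samples * n_attributes, sd = noise_sd),
                  nrow = n_samples, dimnames = list(NULL, ids))
    shift <- effect_size * noise_sd
    mat[y == 1L, informative] <- mat[y == 1L, informative] + shift
    df <- tibble::as_tibble(mat)
    df <- tibble::add_column(df,
      sample_id = sprintf("s%03d", seq_len(n_samples)),
      class = factor(ifelse(y == 1L, "case", "control"),
                     levels = c("control", "case")),
      .before = 1)
    list(data = df, informative = informative)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Write run results to a directory
#'
#' Writes three plain-text files: `selected_attributes.tsv` (rank, probe
#' ID, weight for every selected attribute), `run_summary.tsv`
#' (key-value echo of the configuration, best accuracy / subset size /
#' fitness, termination reason and generations used) and
#' `generation_log.tsv` (the per-generation log). Output is
#' deterministic: re-running with the same seed reproduces byte-identical
#' files.
#'
#' @param result A `dgs_result` from [dgs_run()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dgs_result <- function(result, out_dir) {
  stopifnot(inherits(result, "dgs_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  sel_path <- file.path(out_dir, "selected_attributes.tsv")
  readr::write_tsv(generics::tidy(result), sel_path)
  log_path <- file.path(out_dir, "generation_log.tsv")
  readr::write_tsv(result$log, log_path)
  summ <- glance_to_kv(result)
  summ_path <- file.path(out_dir, "run_summary.tsv")
  readr::write_tsv(summ, summ_path)
  invisible(c(sel_path, summ_path, log_path))
}

glance_to_kv <- function(result) {
  cfg <- result$config
  kv <- c(
    best_accuracy = format(result$best$AC, digits = 15),
    best_subset_size = result$best$s,
    best_fitness = format(result$best$f, digits = 15),
    generations = nrow(result$log),
    termination = result$termination,
    selected = paste(result$selected, collapse = ","),
    CH = cfg$CH, N = cfg$N, r = cfg$r,
    mutation_rate = cfg$mutation_rate,
    recombination_rate = cfg$recombination_rate,
    max_generations = cfg$max_generations, patience = cfg$patience,
    cv_folds = cfg$cv_folds, h_min = cfg$h_min,
    seed = if (is.null(cfg$seed)) NA else cfg$seed
  )
  tibble::tibble(key = names(kv), value = as.character(kv))
}

#' Write a tidy expression dataset as delimited text
#'
#' Inverse of [read_expression()] for the samples-in-rows orientation:
#' writes `sample_id`, `class` and the attribute columns as CSV (or TSV
#' if `path` ends in `.tsv`). Doubles use the shortest round-trippable
#' representation, so write-then-read reproduces the matrix exactly.
#'
#' @param data Tibble with `sample_id`, `class` and numeric attribute
#'   columns.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(data, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

#' Write a gain-ratio weight table as TSV
#'
#' Two columns (`attribute`, `weight`), sorted by descending weight.
#'
#' @param weights Tibble from [compute_weights()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_weights <- function(weights, path) {
  readr::write_tsv(weights[, c("attribute", "weight")], path)
  invisible(path)
}
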