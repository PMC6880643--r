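#' Function sets for GEP chromosomes
#'
#' A function set maps operator tokens to their arities. GEP genes place
#' functions only in the head; the maximum arity `n` of the set fixes the
#' tail length through `t = h*(n - 1) + 1`, which guarantees that every
#' chromosome decodes to a complete expression tree. In this package the
#' functions are never evaluated arithmetically: a decoded tree only
#' determines *which* attributes (its leaves) a chromosome selects, so the
#' operators act purely as arity-bearing connectors and no protected
#' division or domain guards are needed.
#'
#' @param symbols Character vector of operator tokens, a subset of
#'   `c("+", "-", "*", "/", "Q")`. `Q` (square root) is unary; the four
#'   arithmetic operators are binary.
#' @return A named integer vector of arities with class `dgs_functions`.
#' @examples
#' fs <- dgs_functions()
#' max_arity(fs) # 2
#' @export
dgs_functions <- function(symbols = c("+", "-", "*", "/", "Q")) {
  known <- c("+" = 2L, "-" = 2L, "*" = 2L, "/" = 2L, "Q" = 1L)
  bad <- setdiff(symbols, names(known))
  if (length(bad) > 0) {
    stop("unknown function symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(symbols) == 0) stop("function set must be non-empty", call. = FALSE)
  structure(known[symbols], class = "dgs_functions")
}

#' @rdname dgs_functions
#' @param functions A `dgs_functions` set.
#' @export
max_arity <- function(functions) {
  max(as.integer(functions))
}

arity_of <- function(symbols, functions) {
  ar <- unname(functions)[match(symbols, names(functions))]
  ar[is.na(ar)] <- 0L
  as.integer(ar)
}

is_function_symbol <- function(symbols, functions) {
  symbols %in% names(functions)
}

#' Construct a GEP gene
#'
#' A gene is a fixed-length karva string split into a head of length `h`
#' (functions or terminals) and a tail of length `t = h*(n - 1) + 1`
#' (terminals only, where `n` is the function set's maximum arity).
#'
#' @param head Character vector of head symbols.
#' @param tail Character vector of tail symbols (attribute IDs only).
#' @return A list with elements `head` and `tail`, class `dgs_gene`.
#' @export
new_gene <- function(head, tail) {
  structure(list(head = as.character(head), tail = as.character(tail)),
            class = "dgs_gene")
}

#' Draw a random gene over a terminal set
#'
#' Each head position independently becomes a function with probability
#' `head_function_prob` (uniform over the function set) and otherwise a
#' terminal (uniform over the terminal set); tail positions are drawn
#' uniformly from the terminals. Balancing the function/terminal choice —
#' rather than sampling uniformly from the pooled alphabet — is the
#' standard GEP construction: with thousands of candidate attributes a
#' pooled draw would almost never place a function, every tree would
#' collapse to a single leaf, and a population would express only a tiny
#' fraction of the attribute space. Uses the current R random stream.
#'
#' @param terminal_set Character vector of candidate attribute IDs.
#' @param functions A [dgs_functions()] set.
#' @param h Head length (>= 1).
#' @param head_function_prob Probability that a head position holds a
#'   function rather than a terminal.
#' @param terminal_prob Optional vector of selection weights over
#'   `terminal_set` (recycled to probabilities); `NULL` draws uniformly.
#'   Passing the current attribute weights makes generation systematic:
#'   strong attributes enter chromosomes roughly in proportion to their
#'   gain-ratio weight.
#' @return A `dgs_gene`.
#' @export
random_gene <- function(terminal_set, functions = dgs_functions(), h = 3L,
                        head_function_prob = 0.5, terminal_prob = NULL) {
  if (length(terminal_set) == 0) stop("terminal set exhausted", call. = FALSE)
  if (h < 1) stop("head length must be >= 1", call. = FALSE)
  n <- max_arity(functions)
  t_len <- tail_length(h, n)
  draw_terminals <- function(k) {
    terminal_set[sample.int(length(terminal_set), k, replace = TRUE,
                            prob = terminal_prob)]
  }
  is_fun <- stats::runif(h) < head_function_prob
  head <- character(h)
  if (any(is_fun)) {
    head[is_fun] <- names(functions)[
      sample.int(length(functions), sum(is_fun), replace = TRUE)]
  }
  if (any(!is_fun)) {
    head[!is_fun] <- draw_terminals(sum(!is_fun))
  }
  tail <- draw_terminals(t_len)
  new_gene(head, tail)
}

#' Construct a chromosome from genes
#'
#' All genes of a chromosome share the same head length and terminal
#' alphabet; the chromosome length is `N * (h + t)`.
#'
#' @param genes List of `dgs_gene` objects.
#' @return A list of genes with class `dgs_chromosome`.
#' @export
new_chromosome <- function(genes) {
  structure(list(genes = genes), class = "dgs_chromosome")
}

gene_symbols <- function(gene) c(gene$head, gene$tail)

#' Random chromosome of N genes
#' @inheritParams random_gene
#' @param n_genes Number of genes per chromosome.
#' @export
random_chromosome <- function(terminal_set, functions = dgs_functions(),
                              h = 3L, n_genes = 2L,
                              head_function_prob = 0.5,
                              terminal_prob = NULL) {
  new_chromosome(lapply(seq_len(n_genes), function(i) {
    random_gene(terminal_set, functions, h, head_function_prob,
                terminal_prob)
  }))
}

# Length of the expressed prefix (K-expression) of a karva symbol string:
# reading left to right, one open slot is consumed per symbol and each
# function opens `arity` new slots; the prefix ends when no slot is open.
k_expression_length <- function(symbols, functions) {
  ar <- arity_of(symbols, functions)
  open <- 1L + cumsum(ar) - seq_along(ar)
  idx <- which(open == 0L)
  if (length(idx) == 0) {
    stop("gene does not close: malformed karva string", call. = FALSE)
  }
  idx[1]
}

#' Decode a gene into its expression tree
#'
#' Karva decoding fills the tree breadth-first: position 1 is the root and
#' each function node consumes the next `arity` unread positions, in
#' order, as its children. Decoding stops as soon as every open slot is
#' filled; the consumed prefix is the gene's expressed region
#' (K-expression).
#'
#' @param gene A `dgs_gene`.
#' @param functions The function set the gene was built over.
#' @return A list with `root` (nested nodes, each
#'   `list(symbol=, children=list())`) and `expressed_length`.
#' @examples
#' g <- new_gene(c("+", "-", "a12"), c("a9", "a3", "a11", "a7"))
#' tr <- decode_gene(g)
#' tr$expressed_length # 5
#' @export
decode_gene <- function(gene, functions = dgs_functions()) {
  symbols <- gene_symbols(gene)
  if (any(is_function_symbol(gene$tail, functions))) {
    stop("malformed gene: function symbol in tail", call. = FALSE)
  }
  e_len <- k_expression_length(symbols, functions)
  expressed <- symbols[seq_len(e_len)]
  ar <- arity_of(expressed, functions)
  # node i's children occupy consecutive positions after those consumed by
  # nodes 1..(i-1); precompute each node's first-child offset.
  offsets <- 1L + c(0L, cumsum(ar)[-length(ar)])
  build <- function(i) {
    k <- ar[i]
    children <- if (k > 0) lapply(seq_len(k), function(j) build(offsets[i] + j)) else list()
    list(symbol = expressed[i], children = children)
  }
  list(root = build(1L), expressed_length = e_len)
}

tree_leaves <- function(node) {
  if (length(node$children) == 0) return(node$symbol)
  unlist(lapply(node$children, tree_leaves), use.names = FALSE)
}

# Expressed terminals of one gene: terminals in its K-expression prefix.
gene_expressed_terminals <- function(gene, functions = dgs_functions()) {
  symbols <- gene_symbols(gene)
  e_len <- k_expression_length(symbols, functions)
  expressed <- symbols[seq_len(e_len)]
  unique(expressed[!is_function_symbol(expressed, functions)])
}

#' Attributes selected by a chromosome
#'
#' The union, over all genes, of the distinct terminal symbols appearing
#' in each gene's decoded expression tree. Its cardinality is the selected
#' subset size `s` used by the fitness function.
#'
#' @param chromosome A `dgs_chromosome`.
#' @param functions The function set.
#' @return Character vector of attribute IDs.
#' @export
expressed_terminals <- function(chromosome, functions = dgs_functions()) {
  unique(unlist(lapply(chromosome$genes, gene_expressed_terminals,
                       functions = functions), use.names = FALSE))
}

#' Validate a chromosome against a terminal set
#'
#' Checks the structural invariants of every gene (tail holds terminals
#' only, `t = h*(n-1) + 1`, shared head length) and that every terminal
#' belongs to the given terminal set. Violations are returned, not raised.
#'
#' @param chromosome A `dgs_chromosome`.
#' @param terminal_set Character vector of permitted attribute IDs.
#' @param functions The function set.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_chromosome <- function(chromosome, terminal_set,
                                functions = dgs_functions()) {
  violations <- character()
  genes <- chromosome$genes
  if (length(genes) < 1) {
    return("chromosome has no genes")
  }
  n <- max_arity(functions)
  h0 <- length(genes[[1]]$head)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    h <- length(g$head)
    if (h != h0) {
      violations <- c(violations, sprintf(
        "gene %d: head length %d differs from gene 1 (%d)", i, h, h0))
    }
    if (length(g$tail) != tail_length(h, n)) {
      violations <- c(violations, sprintf(
        "gene %d: tail length %d != h*(n-1)+1 = %d",
        i, length(g$tail), tail_length(h, n)))
    }
    bad_tail <- which(is_function_symbol(g$tail, functions))
    for (p in bad_tail) {
      violations <- c(violations, sprintf(
        "gene %d: function symbol '%s' in tail position %d", i, g$tail[p], p))
    }
    terms <- gene_symbols(g)
    terms <- terms[!is_function_symbol(terms, functions)]
    missing <- setdiff(unique(terms), terminal_set)
    for (a in missing) {
      violations <- c(violations, sprintf(
        "gene %d: terminal '%s' not in current terminal set", i, a))
    }
  }
  violations
}

#' Serialize / parse chromosomes as karva strings
#'
#' Genes are separated by `"|"` and symbols by single spaces, e.g.
#' `"+ - a12 a9 a3 a11 a7 | Q a4 a1 a2 a2 a0 a5"`. The head length is
#' recovered on parsing from the gene length and the function set's
#' maximum arity (`g = h*n + 1`).
#'
#' @param chromosome A `dgs_chromosome`.
#' @param functions The function set (needed to re-split head and tail).
#' @return `karva_string()` returns a length-1 character vector;
#'   `parse_karva()` returns a `dgs_chromosome`.
#' @export
karva_string <- function(chromosome) {
  paste(vapply(chromosome$genes,
               function(g) paste(gene_symbols(g), collapse = " "),
               character(1)),
        collapse = " | ")
}

#' @rdname karva_string
#' @param x Karva string to parse.
#' @export
parse_karva <- function(x, functions = dgs_functions()) {
  n <- max_arity(functions)
  gene_strs <- strsplit(x, "|", fixed = TRUE)[[1]]
  genes <- lapply(gene_strs, function(s) {
    symbols <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    g_len <- length(symbols)
    # g = h + h*(n-1) + 1 = h*n + 1
    h <- (g_len - 1L) / n
    if (h != round(h) || h < 1) {
      stop("gene length ", g_len, " incompatible with max arity ", n,
           call. = FALSE)
    }
    new_gene(symbols[seq_len(h)], symbols[(h + 1L):g_len])
  })
  new_chromosome(genes)
}

#' @export
print.dgs_chromosome <- function(x, ...) {
  cat("<dgs_chromosome> ", karva_string(x), "\n", sep = "")
  invisible(x)
}
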