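Package: dgsel
Title: Deep Gene Selection for High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary wrapper feature selection for gene-expression
    matrices using gene expression programming (GEP). Chromosomes encode
    candidate gene subsets in karva notation; subsets are scored by
    cross-validated support-vector-machine accuracy penalized by subset
    size, and the attribute search space is shrunk every generation by
    retaining only the attributes carried by the fittest half of the
    population. Mutation and recombination are guided by gain-ratio
    attribute weights. Includes a synthetic microarray-like data
    generator with planted informative genes, tidy accessors for run
    results, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
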