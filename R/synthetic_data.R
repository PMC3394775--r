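#' Specification for a synthetic two-class expression dataset
#'
#' Emulates the structure of two-class microarray studies: a Gaussian
#' background, a small planted set of informative genes whose class-2 mean is
#' shifted by `effect` noise-SD units, optional blocks of redundant genes
#' correlated with an informative parent (there to exercise redundancy-aware
#' selection), and an optional perfectly separable marker gene.
#'
#' @param n_per_class integer vector of length 2: samples in each class.
#' @param n_genes total number of genes.
#' @param n_informative number of planted informative genes.
#' @param effect mean shift of informative genes in class 2, in units of
#'   `noise_sd`.
#' @param noise_sd background standard deviation (expression units are
#'   arbitrary).
#' @param n_redundant_blocks,block_size,block_rho optional correlated copies:
#'   each block of `block_size` genes tracks one informative parent with
#'   within-class correlation approximately `block_rho`.
#' @param separable if `TRUE`, the first informative gene is rebuilt with
#'   disjoint class ranges so a single interval rule separates the classes.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_per_class = c(50, 50), n_genes = 200,
                                n_informative = 10, effect = 2, noise_sd = 1,
                                n_redundant_blocks = 0, block_size = 0,
                                block_rho = 0.8, separable = FALSE, seed = 1) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 1), n_genes >= 1,
            n_informative >= 0, effect >= 0, noise_sd > 0,
            n_redundant_blocks >= 0, block_rho >= 0, block_rho < 1)
  if (n_redundant_blocks > 0 && n_informative == 0)
    stop("redundant blocks need at least one informative parent gene")
  if (n_informative + n_redundant_blocks * block_size > n_genes)
    stop("n_informative + redundant genes exceeds n_genes")
  structure(list(n_per_class = as.integer(n_per_class), n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative), effect = effect,
                 noise_sd = noise_sd,
                 n_redundant_blocks = as.integer(n_redundant_blocks),
                 block_size = as.integer(block_size), block_rho = block_rho,
                 separable = isTRUE(separable), seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Generate a synthetic expression dataset with planted informative genes
#'
#' @param spec an [expression_sim_spec].
#' @return A list with `dataset` (an [expr_dataset], classes `"case"` and
#'   `"control"`, the shift applied to `"case"`), `informative` (planted gene
#'   names) and `redundant` (names of correlated copies, possibly empty).
#' @examples
#' sim <- generate_expression(expression_sim_spec(n_per_class = c(10, 10),
#'                                                n_genes = 20, seed = 7))
#' sim$informative
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  n1 <- spec$n_per_class[1]; n2 <- spec$n_per_class[2]
  n <- n1 + n2; p <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(p))
  samples <- sprintf("s%03d", seq_len(n))
  labels <- c(rep("case", n1), rep("control", n2))
  names(labels) <- samples
  inf_idx <- seq_len(spec$n_informative)
  with_seed(spec$seed, {
    m <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p,
                dimnames = list(samples, genes))
    if (spec$n_informative > 0 && spec$effect > 0)
      m[labels == "case", inf_idx] <- m[labels == "case", inf_idx] +
        spec$effect * spec$noise_sd
    red_idx <- integer(0)
    if (spec$n_redundant_blocks > 0 && spec$block_size > 0) {
      nxt <- spec$n_informative + 1L
      for (b in seq_len(spec$n_redundant_blocks)) {
        parent <- inf_idx[((b - 1L) %% spec$n_informative) + 1L]
        cols <- seq(nxt, nxt + spec$block_size - 1L)
        eps <- matrix(rnorm(n * spec$block_size, sd = spec$noise_sd), n)
        m[, cols] <- spec$block_rho * m[, parent] +
          sqrt(1 - spec$block_rho^2) * eps
        red_idx <- c(red_idx, cols)
        nxt <- nxt + spec$block_size
      }
    }
    if (spec$separable) {
      if (spec$n_informative < 1) stop("separable = TRUE needs n_informative >= 1")
      # disjoint uniform ranges with a full noise-SD margin between classes
      m[labels == "control", 1] <- runif(n2, -1.5, -0.5) * spec$noise_sd
      m[labels == "case", 1] <- runif(n1, 0.5, 1.5) * spec$noise_sd
    }
  })
  list(dataset = expr_dataset(m, labels), informative = genes[inf_idx],
       redundant = genes[red_idx])
}

#' Specification for a synthetic literature corpus
#'
#' Documents are simulated independently: every term occurs with probability
#' `base_rate` per document, except planted gene/disease pairs whose joint
#' probability is lifted by `assoc_lift` (capped so it remains a valid
#' probability, with a warning when the cap binds). Counts are document
#' counts, so relative frequencies are exactly counts / `n_docs`.
#'
#' @param n_docs number of documents.
#' @param n_genes size of the gene-term universe (terms `gene0001`, ...).
#' @param disease_terms character vector of disease term names.
#' @param base_rate background per-document term probability, in (0, 1).
#' @param assoc_genes planted associated gene terms (subset of the universe).
#' @param assoc_lift multiplicative co-occurrence enrichment, >= 1.
#' @param seed integer seed.
#' @return An object of class `corpus_sim_spec`.
#' @export
corpus_sim_spec <- function(n_docs = 20000, n_genes = 200,
                            disease_terms = "disease", base_rate = 0.05,
                            assoc_genes = character(), assoc_lift = 1,
                            seed = 1) {
  if (n_docs < 1) stop("n_docs must be at least 1")
  stopifnot(n_genes >= 1, base_rate > 0, base_rate < 1, assoc_lift >= 1,
            length(disease_terms) >= 1)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  assoc_genes <- as.character(assoc_genes)
  bad <- setdiff(assoc_genes, genes)
  if (length(bad)) stop("planted gene outside the universe: ", bad[1])
  structure(list(n_docs = as.integer(n_docs), n_genes = as.integer(n_genes),
                 genes = genes, disease_terms = disease_terms,
                 base_rate = base_rate, assoc_genes = assoc_genes,
                 assoc_lift = assoc_lift, seed = as.integer(seed)),
            class = "corpus_sim_spec")
}

#' Generate synthetic corpus counts with planted gene-disease associations
#'
#' @param spec a [corpus_sim_spec].
#' @return A list with `corpus` (a [corpus_counts]) and `associated`
#'   (the planted gene terms).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_sim_spec"))
  p <- spec$base_rate
  n <- spec$n_docs
  joint <- spec$assoc_lift * p * p
  if (joint > p) {
    warning("assoc_lift * base_rate exceeds 1; joint probability capped at ",
            "the marginal")
    joint <- p
  }
  with_seed(spec$seed, {
    term_count <- integer(0)
    # disease-term document indicators; the planted dependence couples the
    # associated genes to the FIRST disease term, further terms are background
    disease_occ <- matrix(rbinom(n * length(spec$disease_terms), 1L, p), n,
                          dimnames = list(NULL, spec$disease_terms))
    gene_occ <- matrix(rbinom(n * spec$n_genes, 1L, p), n, spec$n_genes,
                       dimnames = list(NULL, spec$genes))
    if (length(spec$assoc_genes)) {
      docs_d <- disease_occ[, 1L]
      # conditional rates preserving the marginal base_rate
      p1 <- min(joint / p, 1)
      p0 <- max((p - joint) / (1 - p), 0)
      for (g in spec$assoc_genes)
        gene_occ[, g] <- ifelse(docs_d == 1L, rbinom(n, 1L, p1),
                                rbinom(n, 1L, p0))
    }
    term_count[spec$disease_terms] <- colSums(disease_occ)
    term_count[spec$genes] <- colSums(gene_occ)
    pairs <- do.call(rbind, lapply(spec$disease_terms, function(d)
      data.frame(term_a = spec$genes, term_b = d,
                 count = as.integer(colSums(gene_occ * disease_occ[, d])),
                 stringsAsFactors = FALSE)))
  })
  list(corpus = corpus_counts(n, term_count, pairs),
       associated = spec$assoc_genes)
}
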