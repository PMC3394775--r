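# Small in-code fixtures shared across the suite.

# tiny labelled dataset with a hand-picked signal on the first gene
tiny_dataset <- function(n_per_class = 6, n_genes = 5, delta = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(rnorm(n * n_genes), n, n_genes,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(n_genes))))
  labels <- rep(c("case", "control"), each = n_per_class)
  m[labels == "case", 1] <- m[labels == "case", 1] + delta
  expr_dataset(m, labels)
}

# GA budgets used throughout the suite: small enough to keep the tests quick,
# large enough that the evolutionary search reliably finds interval rules on
# the planted-signal data the generator produces
desk_params <- function(...) {
  args <- list(ga_generations = 100, population_size = 100)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(learner_params, args)
}

# a random but valid decision list over the given gene names
random_decision_list <- function(genes, classes = c("case", "control"),
                                 max_rules = 4) {
  n_rules <- sample.int(max_rules, 1)
  rules <- lapply(seq_len(n_rules), function(i) {
    k <- sample.int(min(3, length(genes)), 1)
    g <- sample(genes, k)
    lo <- rnorm(k)
    hi <- lo + abs(rnorm(k))
    interval_rule(g, lo, hi, sample(classes, 1))
  })
  decision_list(rules, sample(classes, 1))
}

# corpus with hand-set counts for exact PMI arithmetic
fixed_corpus <- function() {
  corpus_counts(
    n_docs = 1000,
    term_counts = c(geneA = 100, geneB = 50, geneC = 100, disease = 50),
    pair_counts = data.frame(
      term_a = c("geneA", "geneB", "geneC"),
      term_b = "disease",
      count = c(50, 0, 1)))   # geneA: PMI log2(10); geneC: negative PMI
}
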