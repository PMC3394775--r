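#' Document-count container for literature mining
#'
#' Holds the total number of documents, per-term document counts and
#' unordered per-pair co-occurrence counts from which relative frequencies
#' `f(x) = count(x) / n_docs` and `f(x, y) = count(x, y) / n_docs` are
#' derived.
#'
#' @param n_docs total document count (>= 1).
#' @param term_counts named non-negative integer vector of per-term document
#'   counts.
#' @param pair_counts data frame with columns `term_a`, `term_b`, `count`;
#'   pairs are unordered and must satisfy
#'   `count <= min(term_counts[a], term_counts[b])`.
#' @return An object of class `corpus_counts`.
#' @export
corpus_counts <- function(n_docs, term_counts, pair_counts) {
  if (n_docs < 1) stop("n_docs must be at least 1")
  stopifnot(!is.null(names(term_counts)), all(term_counts >= 0),
            all(term_counts <= n_docs))
  stopifnot(all(c("term_a", "term_b", "count") %in% names(pair_counts)))
  key <- pair_key(pair_counts$term_a, pair_counts$term_b)
  counts <- as.integer(pair_counts$count)
  ca <- term_counts[pair_counts$term_a]
  cb <- term_counts[pair_counts$term_b]
  bad <- which(counts < 0 | counts > pmin(ca, cb, na.rm = FALSE))
  if (length(bad))
    stop("pair count exceeds a term count for pair ", key[bad[1]])
  pairs <- stats::setNames(counts, key)
  structure(list(n_docs = as.integer(n_docs),
                 term_counts = stats::setNames(as.integer(term_counts),
                                               names(term_counts)),
                 pair_counts = pairs),
            class = "corpus_counts")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

term_count <- function(corpus, term) {
  cnt <- corpus$term_counts[term]
  if (is.na(cnt)) {
    message("term not in corpus, treated as count 0: ", term)
    cnt <- 0L
  }
  unname(cnt)
}

#' Pointwise mutual information of two terms
#'
#' `PMI(x, y) = log2( f(x, y) / (f(x) * f(y)) )` over document relative
#' frequencies. When any of the three frequencies is zero the association is
#' undefined and `NA` is returned; downstream scoring treats the sentinel as
#' an irrelevant (non-positive) association. Base 2 is cosmetic: set scores
#' scale by a positive constant and permutation p-values are invariant.
#'
#' @param x,y term names.
#' @param corpus a [corpus_counts].
#' @return The PMI in bits, or `NA` when undefined.
#' @export
pmi <- function(x, y, corpus) {
  stopifnot(inherits(corpus, "corpus_counts"))
  cx <- term_count(corpus, x)
  cy <- term_count(corpus, y)
  cxy <- unname(corpus$pair_counts[pair_key(x, y)])
  if (is.na(cxy)) cxy <- 0L
  if (cx == 0 || cy == 0 || cxy == 0) return(NA_real_)
  n <- corpus$n_docs
  log2((cxy / n) / ((cx / n) * (cy / n)))
}

#' Positive-PMI score of a gene set against a disease term
#'
#' Sums `max(0, PMI(gene, disease))` over the set: negative associations are
#' considered irrelevant (their magnitude is dominated by sampling noise) and
#' contribute zero, as do undefined sentinels. Monotone non-decreasing under
#' adding a gene.
#'
#' @param genes non-empty character vector of gene terms.
#' @param disease_term disease term name.
#' @param corpus a [corpus_counts].
#' @return Non-negative numeric score.
#' @export
gene_set_pmi_score <- function(genes, disease_term, corpus) {
  stopifnot(length(genes) >= 1)
  scores <- vapply(genes, function(g) {
    s <- suppressMessages(pmi(g, disease_term, corpus))
    if (is.na(s) || s < 0) 0 else s
  }, 0)
  sum(scores)
}

#' Permutation significance of a gene set's literature score
#'
#' Compares the observed positive-PMI sum against `n_perm` random gene sets
#' of the same size drawn without replacement from the platform's gene
#' universe. The p-value is the proportion of random sets that score
#' strictly higher than the observed set, so with 100 permutations it takes
#' values on a grid of 0.01 (including an exact 0).
#'
#' @param genes observed gene set.
#' @param disease_term disease term name.
#' @param corpus a [corpus_counts].
#' @param universe character vector of candidate gene terms
#'   (`length(universe) >= length(genes)`).
#' @param n_perm number of random sets (default 100).
#' @param seed integer seed; deterministic given the seed.
#' @return A `pmi_prioritization`: observed per-gene PMI, `score`,
#'   `null_scores` and `p_value`.
#' @export
permutation_pvalue <- function(genes, disease_term, corpus, universe,
                               n_perm = 100, seed = 1) {
  stopifnot(inherits(corpus, "corpus_counts"), n_perm >= 1)
  if (length(universe) < length(genes))
    stop("universe smaller than the gene set")
  per_gene <- vapply(genes, function(g)
    suppressMessages(pmi(g, disease_term, corpus)), 0)
  observed <- gene_set_pmi_score(genes, disease_term, corpus)
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    gene_set_pmi_score(sample(universe, length(genes)), disease_term, corpus)
  }, 0))
  structure(list(genes = genes, disease_term = disease_term,
                 per_gene_pmi = per_gene, score = observed,
                 null_scores = null_scores,
                 p_value = mean(null_scores > observed)),
            class = "pmi_prioritization")
}

#' @export
print.pmi_prioritization <- function(x, ...) {
  cat(sprintf("<pmi_prioritization> %d genes vs '%s': score %.3f, p = %.2f (%d permutations)\n",
              length(x$genes), x$disease_term, x$score, x$p_value,
              length(x$null_scores)))
  invisible(x)
}

#' Read and write corpus counts as TSV
#'
#' `terms_path` holds `term<TAB>doc_count` rows preceded by a
#' `#n_docs=<N>` header line; `pairs_path` holds
#' `term_a<TAB>term_b<TAB>doc_count` rows.
#'
#' @param corpus a [corpus_counts].
#' @param terms_path,pairs_path file paths.
#' @export
write_corpus_counts <- function(corpus, terms_path, pairs_path) {
  con <- file(terms_path, "w")
  writeLines(paste0("#n_docs=", corpus$n_docs), con)
  write.table(data.frame(term = names(corpus$term_counts),
                         doc_count = unname(corpus$term_counts)),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  key <- strsplit(names(corpus$pair_counts), "\r", fixed = TRUE)
  write.table(data.frame(term_a = vapply(key, `[[`, "", 1),
                         term_b = vapply(key, `[[`, "", 2),
                         doc_count = unname(corpus$pair_counts)),
              pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(terms_path, pairs_path))
}

#' @rdname write_corpus_counts
#' @export
read_corpus_counts <- function(terms_path, pairs_path) {
  first <- readLines(terms_path, n = 1)
  m <- regmatches(first, regexec("^#n_docs=(\\d+)$", first))[[1]]
  if (!length(m)) stop("terms file must start with an '#n_docs=<N>' header")
  n_docs <- as.integer(m[2])
  terms <- read.delim(terms_path, sep = "\t", skip = 1,
                      stringsAsFactors = FALSE)
  pairs <- read.delim(pairs_path, sep = "\t", stringsAsFactors = FALSE)
  names(pairs) <- c("term_a", "term_b", "count")
  corpus_counts(n_docs, stats::setNames(terms$doc_count, terms$term), pairs)
}
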