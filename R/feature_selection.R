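#' One-way ANOVA F statistic for a single gene
#'
#' Two-group F statistic with pooled variance; for two classes it equals the
#' square of the pooled-variance two-sample t statistic. A gene that is
#' constant across all samples scores 0 by convention; a gene with zero
#' within-group variance but distinct group means is a perfect separator and
#' scores `Inf` (ranked above every finite score).
#'
#' @param values numeric vector, one expression value per sample.
#' @param labels class label per sample (exactly two classes).
#' @return The F statistic (non-negative, possibly `Inf`).
#' @export
f_statistic <- function(values, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("f_statistic needs exactly two classes")
  x1 <- values[labels == classes[1]]
  x2 <- values[labels == classes[2]]
  if (length(x1) < 2 || length(x2) < 2)
    stop("each class needs at least two samples")
  ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  d <- mean(x1) - mean(x2)
  if (ssw == 0) {
    if (d == 0) return(0)        # constant gene
    return(Inf)                  # perfect separator
  }
  sp2 <- ssw / (length(values) - 2)
  d^2 / (sp2 * (1 / length(x1) + 1 / length(x2)))
}

new_feature_ranking <- function(genes, scores, method) {
  structure(data.frame(rank = seq_along(genes), gene = genes, score = scores,
                       stringsAsFactors = FALSE),
            method = method, class = c("feature_ranking", "data.frame"))
}

new_feature_set <- function(genes, method, max_size = length(genes)) {
  structure(list(genes = unique(as.character(genes)), method = method,
                 max_size = max_size), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> method =", x$method, "|", length(x$genes), "genes (cap",
      x$max_size, ")\n")
  invisible(x)
}

#' Univariate feature ranking by the ANOVA F statistic (PLSS)
#'
#' Ranks genes by decreasing two-group F statistic. For two-class data this
#' ordering is equivalent to ordering by the absolute weights of the first
#' partial-least-squares component on standardized predictors, which is why
#' the selector carries the PLSS name; the F statistic is computed directly.
#' Ties (and infinite scores) are broken by gene identifier so the ranking is
#' deterministic.
#'
#' @param dataset an [expr_dataset] with both classes present.
#' @return A `feature_ranking` data frame with columns rank, gene, score.
#' @export
plss_rank <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (length(dataset$classes) != 2) stop("training data must have two classes")
  X <- dataset$values
  y <- dataset$labels
  i1 <- y == dataset$classes[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  ssw <- colSums(sweep(X[i1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[!i1, , drop = FALSE], 2, m2)^2)
  d <- m1 - m2
  f <- ifelse(ssw == 0, ifelse(d == 0, 0, Inf),
              d^2 / ((ssw / (n1 + n2 - 2)) * (1 / n1 + 1 / n2)))
  ord <- order(-f, colnames(X))
  new_feature_ranking(colnames(X)[ord], unname(f[ord]), "plss")
}

#' CFS merit of a feature subset
#'
#' `merit = k * r_cf / sqrt(k + k * (k - 1) * r_ff)`: the numerator rewards
#' features correlated with the class, the denominator penalizes subsets
#' whose members are correlated with each other. Correlations are averages
#' of absolute values, so both arguments lie in \[0, 1\].
#'
#' @param k subset size (>= 1).
#' @param r_cf mean absolute feature-class correlation over the subset.
#' @param r_ff mean absolute feature-feature correlation over distinct pairs
#'   (0 when k = 1).
#' @return The merit score (finite, non-negative).
#' @export
cfs_merit <- function(k, r_cf, r_ff = 0) {
  if (k < 1) stop("k must be at least 1")
  stopifnot(r_cf >= 0, r_cf <= 1, r_ff >= 0, r_ff <= 1)
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' Correlation-based feature selection with greedy best-first search
#'
#' Searches subsets scored by [cfs_merit()], expanding the best unexpanded
#' subset by one feature at a time. Feature-class correlation is the absolute
#' Pearson (point-biserial) correlation against a 0/1 class code;
#' feature-feature correlation is absolute Pearson. The search stops after
#' `stall` consecutive expansions that fail to improve the best merit seen,
#' or when subsets reach `max_size`; it may return fewer than `max_size`
#' features.
#'
#' @param dataset an [expr_dataset].
#' @param max_size maximum subset size (default 30).
#' @param stall consecutive non-improving expansions tolerated (default 5).
#' @return A `feature_set`.
#' @export
cfs_select <- function(dataset, max_size = 30, stall = 5) {
  stopifnot(inherits(dataset, "expr_dataset"), max_size >= 1)
  if (length(dataset$classes) != 2) stop("training data must have two classes")
  X <- dataset$values
  y01 <- as.numeric(dataset$labels == dataset$classes[2])
  if (var(y01) == 0) stop("class is constant")
  sds <- apply(X, 2, sd)
  rcf <- abs(suppressWarnings(as.vector(cor(X, y01))))
  rcf[sds == 0 | is.na(rcf)] <- 0          # constant genes: zero correlation
  names(rcf) <- colnames(X)
  p <- ncol(X)

  # pairwise |r| cache, filled lazily one column at a time
  ff_cache <- new.env(parent = emptyenv())
  ff_col <- function(j) {
    key <- as.character(j)
    v <- ff_cache[[key]]
    if (is.null(v)) {
      v <- abs(suppressWarnings(as.vector(cor(X, X[, j]))))
      v[is.na(v)] <- 0
      ff_cache[[key]] <- v
    }
    v
  }

  merit_of <- function(subset, ff_sum) {
    k <- length(subset)
    r_cf <- mean(rcf[subset])
    r_ff <- if (k > 1) ff_sum / (k * (k - 1) / 2) else 0
    cfs_merit(k, r_cf, min(r_ff, 1))
  }

  # best-first: frontier of candidate subsets keyed by merit
  start <- which.max(rcf)
  frontier <- list(list(subset = start, ff_sum = 0,
                        merit = merit_of(start, 0)))
  best <- frontier[[1]]
  stalled <- 0
  while (length(frontier) > 0 && stalled < stall) {
    idx <- which.max(vapply(frontier, `[[`, 0, "merit"))
    node <- frontier[[idx]]
    frontier[[idx]] <- NULL
    if (length(node$subset) >= max_size) next
    # expand: add each unused feature; keep the best child on the frontier
    unused <- setdiff(seq_len(p), node$subset)
    if (!length(unused)) next
    add_ff <- rep(0, length(unused))
    for (j in node$subset) add_ff <- add_ff + ff_col(j)[unused]
    k1 <- length(node$subset) + 1
    r_cf <- (mean(rcf[node$subset]) * (k1 - 1) + rcf[unused]) / k1
    ff_sum <- node$ff_sum + add_ff
    r_ff <- if (k1 > 1) ff_sum / (k1 * (k1 - 1) / 2) else 0
    merits <- k1 * r_cf / sqrt(k1 + k1 * (k1 - 1) * pmin(r_ff, 1))
    bi <- which.max(merits)
    child <- list(subset = c(node$subset, unused[bi]), ff_sum = ff_sum[bi],
                  merit = merits[bi])
    frontier[[length(frontier) + 1]] <- child
    if (child$merit > best$merit + 1e-12) {
      best <- child
      stalled <- 0
    } else {
      stalled <- stalled + 1
    }
  }
  new_feature_set(colnames(X)[best$subset], "cfs", max_size)
}

#' Random-forest Gini-importance feature ranking (RFS)
#'
#' Trains a random forest (via \pkg{randomForest}) and ranks genes by mean
#' decrease in Gini node impurity aggregated over all nodes of all trees.
#' Deterministic given `seed`.
#'
#' @param dataset an [expr_dataset].
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @return A `feature_ranking`.
#' @export
rfs_rank <- function(dataset, n_trees = 500, seed = 1) {
  stopifnot(inherits(dataset, "expr_dataset"), n_trees >= 1)
  if (length(dataset$classes) != 2) stop("training data must have two classes")
  y <- factor(dataset$labels, levels = dataset$classes)
  imp <- with_seed(seed, {
    fit <- randomForest::randomForest(x = dataset$values, y = y,
                                      ntree = n_trees)
    fit$importance[, "MeanDecreaseGini"]
  })
  ord <- order(-imp, names(imp))
  new_feature_ranking(names(imp)[ord], unname(imp[ord]), "rfs")
}

#' Take the top k genes of a ranking as a feature set
#'
#' Rankings already break score ties by gene identifier, so the boundary tie
#' rule (lexicographically smaller gene kept) is inherited from the ranking.
#'
#' @param ranking a `feature_ranking`.
#' @param k number of genes to keep, `1 <= k <= nrow(ranking)`.
#' @return A `feature_set`.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k < 1 || k > nrow(ranking))
    stop("k must be between 1 and ", nrow(ranking))
  new_feature_set(ranking$gene[seq_len(k)], attr(ranking, "method"), k)
}

#' Consensus gene selection across feature-selection methods
#'
#' For each method, genes are ranked by the number of cross-validation folds
#' in which they were selected and the `top_k` most frequent are kept (ties
#' by gene identifier). Genes present in at least `min_methods` of those
#' per-method top lists form the consensus ("Ensemble FS"), each annotated
#' with the number of supporting methods.
#'
#' @param per_method_fold_selections named list (one element per method) of
#'   lists of `feature_set`s, one per CV fold.
#' @param top_k size of each per-method frequency top list (default 20).
#' @param min_methods minimum number of supporting methods (default 2).
#' @return A data frame with columns `gene` and `n_methods`, ordered by
#'   decreasing support then gene identifier.
#' @export
consensus_selection <- function(per_method_fold_selections, top_k = 20,
                                min_methods = 2) {
  if (length(per_method_fold_selections) < 2)
    stop("need selections from at least two methods")
  top_lists <- lapply(per_method_fold_selections, function(folds) {
    genes <- unlist(lapply(folds, function(fs) {
      if (inherits(fs, "feature_set")) fs$genes else as.character(fs)
    }))
    if (!length(genes)) return(character())
    freq <- sort(table(genes), decreasing = TRUE)
    ord <- order(-as.integer(freq), names(freq))
    head(names(freq)[ord], top_k)
  })
  all_genes <- sort(unique(unlist(top_lists)))
  if (!length(all_genes)) {
    warning("no genes selected in any fold; empty consensus")
    return(data.frame(gene = character(), n_methods = integer()))
  }
  support <- vapply(all_genes, function(g)
    sum(vapply(top_lists, function(tl) g %in% tl, TRUE)), 1L)
  keep <- support >= min_methods
  out <- data.frame(gene = all_genes[keep], n_methods = unname(support[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$n_methods, out$gene), , drop = FALSE]
}
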