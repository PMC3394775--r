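#' Classifier plugin contract
#'
#' The cross-validation harness accepts any classifier exposing a
#' `fit(train)` / `predict(model, values)` pair, so established
#' implementations (e.g. support vector machines or random forests) can be
#' plugged in next to the rule learners without re-implementing them.
#'
#' @param fit function of an [expr_dataset] returning a fitted model.
#' @param predict function of (model, samples-by-genes matrix) returning a
#'   character vector of class names.
#' @param grid optional list of parameter lists for [nested_param_search()].
#' @param label short classifier label.
#' @return A `cv_classifier`.
#' @export
cv_classifier <- function(fit, predict, grid = NULL, label = "classifier") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, grid = grid, label = label),
            class = "cv_classifier")
}

#' @rdname cv_classifier
#' @param learner,n_members,base_seed,params ensemble settings passed to
#'   [train_ensemble()].
#' @export
classifier_rule_ensemble <- function(learner = c("biohel", "gassist"),
                                     n_members = 100, base_seed = 1,
                                     params = learner_params()) {
  learner <- match.arg(learner)
  cv_classifier(
    fit = function(train) train_ensemble(train, learner, n_members, base_seed,
                                         params),
    predict = function(model, values) unname(ensemble_predict(model, values)),
    label = learner)
}

#' @rdname cv_classifier
#' @export
classifier_majority <- function() {
  cv_classifier(
    fit = function(train) majority_class(train$labels, train$classes),
    predict = function(model, values) rep(model, nrow(values)),
    label = "majority")
}

#' External cross-validation of a selector/classifier combination
#'
#' For every fold, the feature selector runs on the training samples only,
#' the classifier trains on the selected gene columns of the training
#' samples, and the held-out samples are predicted. The harness passes
#' nothing but training rows to the selector and the classifier, so no
#' test-fold information can reach feature selection or training.
#'
#' @param dataset an [expr_dataset].
#' @param selector `NULL` (use all genes) or a function of a training
#'   [expr_dataset] returning a `feature_set`, `feature_ranking` or character
#'   vector of genes.
#' @param classifier a [cv_classifier].
#' @param fold_plan a fold plan from [make_fold_plan()].
#' @return A `cv_result`: per-fold accuracies (percent), per-fold selected
#'   feature sets, per-sample predictions, and the AVG/STDDEV summary from
#'   [accuracy_stats()].
#' @export
external_cv <- function(dataset, selector, classifier, fold_plan) {
  stopifnot(inherits(dataset, "expr_dataset"), inherits(classifier, "cv_classifier"),
            inherits(fold_plan, "fold_plan"))
  folds <- sort(unique(fold_plan$assignments))
  acc <- numeric(length(folds))
  sel_sets <- vector("list", length(folds))
  predictions <- character(n_samples(dataset))
  names(predictions) <- rownames(dataset$values)
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    test_ids <- names(fold_plan$assignments)[fold_plan$assignments == f]
    train_ids <- setdiff(rownames(dataset$values), test_ids)
    train <- subset_samples(dataset, train_ids)
    genes <- colnames(dataset$values)
    if (!is.null(selector)) {
      sel <- selector(train)
      genes <- if (inherits(sel, "feature_set")) sel$genes
      else if (inherits(sel, "feature_ranking")) sel$gene
      else as.character(sel)
      if (!length(genes)) stop("selector returned 0 features in fold ", f)
      sel_sets[[fi]] <- genes
      train <- subset_genes(train, genes)
    }
    model <- tryCatch(classifier$fit(train), error = function(e)
      stop("classifier failed in fold ", f, ": ", conditionMessage(e)))
    test_values <- dataset$values[test_ids, genes, drop = FALSE]
    pred <- classifier$predict(model, test_values)
    predictions[test_ids] <- pred
    acc[fi] <- 100 * mean(pred == dataset$labels[test_ids])
  }
  stats <- accuracy_stats(acc)
  structure(list(fold_accuracy = acc, fold_features = sel_sets,
                 predictions = predictions, avg = stats$avg,
                 stddev = stats$stddev, scheme = fold_plan$scheme,
                 seed = fold_plan$seed), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AVG %.0f%% STDDEV %.0f (%d folds)\n",
              x$scheme, x$avg, x$stddev, length(x$fold_accuracy)))
  invisible(x)
}

#' Nested grid search on a training fold
#'
#' Inner stratified cross-validation on the training fold only; returns the
#' grid point with the highest mean inner accuracy, ties going to the first
#' point in grid order. This is the second level of two-level external
#' cross-validation, used to fit hyperparameters of plugin classifiers.
#'
#' @param train_fold an [expr_dataset] (a training fold).
#' @param classifier_family function of one parameter list returning a
#'   [cv_classifier].
#' @param grid non-empty list of parameter lists, in preference order.
#' @param inner_k inner folds (default 5).
#' @param seed seed for the inner fold plan.
#' @return The winning parameter list, with mean inner accuracies attached
#'   as attribute `inner_accuracy`.
#' @export
nested_param_search <- function(train_fold, classifier_family, grid,
                                inner_k = 5, seed = 1) {
  stopifnot(length(grid) >= 1, inner_k >= 2)
  plan <- make_fold_plan(train_fold$labels, "kfold", k = inner_k, seed = seed)
  scores <- vapply(grid, function(par) {
    clf <- classifier_family(par)
    external_cv(train_fold, NULL, clf, plan)$avg
  }, 0)
  best <- which.max(scores)   # ties -> first in grid order
  out <- grid[[best]]
  attr(out, "inner_accuracy") <- scores
  out
}

#' Mean and standard deviation of per-fold accuracies
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) on the
#' 0-100 percent scale; a single fold has SD 0 by convention. Leave-one-out
#' folds score 0 or 100, which is what produces the characteristically large
#' LOOCV standard deviations.
#'
#' @param per_fold_accuracies numeric vector of per-fold accuracies in
#'   percent.
#' @return List with `avg` and `stddev`.
#' @export
accuracy_stats <- function(per_fold_accuracies) {
  stopifnot(length(per_fold_accuracies) >= 1)
  list(avg = mean(per_fold_accuracies),
       stddev = if (length(per_fold_accuracies) > 1) sd(per_fold_accuracies)
       else 0)
}

#' Friedman test with average ranks over an accuracy table
#'
#' Within every block (row), methods are ranked by decreasing accuracy with
#' mid-ranks for ties (rank 1 = most accurate); per-method average ranks are
#' taken over blocks and the tie-corrected Friedman chi-square statistic and
#' p-value are computed.
#'
#' @param accuracy_table numeric matrix, blocks in rows, methods in columns
#'   (no missing cells).
#' @return A `rank_table`: per-block rank matrix, per-method average ranks,
#'   `statistic`, `df` and `p_value`.
#' @export
friedman_average_ranks <- function(accuracy_table) {
  m <- as.matrix(accuracy_table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 blocks and 2 methods")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing cell at block ", rownames(m)[bad[1]] %||% bad[1],
         ", method ", colnames(m)[bad[2]] %||% bad[2])
  }
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(-m, 1, rank))          # rank 1 = highest accuracy, mid-ranks
  Rj <- colSums(r)
  # tie correction as in the classical Friedman statistic
  tie_term <- sum(apply(r, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  statistic <- if (denom > 0)
    12 * sum((Rj - n * (k + 1) / 2)^2) / denom else 0
  structure(list(ranks = r, avg_ranks = colMeans(r), statistic = statistic,
                 df = k - 1,
                 p_value = pchisq(statistic, k - 1, lower.tail = FALSE)),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Average ranks (1 = best):\n")
  print(round(x$avg_ranks, 2))
  cat(sprintf("Friedman chi-square = %.3f, df = %d, p = %.4g\n", x$statistic,
              x$df, x$p_value))
  invisible(x)
}

#' Reshape a benchmark accuracy table and rank methods
#'
#' Convenience wrapper: pivots a long accuracy table (columns `dataset`,
#' `selector`, `classifier`, `avg`) into the blocks-by-methods matrix
#' expected by [friedman_average_ranks()]. When comparing classifiers,
#' blocks are dataset-selector combinations; rows whose selector is in
#' `exclude_selector` (default `"none"`) are dropped, since a
#' without-selection run has no selector block to belong to. When comparing
#' selectors, blocks are dataset-classifier combinations.
#'
#' @param tbl data frame with columns dataset, selector, classifier, avg.
#' @param compare `"classifier"` or `"selector"`.
#' @param exclude_selector selector labels to drop (default `"none"`).
#' @return A `rank_table`.
#' @export
cv_rank_table <- function(tbl, compare = c("classifier", "selector"),
                          exclude_selector = "none") {
  compare <- match.arg(compare)
  tbl <- tbl[!(tbl$selector %in% exclude_selector), , drop = FALSE]
  block_cols <- if (compare == "classifier") c("dataset", "selector")
  else c("dataset", "classifier")
  block <- interaction(tbl[block_cols], drop = TRUE)
  methods <- unique(tbl[[compare]])
  m <- matrix(NA_real_, nlevels(block), length(methods),
              dimnames = list(levels(block), methods))
  m[cbind(as.integer(block), match(tbl[[compare]], methods))] <- tbl$avg
  friedman_average_ranks(m)
}

#' Holm step-down adjustment of pairwise p-values
#'
#' Sorted ascending, p(i) is compared against alpha / (m - i + 1); once one
#' test fails every larger one fails. Returns monotone adjusted p-values
#' (capped at 1) and rejection flags at `alpha`.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @param alpha significance level (confidence levels of 80 or 90 percent
#'   correspond to alpha 0.2 or 0.1).
#' @return Data frame with `p`, `p_adjusted`, `reject`, in the input order.
#' @export
holm_adjust <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * pvalues[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  data.frame(p = pvalues, p_adjusted = adj, reject = adj <= alpha)
}

#' Published benchmark accuracies for three cancer microarray datasets
#'
#' Cross-validated accuracy tables (average percent accuracy and per-fold
#' standard deviation) for five classifiers -- two evolutionary rule learners
#' (biohel, gassist) and three standard baselines (svm, rf, pam) -- combined
#' with three feature selectors (cfs, plss, rfs) and, for the iterative rule
#' learner, no selection, on prostate cancer, diffuse large B-cell lymphoma
#' and breast cancer microarray datasets. These published benchmark results
#' ship with the package as the worked input for [cv_rank_table()].
#'
#' @param scheme `"10fold"` or `"loocv"`.
#' @return Data frame with columns dataset, selector, classifier, avg, sd.
#' @export
benchmark_accuracies <- function(scheme = c("10fold", "loocv")) {
  scheme <- match.arg(scheme)
  path <- system.file("extdata", paste0("benchmark_cv_", scheme, ".tsv"),
                      package = "rulemine", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
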