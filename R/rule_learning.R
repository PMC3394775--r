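#' Interval rules and decision lists
#'
#' An interval rule is a conjunction of per-gene closed-interval predicates
#' `lo <= Exp(gene) <= hi` together with a predicted class; a rule with no
#' predicates matches every sample (the default-rule form). A decision list
#' is an ordered collection of such rules evaluated by first match, closed by
#' a default class that guarantees every sample receives a prediction.
#'
#' @param genes character vector of gene identifiers (at most one predicate
#'   per gene).
#' @param lo,hi numeric interval bounds, `lo <= hi`, both inclusive.
#' @param class predicted class name.
#' @return `interval_rule` returns an object of class `interval_rule`.
#' @export
interval_rule <- function(genes, lo, hi, class) {
  genes <- as.character(genes)
  stopifnot(length(genes) == length(lo), length(genes) == length(hi),
            is.character(class), length(class) == 1)
  if (anyDuplicated(genes)) stop("at most one predicate per gene")
  if (any(lo > hi)) stop("interval bounds must satisfy lo <= hi")
  structure(list(genes = genes, lo = as.numeric(lo), hi = as.numeric(hi),
                 class = class), class = "interval_rule")
}

#' @rdname interval_rule
#' @param rules list of `interval_rule`s (possibly empty).
#' @param default_class class assigned when no rule matches.
#' @param meta optional training metadata (seed, learner, parameters).
#' @return `decision_list` returns an object of class `decision_list`.
#' @export
decision_list <- function(rules, default_class, meta = list()) {
  stopifnot(is.list(rules), is.character(default_class),
            length(default_class) == 1)
  for (r in rules) if (!inherits(r, "interval_rule"))
    stop("all rules must be interval_rule objects")
  structure(list(rules = rules, default_class = default_class, meta = meta),
            class = "decision_list")
}

#' @export
print.decision_list <- function(x, ...) {
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    preds <- if (length(r$genes))
      paste(sprintf("Exp(%s) in [%.3g,%.3g]", r$genes, r$lo, r$hi),
            collapse = " AND ")
    else "TRUE"
    cat(i, ": ", preds, " -> ", r$class, "\n", sep = "")
  }
  cat(length(x$rules) + 1, ": DEFAULT -> ", x$default_class, "\n", sep = "")
  invisible(x)
}

#' Does a rule match a sample?
#'
#' True iff every predicate's closed interval contains the sample's value;
#' a predicate-free rule matches everything.
#'
#' @param rule an [interval_rule].
#' @param sample_values named numeric vector of expression values.
#' @return Logical scalar.
#' @export
rule_matches <- function(rule, sample_values) {
  stopifnot(inherits(rule, "interval_rule"))
  if (!length(rule$genes)) return(TRUE)
  missing <- setdiff(rule$genes, names(sample_values))
  if (length(missing)) stop("sample provides no value for gene: ", missing[1])
  v <- sample_values[rule$genes]
  all(v >= rule$lo & v <= rule$hi)
}

#' Predict with a decision list
#'
#' First-match semantics: the class of the first matching rule, or the
#' default class when no rule matches.
#'
#' @param dl a [decision_list].
#' @param sample_values named numeric vector (single sample).
#' @return The predicted class name.
#' @export
predict_decision_list <- function(dl, sample_values) {
  stopifnot(inherits(dl, "decision_list"))
  for (r in dl$rules) if (rule_matches(r, sample_values)) return(r$class)
  dl$default_class
}

#' @export
predict.decision_list <- function(object, newdata, ...) {
  m <- as_value_matrix(newdata)
  dl_predict_matrix(object, m)
}

as_value_matrix <- function(newdata) {
  if (inherits(newdata, "expr_dataset")) return(newdata$values)
  if (is.matrix(newdata)) return(newdata)
  if (is.numeric(newdata)) return(matrix(newdata, 1,
                                         dimnames = list("s", names(newdata))))
  stop("newdata must be an expr_dataset, matrix or named numeric vector")
}

# fast path used by learners and ensembles: classes encoded by position in
# `classes`, genes mapped to matrix columns
dl_predict_matrix <- function(dl, m, classes = NULL) {
  classes <- classes %||% sort(unique(c(dl$default_class,
                                        vapply(dl$rules, `[[`, "", "class"))))
  for (r in dl$rules) {
    missing <- setdiff(r$genes, colnames(m))
    if (length(missing)) stop("sample provides no value for gene: ", missing[1])
  }
  gidx <- lapply(dl$rules, function(r) match(r$genes, colnames(m)))
  lo <- lapply(dl$rules, `[[`, "lo")
  hi <- lapply(dl$rules, `[[`, "hi")
  cls <- vapply(dl$rules, function(r) match(r$class, classes), 1L)
  codes <- .predict_dl_cpp(m, gidx, lo, hi, cls,
                           match(dl$default_class, classes))
  stats::setNames(classes[codes], rownames(m))
}

#' Learner parameters
#'
#' Tunable parameters shared by the iterative rule learner ([biohel_learn()])
#' and the Pittsburgh-style learner ([gassist_learn()]). The coverage term of
#' the rule fitness rises steeply up to the coverage breakpoint and only
#' gently beyond it, so the search favours rules that cover at least a
#' minimum share of the remaining examples without chasing coverage at the
#' expense of accuracy.
#'
#' @param ga_generations GA generations (default 500).
#' @param population_size GA population size (default 500).
#' @param tournament_size tournament size for selection (default 4).
#' @param crossover_prob,mutation_prob per-individual operator probabilities
#'   (defaults 0.6).
#' @param p_generalize probability that a mutation generalizes rather than
#'   specializes a rule (default 0.5, i.e. generalize and specialize are
#'   equally likely).
#' @param coverage_breakpoint coverage level CB in (0, 1] at which the
#'   coverage reward saturates (default 0.25).
#' @param coverage_slope_after slope w of the coverage term beyond the
#'   breakpoint (default 0.1).
#' @param complexity_weight penalty lambda per predicate (default 0.001).
#' @param max_genes_per_ruleset cap on distinct genes across a decision list
#'   (default 30), the role feature selection plays when the learner runs
#'   without an external selector.
#' @param min_rule_accuracy rules below this accuracy are unusable and stop
#'   the iterative covering loop (default 0.5).
#' @param max_predicates cap on predicates within a single rule (default 8).
#' @param max_init_predicates predicates seeded into initial rules (default 3).
#' @param init_fraction width of seeded intervals as a fraction of the
#'   observed per-gene range (default 0.5).
#' @param max_rules cap on specific rules per Pittsburgh individual
#'   (default 10).
#' @return A `learner_params` list.
#' @export
learner_params <- function(ga_generations = 500, population_size = 500,
                           tournament_size = 4, crossover_prob = 0.6,
                           mutation_prob = 0.6, p_generalize = 0.5,
                           coverage_breakpoint = 0.25,
                           coverage_slope_after = 0.1,
                           complexity_weight = 0.001,
                           max_genes_per_ruleset = 30,
                           min_rule_accuracy = 0.5, max_predicates = 8,
                           max_init_predicates = 3, init_fraction = 0.5,
                           max_rules = 10) {
  stopifnot(ga_generations >= 1, population_size >= 2, tournament_size >= 1,
            crossover_prob >= 0, crossover_prob <= 1, mutation_prob >= 0,
            mutation_prob <= 1, p_generalize >= 0, p_generalize <= 1,
            coverage_breakpoint > 0, coverage_breakpoint <= 1,
            max_genes_per_ruleset >= 1, max_predicates >= 1, max_rules >= 1)
  structure(list(ga_generations = as.integer(ga_generations),
                 population_size = as.integer(population_size),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 p_generalize = p_generalize,
                 coverage_breakpoint = coverage_breakpoint,
                 coverage_slope_after = coverage_slope_after,
                 complexity_weight = complexity_weight,
                 max_genes_per_ruleset = as.integer(max_genes_per_ruleset),
                 min_rule_accuracy = min_rule_accuracy,
                 max_predicates = as.integer(max_predicates),
                 max_init_predicates = as.integer(max_init_predicates),
                 init_fraction = init_fraction,
                 max_rules = as.integer(max_rules)),
            class = "learner_params")
}

#' Fitness of a single rule on a set of examples
#'
#' With coverage `cov` (matched / examples) and accuracy `acc` (correct among
#' matched; 0 when nothing matches), the coverage term is `cov / CB` below
#' the breakpoint CB and `1 + w * (cov - CB)` beyond it (continuous at CB),
#' and the fitness is `acc * CT - lambda * n_predicates`. Higher is better.
#'
#' @param rule an [interval_rule].
#' @param dataset an [expr_dataset]: the not-yet-covered examples of the
#'   current covering iteration.
#' @param params a [learner_params].
#' @return A list with `fitness`, `coverage`, `accuracy` and `usable` (rule
#'   accuracy at or above `min_rule_accuracy` with non-zero coverage).
#' @export
rule_fitness <- function(rule, dataset, params = learner_params()) {
  stopifnot(inherits(rule, "interval_rule"), inherits(dataset, "expr_dataset"))
  if (n_samples(dataset) == 0) stop("examples must be non-empty")
  m <- dataset$values
  matched <- if (length(rule$genes)) {
    gidx <- match(rule$genes, colnames(m))
    if (anyNA(gidx)) stop("rule gene not in dataset: ",
                          rule$genes[which(is.na(gidx))[1]])
    .rule_match_cpp(m, gidx, rule$lo, rule$hi)
  } else rep(TRUE, nrow(m))
  cov <- mean(matched)
  acc <- if (any(matched)) mean(dataset$labels[matched] == rule$class) else 0
  cb <- params$coverage_breakpoint
  ct <- if (cov < cb) cov / cb else 1 + params$coverage_slope_after * (cov - cb)
  list(fitness = acc * ct - params$complexity_weight * length(rule$genes),
       coverage = cov, accuracy = acc,
       usable = cov > 0 && acc >= params$min_rule_accuracy)
}

#' Evolve a single rule with a generational genetic algorithm
#'
#' One covering step of the iterative rule learner: a generational GA
#' (tournament selection, one-point crossover on predicate collections,
#' bound-perturbing mutation with equiprobable generalize/specialize moves,
#' elitism of one) searches for the interval rule with the best
#' [rule_fitness()] on the supplied examples. Deterministic given `seed`.
#'
#' @param dataset an [expr_dataset] holding the remaining examples.
#' @param params a [learner_params].
#' @param seed integer seed.
#' @param pool optional character vector restricting candidate genes.
#' @return The best [interval_rule] found, with its fitness attached as
#'   attributes `fitness`, `coverage` and `accuracy`.
#' @export
evolve_rule <- function(dataset, params = learner_params(), seed = 1,
                        pool = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (n_samples(dataset) < 1) stop("examples must be non-empty")
  with_seed(seed, evolve_rule_impl(dataset, params, pool))
}

evolve_rule_impl <- function(dataset, params, pool = NULL) {
  m <- dataset$values
  if (!is.null(pool)) m <- m[, intersect(colnames(m), pool), drop = FALSE]
  classes <- sort(unique(dataset$labels))
  y <- match(dataset$labels, classes)
  res <- .evolve_rule_cpp(m, y, params)
  r <- interval_rule(colnames(m)[res$gidx + 1L], res$lo, res$hi,
                     classes[res$cls])
  attr(r, "fitness") <- res$fitness
  attr(r, "coverage") <- res$coverage
  attr(r, "accuracy") <- res$accuracy
  r
}

majority_class <- function(labels, classes) {
  tab <- tabulate(factor(labels, classes), nbins = length(classes))
  classes[order(-tab, classes)][1]   # tie -> lexicographically first
}

#' Iterative rule learning of a decision list
#'
#' Separate-and-conquer induction: a GA evolves the best rule for the
#' examples not yet covered, the rule is appended and the examples it
#' matches are removed, until the remaining examples are empty or
#' single-class or the best rule is unusable (accuracy below
#' `min_rule_accuracy`, or zero coverage). The list is closed by a default
#' rule predicting the majority class of the remaining examples (overall
#' training majority when none remain; ties broken lexicographically). The
#' number of distinct genes across the list is capped at
#' `max_genes_per_ruleset`.
#'
#' @param train an [expr_dataset] with both classes present (a single-class
#'   input yields a default-only list with a warning).
#' @param params a [learner_params].
#' @param seed integer seed; learning is a pure function of (data, params,
#'   seed).
#' @return A [decision_list].
#' @export
biohel_learn <- function(train, params = learner_params(), seed = 1) {
  stopifnot(inherits(train, "expr_dataset"))
  classes <- train$classes
  if (length(unique(train$labels)) < 2) {
    warning("single-class training data: returning default-only decision list")
    return(decision_list(list(), unique(train$labels),
                         meta = list(seed = seed, learner = "biohel")))
  }
  with_seed(seed, {
    remaining <- seq_len(n_samples(train))
    rules <- list()
    used_genes <- character()
    default_class <- majority_class(train$labels, classes)
    repeat {
      if (!length(remaining)) break
      rem_labels <- train$labels[remaining]
      if (length(unique(rem_labels)) == 1) {
        default_class <- rem_labels[[1]]
        break
      }
      pool <- if (length(used_genes) >= params$max_genes_per_ruleset)
        used_genes else NULL
      sub <- subset_samples(train, remaining)
      rule <- evolve_rule_impl(sub, params, pool)
      if (attr(rule, "coverage") == 0 ||
          attr(rule, "accuracy") < params$min_rule_accuracy) {
        default_class <- majority_class(rem_labels, classes)
        break
      }
      rules[[length(rules) + 1]] <- rule
      used_genes <- union(used_genes, rule$genes)
      gidx <- match(rule$genes, colnames(sub$values))
      matched <- if (length(rule$genes))
        .rule_match_cpp(sub$values, gidx, rule$lo, rule$hi)
      else rep(TRUE, length(remaining))
      remaining <- remaining[!matched]
    }
    decision_list(rules, default_class,
                  meta = list(seed = seed, learner = "biohel", params = params))
  })
}

# internal representation used by the Pittsburgh GA: list(rules = list of
# list(g, lo, hi, cls)), classes coded 1/2
gassist_eval <- function(ind, m, y, nclass, default_cls, lambda) {
  gidx <- lapply(ind$rules, `[[`, "g")
  lo <- lapply(ind$rules, `[[`, "lo")
  hi <- lapply(ind$rules, `[[`, "hi")
  cls <- vapply(ind$rules, `[[`, 1L, "cls")
  pred <- .predict_dl_cpp(m, gidx, lo, hi, cls, default_cls)
  acc <- mean(pred == y)
  npred <- sum(lengths(gidx))
  acc - lambda * npred
}

gassist_seed_rule <- function(m, y, cmin, cmax, params) {
  e <- sample.int(nrow(m), 1)
  k <- sample.int(min(params$max_init_predicates, ncol(m)), 1)
  g <- sample.int(ncol(m), k)
  range <- pmax(cmax[g] - cmin[g], 1)
  w <- params$init_fraction * range
  list(g = as.integer(g), lo = m[e, g] - w / 2, hi = m[e, g] + w / 2,
       cls = y[e])
}

gassist_mutate_rule <- function(r, m, y, cmin, cmax, params) {
  np <- length(r$g)
  if (np > 0) {
    j <- sample.int(np, 1)
    step <- 0.1 * (cmax[r$g[j]] - cmin[r$g[j]])
    if (runif(1) < 0.5) r$lo[j] <- r$lo[j] + rnorm(1, sd = max(step, 1e-9))
    else r$hi[j] <- r$hi[j] + rnorm(1, sd = max(step, 1e-9))
    if (r$lo[j] > r$hi[j]) { tmp <- r$lo[j]; r$lo[j] <- r$hi[j]; r$hi[j] <- tmp }
  }
  if (runif(1) < params$p_generalize) {
    if (np > 0) {
      j <- sample.int(np, 1)
      if (runif(1) < 0.5) {
        r$g <- r$g[-j]; r$lo <- r$lo[-j]; r$hi <- r$hi[-j]
      } else if (runif(1) < 0.5) r$lo[j] <- cmin[r$g[j]]
      else r$hi[j] <- cmax[r$g[j]]
    }
  } else {
    free <- setdiff(seq_len(ncol(m)), r$g)
    if (length(free) && np < params$max_predicates &&
        (np == 0 || runif(1) < 0.5)) {
      g <- free[sample.int(length(free), 1)]
      e <- sample.int(nrow(m), 1)
      w <- params$init_fraction * max(cmax[g] - cmin[g], 1)
      r$g <- c(r$g, g); r$lo <- c(r$lo, m[e, g] - w / 2)
      r$hi <- c(r$hi, m[e, g] + w / 2)
    } else if (np > 0) {
      j <- sample.int(np, 1)
      mid <- (r$lo[j] + r$hi[j]) / 2
      if (runif(1) < 0.5) r$lo[j] <- (r$lo[j] + mid) / 2
      else r$hi[j] <- (r$hi[j] + mid) / 2
    }
  }
  r
}

#' Pittsburgh-style evolution of whole decision lists
#'
#' A generational GA whose individuals are complete decision lists (1 to
#' `max_rules` interval rules plus a default class fixed to the training
#' majority). Fitness is training accuracy minus
#' `complexity_weight * total predicates`; crossover exchanges contiguous
#' rule blocks; mutation edits a random rule (as in [evolve_rule()]) or
#' inserts/deletes a rule; elitism of one. Deterministic given `seed`.
#'
#' @inheritParams biohel_learn
#' @return A [decision_list].
#' @export
gassist_learn <- function(train, params = learner_params(), seed = 1) {
  stopifnot(inherits(train, "expr_dataset"))
  classes <- train$classes
  if (length(unique(train$labels)) < 2) {
    warning("single-class training data: returning default-only decision list")
    return(decision_list(list(), unique(train$labels),
                         meta = list(seed = seed, learner = "gassist")))
  }
  m <- train$values
  y <- match(train$labels, classes)
  default_cls <- match(majority_class(train$labels, classes), classes)
  cmin <- apply(m, 2, min); cmax <- apply(m, 2, max)
  lambda <- params$complexity_weight
  with_seed(seed, {
    pop <- lapply(seq_len(params$population_size), function(i) {
      nr <- sample.int(3, 1)
      list(rules = lapply(seq_len(nr), function(j)
        gassist_seed_rule(m, y, cmin, cmax, params)))
    })
    fit <- vapply(pop, gassist_eval, 0, m, y, length(classes), default_cls,
                  lambda)
    best_i <- which.max(fit)
    best <- pop[[best_i]]; best_fit <- fit[best_i]
    for (gen in seq_len(params$ga_generations)) {
      nxt <- vector("list", params$population_size)
      nxt[[1]] <- best
      for (i in seq(2, params$population_size)) {
        pa <- tournament(fit, params$tournament_size)
        if (runif(1) < params$crossover_prob) {
          pb <- tournament(fit, params$tournament_size)
          child <- gassist_crossover(pop[[pa]], pop[[pb]], params$max_rules)
        } else child <- pop[[pa]]
        if (runif(1) < params$mutation_prob)
          child <- gassist_mutate(child, m, y, cmin, cmax, params)
        nxt[[i]] <- child
      }
      pop <- nxt
      fit <- vapply(pop, gassist_eval, 0, m, y, length(classes), default_cls,
                    lambda)
      if (max(fit) > best_fit) {
        best_i <- which.max(fit); best <- pop[[best_i]]; best_fit <- fit[best_i]
      }
    }
    rules <- lapply(best$rules, function(r)
      interval_rule(colnames(m)[r$g], r$lo, r$hi, classes[r$cls]))
    decision_list(rules, classes[default_cls],
                  meta = list(seed = seed, learner = "gassist",
                              params = params, fitness = best_fit))
  })
}

tournament <- function(fit, k) {
  cand <- sample.int(length(fit), min(k, length(fit)), replace = TRUE)
  cand[which.max(fit[cand])]
}

gassist_crossover <- function(a, b, max_rules) {
  na <- length(a$rules); nb <- length(b$rules)
  i <- sample.int(na + 1, 1) - 1          # keep a$rules[seq_len(i)]
  j <- sample.int(nb + 1, 1) - 1          # append b$rules[(j+1)..nb]
  rules <- c(a$rules[seq_len(i)],
             if (j < nb) b$rules[seq(j + 1, nb)] else list())
  if (!length(rules)) rules <- a$rules[1]
  if (length(rules) > max_rules) rules <- rules[seq_len(max_rules)]
  list(rules = rules)
}

gassist_mutate <- function(ind, m, y, cmin, cmax, params) {
  nr <- length(ind$rules)
  op <- sample.int(3, 1)
  if (op == 1 || nr == 0) {               # edit a random rule
    if (nr > 0) {
      j <- sample.int(nr, 1)
      ind$rules[[j]] <- gassist_mutate_rule(ind$rules[[j]], m, y, cmin, cmax,
                                            params)
    }
  } else if (op == 2 && nr < params$max_rules) {   # insert
    pos <- sample.int(nr + 1, 1)
    ind$rules <- append(ind$rules, list(gassist_seed_rule(m, y, cmin, cmax,
                                                          params)), pos - 1)
  } else if (nr > 1) {                    # delete
    ind$rules[[sample.int(nr, 1)]] <- NULL
  }
  ind
}

#' Train a seed ensemble of decision lists
#'
#' Repeats the (stochastic) learner with seeds `base_seed + 0 .. n_members-1`
#' on the same training data and keeps every resulting decision list.
#' Majority voting over members reduces the variance of single evolved rule
#' sets.
#'
#' @param train an [expr_dataset].
#' @param learner `"biohel"` or `"gassist"`.
#' @param n_members ensemble size (default 100).
#' @param base_seed first member seed.
#' @param params a [learner_params].
#' @return A `rule_ensemble`: list with `members` (decision lists) and
#'   `prevalence` (training-class proportions, used for vote tie-breaking).
#' @export
train_ensemble <- function(train, learner = c("biohel", "gassist"),
                           n_members = 100, base_seed = 1,
                           params = learner_params()) {
  learner <- match.arg(learner)
  fn <- switch(learner, biohel = biohel_learn, gassist = gassist_learn)
  members <- lapply(seq_len(n_members) - 1L, function(i)
    fn(train, params, seed = base_seed + i))
  prevalence <- table(train$labels) / n_samples(train)
  rule_ensemble(members, stats::setNames(as.numeric(prevalence),
                                         names(prevalence)))
}

#' @rdname train_ensemble
#' @param members list of [decision_list]s.
#' @param prevalence named numeric vector of training-class proportions.
#' @export
rule_ensemble <- function(members, prevalence) {
  stopifnot(length(members) >= 1)
  structure(list(members = members, prevalence = prevalence),
            class = "rule_ensemble")
}

#' Majority-vote prediction with a rule ensemble
#'
#' Each member decision list votes; the class with most votes wins. An exact
#' tie goes to the class with the higher training prevalence, and a
#' still-standing tie to the lexicographically first class.
#'
#' @param ensemble a [rule_ensemble].
#' @param newdata an [expr_dataset], samples-by-genes matrix, or single named
#'   numeric vector.
#' @return Named character vector of predicted classes.
#' @export
ensemble_predict <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "rule_ensemble"))
  m <- as_value_matrix(newdata)
  classes <- sort(names(ensemble$prevalence))
  votes <- matrix(0L, nrow(m), length(classes),
                  dimnames = list(rownames(m), classes))
  for (dl in ensemble$members) {
    pred <- dl_predict_matrix(dl, m, classes)
    for (k in seq_along(classes))
      votes[, k] <- votes[, k] + (pred == classes[k])
  }
  prev <- ensemble$prevalence[classes]
  apply_names <- rownames(m)
  out <- vapply(seq_len(nrow(m)), function(i) {
    v <- votes[i, ]
    # most votes, then higher prevalence, then lexicographic order
    classes[order(-v, -prev, classes)][1]
  }, character(1))
  stats::setNames(out, apply_names)
}

#' @export
predict.rule_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}

#' Rule-frequency gene ranking from trained ensembles
#'
#' Scores each gene by the percentage of non-default rules (across all
#' ensemble members and all supplied ensembles, e.g. one per CV cycle) that
#' carry a predicate on it. This is the rule-frequency ranking used to
#' prioritize genes directly from the learned models.
#'
#' @param ensembles a [rule_ensemble] or list of them.
#' @param genes optional gene universe; when given, genes absent from every
#'   rule are kept in the ranking with score 0.
#' @return A `feature_ranking` with percentage scores.
#' @export
attribute_frequency <- function(ensembles, genes = NULL) {
  if (inherits(ensembles, "rule_ensemble")) ensembles <- list(ensembles)
  counts <- new.env(parent = emptyenv())
  total_rules <- 0L
  for (ens in ensembles) for (dl in ens$members) for (r in dl$rules) {
    total_rules <- total_rules + 1L
    for (g in unique(r$genes))
      counts[[g]] <- (counts[[g]] %||% 0L) + 1L
  }
  if (total_rules == 0L) {
    warning("no non-default rules in any ensemble; empty ranking")
    return(new_feature_ranking(character(), numeric(), "biohel_fr"))
  }
  genes <- union(ls(counts), genes)
  score <- 100 * vapply(genes, function(g) counts[[g]] %||% 0L, 1L) /
    total_rules
  ord <- order(-score, genes)
  new_feature_ranking(genes[ord], unname(score[ord]), "biohel_fr")
}
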