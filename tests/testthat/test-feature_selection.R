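test_that("the F statistic matches the pooled-t-squared identity", {
  # constant gene scores 0; perfect separator scores Inf
  expect_equal(f_statistic(rep(1, 8), rep(c("A", "B"), 4)), 0)
  expect_equal(f_statistic(c(0, 0, 1, 1), c("A", "A", "B", "B")), Inf)

  set.seed(33)
  for (i in 1:10) {
    v <- rnorm(20)
    lab <- rep(c("A", "B"), each = 10)
    t_pooled <- t.test(v[lab == "A"], v[lab == "B"], var.equal = TRUE)$statistic
    expect_equal(f_statistic(v, lab), unname(t_pooled^2), tolerance = 1e-10)
  }
  expect_error(f_statistic(rnorm(4), rep("A", 4)), "two classes")
})

test_that("plss_rank orders genes by decreasing F with deterministic ties", {
  ds <- tiny_dataset(n_per_class = 10, n_genes = 8, delta = 4, seed = 5)
  r <- plss_rank(ds)
  expect_equal(r$gene[1], "g01")
  expect_true(all(diff(r$score[is.finite(r$score)]) <= 1e-12))

  # duplicated gene columns share a score and sit on adjacent ranks
  m <- ds$values
  m <- cbind(m, g99 = m[, "g01"])
  dup <- expr_dataset(m, ds$labels)
  rd <- plss_rank(dup)
  expect_equal(which(rd$gene %in% c("g01", "g99")), c(1, 2))
  expect_equal(rd$score[1], rd$score[2])
})

test_that("plss_rank is invariant to affine rescaling of a gene", {
  ds <- tiny_dataset(n_per_class = 10, n_genes = 8, delta = 2, seed = 6)
  m <- ds$values
  m[, "g03"] <- 5 + 100 * m[, "g03"]
  expect_identical(plss_rank(expr_dataset(m, ds$labels))$gene,
                   plss_rank(ds)$gene)
})

test_that("cfs merit follows its closed form", {
  expect_equal(cfs_merit(1, 0.6), 0.6)
  expect_equal(cfs_merit(2, 0.6, 1), 1.2 / sqrt(4))   # duplicate adds nothing
  # independent direct evaluation of the formula
  expect_equal(cfs_merit(3, 0.5, 0.2), 3 * 0.5 / sqrt(3 + 3 * 2 * 0.2))
  expect_error(cfs_merit(0, 0.5), "k")

  # with r_ff = 0 the merit grows as sqrt(k); with r_ff = 1 it is flat
  for (k in 1:8) {
    expect_equal(cfs_merit(k, 0.4, 0), sqrt(k) * 0.4)
    expect_equal(cfs_merit(k, 0.4, 1), 0.4)
  }
})

test_that("cfs_select keeps dominant features and drops redundant copies", {
  set.seed(9)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  signal <- y + rnorm(n, sd = 0.3)
  signal2 <- y + rnorm(n, sd = 0.3)
  m <- cbind(gA = signal, gDup = signal, gB = signal2,
             matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("noise", 1:4))))
  rownames(m) <- sprintf("s%02d", 1:n)
  ds <- expr_dataset(m, ifelse(y == 1, "case", "control"))
  fs <- cfs_select(ds, max_size = 5)
  expect_true("gA" %in% fs$genes || "gDup" %in% fs$genes)
  expect_false(all(c("gA", "gDup") %in% fs$genes))
  expect_true("gB" %in% fs$genes)
  expect_lte(length(fs$genes), 5)
})

test_that("greedy best-first merit is bounded by the exhaustive optimum", {
  # brute force over all 2^10 - 1 subsets as the independent oracle
  exhaustive_best <- function(rcf, ff) {
    p <- length(rcf)
    best <- -Inf
    for (mask in seq_len(2^p - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
      k <- length(sel)
      r_ff <- if (k > 1) mean(ff[sel, sel][upper.tri(ff[sel, sel])]) else 0
      best <- max(best, cfs_merit(k, mean(rcf[sel]), min(r_ff, 1)))
    }
    best
  }
  set.seed(71)
  for (i in 1:10) {
    n <- 24
    y <- rep(c(0, 1), each = n / 2)
    m <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:10)))
    m[, 1] <- m[, 1] + y * runif(1, 0.5, 2)
    ds <- expr_dataset(m, ifelse(y == 1, "case", "control"))
    fs <- cfs_select(ds, max_size = 10)
    rcf <- abs(as.vector(cor(m, y)))
    ff <- abs(cor(m))
    sel <- match(fs$genes, colnames(m))
    k <- length(sel)
    r_ff <- if (k > 1) mean(ff[sel, sel][upper.tri(ff[sel, sel])]) else 0
    greedy_merit <- cfs_merit(k, mean(rcf[sel]), min(r_ff, 1))
    expect_lte(greedy_merit, exhaustive_best(rcf, ff) + 1e-9)
    expect_gte(greedy_merit, max(rcf) - 1e-9)  # at least the best single gene
  }
})

test_that("random-forest importance ranks a strong planted gene first", {
  hits <- 0
  for (s in 1:10) {
    sim <- generate_expression(expression_sim_spec(
      n_per_class = c(25, 25), n_genes = 40, n_informative = 1, effect = 3,
      seed = 100 + s))
    r <- rfs_rank(sim$dataset, n_trees = 500, seed = s)
    expect_true(all(r$score >= 0))
    expect_gt(sum(r$score), 0)
    hits <- hits + (r$gene[1] == "g0001")
  }
  expect_gte(hits, 9)
  # deterministic given the seed
  sim <- generate_expression(expression_sim_spec(n_per_class = c(15, 15),
                                                 n_genes = 20, seed = 1))
  expect_identical(rfs_rank(sim$dataset, 100, seed = 7),
                   rfs_rank(sim$dataset, 100, seed = 7))
})

test_that("select_top_k slices rankings and validates its bounds", {
  ds <- tiny_dataset(n_per_class = 10, n_genes = 12, seed = 2)
  r <- plss_rank(ds)
  expect_equal(select_top_k(r, 5)$genes, r$gene[1:5])
  expect_setequal(select_top_k(r, 12)$genes, colnames(ds$values))
  expect_error(select_top_k(r, 0), "between")
  expect_error(select_top_k(r, 13), "between")
})

test_that("consensus selection honours frequency top lists and method support", {
  fs <- function(genes) structure(
    list(genes = genes, method = "m", max_size = 30), class = "feature_set")
  sel <- list(
    plss = list(fs(c("g1", "g2")), fs(c("g1", "g3")), fs(c("g1", "g2"))),
    cfs  = list(fs(c("g1", "g4")), fs(c("g1", "g4")), fs(c("g1", "g5"))),
    rfs  = list(fs(c("g1", "g6")), fs(c("g6", "g7")), fs(c("g1", "g6"))))
  out <- consensus_selection(sel, top_k = 2, min_methods = 2)
  expect_equal(out$gene[1], "g1")          # in every method's top list
  expect_equal(out$n_methods[1], 3)
  expect_false("g6" %in% out$gene)         # frequent in one method only
  out1 <- consensus_selection(sel, top_k = 2, min_methods = 1)
  expect_true("g6" %in% out1$gene)
})

test_that("consensus recovers planted genes across selectors and folds", {
  sim <- generate_expression(expression_sim_spec(seed = 77))
  ds <- sim$dataset
  plan <- make_fold_plan(ds$labels, "kfold", k = 5, seed = 77)
  per_fold <- function(select_fun) lapply(1:5, function(f) {
    train <- rulemine:::subset_samples(
      ds, names(plan$assignments)[plan$assignments != f])
    select_fun(train)
  })
  sel <- list(plss = per_fold(function(tr) select_top_k(plss_rank(tr), 15)),
              cfs = per_fold(function(tr) cfs_select(tr, max_size = 15)),
              rfs = per_fold(function(tr)
                select_top_k(rfs_rank(tr, 200, seed = 1), 15)))
  out <- consensus_selection(sel, top_k = 15, min_methods = 2)
  expect_gte(sum(out$gene %in% sim$informative), 8)
  expect_lte(mean(!out$gene %in% sim$informative), 0.2)
})
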