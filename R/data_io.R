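#' Construct an expression dataset
#'
#' The central container: a numeric samples-by-genes matrix plus a two-class
#' label per sample. Training functions require both classes to be present.
#'
#' @param values numeric matrix, samples in rows, genes in columns, with
#'   unique row (sample) and column (gene) names and no missing values.
#' @param labels character or factor of class labels, one per sample, in row
#'   order of `values` (or named by sample).
#' @return An object of class `expr_dataset` with elements `values`, `labels`
#'   (named character) and `classes` (sorted unique class names).
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' ds <- expr_dataset(m, c("A", "A", "B", "B"))
#' n_samples(ds)
#' @export
expr_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and gene column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate sample identifier: ", dup[1])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate gene identifier: ", dup[1])
  if (anyNA(values)) stop("expression matrix contains missing values")
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(values), names(labels))
    if (length(missing)) stop("sample without label: ", missing[1])
    labels <- labels[rownames(values)]
  } else {
    if (length(labels) != nrow(values))
      stop("need one label per sample (", nrow(values), "), got ", length(labels))
    names(labels) <- rownames(values)
  }
  if (anyNA(labels)) stop("sample without label")
  classes <- sort(unique(labels))
  if (length(classes) > 2)
    stop("more than two classes in labels: ", paste(classes, collapse = ", "))
  structure(list(values = values, labels = labels, classes = classes),
            class = "expr_dataset")
}

#' @rdname expr_dataset
#' @param x an `expr_dataset`.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname expr_dataset
#' @export
n_genes <- function(x) ncol(x$values)

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", n_samples(x), " samples x ", n_genes(x), " genes; classes: ",
      paste(sprintf("%s (n=%d)", x$classes, tabulate(factor(x$labels, x$classes))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# row subset that keeps the container valid (used by the CV harness)
subset_samples <- function(dataset, idx) {
  expr_dataset(dataset$values[idx, , drop = FALSE], dataset$labels[idx])
}

subset_genes <- function(dataset, genes) {
  missing <- setdiff(genes, colnames(dataset$values))
  if (length(missing)) stop("gene not in dataset: ", missing[1])
  expr_dataset(dataset$values[, genes, drop = FALSE], dataset$labels)
}

#' Read an expression matrix and its sample labels
#'
#' Expression files are tab-delimited with a `gene_id` first column and one
#' column per sample, the usual microarray export layout (genes as rows).
#' The internal model is samples x genes; orientation is auto-detected by
#' intersecting the file's row/column identifiers with the label table's
#' sample identifiers, with an explicit override available.
#'
#' @param matrix_path path to the TSV expression matrix.
#' @param labels_path path to a two-column TSV (sample_id, class).
#' @param orientation `"auto"` (default), `"genes_rows"` or `"samples_rows"`.
#' @return An [expr_dataset].
#' @export
read_expression_matrix <- function(matrix_path, labels_path,
                                   orientation = c("auto", "genes_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression matrix needs an identifier column plus data columns")
  ids <- as.character(raw[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate identifier in first column: ", dup[1])
  for (j in seq(2, ncol(raw))) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric value at row ", bad, ", column '", colnames(raw)[j], "'")
    }
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids

  lab <- read.delim(labels_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file needs columns (sample_id, class)")
  labels <- as.character(lab[[2]])
  names(labels) <- as.character(lab[[1]])
  dup <- names(labels)[duplicated(names(labels))]
  if (length(dup)) stop("duplicate sample identifier in labels: ", dup[1])
  if (length(unique(labels)) > 2)
    stop("labels define more than two classes: ",
         paste(unique(labels), collapse = ", "))

  if (orientation == "auto") {
    hit_cols <- mean(colnames(m) %in% names(labels))
    hit_rows <- mean(rownames(m) %in% names(labels))
    orientation <- if (hit_cols >= hit_rows) "genes_rows" else "samples_rows"
  }
  if (orientation == "genes_rows") m <- t(m)
  expr_dataset(m, labels)
}

#' Write an expression dataset to TSV files
#'
#' Writes the genes-as-rows layout read back by [read_expression_matrix()].
#'
#' @param dataset an [expr_dataset].
#' @param matrix_path,labels_path output paths.
#' @export
write_expression_matrix <- function(dataset, matrix_path, labels_path) {
  m <- t(dataset$values)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = names(dataset$labels), class = dataset$labels)
  write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, labels_path))
}

# repr-level precision so text round trips are exact for doubles
num_repr <- function(x) sprintf("%.17g", x)

#' Serialize a decision list as readable rule text
#'
#' One rule per line in the form
#' `Exp(gene) in [lo,hi] AND ... -> class`, closed by a final
#' `DEFAULT -> class` line. Bounds are written with full double precision so
#' a write/read round trip reproduces the list exactly.
#'
#' @param dl a [decision_list].
#' @param path output file path.
#' @export
write_ruleset <- function(dl, path) {
  stopifnot(inherits(dl, "decision_list"))
  lines <- vapply(dl$rules, function(r) {
    preds <- paste(sprintf("Exp(%s) in [%s,%s]", r$genes, num_repr(r$lo),
                           num_repr(r$hi)), collapse = " AND ")
    if (!length(r$genes)) preds <- "TRUE"
    paste(preds, "->", r$class)
  }, character(1))
  lines <- c(lines, paste("DEFAULT ->", dl$default_class))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ruleset
#' @return `read_ruleset` returns the parsed [decision_list].
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty rule file: ", path)
  last <- trimws(lines[length(lines)])
  m <- regmatches(last, regexec("^DEFAULT\\s*->\\s*(.+)$", last))[[1]]
  if (!length(m)) stop("default rule absent (last line must be 'DEFAULT -> <class>')")
  default_class <- trimws(m[2])
  body <- lines[-length(lines)]
  rules <- lapply(seq_along(body), function(i) parse_rule_line(body[i], i))
  decision_list(rules, default_class)
}

parse_rule_line <- function(line, lineno) {
  m <- regmatches(line, regexec("^(.*)->\\s*(\\S.*?)\\s*$", line))[[1]]
  if (!length(m)) stop("malformed rule at line ", lineno, ": ", line)
  lhs <- trimws(m[2])
  cls <- m[3]
  if (identical(lhs, "TRUE")) return(interval_rule(character(), numeric(), numeric(), cls))
  parts <- strsplit(lhs, "\\s+AND\\s+")[[1]]
  pat <- "^Exp\\((.+)\\)\\s+in\\s+\\[([^,]+),([^]]+)\\]$"
  genes <- character(length(parts)); lo <- numeric(length(parts)); hi <- numeric(length(parts))
  for (k in seq_along(parts)) {
    pm <- regmatches(trimws(parts[k]), regexec(pat, trimws(parts[k])))[[1]]
    if (!length(pm)) stop("malformed predicate at line ", lineno, ": ", parts[k])
    genes[k] <- pm[2]
    lo[k] <- as.numeric(pm[3])
    hi[k] <- as.numeric(pm[4])
    if (is.na(lo[k]) || is.na(hi[k]))
      stop("non-numeric bound at line ", lineno, ": ", parts[k])
  }
  interval_rule(genes, lo, hi, cls)
}

#' Build a cross-validation fold plan
#'
#' k-fold plans are stratified: within each class, shuffled samples are dealt
#' round-robin so per-class fold counts differ by at most one. Leave-one-out
#' ignores `k` and yields one singleton fold per sample.
#'
#' @param labels named character vector of class labels (names = sample ids).
#' @param scheme `"kfold"` or `"loocv"`.
#' @param k number of folds for `"kfold"` (default 10).
#' @param seed integer seed; plans are deterministic given the seed.
#' @return A `fold_plan`: list with `scheme`, `k`, `seed` and `assignments`
#'   (named integer fold index per sample).
#' @export
make_fold_plan <- function(labels, scheme = c("kfold", "loocv"), k = 10, seed = 1) {
  scheme <- match.arg(scheme)
  if (is.null(names(labels))) stop("`labels` must be named by sample id")
  labels <- stats::setNames(as.character(labels), names(labels))
  n <- length(labels)
  if (scheme == "loocv") {
    assignments <- seq_len(n)
    names(assignments) <- names(labels)
    return(structure(list(scheme = scheme, k = n, seed = seed,
                          assignments = assignments), class = "fold_plan"))
  }
  if (k < 2 || n < k) stop("need n >= k >= 2 for k-fold")
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small))
    stop("cannot stratify: class '", small[1], "' has fewer than k = ", k,
         " members")
  assignments <- integer(n)
  names(assignments) <- names(labels)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(scheme = scheme, k = k, seed = seed, assignments = assignments),
            class = "fold_plan")
}

#' @rdname make_fold_plan
#' @param plan a `fold_plan`.
#' @param path output TSV path.
#' @export
write_fold_plan <- function(plan, path) {
  df <- data.frame(sample_id = names(plan$assignments),
                   fold = unname(plan$assignments), scheme = plan$scheme)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname make_fold_plan
#' @export
read_fold_plan <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  assignments <- as.integer(df$fold)
  names(assignments) <- df$sample_id
  structure(list(scheme = df$scheme[1], k = max(assignments), seed = NA_integer_,
                 assignments = assignments), class = "fold_plan")
}

#' Serialize a rule ensemble to JSON
#'
#' Structured serialization of every member decision list (ordered rules,
#' predicates, classes, seed and training metadata) plus the ensemble's
#' training-class prevalences.
#'
#' @param ensemble a [rule_ensemble].
#' @param path output JSON path.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "rule_ensemble"))
  obj <- list(
    prevalence = as.list(ensemble$prevalence),
    members = lapply(ensemble$members, function(dl) {
      list(seed = dl$meta$seed %||% NA,
           learner = dl$meta$learner %||% NA,
           default_class = dl$default_class,
           rules = lapply(dl$rules, function(r)
             list(genes = r$genes, lo = r$lo, hi = r$hi, class = r$class)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  members <- lapply(obj$members, function(m) {
    rules <- lapply(m$rules, function(r)
      interval_rule(unlist(r$genes) %||% character(), unlist(r$lo) %||% numeric(),
                    unlist(r$hi) %||% numeric(), r$class))
    decision_list(rules, m$default_class,
                  meta = list(seed = m$seed, learner = m$learner))
  })
  prevalence <- unlist(obj$prevalence)
  rule_ensemble(members, prevalence)
}
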