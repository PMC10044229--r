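#' Random-Forest configuration per call category
#'
#' Variable sets and split parameters used to validate the aural-visual
#' classification: six variables for harmonic calls (`dur`, `f0`, `Fmax`,
#' `Q25`, `Q50`, `Q75` — the variables measurable for every type of the
#' category; `excF` is unavailable for two types and excluded), five for
#' noisy calls and two for pulsative calls. `mtry` is 2, 2 and 1
#' respectively and 500 trees are grown.
#'
#' @param category `"harmonic"`, `"noisy"` or `"pulsative"`
#' @param n_trees number of trees
#' @param mtry variables tried per split (category default when NULL)
#' @return list with `variables`, `mtry`, `n_trees`
#' @export
rf_config <- function(category = c("harmonic", "noisy", "pulsative"),
                      n_trees = 500L, mtry = NULL) {
  category <- match.arg(category)
  variables <- switch(category,
                      harmonic = c("dur", "f0", "Fmax", "Q25", "Q50", "Q75"),
                      noisy = c("dur", "Fmax", "Q25", "Q50", "Q75"),
                      pulsative = c("dur", "PR"))
  if (is.null(mtry)) mtry <- if (category == "pulsative") 1L else 2L
  if (mtry > length(variables)) stop("mtry exceeds the variable set")
  list(category = category, variables = variables,
       mtry = as.integer(mtry), n_trees = as.integer(n_trees))
}

#' Validate a call-type classification by Random Forest
#'
#' Grows a forest on the labelled feature table, aggregates out-of-bag
#' predictions into a confusion matrix (rows = true type, columns =
#' predicted) and reports per-class errors, the overall OOB error, the
#' accuracy (exactly `1 - OOB error`) and Gini variable importances in
#' descending order.
#'
#' @param features data.frame with a `type` column and the configured
#'   variables
#' @param config an [rf_config()]
#' @param seed integer seed (forest growth is reproducible given a seed)
#' @return object of class `rf_result`: list with `confusion`,
#'   `per_class_error`, `oob_error`, `accuracy`, `importance`, `config`
#' @export
rf_validate <- function(features, config, seed = NULL) {
  vars <- config$variables
  missing_vars <- setdiff(c("type", vars), names(features))
  if (length(missing_vars)) {
    stop("feature table lacks column(s): ", paste(missing_vars, collapse = ", "))
  }
  X <- as.matrix(features[, vars, drop = FALSE])
  bad <- which(!stats::complete.cases(X))
  if (length(bad)) {
    stop("missing values in configured variables at row(s): ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) sprintf(" (and %d more)", length(bad) - 20) else "")
  }
  y <- factor(features$type, levels = unique(features$type))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (!is.null(seed)) set.seed(seed)
  fit <- .forest_oob(X, as.integer(y) - 1L, nlevels(y),
                     config$n_trees, config$mtry)
  pred <- factor(levels(y)[fit$oob_pred + 1L], levels = levels(y))
  cm <- table(true = y, predicted = pred)
  cm <- matrix(as.integer(cm), nrow = nlevels(y),
               dimnames = list(levels(y), levels(y)))
  imp <- sort(stats::setNames(fit$importance, vars), decreasing = TRUE)
  err <- overall_error(cm) / 100
  structure(list(confusion = cm,
                 per_class_error = per_class_error(cm),
                 oob_error = err, accuracy = 1 - err,
                 importance = imp, config = config),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("Random-Forest validation (%s): %d classes, %d trees, mtry %d\n",
              x$config$category, nrow(x$confusion), x$config$n_trees,
              x$config$mtry))
  cat(sprintf("OOB error %.1f%%  accuracy %.1f%%\n",
              100 * x$oob_error, 100 * x$accuracy))
  cat("Gini importance: ",
      paste(sprintf("%s=%.1f", names(x$importance), x$importance),
            collapse = "  "), "\n")
  print(cbind(x$confusion, error = round(x$per_class_error, 3)))
  invisible(x)
}

check_confusion <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("negative counts")
  m
}

#' Per-class classification error
#'
#' `(row sum - diagonal) / row sum` for a class of a confusion matrix.
#'
#' @param m square count matrix, rows = true class
#' @param class class name or index; all classes when NULL
#' @return fraction(s) in `[0, 1]`
#' @export
per_class_error <- function(m, class = NULL) {
  m <- check_confusion(m)
  rs <- rowSums(m)
  if (!is.null(class)) {
    i <- if (is.character(class)) match(class, rownames(m)) else class
    if (is.na(i)) stop("unknown class: ", class)
    if (rs[i] == 0) stop("empty class row: ", class)
    return(unname((rs[i] - m[i, i]) / rs[i]))
  }
  if (any(rs == 0)) stop("empty class row(s)")
  (rs - diag(m)) / rs
}

#' Overall out-of-bag error
#'
#' `100 * (total - trace) / total` percent.
#'
#' @inheritParams per_class_error
#' @return percent
#' @export
overall_error <- function(m) {
  m <- check_confusion(m)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  100 * (total - sum(diag(m))) / total
}

#' Global classification accuracy
#'
#' `accuracy = 1 - OOB error`, reported in percent.
#'
#' @inheritParams per_class_error
#' @return percent
#' @export
accuracy <- function(m) 100 - overall_error(m)

#' Chance classification rate of a class
#'
#' The rate a no-information classifier would reach: class row sum over
#' the total number of calls.
#'
#' @inheritParams per_class_error
#' @return fraction(s)
#' @export
chance_rate <- function(m, class = NULL) {
  m <- check_confusion(m)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  rs <- rowSums(m) / total
  if (is.null(class)) return(rs)
  i <- if (is.character(class)) match(class, rownames(m)) else class
  if (is.na(i)) stop("unknown class: ", class)
  unname(rs[i])
}
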