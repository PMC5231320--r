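#' Build an undersampled training set
#'
#' Compensates extreme class imbalance by capping every class at `cap`
#' training cells: classes above the cap are subsampled without
#' replacement (seeded, deterministic); minority classes keep all their
#' members. Classes present in `class_order` but absent from the data are
#' retained with empty support, with a warning.
#'
#' @param labels Named character vector mapping `cell_id` to phase label.
#' @param cap Maximum training cells per class (default 100).
#' @param seed Integer seed for the subsampling.
#' @param class_order Fixed class order (default [phase_levels()]).
#' @return A list of class `ifc_training_set`: `cell_ids`, `labels`,
#'   `counts_before`, `counts_after`, `cap`, `seed`, `class_order`.
#' @export
build_training_set <- function(labels, cap = 100, seed = 1,
                               class_order = phase_levels()) {
  stopifnot(!is.null(names(labels)), cap >= 1)
  labels <- labels[!is.na(labels)]
  present <- unique(labels)
  if (length(present) < 2)
    stop("need at least 2 classes to build a training set", call. = FALSE)
  missing <- setdiff(class_order, present)
  if (length(missing))
    warning("class(es) with no members retained with empty support: ",
            paste(missing, collapse = ", "), call. = FALSE)
  before <- table(factor(labels, levels = class_order))
  keep <- withr::with_seed(seed, {
    unlist(lapply(class_order, function(cl) {
      ids <- names(labels)[labels == cl]
      if (length(ids) > cap) sort(sample(ids, cap)) else ids
    }), use.names = FALSE)
  })
  keep <- keep[order(match(keep, names(labels)))]   # container order
  after <- table(factor(labels[keep], levels = class_order))
  structure(list(cell_ids = keep, labels = labels[keep],
                 counts_before = as.integer(before),
                 counts_after = as.integer(after),
                 cap = as.integer(cap), seed = as.integer(seed),
                 class_order = class_order),
            class = "ifc_training_set")
}

#' @export
print.ifc_training_set <- function(x, ...) {
  cat("<ifc_training_set> cap ", x$cap, "\n", sep = "")
  print(tibble::tibble(class = x$class_order, before = x$counts_before,
                       after = x$counts_after))
  invisible(x)
}

feature_matrix <- function(table, feature_names) {
  missing <- setdiff(feature_names, names(table))
  if (length(missing))
    stop("feature table lacks column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  m <- as.matrix(table[, feature_names, drop = FALSE])
  m[!is.finite(m)] <- 0   # NaN sentinels imputed to 0 for tree ensembles
  storage.mode(m) <- "double"
  rownames(m) <- table$cell_id
  m
}

#' Train a phase classifier
#'
#' Two tree-ensemble algorithms, both exposing per-feature importance
#' scores and deterministic under a fixed seed:
#' * `"gradient_boosting"` — stage-wise additive ensemble of shallow
#'   trees fit to the gradient of the multiclass log-loss (defaults:
#'   depth 3, 300 stages, learning rate 0.1; via xgboost, single thread).
#' * `"random_forest"` — 500 bootstrap-bagged deep trees with
#'   `sqrt(p)` candidate features per split, majority vote.
#'
#' @param ts An [build_training_set()] object.
#' @param table Feature table (already passed through [filter_features()]).
#' @param algorithm `"gradient_boosting"` or `"random_forest"`.
#' @param params Optional named list overriding hyperparameters
#'   (`max_depth`, `nrounds`, `eta` for boosting; `ntree`, `mtry` for the
#'   forest).
#' @param seed Integer training seed.
#' @return An object of class `ifc_classifier`.
#' @export
train_classifier <- function(ts, table,
                             algorithm = c("gradient_boosting", "random_forest"),
                             params = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ts, "ifc_training_set"))
  feats <- setdiff(names(table), c("cell_id", "flagged"))
  idx <- match(ts$cell_ids, table$cell_id)
  if (anyNA(idx))
    stop("training cells missing from feature table: ",
         paste(utils::head(ts$cell_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  xm <- feature_matrix(table[idx, ], feats)
  y <- factor(ts$labels, levels = ts$class_order)
  if (length(unique(as.character(y))) < 2)
    stop("training set contains a single class", call. = FALSE)
  fit <- switch(algorithm,
    gradient_boosting = {
      p <- utils::modifyList(list(max_depth = 3, nrounds = 300, eta = 0.1), params)
      yf <- droplevels(y)
      obj <- if (nlevels(yf) > 2) "multi:softprob" else "binary:logistic"
      withr::with_seed(seed, {
        xgboost::xgboost(
          xm, yf, objective = obj,
          max_depth = p$max_depth, learning_rate = p$eta, nrounds = p$nrounds,
          nthreads = 1, seed = seed %% .Machine$integer.max, verbosity = 0)
      })
    },
    random_forest = {
      p <- utils::modifyList(
        list(ntree = 500, mtry = max(1, floor(sqrt(ncol(xm))))), params)
      withr::with_seed(seed, {
        randomForest::randomForest(x = xm, y = droplevels(y),
                                   ntree = p$ntree, mtry = p$mtry)
      })
    })
  structure(list(algorithm = algorithm, fit = fit, feature_names = feats,
                 class_order = ts$class_order,
                 classes_fit = levels(droplevels(y)),
                 training_ids = ts$cell_ids,
                 seed = as.integer(seed), params = params),
            class = "ifc_classifier")
}

#' @export
print.ifc_classifier <- function(x, ...) {
  cat("<ifc_classifier> ", x$algorithm, ", ", length(x$feature_names),
      " features, classes [", paste(x$class_order, collapse = ", "),
      "], trained on ", length(x$training_ids), " cells\n", sep = "")
  invisible(x)
}

#' Predict phase labels
#'
#' Class-probability argmax; ties broken by the fixed class order.
#'
#' @param object An `ifc_classifier`.
#' @param table Feature table containing at least the model's features.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row of `table`.
#' @export
predict.ifc_classifier <- function(object, table, ...) {
  xm <- feature_matrix(table, object$feature_names)
  p <- switch(object$algorithm,
    gradient_boosting = predict(object$fit, xm),
    random_forest = predict(object$fit, xm, type = "prob"))
  if (!is.matrix(p)) {  # binary boosting: P(second fitted class)
    p <- matrix(c(1 - p, p), ncol = 2,
                dimnames = list(NULL, object$classes_fit))
  }
  # map onto the full fixed class order; argmax ties break by class order
  probs <- matrix(0, nrow(xm), length(object$class_order),
                  dimnames = list(NULL, object$class_order))
  probs[, colnames(p)] <- p
  object$class_order[apply(probs, 1, which.max)]
}

#' Score every cell outside the training set
#'
#' Emulates whole-population scoring: predicts each cell of `table` whose
#' id is not in the model's training set (exclusion is by id, so a cell
#' identical to a training cell under a different id is still scored).
#'
#' @param model An `ifc_classifier`.
#' @param table Feature table for the full population.
#' @return Tibble `cell_id, predicted`.
#' @export
score_all <- function(model, table) {
  stopifnot(inherits(model, "ifc_classifier"))
  test <- table[!(table$cell_id %in% model$training_ids), , drop = FALSE]
  tibble::tibble(cell_id = test$cell_id,
                 predicted = if (nrow(test)) predict(model, test) else character())
}

#' Row-normalised percentage confusion matrix and per-class TPR
#'
#' Entry `(i, j)` is `100 * |true = i & pred = j| / |true = i|`; the
#' diagonal is the per-class true-positive rate (correctly predicted
#' members of a class divided by its total). Classes with zero support
#' get `NA` rows and are excluded from macro averages.
#'
#' @param true_labels,predicted Equal-length label vectors.
#' @param class_order Fixed class order (default [phase_levels()]).
#' @param note Free-text description of the test set.
#' @return An object of class `ifc_evaluation` with elements `confusion`
#'   (percent matrix), `tpr`, `support`, `class_order`, `note`.
#' @export
confusion_matrix_pct <- function(true_labels, predicted,
                                 class_order = phase_levels(), note = "") {
  stopifnot(length(true_labels) == length(predicted))
  bad <- setdiff(c(true_labels, predicted), class_order)
  if (length(bad))
    stop("label(s) outside class order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(true_labels, levels = class_order)
  pf <- factor(predicted, levels = class_order)
  counts <- table(tf, pf)
  support <- as.integer(rowSums(counts))
  pct <- 100 * sweep(unclass(counts), 1, pmax(support, 1L), "/")
  pct[support == 0, ] <- NA_real_
  dimnames(pct) <- list(True = class_order, Predicted = class_order)
  structure(list(confusion = pct, tpr = diag(pct),
                 support = stats::setNames(support, class_order),
                 class_order = class_order, note = note),
            class = "ifc_evaluation")
}

#' @export
print.ifc_evaluation <- function(x, ...) {
  cat("<ifc_evaluation>", if (nzchar(x$note)) paste0(" (", x$note, ")"), "\n",
      sep = "")
  print(round(x$confusion, 2))
  g <- glance(x)
  cat("macro TPR: ", sprintf("%.2f%%", g$macro_tpr),
      "  accuracy: ", sprintf("%.2f%%", g$accuracy), "\n", sep = "")
  invisible(x)
}

#' @rdname confusion_matrix_pct
#' @param x An `ifc_evaluation`.
#' @param ... Unused.
#' @export
tidy.ifc_evaluation <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(df) <- c("true", "predicted", "pct")
  tibble::as_tibble(df) |>
    dplyr::mutate(n_true = x$support[.data$true]) |>
    dplyr::arrange(match(.data$true, x$class_order),
                   match(.data$predicted, x$class_order))
}

#' @rdname confusion_matrix_pct
#' @export
glance.ifc_evaluation <- function(x, ...) {
  pop <- x$support > 0
  acc <- sum(x$tpr[pop] * x$support[pop]) / sum(x$support[pop])
  tibble::tibble(macro_tpr = mean(x$tpr[pop]),
                 min_tpr = min(x$tpr[pop]),
                 accuracy = acc,
                 n = sum(x$support),
                 n_classes = sum(pop))
}

#' @rdname confusion_matrix_pct
#' @param object An `ifc_evaluation`.
#' @export
autoplot.ifc_evaluation <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(object$class_order))
  df$predicted <- factor(df$predicted, levels = object$class_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$pct), "", sprintf("%.1f", .data$pct))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 na.value = "grey90", limits = c(0, 100)) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' Stratified k-fold cross-validation of the training set
#'
#' Splits the training set into `k` stratified folds (a class with fewer
#' members than `k` contributes to as many folds as it has members), fits
#' the classifier on each training split and scores the held-out fold;
#' the confusion matrix aggregates all held-out predictions.
#'
#' @param ts An `ifc_training_set`.
#' @param table Filtered feature table.
#' @param algorithm,params Passed to [train_classifier()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and fold-model training.
#' @return An `ifc_evaluation` covering every training cell once.
#' @export
cross_validate <- function(ts, table,
                           algorithm = c("gradient_boosting", "random_forest"),
                           params = list(), k = 10, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ts, "ifc_training_set"), k >= 2)
  n <- length(ts$cell_ids)
  if (k > n) stop("k exceeds the number of training cells", call. = FALSE)
  fold <- withr::with_seed(seed, {
    f <- integer(n)
    for (cl in ts$class_order) {
      m <- which(ts$labels == cl)
      if (!length(m)) next
      # cycle fold ids over a shuffled class so each fold gets a near-equal
      # share; classes smaller than k land in distinct folds
      f[sample(m)] <- rep_len(sample(k), length(m))
    }
    f
  })
  preds <- character(n)
  for (j in sort(unique(fold))) {
    hold <- fold == j
    sub_ts <- ts
    sub_ts$cell_ids <- ts$cell_ids[!hold]
    sub_ts$labels <- ts$labels[!hold]
    model <- train_classifier(sub_ts, table, algorithm, params,
                              seed = seed + j)
    hold_tab <- table[match(ts$cell_ids[hold], table$cell_id), , drop = FALSE]
    preds[hold] <- predict(model, hold_tab)
  }
  confusion_matrix_pct(as.character(ts$labels), preds, ts$class_order,
                       note = sprintf("%d-fold CV, %s, n=%d", k, algorithm, n))
}

#' Rank features by model importance
#'
#' Importance scores are xgboost gain for gradient boosting and mean
#' decrease in Gini impurity for the random forest, sorted descending,
#' ties broken lexicographically by feature name.
#'
#' @param model An `ifc_classifier`.
#' @param k Ranking length (default 20; capped at the feature count).
#' @return A tibble `rank, feature, score` of class `ifc_ranking`.
#' @export
rank_features <- function(model, k = 20) {
  stopifnot(inherits(model, "ifc_classifier"))
  score <- switch(model$algorithm,
    gradient_boosting = {
      imp <- xgboost::xgb.importance(model = model$fit)
      s <- stats::setNames(rep(0, length(model$feature_names)),
                           model$feature_names)
      s[imp$Feature] <- imp$Gain
      s
    },
    random_forest = {
      imp <- randomForest::importance(model$fit)
      stats::setNames(imp[, "MeanDecreaseGini"], rownames(imp))
    })
  ord <- order(-score, names(score))
  out <- tibble::tibble(rank = seq_len(min(k, length(score))),
                        feature = names(score)[ord][seq_len(min(k, length(score)))],
                        score = unname(score[ord])[seq_len(min(k, length(score)))])
  class(out) <- c("ifc_ranking", class(out))
  out
}

#' @export
autoplot.ifc_ranking <- function(object, ...) {
  df <- as.data.frame(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Importance", y = NULL) +
    ggplot2::theme_minimal()
}
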