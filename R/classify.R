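#' Linear-SVM training configuration
#'
#' @param cost_grid candidate soft-margin costs (default
#'   `c(0.1, 0.5, 1, 5, 10)`).
#' @param cv_folds cross-validation folds (default 5).
#' @param fold_unit `"case"` (default; whole cases are held out together,
#'   preventing within-case leakage) or `"spot"`.
#' @param seed RNG seed controlling fold assignment.
#' @return An object of class `svm_config`. The kernel is fixed linear.
#' @export
svm_config <- function(cost_grid = c(0.1, 0.5, 1, 5, 10), cv_folds = 5,
                       fold_unit = c("case", "spot"), seed = 1L) {
  if (!length(cost_grid) || any(cost_grid <= 0))
    stop("cost_grid must be non-empty and > 0", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(kernel = "linear", cost_grid = sort(cost_grid),
                 cv_folds = as.integer(cv_folds),
                 fold_unit = match.arg(fold_unit), seed = as.integer(seed)),
            class = "svm_config")
}

#' Assign cases to study and validation sets
#'
#' Random case-level split (a case's spots are never separated): the
#' requested numbers of cases per class go to the study set, every
#' remaining case to validation.
#'
#' @param dataset a [profile_dataset()].
#' @param n_study_per_class named or ordered pair `c(LGP = , FA = )` of
#'   study-set sizes.
#' @param seed RNG seed.
#' @return The dataset with its partition filled in.
#' @export
split_dataset <- function(dataset, n_study_per_class, seed = 1L) {
  stopifnot(inherits(dataset, "profile_dataset"))
  meta <- dataset_meta(dataset)
  by_case <- meta[!duplicated(meta$case_id), c("case_id", "class_label")]
  if (is.null(names(n_study_per_class)))
    names(n_study_per_class) <- c("LGP", "FA")
  set.seed(as.integer(seed))
  partition <- stats::setNames(rep("validation", nrow(by_case)),
                               by_case$case_id)
  for (cl in names(n_study_per_class)) {
    ids <- by_case$case_id[by_case$class_label == cl]
    k <- n_study_per_class[[cl]]
    if (k > length(ids))
      stop(sprintf("class %s has %d cases, %d requested for the study set",
                   cl, length(ids), k), call. = FALSE)
    partition[sample(ids, k)] <- "study"
  }
  if (!any(partition == "validation"))
    warning("validation set is empty", call. = FALSE)
  dataset$partition <- partition
  dataset
}

# internal: stratified fold ids grouped by fold_unit
make_folds <- function(meta, k, fold_unit, seed) {
  set.seed(seed)
  fold <- integer(nrow(meta))
  if (fold_unit == "case") {
    by_case <- meta[!duplicated(meta$case_id), c("case_id", "class_label")]
    case_fold <- stats::setNames(integer(nrow(by_case)), by_case$case_id)
    for (cl in unique(by_case$class_label)) {
      ids <- sample(by_case$case_id[by_case$class_label == cl])
      case_fold[ids] <- rep_len(seq_len(k), length(ids))
    }
    fold <- unname(case_fold[meta$case_id])
  } else {
    for (cl in unique(meta$class_label)) {
      rows <- sample(which(meta$class_label == cl))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  }
  fold
}

#' Tune and train the linear SVM on the study set
#'
#' Features are standardized (zero mean, unit variance on the training
#' data; the parameters are stored and reused at prediction). For every
#' cost on the grid a stratified k-fold cross-validation grouped by
#' `fold_unit` is run; the tuned cost maximizes pooled spot-level CV
#' accuracy (ties break to the smaller cost, i.e. more regularization),
#' and the final model is refit on all study spots at that cost.
#'
#' @param pm a [peak_matrix()] restricted to study-set rows.
#' @param config an [svm_config()].
#' @return An object of class `svm_profile_model`: the fitted e1071 SVM,
#'   standardization parameters, `tuned_cost`, `cv_accuracy_by_cost`
#'   table and the training peak centres.
#' @export
tune_and_train <- function(pm, config = svm_config()) {
  stopifnot(inherits(pm, "peak_matrix"), inherits(config, "svm_config"))
  y <- factor(pm$meta$class_label)
  if (nlevels(y) < 2) stop("need at least 2 classes to train", call. = FALSE)
  x <- pm$values
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fold <- make_folds(pm$meta, config$cv_folds, config$fold_unit, config$seed)
  cv_acc <- vapply(config$cost_grid, function(cost) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      pred[!tr] <- stats::predict(fit, xs[!tr, , drop = FALSE])
    }
    mean(pred == y, na.rm = TRUE)
  }, numeric(1))
  tuned <- config$cost_grid[which.max(cv_acc)]  # grid sorted: tie -> smaller
  final <- e1071::svm(xs, y, kernel = "linear", cost = tuned, scale = FALSE)
  structure(list(svm = final, center = center, scale = scale,
                 tuned_cost = tuned,
                 cv_accuracy_by_cost = data.frame(cost = config$cost_grid,
                                                  cv_accuracy = cv_acc),
                 mz = pm$mz, levels = levels(y)),
            class = "svm_profile_model")
}

#' @export
print.svm_profile_model <- function(x, ...) {
  cat(sprintf("<svm_profile_model> linear kernel, tuned cost %g, %d features\n",
              x$tuned_cost, length(x$mz)))
  invisible(x)
}

#' Predict class calls for every spot
#'
#' @param model an [tune_and_train()] result.
#' @param pm a `peak_matrix` with exactly the training peak columns.
#' @return data.frame: case_id, spot_id, compartment, predicted (one call
#'   per row; no abstentions).
#' @export
predict_spots <- function(model, pm) {
  stopifnot(inherits(model, "svm_profile_model"), inherits(pm, "peak_matrix"))
  if (length(pm$mz) != length(model$mz) ||
      any(abs(pm$mz - model$mz) > 1e-8)) {
    missing <- setdiff(sprintf("%.4f", model$mz), sprintf("%.4f", pm$mz))
    extra <- setdiff(sprintf("%.4f", pm$mz), sprintf("%.4f", model$mz))
    stop(sprintf("peak columns do not match training columns (missing: %s; extra: %s)",
                 paste(missing, collapse = ","),
                 paste(extra, collapse = ",")), call. = FALSE)
  }
  xs <- sweep(sweep(pm$values, 2, model$center), 2, model$scale, "/")
  pred <- stats::predict(model$svm, xs)
  data.frame(case_id = pm$meta$case_id, spot_id = pm$meta$spot_id,
             compartment = pm$meta$compartment,
             predicted = as.character(pred), stringsAsFactors = FALSE)
}

#' Aggregate spot calls into case-level calls
#'
#' Each case receives the modal spot call; `consistency` is the fraction
#' of its spots agreeing with that call. An exact tie yields
#' `"indeterminate"` and is scored incorrect.
#'
#' @param spot_predictions data.frame from [predict_spots()].
#' @param truth optional named character vector of true classes by case.
#' @return data.frame of case calls: case_id, n_spots, final_call,
#'   consistency, and (when truth is given) truth and correct.
#' @export
aggregate_cases <- function(spot_predictions, truth = NULL) {
  sp <- split(spot_predictions$predicted, spot_predictions$case_id)
  sp <- sp[lengths(sp) > 0]
  rows <- lapply(names(sp), function(cs) {
    tab <- table(sp[[cs]])
    top <- tab[tab == max(tab)]
    final <- if (length(top) > 1) "indeterminate" else names(top)
    data.frame(case_id = cs, n_spots = length(sp[[cs]]), final_call = final,
               consistency = max(tab) / length(sp[[cs]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth)) {
    out$truth <- unname(truth[out$case_id])
    out$correct <- !is.na(out$truth) & out$final_call == out$truth
  }
  out
}

#' Evaluate case-level calls against truth
#'
#' @param case_calls data.frame from [aggregate_cases()].
#' @param truth optional named truth vector (required unless `case_calls`
#'   already carries `truth`/`correct` columns).
#' @return list: `overall_accuracy`, `per_class` data.frame (class,
#'   correct, total), `n_fully_consistent` (cases with consistency 1.0)
#'   and `n_cases`.
#' @export
evaluate_cases <- function(case_calls, truth = NULL) {
  if (!is.null(truth)) {
    case_calls$truth <- unname(truth[case_calls$case_id])
    case_calls$correct <- !is.na(case_calls$truth) &
      case_calls$final_call == case_calls$truth
  }
  if (is.null(case_calls$correct))
    stop("truth is required to evaluate case calls", call. = FALSE)
  per_class <- do.call(rbind, lapply(split(case_calls, case_calls$truth),
                                     function(d) data.frame(
                                       class = d$truth[1],
                                       correct = sum(d$correct),
                                       total = nrow(d))))
  rownames(per_class) <- NULL
  list(overall_accuracy = mean(case_calls$correct),
       per_class = per_class,
       n_fully_consistent = sum(case_calls$consistency == 1),
       n_cases = nrow(case_calls))
}
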