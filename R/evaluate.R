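# Evaluation: stratified splits, ROC/AUC/ACC, repeated within-cell
# evaluation, cross-cell transfer and |dAUC|.

#' Stratified train/test split
#'
#' The training fraction is applied within each class independently
#' (`floor(frac * n_class)` rows per class), so the class ratio is
#' preserved to within one row. Same seed, same split.
#'
#' @param fm a `feature_matrix` with both classes present, >= 3 rows each.
#' @param train_frac fraction of each class assigned to training
#'   (default 2/3).
#' @param seed integer seed.
#' @return list with `train` and `test` feature matrices (disjoint,
#'   exhaustive).
#' @export
split_stratified <- function(fm, train_frac = 2 / 3, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  for (cl in c(0L, 1L)) {
    if (sum(fm$label == cl) < 3) {
      stop("class ", cl, " has fewer than 3 rows")
    }
  }
  set.seed(seed)
  train_idx <- integer()
  for (cl in c(0L, 1L)) {
    idx <- which(fm$label == cl)
    n_train <- floor(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  subset_fm <- function(rows) {
    out <- fm[rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "feature_names") <- attr(fm, "feature_names")
    class(out) <- c("feature_matrix", "data.frame")
    out
  }
  list(train = subset_fm(sort(train_idx)),
       test = subset_fm(sort(setdiff(seq_len(nrow(fm)), train_idx))))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; the AUC equals the rank
#' statistic `P(score_pos > score_neg) + P(tie)/2` (ties counted half).
#'
#' @param scores real-valued scores, higher = more positive-like.
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `roc` (data.frame of `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  r <- rank(scores) # midranks: ties counted half in the rank statistic
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(y)[last_of_run] / n1
  fpr <- cumsum(1 - y)[last_of_run] / n0
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc = roc, auc = auc)
}

#' Classification accuracy at a score threshold
#'
#' @param scores real-valued scores (0-centered for all model kinds here).
#' @param labels 0/1 labels.
#' @param threshold scores above it predict class 1 (default 0).
#' @return fraction of rows classified correctly.
#' @export
accuracy <- function(scores, labels, threshold = 0) {
  mean(as.integer(scores > threshold) == as.integer(labels))
}

new_evaluation_result <- function(auc, acc, roc, train_cell, test_cell,
                                  feature_set, kind, seed) {
  structure(
    list(auc_per_rep = auc, acc_per_rep = acc,
         mean_auc = mean(auc), mean_acc = mean(acc), roc_points = roc,
         train_cell = train_cell, test_cell = test_cell,
         feature_set = feature_set, classifier = kind, seed = seed),
    class = "evaluation_result"
  )
}

#' Repeated split/fit/score evaluation within one cell
#'
#' Repeats the stratified split, fits the classifier on the training
#' portion and scores the held-out portion, recording AUC and ACC per
#' repetition and their means (10 repetitions by default). The ROC points
#' of the last repetition are kept for plotting. The master seed fans out
#' deterministically to the per-repetition splits and fits.
#'
#' @param fm a `feature_matrix`.
#' @param spec a [classifier_spec()].
#' @param reps number of repetitions (default 10).
#' @param seed master seed.
#' @param train_frac training fraction per class (default 2/3).
#' @param cell,feature_set provenance labels carried into the result.
#' @return object of class `evaluation_result`.
#' @export
evaluate_classifier <- function(fm, spec, reps = 10, seed = 1L,
                                train_frac = 2 / 3, cell = NA_character_,
                                feature_set = "all") {
  aucs <- numeric(reps); accs <- numeric(reps); roc <- NULL
  for (rep in seq_len(reps)) {
    rep_seed <- (seed + 7919L * (rep - 1L)) %% .Machine$integer.max
    sp <- split_stratified(fm, train_frac, seed = rep_seed)
    rep_spec <- classifier_spec(spec$kind, spec$hyper, seed = rep_seed)
    model <- fit_classifier(rep_spec, sp$train, train_cell = cell)
    sc <- score_classifier(model, sp$test)
    ra <- roc_auc(sc, sp$test$label)
    aucs[rep] <- ra$auc
    accs[rep] <- accuracy(sc, sp$test$label)
    roc <- ra$roc
  }
  new_evaluation_result(aucs, accs, roc, cell, cell, feature_set,
                        spec$kind, seed)
}

#' Apply a trained model to another cell's feature matrix
#'
#' No refitting: the training cell's standardization and parameters are
#' reused and the full other-cell matrix is scored (no split).
#'
#' @param model a `trained_model`.
#' @param fm_other the other cell's `feature_matrix` (identical feature
#'   set).
#' @param test_cell label of the tested cell.
#' @param feature_set provenance label.
#' @return an `evaluation_result` with a single repetition.
#' @export
cross_cell <- function(model, fm_other, test_cell = NA_character_,
                       feature_set = "all") {
  sc <- score_classifier(model, fm_other)
  ra <- roc_auc(sc, fm_other$label)
  new_evaluation_result(ra$auc, accuracy(sc, fm_other$label), ra$roc,
                        model$train_cell, test_cell, feature_set,
                        model$spec$kind, model$spec$seed)
}

#' Absolute AUC change between within-cell and cross-cell evaluation
#'
#' `|dAUC|`: the absolute difference of mean AUCs of two evaluations of the
#' same test cell, used to quantify how well a model transfers across cell
#' types (small = the feature/co-occupancy relationship is conserved).
#'
#' @param within,cross `evaluation_result`s sharing the test cell.
#' @return absolute difference of mean AUCs, in `[0, 1]`.
#' @export
delta_auc <- function(within, cross) {
  stopifnot(inherits(within, "evaluation_result"),
            inherits(cross, "evaluation_result"))
  same <- identical(within$test_cell, cross$test_cell) ||
    (is.na(within$test_cell) && is.na(cross$test_cell))
  if (!same) {
    stop("evaluations test different cells: ", within$test_cell, " vs ",
         cross$test_cell)
  }
  abs(within$mean_auc - cross$mean_auc)
}

#' Flatten evaluation results into a per-repetition table
#' @param results list of `evaluation_result`s (or a single one).
#' @return data.frame with one row per repetition.
#' @export
evaluation_table <- function(results) {
  if (inherits(results, "evaluation_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(train_cell = r$train_cell, test_cell = r$test_cell,
               feature_set = r$feature_set, classifier = r$classifier,
               rep = seq_along(r$auc_per_rep), auc = r$auc_per_rep,
               acc = r$acc_per_rep, seed = r$seed,
               stringsAsFactors = FALSE)
  }))
}
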