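# -- feature scaling, RBF-SVM training/prediction, stratified CV, grid search

#' Fit / apply a (-1, +1) min-max feature scaler
#'
#' The per-feature linear map sending the training minimum to -1 and the
#' training maximum to +1. Values outside the training range map outside
#' `[-1, 1]`; constant features map to 0.
#'
#' @param x numeric training matrix (>= 2 rows).
#' @return `fit_scaler()` returns an object of class `hgt_scaler`;
#'   `apply_scaler()` returns the transformed matrix.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "hgt_scaler")
}

#' @rdname fit_scaler
#' @param scaler an `hgt_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  stopifnot(inherits(scaler, "hgt_scaler"), ncol(x) == length(scaler$min))
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  out[, rng == 0] <- 0
  out
}

#' SVM model-selection configuration
#'
#' Defaults follow the canonical libsvm grid-search recommendation:
#' `c = 2^(-5), 2^(-3), ..., 2^15` and `g = 2^(-15), 2^(-13), ..., 2^3`,
#' evaluated by stratified 5-fold cross-validation on the training data.
#'
#' @param c_grid penalty values (> 0).
#' @param g_grid RBF widths (> 0).
#' @param inner_cv_folds folds for the (c, g) evaluation (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(c_grid = 2^seq(-5, 15, 2), g_grid = 2^seq(-15, 3, 2),
                       inner_cv_folds = 5, seed = 1) {
  stopifnot(length(c_grid) >= 1, length(g_grid) >= 1,
            all(c_grid > 0), all(g_grid > 0), inner_cv_folds >= 2)
  structure(list(c_grid = sort(c_grid), g_grid = sort(g_grid),
                 inner_cv_folds = as.integer(inner_cv_folds), seed = seed),
            class = "svm_config")
}

#' Stratified fold assignment
#'
#' Assigns each row to one of `n_folds` folds so that fold sizes differ by
#' at most one per class and every fold preserves the class ratio.
#'
#' @param label class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_stratified_folds <- function(label, n_folds = 5, seed = 1) {
  folds <- integer(length(label))
  with_seed(seed, {
    for (cl in unique(label)) {
      idx <- which(label == cl)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Train an RBF-SVM on a labelled feature matrix
#'
#' Fits the (-1, +1) scaler on the training rows only, restricts to the
#' masked features, and solves the soft-margin dual by sequential minimal
#' optimization. The positive class is `HGT`.
#'
#' @param x numeric feature matrix (training rows).
#' @param label labels (`HGT` / `NATIVE`), both classes present.
#' @param c penalty parameter (> 0).
#' @param g RBF width gamma (> 0).
#' @param mask logical or 0/1 vector over features; at least one selected.
#' @return An object of class `hgt_model`.
#' @export
train_svm <- function(x, label, c = 1, g = 1 / ncol(x), mask = NULL) {
  x <- as.matrix(x)
  if (is.null(mask)) mask <- rep(TRUE, ncol(x))
  mask <- as.logical(mask)
  if (!any(mask)) stop("feature mask selects no features")
  if (length(unique(label)) < 2) stop("training data contains a single class")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)[, mask, drop = FALSE]
  y <- ifelse(label == "HGT", 1, -1)
  fit <- smo_fit(xs, y, C = c, gamma = g)
  structure(list(scaler = scaler, mask = mask, c = c, g = g,
                 sv_x = fit$sv_x, coef = fit$coef, b = fit$b,
                 iterations = fit$iterations, n_sv = fit$n_sv),
            class = "hgt_model")
}

#' @export
print.hgt_model <- function(x, ...) {
  cat(sprintf("hgt_model: RBF-SVM, c=%g g=%g, %d features, %d SVs\n",
              x$c, x$g, sum(x$mask), x$n_sv))
  invisible(x)
}

#' Predict HGT/NATIVE labels
#'
#' @param object an `hgt_model` from [train_svm()].
#' @param newdata feature matrix on the original (unscaled) scale.
#' @param decision if TRUE return decision values instead of labels.
#' @param ... unused.
#' @return Character vector of labels (decision value > 0 -> `HGT`), or
#'   numeric decision values.
#' @export
predict.hgt_model <- function(object, newdata, decision = FALSE, ...) {
  xs <- apply_scaler(object$scaler, as.matrix(newdata))[, object$mask, drop = FALSE]
  dec <- rbf_decision(object$sv_x, object$coef, object$b, object$g, xs)
  if (decision) dec else ifelse(dec > 0, "HGT", "NATIVE")
}

#' Save / load a trained model
#' @param model an `hgt_model`.
#' @param path file path.
#' @return `hgt_read_model()` returns the model.
#' @export
hgt_save_model <- function(model, path) {
  stopifnot(inherits(model, "hgt_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname hgt_save_model
#' @export
hgt_read_model <- function(path) readRDS(path)

# stratified k-fold CV of the SVM at fixed (c, g, mask); scaler refitted
# inside each training split; optional SMOTE applied strictly within each
# training split (never before the fold split, which would leak synthetic
# points whose parents sit in the validation fold); macro-averaged metrics
cv_svm <- function(x, label, c, g, mask, n_folds, seed, smote_cfg = NULL) {
  folds <- make_stratified_folds(label, n_folds, seed)
  conf <- lapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]; ltr <- label[tr]
    if (!is.null(smote_cfg)) {
      sm <- smote_cfg
      sm$seed <- derive_seed(if (is.null(sm$seed)) 0 else sm$seed, f)
      ds <- smote(hgt_dataset(x = xtr, label = ltr), sm)
      xtr <- ds$x; ltr <- ds$label
    }
    model <- train_svm(xtr, ltr, c = c, g = g, mask = mask)
    pred <- predict(model, x[!tr, , drop = FALSE])
    confusion_from_labels(label[!tr], pred)
  })
  aggregate_folds(conf)
}

#' Grid search for the RBF-SVM parameters
#'
#' Evaluates every `(c, g)` point of the grid by stratified inner
#' cross-validation (fold assignment fixed across points) and returns the
#' point with the highest CV Recall; ties are broken by lower Mean error,
#' then smaller `c`, then smaller `g`, so the result does not depend on
#' grid order.
#'
#' @param x feature matrix. @param label class labels.
#' @param cfg an [svm_config()].
#' @param mask optional feature mask.
#' @param smote_cfg optional [smote_config()]: oversample each inner
#'   training split (validation folds stay imbalanced).
#' @return List with `best_c`, `best_g`, `recall_pct`, `mean_error_pct`
#'   and the full evaluation `table`.
#' @export
grid_search <- function(x, label, cfg = svm_config(), mask = NULL,
                        smote_cfg = NULL) {
  stopifnot(inherits(cfg, "svm_config"))
  if (length(unique(label)) < 2) stop("training data contains a single class")
  if (is.null(mask)) mask <- rep(TRUE, ncol(x))
  grid <- expand.grid(c = cfg$c_grid, g = cfg$g_grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ev <- cv_svm(x, label, grid$c[i], grid$g[i], mask,
                 cfg$inner_cv_folds, cfg$seed, smote_cfg)
    c(recall = ev$recall_pct, mean_error = ev$mean_error_pct)
  })
  tab <- cbind(grid, do.call(rbind, res))
  ord <- order(-tab$recall, tab$mean_error, tab$c, tab$g)
  best <- tab[ord[1], ]
  list(best_c = best$c, best_g = best$g, recall_pct = best$recall,
       mean_error_pct = best$mean_error, table = tab)
}
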