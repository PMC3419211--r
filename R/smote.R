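# -- SMOTE: synthetic minority oversampling by k-NN interpolation

#' SMOTE configuration
#'
#' @param k_neighbors number of nearest minority neighbors to interpolate
#'   towards (default 5, the original SMOTE setting).
#' @param target_ratio desired minority:majority ratio after oversampling
#'   (default 1, i.e. parity).
#' @param seed optional integer seed for reproducible interpolation.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1, seed = NULL) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = seed),
            class = "smote_config")
}

#' Oversample the minority class with SMOTE
#'
#' Each synthetic example is `x_new = x_i + u * (x_nn - x_i)` with `u`
#' uniform on `[0, 1]`, `x_i` a minority row and `x_nn` one of its
#' `k_neighbors` nearest minority neighbors (Euclidean distance computed
#' in the min-max-scaled feature space; interpolation is performed in the
#' original space, which is equivalent per coordinate). Parents are
#' cycled through the minority rows so the oversampling burden is spread
#' evenly; neighbor ties are broken by row index. Original rows pass
#' through bit-identical; synthetic rows carry `synthetic = TRUE` and ids
#' suffixed `_smoteN`.
#'
#' @param dataset an [hgt_dataset()] with both classes present.
#' @param cfg a [smote_config()].
#' @return An [hgt_dataset()] whose minority:majority ratio is at least
#'   `cfg$target_ratio`.
#' @export
smote <- function(dataset, cfg = smote_config()) {
  stopifnot(inherits(dataset, "hgt_dataset"), inherits(cfg, "smote_config"))
  tab <- table(factor(dataset$label, levels = c("HGT", "NATIVE")))
  if (any(tab == 0)) stop("both classes must be present")
  minority <- names(tab)[which.min(tab)]           # ties resolve to HGT
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min <= cfg$k_neighbors)
    stop("minority class has ", n_min, " rows <= k_neighbors = ",
         cfg$k_neighbors, "; use a smaller k")
  n_needed <- ceiling(n_maj * cfg$target_ratio) - n_min
  if (n_needed <= 0) return(dataset)

  min_idx <- which(dataset$label == minority)
  xm <- dataset$x[min_idx, , drop = FALSE]
  # neighbor search in the scaled space
  sc <- fit_scaler(dataset$x)
  xs <- apply_scaler(sc, xm)
  d2 <- as.matrix(stats::dist(xs))^2
  diag(d2) <- Inf
  # order() is stable, so distance ties resolve to the lower row index
  nn <- t(matrix(apply(d2, 1, function(r) order(r)[seq_len(cfg$k_neighbors)]),
                 nrow = cfg$k_neighbors))

  with_seed(cfg$seed, {
    parents <- rep_len(seq_len(nrow(xm)), n_needed)
    pick <- sample.int(cfg$k_neighbors, n_needed, replace = TRUE)
    u <- runif(n_needed)
    xnew <- xm[parents, , drop = FALSE] +
      u * (xm[nn[cbind(parents, pick)], , drop = FALSE] - xm[parents, , drop = FALSE])
    new_ids <- sprintf("%s_smote%d", dataset$ids[min_idx][parents],
                       seq_len(n_needed))
    rownames(xnew) <- NULL                  # originals pass through untouched
    hgt_dataset(x = rbind(dataset$x, xnew),
                ids = c(dataset$ids, new_ids),
                label = c(dataset$label, rep(minority, n_needed)),
                synthetic = c(dataset$synthetic, rep(TRUE, n_needed)))
  })
}
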