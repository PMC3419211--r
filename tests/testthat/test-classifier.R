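test_that("scaler maps training range to (-1, +1) with documented edge cases", {
  x <- cbind(a = c(2, 4), b = c(3, 3))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(xs[, "a"], c(-1, 1))
  expect_equal(xs[, "b"], c(0, 0))                  # constant column
  expect_equal(apply_scaler(fit_scaler(cbind(c(0, 10))), cbind(12))[1, 1], 1.4)
  # idempotence: rescaling already-scaled training data is the identity
  x2 <- make_planted(1, n = 30)$x
  xs2 <- apply_scaler(fit_scaler(x2), x2)
  expect_equal(apply_scaler(fit_scaler(xs2), xs2), xs2)
})

test_that("SMO solution matches an independent quadprog dual solver", {
  skip_if_not_installed("quadprog")
  d <- make_blobs(2, n_per = 15, d = 3, delta = 2.5)
  xs <- apply_scaler(fit_scaler(d$x), d$x)
  y <- ifelse(d$label == "HGT", 1, -1)
  C <- 4; gamma <- 0.5; n <- nrow(xs)
  K <- exp(-gamma * as.matrix(dist(xs))^2)
  Q <- (y %o% y) * K + diag(1e-10, n)
  sol <- quadprog::solve.QP(Dmat = Q, dvec = rep(1, n),
                            Amat = cbind(y, diag(n), -diag(n)),
                            bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  fnb <- as.vector(K %*% (a * y))
  free <- a > 1e-6 & a < C - 1e-6
  b <- mean((y - fnb)[free])
  dec_qp <- fnb + b

  m <- train_svm(d$x, d$label, c = C, g = gamma)
  dec_smo <- predict(m, d$x, decision = TRUE)
  expect_lt(max(abs(dec_qp - dec_smo)), 0.02)
  expect_equal(ifelse(dec_qp > 0, "HGT", "NATIVE"), predict(m, d$x))
})

test_that("separable classes are learned and memorized", {
  d <- make_blobs(3, n_per = 60)
  tr <- c(1:40, 61:100); te <- setdiff(1:120, tr)
  m <- train_svm(d$x[tr, ], d$label[tr], c = 8, g = 1 / 15)
  cc <- hgtident:::confusion_from_labels(d$label[te], predict(m, d$x[te, ]))
  expect_gte(recall_pct(cc), 99)
  expect_lte(mean_error_pct(cc), 1)

  over <- make_blobs(4, n_per = 25, delta = 1)     # overlapping classes
  mm <- train_svm(over$x, over$label, c = 1e6, g = 4)
  expect_equal(predict(mm, over$x), over$label)    # memorization at huge c
})

test_that("models validate inputs, round-trip, and ignore row order", {
  d <- make_blobs(5, n_per = 20)
  expect_error(train_svm(d$x, d$label, mask = rep(FALSE, 15)), "mask")
  expect_error(train_svm(d$x, rep("HGT", 40)), "single class")

  m <- train_svm(d$x, d$label, c = 2, g = 0.1)
  f <- withr::local_tempfile(fileext = ".rds")
  hgt_save_model(m, f)
  m2 <- hgt_read_model(f)
  expect_identical(predict(m2, d$x), predict(m, d$x))

  perm <- sample(nrow(d$x))
  expect_identical(predict(m, d$x[perm, ]), predict(m, d$x)[perm])
})

test_that("grid search maximizes inner-CV recall with canonical tie-breaks", {
  d <- make_blobs(6, n_per = 25)
  one <- svm_config(c_grid = 2, g_grid = 0.125, inner_cv_folds = 3, seed = 1)
  gs1 <- grid_search(d$x, d$label, one)
  expect_equal(c(gs1$best_c, gs1$best_g), c(2, 0.125))

  cfg <- small_svm_cfg(seed = 2, folds = 3)
  gs <- grid_search(d$x, d$label, cfg)
  expect_equal(gs$recall_pct, 100)                 # separable construction

  # grid order must not matter: reversed grids select the same point
  rev_cfg <- svm_config(c_grid = rev(cfg$c_grid), g_grid = rev(cfg$g_grid),
                        inner_cv_folds = 3, seed = 2)
  gs_rev <- grid_search(d$x, d$label, rev_cfg)
  expect_equal(c(gs_rev$best_c, gs_rev$best_g), c(gs$best_c, gs$best_g))
})

test_that("stratified folds partition rows and preserve class ratio", {
  lab <- c(rep("HGT", 15), rep("NATIVE", 85))
  f <- make_stratified_folds(lab, 5, seed = 9)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 20))
  expect_true(all(table(f[lab == "HGT"]) == 3))
  expect_identical(f, make_stratified_folds(lab, 5, seed = 9))
})
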