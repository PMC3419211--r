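# -- genetic-algorithm wrapper feature-subset selection over the 15 features

#' GA configuration
#'
#' Defaults follow the published protocol: 100 individuals per
#' generation, crossover probability 0.9, per-bit mutation probability
#' 0.1, 200 generations, with the best two individuals passed unchanged
#' to the next generation.
#'
#' @param pop_size population size (even, >= 4).
#' @param crossover_p single-point crossover probability.
#' @param mutation_p per-bit flip probability.
#' @param generations number of generations.
#' @param elitism number of top individuals copied unchanged.
#' @param seed integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, crossover_p = 0.9, mutation_p = 0.1,
                      generations = 200, elitism = 2, seed = 1) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0,
            crossover_p >= 0, crossover_p <= 1,
            mutation_p >= 0, mutation_p <= 1,
            generations >= 0, elitism >= 0, elitism < pop_size)
  structure(list(pop_size = as.integer(pop_size), crossover_p = crossover_p,
                 mutation_p = mutation_p, generations = as.integer(generations),
                 elitism = as.integer(elitism), seed = seed),
            class = "ga_config")
}

#' Evaluate one feature-subset chromosome
#'
#' Fitness is `10000 * Recall` (Recall as a fraction, so the maximum is
#' 10000), where Recall is the best stratified inner-CV Recall over the
#' `(c, g)` grid of `svm_cfg` for the SVM restricted to the chromosome's
#' features; the corresponding Mean error is recorded so the error at the
#' highest Recall is always reportable (and serves as the tie-break).
#' Evaluations are memoized by bit pattern in `cache`.
#'
#' @param bits 0/1 vector over the 15 features (at least one set).
#' @param x feature matrix. @param label class labels.
#' @param svm_cfg an [svm_config()].
#' @param cache optional environment used for memoization.
#' @return List with `bits`, `fitness`, `recall_pct`, `mean_error_pct`,
#'   `best_c`, `best_g`.
#' @export
evaluate_chromosome <- function(bits, x, label, svm_cfg, cache = NULL) {
  stopifnot(length(bits) == ncol(x), any(bits == 1))
  key <- paste(bits, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  gs <- grid_search(x, label, svm_cfg, mask = bits == 1)
  out <- list(bits = bits, fitness = 10000 * gs$recall_pct / 100,
              recall_pct = gs$recall_pct, mean_error_pct = gs$mean_error_pct,
              best_c = gs$best_c, best_g = gs$best_g)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# ranking used for elitism and the best-ever record: higher fitness, then
# lower mean error, then fewer selected features
chromosome_order <- function(evals) {
  order(-vapply(evals, `[[`, numeric(1), "fitness"),
        vapply(evals, `[[`, numeric(1), "mean_error_pct"),
        vapply(evals, function(e) sum(e$bits), numeric(1)))
}

#' Run GA feature-subset selection
#'
#' Binary chromosomes over the 15 features; fitness-proportional
#' (roulette) selection, single-point crossover, per-bit mutation, and
#' elitism. All-zero chromosomes are repaired by setting one random bit
#' before evaluation. The best-ever fitness trace is non-decreasing by
#' construction.
#'
#' @param x feature matrix. @param label class labels.
#' @param ga_cfg a [ga_config()]. @param svm_cfg an [svm_config()].
#' @return List with `best` (the best-ever evaluated chromosome), `trace`
#'   (best-ever fitness per generation, length `generations + 1`),
#'   `evaluations` (number of non-memoized evaluations) and
#'   `feature_names` of the selected subset.
#' @export
run_ga <- function(x, label, ga_cfg = ga_config(), svm_cfg = svm_config()) {
  stopifnot(inherits(ga_cfg, "ga_config"), inherits(svm_cfg, "svm_config"))
  nbits <- ncol(x)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_all <- function(pop) {
    lapply(seq_len(nrow(pop)), function(i) {
      key <- paste(pop[i, ], collapse = "")
      if (is.null(cache[[key]])) n_eval <<- n_eval + 1L
      evaluate_chromosome(pop[i, ], x, label, svm_cfg, cache)
    })
  }
  repair <- function(pop) {
    zero <- rowSums(pop) == 0
    for (i in which(zero)) pop[i, sample.int(nbits, 1)] <- 1L
    pop
  }

  with_seed(ga_cfg$seed, {
    pop <- matrix(rbinom(ga_cfg$pop_size * nbits, 1, 0.5),
                  ga_cfg$pop_size, nbits)
    pop <- repair(pop)
    evals <- eval_all(pop)
    best <- evals[[chromosome_order(evals)[1]]]
    trace <- best$fitness

    for (gen in seq_len(ga_cfg$generations)) {
      ord <- chromosome_order(evals)
      elite <- pop[ord[seq_len(ga_cfg$elitism)], , drop = FALSE]
      fit <- vapply(evals, `[[`, numeric(1), "fitness")
      prob <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / length(fit), length(fit))
      n_off <- ga_cfg$pop_size - ga_cfg$elitism
      off <- matrix(0L, n_off, nbits)
      i <- 1L
      while (i <= n_off) {
        pa <- pop[sample.int(nrow(pop), 1, prob = prob), ]
        pb <- pop[sample.int(nrow(pop), 1, prob = prob), ]
        if (runif(1) < ga_cfg$crossover_p && nbits >= 2) {
          cut <- sample.int(nbits - 1, 1)
          child1 <- c(pa[1:cut], pb[(cut + 1):nbits])
          child2 <- c(pb[1:cut], pa[(cut + 1):nbits])
        } else {
          child1 <- pa; child2 <- pb
        }
        off[i, ] <- child1
        if (i + 1L <= n_off) off[i + 1L, ] <- child2
        i <- i + 2L
      }
      flip <- matrix(runif(n_off * nbits) < ga_cfg$mutation_p, n_off, nbits)
      off <- abs(off - flip * 1L)
      pop <- rbind(elite, repair(off))
      evals <- eval_all(pop)
      cand <- evals[[chromosome_order(evals)[1]]]
      better <- cand$fitness > best$fitness ||
        (cand$fitness == best$fitness &&
           (cand$mean_error_pct < best$mean_error_pct ||
              (cand$mean_error_pct == best$mean_error_pct &&
                 sum(cand$bits) < sum(best$bits))))
      if (better) best <- cand
      trace <- c(trace, best$fitness)
    }
    list(best = best, trace = trace, evaluations = n_eval,
         feature_names = colnames(x)[best$bits == 1])
  })
}
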