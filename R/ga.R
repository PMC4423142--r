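#' Genetic-algorithm configuration for descriptor selection
#'
#' Hyperparameters of [ga_select()]. The population-size band 80-125
#' reflects the typical GA-PLS practice for descriptor pools of a few
#' hundred; sizes outside it are allowed but warned about. Initial
#' chromosomes switch each gene on with probability `init_p`, keeping early
#' models sparse.
#'
#' @param population_size chromosomes per generation (default 100).
#' @param generations number of generations (default 100).
#' @param p_crossover single-point crossover probability (default 0.9).
#' @param p_mutation per-gene mutation probability (default `1/pool size`,
#'   resolved at run time when `NULL`).
#' @param elitism number of best chromosomes copied unchanged (default 2).
#' @param tournament_size selection tournament size (default 2).
#' @param leave_n cross-validation hold-out block for the fitness (default
#'   1 = leave-one-out).
#' @param max_components PLS component ceiling; the per-chromosome count is
#'   chosen internally by LOO up to `min(max_components, n - 2)`.
#' @param init_p initial gene-on probability (default 0.1).
#' @param sparsity penalty subtracted per selected descriptor
#'   (default 0.005), implementing the preference for the smallest
#'   descriptor subsets among equally predictive ones.
#' @param seed integer RNG seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      p_crossover = 0.9, p_mutation = NULL, elitism = 2L,
                      tournament_size = 2L, leave_n = 1L,
                      max_components = 5L, init_p = 0.1,
                      sparsity = 0.005, seed = 1L) {
  if (population_size < 80L || population_size > 125L)
    warning("population size ", population_size,
            " is outside the usual 80-125 band")
  stopifnot(p_crossover >= 0, p_crossover <= 1,
            is.null(p_mutation) || (p_mutation >= 0 && p_mutation <= 1))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 leave_n = as.integer(leave_n),
                 max_components = as.integer(max_components),
                 init_p = init_p, sparsity = sparsity,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Fitness of one chromosome: best leave-n-out Q2 over component counts,
# minus the sparsity penalty. All-zero chromosomes are -Inf.
ga_fitness <- function(on, X, y, cfg, cache) {
  k <- sum(on)
  if (k == 0L) return(-Inf)
  key <- paste(which(on), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  Xs <- X[, on, drop = FALSE]
  n <- nrow(Xs)
  Amax <- min(cfg$max_components, n - 2L, k)
  press <- tryCatch(pls_loo_press(Xs, y, Amax, cfg$leave_n),
                    error = function(e) NULL)
  val <- if (is.null(press) || !length(press)) -Inf else {
    q2 <- 1 - min(press) / sum((y - mean(y))^2)
    q2 - cfg$sparsity * k
  }
  cache[[key]] <- val
  val
}

#' Genetic-algorithm descriptor selection with PLS fitness
#'
#' Seeded binary GA over descriptor-inclusion chromosomes: tournament
#' selection, single-point crossover, per-gene mutation and elitism. The
#' fitness of a chromosome is the leave-n-out Q2 of a PLS model on the
#' encoded descriptor subset (component count chosen internally by LOO)
#' minus a sparsity penalty per selected descriptor, so search pressure
#' favours small, predictive subsets. Elitism makes the best-ever fitness
#' non-decreasing across generations.
#'
#' @param X descriptor-pool matrix.
#' @param y activity vector.
#' @param config a [ga_config()].
#' @return object of class `gapls_fit`: `chromosome` (logical inclusion
#'   vector), `descriptors`, `fitness`, `q2_loo`, `model` (the refitted
#'   [pls_fit()] on the winning subset), `trace` (per-generation best
#'   fitness and gene count), `config`.
#' @export
ga_select <- function(X, y, config = ga_config()) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1L) stop("empty descriptor pool")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  cfg <- config
  if (is.null(cfg$p_mutation)) cfg$p_mutation <- 1 / p
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  cache <- new.env(parent = emptyenv())
  pop <- matrix(stats::runif(cfg$population_size * p) < cfg$init_p,
                cfg$population_size, p)
  fit <- vapply(seq_len(nrow(pop)), function(i) ga_fitness(pop[i, ], X, y, cfg, cache), 0)
  best_chrom <- pop[which.max(fit), ]
  best_fit <- max(fit)
  trace <- data.frame(generation = 0L, best_fitness = best_fit,
                      genes_on = sum(best_chrom))
  for (g in seq_len(cfg$generations)) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
    newpop <- pop[elite_idx, , drop = FALSE]
    while (nrow(newpop) < cfg$population_size) {
      pick <- function() {
        cand <- sample.int(cfg$population_size, cfg$tournament_size,
                           replace = TRUE)
        pop[cand[which.max(fit[cand])], ]
      }
      a <- pick(); b <- pick()
      if (stats::runif(1) < cfg$p_crossover && p >= 2L) {
        cut <- sample.int(p - 1L, 1L)
        child1 <- c(a[seq_len(cut)], b[(cut + 1L):p])
        child2 <- c(b[seq_len(cut)], a[(cut + 1L):p])
      } else {
        child1 <- a; child2 <- b
      }
      for (child in list(child1, child2)) {
        flip <- stats::runif(p) < cfg$p_mutation
        child <- xor(child, flip)
        newpop <- rbind(newpop, child)
        if (nrow(newpop) >= cfg$population_size) break
      }
    }
    pop <- newpop
    fit <- vapply(seq_len(nrow(pop)), function(i) ga_fitness(pop[i, ], X, y, cfg, cache), 0)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_chrom <- pop[which.max(fit), ]
    }
    trace <- rbind(trace, data.frame(generation = g, best_fitness = best_fit,
                                     genes_on = sum(best_chrom)))
  }
  sel <- which(best_chrom)
  Xs <- X[, sel, drop = FALSE]
  n <- nrow(Xs)
  Amax <- min(cfg$max_components, n - 2L, length(sel))
  press <- pls_loo_press(Xs, y, Amax, cfg$leave_n)
  A_best <- which.min(press)
  model <- pls_fit(Xs, y, A_best)
  structure(list(chromosome = best_chrom,
                 descriptors = colnames(X)[sel],
                 fitness = best_fit,
                 q2_loo = 1 - press[A_best] / sum((y - mean(y))^2),
                 model = model, trace = trace, config = cfg),
            class = "gapls_fit")
}

#' @export
print.gapls_fit <- function(x, ...) {
  cat("<gapls_fit>", length(x$descriptors), "descriptors selected,",
      "fitness", formatC(x$fitness, digits = 4, format = "g"),
      sprintf("(Q2_LOO = %.3f)\n", x$q2_loo))
  cat("  descriptors:", paste(x$descriptors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.gapls_fit <- function(object, newdata, ...)
  predict(object$model, newdata, ...)

#' @export
coef.gapls_fit <- function(object, ...) coef(object$model)
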