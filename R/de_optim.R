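## Differential evolution (rand/1/bin) used to find global starting values
## for the nonlinear mixture fits. Kept minimal and fully seeded: the result
## is only a warm start that a derivative-based least-squares step refines.

#' Differential-evolution global minimiser
#'
#' Classic rand/1/bin differential evolution over a box. The population is
#' evaluated in a vectorised sweep per generation; out-of-box mutants are
#' clipped to the bounds. Deterministic for a fixed seed.
#'
#' @param fn objective taking a parameter matrix (rows = candidates) and
#'   returning a numeric vector of objective values.
#' @param lower,upper numeric bound vectors of equal length (the search box).
#' @param popSize population size; default `10 * length(lower)`.
#' @param generations number of generations (default 300).
#' @param F differential weight (default 0.8).
#' @param CR crossover probability (default 0.9).
#' @param seed integer seed.
#' @return List with `par` (best parameters), `value`, and `trace` (best
#'   objective per generation).
#' @export
deOptim <- function(fn, lower, upper, popSize = NULL, generations = 300,
                    F = 0.8, CR = 0.9, seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  if (is.null(popSize)) popSize <- 10L * d
  popSize <- max(popSize, 4L)
  withSeed(seed, {
    pop <- matrix(stats::runif(popSize * d), popSize, d)
    pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
    val <- fn(pop)
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      r <- t(vapply(seq_len(popSize), function(i)
        sample(seq_len(popSize)[-i], 3L), integer(3)))
      mut <- pop[r[, 1], , drop = FALSE] +
        F * (pop[r[, 2], , drop = FALSE] - pop[r[, 3], , drop = FALSE])
      mut <- pmin(pmax(mut, matrix(lower, popSize, d, byrow = TRUE)),
                  matrix(upper, popSize, d, byrow = TRUE))
      cross <- matrix(stats::runif(popSize * d) < CR, popSize, d)
      forced <- cbind(seq_len(popSize),
                      sample.int(d, popSize, replace = TRUE))
      cross[forced] <- TRUE
      trial <- ifelse(cross, mut, pop)
      tval <- fn(trial)
      better <- tval < val
      pop[better, ] <- trial[better, , drop = FALSE]
      val[better] <- tval[better]
      trace[g] <- min(val)
    }
    best <- which.min(val)
    list(par = pop[best, ], value = val[best], trace = trace)
  })
}
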