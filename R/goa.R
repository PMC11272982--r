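#' Grasshopper-swarm optimizer configuration
#'
#' Parameters of the swarm search. The social coefficient `C` decays linearly
#' from `c_max` to `c_min` over the iterations, trading exploration for
#' exploitation; `g` and `u_wind` are kept small so the social interaction
#' dominates the movement.
#'
#' @param swarm_size number of grasshoppers N (default 30)
#' @param iterations number of iterations L (default 50)
#' @param c_max,c_min endpoints of the linear decay of the social coefficient
#'   (defaults 1.0 and 1e-4)
#' @param g gravity constant pulling toward the search-space center (0.01)
#' @param u_wind wind constant pulling toward the incumbent best (0.01)
#' @param center center of the search space `o`; defaults to the bounds
#'   midpoint
#' @param lower,upper per-dimension box bounds (defaults 0 and 1)
#' @param social `"linear"` for the simplified attraction
#'   `C * mean_j(x_j - x_i)`, or `"exponential"` for the original 2017 social
#'   kernel `s(d) = 0.5 exp(-d/1.5) - exp(-d)` applied pairwise
#' @param init_positions optional matrix of starting positions (rows =
#'   grasshoppers); random uniform in the bounds when omitted
#' @param seed integer seed (initialization only; the movement itself is
#'   deterministic)
#' @return an object of class `goa_config`
#' @export
goa_config <- function(swarm_size = 30, iterations = 50,
                       c_max = 1.0, c_min = 1e-4,
                       g = 0.01, u_wind = 0.01, center = NULL,
                       lower = 0, upper = 1,
                       social = c("linear", "exponential"),
                       init_positions = NULL, seed = 0) {
  social <- match.arg(social)
  stopifnot(swarm_size >= 2, iterations >= 1, c_max > c_min, c_min >= 0,
            lower < upper)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 c_max = c_max, c_min = c_min, g = g, u_wind = u_wind,
                 center = center, lower = lower, upper = upper,
                 social = social, init_positions = init_positions,
                 seed = as.integer(seed)),
            class = "goa_config")
}

#' Maximize an objective with a grasshopper swarm
#'
#' Positions live in a box (default the unit hypercube). Each iteration, every
#' grasshopper moves by the sum of a social component
#' `S_i = C * mean_j(x_j - x_i)`, a gravity component `G_i = -g (x_i - o)`
#' toward the center `o`, and a wind component `A_i = U (x_e - x_i)` toward
#' the incumbent best `x_e`; positions are clipped into the bounds, evaluated,
#' and the incumbent is updated when strictly better (so the best fitness is
#' non-decreasing). The initial population is also evaluated, so a swarm
#' seeded at the optimum reports it from iteration 0.
#'
#' @param objective function mapping a position vector to a finite real,
#'   maximized
#' @param dim dimensionality of the search space
#' @param cfg a [goa_config()]
#' @return list with `best_position`, `best_fitness`, and `trace` (incumbent
#'   best fitness after each iteration, length `iterations + 1` including the
#'   initial population)
#' @export
goa_optimize <- function(objective, dim, cfg = goa_config()) {
  N <- cfg$swarm_size
  L <- cfg$iterations
  o <- if (is.null(cfg$center)) rep((cfg$lower + cfg$upper) / 2, dim) else
    rep(cfg$center, length.out = dim)
  eval_or_die <- function(x) {
    f <- objective(x)
    if (!is.finite(f)) {
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 4), collapse = ", "), ")", call. = FALSE)
    }
    f
  }
  X <- if (!is.null(cfg$init_positions)) {
    stopifnot(ncol(cfg$init_positions) == dim)
    cfg$init_positions
  } else {
    with_local_seed(cfg$seed,
      matrix(stats::runif(N * dim, cfg$lower, cfg$upper), nrow = N))
  }
  N <- nrow(X)
  fit <- apply(X, 1, eval_or_die)
  best_i <- which.max(fit)
  best_pos <- X[best_i, ]
  best_fit <- fit[best_i]
  trace <- numeric(L + 1)
  trace[1] <- best_fit

  for (l in seq_len(L)) {
    C <- goa_coefficient(cfg, l)
    for (i in seq_len(N)) {
      xi <- X[i, ]
      if (cfg$social == "linear") {
        S <- C * (colMeans(X) - xi)
      } else {
        diffs <- sweep(X, 2, xi)               # x_j - x_i
        d <- sqrt(rowSums(diffs^2))
        s <- 0.5 * exp(-d / 1.5) - exp(-d)
        unit <- diffs / ifelse(d > 0, d, 1)
        S <- C * colSums(s * unit)
      }
      G <- -cfg$g * (xi - o)
      A <- cfg$u_wind * (best_pos - xi)
      xi <- pmin(pmax(xi + S + G + A, cfg$lower), cfg$upper)
      X[i, ] <- xi
      f <- eval_or_die(xi)
      if (f > best_fit) {
        best_fit <- f
        best_pos <- xi
      }
    }
    trace[l + 1] <- best_fit
  }
  list(best_position = best_pos, best_fitness = best_fit, trace = trace)
}

#' Social coefficient at a given iteration
#'
#' Linear decay from `c_max` (iteration 0) to `c_min` (the final iteration).
#' @param cfg a [goa_config()]
#' @param l iteration index in `0..iterations`
#' @return the coefficient C
#' @export
goa_coefficient <- function(cfg, l) {
  cfg$c_max - l * (cfg$c_max - cfg$c_min) / cfg$iterations
}

#' Map a continuous position to a feature subset
#'
#' A feature is selected when its coordinate exceeds the threshold; an empty
#' subset falls back to the single highest-coordinate feature so the wrapper
#' objective always has something to evaluate.
#'
#' @param position numeric vector in `[0, 1]^d`
#' @param threshold selection cut (default 0.5)
#' @return integer vector of selected feature indices
#' @export
binarize_position <- function(position, threshold = 0.5) {
  sel <- which(position > threshold)
  if (length(sel) == 0) sel <- which.max(position)
  sel
}
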