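#' Default search bounds for the inverse problem
#'
#' Brackets typical macromolecule-in-hydrogel transport values with about
#' two decades of margin on each side: `d_eff` in \[1e-12, 1e-8\] m^2/s and
#' `k` in \[1e-8, 1e-3\] m/s, both searched in log10 space; `c_eq` is
#' searched as the linear ratio `c_eq / c_initial` in \[0, 1\] (its natural
#' lower bound of zero rules out a log scale).
#'
#' @return Named list of `c(low, high)` pairs for `d_eff`, `k` and
#'   `c_eq_ratio`.
#' @export
default_bounds <- function() {
  list(d_eff = c(1e-12, 1e-8),
       k = c(1e-8, 1e-3),
       c_eq_ratio = c(0, 1))
}

#' Genetic-algorithm configuration
#'
#' A real-coded GA searching `d_eff` and `k` in log10 space (and the
#' `c_eq`/`c_initial` ratio linearly): tournament selection of size 3,
#' blend (BLX-alpha) crossover, Gaussian mutation, one elite individual.
#' With `polish = TRUE`, a Nelder-Mead simplex started at the GA optimum
#' refines the estimate to an objective tolerance of about 1e-15 relative,
#' which the GA alone cannot reach.
#'
#' @param population_size Individuals per generation (>= 10).
#' @param generations Number of generations.
#' @param crossover_rate Probability a selected pair is recombined.
#' @param mutation_rate Per-gene mutation probability.
#' @param bounds Named list of `c(low, high)` per parameter, as
#'   [default_bounds()]; `d_eff` and `k` bounds are on the original scale
#'   but searched in log10. Equal low and high pin a parameter to a point.
#' @param seed Integer seed; identical configuration and data give
#'   identical results.
#' @param polish Run the local simplex refinement after the GA.
#' @param tournament_size Selection tournament size.
#' @param mutation_sd Mutation standard deviation as a fraction of each
#'   gene's search range.
#' @param blx_alpha Blend-crossover expansion factor.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 60L, generations = 80L,
                      crossover_rate = 0.9, mutation_rate = 0.2,
                      bounds = default_bounds(), seed = 1L,
                      polish = TRUE, tournament_size = 3L,
                      mutation_sd = 0.15, blx_alpha = 0.5) {
  if (population_size < 10) {
    stop("`population_size` must be at least 10", call. = FALSE)
  }
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  for (r in c(crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1L] > b[2L]) {
      stop("bounds for `", nm, "` must be c(low, high) with low <= high",
           call. = FALSE)
    }
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 bounds = bounds, seed = as.integer(seed),
                 polish = isTRUE(polish),
                 tournament_size = as.integer(tournament_size),
                 mutation_sd = mutation_sd, blx_alpha = blx_alpha),
            class = "ga_config")
}

#' Misfit between an observed curve and the forward model
#'
#' Sum of squared differences between observed and modelled cumulative
#' release percentages at the observation times. Working on percentages
#' (not absolute mass) makes loadings comparable across conditions. A
#' forward-solver failure is penalised with a large finite value so the
#' optimiser can route around it.
#'
#' @param params A [transport_params()] candidate.
#' @param curve The observed [release_curve()].
#' @param geometry,disc,c_initial Forward-model inputs as in
#'   [solve_release()].
#' @return Non-negative misfit (percent^2).
#' @export
release_objective <- function(params, curve, geometry, disc, c_initial) {
  pct <- tryCatch(
    cn_release_percent(geometry, as_transport_params(params), c_initial,
                       disc, curve$times),
    error = function(e) {
      message("forward solve failed (", conditionMessage(e),
              "); penalising candidate")
      NULL
    })
  if (is.null(pct)) return(1e12)
  sum((curve$cumulative_percent - pct)^2)
}

# gene vector <-> transport_params; free d_eff/k live in log10 space,
# free c_eq as the linear ratio c_eq / c_initial.
decode_genes <- function(genes, free, fixed, c_initial) {
  vals <- fixed
  for (i in seq_along(free)) {
    nm <- free[i]
    vals[[nm]] <- switch(nm,
                         d_eff = 10^genes[i],
                         k = 10^genes[i],
                         c_eq = genes[i] * c_initial)
  }
  transport_params(vals$d_eff, vals$k, vals$c_eq)
}

gene_bounds <- function(free, bounds) {
  lo <- hi <- numeric(length(free))
  for (i in seq_along(free)) {
    nm <- free[i]
    b <- if (nm == "c_eq") bounds$c_eq_ratio else bounds[[nm]]
    if (is.null(b)) stop("no bounds supplied for `", nm, "`", call. = FALSE)
    if (nm %in% c("d_eff", "k")) {
      if (b[1L] <= 0) stop("log10 bounds for `", nm, "` must be positive",
                           call. = FALSE)
      b <- log10(b)
    }
    lo[i] <- b[1L]; hi[i] <- b[2L]
  }
  list(lo = lo, hi = hi)
}

#' Estimate transport parameters from a release curve
#'
#' Solves the inverse problem: finds the transport parameters whose forward
#' simulation best matches an observed cumulative release curve, by a
#' seeded real-coded genetic algorithm followed (optionally) by Nelder-Mead
#' simplex refinement of the GA optimum. The objective is
#' [release_objective()].
#'
#' @param curve Observed [release_curve()] with at least 4 time points.
#' @param geometry,disc,c_initial Forward-model inputs.
#' @param free_params Character subset of `c("d_eff", "k", "c_eq")` to
#'   estimate; the remainder are fixed at the values in `fixed`.
#' @param fixed A [transport_params()] (or list) providing values for the
#'   parameters not being estimated (and starting metadata for those that
#'   are; their `fixed` values are ignored).
#' @param config A [ga_config()].
#' @return An object of class `fit_result`: list with `params` (a
#'   [transport_params()]), `sse`, `r_squared`, `n_evaluations`,
#'   `converged`, `seed` and `history` (best objective per generation,
#'   non-increasing).
#' @examples
#' \donttest{
#' geom <- hydrogel_geometry(); dis <- discretization()
#' truth <- transport_params(1.40e-9, 1.190e-5, 0)
#' obs <- solve_release(geom, truth, 1, dis, c(0.5, 1, 2, 4, 6, 8, 24, 48))
#' fit <- estimate_transport(obs$curve, geom, dis, 1,
#'                           fixed = truth,
#'                           config = ga_config(population_size = 20,
#'                                              generations = 15, seed = 7))
#' fit$params
#' }
#' @export
estimate_transport <- function(curve, geometry, disc, c_initial,
                               free_params = c("d_eff", "k"),
                               fixed = transport_params(1e-9, 1e-5, 0),
                               config = ga_config()) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(curve$times) < 4L) {
    stop("`curve` must have at least 4 time points", call. = FALSE)
  }
  free_params <- match.arg(free_params, c("d_eff", "k", "c_eq"),
                           several.ok = TRUE)
  fixed <- as_transport_params(fixed)
  gb <- gene_bounds(free_params, config$bounds)
  d <- length(free_params)
  n_eval <- 0L

  obj_genes <- function(g) {
    out_of_bounds <- g < gb$lo - 1e-12 | g > gb$hi + 1e-12
    if (any(out_of_bounds)) {
      return(1e12 * (1 + sum(pmax(gb$lo - g, 0) + pmax(g - gb$hi, 0))))
    }
    n_eval <<- n_eval + 1L
    release_objective(decode_genes(g, free_params, fixed, c_initial),
                      curve, geometry, disc, c_initial)
  }

  # seeded, with the caller's RNG state restored on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)

  np <- config$population_size
  range_ <- gb$hi - gb$lo
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2L, range_, `*`), 2L, gb$lo, `+`)
  fit <- apply(pop, 1L, obj_genes)
  history <- numeric(config$generations)

  clip <- function(g) pmin(pmax(g, gb$lo), gb$hi)
  tournament <- function() {
    idx <- sample.int(np, config$tournament_size)
    idx[which.min(fit[idx])]
  }

  if (all(range_ == 0)) {
    # bounds collapsed to a single point: nothing to search
    best_g <- gb$lo
    best_f <- obj_genes(best_g)
    history <- rep(best_f, config$generations)
  } else {
    for (gen in seq_len(config$generations)) {
      new_pop <- matrix(0, np, d)
      elite <- which.min(fit)
      new_pop[1L, ] <- pop[elite, ]
      i <- 2L
      while (i <= np) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        if (stats::runif(1) < config$crossover_rate) {
          lo_g <- pmin(p1, p2); hi_g <- pmax(p1, p2)
          span <- hi_g - lo_g
          c1 <- stats::runif(d, lo_g - config$blx_alpha * span,
                             hi_g + config$blx_alpha * span)
          c2 <- stats::runif(d, lo_g - config$blx_alpha * span,
                             hi_g + config$blx_alpha * span)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i > np) break
          mut <- stats::runif(d) < config$mutation_rate
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, config$mutation_sd * range_[mut])
          new_pop[i, ] <- clip(child)
          i <- i + 1L
        }
      }
      pop <- new_pop
      new_fit <- apply(pop, 1L, obj_genes)
      # elitism: the carried-over elite guarantees monotone improvement
      fit <- new_fit
      history[gen] <- min(fit)
    }
    best_g <- pop[which.min(fit), ]
    best_f <- min(fit)
  }

  converged <- FALSE
  if (config$polish && any(range_ > 0)) {
    if (d == 1L) {
      op <- stats::optim(best_g, obj_genes, method = "Brent",
                         lower = gb$lo, upper = gb$hi,
                         control = list(reltol = 1e-15))
    } else {
      op <- stats::optim(best_g, obj_genes, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 2000))
    }
    if (op$value <= best_f) {
      best_g <- clip(op$par)
      best_f <- obj_genes(best_g)
    }
    converged <- op$convergence == 0
  }

  params <- decode_genes(best_g, free_params, fixed, c_initial)
  sim <- solve_release(geometry, params, c_initial, disc, curve$times)
  r2 <- tryCatch(
    r_squared(curve$cumulative_percent, sim$curve$cumulative_percent),
    error = function(e) NA_real_)
  structure(list(params = params, sse = best_f, r_squared = r2,
                 n_evaluations = n_eval, converged = converged,
                 seed = config$seed, history = history,
                 free_params = free_params),
            class = "fit_result")
}

#' One-dimensional objective profile (identifiability diagnostic)
#'
#' Evaluates [release_objective()] along a grid of one parameter with the
#' others held at their estimates. A nearly flat profile flags a weakly
#' identified direction: at high Biot number (`k L / d_eff >> 1`) the
#' release curve barely responds to `k`, so its profile is flat and the
#' data cannot pin it down. Flatness is measured as the objective range
#' per observation point (percent^2); below `flatness_threshold` a warning
#' is emitted.
#'
#' @param curve Observed [release_curve()].
#' @param geometry,disc,c_initial Forward-model inputs.
#' @param param_name One of `"d_eff"`, `"k"`, `"c_eq"`.
#' @param grid Parameter values to scan (original scale).
#' @param at A [transport_params()] holding the other parameters.
#' @param flatness_threshold Objective-range-per-point below which the
#'   direction is declared weakly identified (default 0.5 percent^2: an
#'   RMS curve response under ~0.7 percentage points per observation over
#'   the grid, smaller than typical replicate scatter).
#' @return A data.frame with columns `value` and `objective`.
#' @export
profile_objective <- function(curve, geometry, disc, c_initial,
                              param_name = c("d_eff", "k", "c_eq"),
                              grid, at, flatness_threshold = 0.5) {
  param_name <- match.arg(param_name)
  at <- as_transport_params(at)
  obj <- vapply(grid, function(v) {
    vals <- at
    vals[[param_name]] <- v
    release_objective(transport_params(vals$d_eff, vals$k, vals$c_eq),
                      curve, geometry, disc, c_initial)
  }, numeric(1))
  variation <- (max(obj) - min(obj)) / length(curve$times)
  if (variation < flatness_threshold) {
    warning(sprintf(
      "`%s` is weakly identified: objective range over the grid is %.3g ",
      param_name, variation),
      "percent^2 per observation point", call. = FALSE)
  }
  data.frame(value = grid, objective = obj)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> d_eff = %.4g m^2/s, k = %.4g m/s, c_eq = %.4g\n  sse = %.4g, R^2 = %.4f, %d evaluations, seed %d%s\n",
    x$params$d_eff, x$params$k, x$params$c_eq, x$sse, x$r_squared,
    x$n_evaluations, x$seed,
    if (x$converged) ", converged" else ""))
  invisible(x)
}
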