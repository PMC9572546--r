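#' Bayesian optimization over a box-bounded parameter space
#'
#' Sequential model-based maximization: a maximin Latin-hypercube initial
#' design, then a Gaussian-process surrogate (RBF kernel on the unit cube,
#' [kernlab::gausspr()] with a predictive-variance model) proposing the next
#' point by expected improvement over a random candidate set. Integer and
#' log-scaled parameters are handled by the parameter definitions.
#' Deterministic given the seed.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar to maximize.
#' @param bounds List of parameter definitions, each a list with `name`,
#'   `type` (`"real"`, `"int"`, `"log"`) and `lower`, `upper`.
#' @param budget Total number of objective evaluations (>= `n_init`).
#' @param n_init Size of the initial Latin-hypercube design; default
#'   `max(5, 2 * d)`.
#' @param n_candidates Random candidate points scored by EI per iteration.
#' @param seed Integer seed.
#' @return List with `best_par` (named list), `best_value`, and `trace`
#'   (data frame of iteration, parameters, objective).
#' @export
bayes_optimize <- function(objective, bounds, budget = 50,
                           n_init = max(5L, 2L * length(bounds)),
                           n_candidates = 500L, seed = 1) {
  d <- length(bounds)
  stopifnot(d >= 1)
  if (budget < n_init) {
    stop("budget must cover at least the initial design (", n_init, " points)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  unit_to_par <- function(u) {
    stats::setNames(lapply(seq_len(d), function(j) {
      b <- bounds[[j]]
      v <- switch(b$type,
        real = b$lower + u[j] * (b$upper - b$lower),
        log = exp(log(b$lower) + u[j] * (log(b$upper) - log(b$lower))),
        int = as.integer(round(b$lower + u[j] * (b$upper - b$lower))),
        stop("unknown parameter type: ", b$type, call. = FALSE))
      v
    }), vapply(bounds, `[[`, character(1), "name"))
  }

  U <- lhs::maximinLHS(n_init, d)
  vals <- apply(U, 1, function(u) objective(unit_to_par(u)))

  while (nrow(U) < budget) {
    cand <- matrix(stats::runif(n_candidates * d), ncol = d)
    ei <- tryCatch({
      y <- as.vector(scale(vals))
      if (!all(is.finite(y))) y <- rep(0, length(vals))
      gp <- kernlab::gausspr(U, y, kernel = "rbfdot",
                             kpar = list(sigma = 1), var = 0.01,
                             variance.model = TRUE, scaled = FALSE)
      mu <- kernlab::predict(gp, cand)
      sdev <- pmax(kernlab::predict(gp, cand, type = "sdeviation"), 1e-9)
      best <- max(y)
      z <- (mu - best) / sdev
      (mu - best) * stats::pnorm(z) + sdev * stats::dnorm(z)
    }, error = function(e) stats::runif(n_candidates))
    u_next <- cand[which.max(ei), ]
    # avoid re-evaluating an already-visited point (possible after integer
    # rounding): nudge to the best unseen candidate
    seen <- apply(U, 1, function(r) all(abs(r - u_next) < 1e-12))
    if (any(seen)) u_next <- cand[order(ei, decreasing = TRUE)[2], ]
    U <- rbind(U, u_next)
    vals <- c(vals, objective(unit_to_par(u_next)))
  }

  pars <- lapply(seq_len(nrow(U)), function(i) unit_to_par(U[i, ]))
  trace <- cbind(data.frame(iteration = seq_along(vals)),
                 do.call(rbind, lapply(pars, as.data.frame)),
                 objective = vals)
  best <- which.max(vals)
  list(best_par = pars[[best]], best_value = vals[best], trace = trace)
}
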