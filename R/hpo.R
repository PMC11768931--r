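# Gaussian-process Bayesian hyperparameter optimization with expected
# improvement: Matern-5/2 surrogate over normalized parameters, seeded
# candidate sets (Latin hypercube for continuous dimensions, enumeration for
# choices).

#' Define a log-scaled continuous search dimension
#' @param name Parameter name.
#' @param low,high Finite bounds, `0 < low < high`.
#' @return A search-dimension definition.
#' @export
param_log <- function(name, low, high) {
  check_field(is_scalar_num(low) && is_scalar_num(high) && 0 < low && low < high,
              name, "log-scale bounds must satisfy 0 < low < high")
  list(name = name, type = "log", low = low, high = high)
}

#' Define a linear continuous search dimension
#' @inheritParams param_log
#' @export
param_lin <- function(name, low, high) {
  check_field(is_scalar_num(low) && is_scalar_num(high) && low < high,
              name, "bounds must be finite with low < high")
  list(name = name, type = "lin", low = low, high = high)
}

#' Define an ordered discrete-choice search dimension
#' @param name Parameter name.
#' @param choices Ordered vector of allowed values.
#' @return A search-dimension definition.
#' @export
param_choice <- function(name, choices) {
  check_field(length(choices) >= 1, name, "needs at least one choice")
  list(name = name, type = "choice", choices = choices)
}

#' Assemble a hyperparameter search space
#' @param ... Dimensions from [param_log()], [param_lin()], [param_choice()].
#' @return A `search_space` object.
#' @export
search_space <- function(...) {
  dims <- list(...)
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(dims, class = "search_space")
}

#' The default space: learning rate, dropout, kernel size
#'
#' Learning rate log-uniform on `[1e-4, 1e-2]`, dropout uniform on
#' `[0, 0.5]`, kernel size from the odd choices `{3, 5, 7, 9}`.
#' @return A `search_space`.
#' @export
default_search_space <- function() {
  search_space(
    param_log("learning_rate", 1e-4, 1e-2),
    param_lin("dropout_p", 0, 0.5),
    param_choice("kernel_size", c(3, 5, 7, 9))
  )
}

# Unit-cube encoding: log10 for log dims, linear rescale for lin dims,
# index scale for choices.
encode_params <- function(space, params) {
  vapply(space, function(d) {
    v <- params[[d$name]]
    switch(d$type,
      log = (log10(v) - log10(d$low)) / (log10(d$high) - log10(d$low)),
      lin = (v - d$low) / (d$high - d$low),
      choice = {
        i <- match(v, d$choices)
        if (length(d$choices) == 1) 0.5 else (i - 1) / (length(d$choices) - 1)
      })
  }, numeric(1))
}

decode_unit <- function(space, u) {
  out <- purrr::imap(unclass(space), function(d, nm) {
    x <- u[[match(nm, names(space))]]
    switch(d$type,
      log = 10^(log10(d$low) + x * (log10(d$high) - log10(d$low))),
      lin = d$low + x * (d$high - d$low),
      choice = d$choices[[pmin(length(d$choices),
                               pmax(1, round(x * (length(d$choices) - 1)) + 1))]])
  })
  names(out) <- names(space)
  out
}

#' Draw quasi-random points from a search space
#' @param space A `search_space`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return Tibble of parameter settings, one row per point.
#' @export
sample_space <- function(space, n, seed = 1L) {
  u <- withr::with_seed(as.integer(seed), lhs::randomLHS(n, length(space)))
  dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    as_tibble(decode_unit(space, u[i, ]))
  }))
}

#' Expected improvement acquisition
#'
#' For maximization: `EI = (mu - best) * pnorm(z) + sigma * dnorm(z)` with
#' `z = (mu - best)/sigma` when `sigma > 0`, and `max(mu - best, 0)` at
#' `sigma = 0`. Always non-negative and non-decreasing in `mu`.
#'
#' @param mu Posterior mean(s).
#' @param sigma Posterior standard deviation(s), `>= 0`.
#' @param best_so_far Incumbent objective value.
#' @return Expected improvement, vectorized over `mu`/`sigma`.
#' @export
expected_improvement <- function(mu, sigma, best_so_far) {
  if (any(sigma < 0)) {
    abort("invalid `sigma`: must be >= 0", class = "tembo_validation_error")
  }
  d <- mu - best_so_far
  out <- pmax(d, 0)
  pos <- sigma > 0
  z <- d[pos] / sigma[pos]
  out[pos] <- d[pos] * pnorm(z) + sigma[pos] * dnorm(z)
  pmax(out, 0)
}

# ---- Matern-5/2 GP ---------------------------------------------------------

matern52 <- function(X1, X2, ls) {
  d2 <- outer(rowSums(sweep(X1, 2, ls, "/")^2), rowSums(sweep(X2, 2, ls, "/")^2), "+") -
    2 * tcrossprod(sweep(X1, 2, ls, "/"), sweep(X2, 2, ls, "/"))
  r <- sqrt(pmax(d2, 0))
  (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

gp_fit <- function(X, y) {
  n <- nrow(X)
  d <- ncol(X)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  nll <- function(theta) {
    ls <- exp(theta[seq_len(d)])
    s2 <- exp(theta[d + 1])
    noise <- exp(theta[d + 2])
    K <- s2 * matern52(X, X, ls) + diag(noise + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
  }
  init <- c(rep(log(0.3), d), log(1), log(1e-2))
  opt <- tryCatch(
    optim(init, nll, method = "L-BFGS-B",
          lower = c(rep(log(0.03), d), log(1e-3), log(1e-6)),
          upper = c(rep(log(10), d), log(1e2), log(1))),
    error = function(e) list(par = init)
  )
  ls <- exp(opt$par[seq_len(d)])
  s2 <- exp(opt$par[d + 1])
  noise <- exp(opt$par[d + 2])
  K <- s2 * matern52(X, X, ls) + diag(noise + 1e-8, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, ls = ls, s2 = s2, noise = noise,
       y_mean = y_mean, y_sd = y_sd)
}

gp_predict <- function(fit, Xs) {
  ks <- fit$s2 * matern52(fit$X, Xs, fit$ls)
  mu <- drop(crossprod(ks, fit$alpha)) * fit$y_sd + fit$y_mean
  v <- forwardsolve(t(fit$L), ks)
  var <- pmax(fit$s2 - colSums(v^2), 0)
  list(mu = mu, sigma = sqrt(var) * fit$y_sd)
}

# ---- suggestion loop -------------------------------------------------------

completed_trials <- function(history) {
  if (is.null(history) || nrow(history) == 0) return(history[0, ])
  history[history$status == "completed" & is.finite(history$objective_value), ]
}

#' Suggest the next hyperparameter setting
#'
#' With fewer than `n_init` completed trials, returns a quasi-random draw.
#' Otherwise fits a Matern-5/2 Gaussian process (constant mean, fitted
#' length scales, observation-noise jitter) on normalized parameters versus
#' objective and maximizes expected improvement over a seeded candidate set
#' (Latin hypercube over continuous dimensions crossed with enumerated
#' choices). Deterministic given `(history, seed)`. If every trial failed,
#' falls back to a random draw.
#'
#' @param history Trials tibble (columns: the parameter names,
#'   `objective_value`, `status`), possibly empty or `NULL`.
#' @param space A `search_space`.
#' @param seed Integer seed.
#' @param n_init Completed trials required before the surrogate engages.
#' @param n_candidates Continuous candidate count per choice combination.
#' @return Named list of parameter values inside the space.
#' @export
suggest <- function(history, space, seed = 1L, n_init = 5, n_candidates = 256) {
  done <- completed_trials(history)
  n_hist <- if (is.null(history)) 0L else nrow(history)
  if (is.null(done) || nrow(done) < n_init) {
    u <- withr::with_seed(sub_seed(seed, n_hist),
                          as.vector(lhs::randomLHS(1, length(space))))
    return(decode_unit(space, u))
  }
  X <- do.call(rbind, lapply(seq_len(nrow(done)), function(i) {
    encode_params(space, as.list(done[i, names(space)]))
  }))
  y <- done$objective_value
  fit <- gp_fit(X, y)
  cont <- names(space)[vapply(space, function(d) d$type != "choice", logical(1))]
  choice_dims <- names(space)[vapply(space, function(d) d$type == "choice", logical(1))]
  base <- withr::with_seed(sub_seed(seed, n_hist + 7L),
                           lhs::randomLHS(n_candidates, max(1, length(cont))))
  choice_grid <- if (length(choice_dims) == 0) {
    matrix(numeric(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(lapply(choice_dims, function(nm) {
      k <- length(space[[nm]]$choices)
      if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1)
    })))
  }
  cands <- do.call(rbind, lapply(seq_len(nrow(choice_grid)), function(j) {
    m <- matrix(0, n_candidates, length(space),
                dimnames = list(NULL, names(space)))
    if (length(cont) > 0) m[, cont] <- base[, seq_along(cont)]
    if (length(choice_dims) > 0) {
      m[, choice_dims] <- matrix(choice_grid[j, ], n_candidates,
                                 length(choice_dims), byrow = TRUE)
    }
    m
  }))
  pr <- gp_predict(fit, cands)
  ei <- expected_improvement(pr$mu, pr$sigma, max(y))
  decode_unit(space, cands[which.max(ei), ])
}

#' Run Bayesian hyperparameter optimization
#'
#' `n_init` quasi-random evaluations followed by `n_iter` GP-EI suggestions.
#' Failed evaluations (errors in `objective_fn`) are recorded as failed
#' trials, not fatal.
#'
#' @param objective_fn Function taking a named parameter list, returning a
#'   bounded score to maximize (e.g. validation accuracy).
#' @param space A `search_space`.
#' @param n_init Random initial evaluations (>= 2).
#' @param n_iter Surrogate-guided evaluations (>= 0).
#' @param seed Integer seed.
#' @return A `tembo_hpo`: list with `best_params`, `best_value`, and the
#'   `trials` tibble.
#' @export
run_hpo <- function(objective_fn, space, n_init = 5, n_iter = 15, seed = 1L) {
  check_field(n_init >= 2, "n_init", "must be >= 2")
  check_field(n_iter >= 0, "n_iter", "must be >= 0")
  trials <- NULL
  for (i in seq_len(n_init + n_iter)) {
    params <- suggest(trials, space, seed = seed, n_init = n_init)
    val <- tryCatch(as.numeric(objective_fn(params)), error = function(e) NA_real_)
    row <- as_tibble(params)
    row$objective_value <- val
    row$status <- if (is.finite(val)) "completed" else "failed"
    trials <- dplyr::bind_rows(trials, row)
  }
  done <- completed_trials(trials)
  if (nrow(done) == 0) {
    abort(sprintf("all %d trials failed", nrow(trials)),
          class = "tembo_hpo_error")
  }
  best <- done[which.max(done$objective_value), ]
  structure(list(
    best_params = as.list(best[names(space)]),
    best_value = best$objective_value,
    trials = trials
  ), class = "tembo_hpo")
}

#' Pure random search (comparison baseline)
#'
#' @inheritParams run_hpo
#' @param n Evaluation budget.
#' @return A `tembo_hpo` with the same structure as [run_hpo()].
#' @export
random_search <- function(objective_fn, space, n, seed = 1L) {
  pts <- sample_space(space, n, seed = seed)
  trials <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    params <- as.list(pts[i, ])
    val <- tryCatch(as.numeric(objective_fn(params)), error = function(e) NA_real_)
    row <- as_tibble(params)
    row$objective_value <- val
    row$status <- if (is.finite(val)) "completed" else "failed"
    row
  }))
  done <- completed_trials(trials)
  if (nrow(done) == 0) {
    abort("all random-search trials failed", class = "tembo_hpo_error")
  }
  best <- done[which.max(done$objective_value), ]
  structure(list(best_params = as.list(best[names(space)]),
                 best_value = best$objective_value, trials = trials),
            class = "tembo_hpo")
}

#' @export
print.tembo_hpo <- function(x, ...) {
  cat(sprintf("<tembo_hpo> %d trials, best objective %.4f\n",
              nrow(x$trials), x$best_value))
  invisible(x)
}

#' @export
tidy.tembo_hpo <- function(x, ...) x$trials

#' @export
glance.tembo_hpo <- function(x, ...) {
  tibble(n_trials = nrow(x$trials),
         n_failed = sum(x$trials$status == "failed"),
         best_value = x$best_value)
}

#' @export
autoplot.tembo_hpo <- function(object, ...) {
  df <- object$trials |>
    dplyr::mutate(trial = dplyr::row_number(),
                  best_so_far = cummax(dplyr::coalesce(.data$objective_value, -Inf)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$objective_value,
                                     colour = .data$status)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far)) +
    ggplot2::labs(y = "objective", title = "Hyperparameter optimization trace")
}
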