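test_that("expected improvement matches its closed form", {
  expect_equal(expected_improvement(0.5, 0, 0.5), 0)
  expect_equal(expected_improvement(1, 1, 0), pnorm(1) + dnorm(1),
               tolerance = 1e-12)
  expect_equal(expected_improvement(0, 0, 1), 0)   # no improvement, no sigma
  expect_error(expected_improvement(0, -1, 0), class = "tembo_validation_error")
  # monotone non-decreasing in mu at fixed sigma and incumbent
  mus <- seq(-2, 2, length.out = 41)
  ei <- expected_improvement(mus, 0.7, 0.3)
  expect_true(all(diff(ei) >= -1e-12))
  expect_true(all(ei >= 0))
})

test_that("suggestions always respect box and choice constraints", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      lo <- runif(1, 1e-5, 1e-3)
      hi <- lo * 10^runif(1, 0.5, 3)
      choices <- sort(sample(seq(3, 15, by = 2), sample(2:4, 1)))
      space <- search_space(
        param_log("lr", lo, hi),
        param_lin("d", 0, runif(1, 0.3, 0.9)),
        param_choice("k", choices)
      )
      hist <- NULL
      for (i in 1:8) {
        p <- suggest(hist, space, seed = rep * 100 + i, n_init = 4)
        expect_gte(p$lr, lo); expect_lte(p$lr, hi)
        expect_gte(p$d, 0)
        expect_true(p$k %in% choices)
        row <- tibble::as_tibble(p)
        row$objective_value <- -(log10(p$lr) - log10(lo * 3))^2
        row$status <- "completed"
        hist <- dplyr::bind_rows(hist, row)
      }
    }
  })
})

test_that("suggest is deterministic and survives duplicated observations", {
  space <- default_search_space()
  hist <- sample_space(space, 6, seed = 1)
  hist$objective_value <- seq(0.2, 0.7, length.out = 6)
  hist$status <- "completed"
  dup <- dplyr::bind_rows(hist, hist)   # duplicated points: jitter keeps PD
  s1 <- suggest(dup, space, seed = 4)
  s2 <- suggest(dup, space, seed = 4)
  expect_identical(s1, s2)
  expect_true(s1$kernel_size %in% c(3, 5, 7, 9))
})

test_that("an observed sharp optimum pulls suggestions toward it", {
  space <- search_space(param_lin("x", 0, 1))
  x0 <- 0.62
  f <- function(x) exp(-200 * (x - x0)^2)
  dist_bo <- dist_unif <- numeric(20)
  for (s in 1:20) {
    hist <- sample_space(space, 8, seed = s)
    hist$objective_value <- f(hist$x)
    hist$status <- "completed"
    sug <- suggest(hist, space, seed = s, n_init = 5)
    dist_bo[s] <- abs(sug$x - x0)
    dist_unif[s] <- abs(withr::with_seed(s, runif(1)) - x0)
  }
  expect_lt(mean(dist_bo), mean(dist_unif))
})

test_that("run_hpo finds the learning-rate optimum of a smooth objective", {
  space <- search_space(param_log("learning_rate", 1e-4, 1e-2))
  obj <- function(p) -(log10(p$learning_rate) + 3)^2
  res <- run_hpo(obj, space, n_init = 5, n_iter = 15, seed = 11)
  expect_equal(nrow(res$trials), 20)
  expect_lt(abs(log10(res$best_params$learning_rate) + 3), 0.3)
})

test_that("n_iter = 0 reduces to the random initial trials", {
  space <- search_space(param_lin("x", 0, 1))
  res <- run_hpo(function(p) p$x, space, n_init = 4, n_iter = 0, seed = 3)
  expect_equal(nrow(res$trials), 4)
  expect_equal(res$best_value, max(res$trials$objective_value))
})

test_that("failures are recorded, not fatal; total failure raises", {
  space <- search_space(param_lin("x", 0, 1))
  flaky <- function(p) if (p$x > 0.5) stop("boom") else p$x
  res <- run_hpo(flaky, space, n_init = 4, n_iter = 4, seed = 2)
  expect_equal(nrow(res$trials), 8)
  expect_true(any(res$trials$status == "failed"))
  expect_true(all(res$trials$objective_value[res$trials$status == "completed"] <= 0.5))
  expect_error(run_hpo(function(p) stop("always"), space, 3, 2, seed = 1),
               class = "tembo_hpo_error")
})

test_that("GP-EI search matches or beats random search at equal budget", {
  objectives <- list(
    function(x) -(x - 0.3)^2,
    function(x) sin(8 * x) * exp(-x),
    function(x) -abs(x - 0.7)^0.5
  )
  space <- search_space(param_lin("x", 0, 1))
  bo <- rs <- numeric(0)
  for (s in 1:20) {
    for (k in seq_along(objectives)) {
      f <- function(p) objectives[[k]](p$x)
      seed <- s * 10 + k
      bo <- c(bo, run_hpo(f, space, n_init = 5, n_iter = 15, seed = seed)$best_value)
      rs <- c(rs, random_search(f, space, 20, seed = seed)$best_value)
    }
  }
  expect_gte(mean(bo), mean(rs))
})
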