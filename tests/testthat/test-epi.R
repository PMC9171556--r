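toy_persons <- function() {
  data.frame(
    person_id = c("a", "b", "c"),
    sex = c(0, 1, 1), birth_year = c(1980, 1985, 1990),
    entry_age = c(15, 15, 17),
    exit_age = c(40, 30, 35),
    ocd_dx_age = c(NA, 28, 16),
    event_age_alcohol = c(NA, 30, NA),
    exit_reason = c("admin_censor", "event", "admin_censor"),
    stringsAsFactors = FALSE
  )
}

test_that("counting-process rows split at the diagnosis age", {
  rows <- build_counting_process(toy_persons(), "alcohol", ref_year = 1985)
  a <- rows[rows$person_id == "a", ]
  expect_identical(nrow(a), 1L)
  expect_equal(c(a$start_age, a$stop_age, a$event, a$exposed), c(15, 40, 0, 0))
  b <- rows[rows$person_id == "b", ]
  expect_equal(b$start_age, c(15, 28))
  expect_equal(b$stop_age, c(28, 30))
  expect_equal(b$event, c(0, 1))
  expect_equal(b$exposed, c(0, 1))
  # diagnosis before entry: one fully exposed row
  cc <- rows[rows$person_id == "c", ]
  expect_identical(nrow(cc), 1L)
  expect_equal(cc$exposed, 1L)
  expect_error(build_counting_process(
    transform(toy_persons(), event_age_alcohol = c(NA, 14, NA)), "alcohol"),
    "before entry")
  expect_error(build_counting_process(toy_persons(), "nonexistent"),
               "available outcomes")
})

test_that("Cox coefficient matches a brute-force partial likelihood", {
  # two untied events with mixed-exposure risk sets; the one-parameter
  # partial likelihood has the closed-form maximum exp(beta) = sqrt(2)
  rows <- data.frame(
    person_id = 1:4,
    start_age = c(15, 15, 16, 17),
    stop_age = c(20, 23, 22, 25),
    event = c(1, 0, 1, 0),
    exposed = c(1, 0, 0, 1),
    sex = c(0, 1, 0, 1), by_decade = c(0, 0.1, -0.1, 0.2)
  )
  cf <- cox_fit(rows, covariates = character(0))
  grid <- optimize(function(b) -oracle_cox_loglik(b, rows),
                   interval = c(-5, 5), tol = 1e-9)
  expect_equal(unname(cf$coef[["exposed"]]), grid$minimum, tolerance = 1e-6)
  expect_equal(unname(cf$coef[["exposed"]]), log(sqrt(2)), tolerance = 1e-6)
})

test_that("duplicating every row leaves the hazard ratio unchanged", {
  set.seed(131)
  pr <- load_preset("population-registry")
  persons <- simulate_registry(4000, pr$config, seed = 137)
  rows <- build_counting_process(persons, "alcohol", ref_year = 1980)
  # exact score proportionality holds under Breslow ties (Efron reweights
  # duplicated tied events and so breaks exact invariance by design)
  cf1 <- cox_fit(rows, ties = "breslow")
  cf2 <- cox_fit(rbind(rows, rows), ties = "breslow")
  expect_equal(cf1$hr[["exposed"]], cf2$hr[["exposed"]], tolerance = 1e-6)
})

test_that("Cox errors on constant covariates and empty event sets", {
  rows <- data.frame(person_id = 1:3, start_age = c(15, 15, 15),
                     stop_age = c(20, 21, 22), event = c(0, 0, 0),
                     exposed = c(1, 0, 1), sex = c(0, 1, 0),
                     by_decade = c(0, 0, 0))
  expect_error(cox_fit(rows), "no events")
  rows$event[1] <- 1
  expect_error(cox_fit(rows), "constant")
})

test_that("Kaplan-Meier product limit matches a hand computation", {
  # risk set of 4 at age 16 with one event, then 2 at age 20 with one event:
  # S(20) = (3/4)(1/2) = 0.375
  rows <- data.frame(
    person_id = letters[1:4],
    start_age = c(15, 15, 15, 15),
    stop_age = c(16, 17, 20, 21),
    event = c(1, 0, 1, 0),
    exposed = 0, sex = 0, by_decade = 0
  )
  rows$stop_age[4] <- 21; rows$event[4] <- 0
  # drop person b to age 17 (censored) leaves risk set 2 at age 20
  km <- km_cumulative_incidence(rows, rep("all", 4), eval_ages = c(14, 20))
  expect_true(is.na(km$cum_incidence[km$age == 14]))
  expect_equal(km$cum_incidence[km$age == 20], 0.625, tolerance = 1e-12)
})

test_that("cumulative incidence is zero without events and matches the ECDF", {
  rows0 <- data.frame(person_id = 1:5, start_age = 15, stop_age = 20:24,
                      event = 0, exposed = 0, sex = 0, by_decade = 0)
  km0 <- km_cumulative_incidence(rows0, rep("g", 5), eval_ages = c(18, 23))
  expect_true(all(km0$cum_incidence == 0))
  set.seed(139)
  tt <- 15 + rexp(400, 0.1)
  rows1 <- data.frame(person_id = seq_along(tt), start_age = 15,
                      stop_age = tt, event = 1, exposed = 0, sex = 0,
                      by_decade = 0)
  km1 <- km_cumulative_incidence(rows1, rep("g", length(tt)),
                                 eval_ages = c(20, 30))
  expect_equal(km1$cum_incidence, ecdf(tt)(c(20, 30)), tolerance = 1e-12)
})

test_that("KM is invariant to splitting censoring-free intervals", {
  rows <- data.frame(person_id = 1:3, start_age = 15,
                     stop_age = c(25, 30, 28), event = c(1, 0, 1),
                     exposed = 0, sex = 0, by_decade = 0)
  split <- rbind(
    data.frame(person_id = 1:3, start_age = 15, stop_age = c(20, 22, 21),
               event = 0, exposed = 0, sex = 0, by_decade = 0),
    data.frame(person_id = 1:3, start_age = c(20, 22, 21),
               stop_age = c(25, 30, 28), event = c(1, 0, 1),
               exposed = 0, sex = 0, by_decade = 0)
  )
  ages <- c(24, 26, 29)
  expect_equal(km_cumulative_incidence(split, rep("g", 6), ages)$cum_incidence,
               km_cumulative_incidence(rows, rep("g", 3), ages)$cum_incidence,
               tolerance = 1e-12)
})

test_that("standardized OLS with one predictor returns the correlation", {
  set.seed(149)
  x <- rnorm(300); y <- 0.4 * x + rnorm(300)
  fit <- ols_cluster_robust(y, x, cluster = seq_along(x))
  expect_equal(fit$beta, cor(x, y), tolerance = 1e-10)
})

test_that("cluster sandwich matches a hand-computed oracle", {
  y <- c(1.2, 0.8, -0.3, 0.5, -1.1, 0.2)
  x <- c(0.5, 0.7, -0.2, 0.1, -0.9, 0.3)
  cl <- c("p1", "p1", "p2", "p2", "p3", "p3")
  fit <- ols_cluster_robust(y, x, cluster = cl)
  ys <- scale(y)[, 1]; xs <- scale(x)[, 1]
  X <- cbind(1, xs)
  b <- solve(crossprod(X), crossprod(X, ys))
  e <- ys - X %*% b
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    sg <- colSums(X[cl == g, , drop = FALSE] * e[cl == g])
    meat <- meat + tcrossprod(sg)
  }
  bread <- solve(crossprod(X))
  V <- (3 / 2) * (5 / 4) * bread %*% meat %*% bread
  expect_equal(fit$se, sqrt(V[2, 2]), tolerance = 1e-8)
})

test_that("singleton clusters reduce to heteroskedasticity-robust errors", {
  skip_if_not_installed("sandwich")
  set.seed(151)
  x <- rnorm(120); y <- 0.3 * x + rnorm(120)
  fit <- ols_cluster_robust(y, x, cluster = seq_along(x))
  lmfit <- lm(scale(y)[, 1] ~ scale(x)[, 1])
  se_hc1 <- sqrt(diag(sandwich::vcovHC(lmfit, type = "HC1")))[2]
  expect_equal(fit$se, unname(se_hc1), tolerance = 1e-10)
})

test_that("OLS is invariant to cluster relabeling and validates input", {
  set.seed(157)
  x <- rnorm(80); y <- 0.3 * x + rnorm(80)
  cl <- rep(1:40, each = 2)
  f1 <- ols_cluster_robust(y, x, cluster = cl)
  f2 <- ols_cluster_robust(y, x, cluster = sample(9000:9999)[cl])
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
  expect_error(ols_cluster_robust(y, x, cluster = rep(1, 80)), "2 clusters")
  expect_error(ols_cluster_robust(y, x, covariates = cbind(x, x),
                                  cluster = cl), "rank deficient")
})
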