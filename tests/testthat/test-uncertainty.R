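test_that("gamma moment fit reproduces closed forms and sampled moments", {
  fit <- fit_gamma_moments(4, 2)
  expect_equal(fit$shape, 4)
  expect_equal(fit$scale, 1)
  # boundary case: unit mean and sd give the exponential
  fit1 <- fit_gamma_moments(1, 1)
  expect_equal(fit1$shape, 1)
  expect_equal(fit1$scale, 1)
  expect_error(fit_gamma_moments(0, 1), "mean > 0")
  expect_error(fit_gamma_moments(1, 0), "sd > 0")

  set.seed(101)
  for (p in list(c(0.85, 0.07), c(4, 2), c(0.2, 0.15))) {
    f <- fit_gamma_moments(p[1], p[2])
    x <- rgamma(1e6, shape = f$shape, scale = f$scale)
    expect_lt(abs(mean(x) - p[1]) / p[1], 0.01)
    expect_lt(abs(sd(x) - p[2]) / p[2], 0.01)
  }
})

test_that("beta moment fit reproduces closed forms and sampled moments", {
  # the printed potato wastage example: mean 0.45, sd 0.0142
  fit <- fit_beta_moments(0.45, 0.0142)
  nu <- 0.45 * 0.55 / 0.0142^2 - 1
  expect_equal(fit$alpha, 0.45 * nu)
  expect_equal(fit$beta, 0.55 * nu)
  expect_equal(fit$alpha / (fit$alpha + fit$beta), 0.45)

  expect_error(fit_beta_moments(0.5, 0.5), "too large")
  expect_error(fit_beta_moments(1.2, 0.1), "0 < mean < 1")

  set.seed(202)
  x <- rbeta(1e6, fit$alpha, fit$beta)
  expect_lt(abs(mean(x) - 0.45) / 0.45, 0.01)
  expect_lt(abs(sd(x) - 0.0142) / 0.0142, 0.01)
})

test_that("degenerate uncertainty reproduces the input database exactly", {
  db <- tiny_db()
  db$items$price_sd <- 0
  db$items$wastage_sd <- 0
  db$requirements$sd <- 0
  spec <- uncertainty_spec(n_iterations = 3, seed = 1, nutrient_cv = 0)
  world <- sample_world(db, spec, 1)
  expect_equal(world$items, db$items)
  expect_equal(world$nutrients, db$nutrients)
  expect_equal(world$requirements, db$requirements)
})

test_that("worlds are reproducible from (seed, draw index) alone", {
  db <- tiny_db()
  spec <- uncertainty_spec(n_iterations = 10, seed = 42)
  w1 <- sample_world(db, spec, 7)
  w2 <- sample_world(db, spec, 7)
  expect_identical(w1, w2)
  # order independence: drawing 3 then 7 equals drawing 7 directly
  invisible(sample_world(db, spec, 3))
  expect_identical(sample_world(db, spec, 7), w1)
  # different indices give different worlds
  expect_false(identical(sample_world(db, spec, 8), w1))
  # the input database is untouched
  expect_identical(db, tiny_db())
})

test_that("sampled prices and wastage match their specified moments", {
  db <- tiny_db()
  db$items$price_mean[1] <- 1.00
  db$items$price_sd[1] <- 0.10
  spec <- uncertainty_spec(n_iterations = 2000, seed = 5)
  prices <- vapply(seq_len(2000), function(k)
    sample_world(db, spec, k)$items$price_mean[1], numeric(1))
  expect_gt(mean(prices), 0.99)
  expect_lt(mean(prices), 1.01)
  expect_true(all(prices > 0))
  wast <- vapply(seq_len(500), function(k)
    sample_world(db, spec, k)$items$wastage_mean[3], numeric(1))
  expect_true(all(wast > 0 & wast < 1))
  expect_lt(abs(mean(wast) - db$items$wastage_mean[3]), 0.01)
})

test_that("price variability falls back to the category-typical CV", {
  db <- tiny_db()
  db$items$price_sd[2] <- NA # beans lose their own sd
  spec <- uncertainty_spec(n_iterations = 400, seed = 6)
  p <- vapply(seq_len(400), function(k)
    sample_world(db, spec, k)$items$price_mean[2], numeric(1))
  # no other pulse food: falls back to the database-wide median CV
  cvs <- db$items$price_sd / db$items$price_mean
  cv_fb <- median(cvs, na.rm = TRUE)
  expect_lt(abs(sd(p) / mean(p) - cv_fb) / cv_fb, 0.25)
})

test_that("zero-variance simulation collapses to the deterministic optimum", {
  db <- tiny_db()
  db$items$price_sd <- 0
  db$items$wastage_sd <- 0
  db$requirements$sd <- 0
  spec <- uncertainty_spec(n_iterations = 5, seed = 1, nutrient_cv = 0)
  det <- optimize_diet(db, tiny_scenario())
  sim <- run_simulation(db, tiny_scenario(), spec)
  row <- sim$summary[sim$summary$output == "objective", ]
  expect_equal(row$lower95, det$objective_value, tolerance = 1e-12)
  expect_equal(row$median, det$objective_value, tolerance = 1e-12)
  expect_equal(row$upper95, det$objective_value, tolerance = 1e-12)
  expect_equal(sim$n_infeasible, 0L)
})

test_that("simulation summaries are seed-deterministic and seed-stable", {
  db <- tiny_db()
  scn <- tiny_scenario()
  s1 <- run_simulation(db, scn, uncertainty_spec(n_iterations = 150,
                                                 seed = 11))
  s1b <- run_simulation(db, scn, uncertainty_spec(n_iterations = 150,
                                                  seed = 11))
  expect_identical(s1$summary, s1b$summary)
  # two seeds agree within a few inter-seed standard errors
  s2 <- run_simulation(db, scn, uncertainty_spec(n_iterations = 150,
                                                 seed = 12))
  m1 <- s1$summary$median[s1$summary$output == "cost"]
  m2 <- s2$summary$median[s2$summary$output == "cost"]
  sdl <- s1$summary[s1$summary$output == "cost", ]
  se <- (sdl$upper95 - sdl$lower95) / (2 * 1.96) / sqrt(150)
  expect_lt(abs(m1 - m2), 5 * se)
})

test_that("infeasible draws are counted and excluded, not redrawn", {
  # single food capped at 100 g: max attainable energy is 1000 kJ; an energy
  # floor drawn around 1000 kJ is unattainable on about half the draws
  items <- data.frame(
    id = "only", name = "Only", category = "other", price_mean = 0.5,
    price_sd = 0, wastage_mean = 0, wastage_sd = 0, ghg_factor = 1,
    tags = "", stringsAsFactors = FALSE)
  nutrients <- matrix(1000, 1, 1, dimnames = list("only", "energy"))
  req <- data.frame(nutrient_id = "energy", unit = "kJ", min = 1000,
                    max = NA, sd = 60)
  db <- food_db(items, nutrients, req)
  scn <- scenario("HALF", objective = "min_cost",
                  per_food_max = c(only = 100), min_if_included = 0)
  spec <- uncertainty_spec(n_iterations = 400, seed = 3,
                           vary_nutrients = FALSE)
  expect_warning(sim <- run_simulation(db, scn, spec), NA)
  expect_equal(sim$n_feasible + sim$n_infeasible, 400L)
  expect_gt(sim$n_infeasible, 120)
  expect_lt(sim$n_infeasible, 280)
  # zero feasible draws is an error
  req2 <- req; req2$min <- 2000; req2$sd <- 0
  db2 <- food_db(items, nutrients, req2)
  expect_warning(expect_error(
    run_simulation(db2, scn, uncertainty_spec(n_iterations = 5, seed = 1)),
    "no feasible draws"), "infeasible")
})

test_that("simulation intervals match analytic quantiles on a one-price instance", {
  # one food, one binding floor: x = 500 g always, cost = 5 * price with
  # price ~ gamma(mean 1, sd 0.2); the 95% SI is the scaled gamma quantile
  items <- data.frame(
    id = "only", name = "Only", category = "other", price_mean = 1,
    price_sd = 0.2, wastage_mean = 0, wastage_sd = 0, ghg_factor = 1,
    tags = "", stringsAsFactors = FALSE)
  nutrients <- matrix(10, 1, 1, dimnames = list("only", "protein"))
  req <- data.frame(nutrient_id = "protein", unit = "g", min = 50, max = NA,
                    sd = 0)
  db <- food_db(items, nutrients, req)
  scn <- scenario("ONEPRICE", objective = "min_cost", min_if_included = 0)
  spec <- uncertainty_spec(n_iterations = 2000, seed = 17,
                           vary_nutrients = FALSE, vary_wastage = FALSE,
                           vary_requirements = FALSE)
  sim <- run_simulation(db, scn, spec)
  fit <- fit_gamma_moments(1, 0.2)
  expected <- 5 * qgamma(c(0.025, 0.5, 0.975), shape = fit$shape,
                         scale = fit$scale)
  row <- sim$summary[sim$summary$output == "cost", ]
  # Monte Carlo error of a quantile at n = 2000:
  # se = sqrt(p(1-p)/n) / f(q); allow 4 se
  se_q <- function(p) {
    q <- qgamma(p, shape = fit$shape, scale = fit$scale)
    5 * sqrt(p * (1 - p) / 2000) /
      dgamma(q, shape = fit$shape, scale = fit$scale)
  }
  expect_lt(abs(row$lower95 - expected[1]), 4 * se_q(0.025))
  expect_lt(abs(row$median - expected[2]), 4 * se_q(0.5))
  expect_lt(abs(row$upper95 - expected[3]), 4 * se_q(0.975))
})

test_that("ratio outputs are ratios of summary statistics", {
  db <- tiny_db()
  sim <- run_simulation(db, tiny_scenario(),
                        uncertainty_spec(n_iterations = 60, seed = 2))
  r <- sim$ratios[sim$ratios$ratio == "pufa_over_sat_fat", ]
  num <- sim$summary[sim$summary$output == "nutrient_pufa", ]
  den <- sim$summary[sim$summary$output == "nutrient_sat_fat", ]
  expect_equal(r$median, num$median / den$median)
  expect_equal(r$mean, num$mean / den$mean)
})

test_that("simulation exports per-draw CSV and JSON summary", {
  db <- tiny_db()
  sim <- run_simulation(db, tiny_scenario(),
                        uncertainty_spec(n_iterations = 25, seed = 4))
  stem <- file.path(withr::local_tempdir(), "sim")
  paths <- write_simulation(sim, stem)
  d <- read.csv(paste0(stem, "_draws.csv"))
  expect_equal(nrow(d), 25)
  expect_true(all(c("draw", "feasible", "objective", "cost", "ghg") %in%
                    names(d)))
  js <- jsonlite::read_json(paste0(stem, "_summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_feasible + js$n_infeasible, 25)
  expect_close(js$summary$median[js$summary$output == "cost"],
               sim$summary$median[sim$summary$output == "cost"], rel = 1e-12)
})
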