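#' Fit a gamma distribution by the method of moments
#'
#' Matches the first two moments: `shape = mean^2/sd^2`,
#' `scale = sd^2/mean`. Used for food prices, whose month-to-month variation
#' is positive and right-skewed.
#'
#' @param mean,sd positive reals.
#' @return list with `shape` and `scale`.
#' @examples
#' fit_gamma_moments(4, 2) # shape 4, scale 1
#' @export
fit_gamma_moments <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0))
    stop("gamma moment fit requires mean > 0 and sd > 0")
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Fit a beta distribution by the method of moments
#'
#' With `nu = mean(1-mean)/sd^2 - 1`: `alpha = mean * nu`,
#' `beta = (1-mean) * nu`. Used for wastage fractions, which must stay in
#' (0, 1). The variance of a beta cannot reach `mean(1-mean)`; larger `sd`
#' values are rejected.
#'
#' @param mean fraction strictly between 0 and 1.
#' @param sd positive real with `sd^2 < mean(1-mean)`.
#' @return list with `alpha` and `beta`.
#' @examples
#' fit_beta_moments(0.45, 0.0142)
#' @export
fit_beta_moments <- function(mean, sd) {
  if (any(mean <= 0) || any(mean >= 1))
    stop("beta moment fit requires 0 < mean < 1")
  if (any(sd <= 0)) stop("beta moment fit requires sd > 0")
  bound <- sqrt(mean * (1 - mean))
  if (any(sd >= bound))
    stop("sd too large for a beta distribution: need sd < sqrt(mean(1-mean))",
         " = ", signif(bound, 6))
  nu <- mean * (1 - mean) / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Specification of the Monte Carlo uncertainty model
#'
#' Distributions for one simulation draw:
#' * prices — gamma, moment-matched to `(price_mean, price_sd)`; foods
#'   without `price_sd` use the median coefficient of variation of their
#'   category (falling back to the database-wide median);
#' * nutrient contents — normal with sd equal to `nutrient_cv` (default 5%)
#'   of the mean, truncated at 0;
#' * wastage — beta, moment-matched to `(wastage_mean, wastage_sd)`;
#' * requirement minima (including the energy target, whose default sd is
#'   184.4 kJ) — normal with the requirement's heterogeneity sd, truncated
#'   at 0 and clamped to any upper bound.
#' All draws are independent across foods, nutrients and requirements.
#'
#' @param n_iterations number of Monte Carlo draws (default 2000).
#' @param seed integer; draw `k` is reproducible from `(seed, k)` alone.
#' @param nutrient_cv coefficient of variation for nutrient contents.
#' @param vary_prices,vary_nutrients,vary_wastage,vary_requirements logical
#'   switches for each uncertainty source.
#' @return object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(n_iterations = 2000L, seed = 1L,
                             nutrient_cv = 0.05,
                             vary_prices = TRUE, vary_nutrients = TRUE,
                             vary_wastage = TRUE, vary_requirements = TRUE) {
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), nutrient_cv = nutrient_cv,
                 vary_prices = vary_prices, vary_nutrients = vary_nutrients,
                 vary_wastage = vary_wastage,
                 vary_requirements = vary_requirements),
            class = "uncertainty_spec")
}

# normal truncated at zero (and optionally above), by inverse-cdf sampling
rtruncnorm0 <- function(n, mean, sd, upper = Inf) {
  out <- mean
  vary <- sd > 0
  if (any(vary)) {
    plo <- stats::pnorm(0, mean[vary], sd[vary])
    phi <- stats::pnorm(pmin(upper[vary], Inf), mean[vary], sd[vary])
    u <- stats::runif(sum(vary), plo, phi)
    out[vary] <- stats::qnorm(u, mean[vary], sd[vary])
  }
  pmin(out, upper)
}

category_cv_fallback <- function(db) {
  cv <- db$items$price_sd / db$items$price_mean
  med_all <- stats::median(cv, na.rm = TRUE)
  if (!is.finite(med_all)) med_all <- 0
  vapply(seq_len(n_foods(db)), function(i) {
    if (!is.na(cv[i])) return(cv[i])
    same <- db$items$category == db$items$category[i]
    m <- stats::median(cv[same], na.rm = TRUE)
    if (is.finite(m)) m else med_all
  }, numeric(1))
}

#' Draw one perturbed world from a food database
#'
#' Returns a copy of `db` with prices, nutrient contents, wastage fractions
#' and requirement minima independently redrawn from the distributions in
#' `spec`. Reproducible: the random state depends only on
#' `(spec$seed, draw_index)`, so draws can be recomputed out of order.
#'
#' @param db a `food_db`.
#' @param spec an [uncertainty_spec()].
#' @param draw_index positive integer index of the draw.
#' @return a perturbed `food_db` (the input is not modified).
#' @export
sample_world <- function(db, spec, draw_index) {
  stopifnot(inherits(spec, "uncertainty_spec"), draw_index >= 1)
  draw_seed <- (as.numeric(spec$seed) * 1000003 + draw_index) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(draw_seed))

  out <- db
  n <- n_foods(db)
  if (spec$vary_prices) {
    cv <- category_cv_fallback(db)
    sd <- cv * db$items$price_mean
    vary <- sd > 0
    if (any(vary)) {
      fit <- fit_gamma_moments(db$items$price_mean[vary], sd[vary])
      out$items$price_mean[vary] <- stats::rgamma(sum(vary), shape = fit$shape,
                                                  scale = fit$scale)
    }
  }
  if (spec$vary_nutrients) {
    m <- db$nutrients
    pos <- m > 0
    if (any(pos)) {
      mu <- m[pos]
      m[pos] <- rtruncnorm0(length(mu), mu, spec$nutrient_cv * mu,
                            upper = rep(Inf, length(mu)))
    }
    out$nutrients <- m
  }
  if (spec$vary_wastage) {
    wm <- db$items$wastage_mean
    ws <- db$items$wastage_sd
    vary <- ws > 0 & wm > 0 & wm < 1 & ws^2 < wm * (1 - wm)
    if (any(vary)) {
      fit <- fit_beta_moments(wm[vary], ws[vary])
      out$items$wastage_mean[vary] <- stats::rbeta(sum(vary), fit$alpha,
                                                   fit$beta)
    }
  }
  if (spec$vary_requirements) {
    req <- db$requirements
    hasmin <- !is.na(req$min) & req$sd > 0
    if (any(hasmin)) {
      upper <- ifelse(is.na(req$max[hasmin]), Inf, req$max[hasmin])
      out$requirements$min[hasmin] <-
        rtruncnorm0(sum(hasmin), req$min[hasmin], req$sd[hasmin], upper)
    }
  }
  out
}

#' Run the Monte Carlo simulation for a scenario
#'
#' Optimizes the scenario on `n_iterations` independently perturbed copies of
#' the database and summarizes every output (objective, cost, GHG, nutrient
#' intakes, per-food quantities) by its mean, median and 95% simulation
#' interval (2.5th-97.5th percentiles, linear-interpolation quantiles).
#' Draws where the perturbed problem is infeasible are counted and excluded
#' from the summaries, not redrawn. The polyunsaturated/saturated-fat and
#' potassium/sodium ratios are reported as ratios of the summary statistics,
#' not statistics of per-draw ratios.
#'
#' @param db a `food_db`.
#' @param scn a [scenario()].
#' @param spec an [uncertainty_spec()].
#' @param keep_draws keep the per-draw output matrix (needed for
#'   [write_simulation()]'s draw export).
#' @return object of class `simulation_summary`: `summary` (one row per
#'   output), `ratios`, `n_feasible`, `n_infeasible`, and optionally `draws`.
#' @export
run_simulation <- function(db, scn, spec = uncertainty_spec(),
                           keep_draws = TRUE) {
  base <- optimize_diet(db, scn)
  if (base$status != "optimal")
    warning("scenario ", scn$id, " is ", base$status,
            " on the unperturbed database")
  outputs <- c("objective", "cost", "ghg",
               paste0("nutrient_", nutrient_ids(db)),
               paste0("food_", food_ids(db)))
  draws <- matrix(NA_real_, spec$n_iterations, length(outputs),
                  dimnames = list(NULL, outputs))
  feasible <- logical(spec$n_iterations)
  for (k in seq_len(spec$n_iterations)) {
    world <- sample_world(db, spec, k)
    sol <- optimize_diet(world, scn)
    if (sol$status != "optimal") next
    feasible[k] <- TRUE
    q <- stats::setNames(rep(0, n_foods(db)), food_ids(db))
    q[names(sol$quantities)] <- sol$quantities
    draws[k, ] <- c(sol$objective_value, sol$cost, sol$ghg,
                    sol$nutrient_intakes[nutrient_ids(db)], q)
  }
  n_ok <- sum(feasible)
  if (n_ok == 0L)
    stop("no feasible draws: scenario ", scn$id,
         " failed on all ", spec$n_iterations, " perturbed worlds")
  ok <- draws[feasible, , drop = FALSE]
  qs <- apply(ok, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE, type = 7)
  summary <- data.frame(
    output = outputs,
    mean = colMeans(ok),
    median = qs[2, ],
    lower95 = qs[1, ],
    upper95 = qs[3, ],
    row.names = NULL, stringsAsFactors = FALSE)
  ratio_of <- function(num, den) {
    a <- summary[summary$output == num, c("mean", "median", "lower95",
                                          "upper95")]
    b <- summary[summary$output == den, c("mean", "median", "lower95",
                                          "upper95")]
    if (!nrow(a) || !nrow(b)) return(NULL)
    cbind(data.frame(ratio = paste0(sub("nutrient_", "", num), "_over_",
                                    sub("nutrient_", "", den))),
          a / b)
  }
  ratios <- rbind(ratio_of("nutrient_pufa", "nutrient_sat_fat"),
                  ratio_of("nutrient_potassium", "nutrient_sodium"))
  structure(list(
    scenario_id = scn$id, summary = summary, ratios = ratios,
    n_feasible = n_ok, n_infeasible = spec$n_iterations - n_ok,
    n_iterations = spec$n_iterations,
    draws = if (keep_draws) draws else NULL
  ), class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("<simulation_summary> scenario ", x$scenario_id, ": ",
      x$n_feasible, "/", x$n_iterations, " feasible draws\n", sep = "")
  key <- x$summary[x$summary$output %in% c("objective", "cost", "ghg"), ]
  for (i in seq_len(nrow(key)))
    cat(sprintf("  %-9s median %.3f (95%% SI %.3f-%.3f)\n", key$output[i],
                key$median[i], key$lower95[i], key$upper95[i]))
  invisible(x)
}

#' Export simulation results
#'
#' Writes a per-draw CSV (`<stem>_draws.csv`: draw index, feasibility,
#' objective, cost, GHG, nutrient intakes) and a JSON summary
#' (`<stem>_summary.json`) holding the per-output statistics, ratio rows
#' and infeasibility count.
#'
#' @param sim a `simulation_summary` produced with `keep_draws = TRUE`.
#' @param stem output path prefix.
#' @return invisibly, the two file paths written.
#' @export
write_simulation <- function(sim, stem) {
  if (is.null(sim$draws))
    stop("simulation was run with keep_draws = FALSE; no draws to export")
  keep <- !grepl("^food_", colnames(sim$draws))
  d <- data.frame(draw = seq_len(nrow(sim$draws)),
                  feasible = !is.na(sim$draws[, "objective"]),
                  sim$draws[, keep, drop = FALSE])
  draws_path <- paste0(stem, "_draws.csv")
  utils::write.csv(d, draws_path, row.names = FALSE)
  json_path <- paste0(stem, "_summary.json")
  jsonlite::write_json(
    list(scenario = sim$scenario_id, n_feasible = sim$n_feasible,
         n_infeasible = sim$n_infeasible, summary = sim$summary,
         ratios = sim$ratios),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(draws_path, json_path))
}
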