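# Shared fixtures and independent oracles for the test suite.

# a small hand-built database: staple, pulse, vegetable, oil; one requirement
# table with a subset of nutrient rows so solutions are easy to reason about
tiny_db <- function() {
  items <- data.frame(
    id = c("grain", "beans", "greens", "oil"),
    name = c("Grain", "Beans", "Greens", "Oil"),
    category = c("cereal_grain", "pulse_seed_nut", "fruit_veg", "fat_oil"),
    price_mean = c(0.20, 0.40, 0.50, 0.60),
    price_sd = c(0.01, 0.02, 0.06, 0.03),
    wastage_mean = c(0.05, 0.02, 0.25, 0),
    wastage_sd = c(0.002, 0.001, 0.02, 0),
    ghg_factor = c(1.0, 0.9, 0.4, 3.5),
    tags = c("staple", "pulse", "vegetable", "oil"),
    stringsAsFactors = FALSE)
  nutrients <- rbind(
    grain  = c(energy = 1450, protein = 12, sat_fat = 0.5, pufa = 1.0,
               sodium = 5),
    beans  = c(energy = 1400, protein = 23, sat_fat = 0.3, pufa = 0.7,
               sodium = 12),
    greens = c(energy = 150, protein = 2, sat_fat = 0.05, pufa = 0.1,
               sodium = 40),
    oil    = c(energy = 3700, protein = 0, sat_fat = 9, pufa = 55,
               sodium = 0))
  req <- data.frame(
    nutrient_id = c("energy", "protein", "sat_fat", "pufa", "sodium"),
    unit = c("kJ", "g", "g", "g", "mg"),
    min = c(9000, 40, NA, 8, NA),
    max = c(NA, NA, 25, NA, 2300),
    sd = c(184.4, 2, 0, 0.4, 0))
  food_db(items, nutrients, req, metadata = list(provenance = "test fixture"))
}

tiny_scenario <- function(...) scenario("TINY", objective = "min_cost", ...)

# Independent LP oracle: enumerate candidate vertices as solutions of every
# n-subset of the active-constraint system (rows + variable bounds), keep the
# feasible ones, return the best objective. Exact for small dense problems.
brute_force_lp <- function(objective, A, dir, rhs, lower, upper,
                           tol = 1e-7) {
  n <- length(objective)
  rows <- list()
  if (!is.null(A) && nrow(A)) {
    for (i in seq_len(nrow(A))) rows[[length(rows) + 1L]] <-
        list(a = A[i, ], b = rhs[i])
  }
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    rows[[length(rows) + 1L]] <- list(a = e, b = lower[j])
    if (is.finite(upper[j]))
      rows[[length(rows) + 1L]] <- list(a = e, b = upper[j])
  }
  feasible <- function(x) {
    if (any(x < lower - tol) || any(x > upper + tol)) return(FALSE)
    if (!is.null(A) && nrow(A)) {
      lhs <- as.numeric(A %*% x)
      ok <- mapply(function(l, d, r) switch(d,
        "<=" = l <= r + tol * max(1, abs(r)),
        ">=" = l >= r - tol * max(1, abs(r)),
        "="  = abs(l - r) <= tol * max(1, abs(r))), lhs, dir, rhs)
      if (!all(ok)) return(FALSE)
    }
    TRUE
  }
  best <- Inf; best_x <- NULL; found <- FALSE
  idx <- utils::combn(length(rows), n)
  for (k in seq_len(ncol(idx))) {
    M <- do.call(rbind, lapply(rows[idx[, k]], `[[`, "a"))
    b <- vapply(rows[idx[, k]], `[[`, numeric(1), "b")
    if (abs(det(M)) < 1e-10) next
    x <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    found <- TRUE
    v <- sum(objective * x)
    if (v < best) { best <- v; best_x <- x }
  }
  if (!found) return(list(status = "infeasible", objective_value = NA_real_))
  list(status = "optimal", objective_value = best, x = best_x)
}

# random small diet instance: 3-5 foods, 2-4 nutrient rows, always includes
# an energy-like floor so most instances are feasible and bounded
random_small_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:5, 1)
  k <- sample(2:4, 1)
  nut_names <- paste0("n", seq_len(k))
  items <- data.frame(
    id = paste0("f", seq_len(n)), name = paste0("Food ", seq_len(n)),
    category = "other",
    price_mean = round(runif(n, 0.1, 2), 3), price_sd = 0,
    wastage_mean = round(runif(n, 0, 0.4), 3), wastage_sd = 0,
    ghg_factor = round(runif(n, 0.3, 20), 3), tags = "",
    stringsAsFactors = FALSE)
  nutrients <- matrix(round(runif(n * k, 0, 30), 2), n, k,
                      dimnames = list(items$id, nut_names))
  nutrients[, 1] <- round(runif(n, 5, 30), 2) # floor nutrient present in all
  req <- data.frame(nutrient_id = nut_names,
                    unit = "g",
                    min = c(round(runif(1, 20, 60), 1),
                            round(runif(k - 1, 0, 15), 1)),
                    max = NA_real_, sd = 0)
  # occasionally add an upper bound row
  if (runif(1) < 0.4) req$max[k] <- req$min[k] + round(runif(1, 10, 40), 1)
  db <- food_db(items, nutrients, req,
                metadata = list(provenance = "random test instance"))
  ub <- round(runif(n, 150, 600))
  scn <- scenario(paste0("RND", seed), objective = "min_cost",
                  per_food_max = stats::setNames(ub, items$id),
                  min_if_included = 0)
  list(db = db, scenario = scn)
}

expect_close <- function(actual, expected, rel = 1e-6) {
  testthat::expect_lt(abs(actual - expected),
                      rel * max(1, abs(expected)))
}
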