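test_that("the simplex solver reproduces analytic optima", {
  # protein floor, two foods: cost per gram protein decides (0.05 vs 0.06)
  res <- solve_lp(c(1.00, 0.60) / 100, rbind(c(0.20, 0.10)), ">=", 50)
  expect_equal(res$status, "optimal")
  expect_equal(res$x, c(250, 0), tolerance = 1e-9)
  expect_equal(res$objective_value, 2.50, tolerance = 1e-9)

  # vacuous floor: empty diet
  res0 <- solve_lp(c(1.00, 0.60) / 100, rbind(c(0.20, 0.10)), ">=", 0)
  expect_equal(res0$objective_value, 0)

  # no variables can supply the floor: infeasible
  resi <- solve_lp(c(1, 1), rbind(c(0, 0)), ">=", 50)
  expect_equal(resi$status, "infeasible")

  # unbounded when a profitable direction exists
  resu <- solve_lp(c(-1, 0), rbind(c(0, 1)), "<=", 5)
  expect_equal(resu$status, "unbounded")

  # degenerate/equality mix
  rese <- solve_lp(c(2, 3), rbind(c(1, 1), c(1, -1)), c("=", "="), c(10, 2))
  expect_equal(rese$x, c(6, 4))
})

test_that("solver matches vertex-enumeration brute force on random instances", {
  n_match <- 0
  for (s in 1:40) {
    inst <- random_small_instance(1000 + s)
    sys <- compile_constraints(inst$scenario, inst$db)
    mine <- solve_lp(sys$objective_coef, sys$A, sys$dir, sys$rhs,
                     sys$lower, sys$upper)
    oracle <- brute_force_lp(sys$objective_coef, sys$A, sys$dir, sys$rhs,
                             sys$lower, sys$upper)
    expect_equal(mine$status, oracle$status, info = paste("seed", 1000 + s))
    if (mine$status == "optimal") {
      expect_close(mine$objective_value, oracle$objective_value, rel = 1e-5)
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 20) # most random instances should be solvable
})

test_that("solver agrees with the boot package simplex on random instances", {
  skip_if_not_installed("boot")
  for (s in 1:15) {
    inst <- random_small_instance(2000 + s)
    sys <- compile_constraints(inst$scenario, inst$db)
    ge <- sys$dir == ">="
    le <- sys$dir == "<="
    # boot::simplex solves min over x >= 0 with A1 x <= b1, A2 x >= b2;
    # upper bounds enter as extra <= rows
    A1 <- rbind(sys$A[le, , drop = FALSE], diag(length(sys$food_ids)))
    b1 <- c(sys$rhs[le], sys$upper)
    ref <- boot::simplex(a = sys$objective_coef, A1 = A1, b1 = b1,
                         A2 = sys$A[ge, , drop = FALSE], b2 = sys$rhs[ge],
                         maxi = FALSE)
    mine <- solve_lp(sys$objective_coef, sys$A, sys$dir, sys$rhs,
                     sys$lower, sys$upper)
    if (ref$solved == 1) {
      expect_equal(mine$status, "optimal")
      expect_close(mine$objective_value, ref$value, rel = 1e-5)
    } else if (ref$solved == -1) {
      expect_equal(mine$status, "infeasible")
    }
  }
})

test_that("optimized diets satisfy every compiled constraint", {
  db <- generate_food_database(generator_config(seed = 11))
  for (id in c("C1", "G1", "MED", "NZ_M")) {
    scn <- builtin_scenario(id)
    sys <- compile_constraints(scn, db)
    sol <- optimize_diet(db, scn)
    expect_equal(sol$status, "optimal", info = id)
    x <- sol$quantities[sys$food_ids]
    lhs <- as.numeric(sys$A %*% x)
    ok <- mapply(function(l, d, r) switch(d,
      "<=" = l <= r + 1e-6 * max(1, abs(r)),
      ">=" = l >= r - 1e-6 * max(1, abs(r)),
      "="  = abs(l - r) <= 1e-6 * max(1, abs(r))), lhs, sys$dir, sys$rhs)
    expect_true(all(ok), info = id)
    expect_true(all(x >= sys$lower - 1e-6 & x <= sys$upper + 1e-6),
                info = id)
    # reported aggregates are consistent with the quantities
    expect_close(sol$cost, sum(sys$cost * x), rel = 1e-9)
    expect_close(sol$ghg, sum(sys$ghg * x), rel = 1e-9)
    expect_close(sol$nutrient_intakes[["energy"]],
                 sum(sys$nutrients[, "energy"] * x) / 100, rel = 1e-9)
  }
})

test_that("minimum-portion rule leaves no food strictly between 0 and 10 g", {
  # force a sub-minimum optimum: one nutrient only available from one food,
  # needed at an amount worth < 10 g
  items <- data.frame(
    id = c("bulk", "trace"), name = c("Bulk", "Trace"), category = "other",
    price_mean = c(0.2, 5), price_sd = 0, wastage_mean = 0, wastage_sd = 0,
    ghg_factor = 1, tags = "", stringsAsFactors = FALSE)
  nutrients <- rbind(bulk = c(energy = 1500, vit_x = 0),
                     trace = c(energy = 500, vit_x = 10))
  req <- data.frame(nutrient_id = c("energy", "vit_x"),
                    unit = c("kJ", "g"), min = c(9000, 0.5), max = NA,
                    sd = 0)
  db <- food_db(items, nutrients, req)
  scn <- scenario("TRACE", objective = "min_cost")
  for (method in c("iterative", "milp")) {
    sol <- optimize_diet(db, scn, method = method)
    expect_equal(sol$status, "optimal")
    # the plain LP would buy 5 g of 'trace'; the rule pushes it to 10 g
    expect_equal(unname(sol$quantities[["trace"]]), 10, tolerance = 1e-6)
  }
  # and the heuristic matches the exact branch-and-bound objective here
  expect_close(optimize_diet(db, scn, method = "iterative")$objective_value,
               optimize_diet(db, scn, method = "milp")$objective_value,
               rel = 1e-9)
})

test_that("iterative minimum-portion heuristic tracks the exact optimum on random instances", {
  n_checked <- 0
  for (s in 1:20) {
    inst <- random_small_instance(3000 + s)
    scn <- inst$scenario
    scn$min_if_included <- 10
    it <- optimize_diet(inst$db, scn, method = "iterative")
    ex <- optimize_diet(inst$db, scn, method = "milp")
    expect_equal(it$status, ex$status)
    if (it$status != "optimal") next
    n_checked <- n_checked + 1
    for (sol in list(it, ex)) {
      q <- sol$quantities
      expect_false(any(q > 1e-6 & q < 10 - 1e-6), info = paste("seed", s))
    }
    # heuristic is an upper bound on the exact semicontinuous optimum
    expect_gte(it$objective_value, ex$objective_value - 1e-9)
    # and never strays far on these instances
    expect_lt(it$objective_value,
              ex$objective_value * 1.2 + 1e-9)
  }
  expect_gt(n_checked, 10)
})

test_that("evaluating a fixed diet reproduces direct arithmetic", {
  items <- data.frame(
    id = "single", name = "Single", category = "other", price_mean = 0.50,
    price_sd = 0, wastage_mean = 0, wastage_sd = 0, ghg_factor = 2,
    tags = "", stringsAsFactors = FALSE)
  nutrients <- matrix(800, 1, 1, dimnames = list("single", "energy"))
  req <- data.frame(nutrient_id = "energy", unit = "kJ", min = 1, max = NA,
                    sd = 0)
  db <- food_db(items, nutrients, req)
  sol <- evaluate_diet(db, c(single = 100))
  expect_equal(sol$status, "evaluated")
  expect_equal(sol$cost, 0.50)
  expect_equal(sol$ghg, 0.20)
  expect_equal(unname(sol$nutrient_intakes[["energy"]]), 800)

  # wastage doubles the purchased weight and hence the cost
  db2 <- db
  db2$items$wastage_mean <- 0.5
  db2$items$price_mean <- 1
  sol2 <- evaluate_diet(db2, c(single = 100))
  expect_equal(sol2$cost, 2.00)

  empty <- evaluate_diet(db, stats::setNames(numeric(0), character(0)))
  expect_equal(empty$cost, 0)
  expect_equal(empty$ghg, 0)
  expect_error(evaluate_diet(db, c(ghost = 10)), "ghost")
})

test_that("energy rescaling hits the target exactly", {
  db <- tiny_db()
  q <- c(grain = 300, greens = 200)
  scaled <- scale_to_energy(q, db, 11450)
  e <- sum(scaled * db$nutrients[names(scaled), "energy"] / 100)
  expect_close(e, 11450, rel = 1e-9)
  # published rescale: 9,996 kJ worth of food scaled to 11,450 kJ
  q9996 <- q * 9996 / sum(q * db$nutrients[names(q), "energy"] / 100)
  s2 <- scale_to_energy(q9996, db, 11450)
  expect_equal(unname(s2 / q9996), rep(11450 / 9996, 2), tolerance = 1e-12)
  # identity when already on target
  expect_equal(scale_to_energy(scaled, db, 11450), scaled, tolerance = 1e-12)
  expect_error(scale_to_energy(c(grain = 0), db, 100), "no energy")
})

test_that("tightening constraints can only worsen the optimum", {
  db <- generate_food_database(generator_config(seed = 9))
  base <- optimize_diet(db, builtin_scenario("C1"))
  # raising a nutrient floor never lowers minimum cost
  for (mult in c(1.05, 1.2, 1.5)) {
    db2 <- db
    k <- which(db2$requirements$nutrient_id == "protein")
    db2$requirements$min[k] <- db2$requirements$min[k] * mult
    tightened <- optimize_diet(db2, builtin_scenario("C1"))
    if (tightened$status == "optimal")
      expect_gte(tightened$objective_value, base$objective_value - 1e-9)
  }
  # tightening the budget never lowers minimum emissions
  g_loose <- optimize_diet(db, builtin_scenario("G2")) # cap 9
  g_tight <- optimize_diet(db, builtin_scenario("G1")) # cap 5
  expect_gte(g_tight$objective_value, g_loose$objective_value - 1e-9)

  # a cap below the minimum achievable cost is infeasible
  c1 <- optimize_diet(db, builtin_scenario("C1"))
  too_low <- scenario("GX", objective = "min_ghg",
                      budget_cap = c1$objective_value * 0.5,
                      tag_maxima = DEFAULT_TAG_MAXIMA)
  expect_equal(optimize_diet(db, too_low)$status, "infeasible")
})

test_that("optimum bounds any hand-built feasible diet (weak duality)", {
  db <- tiny_db()
  scn <- tiny_scenario()
  opt <- optimize_diet(db, scn)
  expect_equal(opt$status, "optimal")
  # a deliberately generous feasible diet
  hand <- c(grain = 500, beans = 250, greens = 120, oil = 40)
  ev <- evaluate_diet(db, hand)
  req <- db$requirements
  for (k in seq_len(nrow(req))) {
    v <- ev$nutrient_intakes[[req$nutrient_id[k]]]
    if (!is.na(req$min[k])) expect_gte(v, req$min[k])
    if (!is.na(req$max[k])) expect_lte(v, req$max[k])
  }
  expect_lte(opt$objective_value, ev$cost)
})

test_that("solutions export to flat CSV and JSON", {
  db <- tiny_db()
  sol <- optimize_diet(db, tiny_scenario())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_solution(sol, db, csv, "csv")
  write_solution(sol, db, js, "json")
  flat <- read.csv(csv)
  expect_setequal(names(flat), c("food_id", "grams_edible",
                                 "grams_purchased", "cost_share",
                                 "ghg_share"))
  expect_close(sum(flat$cost_share), 1, rel = 1e-9)
  w <- db$items$wastage_mean[match(flat$food_id, db$items$id)]
  expect_equal(flat$grams_purchased, flat$grams_edible / (1 - w))
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$status, "optimal")
  expect_close(doc$cost, sol$cost, rel = 1e-9)
})
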