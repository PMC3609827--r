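#' @title Dietary scenarios
#' @description
#' A `scenario` is a declarative bundle of objective and constraints that,
#' together with a food database, compiles into a linear program. Sixteen
#' built-in scenarios cover four families: lowest-cost diets (C1-C4),
#' lowest-emission diets under a budget cap (G1-G4), Mediterranean- and
#' Asian-style high-vegetable diets (MED, MED_G, ASIAN, ASIAN_G), and diets
#' anchored on familiar New Zealand meals (NZ_M, NZ_S, NZ_T, NZ_P).
#' @name scenarios
NULL

#' Ids of the sixteen built-in dietary scenarios
#'
#' Cost-minimizing (C1-C4), emission-minimizing under a budget (G1-G4),
#' Mediterranean- and Asian-style (MED, MED_G, ASIAN, ASIAN_G), and familiar
#' New Zealand meal scenarios (NZ_M, NZ_S, NZ_T, NZ_P). See
#' [builtin_scenario()].
#'
#' @format character vector of length 16.
#' @export
SCENARIO_IDS <- c("C1", "C2", "C3", "C4", "G1", "G2", "G3", "G4",
                  "MED", "MED_G", "ASIAN", "ASIAN_G",
                  "NZ_M", "NZ_S", "NZ_T", "NZ_P")

# daily variety caps applied by every built-in scenario (grams edible):
# flour/pasta/oats-type staples and pulses 240 g, any single vegetable or
# fruit 200 g, vegetable oils 60 g
DEFAULT_TAG_MAXIMA <- c(staple = 240, pulse = 240, vegetable = 200,
                        fruit = 200, oil = 60)

#' Construct a dietary scenario
#'
#' @param id short identifier.
#' @param objective `"min_cost"` (NZ$/day) or `"min_ghg"` (kg CO2e/day).
#' @param budget_cap daily cost ceiling in NZ$; required when the objective
#'   is `min_ghg`, disallowed for `min_cost`.
#' @param excluded_tags foods carrying any of these tags get no decision
#'   variable (e.g. `"animal_product"` for a vegan scenario).
#' @param per_food_min named grams/day minima for specific foods (recipe
#'   components); these foods are exempt from the 10 g inclusion rule and a
#'   minimum above a default cap lifts that cap.
#' @param per_food_max named grams/day maxima for specific foods.
#' @param category_constraints list of aggregate constraints; each element is
#'   a list with a `selector` (see [select_foods()]) plus optional
#'   `total_min`, `total_max`, `per_member_max` (grams/day) and an `id`.
#' @param linked_ratios list of `list(food_a=, food_b=, ratio=)`; compiled as
#'   the equality `x_a = ratio * x_b` (e.g. flour 7:1 to oil for flatbreads).
#' @param added_sugar_max grams/day cap on the total of foods tagged
#'   `added_sugar`, or `NA`.
#' @param min_if_included semicontinuous minimum portion (grams/day): any
#'   selected food must enter at at least this amount or not at all.
#'   Condiments (tag `condiment_exempt_from_min`) and recipe-pinned foods are
#'   exempt.
#' @param tag_maxima named grams/day caps applied to every food carrying the
#'   tag (the built-ins use `DEFAULT_TAG_MAXIMA`-style variety caps).
#' @param price_overrides named NZ$ per 100 g purchased prices that replace
#'   the database price within this scenario only (e.g. bulk rice).
#' @param name human-readable label.
#' @return object of class `scenario`.
#' @export
scenario <- function(id, objective = c("min_cost", "min_ghg"),
                     budget_cap = NA_real_,
                     excluded_tags = character(0),
                     per_food_min = numeric(0),
                     per_food_max = numeric(0),
                     category_constraints = list(),
                     linked_ratios = list(),
                     added_sugar_max = NA_real_,
                     min_if_included = 10,
                     tag_maxima = numeric(0),
                     price_overrides = numeric(0),
                     name = id) {
  objective <- match.arg(objective)
  if (objective == "min_cost" && !is.na(budget_cap))
    stop("min_cost scenarios take no budget_cap (the cost IS the objective)")
  if (objective == "min_ghg" && (is.na(budget_cap) || budget_cap <= 0))
    stop("min_ghg scenarios require a positive budget_cap")
  if (any(per_food_min < 0) || any(per_food_max < 0))
    stop("per-food bounds must be non-negative")
  both <- intersect(names(per_food_min), names(per_food_max))
  bad <- both[per_food_min[both] > per_food_max[both]]
  if (length(bad))
    stop("per_food_min exceeds per_food_max for: ", paste(bad, collapse = ", "))
  structure(list(
    id = id, name = name, objective = objective, budget_cap = budget_cap,
    excluded_tags = excluded_tags,
    per_food_min = per_food_min, per_food_max = per_food_max,
    category_constraints = category_constraints,
    linked_ratios = linked_ratios, added_sugar_max = added_sugar_max,
    min_if_included = min_if_included, tag_maxima = tag_maxima,
    price_overrides = price_overrides
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$id, " (", x$name, ")\n", sep = "")
  cat("  objective: ", x$objective,
      if (!is.na(x$budget_cap)) paste0(", budget cap NZ$", x$budget_cap),
      "\n", sep = "")
  if (length(x$excluded_tags))
    cat("  excludes tags:", paste(x$excluded_tags, collapse = ", "), "\n")
  if (length(x$per_food_min))
    cat("  recipe minima:", length(x$per_food_min), "food(s)\n")
  if (length(x$category_constraints))
    cat("  aggregate constraints:", length(x$category_constraints), "\n")
  invisible(x)
}

# standard porridge breakfast + sandwich/fruit lunch shared by the NZ_*
# "familiar meals" scenarios (grams edible/day)
standard_breakfast_lunch <- function() {
  c(oats = 39, milk_powder = 25, sugar = 7, bread_wholemeal = 112,
    cheese = 24, peanut_butter = 25, margarine = 20, apple = 130)
}

nonstarchy_veg <- function(exclude_ids = character(0)) {
  list(any_of = "vegetable", none_of = "starchy_root",
       exclude_ids = exclude_ids)
}

#' Built-in dietary scenarios
#'
#' Returns one of the sixteen shipped scenarios, fully populated with its
#' objective, budget cap, recipe minima, exclusions, aggregate vegetable
#' constraints and variety caps. All sixteen share: the default nutrient
#' requirement bounds, an added-sugar cap of 60 g/day, daily maxima of 240 g
#' for flour/pasta/oats-type staples and pulses, 200 g for any single
#' vegetable or fruit, 60 g for vegetable oils, 100 g for peanut butter, and
#' the 10 g minimum portion rule (condiments exempt).
#'
#' @param id one of `C1, C2, C3, C4, G1, G2, G3, G4, MED, MED_G, ASIAN,
#'   ASIAN_G, NZ_M, NZ_S, NZ_T, NZ_P`.
#' @param match_paper if `TRUE`, use the just-binding G1 budget cap of 4.99
#'   NZ$/day instead of the nominal 5.00 (a strict "< 5" cannot be expressed
#'   in an LP; 4.99 reproduces the published binding value).
#' @return a [scenario()].
#' @examples
#' builtin_scenario("G1")$budget_cap # 5
#' builtin_scenario("C1")$added_sugar_max # 60
#' @export
builtin_scenario <- function(id, match_paper = FALSE) {
  if (!id %in% SCENARIO_IDS)
    stop("unknown scenario id '", id, "'; valid ids: ",
         paste(SCENARIO_IDS, collapse = ", "))
  base <- list(added_sugar_max = 60, tag_maxima = DEFAULT_TAG_MAXIMA,
               per_food_max = c(peanut_butter = 100))
  arg <- switch(id,
    C1 = list(name = "Minimum cost"),
    C2 = list(
      name = "Minimum cost with porridge and flatbreads",
      per_food_min = c(oats = 39, milk_powder = 25, salt = 4.5),
      linked_ratios = list(list(food_a = "flour_wholemeal",
                                food_b = "vegetable_oil", ratio = 7))),
    C3 = list(
      name = "Minimum cost, minimal cooking skills",
      excluded_tags = "requires_cooking_skill"),
    C4 = list(
      name = "Minimum cost with high vegetable intake",
      category_constraints = list(list(
        id = "veg_total", selector = nonstarchy_veg(), total_min = 412))),
    G1 = list(
      name = "Minimum emissions, budget < NZ$5/day",
      objective = "min_ghg", budget_cap = if (match_paper) 4.99 else 5.00),
    G2 = list(
      name = "Minimum emissions, budget < NZ$9/day",
      objective = "min_ghg", budget_cap = 9.00),
    G3 = list(
      name = "Minimum emissions with porridge, budget < NZ$9/day",
      objective = "min_ghg", budget_cap = 9.00,
      per_food_min = c(oats = 39, milk_powder = 25, salt = 1.5)),
    G4 = list(
      name = "Minimum emissions, vegan, budget < NZ$9/day",
      objective = "min_ghg", budget_cap = 9.00,
      excluded_tags = c("animal_product", "dairy_product", "fish", "meat",
                        "egg")),
    MED = list(
      name = "Mediterranean-style, minimum cost",
      per_food_min = c(olive_oil = 56, salt = 3),
      category_constraints = list(
        list(id = "veg_total", selector = nonstarchy_veg(), total_min = 549),
        list(id = "fruit_nut_total",
             selector = list(any_of = c("fruit", "nut")), total_min = 363),
        list(id = "fish_total", selector = list(any_of = "fish"),
             total_min = 24))),
    MED_G = list(
      name = "Mediterranean-style, minimum emissions, budget < NZ$9/day",
      objective = "min_ghg", budget_cap = 9.00,
      per_food_min = c(olive_oil = 56, salt = 3),
      category_constraints = list(
        list(id = "veg_total", selector = nonstarchy_veg(), total_min = 549),
        list(id = "fruit_nut_total",
             selector = list(any_of = c("fruit", "nut")), total_min = 363))),
    ASIAN = list(
      name = "Asian-style stir-fry, minimum cost",
      per_food_min = c(rice = 200, vegetable_oil = 14, carrots = 50,
                       cabbage = 50, broccoli = 50, onion = 50,
                       bok_choy = 50, salt = 3),
      category_constraints = list(list(
        id = "veg_total", selector = nonstarchy_veg(), total_min = 500)),
      price_overrides = c(rice = 0.18)),
    ASIAN_G = list(
      name = "Asian-style stir-fry, minimum emissions, budget < NZ$9/day",
      objective = "min_ghg", budget_cap = 9.00,
      per_food_min = c(rice = 200, vegetable_oil = 14, carrots = 50,
                       cabbage = 50, broccoli = 50, onion = 50,
                       bok_choy = 50, salt = 3),
      category_constraints = list(list(
        id = "veg_total", selector = nonstarchy_veg(), total_min = 500)),
      price_overrides = c(rice = 0.18)),
    NZ_M = list(
      name = "Familiar meals: mince on toast",
      # bread: 112 g lunch sandwiches + 28 g toast under the mince
      per_food_min = local({
        m <- standard_breakfast_lunch()
        m["bread_wholemeal"] <- m["bread_wholemeal"] + 28
        c(beef_mince = 125, onion = 28, carrots = 15, flour_wholemeal = 8,
          m, salt = 3.5)
      }),
      category_constraints = list(list(
        id = "other_veg",
        selector = list(any_of = "vegetable",
                        exclude_ids = c("onion", "carrots")),
        total_min = 40))),
    NZ_S = list(
      name = "Familiar meals: sausages and potatoes",
      per_food_min = c(sausages = 96, potatoes = 426, ice_cream = 66,
                       canned_fruit = 147, standard_breakfast_lunch(),
                       salt = 1.5),
      category_constraints = list(list(
        id = "other_veg", selector = nonstarchy_veg(), total_min = 200))),
    NZ_T = list(
      name = "Familiar meals: tuna pasta bake",
      per_food_min = c(canned_tuna = 124, pasta = 118, canned_tomatoes = 120,
                       standard_breakfast_lunch(), salt = 3),
      category_constraints = list(list(
        id = "other_veg",
        selector = nonstarchy_veg(exclude_ids = "canned_tomatoes"),
        total_min = 100))),
    NZ_P = list(
      name = "Familiar meals: Pacific-style taro and seafood",
      per_food_min = c(taro = 104, canned_tuna = 77, coconut_cream = 222,
                       onion = 14, vegetable_oil = 7,
                       standard_breakfast_lunch(), salt = 3.5))
  )
  do.call(scenario, c(list(id = id), utils::modifyList(base, arg)))
}

#' Select foods by tags, category and id
#'
#' Selector fields (all optional): `categories` (food must be in one of
#' them), `any_of` (must carry at least one tag), `all_of` (must carry all),
#' `none_of` (must carry none), `exclude_ids` (dropped regardless).
#'
#' @param db a `food_db`.
#' @param selector a list of the fields above.
#' @return character vector of matching food ids.
#' @export
select_foods <- function(db, selector) {
  keep <- rep(TRUE, n_foods(db))
  tag_list <- strsplit(db$items$tags, ";", fixed = TRUE)
  tag_list <- lapply(tag_list, trimws)
  if (!is.null(selector$categories))
    keep <- keep & db$items$category %in% selector$categories
  if (!is.null(selector$any_of))
    keep <- keep & vapply(tag_list, function(tt)
      any(selector$any_of %in% tt), logical(1))
  if (!is.null(selector$all_of))
    keep <- keep & vapply(tag_list, function(tt)
      all(selector$all_of %in% tt), logical(1))
  if (!is.null(selector$none_of))
    keep <- keep & vapply(tag_list, function(tt)
      !any(selector$none_of %in% tt), logical(1))
  if (!is.null(selector$exclude_ids))
    keep <- keep & !db$items$id %in% selector$exclude_ids
  db$items$id[keep]
}

#' Compile a scenario against a database into a linear constraint system
#'
#' Decision variables are grams edible/day of each non-excluded food. Rows
#' are emitted in a fixed, documented order (nutrient rows in
#' requirement-table order, then category aggregates in scenario order, the
#' added-sugar cap, linked-ratio equalities, and the budget row), so
#' compilation is deterministic.
#'
#' Cost coefficients charge the purchased weight,
#' `price / (100 * (1 - wastage))` NZ$ per gram edible; GHG likewise,
#' `ghg_factor / (1000 * (1 - wastage))` kg CO2e per gram edible (emissions
#' accrue to everything bought, including the wasted share). Nutrient
#' coefficients are per gram edible, `content / 100`.
#'
#' @param scn a [scenario()].
#' @param db a `food_db`.
#' @return object of class `diet_lp`: the matrix `A` with `dir`, `rhs` and
#'   `row_ids`; per-variable `lower`/`upper`; coefficient vectors `cost`,
#'   `ghg` and `objective_coef`; bookkeeping for the minimum-portion rule.
#' @export
compile_constraints <- function(scn, db) {
  stopifnot(inherits(scn, "scenario"), inherits(db, "food_db"))
  tag_list <- lapply(strsplit(db$items$tags, ";", fixed = TRUE), trimws)
  excl <- vapply(tag_list, function(tt) any(scn$excluded_tags %in% tt),
                 logical(1))
  ids <- db$items$id[!excl]
  if (!length(ids)) stop("scenario excludes every food in the database")
  # minima and linked ratios force foods into the diet, so a dangling id is
  # an error; maxima and price overrides on absent foods are vacuous
  ref <- c(names(scn$per_food_min),
           unlist(lapply(scn$linked_ratios, function(l)
             c(l$food_a, l$food_b))))
  missing_ids <- setdiff(ref, db$items$id)
  if (length(missing_ids))
    stop("scenario references food id(s) absent from the database: ",
         paste(unique(missing_ids), collapse = ", "))
  dropped <- intersect(ref, db$items$id[excl])
  if (length(dropped))
    stop("scenario pins food(s) that its own exclusions remove: ",
         paste(unique(dropped), collapse = ", "))
  scn$per_food_max <- scn$per_food_max[names(scn$per_food_max) %in% ids]
  scn$price_overrides <-
    scn$price_overrides[names(scn$price_overrides) %in% ids]

  sub <- db$items[match(ids, db$items$id), ]
  nut <- db$nutrients[ids, , drop = FALSE]
  n <- length(ids)
  tags_sub <- tag_list[!excl]

  price <- sub$price_mean
  ov <- scn$price_overrides
  if (length(ov)) price[match(names(ov), ids)] <- ov
  w <- sub$wastage_mean
  cost_coef <- price / (100 * (1 - w))        # NZ$ per g edible
  ghg_coef <- sub$ghg_factor / (1000 * (1 - w)) # kg CO2e per g edible

  lower <- rep(0, n)
  upper <- rep(Inf, n)
  if (length(scn$tag_maxima)) {
    for (tg in names(scn$tag_maxima)) {
      hit <- vapply(tags_sub, function(tt) tg %in% tt, logical(1))
      upper[hit] <- pmin(upper[hit], scn$tag_maxima[[tg]])
    }
  }
  if (length(scn$per_food_max)) {
    j <- match(names(scn$per_food_max), ids)
    upper[j] <- pmin(upper[j], scn$per_food_max)
  }
  if (length(scn$per_food_min)) {
    j <- match(names(scn$per_food_min), ids)
    lower[j] <- scn$per_food_min
    # a recipe minimum above a default variety cap lifts the cap
    upper[j] <- pmax(upper[j], lower[j])
  }

  req <- db$requirements
  # cooking-salt minima yield to the sodium ceiling: trim the forced salt so
  # recipe components can never push sodium past its upper bound (the bound
  # row itself always stays active)
  if ("sodium" %in% colnames(nut)) {
    na_max <- req$max[req$nutrient_id == "sodium"]
    if (length(na_max) == 1L && !is.na(na_max)) {
      is_salt <- vapply(tags_sub, function(tt) "salt" %in% tt, logical(1))
      salt_j <- which(is_salt & lower > 0)
      if (length(salt_j)) {
        na_dens <- nut[, "sodium"] / 100  # mg per g edible
        forced_other <- sum(lower[-salt_j] * na_dens[-salt_j])
        headroom <- 0.95 * max(0, na_max - forced_other)
        for (j in salt_j) if (na_dens[j] > 0)
          lower[j] <- min(lower[j], headroom / na_dens[j])
      }
    }
  }

  rows <- list(); dirs <- character(0); rhs <- numeric(0); rid <- character(0)
  for (k in seq_len(nrow(req))) {
    nid <- req$nutrient_id[k]
    coefs <- nut[, nid] / 100
    if (!is.na(req$min[k])) {
      rows <- c(rows, list(coefs)); dirs <- c(dirs, ">=")
      rhs <- c(rhs, req$min[k]); rid <- c(rid, paste0("nut_min_", nid))
    }
    if (!is.na(req$max[k])) {
      rows <- c(rows, list(coefs)); dirs <- c(dirs, "<=")
      rhs <- c(rhs, req$max[k]); rid <- c(rid, paste0("nut_max_", nid))
    }
  }
  for (cc in scn$category_constraints) {
    members <- intersect(select_foods(db, cc$selector), ids)
    cid <- if (is.null(cc$id)) "category" else cc$id
    if (!length(members)) {
      if (!is.null(cc$total_min) && cc$total_min > 0)
        stop("category constraint '", cid,
             "' selects no foods but requires a positive total")
      next
    }
    coefs <- as.numeric(ids %in% members)
    if (!is.null(cc$total_min)) {
      rows <- c(rows, list(coefs)); dirs <- c(dirs, ">=")
      rhs <- c(rhs, cc$total_min); rid <- c(rid, paste0("cat_min_", cid))
    }
    if (!is.null(cc$total_max)) {
      rows <- c(rows, list(coefs)); dirs <- c(dirs, "<=")
      rhs <- c(rhs, cc$total_max); rid <- c(rid, paste0("cat_max_", cid))
    }
    if (!is.null(cc$per_member_max)) {
      j <- match(members, ids)
      upper[j] <- pmin(upper[j], cc$per_member_max)
      upper[j] <- pmax(upper[j], lower[j])
    }
  }
  if (!is.na(scn$added_sugar_max)) {
    hit <- vapply(tags_sub, function(tt) "added_sugar" %in% tt, logical(1))
    if (any(hit)) {
      rows <- c(rows, list(as.numeric(hit))); dirs <- c(dirs, "<=")
      rhs <- c(rhs, scn$added_sugar_max); rid <- c(rid, "added_sugar_max")
    }
  }
  for (lr in scn$linked_ratios) {
    ja <- match(lr$food_a, ids); jb <- match(lr$food_b, ids)
    coefs <- rep(0, n); coefs[ja] <- 1; coefs[jb] <- -lr$ratio
    rows <- c(rows, list(coefs)); dirs <- c(dirs, "=")
    rhs <- c(rhs, 0)
    rid <- c(rid, paste0("ratio_", lr$food_a, "_", lr$food_b))
  }
  if (!is.na(scn$budget_cap)) {
    rows <- c(rows, list(cost_coef)); dirs <- c(dirs, "<=")
    rhs <- c(rhs, scn$budget_cap); rid <- c(rid, "budget")
  }

  if (any(lower > upper + 1e-12)) {
    bad <- ids[lower > upper + 1e-12]
    stop("infeasible per-food bound pair (min > max) for: ",
         paste(bad, collapse = ", "))
  }

  A <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, n)
  rownames(A) <- rid
  colnames(A) <- ids
  exempt <- vapply(tags_sub, function(tt)
    "condiment_exempt_from_min" %in% tt, logical(1)) | lower > 0
  structure(list(
    scenario_id = scn$id, objective = scn$objective,
    food_ids = ids, A = A, dir = dirs, rhs = rhs, row_ids = rid,
    lower = lower, upper = upper,
    cost = cost_coef, ghg = ghg_coef,
    objective_coef = if (scn$objective == "min_cost") cost_coef else ghg_coef,
    nutrients = nut, min_if_included = scn$min_if_included,
    exempt_from_min = exempt
  ), class = "diet_lp")
}

#' @export
print.diet_lp <- function(x, ...) {
  cat("<diet_lp> scenario ", x$scenario_id, ": ", length(x$food_ids),
      " variables, ", nrow(x$A), " rows (objective ", x$objective, ")\n",
      sep = "")
  invisible(x)
}

#' Read or write a scenario definition file
#'
#' Scenarios serialize to a small JSON document (YAML also readable when the
#' `yaml` package is installed). The sixteen built-ins ship under
#' `system.file("extdata", "scenarios", package = "dietlp")` as copy-editable
#' starting points.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return `read_scenario`: a [scenario()].
#' @export
read_scenario <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML scenarios requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  num <- function(x) if (is.null(x) || !length(x)) numeric(0) else
    vapply(x, as.numeric, numeric(1))
  chr <- function(x) if (is.null(x) || !length(x)) character(0) else
    vapply(x, as.character, character(1))
  scalar <- function(x, default) {
    if (is.null(x) || (is.list(x) && !length(x))) return(default)
    if (is.list(x)) x <- x[[1]]
    if (is.null(x)) default else x
  }
  parse_cc <- function(cc) {
    sel <- lapply(cc$selector, chr)
    list(id = scalar(cc$id, NULL), selector = sel,
         total_min = scalar(cc$total_min, NULL),
         total_max = scalar(cc$total_max, NULL),
         per_member_max = scalar(cc$per_member_max, NULL))
  }
  parse_lr <- function(lr)
    list(food_a = scalar(lr$food_a, NULL), food_b = scalar(lr$food_b, NULL),
         ratio = scalar(lr$ratio, NULL))
  scenario(
    id = scalar(doc$id, stop("scenario file lacks an id")),
    objective = scalar(doc$objective, "min_cost"),
    budget_cap = as.numeric(scalar(doc$budget_cap, NA_real_)),
    excluded_tags = chr(doc$excluded_tags),
    per_food_min = num(doc$per_food_min),
    per_food_max = num(doc$per_food_max),
    category_constraints = if (is.null(doc$category_constraints)) list()
                           else lapply(doc$category_constraints, parse_cc),
    linked_ratios = if (is.null(doc$linked_ratios)) list()
                    else lapply(doc$linked_ratios, parse_lr),
    added_sugar_max = as.numeric(scalar(doc$added_sugar_max, NA_real_)),
    min_if_included = scalar(doc$min_if_included, 10),
    tag_maxima = num(doc$tag_maxima),
    price_overrides = num(doc$price_overrides),
    name = scalar(doc$name, scalar(doc$id, ""))
  )
}

#' @rdname read_scenario
#' @param scn a [scenario()].
#' @return `write_scenario`: `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  doc <- unclass(scn)
  doc$per_food_min <- as.list(doc$per_food_min)
  doc$per_food_max <- as.list(doc$per_food_max)
  doc$tag_maxima <- as.list(doc$tag_maxima)
  doc$price_overrides <- as.list(doc$price_overrides)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
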