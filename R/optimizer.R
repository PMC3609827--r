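#' @title Diet solutions
#' @description
#' A `diet_solution` holds optimized (or evaluated) daily food quantities in
#' grams edible/day together with the derived daily cost (NZ$), greenhouse-gas
#' emissions (kg CO2e), nutrient intakes, solver status and the constraint
#' rows binding at the optimum.
#' @name diet_solution
NULL

new_diet_solution <- function(quantities, objective, objective_value,
                              cost, ghg, nutrient_intakes, status,
                              binding_constraints = character(0)) {
  structure(list(
    quantities = quantities, objective = objective,
    objective_value = objective_value, cost = cost, ghg = ghg,
    nutrient_intakes = nutrient_intakes, status = status,
    binding_constraints = binding_constraints,
    n_foods_selected = sum(quantities > 1e-7, na.rm = TRUE)
  ), class = "diet_solution")
}

#' @export
print.diet_solution <- function(x, digits = 2, ...) {
  cat("<diet_solution> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal" || x$status == "evaluated") {
    cat(sprintf("  cost NZ$%.2f/day, GHG %.2f kg CO2e/day, %d foods selected\n",
                x$cost, x$ghg, x$n_foods_selected))
    q <- sort(x$quantities[x$quantities > 1e-7], decreasing = TRUE)
    if (length(q)) {
      show <- utils::head(q, 12)
      cat("  top quantities (g edible/day):\n")
      for (i in seq_along(show))
        cat(sprintf("    %-22s %8.1f\n", names(show)[i], show[i]))
      if (length(q) > length(show))
        cat("    ... and ", length(q) - length(show), " more\n", sep = "")
    }
  }
  invisible(x)
}

solution_from_x <- function(x, sys, status) {
  if (status != "optimal") {
    return(new_diet_solution(
      quantities = stats::setNames(rep(NA_real_, length(sys$food_ids)),
                                   sys$food_ids),
      objective = sys$objective, objective_value = NA_real_,
      cost = NA_real_, ghg = NA_real_,
      nutrient_intakes = stats::setNames(
        rep(NA_real_, ncol(sys$nutrients)), colnames(sys$nutrients)),
      status = status))
  }
  names(x) <- sys$food_ids
  intakes <- as.numeric(crossprod(sys$nutrients, x)) / 100
  names(intakes) <- colnames(sys$nutrients)
  cost <- sum(sys$cost * x)
  ghg <- sum(sys$ghg * x)
  binding <- character(0)
  if (nrow(sys$A)) {
    lhs <- as.numeric(sys$A %*% x)
    tight <- abs(lhs - sys$rhs) <= 1e-6 * pmax(1, abs(sys$rhs))
    binding <- sys$row_ids[tight]
  }
  new_diet_solution(
    quantities = x, objective = sys$objective,
    objective_value = if (sys$objective == "min_cost") cost else ghg,
    cost = cost, ghg = ghg, nutrient_intakes = intakes,
    status = "optimal", binding_constraints = binding)
}

solve_compiled <- function(sys) {
  res <- solve_lp(sys$objective_coef, sys$A, sys$dir, sys$rhs,
                  lower = sys$lower, upper = sys$upper)
  list(res = res, sol = solution_from_x(res$x, sys, res$status))
}

#' Optimize a diet for a scenario
#'
#' Compiles the scenario against the database and minimizes its objective
#' (daily cost or daily GHG emissions) with the simplex solver, then enforces
#' the minimum-portion rule: every selected food must appear at
#' `min_if_included` grams (default 10) or not at all, except condiments and
#' recipe-pinned foods. Quantities strictly between 0 and the minimum make a
#' diet impractical (trace purchases), so they are disallowed.
#'
#' Two enforcement strategies are available. `"iterative"` (default)
#' re-solves the LP after fixing sub-minimum foods to zero (forcing them up
#' to the minimum instead when fixing makes the system infeasible), repeating
#' to a fixpoint; it is fast and matches plain-simplex practice.
#' `"milp"` performs exact branch-and-bound over the semicontinuous choices
#' (each violating food branches into "absent" and "at least the minimum")
#' and is intended for small instances and as the oracle for the heuristic.
#'
#' @param db a `food_db`.
#' @param scn a [scenario()].
#' @param method `"iterative"` or `"milp"`.
#' @param max_rounds fixpoint cap for the iterative strategy.
#' @return a `diet_solution`.
#' @export
optimize_diet <- function(db, scn, method = c("iterative", "milp"),
                          max_rounds = 20L) {
  method <- match.arg(method)
  sys <- compile_constraints(scn, db)
  if (method == "iterative") optimize_iterative(sys, max_rounds)
  else optimize_milp(sys)
}

sub_minimum <- function(x, sys, tol = 1e-6) {
  which(!sys$exempt_from_min &
          x > tol &
          x < sys$min_if_included - tol)
}

optimize_iterative <- function(sys, max_rounds = 20L) {
  cur <- sys
  out <- solve_compiled(cur)
  if (out$res$status != "optimal") return(out$sol)
  for (round in seq_len(max_rounds)) {
    viol <- sub_minimum(out$res$x, cur)
    if (!length(viol)) break
    fixed <- cur
    fixed$upper[viol] <- 0
    try_fix <- solve_compiled(fixed)
    if (try_fix$res$status == "optimal") {
      cur <- fixed
      out <- try_fix
      next
    }
    # zeroing them breaks feasibility: force them up to the minimum instead
    forced <- cur
    forced$lower[viol] <- forced$min_if_included
    forced$upper[viol] <- pmax(forced$upper[viol], forced$min_if_included)
    try_force <- solve_compiled(forced)
    if (try_force$res$status != "optimal") return(try_force$sol)
    cur <- forced
    out <- try_force
  }
  out$sol
}

optimize_milp <- function(sys, tol = 1e-9) {
  best <- new.env(parent = emptyenv())
  best$value <- Inf
  best$x <- NULL
  explore <- function(lower, upper) {
    node <- sys
    node$lower <- lower
    node$upper <- upper
    res <- solve_lp(node$objective_coef, node$A, node$dir, node$rhs,
                    lower = lower, upper = upper)
    if (res$status != "optimal") return(invisible(NULL))
    if (is.finite(best$value) &&
        res$objective_value >= best$value - 1e-12 * max(1, abs(best$value)))
      return(invisible(NULL))
    viol <- sub_minimum(res$x, node)
    if (!length(viol)) {
      best$value <- res$objective_value
      best$x <- res$x
      return(invisible(NULL))
    }
    j <- viol[1L]
    up0 <- upper; up0[j] <- 0
    explore(lower, up0)
    lo1 <- lower; lo1[j] <- sys$min_if_included
    up1 <- upper; up1[j] <- max(upper[j], sys$min_if_included)
    explore(lo1, up1)
    invisible(NULL)
  }
  explore(sys$lower, sys$upper)
  if (is.null(best$x))
    return(solution_from_x(rep(NA_real_, length(sys$food_ids)), sys,
                           "infeasible"))
  solution_from_x(best$x, sys, "optimal")
}

#' Evaluate a fixed diet (no optimization)
#'
#' Computes the daily cost, GHG emissions and nutrient intakes of a given
#' food composition — e.g. a typical national diet used as a comparator for
#' the optimized scenarios. No constraints are checked.
#'
#' @param db a `food_db`.
#' @param quantities named numeric vector, grams edible/day per food id.
#' @return a `diet_solution` with status `"evaluated"`.
#' @examples
#' \dontrun{
#' evaluate_diet(db, c(flour_wholemeal = 240, carrots = 100))
#' }
#' @export
evaluate_diet <- function(db, quantities) {
  if (any(quantities < 0)) stop("quantities must be non-negative")
  unknown <- setdiff(names(quantities), db$items$id)
  if (length(unknown))
    stop("unknown food id(s): ", paste(unknown, collapse = ", "))
  x <- stats::setNames(rep(0, n_foods(db)), db$items$id)
  x[names(quantities)] <- quantities
  w <- db$items$wastage_mean
  cost <- sum(x * db$items$price_mean / (100 * (1 - w)))
  ghg <- sum(x * db$items$ghg_factor / (1000 * (1 - w)))
  intakes <- as.numeric(crossprod(db$nutrients, x)) / 100
  names(intakes) <- colnames(db$nutrients)
  new_diet_solution(
    quantities = x, objective = "evaluation", objective_value = NA_real_,
    cost = cost, ghg = ghg, nutrient_intakes = intakes, status = "evaluated")
}

#' Rescale a diet to a target daily energy intake
#'
#' Multiplies all quantities by `target_kj / current_energy`, so the rescaled
#' diet supplies exactly the target energy (food composition unchanged).
#'
#' @param quantities named grams edible/day.
#' @param db a `food_db` (supplies the energy densities).
#' @param target_kj desired daily energy in kJ.
#' @return rescaled named quantity vector.
#' @export
scale_to_energy <- function(quantities, db, target_kj) {
  unknown <- setdiff(names(quantities), db$items$id)
  if (length(unknown))
    stop("unknown food id(s): ", paste(unknown, collapse = ", "))
  dens <- db$nutrients[names(quantities), "energy"] / 100
  cur <- sum(quantities * dens)
  if (cur <= 0) stop("diet supplies no energy; cannot rescale")
  quantities * (target_kj / cur)
}

# JSON-friendly form: named vectors become objects, not bare arrays
solution_as_doc <- function(sol) {
  doc <- unclass(sol)
  doc$quantities <- as.list(doc$quantities)
  doc$nutrient_intakes <- as.list(doc$nutrient_intakes)
  doc
}

#' Write a diet solution to disk
#'
#' JSON keeps the full object; CSV is a flat per-food table (food id, grams
#' edible, grams purchased, cost share, GHG share) for spreadsheet
#' inspection.
#'
#' @param sol a `diet_solution`.
#' @param db the `food_db` it was computed against (needed for purchased
#'   weights in the CSV).
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, db, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(solution_as_doc(sol), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    q <- sol$quantities[sol$quantities > 1e-7]
    idx <- match(names(q), db$items$id)
    w <- db$items$wastage_mean[idx]
    cost_i <- q * db$items$price_mean[idx] / (100 * (1 - w))
    ghg_i <- q * db$items$ghg_factor[idx] / (1000 * (1 - w))
    out <- data.frame(
      food_id = names(q),
      grams_edible = as.numeric(q),
      grams_purchased = as.numeric(purchased_weight(q, w)),
      cost_share = if (sum(cost_i) > 0) cost_i / sum(cost_i) else 0,
      ghg_share = if (sum(ghg_i) > 0) ghg_i / sum(ghg_i) else 0
    )
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
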