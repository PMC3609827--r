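#' @title Food database objects
#' @description
#' A `food_db` bundles everything the optimizer needs: one row per food with
#' purchase price, wastage and greenhouse-gas (GHG) factor; a food-by-nutrient
#' content matrix; and the daily nutrient requirement table that supplies the
#' constraint bounds.
#'
#' Unit conventions, relied on throughout the package:
#' * food quantities are grams of EDIBLE (prepared, ready-to-eat) weight/day;
#' * `price_mean`/`price_sd` are NZ$ per 100 g PURCHASED weight;
#' * nutrient contents are per 100 g EDIBLE weight;
#' * `ghg_factor` is kg CO2-equivalents per kg PURCHASED weight;
#' * `wastage_mean` is the fraction of purchased weight never eaten
#'   (inedible portion plus discarded edible food), so
#'   purchased = edible / (1 - wastage).
#' @name food_db
NULL

# canonical nutrient ids and their fixed units (loaders reject other units)
NUTRIENT_UNITS <- c(
  energy    = "kJ",
  protein   = "g",
  sat_fat   = "g",
  pufa      = "g",
  fiber     = "g",
  sugars    = "g",
  sodium    = "mg",
  potassium = "mg",
  calcium   = "mg",
  iron      = "mg",
  zinc      = "mg",
  selenium  = "ug",
  vit_a     = "ug RE",
  thiamine  = "mg",
  vit_c     = "mg",
  vit_e     = "mg"
)

FOOD_CATEGORIES <- c("fruit_veg", "cereal_grain", "pulse_seed_nut", "dairy",
                     "meat_fish_egg", "fat_oil", "condiment", "other")

KNOWN_TAGS <- c("vegetable", "starchy_root", "fruit", "nut", "animal_product",
                "dairy_product", "fish", "meat", "egg",
                "requires_cooking_skill", "condiment_exempt_from_min",
                "added_sugar", "salt", "staple", "pulse", "oil")

#' Default daily nutrient requirements
#'
#' The requirement set used by all built-in scenarios: estimated average
#' requirements (EARs) as lower bounds for adult men, with upper limits for
#' sodium, saturated fat and vitamin A. Iron uses the female EAR (8 mg/day),
#' the stricter of the two sexes. `sd` is the population-heterogeneity
#' standard deviation used by the Monte Carlo engine when redrawing minima:
#' 184.4 kJ for energy, 5% of the minimum elsewhere, 0 for pure upper bounds.
#'
#' @return data.frame with columns `nutrient_id`, `unit`, `min`, `max`, `sd`.
#' @export
default_requirements <- function() {
  req <- data.frame(
    nutrient_id = c("energy", "sat_fat", "pufa", "protein", "fiber",
                    "sodium", "potassium", "calcium", "iron", "zinc",
                    "selenium", "vit_a", "thiamine", "vit_c", "vit_e"),
    min = c(11450, NA, 13.1, 52, 30, NA, 3800, 840, 8, 12, 60, 625, 1, 30, 10),
    max = c(NA, 30, NA, NA, NA, 2300, NA, NA, NA, NA, NA, 3000, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  req$unit <- unname(NUTRIENT_UNITS[req$nutrient_id])
  req$sd <- ifelse(is.na(req$min), 0, 0.05 * req$min)
  req$sd[req$nutrient_id == "energy"] <- 184.4
  req[, c("nutrient_id", "unit", "min", "max", "sd")]
}

#' Construct a food database
#'
#' @param items data.frame with columns `id`, `name`, `category`,
#'   `price_mean`, `price_sd`, `wastage_mean`, `wastage_sd`, `ghg_factor`,
#'   `tags` (character, tags separated by `;`, may be empty).
#' @param nutrients numeric matrix, rows = foods (rownames must equal
#'   `items$id`), columns = nutrient ids; amounts per 100 g edible weight.
#' @param requirements requirement table as in [default_requirements()].
#' @param metadata list of provenance fields (free form; a `seed` entry is
#'   conventional for generated databases).
#' @return validated object of class `food_db`.
#' @export
food_db <- function(items, nutrients, requirements = default_requirements(),
                    metadata = list()) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (!"price_sd" %in% names(items)) items$price_sd <- NA_real_
  if (!"tags" %in% names(items)) items$tags <- ""
  items$tags[is.na(items$tags)] <- ""
  nutrients <- as.matrix(nutrients)
  db <- structure(
    list(items = items, nutrients = nutrients,
         requirements = as.data.frame(requirements, stringsAsFactors = FALSE),
         metadata = metadata),
    class = "food_db"
  )
  validate_food_db(db)
  db
}

#' Validate a food database
#'
#' Checks every structural invariant and raises a single error listing all
#' violations found, so a malformed file can be fixed in one pass.
#'
#' @param db a `food_db`.
#' @return `db`, invisibly, if valid.
#' @export
validate_food_db <- function(db) {
  p <- character(0)
  it <- db$items
  req <- db$requirements
  need <- c("id", "name", "category", "price_mean", "wastage_mean",
            "wastage_sd", "ghg_factor")
  miss <- setdiff(need, names(it))
  if (length(miss))
    p <- c(p, paste0("missing food column(s): ", paste(miss, collapse = ", ")))
  needr <- c("nutrient_id", "unit", "min", "max", "sd")
  missr <- setdiff(needr, names(req))
  if (length(missr))
    p <- c(p, paste0("missing requirement column(s): ",
                     paste(missr, collapse = ", ")))
  if (length(p)) stop("invalid food database:\n  - ",
                      paste(p, collapse = "\n  - "), call. = FALSE)

  if (nrow(it) == 0L) p <- c(p, "database contains no foods")
  dup <- unique(it$id[duplicated(it$id)])
  if (length(dup))
    p <- c(p, paste0("duplicated food id(s): ", paste(dup, collapse = ", ")))
  bad <- it$id[!is.na(it$price_mean) & it$price_mean <= 0]
  if (length(bad))
    p <- c(p, paste0("non-positive price_mean for: ",
                     paste(bad, collapse = ", ")))
  if (anyNA(it$price_mean)) p <- c(p, "price_mean contains NA")
  bw <- it$id[is.na(it$wastage_mean) | it$wastage_mean < 0 |
                it$wastage_mean > 0.95]
  if (length(bw))
    p <- c(p, paste0("wastage_mean outside [0, 0.95] for: ",
                     paste(bw, collapse = ", ")))
  bg <- it$id[is.na(it$ghg_factor) | it$ghg_factor < 0]
  if (length(bg))
    p <- c(p, paste0("negative or missing ghg_factor for: ",
                     paste(bg, collapse = ", ")))
  bc <- unique(it$category[!it$category %in% FOOD_CATEGORIES])
  if (length(bc))
    p <- c(p, paste0("unknown category: ", paste(bc, collapse = ", "),
                     " (expected one of ",
                     paste(FOOD_CATEGORIES, collapse = ", "), ")"))
  if (!identical(rownames(db$nutrients), it$id))
    p <- c(p, "nutrient matrix rownames must equal items$id (same order)")
  unk <- setdiff(colnames(db$nutrients), req$nutrient_id)
  if (length(unk))
    p <- c(p, paste0("nutrient id(s) absent from the requirement table: ",
                     paste(unk, collapse = ", ")))
  if (any(db$nutrients < 0, na.rm = TRUE) || anyNA(db$nutrients))
    p <- c(p, "nutrient contents must be non-negative and non-missing")
  # requirement rows
  nomin <- req$nutrient_id[is.na(req$min) & is.na(req$max)]
  if (length(nomin))
    p <- c(p, paste0("requirement rows with neither min nor max: ",
                     paste(nomin, collapse = ", ")))
  flip <- req$nutrient_id[!is.na(req$min) & !is.na(req$max) & req$min > req$max]
  if (length(flip))
    p <- c(p, paste0("requirement min exceeds max for: ",
                     paste(flip, collapse = ", ")))
  known <- intersect(req$nutrient_id, names(NUTRIENT_UNITS))
  wrongu <- known[req$unit[match(known, req$nutrient_id)] !=
                    NUTRIENT_UNITS[known]]
  if (length(wrongu))
    p <- c(p, paste0("unit mismatch (units are fixed per nutrient, no silent",
                     " conversion) for: ", paste(wrongu, collapse = ", ")))
  if (length(p))
    stop("invalid food database:\n  - ", paste(p, collapse = "\n  - "),
         call. = FALSE)
  invisible(db)
}

#' @export
print.food_db <- function(x, ...) {
  cat("<food_db> ", nrow(x$items), " foods, ",
      ncol(x$nutrients), " nutrients, ",
      nrow(x$requirements), " requirement rows\n", sep = "")
  tab <- table(x$items$category)
  cat("  categories: ",
      paste(names(tab), tab, sep = ":", collapse = ", "), "\n", sep = "")
  if (!is.null(x$metadata$provenance))
    cat("  provenance: ", x$metadata$provenance, "\n", sep = "")
  invisible(x)
}

#' @rdname food_db_accessors
#' @title Small accessors for food databases
#' @param db a `food_db`.
#' @return `food_ids`/`nutrient_ids`: character vectors; `n_foods`: integer;
#'   `has_tag`: named logical vector over foods.
#' @export
food_ids <- function(db) db$items$id

#' @rdname food_db_accessors
#' @export
n_foods <- function(db) nrow(db$items)

#' @rdname food_db_accessors
#' @export
nutrient_ids <- function(db) colnames(db$nutrients)

#' @rdname food_db_accessors
#' @param tag a single tag name, e.g. `"vegetable"`.
#' @export
has_tag <- function(db, tag) {
  out <- vapply(strsplit(db$items$tags, ";", fixed = TRUE),
                function(tt) tag %in% trimws(tt), logical(1))
  names(out) <- db$items$id
  out
}

#' Purchased weight needed to yield a given edible weight
#'
#' Wastage (inedible portions plus discarded food) inflates the amount that
#' must be bought: purchased = edible / (1 - wastage).
#'
#' @param edible_g grams of edible food required (>= 0).
#' @param wastage wastage fraction in `[0, 0.95]`.
#' @return grams purchased.
#' @examples
#' purchased_weight(100, 0.45) # 181.81...
#' @export
purchased_weight <- function(edible_g, wastage) {
  if (any(edible_g < 0)) stop("edible_g must be non-negative")
  if (any(wastage < 0 | wastage > 0.95))
    stop("wastage must lie in [0, 0.95]")
  edible_g / (1 - wastage)
}

#' Combine inedible-portion and discarded-food fractions
#'
#' For databases that record the inedible fraction (skins, bones) separately
#' from post-purchase waste, the two act multiplicatively on the surviving
#' weight: combined = 1 - (1 - inedible)(1 - waste).
#'
#' @param inedible_fraction,waste_fraction fractions in `[0, 1)`.
#' @return single combined wastage fraction.
#' @examples
#' combine_wastage(0.25, 0.20) # 0.40
#' @export
combine_wastage <- function(inedible_fraction, waste_fraction) {
  if (any(inedible_fraction < 0 | inedible_fraction >= 1) ||
      any(waste_fraction < 0 | waste_fraction >= 1))
    stop("fractions must lie in [0, 1)")
  1 - (1 - inedible_fraction) * (1 - waste_fraction)
}

#' Load a food database from disk
#'
#' Two on-disk layouts are supported.
#' `csv_pair`: a directory holding `foods.csv` (one row per food; nutrient
#' columns prefixed `nut_`) and `requirements.csv`
#' (`nutrient_id,unit,min,max,sd`).
#' `json`: one document with `items` (nutrient map per food), `requirements`
#' and `metadata`.
#'
#' @param path directory (csv_pair) or file (json).
#' @param format `"csv_pair"` or `"json"`.
#' @return a validated [food_db()].
#' @seealso [write_food_database()]
#' @export
load_food_database <- function(path, format = c("csv_pair", "json")) {
  format <- match.arg(format)
  if (format == "csv_pair") {
    fpath <- file.path(path, "foods.csv")
    rpath <- file.path(path, "requirements.csv")
    if (!file.exists(fpath)) stop("missing foods.csv under ", path)
    if (!file.exists(rpath)) stop("missing requirements.csv under ", path)
    foods <- utils::read.csv(fpath, stringsAsFactors = FALSE,
                             check.names = FALSE)
    req <- utils::read.csv(rpath, stringsAsFactors = FALSE)
    nut_cols <- grep("^nut_", names(foods), value = TRUE)
    base_need <- c("id", "name", "category", "price_mean", "wastage_mean",
                   "wastage_sd", "ghg_factor")
    miss <- setdiff(base_need, names(foods))
    if (length(miss))
      stop("foods.csv is missing required column(s): ",
           paste(miss, collapse = ", "))
    nutrients <- as.matrix(foods[, nut_cols, drop = FALSE])
    colnames(nutrients) <- sub("^nut_", "", nut_cols)
    rownames(nutrients) <- foods$id
    items <- foods[, setdiff(names(foods), nut_cols), drop = FALSE]
    food_db(items, nutrients, req,
            metadata = list(provenance = paste0("loaded from ", path)))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    items <- as.data.frame(doc$items, stringsAsFactors = FALSE)
    nut <- doc$nutrients
    nutrients <- as.matrix(as.data.frame(nut[setdiff(names(nut), "id")]))
    rownames(nutrients) <- nut$id
    nutrients <- nutrients[match(items$id, rownames(nutrients)), ,
                           drop = FALSE]
    md <- if (is.null(doc$metadata)) list() else as.list(doc$metadata)
    food_db(items, nutrients, as.data.frame(doc$requirements), metadata = md)
  }
}

#' Write a food database to disk
#'
#' Inverse of [load_food_database()]; a written database reloads with all
#' text fields identical and numeric fields equal to full double precision.
#'
#' @param db a `food_db`.
#' @param path directory (csv_pair; created if needed) or file path (json).
#' @param format `"csv_pair"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_food_database <- function(db, path, format = c("csv_pair", "json")) {
  format <- match.arg(format)
  if (format == "csv_pair") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nut <- as.data.frame(db$nutrients)
    names(nut) <- paste0("nut_", names(nut))
    foods <- cbind(db$items, nut)
    utils::write.csv(foods, file.path(path, "foods.csv"), row.names = FALSE)
    utils::write.csv(db$requirements, file.path(path, "requirements.csv"),
                     row.names = FALSE)
  } else {
    nut <- cbind(data.frame(id = rownames(db$nutrients)),
                 as.data.frame(db$nutrients))
    doc <- list(items = db$items, nutrients = nut,
                requirements = db$requirements, metadata = db$metadata)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
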