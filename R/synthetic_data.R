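#' @title Synthetic food databases
#' @description
#' Generates food databases with the statistical structure of a national
#' food-price/composition table: ~76 items across categories, staple grains
#' that are cheap per kJ, plant foods with low greenhouse-gas factors and
#' ruminant meats with high ones, wastage fractions with small uncertainty,
#' and monthly price variability expressed as category-typical coefficients
#' of variation. A fixed catalogue of "anchor" foods carries the ids the
#' built-in scenarios reference (flour, oats, olive oil, beef mince, taro,
#' ...); filler foods are drawn from category-level ranges to reach the
#' requested size. Values are synthetic: realistic in structure and order of
#' magnitude, not transcriptions of any real price or composition survey.
#' @name synthetic_data
NULL

# nutrient order used by the anchor catalogue
NUT_ORDER <- c("energy", "protein", "sat_fat", "pufa", "fiber", "sodium",
               "potassium", "calcium", "iron", "zinc", "selenium", "vit_a",
               "thiamine", "vit_c", "vit_e")

# id, name, category, price NZ$/100 g purchased, wastage mean, wastage sd,
# ghg kg CO2e/kg purchased, tags, then the 15 nutrient densities per 100 g
# edible in NUT_ORDER
anchor_catalogue <- function() {
  a <- function(id, name, cat, price, w, wsd, ghg, tags, nut) {
    list(id = id, name = name, category = cat, price = price, w = w,
         wsd = wsd, ghg = ghg, tags = tags,
         nut = stats::setNames(nut, NUT_ORDER))
  }
  cook <- "requires_cooking_skill"
  list(
    # cereals and grains
    a("flour_wholemeal", "Wholemeal flour", "cereal_grain", 0.15, 0.05, 0.002,
      0.8, paste("staple", cook, sep = ";"),
      c(1420, 12.5, 0.4, 1.1, 10.5, 3, 360, 30, 3.6, 2.9, 10, 0, 0.45, 0, 0.8)),
    a("flour_white", "White flour", "cereal_grain", 0.12, 0.04, 0.002,
      0.8, paste("staple", cook, sep = ";"),
      c(1440, 10, 0.3, 0.9, 3, 3, 150, 20, 1.2, 0.8, 8, 0, 0.30, 0, 0.3)),
    a("pasta", "Pasta (dry)", "cereal_grain", 0.25, 0.03, 0.002, 1.2, "staple",
      c(1560, 12.5, 0.3, 0.8, 3.5, 5, 190, 22, 1.5, 1.3, 10, 0, 0.25, 0, 0.3)),
    a("oats", "Wholegrain oats", "cereal_grain", 0.30, 0.02, 0.001, 0.9,
      "staple",
      c(1590, 13, 1.2, 2.4, 10, 4, 380, 52, 4.0, 3.0, 10, 0, 0.6, 0, 1.0)),
    a("rice", "White rice (dry)", "cereal_grain", 0.22, 0.02, 0.001, 1.5,
      "staple",
      c(1500, 7, 0.4, 0.4, 1.5, 4, 100, 10, 0.7, 1.1, 8, 0, 0.25, 0, 0.2)),
    a("bread_wholemeal", "Wholemeal bread", "cereal_grain", 0.35, 0.10, 0.005,
      1.0, "",
      c(990, 9.5, 0.6, 1.5, 6.5, 400, 230, 55, 2.8, 1.7, 12, 0, 0.35, 0, 0.5)),
    a("semolina", "Semolina", "cereal_grain", 0.20, 0.03, 0.002, 0.9,
      paste("staple", cook, sep = ";"),
      c(1500, 11, 0.2, 0.5, 3.5, 2, 180, 18, 1.1, 1.0, 8, 0, 0.3, 0, 0.2)),
    a("couscous", "Couscous", "cereal_grain", 0.40, 0.02, 0.001, 0.9,
      paste("staple", cook, sep = ";"),
      c(1570, 12, 0.2, 0.4, 4.5, 8, 170, 22, 1.1, 0.9, 8, 0, 0.2, 0, 0.2)),
    a("wheat_germ", "Wheat germ", "cereal_grain", 0.55, 0.02, 0.001, 0.9, "",
      c(1550, 27, 1.7, 6.0, 13, 5, 890, 45, 8.0, 12.0, 60, 0, 1.9, 0, 14)),
    a("instant_noodles", "Instant noodles", "cereal_grain", 0.35, 0.03, 0.002,
      1.4, "staple",
      c(1850, 9, 8.5, 2.0, 3, 1100, 150, 25, 1.5, 0.8, 8, 0, 0.3, 0, 1.5)),
    # pulses, seeds, nuts
    a("dried_peas", "Dried peas", "pulse_seed_nut", 0.30, 0.02, 0.001, 0.9,
      paste("pulse", cook, sep = ";"),
      c(1420, 23, 0.2, 0.6, 24, 12, 950, 55, 4.5, 3.0, 5, 8, 0.7, 1, 0.3)),
    a("lentils", "Red lentils", "pulse_seed_nut", 0.35, 0.02, 0.001, 0.9,
      paste("pulse", cook, sep = ";"),
      c(1450, 24, 0.2, 0.5, 11, 10, 940, 55, 7.5, 3.6, 8, 2, 0.9, 4, 0.5)),
    a("chickpeas_canned", "Canned chickpeas", "pulse_seed_nut", 0.55, 0.02,
      0.001, 1.1, "pulse",
      c(520, 7, 0.3, 1.3, 6, 220, 170, 45, 1.5, 1.1, 4, 2, 0.07, 0, 1.1)),
    a("peanuts", "Peanuts (unsalted)", "pulse_seed_nut", 0.80, 0.03, 0.002,
      1.2, "nut",
      c(2460, 25, 7, 14, 8.5, 6, 680, 60, 2.5, 3.3, 7, 0, 0.6, 0, 8)),
    a("sunflower_seeds", "Sunflower seeds", "pulse_seed_nut", 0.90, 0.02,
      0.001, 0.9, "nut",
      c(2440, 21, 4.5, 23, 8.6, 9, 650, 80, 5.2, 5.0, 53, 2, 1.5, 1, 35)),
    a("almonds", "Almonds", "pulse_seed_nut", 1.60, 0.02, 0.001, 1.1, "nut",
      c(2500, 21, 3.8, 12, 11, 1, 730, 270, 3.7, 3.1, 4, 0, 0.2, 0, 25)),
    a("tofu", "Tofu (calcium-set)", "pulse_seed_nut", 0.90, 0.02, 0.001, 2.0,
      "pulse",
      c(510, 12, 1.1, 4.2, 1, 12, 150, 400, 2.7, 1.1, 10, 0, 0.1, 0, 0.1)),
    # dairy
    a("milk_powder", "Skim milk powder", "dairy", 0.85, 0.01, 0.001, 9.0,
      "dairy_product;animal_product",
      c(1500, 36, 0.5, 0.05, 0, 550, 1650, 1280, 0.3, 4.1, 12, 8, 0.4, 6, 0)),
    a("milk_whole", "Whole milk", "dairy", 0.20, 0.05, 0.003, 1.8,
      "dairy_product;animal_product",
      c(270, 3.3, 2.4, 0.1, 0, 45, 150, 115, 0.03, 0.4, 1.5, 40, 0.04, 1,
        0.07)),
    a("cheese", "Mild cheddar cheese", "dairy", 1.10, 0.03, 0.002, 12.0,
      "dairy_product;animal_product",
      c(1690, 25, 21, 1.0, 0, 620, 90, 720, 0.2, 3.5, 15, 330, 0.03, 0, 0.6)),
    a("yoghurt", "Plain yoghurt", "dairy", 0.45, 0.02, 0.001, 2.5,
      "dairy_product;animal_product",
      c(380, 5, 1.5, 0.1, 0, 70, 240, 160, 0.1, 0.6, 3, 30, 0.05, 1, 0.05)),
    a("ice_cream", "Ice cream (low fat)", "dairy", 0.50, 0.03, 0.002, 3.5,
      "dairy_product;animal_product",
      c(780, 3.5, 4.5, 0.3, 0.2, 60, 180, 130, 0.1, 0.5, 2, 60, 0.04, 1,
        0.2)),
    # meat, fish, eggs
    a("beef_mince", "Beef mince", "meat_fish_egg", 1.40, 0.12, 0.006, 27.0,
      "meat;animal_product",
      c(1050, 26, 6.5, 0.5, 0, 55, 330, 18, 2.7, 6.2, 17, 5, 0.05, 0, 0.4)),
    a("lamb", "Lamb shoulder", "meat_fish_egg", 1.80, 0.15, 0.008, 28.0,
      "meat;animal_product",
      c(1150, 25, 8, 0.6, 0, 70, 310, 15, 2.1, 4.5, 8, 8, 0.1, 0, 0.3)),
    a("sausages", "Beef sausages", "meat_fish_egg", 0.90, 0.08, 0.005, 18.0,
      "meat;animal_product",
      c(1250, 13, 9, 1.5, 1, 600, 200, 40, 1.5, 1.8, 10, 10, 0.15, 0, 0.4)),
    a("chicken", "Whole chicken", "meat_fish_egg", 1.00, 0.25, 0.010, 6.9,
      "meat;animal_product",
      c(800, 27, 2.5, 1.8, 0, 75, 300, 12, 0.7, 1.3, 18, 16, 0.07, 0, 0.3)),
    a("canned_tuna", "Canned tuna in spring water", "meat_fish_egg", 1.30,
      0.02, 0.001, 6.1, "fish;animal_product",
      c(480, 25, 0.4, 0.8, 0, 320, 230, 12, 1.0, 0.7, 60, 10, 0.03, 0, 0.5)),
    a("frozen_fish", "Frozen fish fillets", "meat_fish_egg", 1.60, 0.05,
      0.003, 5.0, "fish;animal_product",
      c(550, 18, 0.5, 1.0, 0, 110, 320, 20, 0.3, 0.4, 30, 5, 0.06, 0, 0.6)),
    a("eggs", "Eggs", "meat_fish_egg", 0.70, 0.12, 0.004, 4.9,
      "egg;animal_product",
      c(600, 12.5, 3.1, 1.9, 0, 140, 130, 50, 1.9, 1.3, 30, 190, 0.07, 0,
        1.1)),
    # fats and oils
    a("vegetable_oil", "Vegetable oil", "fat_oil", 0.45, 0, 0, 3.5, "oil",
      c(3700, 0, 8, 60, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 20)),
    a("olive_oil", "Olive oil", "fat_oil", 1.50, 0, 0, 4.5, "oil",
      c(3700, 0, 14, 10, 0, 1, 1, 1, 0.3, 0, 0, 0, 0, 0, 14)),
    a("margarine", "Margarine (low salt)", "fat_oil", 0.55, 0.02, 0.001, 2.2,
      "",
      c(3000, 0.2, 17, 25, 0, 300, 40, 10, 0, 0, 0, 800, 0, 0, 12)),
    a("butter", "Salted butter", "fat_oil", 0.90, 0.02, 0.001, 9.5,
      "dairy_product;animal_product",
      c(3030, 0.5, 51, 1.5, 0, 600, 25, 22, 0, 0.1, 1, 680, 0, 0, 1.9)),
    # fruit and vegetables
    a("potatoes", "Potatoes", "fruit_veg", 0.25, 0.45, 0.0142, 0.4,
      "vegetable;starchy_root",
      c(320, 1.9, 0.03, 0.05, 1.7, 5, 380, 6, 0.4, 0.4, 0.4, 1, 0.09, 10,
        0.01)),
    a("kumara", "Kumara", "fruit_veg", 0.35, 0.35, 0.012, 0.5,
      "vegetable;starchy_root",
      c(380, 1.4, 0.05, 0.05, 2.4, 25, 350, 25, 0.5, 0.2, 0.7, 700, 0.08, 20,
        0.3)),
    a("taro", "Taro root (peeled)", "fruit_veg", 0.60, 0.30, 0.010, 0.6,
      "vegetable;starchy_root",
      c(470, 0.5, 0.1, 0.2, 4, 15, 480, 18, 0.7, 0.2, 0.9, 5, 0.1, 4, 2.4)),
    a("carrots", "Carrots", "fruit_veg", 0.20, 0.25, 0.020, 0.35, "vegetable",
      c(150, 0.8, 0.03, 0.1, 2.8, 60, 240, 30, 0.4, 0.2, 0.1, 840, 0.07, 4,
        0.5)),
    a("cabbage", "Cabbage", "fruit_veg", 0.25, 0.20, 0.015, 0.30, "vegetable",
      c(100, 1.3, 0.03, 0.05, 2.2, 15, 200, 45, 0.4, 0.2, 0.3, 5, 0.06, 35,
        0.1)),
    a("broccoli", "Broccoli", "fruit_veg", 0.55, 0.30, 0.015, 0.50,
      "vegetable",
      c(140, 2.8, 0.05, 0.1, 3, 30, 300, 45, 0.7, 0.4, 1.5, 30, 0.07, 80,
        0.8)),
    a("onion", "Onions", "fruit_veg", 0.25, 0.10, 0.008, 0.35, "vegetable",
      c(150, 1.0, 0.02, 0.05, 1.5, 5, 150, 25, 0.2, 0.2, 0.5, 1, 0.05, 7,
        0.05)),
    a("bok_choy", "Chinese cabbage (bok choy)", "fruit_veg", 0.60, 0.15,
      0.010, 0.40, "vegetable",
      c(55, 1.5, 0.03, 0.1, 1, 65, 250, 105, 0.8, 0.2, 0.4, 220, 0.04, 45,
        0.1)),
    a("canned_tomatoes", "Canned tomatoes", "fruit_veg", 0.30, 0.02, 0.001,
      1.1, "vegetable",
      c(90, 1.0, 0.02, 0.1, 1, 130, 230, 35, 0.7, 0.2, 0.6, 30, 0.06, 12,
        1.2)),
    a("frozen_mixed_veg", "Frozen mixed vegetables", "fruit_veg", 0.35, 0.05,
      0.003, 0.60, "vegetable",
      c(280, 2.8, 0.1, 0.3, 4, 35, 230, 30, 0.9, 0.4, 0.7, 300, 0.1, 15,
        0.4)),
    a("pumpkin", "Pumpkin", "fruit_veg", 0.15, 0.30, 0.015, 0.30, "vegetable",
      c(170, 1.0, 0.05, 0.05, 1.5, 1, 340, 20, 0.4, 0.2, 0.3, 430, 0.06, 10,
        1.1)),
    a("silverbeet", "Silverbeet", "fruit_veg", 0.50, 0.25, 0.015, 0.40,
      "vegetable",
      c(80, 1.8, 0.03, 0.05, 2, 180, 450, 90, 2.7, 0.3, 0.9, 300, 0.03, 18,
        1.9)),
    a("apple", "Apples", "fruit_veg", 0.30, 0.20, 0.012, 0.55, "fruit",
      c(220, 0.3, 0.03, 0.05, 2.2, 1, 100, 5, 0.1, 0.04, 0, 3, 0.02, 5, 0.2)),
    a("kiwifruit", "Kiwifruit, green", "fruit_veg", 0.30, 0.15, 0.010, 0.50,
      "fruit",
      c(250, 1.1, 0.03, 0.2, 2.5, 3, 300, 25, 0.3, 0.1, 0.3, 4, 0.02, 90,
        1.3)),
    a("banana", "Bananas", "fruit_veg", 0.25, 0.35, 0.015, 1.1, "fruit",
      c(380, 1.1, 0.1, 0.05, 2.3, 1, 360, 5, 0.3, 0.2, 1, 3, 0.04, 9, 0.1)),
    a("oranges", "Oranges", "fruit_veg", 0.35, 0.27, 0.015, 0.50, "fruit",
      c(190, 0.9, 0.02, 0.03, 2, 2, 170, 40, 0.1, 0.07, 0.4, 8, 0.08, 50,
        0.2)),
    a("sultanas", "Sultanas", "fruit_veg", 0.55, 0.01, 0.001, 1.0, "fruit",
      c(1250, 2.5, 0.1, 0.1, 4, 25, 750, 50, 1.9, 0.3, 0.6, 1, 0.1, 1, 0.1)),
    a("canned_fruit", "Canned fruit (apricot halves)", "fruit_veg", 0.45, 0,
      0, 0.9, "fruit",
      c(300, 0.4, 0.01, 0.02, 1.2, 5, 130, 5, 0.3, 0.05, 0.3, 10, 0.02, 15,
        0.5)),
    a("apple_juice", "Apple juice", "fruit_veg", 0.25, 0, 0, 0.9, "",
      c(190, 0.1, 0.01, 0.01, 0.1, 4, 100, 5, 0.1, 0.02, 0.1, 0, 0.01, 30,
        0.1)),
    # condiments
    a("salt", "Iodised salt", "condiment", 0.15, 0, 0, 0.2,
      "condiment_exempt_from_min;salt",
      c(0, 0, 0, 0, 0, 38758, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    a("sugar", "White sugar", "condiment", 0.20, 0, 0, 0.9,
      "condiment_exempt_from_min;added_sugar",
      c(1700, 0, 0, 0, 0, 0, 2, 1, 0, 0, 0, 0, 0, 0, 0)),
    a("marmite", "Yeast spread", "condiment", 1.50, 0, 0, 1.5,
      "condiment_exempt_from_min",
      c(780, 25, 0, 0, 3, 3400, 2600, 65, 3.6, 1.1, 3, 300, 10, 0, 0)),
    # other
    a("peanut_butter", "Peanut butter", "other", 0.70, 0, 0, 1.5, "",
      c(2500, 25, 10, 14, 6, 350, 650, 35, 1.9, 2.9, 5, 0, 0.1, 0, 9)),
    a("coconut_cream", "Coconut cream (lite)", "other", 0.60, 0, 0, 1.3, "",
      c(700, 1.5, 14, 0.1, 0.5, 30, 160, 10, 0.8, 0.4, 3, 0, 0.02, 1, 0.1)),
    a("soy_milk", "Soy milk (calcium fortified)", "other", 0.35, 0, 0, 0.7,
      "",
      c(230, 3.3, 0.3, 1.2, 0.5, 50, 160, 120, 0.5, 0.3, 2, 10, 0.06, 0,
        0.2)),
    a("potato_crisps", "Potato crisps", "other", 1.40, 0, 0, 2.5, "",
      c(2200, 6, 10, 6, 4, 600, 1100, 35, 1.6, 0.9, 3, 0, 0.15, 15, 5)),
    a("chocolate", "Milk chocolate", "other", 1.60, 0, 0, 4.5, "",
      c(2200, 7, 18, 1.5, 2, 80, 400, 220, 2.3, 1.5, 4, 40, 0.07, 0, 0.6)),
    a("meat_pie", "Meat pie", "other", 1.20, 0.05, 0.003, 8.0,
      "meat;animal_product",
      c(1050, 10, 8, 1.5, 2, 450, 180, 30, 1.5, 1.5, 10, 10, 0.15, 2, 0.8)),
    a("canned_soup", "Canned vegetable soup", "other", 0.45, 0, 0, 1.2, "",
      c(230, 2.5, 0.3, 0.3, 1, 350, 150, 15, 0.4, 0.3, 2, 100, 0.03, 2, 0.2))
  )
}

# category-level parameters for filler foods
FILLER_PARAMS <- list(
  price_range = list(
    fruit_veg = c(0.15, 0.80), cereal_grain = c(0.15, 0.60),
    pulse_seed_nut = c(0.30, 1.60), dairy = c(0.20, 1.20),
    meat_fish_egg = c(0.80, 2.00), fat_oil = c(0.40, 1.50),
    condiment = c(0.15, 1.50), other = c(0.30, 1.60)),
  nut_template = list(
    fruit_veg = c(180, 1.5, 0.1, 0.2, 2.5, 20, 250, 35, 0.6, 0.3, 1, 80,
                  0.07, 25, 0.5),
    cereal_grain = c(1400, 11, 0.5, 1.2, 6, 5, 300, 30, 3, 2.5, 8, 0, 0.4, 0,
                     0.8),
    pulse_seed_nut = c(1800, 22, 3, 8, 12, 10, 800, 100, 4, 3.5, 20, 2, 0.5,
                       1, 6),
    dairy = c(800, 15, 8, 0.4, 0, 350, 400, 500, 0.2, 2, 8, 150, 0.1, 1,
              0.4),
    meat_fish_egg = c(900, 22, 4, 1.5, 0, 350, 300, 20, 1.8, 3, 20, 30, 0.1,
                      0, 0.5),
    fat_oil = c(3300, 0.3, 12, 25, 0, 300, 20, 5, 0, 0, 1, 400, 0, 0, 15),
    condiment = c(800, 5, 1, 1, 1, 2000, 300, 40, 1, 0.5, 2, 20, 0.5, 0,
                  0.5),
    other = c(1200, 6, 4, 3, 2, 300, 200, 50, 1, 1, 5, 30, 0.1, 2, 2)),
  filler_tag = list(
    fruit_veg = "vegetable", cereal_grain = "staple", pulse_seed_nut = "pulse",
    dairy = "dairy_product;animal_product",
    meat_fish_egg = "meat;animal_product", fat_oil = "oil", condiment = "",
    other = "")
)

#' Configuration for the synthetic database generator
#'
#' @param n_foods total number of foods (default 76; the anchor catalogue
#'   contributes 62, the rest are category fillers).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @param category_mix named integer vector of per-category food counts; must
#'   sum to `n_foods` and be at least the anchor count per category.
#' @param price_cv_by_category coefficient of variation of monthly prices per
#'   category; used to fill `price_sd` for anchor foods (fillers are left
#'   without `price_sd`, exercising the category-median fallback downstream).
#' @param ghg_ranges named list of `(low, high)` kg CO2e/kg ranges for filler
#'   foods; defaults encode plant << dairy < ruminant meat.
#' @param wastage_ranges named list of `(low, high)` wastage-mean ranges for
#'   filler foods.
#' @param feasibility_guarantee verify (by solving) that the generated
#'   database supports the built-in scenarios, regenerating up to 50 times.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_foods = 76L, seed = 1L,
                             category_mix = NULL,
                             price_cv_by_category = NULL,
                             ghg_ranges = NULL,
                             wastage_ranges = NULL,
                             feasibility_guarantee = TRUE) {
  if (is.null(category_mix))
    category_mix <- c(fruit_veg = 24L, cereal_grain = 12L,
                      pulse_seed_nut = 8L, dairy = 6L, meat_fish_egg = 9L,
                      fat_oil = 4L, condiment = 3L, other = 10L)
  if (sum(category_mix) != n_foods)
    stop("category_mix must sum to n_foods (", sum(category_mix), " != ",
         n_foods, ")")
  if (is.null(price_cv_by_category))
    price_cv_by_category <- c(fruit_veg = 0.12, cereal_grain = 0.05,
                              pulse_seed_nut = 0.06, dairy = 0.06,
                              meat_fish_egg = 0.08, fat_oil = 0.05,
                              condiment = 0.05, other = 0.08)
  if (is.null(ghg_ranges))
    ghg_ranges <- list(fruit_veg = c(0.3, 1.2), cereal_grain = c(0.8, 1.8),
                       pulse_seed_nut = c(0.8, 1.5), dairy = c(1.8, 12),
                       meat_fish_egg = c(5, 28), fat_oil = c(2, 5),
                       condiment = c(0.2, 1), other = c(1, 5))
  if (is.null(wastage_ranges))
    wastage_ranges <- list(fruit_veg = c(0.10, 0.45),
                           cereal_grain = c(0.01, 0.10),
                           pulse_seed_nut = c(0.01, 0.05),
                           dairy = c(0.01, 0.06),
                           meat_fish_egg = c(0.02, 0.25),
                           fat_oil = c(0, 0.02), condiment = c(0, 0.01),
                           other = c(0, 0.10))
  structure(list(n_foods = as.integer(n_foods), seed = as.integer(seed),
                 category_mix = category_mix,
                 price_cv_by_category = price_cv_by_category,
                 ghg_ranges = ghg_ranges, wastage_ranges = wastage_ranges,
                 feasibility_guarantee = isTRUE(feasibility_guarantee)),
            class = "generator_config")
}

# reference diet (grams/day by category) used to adjust nutrient columns so
# the requirement minima are structurally attainable; low-sodium, low-satfat
# foods only, respecting the built-in variety caps
REF_GRAMS <- c(cereal_grain = 150, pulse_seed_nut = 100, fruit_veg = 100,
               dairy = 80, meat_fish_egg = 50, fat_oil = 30, other = 30,
               condiment = 0)

build_raw_db <- function(config, seed) {
  set.seed(seed)
  anchors <- anchor_catalogue()
  cats <- vapply(anchors, `[[`, character(1), "category")
  # take anchors in catalogue order up to the per-category count; categories
  # larger than their anchor pool are topped up with filler foods
  keep <- logical(length(anchors))
  for (cat in names(config$category_mix)) {
    idx <- which(cats == cat)
    keep[utils::head(idx, config$category_mix[[cat]])] <- TRUE
  }
  anchors <- anchors[keep]
  cats <- cats[keep]
  n_anchor <- table(factor(cats, levels = names(config$category_mix)))
  short <- config$category_mix - as.integer(n_anchor)

  rows <- list()
  nut_rows <- list()
  for (an in anchors) {
    price <- an$price * stats::runif(1, 0.90, 1.10)
    ghg <- an$ghg * stats::runif(1, 0.95, 1.05)
    nut <- an$nut * stats::runif(length(an$nut), 0.95, 1.05)
    nut[an$nut == 0] <- 0
    cv <- config$price_cv_by_category[[an$category]]
    rows[[an$id]] <- data.frame(
      id = an$id, name = an$name, category = an$category,
      price_mean = price, price_sd = cv * price,
      wastage_mean = an$w, wastage_sd = an$wsd, ghg_factor = ghg,
      tags = an$tags, stringsAsFactors = FALSE)
    nut_rows[[an$id]] <- nut
  }
  for (cat in names(config$category_mix)) {
    k <- short[[cat]]
    if (k <= 0) next
    for (i in seq_len(k)) {
      id <- sprintf("%s_extra_%02d", cat, i)
      pr <- stats::runif(1, FILLER_PARAMS$price_range[[cat]][1],
                         FILLER_PARAMS$price_range[[cat]][2])
      wr <- config$wastage_ranges[[cat]]
      w <- stats::runif(1, wr[1], wr[2])
      gr <- config$ghg_ranges[[cat]]
      tmpl <- FILLER_PARAMS$nut_template[[cat]]
      nut <- stats::setNames(tmpl * stats::runif(length(tmpl), 0.7, 1.3),
                             NUT_ORDER)
      rows[[id]] <- data.frame(
        id = id, name = gsub("_", " ", id), category = cat,
        price_mean = pr, price_sd = NA_real_,
        wastage_mean = w, wastage_sd = 0.03 * w,
        ghg_factor = stats::runif(1, gr[1], gr[2]),
        tags = FILLER_PARAMS$filler_tag[[cat]], stringsAsFactors = FALSE)
      nut_rows[[id]] <- nut
    }
  }
  items <- do.call(rbind, rows)
  rownames(items) <- NULL
  nutrients <- do.call(rbind, nut_rows)

  # structural feasibility adjustment: a hidden low-sodium reference diet
  # must satisfy every requirement row; scale nutrient columns to close any
  # gap, then discard the reference diet
  req <- default_requirements()
  ref <- REF_GRAMS[items$category]
  ref[items$tags != "" &
        grepl("condiment_exempt_from_min", items$tags)] <- 0
  ref[nutrients[, "sodium"] > 450 | nutrients[, "sat_fat"] > 10] <- 0
  intake <- as.numeric(crossprod(nutrients, ref)) / 100
  names(intake) <- colnames(nutrients)
  for (k in seq_len(nrow(req))) {
    nid <- req$nutrient_id[k]
    if (!is.na(req$min[k]) && intake[nid] < 1.08 * req$min[k]) {
      f <- 1.08 * req$min[k] / max(intake[nid], 1e-9)
      nutrients[, nid] <- nutrients[, nid] * f
      intake[nid] <- intake[nid] * f
    }
  }
  for (k in seq_len(nrow(req))) {
    nid <- req$nutrient_id[k]
    if (is.na(req$max[k])) next
    target <- 0.82 * req$max[k]
    if (intake[nid] > target) {
      f <- target / intake[nid]
      keep <- grepl("condiment_exempt_from_min", items$tags)
      nutrients[!keep, nid] <- nutrients[!keep, nid] * f
      intake[nid] <- as.numeric(crossprod(nutrients[, nid], ref)) / 100
    }
  }

  food_db(items, nutrients, req,
          metadata = list(provenance = "synthetic generator",
                          seed = config$seed))
}

#' Generate a synthetic food database
#'
#' Builds a database of `n_foods` items (anchor catalogue plus category
#' fillers) with the default requirement table, then — unless
#' `feasibility_guarantee` is off — verifies by solving that the minimum-cost
#' scenario is feasible and, when the database carries the full anchor set,
#' that the budget-capped scenarios (G1, G4, MED_G, ASIAN_G) solve too.
#' Infeasible draws are regenerated with a shifted seed, up to 50 attempts.
#'
#' @param config a [generator_config()].
#' @return a validated `food_db`.
#' @examples
#' db <- generate_food_database(generator_config(seed = 42))
#' n_foods(db) # 76
#' @export
generate_food_database <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  for (attempt in seq_len(50L)) {
    seed_k <- (config$seed + 7919L * (attempt - 1L)) %% 2147483647L
    db <- build_raw_db(config, seed_k)
    if (!config$feasibility_guarantee) return(db)
    c1 <- optimize_diet(db, builtin_scenario("C1"))
    ok <- c1$status == "optimal"
    if (ok && all(builtin_anchor_ids() %in% food_ids(db))) {
      for (sid in c("G1", "G4", "MED_G", "ASIAN_G")) {
        s <- optimize_diet(db, builtin_scenario(sid))
        if (s$status != "optimal") { ok <- FALSE; break }
      }
    }
    if (ok) return(db)
  }
  stop("could not generate a feasible database in 50 attempts; ",
       "loosen the generator config (prices, GHG or wastage ranges)")
}

builtin_anchor_ids <- function() {
  c("flour_wholemeal", "vegetable_oil", "oats", "milk_powder", "salt",
    "sugar", "olive_oil", "rice", "carrots", "cabbage", "broccoli", "onion",
    "bok_choy", "beef_mince", "sausages", "potatoes", "ice_cream",
    "canned_fruit", "canned_tuna", "pasta", "canned_tomatoes", "taro",
    "coconut_cream", "bread_wholemeal", "cheese", "peanut_butter",
    "margarine", "apple")
}

#' Construct a small instance with a closed-form optimum
#'
#' Factory of tiny databases/scenarios whose optimal diet is known
#' analytically, used as solver oracles:
#' * `single_binding_nutrient` — two foods, one protein floor; the optimum
#'   buys only the food with the cheaper cost per gram of protein.
#' * `two_constraint_vertex` — two foods, two binding requirement rows; the
#'   optimum is the unique solution of the 2x2 linear system.
#' * `budget_capped` — GHG minimization where the budget cap binds along
#'   with the energy floor; the optimum mixes a cheap high-emission food
#'   with an expensive low-emission one at the analytic ratio point.
#'
#' @param kind one of `"single_binding_nutrient"`, `"two_constraint_vertex"`,
#'   `"budget_capped"`.
#' @return list with `db`, `scenario`, and `expected` (a list holding
#'   `quantities`, `objective_value` and `status`).
#' @export
generate_known_optimum_instance <- function(kind = c("single_binding_nutrient",
                                                     "two_constraint_vertex",
                                                     "budget_capped")) {
  kind <- match.arg(kind)
  mk_db <- function(price, nut, w = c(0, 0), ghg = c(1, 1), req_table) {
    items <- data.frame(
      id = c("food_a", "food_b"), name = c("Food A", "Food B"),
      category = "other", price_mean = price, price_sd = 0,
      wastage_mean = w, wastage_sd = 0, ghg_factor = ghg, tags = "",
      stringsAsFactors = FALSE)
    rownames(nut) <- items$id
    food_db(items, nut, req_table, metadata = list(provenance = "oracle fixture"))
  }
  if (kind == "single_binding_nutrient") {
    req <- data.frame(nutrient_id = "protein", unit = "g", min = 50,
                      max = NA, sd = 0)
    nut <- matrix(c(20, 10), 2, 1, dimnames = list(NULL, "protein"))
    db <- mk_db(price = c(1.00, 0.60), nut = nut, req_table = req)
    scn <- scenario("KNOWN_SBN", objective = "min_cost")
    expected <- list(
      quantities = c(food_a = 250, food_b = 0),
      objective_value = 250 * 1.00 / 100, status = "optimal")
  } else if (kind == "two_constraint_vertex") {
    req <- data.frame(nutrient_id = c("protein", "calcium"),
                      unit = c("g", "mg"), min = c(60, 500), max = NA,
                      sd = 0)
    nut <- matrix(c(30, 5, 100, 250), 2, 2,
                  dimnames = list(NULL, c("protein", "calcium")))
    price <- c(1.00, 0.80)
    db <- mk_db(price = price, nut = nut, req_table = req)
    scn <- scenario("KNOWN_2CV", objective = "min_cost")
    # both rows bind: solve the 2x2 system (per-gram coefficients)
    M <- rbind(c(0.30, 0.05), c(1.00, 2.50))
    q <- solve(M, c(60, 500))
    expected <- list(
      quantities = c(food_a = q[1], food_b = q[2]),
      objective_value = sum(price * q / 100), status = "optimal")
  } else {
    req <- data.frame(nutrient_id = "energy", unit = "kJ", min = 12000,
                      max = NA, sd = 0)
    nut <- matrix(c(1500, 1500), 2, 1, dimnames = list(NULL, "energy"))
    price <- c(0.30, 1.20); w <- c(0.2, 0); ghg <- c(5, 1); cap <- 5
    db <- mk_db(price = price, nut = nut, w = w, ghg = ghg, req_table = req)
    scn <- scenario("KNOWN_BUDGET", objective = "min_ghg", budget_cap = cap)
    cost_g <- price / (100 * (1 - w))   # $/g edible
    ghg_g <- ghg / (1000 * (1 - w))     # kg/g edible
    total <- 12000 / 15                 # grams needed (equal energy density)
    # energy and budget rows both binding
    a <- (cost_g[2] * total - cap) / (cost_g[2] - cost_g[1])
    b <- total - a
    expected <- list(
      quantities = c(food_a = a, food_b = b),
      objective_value = ghg_g[1] * a + ghg_g[2] * b, status = "optimal")
  }
  list(db = db, scenario = scn, expected = expected)
}

#' Default category energy shares for a typical-diet comparator
#'
#' A cereal- and meat-weighted split of daily energy across food categories
#' resembling a current national dietary pattern (meat- and discretionary-
#' food-heavy relative to the optimized diets).
#'
#' @return named numeric vector summing to 1.
#' @export
typical_energy_shares <- function() {
  c(cereal_grain = 0.24, fruit_veg = 0.10, pulse_seed_nut = 0.02,
    dairy = 0.13, meat_fish_egg = 0.22, fat_oil = 0.09, condiment = 0.05,
    other = 0.15)
}

#' Build a typical (non-optimized) diet from category energy shares
#'
#' Allocates each category's share of the energy target equally across that
#' category's energy-supplying members, converts energy to grams via each
#' food's energy density, and rescales so the total energy equals
#' `target_kj` exactly. The result is a comparator diet for the optimized
#' scenarios, evaluated (not optimized) for cost, emissions and nutrients.
#'
#' @param db a `food_db`.
#' @param energy_shares named fractions by category, summing to 1.
#' @param target_kj daily energy target in kJ.
#' @return named grams edible/day.
#' @export
generate_typical_diet <- function(db, energy_shares = typical_energy_shares(),
                                  target_kj = 11450) {
  if (abs(sum(energy_shares) - 1) > 1e-6)
    stop("energy_shares must sum to 1")
  dens <- stats::setNames(db$nutrients[, "energy"],
                          rownames(db$nutrients)) / 100 # kJ per gram
  q <- stats::setNames(rep(0, n_foods(db)), db$items$id)
  for (cat in names(energy_shares)) {
    members <- db$items$id[db$items$category == cat]
    if (!length(members))
      stop("database has no foods in category '", cat, "'")
    members <- members[dens[members] > 0]
    if (!length(members))
      stop("category '", cat, "' contains only zero-energy foods")
    e_each <- energy_shares[[cat]] * target_kj / length(members)
    q[members] <- e_each / dens[members]
  }
  q <- q[q > 0]
  scale_to_energy(q, db, target_kj)
}
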