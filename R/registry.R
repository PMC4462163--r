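#' Grain types recognised by the registry
#'
#' The closed set of cereal grains whose whole-grain (intact-proportion
#' endosperm + germ + bran) content is tracked, on a dry-matter ingredient
#' basis. Unknown grain labels are rejected at load time.
#'
#' @return Character vector of the eight grain types.
#' @export
grain_types <- function() {
  c("wheat", "oats", "maize", "rice", "rye", "barley", "quinoa", "millet")
}

#' Whole-grain food commodity groups
#'
#' The nine commodity groups into which whole-grain foods are sorted:
#' bakes (buns, cakes, scones made with whole-grain flours), bread, pasta,
#' porridge, ready-to-eat cereals (RTEC), rice, savoury snacks (crispbreads,
#' crackers, tortilla chips), sweet snacks (biscuits, cereal bars, popcorn)
#' and other cereals.
#'
#' @return Character vector of the nine group labels.
#' @export
food_groups <- function() {
  c("bakes", "bread", "pasta", "porridge", "RTEC", "rice",
    "savoury_snacks", "sweet_snacks", "other_cereals")
}

#' Derive whole-grain percentage of a food from its recipe ingredients
#'
#' Converts fresh grain-ingredient masses per 100 g of finished food to
#' grams of whole grain on a dry-matter (DM) basis: each ingredient
#' contributes `fresh_mass_per_100g_food * (1 - water_percent/100) *
#' (1 - processing_loss_percent/100)` grams, summed per grain type.
#' Stating content on a DM basis makes intakes comparable across grains
#' with different moisture (wholemeal wheat ~14 % water, whole oat ~8.9 %).
#'
#' @param ingredients data.frame with columns `grain` (one of
#'   [grain_types()]), `fresh_mass_per_100g_food` (g of fresh grain
#'   ingredient per 100 g finished food, in \[0, 100\]), `water_percent`
#'   (percent water of the fresh ingredient, in \[0, 100)) and optionally
#'   `processing_loss_percent` (percent ingredient mass lost in processing,
#'   in \[0, 100); default 0). May have zero rows.
#' @return Named numeric vector: grams of whole grain (DM) per 100 g of food,
#'   one element per grain type present. Zero-row input gives an empty map.
#' @examples
#' derive_wg_percent(data.frame(grain = "wheat",
#'                              fresh_mass_per_100g_food = 70,
#'                              water_percent = 14))
#' @export
derive_wg_percent <- function(ingredients) {
  stopifnot(is.data.frame(ingredients))
  if (nrow(ingredients) == 0L) return(stats::setNames(numeric(0), character(0)))
  need <- c("grain", "fresh_mass_per_100g_food", "water_percent")
  miss <- setdiff(need, names(ingredients))
  if (length(miss))
    stop("missing ingredient column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(ingredients$processing_loss_percent))
    ingredients$processing_loss_percent <- 0
  bad <- setdiff(unique(ingredients$grain), grain_types())
  if (length(bad))
    stop("unknown grain type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  check_number(ingredients$fresh_mass_per_100g_food,
               "fresh_mass_per_100g_food", 0, 100)
  check_number(ingredients$water_percent, "water_percent", 0, 100,
               allow_upper = FALSE)
  check_number(ingredients$processing_loss_percent, "processing_loss_percent",
               0, 100, allow_upper = FALSE)
  dm <- ingredients$fresh_mass_per_100g_food *
    (1 - ingredients$water_percent / 100) *
    (1 - ingredients$processing_loss_percent / 100)
  out <- tapply(dm, factor(ingredients$grain, grain_types()), sum)
  out <- out[!is.na(out)]
  if (sum(out) > 100 + 1e-9)
    stop("derived whole-grain content exceeds 100 g/100 g; recipe inconsistent",
         call. = FALSE)
  out[] <- as.numeric(out)
  stats::setNames(as.numeric(out), names(out))
}

#' Pre-cooking equivalent mass of a cooked portion
#'
#' Maps the mass of a food as eaten after cooking back to the mass basis on
#' which its whole-grain percentage is stated. A food losing
#' `cooking_loss_percent` of its mass during cooking (e.g. wholemeal bread
#' loses 14.6 % when toasted) has pre-cooking mass
#' `consumed_g / (1 - cooking_loss_percent/100)`.
#'
#' @param consumed_g Portion mass as eaten, grams (>= 0). Vectorised.
#' @param cooking_loss_percent Percent mass lost on cooking, in \[0, 100).
#' @return Pre-cooking (registry-basis) mass in grams.
#' @examples
#' cooked_equivalent_mass(85.4, 14.6)  # 100 g of bread, eaten as toast
#' @export
cooked_equivalent_mass <- function(consumed_g, cooking_loss_percent) {
  check_number(consumed_g, "consumed_g", 0)
  check_number(cooking_loss_percent, "cooking_loss_percent", 0, 100,
               allow_upper = FALSE)
  consumed_g / (1 - cooking_loss_percent / 100)
}

#' Construct and validate a whole-grain composition registry
#'
#' A registry holds one row per food code with its commodity group and its
#' whole-grain content by grain type, expressed as grams of whole grain
#' (grain dry matter) per 100 g of the food as consumed in its registry form.
#' A cooked item either appears as its own record (content already stated
#' per cooked mass) or references an uncooked parent via `cooked_form_of`
#' together with `cooking_loss_percent`; in the latter case its own grain
#' columns must be zero and the parent's content applies to the pre-cooking
#' equivalent mass.
#'
#' @param df data.frame with columns `food_code`, `description`,
#'   `food_group`, one numeric column per grain type (missing grain columns
#'   are treated as 0), `cooking_loss_percent` (default 0) and
#'   `cooked_form_of` (default `NA`).
#' @return The validated registry, a data.frame of class `wg_registry` with
#'   all grain columns present.
#' @export
as_wg_registry <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("food_code", "description", "food_group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  extra <- setdiff(names(df), c(need, grain_types(),
                                "cooking_loss_percent", "cooked_form_of"))
  if (length(extra))
    stop("unknown registry column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (g in grain_types()) {
    if (is.null(df[[g]])) df[[g]] <- 0
    df[[g]] <- ifelse(is.na(df[[g]]), 0, as.numeric(df[[g]]))
  }
  df$cooking_loss_percent <- as.numeric(df$cooking_loss_percent %||% 0)
  df$cooking_loss_percent[is.na(df$cooking_loss_percent)] <- 0
  if (is.null(df[["cooked_form_of"]])) df$cooked_form_of <- NA_character_
  df$cooked_form_of <- as.character(df$cooked_form_of)
  df$cooked_form_of[!is.na(df$cooked_form_of) & df$cooked_form_of == ""] <-
    NA_character_
  df$food_code <- as.character(df$food_code)

  if (anyNA(df$food_code) || any(df$food_code == ""))
    stop_rows("empty food_code", which(is.na(df$food_code) | df$food_code == ""))
  if (anyDuplicated(df$food_code)) {
    d <- df$food_code[duplicated(df$food_code)][1]
    stop_rows(sprintf("duplicate food_code '%s'", d), which(df$food_code == d))
  }
  badg <- which(!df$food_group %in% food_groups())
  if (length(badg))
    stop_rows(sprintf("unknown food_group '%s'", df$food_group[badg[1]]), badg)

  gm <- as.matrix(df[grain_types()])
  badv <- which(apply(gm < 0 | gm > 100, 1, any))
  if (length(badv)) stop_rows("grain content outside [0, 100] g/100 g", badv)
  tot <- rowSums(gm)
  badt <- which(tot > 100 + 1e-9)
  if (length(badt)) stop_rows("total whole-grain content exceeds 100 g/100 g", badt)
  badl <- which(df$cooking_loss_percent < 0 | df$cooking_loss_percent >= 100)
  if (length(badl)) stop_rows("cooking_loss_percent outside [0, 100)", badl)

  ck <- which(!is.na(df$cooked_form_of))
  if (length(ck)) {
    parent <- match(df$cooked_form_of[ck], df$food_code)
    if (anyNA(parent))
      stop_rows("cooked_form_of references unknown food_code", ck[is.na(parent)])
    if (any(!is.na(df$cooked_form_of[parent])))
      stop_rows("cooked_form_of must reference an uncooked record",
                ck[!is.na(df$cooked_form_of[parent])])
    own <- which(tot[ck] > 0)
    if (length(own))
      stop_rows("record with cooked_form_of must have zero own grain content",
                ck[own])
  }
  class(df) <- c("wg_registry", "data.frame")
  df
}

#' Read a composition registry from delimited text
#'
#' The delimiter (comma or tab) is auto-detected from the header line.
#' Columns: `food_code`, `description`, `food_group`, one column per grain
#' type (g whole grain DM per 100 g as consumed), `cooking_loss_percent`,
#' `cooked_form_of`. All records are validated; duplicate food codes and
#' out-of-range contents are rejected with row numbers.
#'
#' @param path Path to a UTF-8 CSV/TSV file.
#' @return A `wg_registry` data.frame.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, na.strings = c("", "NA"),
                      fileEncoding = "UTF-8"),
    error = function(e) stop("malformed registry file: ", conditionMessage(e),
                             call. = FALSE))
  as_wg_registry(df)
}

#' Write a composition registry to CSV
#'
#' Full numeric precision is preserved so that save/load round-trips are
#' lossless.
#'
#' @param registry A `wg_registry`.
#' @param path Output path.
#' @export
save_registry <- function(registry, path) {
  registry <- as_wg_registry(registry)
  utils::write.csv(registry, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The small illustrative registry shipped with the package
#'
#' A synthetic registry spanning all nine commodity groups and all eight
#' grain types, including a toast record that references its uncooked
#' wholemeal-bread parent with the 14.6 % toasting weight loss. It is an
#' illustration of the schema, not a survey food-composition list.
#'
#' @return A `wg_registry`.
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "wholegrain_registry.csv",
                            package = "wholegrainr", mustWork = TRUE))
}

#' Water content of fresh whole grains
#'
#' Grain water percentages used when deriving DM-basis whole-grain content
#' from recipes, kept as data rather than code constants. The shipped table
#' carries wholemeal wheat (14 %) and whole oat (8.9 %).
#'
#' @return data.frame with columns `grain` and `water_percent`.
#' @export
grain_water_content <- function() {
  utils::read.csv(system.file("extdata", "grain_water_content.csv",
                              package = "wholegrainr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# effective as-consumed grain content per food: cooked records inherit the
# parent's content scaled to the pre-cooking equivalent mass
registry_effective <- function(registry) {
  gm <- as.matrix(registry[grain_types()])
  parent <- match(registry$cooked_form_of, registry$food_code)
  cooked <- !is.na(parent)
  if (any(cooked)) {
    f <- 1 / (1 - registry$cooking_loss_percent[cooked] / 100)
    gm[cooked, ] <- gm[parent[cooked], , drop = FALSE] * f
  }
  list(food_code = registry$food_code, food_group = registry$food_group,
       grain = gm, total = rowSums(gm))
}

#' Effective whole-grain percent of each registry food as consumed
#'
#' For ordinary records this is the sum of the grain columns; for cooked
#' records referencing a parent it is the parent's total divided by
#' `1 - cooking_loss_percent/100` (the content per 100 g of the cooked food
#' as eaten). This is the percent against which cut-off tiers are applied.
#'
#' @param registry A `wg_registry`.
#' @return Named numeric vector (g whole grain per 100 g as consumed).
#' @export
food_wg_percent <- function(registry) {
  eff <- registry_effective(as_wg_registry(registry))
  stats::setNames(eff$total, eff$food_code)
}
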