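#' Read diary eating occasions from CSV
#'
#' One row per eating occasion: `participant_id`, `day_index` (1-based diary
#' day), `food_code`, `consumed_g` (grams as eaten). Occasions whose food
#' code is absent from the registry are retained — they simply contribute
#' zero whole grain — but are counted and reported via the
#' `unknown_food_codes` attribute, mirroring a survey in which only a
#' minority of consumed foods contain any whole-grain ingredient.
#'
#' @param path CSV path.
#' @param registry Optional `wg_registry` used to flag unknown food codes.
#' @return data.frame of validated occasions (order preserved), with
#'   attribute `unknown_food_codes`.
#' @export
load_diary <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  need <- c("participant_id", "day_index", "food_code", "consumed_g")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("diary missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as_diary(d[need], registry = registry)
}

as_diary <- function(d, registry = NULL) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d$participant_id <- as.character(d$participant_id)
  d$food_code <- as.character(d$food_code)
  bad <- which(!is.finite(d$consumed_g) | d$consumed_g < 0)
  if (length(bad)) stop_rows("consumed_g must be finite and >= 0", bad)
  bad <- which(!is.finite(d$day_index) | d$day_index < 1 |
                 d$day_index != floor(d$day_index))
  if (length(bad)) stop_rows("day_index must be a positive integer", bad)
  unknown <- character(0)
  if (!is.null(registry))
    unknown <- setdiff(unique(d$food_code), registry$food_code)
  attr(d, "unknown_food_codes") <- unknown
  d
}

#' Read the participant table from CSV
#'
#' Columns: `participant_id`, `age_years` (>= 1.5), `sex`
#' (`male`/`female`), `nssec` (NS-SEC class 1-8 of the household reference
#' person, or missing), `survey_weight` (strictly positive), `n_diary_days`
#' (3 or 4 consecutive recorded days) and `energy_MJ_per_day` (mean daily
#' energy intake reported in the diary, MJ, > 0).
#'
#' @param path CSV path.
#' @return Validated participant data.frame.
#' @export
load_participants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  as_participants(p)
}

as_participants <- function(p) {
  need <- c("participant_id", "age_years", "sex", "nssec", "survey_weight",
            "n_diary_days", "energy_MJ_per_day")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("participant table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  rownames(p) <- NULL
  p$participant_id <- as.character(p$participant_id)
  if (anyDuplicated(p$participant_id)) {
    d <- p$participant_id[duplicated(p$participant_id)][1]
    stop_rows(sprintf("duplicate participant_id '%s'", d),
              which(p$participant_id == d))
  }
  bad <- which(!is.finite(p$age_years) | p$age_years < 1.5)
  if (length(bad)) stop_rows("age_years must be >= 1.5", bad)
  bad <- which(!p$sex %in% c("male", "female"))
  if (length(bad)) stop_rows("sex must be 'male' or 'female'", bad)
  bad <- which(!is.na(p$nssec) & !p$nssec %in% 1:8)
  if (length(bad)) stop_rows("nssec must be 1-8 or missing", bad)
  bad <- which(!is.finite(p$survey_weight) | p$survey_weight <= 0)
  if (length(bad)) stop_rows("survey_weight must be > 0", bad)
  bad <- which(!p$n_diary_days %in% c(3, 4))
  if (length(bad)) stop_rows("n_diary_days must be 3 or 4", bad)
  bad <- which(!is.finite(p$energy_MJ_per_day) | p$energy_MJ_per_day <= 0)
  if (length(bad)) stop_rows("energy_MJ_per_day must be > 0", bad)
  p
}

#' Read a composite-food split map from JSON
#'
#' Composite items (e.g. sandwiches) and home-made meals are split into
#' component foods with individual codes. The JSON maps each composite code
#' to an object of component codes and mass fractions, e.g.
#' `{"SANDW1": {"BREAD1": 0.4, "FILL1": 0.6}}`. Fractions must be positive
#' and sum to at most 1 (the remainder is discarded mass, e.g. inedible
#' packaging allowance).
#'
#' @param path JSON path.
#' @return Named list of named numeric fraction vectors.
#' @export
load_split_map <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_split_map(m)
}

validate_split_map <- function(m) {
  if (length(m) == 0L) return(list())
  if (is.null(names(m)) || any(names(m) == ""))
    stop("split map must name each composite food code", call. = FALSE)
  for (code in names(m)) {
    fr <- unlist(m[[code]])
    if (is.null(names(fr)) || any(names(fr) == ""))
      stop("split map components must be named (composite ", code, ")",
           call. = FALSE)
    if (any(!is.finite(fr)) || any(fr <= 0))
      stop("split fractions must be positive (composite ", code, ")",
           call. = FALSE)
    if (sum(fr) > 1 + 1e-9)
      stop("split fractions sum to more than 1 (composite ", code, ")",
           call. = FALSE)
    m[[code]] <- fr
  }
  m
}

#' Split composite eating occasions into component occasions
#'
#' Each occasion whose food code appears in the split map is replaced by one
#' occasion per component, with mass `consumed_g * fraction`; unmapped
#' occasions pass through unchanged. Total mass is conserved whenever the
#' fractions sum to 1.
#'
#' @param occasions Diary occasions data.frame.
#' @param split_map Named list as returned by [load_split_map()].
#' @return Occasions data.frame with composites expanded in place.
#' @export
split_composites <- function(occasions, split_map) {
  split_map <- validate_split_map(split_map)
  if (length(split_map) == 0L) return(occasions)
  hit <- occasions$food_code %in% names(split_map)
  if (!any(hit)) return(occasions)
  pieces <- lapply(seq_len(nrow(occasions)), function(i) {
    row <- occasions[i, , drop = FALSE]
    if (!hit[i]) return(row)
    fr <- split_map[[row$food_code]]
    out <- row[rep(1L, length(fr)), , drop = FALSE]
    out$food_code <- names(fr)
    out$consumed_g <- row$consumed_g * unname(fr)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
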