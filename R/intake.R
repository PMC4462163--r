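#' Whole-grain content cut-off tiers
#'
#' Minimum whole-grain percent (per 100 g of the food as consumed) a food
#' must contain to count towards intake: `any` (> 0 %), `ge10` (>= 10 %,
#' comparable with earlier British surveys) and `ge51` (>= 51 %, the US
#' "substantial whole grain" food definition). The threshold is applied to
#' the food's total whole-grain percent summed over grain types.
#'
#' @return Named numeric vector of tier thresholds (percent).
#' @export
wg_tiers <- function() c(any = 0, ge10 = 10, ge51 = 51)

resolve_tier <- function(tier, tiers = wg_tiers()) {
  if (is.numeric(tier)) return(tier)
  if (!tier %in% names(tiers))
    stop("unknown tier '", tier, "'; expected one of ",
         paste(names(tiers), collapse = ", "), call. = FALSE)
  tiers[[tier]]
}

#' Serving definition for whole grain
#'
#' One serving is 16 g of whole grain per day; intakes are classified into
#' the half-open classes \[0, 16), \[16, 32), \[32, 48) and 48+ g/d, with a
#' dedicated class for exact zero (non-consumers). Three servings equal
#' 48 g/d.
#'
#' @param grams_per_serving Grams of whole grain per serving (default 16).
#' @return List with `grams_per_serving`, class `boundaries` and `labels`.
#' @export
serving_definition <- function(grams_per_serving = 16) {
  check_number(grams_per_serving, "grams_per_serving", 0, allow_lower = FALSE)
  b <- grams_per_serving * c(1, 2, 3)
  list(grams_per_serving = grams_per_serving,
       boundaries = b,
       labels = c("0", sprintf("0to<%g", b[1]),
                  sprintf("%gto<%g", b[1], b[2]),
                  sprintf("%gto<%g", b[2], b[3]),
                  sprintf("%gplus", b[3])))
}

#' Whole-grain mass of eating occasions
#'
#' Grams of whole grain (DM basis) in each occasion: the consumed mass,
#' mapped to its registry basis when the food is a cooked form of an
#' uncooked parent, times the food's whole-grain percent. Foods absent from
#' the registry contribute zero.
#'
#' @param occasions Diary occasions data.frame.
#' @param registry A `wg_registry`.
#' @param per_grain If `TRUE`, return a matrix with one column per grain
#'   type instead of the total.
#' @return Numeric vector (or matrix) of whole-grain grams per occasion.
#' @export
occasion_wg_mass <- function(occasions, registry, per_grain = FALSE) {
  eff <- registry_effective(as_wg_registry(registry))
  i <- match(occasions$food_code, eff$food_code)
  if (per_grain) {
    gm <- matrix(0, nrow(occasions), length(grain_types()),
                 dimnames = list(NULL, grain_types()))
    hit <- !is.na(i)
    gm[hit, ] <- eff$grain[i[hit], , drop = FALSE] * occasions$consumed_g[hit] / 100
    return(gm)
  }
  pct <- ifelse(is.na(i), 0, eff$total[i])
  occasions$consumed_g * pct / 100
}

#' Daily whole-grain intake of one participant
#'
#' Sums the whole-grain mass of occasions whose food meets the tier's
#' whole-grain percent threshold and averages over the recorded diary days.
#'
#' @param occasions Occasions of a single participant.
#' @param n_diary_days Number of recorded diary days (3 or 4).
#' @param tier Tier name (`"any"`, `"ge10"`, `"ge51"`) or numeric percent
#'   threshold.
#' @param registry A `wg_registry`.
#' @return Intake in g/d.
#' @export
daily_intake <- function(occasions, n_diary_days, tier = "any", registry) {
  if (length(n_diary_days) != 1L || !is.finite(n_diary_days) ||
      n_diary_days <= 0)
    stop("n_diary_days must be a positive number", call. = FALSE)
  thr <- resolve_tier(tier)
  eff <- registry_effective(as_wg_registry(registry))
  i <- match(occasions$food_code, eff$food_code)
  pct <- ifelse(is.na(i), 0, eff$total[i])
  keep <- pct >= thr & pct > 0
  sum(occasions$consumed_g[keep] * pct[keep] / 100) / n_diary_days
}

#' Energy-adjust a whole-grain intake
#'
#' Expresses intake per 10 MJ of daily energy to remove differences in
#' total diet quantity across age and sex: `intake_g_d * 10 / energy`.
#'
#' @param intake_g_d Intake in g/d (>= 0). Vectorised.
#' @param energy_MJ_per_day Mean daily energy intake in MJ (> 0).
#' @return Intake in g per 10 MJ per d.
#' @examples
#' energy_adjust(20, 8)  # 25 g/10 MJ per d
#' @export
energy_adjust <- function(intake_g_d, energy_MJ_per_day) {
  check_number(intake_g_d, "intake_g_d", 0)
  if (any(!is.finite(energy_MJ_per_day)) || any(energy_MJ_per_day <= 0))
    stop("energy_MJ_per_day must be > 0 (corrupt participant record?)",
         call. = FALSE)
  intake_g_d * 10 / energy_MJ_per_day
}

#' Classify a daily intake into serving classes
#'
#' Exact zero maps to the dedicated `"0"` class (non-consumer); positive
#' intakes fall into half-open classes closed below, so exactly one serving
#' (16 g/d) is classified as `"16to<32"`.
#'
#' @param intake_g_d Intake in g/d (>= 0). Vectorised.
#' @param definition A [serving_definition()].
#' @return Factor with the definition's class labels.
#' @export
serving_class <- function(intake_g_d, definition = serving_definition()) {
  if (any(!is.finite(intake_g_d)) || any(intake_g_d < 0))
    stop("intake_g_d must be finite and >= 0", call. = FALSE)
  idx <- findInterval(intake_g_d, definition$boundaries) + 2L
  idx[intake_g_d == 0] <- 1L
  factor(definition$labels[idx], levels = definition$labels)
}

#' Estimate whole-grain intake for every participant
#'
#' The full scoring pipeline: per-occasion whole-grain mass (with
#' cooking-loss resolution), food-level tier thresholds, averaging over
#' diary days, energy adjustment to g/10 MJ per d, serving classification
#' (on the any-grain absolute intake) and non-consumer flags per tier.
#' Participants with no diary rows receive zero intakes. Output is
#' deterministic and invariant to diary row order.
#'
#' @param diary Occasions data.frame (all participants).
#' @param participants Participant table; every diary participant must
#'   appear here.
#' @param registry A `wg_registry`.
#' @param tiers Named numeric tier thresholds (percent), default
#'   [wg_tiers()].
#' @param definition A [serving_definition()].
#' @return data.frame with one row per participant: `wg_gd_<tier>`,
#'   `wg_g10mj_<tier>`, `nonconsumer_<tier>` for each tier, and
#'   `serving_class`.
#' @export
estimate_all <- function(diary, participants, registry,
                         tiers = wg_tiers(),
                         definition = serving_definition()) {
  participants <- as_participants(participants)
  registry <- as_wg_registry(registry)
  orphans <- setdiff(unique(diary$participant_id),
                     participants$participant_id)
  if (length(orphans))
    stop("diary participant(s) missing from participant table: ",
         paste(orphans, collapse = ", "), call. = FALSE)

  eff <- registry_effective(registry)
  i <- match(diary$food_code, eff$food_code)
  pct <- ifelse(is.na(i), 0, eff$total[i])
  wg <- diary$consumed_g * pct / 100
  pid <- factor(diary$participant_id, levels = participants$participant_id)

  out <- data.frame(participant_id = participants$participant_id,
                    stringsAsFactors = FALSE)
  for (tname in names(tiers)) {
    thr <- tiers[[tname]]
    keep <- pct >= thr & pct > 0
    tot <- tapply(wg * keep, pid, sum, default = 0)
    gd <- as.numeric(tot) / participants$n_diary_days
    out[[paste0("wg_gd_", tname)]] <- gd
    out[[paste0("wg_g10mj_", tname)]] <-
      energy_adjust(gd, participants$energy_MJ_per_day)
    out[[paste0("nonconsumer_", tname)]] <- gd == 0
  }
  out$serving_class <- serving_class(out[[paste0("wg_gd_", names(tiers)[1])]],
                                     definition)
  out
}
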