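# Small hand-computed fixture used across intake and summary tests.
# Three participants, five registry foods spanning the three cut-off tiers
# and a cooked (toast) record; expected intakes were worked out by hand:
#   P1 (4 d, 8 MJ/d): 100 g WB01 (45 % -> 45 g) + 85.4 g TST1
#     (85.4/0.854 = 100 g bread-equivalent -> 45 g; effective percent
#     45/0.854 = 52.69 so it clears the 51 % cut-off that raw WB01 misses)
#     + 200 g OAT1 (12 % -> 24 g) + 50 g LOW1 (5 % -> 2.5 g)
#     any 116.5/4 = 29.125, ge10 114/4 = 28.5, ge51 45/4 = 11.25
#   P2 (3 d, 6 MJ/d): 150 g MIX1 (28 % -> 42 g): any = ge10 = 14, ge51 = 0
#   P3 (4 d, 10 MJ/d): only a non-registry food -> all zero
fixture_registry <- function() {
  as_wg_registry(data.frame(
    food_code = c("WB01", "TST1", "OAT1", "MIX1", "LOW1"),
    description = c("wholemeal bread", "toast of WB01", "porridge",
                    "cereal bar", "malted barley drink"),
    food_group = c("bread", "bread", "porridge", "sweet_snacks",
                   "other_cereals"),
    wheat = c(45, 0, 0, 8, 0),
    oats = c(0, 0, 12, 20, 0),
    barley = c(0, 0, 0, 0, 5),
    cooking_loss_percent = c(0, 14.6, 0, 0, 0),
    cooked_form_of = c(NA, "WB01", NA, NA, NA),
    stringsAsFactors = FALSE))
}

fixture_participants <- function() {
  data.frame(
    participant_id = c("P1", "P2", "P3"),
    age_years = c(40, 10, 70),
    sex = c("female", "male", "male"),
    nssec = c(2L, NA_integer_, 7L),
    survey_weight = c(1.2, 0.8, 1.0),
    n_diary_days = c(4L, 3L, 4L),
    energy_MJ_per_day = c(8, 6, 10),
    stringsAsFactors = FALSE)
}

fixture_diary <- function() {
  data.frame(
    participant_id = c("P1", "P1", "P1", "P1", "P2", "P3"),
    day_index = c(1L, 1L, 2L, 3L, 1L, 2L),
    food_code = c("WB01", "TST1", "OAT1", "LOW1", "MIX1", "UNK1"),
    consumed_g = c(100, 85.4, 200, 50, 150, 100),
    stringsAsFactors = FALSE)
}

fixture_expected_gd <- function() {
  data.frame(
    participant_id = c("P1", "P2", "P3"),
    any = c(29.125, 14, 0),
    ge10 = c(28.5, 14, 0),
    ge51 = c(11.25, 0, 0))
}
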