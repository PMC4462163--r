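#' Synthetic registry used by the diary-survey generator
#'
#' Built in code: a small illustrative food list spanning all nine
#' commodity groups and all eight grain types, with a spread of whole-grain
#' contents across the three cut-off tiers and one cooked item (toast, a
#' cooked form of wholemeal bread with 14.6 % toasting loss). Contents are
#' plausible DM-basis values for UK-style foods, not measured data.
#'
#' @return A `wg_registry`.
#' @export
synthetic_registry <- function() {
  rec <- function(code, desc, group, loss = 0, parent = NA, ...) {
    g <- list(...)
    row <- data.frame(food_code = code, description = desc,
                      food_group = group, cooking_loss_percent = loss,
                      cooked_form_of = as.character(parent),
                      stringsAsFactors = FALSE)
    for (gr in grain_types()) row[[gr]] <- g[[gr]] %||% 0
    row
  }
  rows <- list(
    rec("BR01", "wholemeal bread", "bread", wheat = 51),
    rec("BR02", "50/50 wheat bread", "bread", wheat = 24),
    rec("BR03", "wholemeal toast", "bread", loss = 14.6, parent = "BR01"),
    rec("RT01", "wholewheat biscuit cereal", "RTEC", wheat = 84),
    rec("RT02", "multigrain flakes", "RTEC", wheat = 38, oats = 22),
    rec("RT03", "wholegrain rice puffs", "RTEC", rice = 58),
    rec("PO01", "porridge made with water", "porridge", oats = 13),
    rec("PA01", "wholewheat pasta, boiled", "pasta", wheat = 31),
    rec("RI01", "brown rice, boiled", "rice", rice = 32),
    rec("SA01", "rye crispbread", "savoury_snacks", rye = 82),
    rec("SA02", "wholegrain cracker", "savoury_snacks", wheat = 22, barley = 6),
    rec("SA03", "corn tortilla chips", "savoury_snacks", maize = 56),
    rec("SW01", "popcorn", "sweet_snacks", maize = 68),
    rec("SW02", "oat cereal bar", "sweet_snacks", oats = 26, wheat = 9),
    rec("SW03", "yoghurt with wholegrain topping", "sweet_snacks", oats = 5),
    rec("BA01", "wholemeal scone", "bakes", wheat = 35),
    rec("OC01", "barley and millet cereal mix", "other_cereals",
        barley = 28, millet = 12),
    rec("OC02", "quinoa, boiled", "other_cereals", quinoa = 28))
  as_wg_registry(do.call(rbind, rows))
}

# relative within-group choice frequency of each synthetic food; wheat-heavy
# breads and biscuit cereals dominate, as in the UK diet being emulated
synthetic_food_prob <- function() {
  c(BR01 = 0.50, BR02 = 0.35, BR03 = 0.15,
    RT01 = 0.50, RT02 = 0.42, RT03 = 0.08,
    PO01 = 1, PA01 = 1, RI01 = 1,
    SA01 = 0.45, SA02 = 0.30, SA03 = 0.25,
    SW01 = 0.25, SW02 = 0.50, SW03 = 0.25,
    BA01 = 1, OC01 = 0.5, OC02 = 0.5)
}

# per-day consumption probability of each food group by age band;
# patterns follow the survey structure being emulated: RTEC declines with
# age, porridge rises, sweet snacks peak in teens, savoury in young adults
default_group_day_prob <- function() {
  m <- rbind(
    bakes          = rep(0.03, 9),
    bread          = c(0.30, 0.40, 0.40, 0.45, 0.45, 0.45, 0.45, 0.45, 0.45),
    pasta          = c(0.04, 0.05, 0.06, 0.07, 0.06, 0.05, 0.04, 0.03, 0.02),
    porridge       = c(0.08, 0.05, 0.04, 0.05, 0.06, 0.08, 0.10, 0.15, 0.25),
    RTEC           = c(0.55, 0.50, 0.40, 0.32, 0.30, 0.28, 0.26, 0.25, 0.25),
    rice           = c(0.02, 0.03, 0.05, 0.06, 0.06, 0.05, 0.04, 0.03, 0.02),
    savoury_snacks = c(0.06, 0.08, 0.10, 0.15, 0.10, 0.08, 0.08, 0.07, 0.06),
    sweet_snacks   = c(0.18, 0.22, 0.30, 0.15, 0.12, 0.10, 0.10, 0.09, 0.08),
    other_cereals  = c(0.02, 0.02, 0.02, 0.03, 0.03, 0.03, 0.04, 0.04, 0.05))
  colnames(m) <- levels(age_band(2))
  m[food_groups(), , drop = FALSE]
}

# portion sizes as consumed, grams; lognormal parameters per food group
default_portion_meanlog <- function() {
  log(c(bakes = 60, bread = 72, pasta = 180, porridge = 180, RTEC = 40,
        rice = 160, savoury_snacks = 25, sweet_snacks = 30,
        other_cereals = 80))[food_groups()]
}

#' Configuration of the synthetic diary-survey generator
#'
#' Defaults describe the emulated survey population: 3073 participants of
#' whom ~49 % are children/teenagers (1.5-17 y), 44 % of adults and 51 % of
#' children male; NS-SEC drawn over eight classes with a 2 % missing rate;
#' diaries of 4 days (98 %) or 3 days (2 %); absolute non-consumer
#' probability 0.18 for adults and 0.15 for children; right-skewed
#' lognormal portion sizes per food group with age-graded daily consumption
#' probabilities; energy intakes lognormal around age/sex-typical means
#' (MJ/d); and lognormal survey weights centred near 1.
#'
#' @param n_participants Number of participants.
#' @param prop_child Probability a participant is aged under 18.
#' @param prop_male Named probabilities of being male, for `child`/`adult`.
#' @param nssec_probs Probabilities of NS-SEC classes 1-8 (normalised).
#' @param nssec_missing Probability NS-SEC is missing.
#' @param nonconsumer_prob Named absolute non-consumer probabilities for
#'   `adult` and `child`.
#' @param diary_day_probs Named probabilities of 4- and 3-day diaries.
#' @param group_day_prob 9 x 9 matrix of per-day consumption probabilities,
#'   food group by age band.
#' @param portion_meanlog,portion_sdlog Lognormal portion parameters per
#'   food group (grams as consumed).
#' @param portion_mu_shift Named additive shift of `portion_meanlog` for
#'   `adult` and `child` participants; the calibration knob (shifting by
#'   `d` scales every portion, hence every intake, by `exp(d)`).
#' @param nssec_meanlog_slope Socio-economic gradient: portion meanlog is
#'   shifted by `slope * (4.5 - nssec)`, so intake declines from NS-SEC
#'   class 1 (most advantaged) to class 8; 0 for missing NS-SEC.
#' @param energy_mean_MJ Named age/sex-typical mean daily energy intakes.
#' @param energy_sdlog Lognormal sd of energy intake.
#' @param weight_sdlog Lognormal sd of survey weights.
#' @param seed Integer seed; the generator is byte-identical under a fixed
#'   seed, with an independent random stream per participant keyed by
#'   (seed, participant index) so subsets are reproducible.
#' @return A validated `wg_synth_config` list.
#' @export
synthetic_config <- function(n_participants = 3073,
                             prop_child = 1502 / 3073,
                             prop_male = c(child = 0.51, adult = 0.44),
                             nssec_probs = c(0.09, 0.20, 0.12, 0.10, 0.10,
                                             0.15, 0.15, 0.09),
                             nssec_missing = 0.02,
                             nonconsumer_prob = c(adult = 0.18, child = 0.15),
                             diary_day_probs = c("4" = 0.98, "3" = 0.02),
                             group_day_prob = default_group_day_prob(),
                             portion_meanlog = default_portion_meanlog(),
                             portion_sdlog = 0.45,
                             portion_mu_shift = c(adult = 0, child = -0.35),
                             nssec_meanlog_slope = 0.08,
                             energy_mean_MJ = c(child_1.5_4 = 4.8,
                                                child_5_12 = 6.4,
                                                teen_male = 7.8,
                                                teen_female = 6.6,
                                                adult_male = 8.8,
                                                adult_female = 6.9),
                             energy_sdlog = 0.18,
                             weight_sdlog = 0.3,
                             seed = 1L) {
  cfg <- list(n_participants = n_participants, prop_child = prop_child,
              prop_male = prop_male, nssec_probs = nssec_probs,
              nssec_missing = nssec_missing,
              nonconsumer_prob = nonconsumer_prob,
              diary_day_probs = diary_day_probs,
              group_day_prob = group_day_prob,
              portion_meanlog = portion_meanlog,
              portion_sdlog = portion_sdlog,
              portion_mu_shift = portion_mu_shift,
              nssec_meanlog_slope = nssec_meanlog_slope,
              energy_mean_MJ = energy_mean_MJ,
              energy_sdlog = energy_sdlog,
              weight_sdlog = weight_sdlog, seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$prop_child, cfg$prop_male, cfg$nssec_missing,
             cfg$nonconsumer_prob, cfg$diary_day_probs,
             as.numeric(cfg$group_day_prob))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$diary_day_probs) - 1) > 1e-9)
    stop("diary_day_probs must sum to 1", call. = FALSE)
  if (any(cfg$nssec_probs < 0)) stop("nssec_probs must be >= 0", call. = FALSE)
  if (cfg$portion_sdlog <= 0 || cfg$energy_sdlog <= 0 || cfg$weight_sdlog <= 0)
    stop("lognormal sd parameters must be > 0", call. = FALSE)
  cfg$nssec_meanlog_slope <- cfg$nssec_meanlog_slope %||% 0
  if (!is.finite(cfg$nssec_meanlog_slope))
    stop("nssec_meanlog_slope must be finite", call. = FALSE)
  if (!setequal(rownames(cfg$group_day_prob), food_groups()))
    stop("group_day_prob must have one row per food group", call. = FALSE)
  if (any(cfg$energy_mean_MJ <= 0))
    stop("energy means must be > 0", call. = FALSE)
  structure(cfg, class = "wg_synth_config")
}

participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + i * 16807) %%
    2147483647L
}

energy_mean_for <- function(cfg, age, sex) {
  if (age < 5) cfg$energy_mean_MJ[["child_1.5_4"]]
  else if (age < 13) cfg$energy_mean_MJ[["child_5_12"]]
  else if (age < 18) cfg$energy_mean_MJ[[paste0("teen_", sex)]]
  else cfg$energy_mean_MJ[[paste0("adult_", sex)]]
}

#' Generate a synthetic diary-survey dataset
#'
#' Draws participants (age, sex, NS-SEC, diary length, survey weight,
#' energy intake), then — unless the participant is drawn as an absolute
#' non-consumer — daily whole-grain eating occasions per food group with
#' lognormal portion sizes, plus one non-registry filler occasion per day
#' (a food contributing no whole grain, exercising the unknown-code path).
#' A consumer is guaranteed at least one whole-grain occasion, so the
#' non-consumer count is exactly binomial in the configured probability.
#' Ground-truth intakes are recomputed from the final tables by an
#' independent plain loop that shares no code with the scoring pipeline.
#'
#' @param config A [synthetic_config()].
#' @return List of class `wg_synth`: `registry`, `participants`, `diary`
#'   and `ground_truth` (per-participant g/d at each tier).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- validate_synthetic_config(config)
  registry <- synthetic_registry()
  groups <- food_groups()
  codes_by_group <- split(registry$food_code, registry$food_group)[groups]
  fp <- synthetic_food_prob()
  prob_by_group <- lapply(codes_by_group, function(cc) {
    p <- fp[cc]
    p[is.na(p)] <- 1
    p / sum(p)
  })
  bands <- colnames(cfg$group_day_prob)

  n <- cfg$n_participants
  pid <- sprintf("S%05d", seq_len(n))
  age <- sex <- nssec <- days <- wt <- energy <- numeric(n)
  sex <- character(n); nssec <- rep(NA_integer_, n)
  nonc <- logical(n)
  occ_pid <- occ_day <- occ_code <- vector("list", n)
  occ_mass <- vector("list", n)

  nssec_p <- cfg$nssec_probs / sum(cfg$nssec_probs)

  for (i in seq_len(n)) {
    set.seed(participant_seed(cfg$seed, i))
    child <- stats::runif(1) < cfg$prop_child
    age[i] <- if (child) stats::runif(1, 1.5, 18) else stats::runif(1, 18, 95)
    stratum <- if (child) "child" else "adult"
    sex[i] <- if (stats::runif(1) < cfg$prop_male[[stratum]]) "male" else "female"
    nssec[i] <- if (stats::runif(1) < cfg$nssec_missing) NA_integer_ else
      sample.int(8L, 1L, prob = nssec_p)
    days[i] <- as.numeric(sample(names(cfg$diary_day_probs), 1L,
                                 prob = cfg$diary_day_probs))
    wt[i] <- stats::rlnorm(1, 0, cfg$weight_sdlog)
    energy[i] <- stats::rlnorm(1, log(energy_mean_for(cfg, age[i], sex[i])),
                               cfg$energy_sdlog)
    nonc[i] <- stats::runif(1) < cfg$nonconsumer_prob[[stratum]]
    if (nonc[i]) next
    band <- as.character(age_band(age[i]))
    p <- cfg$group_day_prob[groups, band]
    mu <- cfg$portion_meanlog[groups] + cfg$portion_mu_shift[[stratum]] +
      if (is.na(nssec[i])) 0 else cfg$nssec_meanlog_slope * (4.5 - nssec[i])
    repeat {
      dl <- cl <- ml <- list()
      for (d in seq_len(days[i])) {
        eat <- which(stats::runif(length(groups)) < p)
        if (!length(eat)) next
        fc <- vapply(eat, function(j) {
          cc <- codes_by_group[[j]]
          cc[sample.int(length(cc), 1L, prob = prob_by_group[[j]])]
        }, "")
        dl[[length(dl) + 1L]] <- rep(d, length(eat))
        cl[[length(cl) + 1L]] <- unname(fc)
        ml[[length(ml) + 1L]] <- stats::rlnorm(length(eat), mu[eat],
                                               cfg$portion_sdlog)
      }
      if (length(dl)) break
    }
    occ_pid[[i]] <- rep(pid[i], length(unlist(dl)))
    occ_day[[i]] <- unlist(dl)
    occ_code[[i]] <- unlist(cl)
    occ_mass[[i]] <- unlist(ml)
  }

  # one non-whole-grain filler occasion per diary day for every participant
  fill_pid <- rep(pid, days)
  fill_day <- unlist(lapply(days, seq_len))
  set.seed(participant_seed(cfg$seed, n + 1L))
  fill_mass <- stats::rlnorm(length(fill_pid), log(250), 0.3)

  diary <- data.frame(
    participant_id = c(unlist(occ_pid), fill_pid),
    day_index = c(unlist(occ_day), fill_day),
    food_code = c(unlist(occ_code), rep("NWG01", length(fill_pid))),
    consumed_g = c(unlist(occ_mass), fill_mass),
    stringsAsFactors = FALSE)
  diary <- diary[order(match(diary$participant_id, pid), diary$day_index), ]
  rownames(diary) <- NULL

  participants <- data.frame(participant_id = pid, age_years = age,
                             sex = sex, nssec = nssec, survey_weight = wt,
                             n_diary_days = days,
                             energy_MJ_per_day = energy,
                             stringsAsFactors = FALSE)

  structure(list(registry = registry, participants = participants,
                 diary = diary,
                 ground_truth = synth_ground_truth(registry, participants,
                                                   diary)),
            class = "wg_synth")
}

# ground truth by a deliberately plain loop, independent of the pipeline:
# per occasion, look the food up, undo cooking loss, apply the percent,
# then average over diary days at each cut-off
synth_ground_truth <- function(registry, participants, diary) {
  pct <- numeric(nrow(registry))
  names(pct) <- registry$food_code
  for (j in seq_len(nrow(registry))) {
    if (is.na(registry$cooked_form_of[j])) {
      tot <- 0
      for (g in grain_types()) tot <- tot + registry[[g]][j]
      pct[j] <- tot
    } else {
      k <- which(registry$food_code == registry$cooked_form_of[j])
      tot <- 0
      for (g in grain_types()) tot <- tot + registry[[g]][k]
      pct[j] <- tot / (1 - registry$cooking_loss_percent[j] / 100)
    }
  }
  out <- data.frame(participant_id = participants$participant_id,
                    gt_gd_any = 0, gt_gd_ge10 = 0, gt_gd_ge51 = 0,
                    stringsAsFactors = FALSE)
  rows <- split(seq_len(nrow(diary)), diary$participant_id)
  for (i in seq_len(nrow(out))) {
    idx <- rows[[out$participant_id[i]]]
    if (is.null(idx)) next
    tot <- c(any = 0, ge10 = 0, ge51 = 0)
    for (r in idx) {
      p <- pct[diary$food_code[r]]
      if (is.na(p) || p <= 0) next
      wg <- diary$consumed_g[r] * p / 100
      tot["any"] <- tot["any"] + wg
      if (p >= 10) tot["ge10"] <- tot["ge10"] + wg
      if (p >= 51) tot["ge51"] <- tot["ge51"] + wg
    }
    nd <- participants$n_diary_days[i]
    out$gt_gd_any[i] <- tot[["any"]] / nd
    out$gt_gd_ge10[i] <- tot[["ge10"]] / nd
    out$gt_gd_ge51[i] <- tot[["ge51"]] / nd
  }
  out
}

#' Calibrate the generator to target medians and non-consumer fractions
#'
#' Sets the non-consumer probabilities directly and adjusts the per-stratum
#' portion meanlog shift by monotone search until the generated
#' survey-weighted median whole-grain intakes (any-grain tier, g/d) are
#' within the stated tolerance of the targets at the configured
#' `n_participants` and seed. Shifting the meanlog by `d` multiplies every
#' portion — and therefore every intake — by `exp(d)` under the same seed,
#' so the search typically converges in one or two rounds.
#'
#' @param config A [synthetic_config()].
#' @param targets List with any of `median_adult`, `median_child` (g/d,
#'   positive finite) and `nonconsumer_adult`, `nonconsumer_child`
#'   (probabilities).
#' @param tol Relative tolerance on the medians (default 0.10).
#' @param max_iter Maximum generate-and-adjust rounds.
#' @return The adjusted `wg_synth_config`, with attribute `achieved`
#'   (the medians realised at the final round).
#' @export
calibrate_config <- function(config = synthetic_config(),
                             targets = list(median_adult = 20,
                                            median_child = 13,
                                            nonconsumer_adult = 0.18,
                                            nonconsumer_child = 0.15),
                             tol = 0.10, max_iter = 6L) {
  cfg <- validate_synthetic_config(config)
  tm <- c(adult = targets$median_adult %||% NA_real_,
          child = targets$median_child %||% NA_real_)
  if (any(!is.na(tm) & (tm <= 0 | !is.finite(tm))))
    stop("target medians must be positive and finite", call. = FALSE)
  if (!is.null(targets$nonconsumer_adult))
    cfg$nonconsumer_prob[["adult"]] <- targets$nonconsumer_adult
  if (!is.null(targets$nonconsumer_child))
    cfg$nonconsumer_prob[["child"]] <- targets$nonconsumer_child
  cfg <- validate_synthetic_config(cfg)
  if (all(is.na(tm))) return(cfg)

  achieved <- c(adult = NA_real_, child = NA_real_)
  for (it in seq_len(max_iter)) {
    ds <- generate_dataset(cfg)
    adult <- ds$participants$age_years >= 18
    for (s in c("adult", "child")) {
      sel <- if (s == "adult") adult else !adult
      achieved[s] <- weighted_quantile(ds$ground_truth$gt_gd_any[sel],
                                       ds$participants$survey_weight[sel],
                                       0.5)
    }
    ok <- is.na(tm) | abs(achieved - tm) <= tol * tm
    if (all(ok)) {
      attr(cfg, "achieved") <- achieved
      return(cfg)
    }
    for (s in c("adult", "child")) {
      if (is.na(tm[[s]]) || ok[[s]]) next
      step <- if (achieved[[s]] <= 0) log(2) else log(tm[[s]] / achieved[[s]])
      cfg$portion_mu_shift[[s]] <- cfg$portion_mu_shift[[s]] + step
    }
  }
  stop(sprintf(paste0("calibration did not converge in %d rounds; best ",
                      "achieved medians: adult %.2f, child %.2f"),
               max_iter, achieved[["adult"]], achieved[["child"]]),
       call. = FALSE)
}

#' Write a synthetic dataset to CSV files
#'
#' @param dataset A `wg_synth`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "wg_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_registry(dataset$registry, file.path(dir, "registry.csv"))
  utils::write.csv(dataset$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dataset$diary, file.path(dir, "diary.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
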