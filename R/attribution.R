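#' Food-group shares of whole-grain eating occasions
#'
#' An eating occasion is one diary row; it counts as a whole-grain eating
#' occasion when its food's whole-grain percent meets the tier threshold
#' (> 0 % at tier `any`). Within each stratum the occasions are tallied by
#' commodity group and expressed as percentages, optionally weighting each
#' occasion by its participant's survey weight.
#'
#' @param occasions Diary occasions data.frame.
#' @param registry A `wg_registry`.
#' @param strata Optional vector (length `nrow(occasions)`) of stratum
#'   labels, e.g. the participant's age band; a single overall stratum when
#'   omitted.
#' @param weights Optional positive occasion weights (survey weights of the
#'   consuming participants).
#' @param tier Tier name or numeric threshold.
#' @return data.frame with one row per stratum: `stratum`, `n_occasions`
#'   (unweighted count) and one percent column per food group. Percent
#'   columns are `NA` for empty strata and sum to 100 otherwise.
#' @export
occasion_shares <- function(occasions, registry, strata = NULL,
                            weights = NULL, tier = "any") {
  registry <- as_wg_registry(registry)
  thr <- resolve_tier(tier)
  eff <- registry_effective(registry)
  i <- match(occasions$food_code, eff$food_code)
  pct <- ifelse(is.na(i), 0, eff$total[i])
  grp <- ifelse(is.na(i), NA_character_, eff$food_group[i])
  keep <- pct >= thr & pct > 0

  if (is.null(strata)) strata <- rep("all", nrow(occasions))
  if (length(strata) != nrow(occasions))
    stop("strata must have one label per occasion", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(occasions))
  if (length(weights) != nrow(occasions) || any(weights <= 0))
    stop("weights must be positive, one per occasion", call. = FALSE)

  sf <- if (is.factor(strata)) strata else factor(strata, unique(strata))
  out <- data.frame(stratum = levels(sf), n_occasions = 0L,
                    stringsAsFactors = FALSE)
  for (g in food_groups()) out[[g]] <- NA_real_
  for (k in seq_along(levels(sf))) {
    sel <- keep & !is.na(sf) & sf == levels(sf)[k]
    out$n_occasions[k] <- sum(sel)
    if (!any(sel)) next
    w <- tapply(weights[sel], factor(grp[sel], food_groups()), sum,
                default = 0)
    out[k, food_groups()] <- 100 * as.numeric(w) / sum(w)
  }
  out
}

#' Grain-type shares of total whole grain consumed
#'
#' Sums the grams of each grain type across all qualifying occasions
#' (foods meeting the tier threshold) and normalises to percent of total
#' whole grain consumed — shares are weighted by whole-grain grams, not by
#' occasion counts.
#'
#' @inheritParams occasion_shares
#' @return Named numeric vector of percentages over [grain_types()]
#'   (summing to 100), or an empty vector with a warning when no whole
#'   grain was consumed at the tier.
#' @export
grain_shares <- function(occasions, registry, tier = "any") {
  registry <- as_wg_registry(registry)
  thr <- resolve_tier(tier)
  eff <- registry_effective(registry)
  i <- match(occasions$food_code, eff$food_code)
  pct <- ifelse(is.na(i), 0, eff$total[i])
  keep <- pct >= thr & pct > 0
  gm <- occasion_wg_mass(occasions, registry, per_grain = TRUE)
  tot <- colSums(gm[keep, , drop = FALSE])
  if (sum(tot) <= 0) {
    warning("no whole grain consumed at this tier", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  100 * tot / sum(tot)
}
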