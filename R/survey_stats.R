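#' Survey-weighted quantiles (type-1, left-continuous)
#'
#' Returns the smallest data value whose cumulative normalised weight
#' reaches `q`. With equal weights this is the ordinary type-1 sample
#' quantile; with integer weights it equals the type-1 quantile of the
#' weight-expanded sample. The convention matters: at even cumulative-weight
#' boundaries a left-continuous median differs from an averaging one.
#'
#' @param x Numeric values.
#' @param w Positive weights (equal if `NULL`).
#' @param probs Quantile levels in \[0, 1\].
#' @return Numeric vector, one quantile per element of `probs`.
#' @examples
#' weighted_quantile(c(10, 20, 30), c(1, 1, 2), 0.5)  # 20
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) stop("weights must match values", call. = FALSE)
  if (anyNA(x) || anyNA(w)) stop("NA in values or weights", call. = FALSE)
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probs must be in [0, 1]", call. = FALSE)
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(q) x[o][which(cw >= q - 1e-10)[1]], numeric(1))
}

new_wg_test <- function(method, statistic, p_value, ...) {
  structure(list(method = method, statistic = statistic,
                 p_value = min(max(p_value, 0), 1), ...),
            class = "wg_test")
}

#' @export
print.wg_test <- function(x, ...) {
  cat(x$method, "\n  ", names(x$statistic)[1], " = ",
      format(x$statistic[[1]], digits = 6),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

# integerized-weight replication used by the weighted option of the rank tests
replicate_by_weight <- function(x, w) {
  if (is.null(w)) return(x)
  if (length(w) != length(x) || any(w <= 0))
    stop("weights must be positive, one per value", call. = FALSE)
  r <- pmax(1L, as.integer(round(w)))
  rep(x, r)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided test of a location difference between two samples, used for
#' sex comparisons of whole-grain intake. The statistic is
#' `U = R_x - n_x(n_x+1)/2` with midranks for ties. For small samples
#' (total n <= 12 by default) the p-value is exact, by enumeration of all
#' `choose(n, n_x)` group assignments of the pooled (mid)ranks; otherwise a
#' normal approximation with tie-corrected variance is used (no continuity
#' correction). Survey weights can optionally be incorporated by
#' integerised-weight replication — an approximation to design-aware
#' rank tests, kept transparent and oracle-testable.
#'
#' @param x,y Numeric samples (non-empty).
#' @param weights_x,weights_y Optional positive weights, replicated as
#'   `round(w)` copies of each observation.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by total sample size.
#' @return A `wg_test` with the U statistic and two-sided p-value.
#' @export
mann_whitney <- function(x, y, weights_x = NULL, weights_y = NULL,
                         exact = NULL) {
  x <- replicate_by_weight(x, weights_x)
  y <- replicate_by_weight(y, weights_y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in samples", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  exact <- exact %||% (n <= 12L)
  if (exact) {
    cmb <- utils::combn(n, n1)
    Us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - center) >= abs(U - center) - 1e-9)
    return(new_wg_test("Mann-Whitney rank-sum test (exact)", c(U = U), p,
                       n = c(n1, n2), exact = TRUE))
  }
  tie <- table(r)
  s2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (s2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U - center) / sqrt(s2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_wg_test("Mann-Whitney rank-sum test (normal approximation)",
              c(U = U), p, n = c(n1, n2), exact = FALSE, z = z)
}

#' Kruskal-Wallis test
#'
#' Rank-based k-sample test of identical distributions, used for
#' whole-grain intake differences across NS-SEC classes. The H statistic
#' uses pooled midranks with the standard tie correction
#' `1 - sum(t^3 - t)/(N^3 - N)`; the p-value comes from the chi-square
#' distribution with k-1 degrees of freedom. Being rank-based, H is
#' invariant under monotone transformations of the data.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @param weights Optional list of positive weights, applied by
#'   integerised-weight replication.
#' @return A `wg_test` with the H statistic, degrees of freedom and
#'   p-value.
#' @export
kruskal_wallis <- function(groups, weights = NULL) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(groups))
    groups <- Map(replicate_by_weight, groups, weights)
  }
  xs <- unlist(groups, use.names = FALSE)
  if (anyNA(xs)) stop("NA in samples", call. = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(xs)
  r <- rank(xs)
  rbar <- tapply(r, g, mean)
  ni <- as.numeric(lengths(groups))
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  tie <- table(r)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H <- if (C <= 0) 0 else H / C
  df <- length(groups) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  new_wg_test("Kruskal-Wallis test", c(H = H), p, df = df)
}

#' Weighted linear trend test
#'
#' Weighted least-squares regression of individual-level intake on an
#' ordinal age-band index; tests the slope against zero with a t statistic
#' on n-2 degrees of freedom. Degenerate perfect fits are resolved
#' deterministically: zero residuals with zero slope give p = 1, with a
#' non-zero slope p = 0.
#'
#' @param y Intakes (one per participant).
#' @param x Ordinal band index (at least two distinct values).
#' @param w Optional positive weights (survey weights).
#' @return A `wg_test` with the slope, its standard error and p-value.
#' @export
linear_trend <- function(y, x, w = NULL) {
  if (length(y) != length(x)) stop("x and y lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in inputs", call. = FALSE)
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  if (sxx == 0)
    stop("a single band carries all the data; trend undefined", call. = FALSE)
  slope <- sum(w * (x - xm) * (y - ym)) / sxx
  e <- y - ym - slope * (x - xm)
  rss <- sum(w * e^2)
  df <- length(y) - 2L
  if (df <= 0L) {
    se <- NA_real_; tval <- NA_real_; p <- NA_real_
  } else {
    se <- sqrt(rss / df / sxx)
    if (se == 0) {
      tval <- if (slope == 0) 0 else sign(slope) * Inf
      p <- if (slope == 0) 1 else 0
    } else {
      tval <- slope / se
      p <- 2 * stats::pt(-abs(tval), df)
    }
  }
  new_wg_test("Weighted linear trend test", c(slope = slope), p,
              se = se, t = tval, df = df)
}

#' Default age-band boundaries
#'
#' Bands used for age-stratified summaries: 1.5-4, 5-12, 13-17, 18-24,
#' 25-34, 35-44, 45-54, 55-64 and 65+ years. A pragmatic default — survey
#' reports vary in their exact banding — and configurable wherever bands
#' are accepted.
#'
#' @return Numeric vector of band lower/upper breaks (right-open).
#' @export
default_age_breaks <- function() c(1.5, 5, 13, 18, 25, 35, 45, 55, 65, Inf)

#' Assign ages to bands
#'
#' @param age_years Ages in years.
#' @param breaks Band breaks as in [default_age_breaks()].
#' @return Ordered factor of band labels such as `"18-24"` and `"65+"`.
#' @export
age_band <- function(age_years, breaks = default_age_breaks()) {
  k <- length(breaks) - 1L
  labs <- character(k)
  for (j in seq_len(k)) {
    labs[j] <- if (is.infinite(breaks[j + 1])) paste0(breaks[j], "+")
    else paste0(breaks[j], "-", if (breaks[j + 1] %% 1 == 0)
      breaks[j + 1] - 1 else breaks[j + 1])
  }
  cut(age_years, breaks, labels = labs, right = FALSE,
      include.lowest = TRUE, ordered_result = TRUE)
}

#' Survey-weighted group summaries of whole-grain intake
#'
#' For each stratum: unweighted n, weighted median and interquartile range
#' (25th/75th weighted percentiles), minimum, maximum, and the weighted
#' percentage of non-consumers (zero intake at the tier). Zero-intake
#' participants are always retained — they are why medians fall below
#' means in right-skewed consumption data. Participants with missing
#' NS-SEC are excluded from NS-SEC strata only.
#'
#' @param intakes Output of [estimate_all()].
#' @param participants Participant table.
#' @param by Stratifier: `"sex"`, `"age_band"`, `"nssec"` or
#'   `"adult_child"` (split at 18 years).
#' @param tier Tier name.
#' @param energy_adjusted Summarise g/10 MJ per d instead of g/d.
#' @param age_breaks Band breaks for `by = "age_band"`.
#' @return data.frame with one row per stratum, in stable stratum order.
#' @export
summarize_intakes <- function(intakes, participants, by = "sex",
                              tier = "any", energy_adjusted = FALSE,
                              age_breaks = default_age_breaks()) {
  participants <- as_participants(participants)
  d <- merge(intakes, participants, by = "participant_id", sort = FALSE)
  col <- paste0(if (energy_adjusted) "wg_g10mj_" else "wg_gd_", tier)
  if (is.null(d[[col]])) stop("unknown tier '", tier, "'", call. = FALSE)
  strata <- switch(by,
    sex = factor(d$sex, c("male", "female")),
    age_band = age_band(d$age_years, age_breaks),
    nssec = factor(d$nssec, 1:8),
    adult_child = factor(ifelse(d$age_years >= 18, "adult", "child"),
                         c("child", "adult")),
    stop("unknown stratum variable '", by, "'", call. = FALSE))
  x <- d[[col]]
  zero <- d[[paste0("wg_gd_", tier)]] == 0
  w <- d$survey_weight
  out <- data.frame(stratum = levels(strata), n = 0L, median = NA_real_,
                    q25 = NA_real_, q75 = NA_real_, min = NA_real_,
                    max = NA_real_, pct_nonconsumer = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(levels(strata))) {
    sel <- !is.na(strata) & strata == levels(strata)[k]
    out$n[k] <- sum(sel)
    if (!any(sel)) next
    qs <- weighted_quantile(x[sel], w[sel], c(0.25, 0.5, 0.75))
    out$q25[k] <- qs[1]; out$median[k] <- qs[2]; out$q75[k] <- qs[3]
    out$min[k] <- min(x[sel]); out$max[k] <- max(x[sel])
    out$pct_nonconsumer[k] <- 100 * sum(w[sel] * zero[sel]) / sum(w[sel])
  }
  out
}
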