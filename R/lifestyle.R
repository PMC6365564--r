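#' @title Lifestyle variable derivation
#' @description Helpers deriving the four single lifestyle variables from raw
#'   questionnaire items: alcohol in grams of pure alcohol per period, lifetime
#'   smoking exposure, a Berkman-style social integration index, and physical
#'   activity in MET hours per period.
#' @name lifestyle-derivation
NULL

#' Total pure alcohol consumed per period
#'
#' Each reported beverage contributes its pure-alcohol content (grams per
#' consumed unit) multiplied by the drinking frequency; beverages are summed.
#'
#' @param beverages data.frame or matrix with columns `grams` (pure alcohol per
#'   unit) and `freq` (units per period), or an empty object for abstainers.
#' @return Grams of pure alcohol per period (one number).
#' @export
derive_alcohol <- function(beverages) {
  if (is.null(beverages) || NROW(beverages) == 0L) return(0)
  b <- as.data.frame(beverages)
  if (!all(c("grams", "freq") %in% names(b)))
    stop("'beverages' needs columns 'grams' and 'freq'")
  if (any(b$grams < 0, na.rm = TRUE) || any(b$freq < 0, na.rm = TRUE))
    stop("beverage entries must be nonnegative")
  sum(b$grams * b$freq)
}

#' Lifetime smoking exposure
#'
#' Years of smoking multiplied by the self-reported number of cigarettes smoked
#' per day. Note this is a cigarette-years quantity; the conventional pack-year
#' definition divides cigarettes per day by 20 — use [cigyears_to_packs()] for
#' that conversion.
#'
#' @param years years of smoking.
#' @param cpd cigarettes per day.
#' @return years x cpd.
#' @export
derive_pack_years <- function(years, cpd) {
  if (any(years < 0, na.rm = TRUE) || any(cpd < 0, na.rm = TRUE))
    stop("'years' and 'cpd' must be >= 0")
  years * cpd
}

#' @rdname derive_pack_years
#' @param cigyears a value produced by [derive_pack_years()].
#' @export
cigyears_to_packs <- function(cigyears) cigyears / 20

#' Social integration index
#'
#' Sum of three domains: marital status (2 for married/cohabiting, 0
#' otherwise), close ties (children + close relatives + friends), and the
#' number of organizations attended at least monthly.
#'
#' @param married logical, married or cohabiting.
#' @param children,relatives,friends,memberships nonnegative counts.
#' @return Integer index.
#' @export
derive_social_index <- function(married, children, relatives, friends, memberships) {
  counts <- cbind(children, relatives, friends, memberships)
  if (any(counts < 0)) stop("counts must be >= 0")
  ifelse(as.logical(married), 2, 0) + children + relatives + friends + memberships
}

#' Physical activity in MET hours per period
#'
#' Each activity's metabolic-equivalent value is multiplied by the hours spent
#' on it; activities are summed. At most four sportive and four other physical
#' activities may be reported.
#'
#' @param activities data.frame with columns `met` (MET value per hour),
#'   `hours` (hours per period) and optionally `type` (`"sport"` or
#'   `"physical"`); or empty for inactive participants.
#' @return MET·h per period.
#' @export
derive_met <- function(activities) {
  if (is.null(activities) || NROW(activities) == 0L) return(0)
  a <- as.data.frame(activities)
  if (!all(c("met", "hours") %in% names(a)))
    stop("'activities' needs columns 'met' and 'hours'")
  if (!is.null(a$type)) {
    tab <- table(a$type)
    if (any(tab > 4L)) stop("at most four activities per type (sportive/physical)")
  } else if (nrow(a) > 8L) {
    stop("at most four sportive plus four physical activities")
  }
  if (any(a$met < 0) || any(a$hours < 0)) stop("activity entries must be nonnegative")
  sum(a$met * a$hours)
}

#' z-transformation
#'
#' Standardize to sample mean 0 and sample SD 1 (n - 1 denominator).
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return Standardized vector.
#' @export
z_transform <- function(x) {
  if (length(x) < 2L) stop("need at least two values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-transform a constant vector")
  (x - mean(x)) / s
}

#' The stepwise-exclusion risk model family
#'
#' Enumerates, in canonical order, the 13 risk score models built from the four
#' lifestyle variables: the combined model (all four), four triple models (each
#' variable left out once), four protective-by-risk pair models, and the four
#' single-variable models. The eight multi-variable reduced models (triples and
#' pairs) form the stepwise-exclusion family; pair models always combine
#' exactly one protective (ACT, SOC) with one risk (ALC, SMO) variable.
#'
#' @return List of `risk_model_spec` objects, each with elements `included`
#'   (character subset of `c("ACT","ALC","SOC","SMO")`) and `label`.
#' @export
enumerate_models <- function() {
  protective <- c("ACT", "SOC")
  risk <- c("ALC", "SMO")
  all4 <- c("ACT", "ALC", "SOC", "SMO")
  spec <- function(vars) {
    structure(list(included = vars, label = paste(vars, collapse = "+")),
              class = "risk_model_spec")
  }
  models <- list(spec(all4))
  for (drop in all4) models <- c(models, list(spec(setdiff(all4, drop))))
  for (p in protective) for (r in risk) models <- c(models, list(spec(sort(c(p, r)))))
  for (v in all4) models <- c(models, list(spec(v)))
  models
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat("risk model:", x$label, "\n")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0, 1].
#' @param m number of tests, >= 1.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  if (m < 1) stop("'m' must be >= 1")
  alpha / m
}

#' Combined lifestyle risk score
#'
#' Builds the per-participant combined risk score from z-transformed lifestyle
#' variables. Protective variables (physical activity ACT, social integration
#' SOC) are sign-reversed and shifted so their contribution is at most 0
#' (exactly 0 at the sample maximum of the behaviour, i.e. the minimum of the
#' reversed score); risk variables (alcohol ALC, smoking SMO) are shifted by
#' their sample minimum so their contribution is at least 0. The shifted
#' contributions of the model's variables are summed: negative scores indicate
#' a protective lifestyle, positive scores a risky one, and 0 a balance point.
#'
#' @param z_by_variable data.frame or matrix of z-scores with columns named
#'   among `ACT`, `ALC`, `SOC`, `SMO` (all standardized over the same
#'   participant set).
#' @param model a `risk_model_spec` from [enumerate_models()]; defaults to the
#'   combined four-variable model.
#' @return Object of class `risk_score`: list with `score` (numeric per
#'   participant), `contributions` (matrix), and `model`.
#' @export
combine_risk_score <- function(z_by_variable, model = enumerate_models()[[1L]]) {
  z <- as.data.frame(z_by_variable)
  protective <- c("ACT", "SOC")
  vars <- model$included
  missing_vars <- setdiff(vars, names(z))
  if (length(missing_vars))
    stop("missing z-score column(s): ", paste(missing_vars, collapse = ", "))
  contrib <- sapply(vars, function(v) {
    zv <- z[[v]]
    if (v %in% protective) min(zv) - zv else zv - min(zv)
  })
  contrib <- matrix(contrib, ncol = length(vars),
                    dimnames = list(NULL, vars))
  structure(list(score = rowSums(contrib), contributions = contrib, model = model),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("risk_score [%s]: n = %d, mean = %.3f, range = [%.2f, %.2f]\n",
              x$model$label, length(x$score), mean(x$score),
              min(x$score), max(x$score)))
  invisible(x)
}

#' Outlier exclusion by standard-deviation rule
#'
#' Single-pass rule: mean and SD are computed from all scores before any
#' exclusion, and participants beyond `k` SD of the mean are flagged.
#'
#' @param scores numeric vector of combined risk scores.
#' @param k SD multiple, default 3.
#' @return Logical vector, TRUE for outliers.
#' @export
exclude_outliers <- function(scores, k = 3) {
  if (length(scores) < 2L) stop("need at least two scores")
  m <- mean(scores); s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(scores)))
  abs(scores - m) > k * s
}

#' Residualized lifestyle variables for sensitivity analysis
#'
#' Replaces each of the four derived lifestyle variables by its residual from
#' an ordinary linear regression (with intercept) on the other three, removing
#' shared variance before re-building the combined score.
#'
#' @param derived data.frame with columns `alcohol_g`, `pack_years`,
#'   `social_index`, `met_total`.
#' @return data.frame of the same four columns, residualized (zero mean).
#' @export
sensitivity_residualize <- function(derived) {
  vars <- c("alcohol_g", "pack_years", "social_index", "met_total")
  if (!all(vars %in% names(derived)))
    stop("'derived' must contain: ", paste(vars, collapse = ", "))
  d <- derived[vars]
  out <- d
  for (v in vars) {
    X <- cbind(1, as.matrix(d[setdiff(vars, v)]))
    if (qr(X)$rank < ncol(X)) stop("collinear predictors in sensitivity residualization")
    fit <- stats::lm.fit(X, d[[v]])
    out[[v]] <- fit$residuals
  }
  out
}

#' Derive lifestyle variables from a raw cohort table
#'
#' Applies the four derivation rules to every participant of a cohort table as
#' produced by [generate_cohort()] (or a real table with the same columns),
#' drops participants with missing behavioural data listwise, z-transforms each
#' derived variable over the retained participants, and returns a table ready
#' for [combine_risk_score()].
#'
#' @param cohort data.frame in the wide cohort layout (see [generate_cohort()]).
#' @return data.frame with `id`, derived variables (`alcohol_g`, `pack_years`,
#'   `social_index`, `met_total`), z-columns (`ACT`, `ALC`, `SOC`, `SMO`), and
#'   carried-over covariates; attribute `n_dropped_missing` records listwise
#'   removals.
#' @export
derive_lifestyle <- function(cohort) {
  bev_g <- as.matrix(cohort[grep("^beverage_[0-9]+_grams$", names(cohort))])
  bev_f <- as.matrix(cohort[grep("^beverage_[0-9]+_freq$", names(cohort))])
  act_m <- as.matrix(cohort[grep("^activity_[0-9]+_met$", names(cohort))])
  act_h <- as.matrix(cohort[grep("^activity_[0-9]+_hours$", names(cohort))])
  alcohol_g <- rowSums(bev_g * bev_f)
  pack_years <- derive_pack_years(cohort$smoking_years, cohort$cigarettes_per_day)
  social_index <- derive_social_index(cohort$married, cohort$n_children,
                                      cohort$n_close_relatives, cohort$n_friends,
                                      cohort$n_memberships)
  met_total <- rowSums(act_m * act_h)

  d <- data.frame(id = cohort$id, alcohol_g = alcohol_g, pack_years = pack_years,
                  social_index = social_index, met_total = met_total)
  keep <- stats::complete.cases(d)
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  d$ALC <- z_transform(d$alcohol_g)
  d$SMO <- z_transform(d$pack_years)
  d$SOC <- z_transform(d$social_index)
  d$ACT <- z_transform(d$met_total)
  for (cov in intersect(c("age", "gender", "bdi", "isced"), names(cohort)))
    d[[cov]] <- cohort[[cov]][keep]
  attr(d, "n_dropped_missing") <- n_dropped
  d
}
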