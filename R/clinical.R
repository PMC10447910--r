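# Clinical covariate handling: the Langeron difficult-ventilation predicate,
# a configurable DIFFMASK risk score, a baseline comparison table, and the
# Riley et al. minimum sample size for binary prediction models.

#' Ideal body weight (Devine formula)
#'
#' `50 kg + 2.3 kg` per inch over 5 feet for men, `45.5 kg` base for women;
#' floored at the base weight for short statures. The formula is
#' configurable at the call sites that consume ideal body weight.
#'
#' @param height_cm height in centimetres.
#' @param gender `"male"` or `"female"` (vectorised).
#' @return Ideal body weight in kg.
#' @export
ideal_body_weight <- function(height_cm, gender) {
  base <- ifelse(gender == "male", 50, 45.5)
  pmax(base, base + 2.3 * (height_cm / 2.54 - 60))
}

#' Difficult mask ventilation predicate
#'
#' Labels a ventilation episode as DMV when any Langeron criterion holds:
#' SpO2 below 92% on 100% oxygen, important mask leak, gas flow above
#' 15 L/min with more than two oxygen-flush uses, no visible chest movement,
#' need for a two-handed technique, or operator substitution - or when the
#' tidal volume falls below 5 mL/kg of ideal body weight.
#'
#' @param ventilation data frame with columns `spo2_min`, `major_leak`,
#'   `flow_over_15_flush_twice`, `no_chest_movement`, `two_handed_needed`,
#'   `operator_substitution`, `tidal_volume`, `ideal_body_weight`.
#' @return Logical vector, one element per row.
#' @export
label_dmv <- function(ventilation) {
  v <- tibble::as_tibble(ventilation)
  need <- c("spo2_min", "major_leak", "flow_over_15_flush_twice",
            "no_chest_movement", "two_handed_needed",
            "operator_substitution", "tidal_volume", "ideal_body_weight")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("missing fields: ", paste(miss, collapse = ", "))
  if (anyNA(v[need])) stop("ventilation record has missing values")
  stopifnot(all(v$spo2_min > 0 & v$spo2_min <= 100), all(v$tidal_volume >= 0))
  v$spo2_min < 92 |
    v$major_leak | v$flow_over_15_flush_twice | v$no_chest_movement |
    v$two_handed_needed | v$operator_substitution |
    v$tidal_volume < 5 * v$ideal_body_weight
}

#' Default DIFFMASK point allocation
#'
#' The DIFFMASK score sums points over ten risk factors (age, sex, BMI,
#' history of difficult intubation, snoring, thyromental distance, modified
#' Mallampati class, beard, sleep apnea, neck radiation) to a theoretical
#' range of 0-18. The exact published allocation is not redistributable, so
#' this packaged default is a synthetic allocation honouring the published
#' structure (ten components, 0-18 range, monotone in each risk factor); it
#' can be replaced wholesale via [read_diffmask_weights()] or a hand-built
#' list of the same shape.
#'
#' Component encodings: `breaks`/`points` pairs score a continuous variable
#' by interval (points for `(-Inf, b1)`, `[b1, b2)`, ..., `[bk, Inf)`);
#' `levels` maps categorical values to points; `yes` gives the points for a
#' TRUE boolean.
#'
#' @return A validated `diffmask_weights` list with attribute `max_score`.
#' @export
diffmask_default_weights <- function() {
  w <- list(
    age = list(breaks = c(45, 60), points = c(0, 1, 2)),
    gender = list(levels = c(female = 0, male = 1)),
    bmi = list(breaks = c(25, 30), points = c(0, 1, 2)),
    tmd = list(breaks = c(4, 6.5), points = c(2, 1, 0)),
    mmt = list(levels = c(`1` = 0, `2` = 0, `3` = 1, `4` = 2)),
    snoring = list(yes = 2),
    neck_radiation = list(yes = 2),
    difficult_intubation_history = list(yes = 2),
    sleep_apnea = list(yes = 2),
    beard = list(yes = 1)
  )
  validate_diffmask_weights(w)
}

component_max <- function(cmp) {
  if (!is.null(cmp$points)) max(cmp$points)
  else if (!is.null(cmp$levels)) max(cmp$levels)
  else if (!is.null(cmp$yes)) cmp$yes
  else stop("weight component needs 'points', 'levels' or 'yes'")
}

#' Validate a DIFFMASK weight table
#'
#' Checks the ten components are present, every allocation is non-negative,
#' interval allocations have one point value per interval, and the
#' theoretical maximum equals 18.
#'
#' @param w a weights list shaped like [diffmask_default_weights()].
#' @return `w` with class `diffmask_weights` and attribute `max_score`.
#' @export
validate_diffmask_weights <- function(w) {
  need <- c("age", "gender", "bmi", "tmd", "mmt", "snoring",
            "neck_radiation", "difficult_intubation_history",
            "sleep_apnea", "beard")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("weights missing components: ",
                         paste(miss, collapse = ", "))
  for (nm in need) {
    # YAML parses nested maps as lists; flatten to named numeric vectors
    for (f in c("breaks", "points", "levels", "yes"))
      if (!is.null(w[[nm]][[f]])) w[[nm]][[f]] <- unlist(w[[nm]][[f]])
    cmp <- w[[nm]]
    if (!is.null(cmp$breaks) &&
        length(cmp$points) != length(cmp$breaks) + 1L)
      stop("component '", nm, "': need one point value per interval")
    vals <- c(cmp$points, cmp$levels, cmp$yes)
    if (any(vals < 0)) stop("component '", nm, "': negative points")
  }
  mx <- sum(vapply(w[need], component_max, 0))
  if (mx != 18)
    stop("theoretical maximum must be 18, got ", mx)
  structure(w, class = "diffmask_weights", max_score = mx)
}

#' Read DIFFMASK weights from YAML
#' @param path YAML file shaped like the packaged
#'   `extdata/diffmask_weights.yaml`.
#' @return Validated `diffmask_weights`.
#' @export
read_diffmask_weights <- function(path) {
  validate_diffmask_weights(yaml::read_yaml(path))
}

score_component <- function(cmp, value) {
  if (!is.null(cmp$breaks)) {
    idx <- findInterval(value, cmp$breaks) + 1L
    cmp$points[idx]
  } else if (!is.null(cmp$levels)) {
    p <- cmp$levels[as.character(value)]
    if (anyNA(p)) stop("value outside the weight table's levels")
    as.numeric(p)
  } else {
    ifelse(as.logical(value), cmp$yes, 0)
  }
}

#' DIFFMASK risk score
#'
#' Sums the configured points over the ten components and flags records at
#' or above the cut-off (default 4, the Youden-optimal cut-off in this
#' cohort) as at risk for difficult mask ventilation.
#'
#' @param records data frame with columns `age`, `gender`, `bmi`, `tmd`,
#'   `mmt`, `snoring`, `neck_radiation`, `difficult_intubation_history`,
#'   `sleep_apnea`, `beard`.
#' @param weights a `diffmask_weights` table.
#' @param cutoff at-risk threshold on the summed score.
#' @return The input tibble with integer column `diffmask` (0-18) and
#'   logical `at_risk` appended.
#' @export
diffmask_score <- function(records, weights = diffmask_default_weights(),
                           cutoff = 4L) {
  weights <- validate_diffmask_weights(unclass(weights))
  r <- tibble::as_tibble(records)
  need <- names(unclass(weights))
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(r[need])) stop("records have missing component values")
  total <- rep(0, nrow(r))
  for (nm in need) total <- total + score_component(weights[[nm]], r[[nm]])
  stopifnot(all(total >= 0), all(total <= attr(weights, "max_score")))
  dplyr::mutate(r, diffmask = as.integer(total),
                at_risk = total >= cutoff)
}

fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
fmt_n_pct <- function(n, total) sprintf("%d (%.1f)", n, 100 * n / total)

#' Baseline comparison table
#'
#' Summarises every covariate by outcome group: continuous variables as
#' mean +/- SD with one-way ANOVA and Mann-Whitney U p-values, categorical
#' variables as n (column %) with Fisher's exact p-value. Percentages use
#' column totals as denominators; continuous summaries carry 2 decimals and
#' percentages 1, the usual reporting precision. Zero-variance continuous
#' variables are summarised but their tests skipped with a note.
#'
#' @param records data frame of covariates including the outcome column.
#' @param outcome name of the logical outcome column (default `"dmv"`).
#' @param variables covariate columns to include; defaults to everything
#'   except the outcome and any `subject` id column.
#' @return Tibble with columns `variable`, `level`, `overall`,
#'   `group_negative`, `group_positive`, `p_anova`, `p_mann_whitney`,
#'   `p_fisher`, `note`.
#' @export
baseline_table <- function(records, outcome = "dmv", variables = NULL) {
  r <- tibble::as_tibble(records)
  if (!outcome %in% names(r)) stop("no outcome column '", outcome, "'")
  y <- as.logical(r[[outcome]])
  if (!any(y) || all(y)) stop("both outcome groups must be non-empty")
  if (is.null(variables))
    variables <- setdiff(names(r), c(outcome, "subject", "sample_id"))
  rows <- list()
  for (v in variables) {
    x <- r[[v]]
    is_continuous <- is.numeric(x) &&
      (length(unique(x)) > 5L || stats::sd(x) < 1e-12)
    if (is_continuous) {
      note <- NA_character_
      if (stats::sd(x) < 1e-12) {
        pa <- pm <- NA_real_
        note <- "zero variance; tests skipped"
      } else {
        pa <- summary(stats::aov(x ~ factor(y)))[[1L]][["Pr(>F)"]][1L]
        pm <- suppressWarnings(stats::wilcox.test(x[y], x[!y])$p.value)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = NA_character_,
        overall = fmt_mean_sd(x),
        group_negative = fmt_mean_sd(x[!y]),
        group_positive = fmt_mean_sd(x[y]),
        p_anova = pa, p_mann_whitney = pm, p_fisher = NA_real_, note = note)
    } else {
      xf <- if (is.logical(x)) factor(x, c(FALSE, TRUE), c("No", "Yes"))
            else factor(x)
      tab <- table(xf, factor(y, c(FALSE, TRUE)))
      lv <- levels(xf)
      note1 <- NA_character_
      if (nrow(tab) < 2L) {
        pf <- NA_real_
        note1 <- "single level; test skipped"
      } else pf <- stats::fisher.test(tab)$p.value
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = lv,
        overall = fmt_n_pct(as.integer(rowSums(tab)), length(x)),
        group_negative = fmt_n_pct(as.integer(tab[, 1L]), sum(!y)),
        group_positive = fmt_n_pct(as.integer(tab[, 2L]), sum(y)),
        p_anova = NA_real_, p_mann_whitney = NA_real_,
        p_fisher = c(pf, rep(NA_real_, length(lv) - 1L)),
        note = c(note1, rep(NA_character_, length(lv) - 1L)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Riley minimum sample size for a binary prediction model
#'
#' Implements the three Riley et al. criteria for developing a binary
#' outcome prediction model: (1) expected shrinkage of predictor effects at
#' least 0.9; (2) small optimism in apparent R2 (absolute difference at most
#' `delta_optimism` of the maximal Cox-Snell R2); (3) precise estimation of
#' the outcome proportion (half-width `margin` at the given `level`). The
#' reported size is the ceiling of the largest criterion.
#'
#' The anticipated Cox-Snell R2 is derived from the expected C statistic and
#' prevalence under a binormal score model. The default `"simulation"`
#' conversion draws a large seeded sample of linear predictor values and
#' fits a logistic calibration model (the convention of the pmsampsize
#' reference implementation, reproduced here including its seed and 4-decimal
#' rounding); `"integration"` evaluates the same quantity by exact numerical
#' integration and is simulation-free. The user's RNG state is untouched.
#'
#' @param c_statistic expected discrimination, in (0.5, 1).
#' @param prevalence expected outcome proportion, in (0, 1).
#' @param n_parameters candidate predictor parameters, >= 1.
#' @param r2_cox_snell optional anticipated Cox-Snell R2, overriding the
#'   C-statistic conversion.
#' @param method conversion method, `"simulation"` (default) or
#'   `"integration"`.
#' @param shrinkage required expected shrinkage factor (criterion 1).
#' @param delta_optimism allowed apparent-R2 optimism (criterion 2).
#' @param margin absolute margin on the outcome proportion (criterion 3).
#' @param level confidence level for criterion 3.
#' @param n_sim,sim_seed simulation size and seed for the `"simulation"`
#'   conversion.
#' @return Integer minimum n, with attributes `r2_cox_snell` and `criteria`
#'   (the three unrounded sizes).
#' @export
riley_min_n <- function(c_statistic = NULL, prevalence, n_parameters,
                        r2_cox_snell = NULL,
                        method = c("simulation", "integration"),
                        shrinkage = 0.9, delta_optimism = 0.05,
                        margin = 0.05, level = 0.95,
                        n_sim = 1e6, sim_seed = 123456L) {
  method <- match.arg(method)
  stopifnot(prevalence > 0, prevalence < 1, n_parameters >= 1)
  if (is.null(r2_cox_snell)) {
    if (is.null(c_statistic)) stop("give c_statistic or r2_cox_snell")
    if (c_statistic <= 0.5 || c_statistic >= 1)
      stop("c_statistic must be in (0.5, 1)")
    r2 <- cstat_to_r2(c_statistic, prevalence, method, n_sim, sim_seed)
  } else {
    r2 <- r2_cox_snell
    stopifnot(r2 > 0, r2 < 1)
  }
  max_r2 <- 1 - (prevalence^prevalence *
                   (1 - prevalence)^(1 - prevalence))^2
  n1 <- n_parameters / ((shrinkage - 1) * log(1 - r2 / shrinkage))
  s2 <- r2 / (r2 + delta_optimism * max_r2)
  n2 <- n_parameters / ((s2 - 1) * log(1 - r2 / s2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  n3 <- (z / margin)^2 * prevalence * (1 - prevalence)
  out <- max(ceiling(n1), ceiling(n2), ceiling(n3))
  structure(as.integer(out), r2_cox_snell = r2,
            criteria = c(shrinkage = n1, optimism = n2, precision = n3))
}

# anticipated Cox-Snell R2 from (C, prevalence) under the binormal model:
# scores of events ~ N(mu, 1), non-events ~ N(0, 1), mu = sqrt(2) qnorm(C)
cstat_to_r2 <- function(C, phi, method, n_sim, sim_seed) {
  mu <- sqrt(2) * stats::qnorm(C)
  if (method == "simulation") {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(sim_seed)
    n0 <- round(phi * n_sim); n1 <- round((1 - phi) * n_sim)
    lp <- c(stats::rnorm(n0, 0, 1), stats::rnorm(n1, mu, 1))
    y <- c(rep(0, n0), rep(1, n1))
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, lp), y, family = stats::binomial()))
    null_dev <- -2 * (sum(y) * log(mean(y)) +
                        sum(1 - y) * log(1 - mean(y)))
    r2 <- 1 - exp(-(null_dev - fit$deviance) / length(y))
    round(r2, 4)
  } else {
    a <- log(phi / (1 - phi)) - mu^2 / 2
    i1 <- stats::integrate(function(x)
      stats::dnorm(x, mu, 1) * stats::plogis(a + mu * x, log.p = TRUE),
      -Inf, Inf, rel.tol = 1e-12)$value
    i0 <- stats::integrate(function(x)
      stats::dnorm(x, 0, 1) * stats::plogis(-(a + mu * x), log.p = TRUE),
      -Inf, Inf, rel.tol = 1e-12)$value
    ll1 <- phi * i1 + (1 - phi) * i0
    ll0 <- phi * log(phi) + (1 - phi) * log(1 - phi)
    1 - exp(2 * (ll0 - ll1))
  }
}
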