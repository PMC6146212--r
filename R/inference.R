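#' Fit the outcome linear mixed model
#'
#' Restricted-maximum-likelihood fit of
#' `outcome ~ trigger_foot * direction + (1 | subject)` with sum-to-zero
#' contrasts (required for meaningful Type-III tests in the presence of the
#' interaction). A singular random-effect variance is reported with a
#' warning but the fit is retained.
#'
#' @param outcomes data.frame from [compute_outcomes()] (possibly stacked
#'   across subjects) with factors `subject`, `trigger_foot`, `direction`
#' @param outcome name of the outcome column to model
#' @return an `lmerModLmerTest` fit
#' @export
fit_outcome_lmm <- function(outcomes, outcome) {
  stopifnot(outcome %in% names(outcomes))
  d <- outcomes
  d$.y <- d[[outcome]]
  if (length(unique(d$subject)) < 2L)
    stop("need at least 2 subjects for a random-intercept model", call. = FALSE)
  if (!is.finite(stats::sd(d$.y)) || stats::sd(d$.y) == 0)
    stop("outcome is constant; model is degenerate", call. = FALSE)
  d$subject <- factor(d$subject)
  d$trigger_foot <- factor(d$trigger_foot)
  d$direction <- factor(d$direction)
  fit <- lmerTest::lmer(
    .y ~ trigger_foot * direction + (1 | subject), data = d, REML = TRUE,
    contrasts = list(trigger_foot = stats::contr.sum, direction = stats::contr.sum)
  )
  if (lme4::isSingular(fit))
    warning("singular random-effect variance (subject SD estimated at 0); fit retained")
  fit
}

#' Type-III ANOVA with Satterthwaite degrees of freedom
#'
#' @param fit a fit from [fit_outcome_lmm()]
#' @return tidy data.frame: `effect`, `num_df`, `den_df`, `F`, `p`
#' @export
anova_fixed <- function(fit) {
  a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  data.frame(effect = rownames(a), num_df = a$NumDF, den_df = a$DenDF,
             F = a$`F value`, p = a$`Pr(>F)`, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Least-squares means with 95% confidence intervals
#'
#' Marginal means per factor level with confidence intervals using a
#' Kenward-Roger approximation when pbkrtest is available (Satterthwaite
#' otherwise, recorded in the `df_method` attribute). A level is flagged
#' significant when its CI excludes zero.
#'
#' @param fit a fit from [fit_outcome_lmm()]
#' @param factor_name factor whose levels to summarize ("direction",
#'   "trigger_foot", or "1" for the grand mean)
#' @param conf confidence level
#' @return data.frame `level`, `mean`, `lower`, `upper`, `significant`;
#'   attribute `df_method`
#' @export
lsmeans_ci <- function(fit, factor_name = "direction", conf = 0.95) {
  method <- if (requireNamespace("pbkrtest", quietly = TRUE)) "kenward-roger"
            else "satterthwaite"
  em <- suppressMessages(emmeans::emmeans(fit, specs = factor_name,
                                          lmer.df = method, level = conf))
  s <- as.data.frame(stats::confint(em, level = conf))
  lvl_col <- if (factor_name %in% names(s)) factor_name else names(s)[1]
  out <- data.frame(level = as.character(s[[lvl_col]]),
                    mean = s$emmean, lower = s$lower.CL, upper = s$upper.CL,
                    stringsAsFactors = FALSE)
  out$significant <- out$lower > 0 | out$upper < 0
  attr(out, "df_method") <- method
  out
}

#' Simulate outcome tables from the random-intercept model
#'
#' Balanced design: each subject contributes `n_reps` first-step outcomes in
#' every trigger-foot x direction cell. The sign-adjusted response magnitude
#' is `effect`; subjects deviate with SD `subject_sd`; residual SD is
#' `resid_sd`.
#'
#' @param n_subjects,n_reps design size
#' @param effect true response magnitude (outcome units)
#' @param subject_sd,resid_sd variance components (outcome units)
#' @param direction_effect optional additional shift applied to the "toward"
#'   level (half to each side of the direction contrast)
#' @return outcomes data.frame with column `value`
#' @export
simulate_outcomes <- function(n_subjects, n_reps, effect = 0,
                              subject_sd = 1, resid_sd = 1,
                              direction_effect = 0) {
  cells <- expand.grid(trigger_foot = c("left", "right"),
                       direction = c("toward", "away"),
                       rep = seq_len(n_reps),
                       subject = sprintf("S%02d", seq_len(n_subjects)),
                       stringsAsFactors = FALSE)
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  names(u) <- sprintf("S%02d", seq_len(n_subjects))
  dir_shift <- ifelse(cells$direction == "toward", direction_effect / 2,
                      -direction_effect / 2)
  cells$value <- effect + dir_shift + u[cells$subject] +
    stats::rnorm(nrow(cells), 0, resid_sd)
  cells
}

#' Simulation-based power analysis
#'
#' Simulates outcome tables with the stated effect from the random-intercept
#' model, refits the mixed model and tests significance (the grand-mean 95%
#' CI excluding zero, the same criterion used for the real outcomes), and
#' reports the fraction of significant replicates as power.
#'
#' @param effect_size true response magnitude (outcome units); must be > 0
#' @param n_subjects number of subjects
#' @param n_reps first-step outcomes per subject and cell
#' @param subject_sd,resid_sd variance components (outcome units)
#' @param n_sims number of simulations
#' @param alpha significance level (CI level is 1 - alpha)
#' @param seed integer seed
#' @return power in percent (0-100)
#' @export
power_simulation <- function(effect_size, n_subjects, n_reps = 10,
                             subject_sd = 1, resid_sd = 1,
                             n_sims = 100, alpha = 0.05, seed = NULL) {
  if (!is.numeric(effect_size) || effect_size <= 0)
    stop("'effect_size' must be positive", call. = FALSE)
  stopifnot(n_sims >= 1, n_subjects >= 2)
  with_seed(seed, {
    hits <- vapply(seq_len(n_sims), function(i) {
      d <- simulate_outcomes(n_subjects, n_reps, effect = effect_size,
                             subject_sd = subject_sd, resid_sd = resid_sd)
      intercept_significant(d, conf = 1 - alpha)
    }, logical(1))
    100 * mean(hits)
  })
}

# grand-mean CI from the random-intercept model, Satterthwaite df
intercept_significant <- function(d, conf = 0.95) {
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ 1 + (1 | subject), data = d, REML = TRUE)))
  s <- stats::coef(summary(fit))
  half <- stats::qt(1 - (1 - conf) / 2, s[1, "df"]) * s[1, "Std. Error"]
  abs(s[1, "Estimate"]) > half
}

#' Smallest N reaching a target power
#'
#' Scans the number of subjects upward from `n_min`, computing
#' [power_simulation()] at each size with paired seeds, and returns the
#' first N whose power reaches `target` percent.
#'
#' @inheritParams power_simulation
#' @param target target power (percent)
#' @param n_min,n_max scan bounds
#' @return list with `n` (NA if not reached by `n_max`) and `power` (vector
#'   of powers for each scanned N)
#' @export
power_required_n <- function(effect_size, target = 95, n_reps = 10,
                             subject_sd = 1, resid_sd = 1, n_sims = 100,
                             alpha = 0.05, n_min = 2, n_max = 30, seed = NULL) {
  powers <- c()
  for (n in n_min:n_max) {
    p <- power_simulation(effect_size, n, n_reps, subject_sd, resid_sd,
                          n_sims, alpha, seed = seed)
    powers[as.character(n)] <- p
    if (p >= target) return(list(n = n, power = powers))
  }
  list(n = NA_integer_, power = powers)
}
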