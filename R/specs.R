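#' Trajectory specification for the longitudinal submodel
#'
#' Defines the fixed-effect part of the true (error-free) log-biomarker
#' trajectory \eqn{m_i(t)}. Two kinds are supported: a linear time trend
#' (`kind = "linear"`) and a nonlinear trend built from a cubic B-spline basis
#' with three basis functions on fixed boundary knots (`kind = "bspline"`).
#' In both cases the subject-specific part is a random intercept plus a
#' random linear slope in time, so for the spline kind only the fixed time
#' trend is nonlinear.
#'
#' @param kind `"linear"` or `"bspline"`.
#' @param beta0 Fixed intercept on the log-biomarker scale.
#' @param beta_time Fixed slope per week (linear kind only).
#' @param beta_spline Numeric vector of 3 coefficients for the cubic B-spline
#'   basis functions of time (bspline kind only).
#' @param beta_age Fixed effect per year of age on the log-biomarker.
#' @param spline_boundary Boundary knots (weeks) of the spline basis.
#' @return An object of class `trajectory_spec`.
#' @examples
#' trajectory_spec()
#' trajectory_spec("bspline", beta_spline = c(-0.35, -0.10, -0.28))
#' @export
trajectory_spec <- function(kind = c("linear", "bspline"),
                            beta0 = 5.85,
                            beta_time = -0.0007,
                            beta_spline = c(-0.35, -0.10, -0.28),
                            beta_age = -0.023,
                            spline_boundary = c(0, 400)) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(beta0), length(beta0) == 1L,
            is.numeric(beta_age), length(beta_age) == 1L)
  if (kind == "bspline") {
    if (length(beta_spline) != 3L || anyNA(beta_spline))
      stop("`beta_spline` must be 3 finite coefficients", call. = FALSE)
    if (length(spline_boundary) != 2L || diff(spline_boundary) <= 0)
      stop("`spline_boundary` must be an increasing pair of times", call. = FALSE)
  } else {
    if (length(beta_time) != 1L || !is.finite(beta_time))
      stop("`beta_time` must be a single finite number", call. = FALSE)
  }
  structure(
    list(kind = kind, beta0 = beta0, beta_time = beta_time,
         beta_spline = beta_spline, beta_age = beta_age,
         spline_boundary = as.numeric(spline_boundary),
         spline_degree = 3L, n_basis = 3L),
    class = "trajectory_spec")
}

#' Cubic B-spline basis used by nonlinear trajectories
#'
#' Evaluates the three retained cubic B-spline basis functions at times `t`.
#' The basis has no interior knots; the intercept-like first column of the
#' full basis is dropped (the model keeps a separate intercept), so the three
#' retained columns are non-negative and sum to at most 1 at every `t`.
#'
#' @param t Times (weeks) within the spline boundary.
#' @param spec A [trajectory_spec()] (its boundary knots are used).
#' @return Numeric matrix with `length(t)` rows and 3 columns.
#' @export
spline_basis <- function(t, spec = trajectory_spec("bspline")) {
  bnd <- spec$spline_boundary
  if (any(t < bnd[1] | t > bnd[2]))
    stop("time outside the spline boundary [", bnd[1], ", ", bnd[2], "]",
         call. = FALSE)
  unname(splines::bs(t, degree = 3L, Boundary.knots = bnd,
                     intercept = FALSE)[, , drop = FALSE])
}

#' Random-effects specification
#'
#' @param D 2x2 covariance matrix of the (intercept, slope-per-week) random
#'   effects. Must be symmetric positive semi-definite.
#' @return Object of class `ranef_spec` holding `D`.
#' @export
ranef_spec <- function(D = matrix(c(0.05, 2e-5, 2e-5, 1.6e-7), 2)) {
  D <- as.matrix(D)
  if (!identical(dim(D), c(2L, 2L)) || max(abs(D - t(D))) > 1e-12)
    stop("`D` must be a symmetric 2x2 matrix", call. = FALSE)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1))
    stop("`D` must be positive semi-definite", call. = FALSE)
  structure(list(D = D), class = "ranef_spec")
}

#' Survival submodel specification
#'
#' The hazard for subject \eqn{i} is
#' \deqn{h_i(t) = \phi t^{\phi-1} \exp\{\gamma_0 + \gamma_1 age_i +
#'   \gamma_2 sex_i + \alpha m_i(t)\},}
#' a Weibull baseline with a current-value association on the true
#' log-biomarker level \eqn{m_i(t)}.
#'
#' `log_scale` (\eqn{\gamma_0}) is the baseline log-scale of the Weibull
#' hazard. Its default was calibrated once, by deterministic numerical
#' integration over the covariate and random-effect distributions of the base
#' data-generating process, so that the expected number of events in a study
#' of 200 subjects equals 60.6 under the default censoring scheme; see the
#' methods vignette.
#'
#' @param phi Weibull shape (> 0), dimensionless.
#' @param gamma_age Log-hazard per year of age.
#' @param gamma_sex Log-hazard for female (sex = 1) vs male.
#' @param alpha Association: log-hazard per unit of current true
#'   log-biomarker.
#' @param log_scale Baseline log-scale \eqn{\gamma_0} of the Weibull hazard.
#' @return Object of class `survival_spec`.
#' @export
survival_spec <- function(phi = 1.97, gamma_age = 0.09, gamma_sex = -0.39,
                          alpha = -1.07, log_scale = -15.377) {
  if (!is.finite(phi) || phi <= 0) stop("`phi` must be > 0", call. = FALSE)
  stopifnot(is.finite(gamma_age), is.finite(gamma_sex), is.finite(alpha),
            is.finite(log_scale))
  structure(list(phi = phi, gamma_age = gamma_age, gamma_sex = gamma_sex,
                 alpha = alpha, log_scale = log_scale),
            class = "survival_spec")
}

#' Censoring specification
#'
#' Censoring time is \eqn{C_i = \min(\tilde C_i, admin\_cap)} with
#' \eqn{\tilde C_i \sim U(0, uniform\_upper)}.
#'
#' @param uniform_upper Upper bound (weeks) of the uniform censoring draw.
#' @param admin_cap Administrative censoring horizon (weeks).
#' @return Object of class `censoring_spec`.
#' @export
censoring_spec <- function(uniform_upper = 800, admin_cap = 400) {
  if (!(admin_cap > 0 && admin_cap <= uniform_upper))
    stop("need 0 < admin_cap <= uniform_upper", call. = FALSE)
  structure(list(uniform_upper = uniform_upper, admin_cap = admin_cap),
            class = "censoring_spec")
}

#' Full specification of one simulation scenario
#'
#' Bundles everything needed to generate replicate datasets: cohort size,
#' visit schedule, trajectory and random-effect specifications, measurement
#' error, survival submodel, censoring, covariate distributions, replication
#' count and the base seed.
#'
#' @param n_subjects Number of subjects per dataset.
#' @param schedule Sorted vector of scheduled visit times in weeks; must start
#'   at 0 and stay within the administrative censoring horizon.
#' @param trajectory A [trajectory_spec()].
#' @param ranef A [ranef_spec()].
#' @param sigma_eps Measurement-error SD on the log-biomarker scale.
#' @param survival A [survival_spec()].
#' @param censoring A [censoring_spec()].
#' @param age_mean,age_sd Age distribution (years): Normal(mean, sd).
#' @param p_female Probability of sex = 1 (female).
#' @param n_reps Number of replicate datasets the scenario calls for.
#' @param seed Base seed; replicate `r` uses stream `seed + r`.
#' @param label Free-text scenario label.
#' @return Object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(n_subjects = 50, n_reps = 10)
#' @export
scenario_config <- function(n_subjects = 200,
                            schedule = c(0, 100, 200, 300, 400),
                            trajectory = trajectory_spec(),
                            ranef = ranef_spec(),
                            sigma_eps = 0.092,
                            survival = survival_spec(),
                            censoring = censoring_spec(),
                            age_mean = 80, age_sd = 6.7,
                            p_female = 0.52,
                            n_reps = 200,
                            seed = 1L,
                            label = "base") {
  stopifnot(inherits(trajectory, "trajectory_spec"),
            inherits(ranef, "ranef_spec"),
            inherits(survival, "survival_spec"),
            inherits(censoring, "censoring_spec"))
  if (length(schedule) < 1L) stop("`schedule` must be nonempty", call. = FALSE)
  if (schedule[1] != 0) stop("`schedule` must start at 0", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE))
    stop("`schedule` must be strictly increasing", call. = FALSE)
  if (max(schedule) > censoring$admin_cap)
    stop("`schedule` exceeds the administrative censoring horizon", call. = FALSE)
  if (sigma_eps < 0) stop("`sigma_eps` must be >= 0", call. = FALSE)
  if (p_female < 0 || p_female > 1) stop("`p_female` must be in [0,1]", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (n_subjects < 0) stop("`n_subjects` must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), schedule = as.numeric(schedule),
         trajectory = trajectory, ranef = ranef, sigma_eps = sigma_eps,
         survival = survival, censoring = censoring,
         age_mean = age_mean, age_sd = age_sd, p_female = p_female,
         n_reps = as.integer(n_reps), seed = as.integer(seed), label = label),
    class = "scenario_config")
}

#' Base scenario configuration of the simulation study
#'
#' The default data-generating conditions: 200 subjects, visits every 100
#' weeks up to week 400, linear log-biomarker trajectory with random
#' intercept and slope, Weibull(shape 1.97) hazard linked to the current true
#' biomarker value with association -1.07, and uniform censoring on (0, 800)
#' weeks capped administratively at 400.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
base_config <- function(...) {
  scenario_config(...)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$label, "\n", sep = "")
  cat("  subjects: ", x$n_subjects, ", reps: ", x$n_reps,
      ", seed: ", x$seed, "\n", sep = "")
  cat("  schedule (weeks): ", paste(x$schedule, collapse = ", "), "\n", sep = "")
  cat("  trajectory: ", x$trajectory$kind,
      ", sigma_eps: ", x$sigma_eps, "\n", sep = "")
  s <- x$survival
  cat(sprintf("  survival: phi=%.3g, gamma=(%.3g age, %.3g sex), alpha=%.3g, log_scale=%.4g\n",
              s$phi, s$gamma_age, s$gamma_sex, s$alpha, s$log_scale))
  invisible(x)
}
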