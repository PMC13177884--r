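#' Draw baseline covariates and random effects for a cohort
#'
#' Samples age from Normal(`age_mean`, `age_sd`^2), sex from
#' Bernoulli(`p_female`) (1 = female) and the (intercept, slope) random
#' effects from a bivariate Normal(0, D). Event and censoring times are left
#' unset.
#'
#' @param config A [scenario_config()].
#' @param seed Optional seed set before drawing; omit to use the current RNG
#'   state.
#' @return Data frame with columns `id`, `age`, `sex`, `b0`, `b1`.
#' @export
sample_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  if (n == 0L)
    return(data.frame(id = integer(), age = numeric(), sex = integer(),
                      b0 = numeric(), b1 = numeric()))
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$p_female)
  D <- config$ranef$D
  ## chol() needs strict PD; fall back to an eigen square root on the boundary
  L <- tryCatch(t(chol(D)), error = function(e) {
    e <- eigen(D, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2) %*% t(e$vectors)
  })
  b <- t(L %*% matrix(stats::rnorm(2L * n), nrow = 2L))
  data.frame(id = seq_len(n), age = age, sex = sex, b0 = b[, 1], b1 = b[, 2])
}

## Fixed-effect part of m_i(t); vectorized over t.
trajectory_fixed <- function(spec, age, t) {
  if (spec$kind == "linear") {
    spec$beta0 + spec$beta_time * t + spec$beta_age * age
  } else {
    B <- spline_basis(t, spec)
    spec$beta0 + drop(B %*% spec$beta_spline) + spec$beta_age * age
  }
}

#' True (error-free) biomarker trajectory of one subject
#'
#' Evaluates \eqn{m_i(t)}: the fixed time trend (linear, or a cubic B-spline
#' with three basis functions) plus age effect plus the subject's random
#' intercept and random linear slope.
#'
#' @param subject List or one-row data frame with `age`, `b0`, `b1`.
#' @param spec A [trajectory_spec()].
#' @param t Times in weeks (vectorized); for the bspline kind, must lie
#'   within the spline boundary.
#' @return Numeric vector of log-biomarker values.
#' @examples
#' sp <- trajectory_spec()
#' true_trajectory(list(age = 80, b0 = 0, b1 = 0), sp, 0)  # 5.85 - 0.023*80
#' @export
true_trajectory <- function(subject, spec, t) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  trajectory_fixed(spec, subject$age, t) + subject$b0 + subject$b1 * t
}

#' Cumulative hazard of one subject under the generating model
#'
#' Computes \eqn{\Lambda_i(t) = \int_0^t \phi s^{\phi-1}
#' \exp\{\gamma_0 + \gamma_1 age_i + \gamma_2 sex_i + \alpha m_i(s)\} ds}
#' by fixed-order Gauss-Legendre quadrature on \eqn{[0, t]}.
#'
#' @param subject List or one-row data frame with `age`, `sex`, `b0`, `b1`
#'   (and optionally `id`, used in error messages).
#' @param trajectory A [trajectory_spec()].
#' @param survival A [survival_spec()].
#' @param t Time in weeks (vectorized).
#' @param n_nodes Gauss-Legendre order per evaluation interval.
#' @return Nonnegative cumulative hazard value(s); \eqn{\Lambda_i(0) = 0}.
#' @export
cumulative_hazard <- function(subject, trajectory, survival, t, n_nodes = 31L) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  gl <- gauss_legendre_rule(n_nodes)
  eta0 <- survival$log_scale + survival$gamma_age * subject$age +
    survival$gamma_sex * subject$sex
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    s <- tt / 2 * (gl$nodes + 1)
    w <- tt / 2 * gl$weights
    m <- trajectory_fixed(trajectory, subject$age, s) +
      subject$b0 + subject$b1 * s
    lh <- eta0 + survival$alpha * m
    integrand <- survival$phi * s^(survival$phi - 1) * exp(lh)
    if (!all(is.finite(integrand)))
      stop("non-finite hazard integrand for subject ",
           if (!is.null(subject$id)) subject$id else "<unknown>",
           " at t = ", signif(tt, 4), call. = FALSE)
    sum(w * integrand)
  }, numeric(1))
}

#' Invert the cumulative hazard to simulate an event time
#'
#' Solves \eqn{\Lambda_i(T^*) = -\log u} for \eqn{T^*} by bracketed
#' root-finding (the inversion method). If the cumulative hazard at
#' `horizon` is still below \eqn{-\log u}, the event lies beyond the search
#' horizon and `Inf` is returned (such a subject is always censored).
#'
#' @param subject,trajectory,survival As in [cumulative_hazard()].
#' @param u A uniform(0, 1) draw.
#' @param horizon Upper end of the root search bracket (weeks); the default
#'   is twice the usual administrative cap.
#' @param tol Absolute tolerance on the residual
#'   \eqn{|\Lambda_i(T^*) + \log u|}.
#' @return Event time in weeks, or `Inf` when beyond the horizon.
#' @export
invert_event_time <- function(subject, trajectory, survival, u,
                              horizon = 800, tol = 1e-8) {
  if (!(u > 0 && u < 1)) stop("`u` must be in (0, 1)", call. = FALSE)
  target <- -log(u)
  Lam <- function(tt) cumulative_hazard(subject, trajectory, survival, tt)
  f_hi <- Lam(horizon) - target
  if (f_hi < 0) return(Inf)
  r <- stats::uniroot(function(tt) Lam(tt) - target,
                      lower = 1e-8, upper = horizon,
                      f.lower = -target, f.upper = f_hi,
                      tol = 1e-10 * horizon, maxiter = 1000L)
  tt <- r$root
  ## Newton polish: the hazard is the exact derivative of Lambda
  for (k in 1:10) {
    res <- Lam(tt) - target
    if (abs(res) <= tol) break
    h <- hazard_at(subject, trajectory, survival, tt)
    step <- res / h
    tt <- min(max(tt - step, 1e-10), horizon)
  }
  if (abs(Lam(tt) - target) > tol)
    stop("event-time inversion did not reach tolerance for subject ",
         if (!is.null(subject$id)) subject$id else "<unknown>", call. = FALSE)
  tt
}

## Instantaneous hazard h_i(t); used for Newton polish and likelihoods.
hazard_at <- function(subject, trajectory, survival, t) {
  m <- trajectory_fixed(trajectory, subject$age, t) + subject$b0 + subject$b1 * t
  survival$phi * t^(survival$phi - 1) *
    exp(survival$log_scale + survival$gamma_age * subject$age +
          survival$gamma_sex * subject$sex + survival$alpha * m)
}

#' Apply the uniform-plus-administrative censoring scheme
#'
#' Censoring time is \eqn{C = \min(\tilde C, admin\_cap)} with
#' \eqn{\tilde C \sim U(0, uniform\_upper)}. The observed time is
#' \eqn{\min(T^*, C)} and the event indicator is the strict inequality
#' \eqn{I(T^* < C)}; an event time beyond the simulation horizon (`Inf`)
#' is therefore always censored.
#'
#' @param t_star Event time(s) in weeks; may be `Inf`.
#' @param cens A [censoring_spec()].
#' @param ctilde Optional uniform censoring draw(s); by default drawn from
#'   the current RNG stream.
#' @return Data frame with columns `time`, `event`, `censor_time`.
#' @export
apply_censoring <- function(t_star, cens, ctilde = NULL) {
  n <- length(t_star)
  if (is.null(ctilde)) ctilde <- stats::runif(n, 0, cens$uniform_upper)
  C <- pmin(ctilde, cens$admin_cap)
  data.frame(time = pmin(t_star, C),
             event = as.integer(t_star < C),
             censor_time = C)
}

#' Generate one replicate dataset from a scenario
#'
#' Runs the full generating pipeline: draw the population, simulate latent
#' event times by inverting the cumulative hazard, apply censoring, and lay
#' down noisy longitudinal measurements at every scheduled visit that falls
#' at or before the subject's observed time. Replicate `rep_index` uses the
#' seed `config$seed + rep_index`, so any single replicate is reproducible
#' in isolation.
#'
#' @param config A [scenario_config()].
#' @param rep_index Replicate number (>= 1 by convention).
#' @return Object of class `sim_dataset`: a list with elements
#'   `longitudinal` (id, time, y), `survival` (id, time, event, age, sex),
#'   `truth` (per-subject latent quantities) and the generating `config`.
#' @examples
#' d <- generate_dataset(scenario_config(n_subjects = 20, seed = 7), 1)
#' head(d$longitudinal)
#' @export
generate_dataset <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + as.integer(rep_index))
  pop <- sample_population(config)
  n <- nrow(pop)
  horizon <- 2 * config$censoring$admin_cap
  u <- stats::runif(n)
  t_star <- numeric(n)
  for (i in seq_len(n))
    t_star[i] <- invert_event_time(pop[i, ], config$trajectory,
                                   config$survival, u[i], horizon = horizon)
  cens <- apply_censoring(t_star, config$censoring)

  truth <- cbind(pop,
                 event_time_true = t_star,
                 censor_time = cens$censor_time,
                 observed_time = cens$time,
                 event = cens$event)

  keep <- lapply(seq_len(n), function(i) {
    tt <- config$schedule[config$schedule <= cens$time[i]]
    data.frame(id = pop$id[i], time = tt)
  })
  long <- do.call(rbind, keep)
  m <- trajectory_fixed(config$trajectory, pop$age[match(long$id, pop$id)],
                        long$time) +
    pop$b0[match(long$id, pop$id)] + pop$b1[match(long$id, pop$id)] * long$time
  long$y <- m + stats::rnorm(nrow(long), 0, config$sigma_eps)
  rownames(long) <- NULL

  structure(
    list(longitudinal = long,
         survival = data.frame(id = pop$id, time = cens$time,
                               event = cens$event, age = pop$age,
                               sex = pop$sex),
         truth = truth,
         config = config,
         rep_index = as.integer(rep_index)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> scenario '", x$config$label, "', replicate ",
      x$rep_index, "\n", sep = "")
  cat("  ", nrow(x$survival), " subjects, ", sum(x$survival$event),
      " events, ", nrow(x$longitudinal), " longitudinal observations\n",
      sep = "")
  invisible(x)
}

#' Write a simulated dataset as plain CSV tables
#'
#' Writes `longitudinal.csv` (id, time_weeks, y), `survival.csv`
#' (id, time_weeks, event, age, sex) and `truth.csv` (latent per-subject
#' quantities) into `dir`.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- dataset$longitudinal
  names(long)[names(long) == "time"] <- "time_weeks"
  surv <- dataset$survival
  names(surv)[names(surv) == "time"] <- "time_weeks"
  utils::write.csv(long, file.path(dir, "longitudinal.csv"), row.names = FALSE)
  utils::write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read longitudinal and survival CSV tables written by [write_dataset()]
#'
#' @param dir Directory containing `longitudinal.csv` and `survival.csv`.
#' @return A list with elements `longitudinal` and `survival` using the
#'   in-memory column names (`time`, not `time_weeks`).
#' @export
read_dataset <- function(dir) {
  long <- utils::read.csv(file.path(dir, "longitudinal.csv"))
  surv <- utils::read.csv(file.path(dir, "survival.csv"))
  names(long)[names(long) == "time_weeks"] <- "time"
  names(surv)[names(surv) == "time_weeks"] <- "time"
  list(longitudinal = long, survival = surv)
}

#' Generate complete longitudinal trajectories without event truncation
#'
#' Draws a population and lays down noisy measurements at every scheduled
#' visit for every subject, ignoring the survival process entirely. This is
#' the "complete data" benchmark used to validate the longitudinal submodel:
#' with no event-driven dropout, a maximum-likelihood mixed-model fit must
#' recover the generating fixed effects and variance components.
#'
#' @param config A [scenario_config()].
#' @param rep_index Replicate number; the seed is `config$seed + rep_index`,
#'   as in [generate_dataset()].
#' @return List with `longitudinal` (id, time, y for every scheduled visit)
#'   and `survival` (id, age, sex only, as a covariate source).
#' @export
generate_complete_longitudinal <- function(config, rep_index = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + as.integer(rep_index))
  pop <- sample_population(config)
  k <- length(config$schedule)
  long <- data.frame(id = rep(pop$id, each = k),
                     time = rep(config$schedule, nrow(pop)))
  i <- match(long$id, pop$id)
  m <- trajectory_fixed(config$trajectory, pop$age[i], long$time) +
    pop$b0[i] + pop$b1[i] * long$time
  long$y <- m + stats::rnorm(nrow(long), 0, config$sigma_eps)
  list(longitudinal = long,
       survival = data.frame(id = pop$id, age = pop$age, sex = pop$sex),
       truth = pop, config = config)
}
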