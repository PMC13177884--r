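test_that("population sampling respects its distributions and determinism", {
  cfg <- scenario_config(n_subjects = 0)
  expect_equal(nrow(sample_population(cfg)), 0L)

  cfg <- small_config(n = 50)
  p1 <- sample_population(cfg, seed = 42)
  p2 <- sample_population(cfg, seed = 42)
  expect_identical(p1, p2)

  big <- scenario_config(n_subjects = 1e5)
  pop <- sample_population(big, seed = 7)
  se <- big$age_sd / sqrt(1e5)
  expect_lt(abs(mean(pop$age) - 80), 3 * se)
  expect_lt(abs(mean(pop$sex) - 0.52), 3 * sqrt(0.52 * 0.48 / 1e5))
  expect_lt(abs(stats::var(pop$b0) - 0.05), 0.05 * 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(ranef_spec(matrix(c(1, 2, 2, 1), 2)), "positive semi-definite")
  expect_error(survival_spec(phi = -1), "phi")
  expect_error(scenario_config(schedule = c(100, 200)), "start at 0")
  expect_error(scenario_config(schedule = c(0, 500)), "horizon")
  expect_error(scenario_config(schedule = numeric()), "nonempty")
  expect_error(censoring_spec(uniform_upper = 100, admin_cap = 400), "admin_cap")
})

test_that("true trajectory evaluates the linear and spline forms", {
  sp <- trajectory_spec()
  # beta0 + beta_age * age at t = 0: 5.85 - 0.023 * 80
  expect_equal(true_trajectory(flat_subject(), sp, 0), 4.010, tolerance = 1e-12)

  # slope-free case is constant in t
  sp0 <- trajectory_spec(beta_time = 0)
  v <- true_trajectory(flat_subject(), sp0, c(0, 100, 400))
  expect_equal(v, rep(v[1], 3))

  # zero spline coefficients collapse to intercept + age + random part
  spb <- trajectory_spec("bspline", beta_spline = c(0, 0, 0))
  subj <- flat_subject(b0 = 0.3, b1 = 0.001)
  tt <- c(0, 50, 200, 400)
  expect_equal(true_trajectory(subj, spb, tt),
               spb$beta0 + spb$beta_age * 80 + 0.3 + 0.001 * tt)
  expect_error(true_trajectory(subj, spb, 401), "boundary")

  # retained B-spline columns: non-negative, summing to <= 1
  B <- spline_basis(seq(0, 400, by = 10))
  expect_true(all(B >= 0))
  expect_true(all(rowSums(B) <= 1 + 1e-12))
})

test_that("cumulative hazard matches closed forms and a dense trapezoid", {
  sp <- trajectory_spec()
  # alpha = 0, gamma = 0, log_scale = 0, phi = 2: Lambda(t) = t^2
  sv <- survival_spec(phi = 2, gamma_age = 0, gamma_sex = 0, alpha = 0,
                      log_scale = 0)
  expect_equal(cumulative_hazard(flat_subject(), sp, sv, 3), 9,
               tolerance = 1e-10)
  expect_equal(cumulative_hazard(flat_subject(), sp, sv, 0), 0)

  # alpha = 0 with covariates: t^phi * exp(gamma'w)
  sv2 <- survival_spec(phi = 1.7, gamma_age = 0.01, gamma_sex = -0.4,
                       alpha = 0, log_scale = -2)
  subj <- flat_subject(age = 75, sex = 1)
  # s^(phi-1) has a mild derivative singularity at 0, so ask for a finer
  # rule than the default when comparing to the closed form
  expect_equal(cumulative_hazard(subj, sp, sv2, 10, n_nodes = 301),
               10^1.7 * exp(-2 + 0.01 * 75 - 0.4), tolerance = 1e-7)

  # general linear trajectory vs 1e5-step trapezoid oracle
  sv3 <- survival_spec()
  subj <- flat_subject(age = 83, sex = 1, b0 = 0.2, b1 = -4e-4)
  for (tt in c(50, 400)) {
    lam <- cumulative_hazard(subj, sp, sv3, tt)
    expect_equal(lam, trapezoid_cumhaz(subj, sp, sv3, tt),
                 tolerance = 1e-6)
  }

  # monotone nondecreasing in t
  tt <- seq(0, 400, by = 50)
  lam <- cumulative_hazard(flat_subject(), sp, sv3, tt)
  expect_true(all(diff(lam) >= 0))
})

test_that("event-time inversion solves Lambda(T) = -log(u)", {
  sp <- trajectory_spec()
  # alpha = gamma = 0, log_scale = 0: T* = E^(1/phi); u = e^-1 gives T* = 1
  sv <- survival_spec(phi = 1.97, gamma_age = 0, gamma_sex = 0, alpha = 0,
                      log_scale = 0)
  expect_equal(invert_event_time(flat_subject(), sp, sv, exp(-1)), 1,
               tolerance = 1e-7)

  # monotone: smaller u (larger E) gives later-or-equal event times... the
  # inversion is decreasing in u
  sv3 <- survival_spec()
  subj <- flat_subject(age = 78)
  us <- c(0.05, 0.2, 0.5, 0.9)
  ts <- vapply(us, function(u)
    invert_event_time(subj, sp, sv3, u, horizon = 1e5), numeric(1))
  expect_true(all(diff(ts) <= 0))

  # residual check against the package cumulative hazard
  for (u in c(0.1, 0.6)) {
    tt <- invert_event_time(subj, sp, sv3, u, horizon = 1e5)
    expect_lt(abs(cumulative_hazard(subj, sp, sv3, tt) + log(u)), 1e-8)
  }

  # beyond-horizon contract
  svnull <- survival_spec(alpha = 0, gamma_age = 0, gamma_sex = 0,
                          log_scale = -50)
  expect_identical(invert_event_time(flat_subject(), sp, svnull, 0.5,
                                     horizon = 800), Inf)
  expect_error(invert_event_time(flat_subject(), sp, sv3, 1.5), "in \\(0, 1\\)")
})

test_that("censoring uses the strict-inequality event indicator", {
  cs <- censoring_spec()
  r <- apply_censoring(100, cs, ctilde = 600)
  expect_equal(c(r$time, r$event), c(100, 1))
  r <- apply_censoring(500, cs, ctilde = 900)
  expect_equal(c(r$time, r$event), c(400, 0))
  # T* = C exactly: strict inequality codes a censoring
  r <- apply_censoring(300, cs, ctilde = 300)
  expect_equal(c(r$time, r$event), c(300, 0))
  # beyond-horizon events are always censored
  r <- apply_censoring(Inf, cs, ctilde = 123)
  expect_equal(c(r$time, r$event), c(123, 0))
})

test_that("generated datasets satisfy their structural invariants", {
  cfg <- small_config(n = 60)
  d <- generate_dataset(cfg, 1)
  expect_s3_class(d, "sim_dataset")
  expect_equal(nrow(d$survival), 60L)
  expect_setequal(unique(d$longitudinal$id), d$survival$id)
  obs_t <- d$truth$observed_time[match(d$longitudinal$id, d$truth$id)]
  expect_true(all(d$longitudinal$time <= obs_t))
  expect_true(all(d$longitudinal$time %in% cfg$schedule))
  expect_equal(d$truth$observed_time,
               pmin(d$truth$event_time_true, d$truth$censor_time))
  expect_true(all(d$truth$event %in% 0:1))
  ev <- d$truth$event == 1
  expect_equal(d$truth$observed_time[ev], d$truth$event_time_true[ev])

  # measurement error recoverable from the retained truth
  i <- d$longitudinal$id[7]
  row <- d$longitudinal[7, ]
  tru <- d$truth[d$truth$id == i, ]
  m <- true_trajectory(tru, cfg$trajectory, row$time)
  expect_true(abs(row$y - m) < 6 * cfg$sigma_eps)

  # bit-identical regeneration
  d2 <- generate_dataset(cfg, 1)
  expect_identical(d$longitudinal, d2$longitudinal)
  expect_identical(d$survival, d2$survival)
  # different replicate differs
  d3 <- generate_dataset(cfg, 2)
  expect_false(identical(d$survival$time, d3$survival$time))
})

test_that("round-trip through CSV preserves the tables", {
  d <- generate_dataset(small_config(n = 10), 1)
  dir <- tempfile()
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_equal(back$longitudinal$y, d$longitudinal$y, tolerance = 1e-12)
  expect_equal(back$survival$event, d$survival$event)
  unlink(dir, recursive = TRUE)
})

test_that("Cox-Snell residuals of simulated event times are unit exponential", {
  # Independent check of the whole simulation path: evaluate Lambda at the
  # simulated T* with a dense trapezoid (not the package quadrature), for
  # subjects drawn from the population. Under a correct implementation the
  # residuals are Exp(1).
  cfg <- scenario_config(n_subjects = 2000, seed = 990)
  pop <- sample_population(cfg, seed = 990)
  set.seed(991)
  u <- runif(nrow(pop))
  res <- numeric(nrow(pop))
  keep <- logical(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    tt <- invert_event_time(pop[i, ], cfg$trajectory, cfg$survival, u[i],
                            horizon = 5e4)
    if (is.finite(tt)) {
      res[i] <- trapezoid_cumhaz(pop[i, ], cfg$trajectory, cfg$survival, tt,
                                 n_steps = 2e3)
      keep[i] <- TRUE
    }
  }
  r <- res[keep]
  expect_gt(length(r), 1990)  # the generous horizon leaves no real truncation
  ks <- stats::ks.test(r, stats::pexp)
  expect_gt(ks$p.value, 0.01)
})

test_that("with no association and no covariates times are Weibull(phi, 1)", {
  cfg <- scenario_config(
    n_subjects = 4000, seed = 1234,
    survival = survival_spec(phi = 1.97, gamma_age = 0, gamma_sex = 0,
                             alpha = 0, log_scale = 0))
  pop <- sample_population(cfg, seed = 55)
  set.seed(56)
  u <- runif(nrow(pop))
  ts <- vapply(seq_len(nrow(pop)), function(i)
    invert_event_time(pop[i, ], cfg$trajectory, cfg$survival, u[i],
                      horizon = 100), numeric(1))
  expect_true(all(is.finite(ts)))
  for (q in c(0.5, 1, 1.5)) {
    emp <- mean(ts > q)
    thr <- exp(-q^1.97)
    expect_lt(abs(emp - thr), 3 * sqrt(thr * (1 - thr) / 4000) + 1e-4)
  }
})

test_that("mean observed y tracks the fixed-effect trajectory", {
  cfg <- scenario_config(n_subjects = 4000, seed = 77)
  set.seed(78)
  pop <- sample_population(cfg)
  for (tt in c(0, 200)) {
    m <- cfg$trajectory$beta0 +
      cfg$trajectory$beta_time * tt + cfg$trajectory$beta_age * mean(pop$age)
    y <- true_trajectory(pop, cfg$trajectory, rep(tt, nrow(pop))) +
      rnorm(nrow(pop), 0, cfg$sigma_eps)
    expect_lt(abs(mean(y) - m), 4 * sd(y) / sqrt(nrow(pop)))
  }
})

test_that("scenario grids vary exactly one quantity over the study ranges", {
  s5 <- build_scenarios("5a")
  sig <- vapply(s5, function(cfg) cfg$sigma_eps, numeric(1))
  expect_true(all(c(0.05, 0.5) %in% sig))
  expect_true(all(vapply(s5, function(cfg) cfg$survival$alpha, numeric(1)) ==
                    -1.07))

  s2 <- build_scenarios("2a")
  al <- vapply(s2, function(cfg) cfg$survival$alpha, numeric(1))
  expect_true(all(c(-1.5, 0) %in% al))

  s3 <- build_scenarios("3b")
  expect_equal(range(vapply(s3, function(cfg) cfg$survival$phi, numeric(1))),
               c(1.6, 2.8))
  expect_true(all(vapply(s3, function(cfg) cfg$trajectory$kind,
                         character(1)) == "bspline"))

  s1 <- build_scenarios("1a")
  expect_true(any(vapply(s1, function(cfg)
    identical(cfg$schedule, c(0, 300)), logical(1))))
  expect_equal(build_scenarios("1a")[[3]]$schedule, seq(0, 400, 100))

  base <- scenario_config()
  expect_equal(base$schedule, c(0, 100, 200, 300, 400))
  expect_error(build_scenarios("9z"), "unknown setting")
})

test_that("the default baseline log-scale is reproduced by recalibration", {
  g0 <- calibrate_log_scale(scenario_config(), 60.6, n_mc = 1e4, seed = 3)
  expect_lt(abs(g0 - scenario_config()$survival$log_scale), 0.05)
})
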