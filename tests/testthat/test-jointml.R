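base_params <- function(cfg = scenario_config()) {
  jointsim:::params_from_config(cfg)
}

test_that("conditional subject loglik matches closed forms and a dense oracle", {
  pars <- base_params()
  tr <- trajectory_spec()
  subj <- list(y = c(4.05, 3.98), t = c(0, 100), T = 150, delta = 1L,
               age = 82, sex = 1)

  # zero-time boundary: no survival contribution when T = 0 and delta = 0
  subj0 <- list(y = numeric(), t = numeric(), T = 0, delta = 0L,
                age = 82, sex = 1)
  expect_equal(subject_loglik_given_b(subj0, c(0, 0), pars, tr), 0)

  # alpha = 0 decouples: survival part is the plain Weibull-with-covariates
  # log density
  p0 <- pars; p0$alpha <- 0
  b <- c(0.1, -2e-4)
  got <- subject_loglik_given_b(subj, b, p0, tr, gl_nodes = 201)
  eta <- p0$log_scale + p0$gamma_age * 82 + p0$gamma_sex * 1
  surv_cf <- log(p0$phi) + (p0$phi - 1) * log(150) + eta -
    150^p0$phi * exp(eta)
  m <- p0$beta[1] + p0$beta[2] * subj$t + p0$beta[3] * 82 + b[1] + b[2] * subj$t
  long_cf <- sum(dnorm(subj$y, m, p0$sigma, log = TRUE))
  expect_equal(got, unname(surv_cf + long_cf), tolerance = 1e-8)

  # general alpha: cumulative hazard against a high-resolution numeric oracle
  got2 <- subject_loglik_given_b(subj, b, pars, tr, gl_nodes = 61)
  s <- seq(0, 150, length.out = 2e5 + 1)
  msubj <- pars$beta[1] + pars$beta[2] * s + pars$beta[3] * 82 +
    b[1] + b[2] * s
  h <- pars$phi * s^(pars$phi - 1) *
    exp(pars$log_scale + pars$gamma_age * 82 + pars$gamma_sex * 1 +
          pars$alpha * msubj)
  h[1] <- 0
  Lam <- sum((h[-1] + h[-length(h)]) / 2) * (150 / 2e5)
  mT <- pars$beta[1] + pars$beta[2] * 150 + pars$beta[3] * 82 +
    b[1] + b[2] * 150
  oracle <- log(pars$phi) + (pars$phi - 1) * log(150) +
    pars$log_scale + pars$gamma_age * 82 + pars$gamma_sex * 1 +
    pars$alpha * mT - Lam +
    sum(dnorm(subj$y, pars$beta[1] + pars$beta[2] * subj$t +
                pars$beta[3] * 82 + b[1] + b[2] * subj$t, pars$sigma,
              log = TRUE))
  expect_equal(got2, unname(oracle), tolerance = 1e-8)
})

test_that("marginal loglik factorizes at alpha = 0 into LMM + Weibull parts", {
  cfg <- scenario_config(n_subjects = 25, seed = 701)
  d <- generate_dataset(cfg, 1)
  pars <- base_params(cfg)
  pars$alpha <- 0
  got <- marginal_loglik(d, pars, n_nodes = 9, gl_nodes = 101)
  want <- dense_lmm_loglik(d$longitudinal, d$survival, pars$beta, pars$D,
                           pars$sigma) +
    weibull_surv_loglik(d$survival, pars$phi, pars$log_scale,
                        pars$gamma_age, pars$gamma_sex)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("marginal loglik agrees with dense 2-D integration per subject", {
  cfg <- scenario_config(n_subjects = 4, seed = 702)
  d <- generate_dataset(cfg, 1)
  pars <- base_params(cfg)
  got <- marginal_loglik(d, pars, n_nodes = 9)
  Dinv <- solve(pars$D)
  ldD <- as.numeric(determinant(pars$D)$modulus)
  want <- 0
  ng <- 701
  g1 <- seq(-6, 6, length.out = ng) * sqrt(pars$D[1, 1])
  g2 <- seq(-6, 6, length.out = ng) * sqrt(pars$D[2, 2])
  B0 <- matrix(g1, ng, ng)        # b0 varies along rows
  B1 <- matrix(g2, ng, ng, byrow = TRUE)
  gl <- jointsim:::gauss_legendre_rule(15)
  for (i in seq_len(4)) {
    s <- d$longitudinal[d$longitudinal$id == d$survival$id[i], ]
    Tt <- d$survival$time[i]; del <- d$survival$event[i]
    age <- d$survival$age[i]; sex <- d$survival$sex[i]
    eta <- pars$log_scale + pars$gamma_age * age + pars$gamma_sex * sex
    mfix <- function(tt) pars$beta[1] + pars$beta[2] * tt + pars$beta[3] * age
    ll <- matrix(0, ng, ng)
    for (j in seq_len(nrow(s)))   # longitudinal density on the grid
      ll <- ll + dnorm(s$y[j], mfix(s$t[j]) + B0 + B1 * s$t[j], pars$sigma,
                       log = TRUE)
    sk <- Tt / 2 * (gl$nodes + 1); wk <- Tt / 2 * gl$weights
    Lam <- 0
    for (k in seq_len(15))        # cumulative hazard on the grid
      Lam <- Lam + wk[k] * pars$phi * sk[k]^(pars$phi - 1) *
        exp(eta + pars$alpha * (mfix(sk[k]) + B0 + B1 * sk[k]))
    ll <- ll - Lam
    if (del == 1)
      ll <- ll + log(pars$phi) + (pars$phi - 1) * log(Tt) + eta +
        pars$alpha * (mfix(Tt) + B0 + B1 * Tt)
    ll <- ll - log(2 * pi) - 0.5 * ldD -
      0.5 * (Dinv[1, 1] * B0^2 + 2 * Dinv[1, 2] * B0 * B1 + Dinv[2, 2] * B1^2)
    want <- want + log(sum(exp(ll)) * diff(g1)[1] * diff(g2)[1])
  }
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("quadrature refinement and degenerate-D limit behave", {
  cfg <- scenario_config(n_subjects = 20, seed = 703)
  d <- generate_dataset(cfg, 1)
  pars <- base_params(cfg)
  expect_equal(marginal_loglik(d, pars, n_nodes = 9),
               marginal_loglik(d, pars, n_nodes = 25), tolerance = 1e-4)
  expect_error(marginal_loglik(d, pars, n_nodes = 2), "n_nodes")

  # D -> 0: approaches the conditional likelihood at b = 0
  tiny <- pars
  tiny$D <- diag(c(1e-10, 1e-16))
  got <- marginal_loglik(d, tiny, n_nodes = 9)
  want <- sum(vapply(seq_len(20), function(i) {
    s <- d$longitudinal[d$longitudinal$id == d$survival$id[i], ]
    subject_loglik_given_b(
      list(y = s$y, t = s$time, T = d$survival$time[i],
           delta = d$survival$event[i], age = d$survival$age[i],
           sex = d$survival$sex[i]),
      c(0, 0), tiny, cfg$trajectory)
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("the joint fit improves on its start and is order invariant", {
  cfg <- scenario_config(n_subjects = 60, seed = 704)
  d <- generate_dataset(cfg, 1)
  f <- fit_joint(d)
  expect_gte(f$loglik, f$start_loglik - 1e-6)
  expect_true(is.finite(f$se[["alpha"]]) || !f$converged)
  # non-PD Hessian forces converged = FALSE regardless of the optimizer code
  expect_true(!f$converged || f$hessian_pd)

  perm <- sample(nrow(d$survival))
  d2 <- d
  d2$survival <- d$survival[perm, ]
  d2$truth <- d$truth[perm, ]
  f2 <- fit_joint(d2)
  expect_equal(f2$estimates[["alpha"]], f$estimates[["alpha"]],
               tolerance = 1e-3)
  expect_equal(f2$loglik, f$loglik, tolerance = 1e-4)
})

test_that("supplying explicit starting values is honoured", {
  cfg <- scenario_config(n_subjects = 50, seed = 705)
  d <- generate_dataset(cfg, 1)
  pars <- base_params(cfg)
  f <- fit_joint(d, start = pars, control = list(maxit = 0, hessian = FALSE))
  expect_equal(unname(f$estimates[["alpha"]]), pars$alpha, tolerance = 1e-8)
  expect_equal(f$start_loglik,
               marginal_loglik(d, pars, n_nodes = 9), tolerance = 1e-6)
})
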