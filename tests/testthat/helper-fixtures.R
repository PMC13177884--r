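# Shared fixtures: small scenario configurations and hand-built subjects
# used across the unit tests. Everything is generated in code; no files.

small_config <- function(n = 40, seed = 101, ...) {
  scenario_config(n_subjects = n, seed = seed, n_reps = 5, ...)
}

# a deterministic "average" subject: mean age, male, no random effects
flat_subject <- function(age = 80, sex = 0, b0 = 0, b1 = 0, id = 1L) {
  list(id = id, age = age, sex = sex, b0 = b0, b1 = b1)
}

# dense-trapezoid oracle for the cumulative hazard of a linear-trajectory
# subject (independent of the package's Gauss-Legendre path)
trapezoid_cumhaz <- function(subject, trajectory, survival, t, n_steps = 1e5) {
  s <- seq(0, t, length.out = n_steps + 1)
  m <- trajectory$beta0 + trajectory$beta_time * s +
    trajectory$beta_age * subject$age + subject$b0 + subject$b1 * s
  h <- survival$phi * s^(survival$phi - 1) *
    exp(survival$log_scale + survival$gamma_age * subject$age +
          survival$gamma_sex * subject$sex + survival$alpha * m)
  h[1] <- 0  # phi > 1 so the integrand vanishes at 0
  sum((h[-1] + h[-length(h)]) / 2) * (t / n_steps)
}

# dense multivariate-normal evaluation of the LMM marginal log-likelihood,
# assembled independently of the fitting code
dense_lmm_loglik <- function(longitudinal, survival, beta, D, sigma) {
  ll <- 0
  for (i in unique(longitudinal$id)) {
    s <- longitudinal[longitudinal$id == i, ]
    age <- survival$age[survival$id == i]
    X <- cbind(1, s$time, age)
    Z <- cbind(1, s$time)
    V <- Z %*% D %*% t(Z) + diag(sigma^2, nrow(s))
    r <- s$y - drop(X %*% beta)
    ll <- ll - 0.5 * (nrow(s) * log(2 * pi) +
                        as.numeric(determinant(V)$modulus) +
                        drop(t(r) %*% solve(V) %*% r))
  }
  ll
}

# closed-form Weibull PH log-likelihood with baseline covariates only
weibull_surv_loglik <- function(survival, phi, log_scale, gamma_age, gamma_sex) {
  eta <- log_scale + gamma_age * survival$age + gamma_sex * survival$sex
  sum(survival$event * (log(phi) + (phi - 1) * log(survival$time) + eta) -
        survival$time^phi * exp(eta))
}
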