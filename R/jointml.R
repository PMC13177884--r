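#' Parameter set of the joint model
#'
#' Bundles the parameters of the correctly specified joint model: fixed
#' effects `beta` of the longitudinal submodel (intercept, time trend, age),
#' residual SD `sigma`, random-effects covariance `D`, Weibull shape `phi`,
#' baseline log-scale `log_scale`, baseline survival covariate effects
#' `gamma_age` and `gamma_sex`, and the current-value association `alpha`.
#'
#' @param beta Named numeric vector of longitudinal fixed effects.
#' @param sigma Residual SD (> 0).
#' @param D 2x2 random-effects covariance (PSD).
#' @param phi Weibull shape (> 0).
#' @param log_scale Baseline log-scale of the Weibull hazard.
#' @param gamma_age,gamma_sex Baseline log-hazard effects.
#' @param alpha Current-value association.
#' @return Object of class `joint_params`.
#' @export
joint_params <- function(beta, sigma, D, phi, log_scale,
                         gamma_age, gamma_sex, alpha) {
  stopifnot(sigma > 0, phi > 0)
  D <- as.matrix(D)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("`D` must be PSD", call. = FALSE)
  structure(list(beta = beta, sigma = sigma, D = D, phi = phi,
                 log_scale = log_scale, gamma_age = gamma_age,
                 gamma_sex = gamma_sex, alpha = alpha),
            class = "joint_params")
}

## joint_params from a scenario config (the generating truth)
params_from_config <- function(config) {
  tr <- config$trajectory
  beta <- if (tr$kind == "linear")
    c("(Intercept)" = tr$beta0, time = tr$beta_time, age = tr$beta_age)
  else c("(Intercept)" = tr$beta0,
         stats::setNames(tr$beta_spline, paste0("spline", 1:3)),
         age = tr$beta_age)
  joint_params(beta = beta, sigma = config$sigma_eps, D = config$ranef$D,
               phi = config$survival$phi, log_scale = config$survival$log_scale,
               gamma_age = config$survival$gamma_age,
               gamma_sex = config$survival$gamma_sex,
               alpha = config$survival$alpha)
}

#' Conditional log-likelihood contribution of one subject given its random
#' effects
#'
#' Evaluates \eqn{\log p(T_i, \delta_i \mid b_i) + \sum_j \log
#' N(y_{ij}; m_i(t_{ij} \mid b_i), \sigma^2)} with
#' \eqn{\log p(T, \delta \mid b) = \delta \log h_i(T \mid b) -
#' \Lambda_i(T \mid b)}, the cumulative hazard computed by Gauss-Legendre
#' quadrature. The random-effects density is *not* included; it enters in
#' [marginal_loglik()] as the mixing distribution.
#'
#' @param subject List with `y`, `t` (longitudinal rows), `T` (observed
#'   time), `delta` (0/1), `age`, `sex`.
#' @param b Length-2 random-effects vector (intercept, slope).
#' @param params A [joint_params()].
#' @param trajectory A [trajectory_spec()] defining the fixed time trend
#'   (its coefficients are ignored; `params$beta` is used).
#' @param gl_nodes Gauss-Legendre order for the cumulative hazard.
#' @return Scalar log density contribution.
#' @export
subject_loglik_given_b <- function(subject, b, params,
                                   trajectory = trajectory_spec(),
                                   gl_nodes = 15L) {
  p <- length(params$beta)
  tcols <- function(tt) {
    if (trajectory$kind == "linear") matrix(tt, ncol = 1)
    else spline_basis(tt, trajectory)
  }
  mfun <- function(tt) {
    params$beta[1] + drop(tcols(tt) %*% params$beta[2:(p - 1)]) +
      params$beta[p] * subject$age + b[1] + b[2] * tt
  }
  eta_w <- params$log_scale + params$gamma_age * subject$age +
    params$gamma_sex * subject$sex
  ll <- 0
  if (subject$T > 0) {
    gl <- gauss_legendre_rule(gl_nodes)
    s <- subject$T / 2 * (gl$nodes + 1)
    w <- subject$T / 2 * gl$weights
    Lam <- sum(w * params$phi * s^(params$phi - 1) *
                 exp(eta_w + params$alpha * mfun(s)))
    ll <- ll - Lam
    if (subject$delta == 1)
      ll <- ll + log(params$phi) + (params$phi - 1) * log(subject$T) +
        eta_w + params$alpha * mfun(subject$T)
  }
  if (length(subject$y))
    ll <- ll + sum(stats::dnorm(subject$y, mfun(subject$t), params$sigma,
                                log = TRUE))
  if (!is.finite(ll)) {
    warning("non-finite conditional log-likelihood; contributing -Inf")
    ll <- -Inf
  }
  unname(ll)
}

## ----- internal packing for the C++ likelihood core ------------------------

## Per-subject quadrature centering: means mu (n x 2) and Cholesky factors
## (lower-triangular) of the scaling covariance. Pseudo-adaptive centering
## uses the random-effects posterior given the longitudinal data only, which
## is available in closed form for any parameter value.
centering_from_params <- function(dataset, params, trajectory) {
  surv <- dataset$survival
  long <- dataset$longitudinal
  n <- nrow(surv)
  p <- length(params$beta)
  D <- params$D
  mu <- matrix(0, n, 2)
  Ls <- vector("list", n)
  tcols <- function(tt) {
    if (trajectory$kind == "linear") matrix(tt, ncol = 1)
    else spline_basis(tt, trajectory)
  }
  sp <- split(long[c("time", "y")], factor(long$id, levels = surv$id))
  for (i in seq_len(n)) {
    s <- sp[[i]]
    Z <- cbind(1, s$time)
    V <- Z %*% D %*% t(Z) + diag(params$sigma^2, nrow(s))
    W <- chol2inv(chol(V))
    fixed <- params$beta[1] + drop(tcols(s$time) %*% params$beta[2:(p - 1)]) +
      params$beta[p] * surv$age[i]
    DZW <- D %*% t(Z) %*% W
    mu[i, ] <- drop(DZW %*% (s$y - fixed))
    Sig <- D - DZW %*% Z %*% D
    Ls[[i]] <- t(chol((Sig + t(Sig)) / 2))
  }
  list(mu = mu, L = Ls)
}

## Prepare the fixed data arrays for the C++ core: design matrices,
## Gauss-Legendre grids ordered by subject, and the per-subject adaptive
## Gauss-Hermite node grids implied by the centering.
pack_joint_data <- function(dataset, trajectory, centering,
                            n_nodes = 9L, gl_nodes = 15L) {
  surv <- dataset$survival
  long <- dataset$longitudinal
  n <- nrow(surv)
  tcols <- function(tt) {
    if (trajectory$kind == "linear") matrix(tt, ncol = 1)
    else spline_basis(tt, trajectory)
  }
  subj_long <- match(long$id, surv$id)
  X_long <- cbind(1, tcols(long$time), surv$age[subj_long])
  X_T <- cbind(1, tcols(surv$time), surv$age)
  gl <- gauss_legendre_rule(gl_nodes)
  s_gl <- as.vector(vapply(surv$time, function(Tt) Tt / 2 * (gl$nodes + 1),
                           numeric(gl_nodes)))
  w_gl <- as.vector(vapply(surv$time, function(Tt) Tt / 2 * gl$weights,
                           numeric(gl_nodes)))
  subj_gl <- rep(seq_len(n), each = gl_nodes)
  X_gl <- cbind(1, tcols(s_gl), surv$age[subj_gl])

  gh <- gauss_hermite_grid(n_nodes)
  Q <- nrow(gh$nodes)
  B0 <- matrix(0, n, Q); B1 <- matrix(0, n, Q); LW <- matrix(0, n, Q)
  for (i in seq_len(n)) {
    L <- centering$L[[i]]
    bb <- sqrt(2) * gh$nodes %*% t(L)
    B0[i, ] <- centering$mu[i, 1] + bb[, 1]
    B1[i, ] <- centering$mu[i, 2] + bb[, 2]
    LW[i, ] <- gh$logw + log(2) + sum(log(diag(L)))
  }
  list(n = n, p = ncol(X_long),
       y = long$y, t_long = long$time, subj_long = subj_long - 1L,
       X_long = X_long, X_T = X_T, X_gl = X_gl,
       Tobs = surv$time, delta = as.integer(surv$event),
       age = surv$age, sex = surv$sex,
       s_gl = s_gl, w_gl = w_gl, subj_gl = subj_gl - 1L,
       B0 = B0, B1 = B1, LW = LW)
}

## Marginal loglik from a pack and natural parameters.
packed_loglik <- function(pack, params) {
  D <- params$D
  Dinv <- solve(D)
  logdetD <- determinant(D, logarithm = TRUE)$modulus
  beta <- params$beta
  mfix_long <- drop(pack$X_long %*% beta)
  mfix_T <- drop(pack$X_T %*% beta)
  mfix_gl <- drop(pack$X_gl %*% beta)
  eta_w <- params$log_scale + params$gamma_age * pack$age +
    params$gamma_sex * pack$sex
  base_gl <- pack$w_gl * params$phi * pack$s_gl^(params$phi - 1)
  ll <- joint_nll_cpp(pack$y, pack$t_long, mfix_long, pack$subj_long,
                      pack$Tobs, pack$delta, eta_w, mfix_T,
                      pack$s_gl, base_gl, mfix_gl, pack$subj_gl,
                      pack$B0, pack$B1, pack$LW,
                      params$sigma, params$phi, params$alpha,
                      Dinv[1, 1], Dinv[1, 2], Dinv[2, 2],
                      as.numeric(logdetD))
  sum(ll)
}

#' Marginal log-likelihood of the joint model
#'
#' Integrates the conditional likelihood over the random effects by adaptive
#' Gauss-Hermite quadrature with `n_nodes` nodes per dimension. The node
#' grid for each subject is recentred and rescaled at the mean and
#' covariance of the random-effects posterior given that subject's
#' longitudinal data at the supplied parameter values (pseudo-adaptive
#' centering, available in closed form); `centering = "prior"` instead
#' centres every grid at the prior N(0, D).
#'
#' @param dataset A `sim_dataset` or list with `longitudinal` and `survival`.
#' @param params A [joint_params()].
#' @param n_nodes Gauss-Hermite nodes per dimension (>= 3).
#' @param gl_nodes Gauss-Legendre order for cumulative hazards.
#' @param centering `"posterior"` (default) or `"prior"`.
#' @param trajectory Optional [trajectory_spec()]; defaults to the dataset's
#'   generating spec or linear.
#' @return Scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(dataset, params, n_nodes = 9L, gl_nodes = 15L,
                            centering = c("posterior", "prior"),
                            trajectory = NULL) {
  centering <- match.arg(centering)
  if (n_nodes < 3L) stop("`n_nodes` must be >= 3", call. = FALSE)
  if (is.null(trajectory))
    trajectory <- if (!is.null(dataset$config)) dataset$config$trajectory
      else trajectory_spec()
  cen <- if (centering == "posterior")
    centering_from_params(dataset, params, trajectory)
  else {
    n <- nrow(dataset$survival)
    L <- t(chol(params$D))
    list(mu = matrix(0, n, 2), L = rep(list(L), n))
  }
  pack <- pack_joint_data(dataset, trajectory, cen, n_nodes, gl_nodes)
  packed_loglik(pack, params)
}

## unconstrained parameter vector <-> joint_params
## theta = (beta[1..p], log sigma, log l11, l21, log l22, log phi,
##          gamma0, gamma_age, gamma_sex, alpha)
theta_to_params <- function(theta, p, beta_names) {
  L <- matrix(c(exp(theta[p + 2]), theta[p + 3], 0, exp(theta[p + 4])), 2, 2)
  joint_params(beta = stats::setNames(theta[1:p], beta_names),
               sigma = exp(theta[p + 1]),
               D = L %*% t(L),
               phi = exp(theta[p + 5]),
               log_scale = theta[p + 6],
               gamma_age = theta[p + 7], gamma_sex = theta[p + 8],
               alpha = theta[p + 9])
}

params_to_theta <- function(params) {
  L <- t(chol(params$D + diag(1e-12, 2)))
  c(params$beta, log(params$sigma), log(L[1, 1]), L[2, 1], log(L[2, 2]),
    log(params$phi), params$log_scale, params$gamma_age, params$gamma_sex,
    params$alpha)
}

## natural-scale report vector (for delta-method SEs)
theta_to_natural <- function(theta, p) {
  l11 <- exp(theta[p + 2]); l21 <- theta[p + 3]; l22 <- exp(theta[p + 4])
  c(theta[1:p], sigma = exp(theta[p + 1]),
    D11 = l11^2, D12 = l11 * l21, D22 = l21^2 + l22^2,
    phi = exp(theta[p + 5]), log_scale = theta[p + 6],
    gamma_age = theta[p + 7], gamma_sex = theta[p + 8], alpha = theta[p + 9])
}

## starting values: stage-1 LMM, stage-2 Cox, and a Weibull PH fit for the
## baseline (via the AFT parameterization of survreg).
joint_start <- function(dataset, trajectory) {
  ts <- run_two_stage(dataset, trajectory = trajectory$kind)
  if (is.null(ts$stage1))
    stop("could not obtain starting values: stage-1 mixed model failed",
         call. = FALSE)
  s1 <- ts$stage1
  wb <- tryCatch(
    survival::survreg(survival::Surv(time, event) ~ age + sex,
                      data = dataset$survival, dist = "weibull"),
    error = function(e) NULL)
  if (!is.null(wb) && is.finite(wb$scale) && wb$scale > 0) {
    phi0 <- 1 / wb$scale
    g0 <- -stats::coef(wb)[["(Intercept)"]] / wb$scale
    ga0 <- -stats::coef(wb)[["age"]] / wb$scale
    gs0 <- -stats::coef(wb)[["sex"]] / wb$scale
  } else {
    phi0 <- 1
    g0 <- log(sum(dataset$survival$event) /
                max(sum(dataset$survival$time), 1))
    ga0 <- 0; gs0 <- 0
  }
  alpha0 <- 0
  if (!is.null(ts$stage2) && all(is.finite(ts$stage2$coef))) {
    ## swap in the stage-2 covariate effects and the association, re-centring
    ## the baseline log-scale so the linear predictor at the covariate means
    ## is unchanged (the Cox fit itself has no intercept to carry over)
    mbar <- mean(dataset$longitudinal$y)
    abar <- mean(dataset$survival$age)
    sbar <- mean(dataset$survival$sex)
    ga1 <- ts$stage2$coef[["age"]]
    gs1 <- ts$stage2$coef[["sex"]]
    alpha0 <- ts$stage2$coef[["value"]]
    g0 <- g0 + (ga0 - ga1) * abar + (gs0 - gs1) * sbar - alpha0 * mbar
    ga0 <- ga1; gs0 <- gs1
  }
  params <- joint_params(beta = s1$beta_hat, sigma = s1$sigma_hat,
                         D = regularize_psd(s1$D_hat),
                         phi = max(phi0, 0.2), log_scale = g0,
                         gamma_age = ga0, gamma_sex = gs0, alpha = alpha0)
  list(params = params, stage1 = s1, twostage = ts)
}

regularize_psd <- function(D, floor1 = 1e-6, floor2 = 1e-10) {
  if (D[1, 1] < floor1) D[1, 1] <- floor1
  if (D[2, 2] < floor2) D[2, 2] <- floor2
  lim <- 0.99 * sqrt(D[1, 1] * D[2, 2])
  if (abs(D[1, 2]) > lim) D[1, 2] <- D[2, 1] <- sign(D[1, 2]) * lim
  D
}

#' Fit the joint model by maximum likelihood
#'
#' Directly maximizes the Gauss-Hermite-approximated marginal log-likelihood
#' over an unconstrained parameterization (log-Cholesky factor of `D`, log
#' `sigma`, log `phi`, free regression coefficients) by quasi-Newton (BFGS)
#' with central-difference gradients. Quadrature grids are pseudo-adaptive:
#' each subject's nodes are centred at the stage-1 BLUP and scaled by the
#' stage-1 conditional covariance, fixed throughout the optimization.
#' Starting values come from the two-stage fit plus a Weibull regression
#' ignoring the biomarker, unless `start` is supplied.
#'
#' Standard errors are delta-method transforms of the inverse numerical
#' Hessian (central differences); `converged` requires the optimizer to
#' report success, the scaled gradient to be small, and the Hessian to be
#' positive definite. When these fail the estimates are still returned so
#' that unconditional simulation summaries remain possible.
#'
#' @param dataset A `sim_dataset` or list with `longitudinal` and `survival`.
#' @param start Optional [joint_params()] starting value.
#' @param trajectory Optional [trajectory_spec()] (defaults to the dataset's
#'   generating spec, else linear).
#' @param control List of options: `n_nodes` (9), `gl_nodes` (15), `maxit`
#'   (300), `reltol` (1e-10), `grad_tol` (1e-3, on the parscale-relative
#'   gradient), `hessian` (TRUE), `hess_step` (1e-4 relative).
#' @return Object of class `joint_fit`: `params_hat` (a `joint_params`),
#'   `estimates`/`se`/`ci95` on the natural scale, `loglik`, `converged`,
#'   `hessian_pd`, `grad_norm`, `start_loglik`, `optim_convergence`.
#' @examples
#' \donttest{
#' d <- generate_dataset(scenario_config(n_subjects = 80, seed = 9), 1)
#' f <- fit_joint(d)
#' f$estimates[c("alpha", "phi")]
#' }
#' @export
fit_joint <- function(dataset, start = NULL, trajectory = NULL,
                      control = list()) {
  n_nodes <- control$n_nodes %||% 9L
  gl_nodes <- control$gl_nodes %||% 15L
  maxit <- control$maxit %||% 300L
  reltol <- control$reltol %||% 1e-10
  grad_tol <- control$grad_tol %||% 1e-3
  do_hess <- control$hessian %||% TRUE
  hess_step <- control$hess_step %||% 1e-4
  if (is.null(trajectory))
    trajectory <- if (!is.null(dataset$config)) dataset$config$trajectory
      else trajectory_spec()
  if (sum(dataset$survival$event) < 1L)
    stop("need at least one event", call. = FALSE)

  st <- NULL
  if (is.null(start)) {
    st <- joint_start(dataset, trajectory)
    start <- st$params
  }
  ## pseudo-adaptive centering at the starting parameter values
  cen <- tryCatch(centering_from_params(dataset, start, trajectory),
                  error = function(e) NULL)
  if (is.null(cen)) {
    L <- t(chol(regularize_psd(start$D)))
    nsub <- nrow(dataset$survival)
    cen <- list(mu = matrix(0, nsub, 2), L = rep(list(L), nsub))
  }
  pack <- pack_joint_data(dataset, trajectory, cen, n_nodes, gl_nodes)
  p <- pack$p
  beta_names <- names(start$beta) %||% paste0("beta", seq_len(p))

  nll <- function(theta) {
    pr <- tryCatch(theta_to_params(theta, p, beta_names),
                   error = function(e) NULL)
    if (is.null(pr)) return(1e10)
    v <- tryCatch(packed_loglik(pack, pr), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }

  theta0 <- params_to_theta(start)
  psc <- pmax(abs(theta0), 1e-3)
  gr <- function(theta) {
    vapply(seq_along(theta), function(j) {
      h <- 1e-6 * psc[j]
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (nll(tp) - nll(tm)) / (2 * h)
    }, numeric(1))
  }

  start_loglik <- -nll(theta0)
  opt <- stats::optim(theta0, nll, gr = gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol,
                                     parscale = psc))
  theta_hat <- opt$par
  loglik <- -opt$value
  grad <- gr(theta_hat)
  grad_rel <- max(abs(grad * psc))

  hess <- NULL; hessian_pd <- FALSE; vcov_nat <- NULL
  se_nat <- rep(NA_real_, p + 9)
  if (do_hess) {
    hess <- numeric_hessian(nll, theta_hat, rel_step = hess_step)
    ch <- tryCatch(chol(hess), error = function(e) NULL)
    hessian_pd <- !is.null(ch)
    if (hessian_pd) {
      vcov_theta <- chol2inv(ch)
      J <- numeric_jacobian(function(th) theta_to_natural(th, p), theta_hat)
      vcov_nat <- J %*% vcov_theta %*% t(J)
      se_nat <- sqrt(pmax(diag(vcov_nat), 0))
    }
  }

  params_hat <- theta_to_params(theta_hat, p, beta_names)
  est <- theta_to_natural(theta_hat, p)
  names(est) <- c(beta_names, "sigma", "D11", "D12", "D22", "phi",
                  "log_scale", "gamma_age", "gamma_sex", "alpha")
  names(se_nat) <- names(est)
  z <- stats::qnorm(0.975)
  ci <- cbind(lower = est - z * se_nat, upper = est + z * se_nat)

  converged <- opt$convergence == 0 && grad_rel < grad_tol &&
    (hessian_pd || !do_hess)

  structure(
    list(params_hat = params_hat, estimates = est, se = se_nat, ci95 = ci,
         loglik = loglik, start_loglik = start_loglik,
         converged = converged, hessian_pd = hessian_pd,
         grad_norm = sqrt(sum(grad^2)), grad_rel = grad_rel,
         optim_convergence = opt$convergence,
         n_nodes = n_nodes, gl_nodes = gl_nodes,
         start = start, stage_fits = st),
    class = "joint_fit")
}

numeric_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

numeric_jacobian <- function(f, x, rel_step = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(abs(x[j]), 1)
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("<joint_fit> loglik = ", format(x$loglik, digits = 8),
      ", converged: ", x$converged,
      " (hessian PD: ", x$hessian_pd, ")\n", sep = "")
  print(round(cbind(estimate = x$estimates, se = x$se, x$ci95), 5))
  invisible(x)
}
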