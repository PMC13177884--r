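#' Maximum-likelihood fit of the random-intercept-and-slope mixed model
#'
#' Fits the longitudinal submodel
#' \deqn{y_{ij} = x_i(t_{ij})'\beta + b_{0i} + b_{1i} t_{ij} +
#'   \varepsilon_{ij}, \quad b_i \sim N(0, D), \quad
#'   \varepsilon_{ij} \sim N(0, \sigma^2)}
#' by direct maximization of the exact marginal Gaussian log-likelihood with
#' per-subject covariance \eqn{V_i = Z_i D Z_i' + \sigma^2 I}. The fixed
#' effects are profiled out by generalized least squares at every step, and
#' \eqn{(D, \sigma)} are optimized on an unconstrained log-Cholesky scale by
#' quasi-Newton. Subject-level random effects are recovered as BLUPs
#' \eqn{\hat b_i = D Z_i' V_i^{-1}(y_i - X_i\hat\beta)}.
#'
#' The fixed design is intercept + time trend + age, where the time trend is
#' linear (`trajectory = "linear"`) or a 3-column cubic B-spline basis
#' (`trajectory = "bspline"`).
#'
#' @param longitudinal Data frame with columns `id`, `time`, `y`.
#' @param survival Data frame with at least `id` and `age` (baseline
#'   covariate source).
#' @param trajectory `"linear"` or `"bspline"` fixed time trend.
#' @param method `"ML"` (default, matching the likelihood used inside joint
#'   models) or `"REML"`.
#' @param spline_boundary Boundary knots when `trajectory = "bspline"`.
#' @param control List: `maxit` (default 500) and `reltol` for the
#'   quasi-Newton iterations.
#' @return Object of class `lmm_fit` with elements `beta_hat` (named),
#'   `se_beta`, `D_hat`, `sigma_hat`, `loglik`, `converged`, `blups`
#'   (per-subject data frame), `method`, and internals used by
#'   [predict_blup()].
#' @examples
#' d <- generate_dataset(scenario_config(n_subjects = 40, seed = 3), 1)
#' f <- fit_lmm(d$longitudinal, d$survival)
#' f$beta_hat
#' @export
fit_lmm <- function(longitudinal, survival, trajectory = c("linear", "bspline"),
                    method = c("ML", "REML"), spline_boundary = c(0, 400),
                    control = list()) {
  trajectory <- match.arg(trajectory)
  method <- match.arg(method)
  maxit <- control$maxit %||% 500L
  reltol <- control$reltol %||% 1e-12

  ids <- unique(longitudinal$id)
  if (length(ids) < 2L) stop("need at least 2 subjects", call. = FALSE)
  age <- survival$age[match(ids, survival$id)]
  if (anyNA(age)) stop("every subject needs an age in `survival`", call. = FALSE)

  ## Group subjects by visit pattern; within a pattern V_i is shared and the
  ## fixed design differs only through the age column, so all per-subject
  ## quadratic forms reduce to a handful of small matrix products.
  ord <- order(match(longitudinal$id, ids), longitudinal$time)
  long <- longitudinal[ord, ]
  sp <- split(long[c("time", "y")], factor(long$id, levels = ids))
  pat_key <- vapply(sp, function(s) paste(signif(s$time, 12), collapse = ","),
                    character(1))
  patterns <- split(seq_along(ids), pat_key)

  time_cols <- function(tt) {
    if (trajectory == "linear") matrix(tt, ncol = 1) else
      spline_basis(tt, trajectory_spec("bspline",
                                       spline_boundary = spline_boundary))
  }
  p_time <- if (trajectory == "linear") 1L else 3L
  p <- 2L + p_time   # intercept + time trend + age

  pats <- lapply(patterns, function(idx) {
    tt <- sp[[idx[1]]]$time
    k <- length(tt)
    U <- cbind(1, time_cols(tt))          # k x (p-1): shared columns
    Z <- cbind(1, tt)                     # k x 2 random-effect design
    Y <- vapply(sp[idx], function(s) s$y, numeric(k))
    Y <- matrix(Y, nrow = k)
    list(idx = idx, t = tt, k = k, U = U, Z = Z, Y = Y,
         age = age[idx])
  })
  N <- nrow(long)

  ## theta = (log l11, l21, log l22, log sigma); D = L L'
  theta_to_par <- function(theta) {
    L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
    list(D = L %*% t(L), sigma2 = exp(2 * theta[4]))
  }

  profile_fit <- function(theta) {
    par <- theta_to_par(theta)
    A <- matrix(0, p, p); cvec <- numeric(p); q <- 0; logdet <- 0
    stats_p <- vector("list", length(pats))
    for (j in seq_along(pats)) {
      pt <- pats[[j]]
      V <- pt$Z %*% par$D %*% t(pt$Z) + diag(par$sigma2, pt$k)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      W <- chol2inv(ch)
      logdet <- logdet + 2 * sum(log(diag(ch))) * length(pt$idx)
      UW <- crossprod(pt$U, W)            # (p-1) x k
      UWU <- UW %*% pt$U
      oW <- colSums(W)                    # 1'W  (k)
      UWo <- UW %*% rep(1, pt$k)          # U'W1
      oWo <- sum(oW)
      UWY <- UW %*% pt$Y                  # (p-1) x n_j
      oWY <- drop(rep(1, pt$k) %*% W %*% pt$Y)
      yWy <- colSums(pt$Y * (W %*% pt$Y))
      np <- length(pt$idx)
      sa <- sum(pt$age); sa2 <- sum(pt$age^2)
      A[1:(p - 1), 1:(p - 1)] <- A[1:(p - 1), 1:(p - 1)] + np * UWU
      A[1:(p - 1), p] <- A[1:(p - 1), p] + sa * UWo
      A[p, 1:(p - 1)] <- A[1:(p - 1), p]
      A[p, p] <- A[p, p] + sa2 * oWo
      cvec[1:(p - 1)] <- cvec[1:(p - 1)] + rowSums(UWY)
      cvec[p] <- cvec[p] + sum(pt$age * oWY)
      q <- q + sum(yWy)
      stats_p[[j]] <- list(W = W, UWY = UWY, oWY = oWY)
    }
    beta <- tryCatch(solve(A, cvec), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    quad <- q - sum(beta * cvec)
    ll <- -0.5 * (N * log(2 * pi) + logdet + quad)
    if (method == "REML") {
      dA <- determinant(A, logarithm = TRUE)
      ll <- ll - 0.5 * as.numeric(dA$modulus) + 0.5 * p * log(2 * pi)
    }
    list(ll = ll, beta = beta, A = A, par = par)
  }

  nll <- function(theta) {
    f <- profile_fit(theta)
    if (is.null(f) || !is.finite(f$ll)) 1e10 else -f$ll
  }

  ## data-driven start: OLS residual split between subject level and noise
  X0 <- cbind(1, time_cols(long$time), age[match(long$id, ids)])
  r0 <- stats::lm.fit(X0, long$y)$residuals
  subj_means <- tapply(r0, factor(long$id, levels = ids), mean)
  v_b0 <- max(stats::var(subj_means), 1e-4)
  v_res <- max(stats::var(r0) - v_b0, 1e-4)
  tmax <- max(long$time, 1)
  start <- c(0.5 * log(v_b0), 0, 0.5 * log(v_b0 / tmax^2 / 100),
             0.5 * log(v_res))

  ## Nelder-Mead first (robust to the very different natural scales of the
  ## Cholesky elements), then a quasi-Newton polish with matched step sizes.
  opt0 <- stats::optim(start, nll, method = "Nelder-Mead",
                       control = list(maxit = 2000L, reltol = 1e-12))
  psc <- pmax(abs(opt0$par), 1e-3)
  opt <- stats::optim(opt0$par, nll, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol,
                                     parscale = psc, ndeps = rep(1e-6, 4)))
  if (opt$value > opt0$value) opt <- opt0
  fit <- profile_fit(opt$par)
  converged <- opt$convergence == 0 && !is.null(fit) && is.finite(fit$ll)

  if (is.null(fit))
    stop("linear mixed model likelihood could not be evaluated at the optimum",
         call. = FALSE)
  D_hat <- fit$par$D
  sigma_hat <- sqrt(fit$par$sigma2)
  Ainv <- tryCatch(solve(fit$A), error = function(e) NULL)
  se_beta <- if (is.null(Ainv)) rep(NA_real_, p) else sqrt(diag(Ainv))
  converged <- converged && all(is.finite(se_beta))

  ## BLUPs and conditional covariances, per pattern
  blup <- matrix(0, length(ids), 2)
  cond_cov <- vector("list", length(pats))
  for (j in seq_along(pats)) {
    pt <- pats[[j]]
    V <- pt$Z %*% D_hat %*% t(pt$Z) + diag(sigma_hat^2, pt$k)
    W <- chol2inv(chol(V))
    Xb_shared <- drop(cbind(1, time_cols(pt$t)) %*%
                        fit$beta[1:(p - 1)])
    resid <- pt$Y - outer(Xb_shared, rep(1, length(pt$idx))) -
      outer(rep(1, pt$k), pt$age * fit$beta[p])
    DZW <- D_hat %*% t(pt$Z) %*% W       # 2 x k
    blup[pt$idx, ] <- t(DZW %*% resid)
    cond_cov[[j]] <- D_hat - DZW %*% pt$Z %*% D_hat
  }
  cond_cov_by_subject <- vector("list", length(ids))
  for (j in seq_along(pats))
    for (i in pats[[j]]$idx) cond_cov_by_subject[[i]] <- cond_cov[[j]]

  beta_names <- c("(Intercept)",
                  if (trajectory == "linear") "time" else
                    paste0("spline", 1:3),
                  "age")
  beta_hat <- stats::setNames(fit$beta, beta_names)

  structure(
    list(beta_hat = beta_hat, se_beta = stats::setNames(se_beta, beta_names),
         D_hat = D_hat, sigma_hat = sigma_hat,
         loglik = fit$ll, converged = converged, method = method,
         trajectory = trajectory, spline_boundary = spline_boundary,
         blups = data.frame(id = ids, b0_hat = blup[, 1], b1_hat = blup[, 2]),
         cond_cov = cond_cov_by_subject,
         subject_age = stats::setNames(age, ids),
         n_obs = N, n_subjects = length(ids),
         theta = opt$par, optim_convergence = opt$convergence),
    class = "lmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ", x$method, ", ", x$n_subjects, " subjects, ",
      x$n_obs, " observations\n", sep = "")
  print(round(rbind(estimate = x$beta_hat, se = x$se_beta), 6))
  cat(sprintf("sigma = %.4g; D = [%.3g, %.3g; %.3g, %.3g]; loglik = %.4f; converged: %s\n",
              x$sigma_hat, x$D_hat[1, 1], x$D_hat[1, 2], x$D_hat[2, 1],
              x$D_hat[2, 2], x$loglik, x$converged))
  invisible(x)
}

#' Predict a subject's trajectory from a fitted mixed model
#'
#' Returns the BLUP-based prediction
#' \eqn{\hat m_i(t) = x_i(t)'\hat\beta + \hat b_{0i} + \hat b_{1i} t},
#' defined for any \eqn{t \ge 0}; extrapolation beyond a subject's last
#' measurement is permitted (the two-stage second stage requires values at
#' event times past dropout).
#'
#' @param fit An `lmm_fit`.
#' @param id Subject id(s), recycled against `t`.
#' @param t Times in weeks.
#' @return Numeric vector of predicted true biomarker values.
#' @export
predict_blup <- function(fit, id, t) {
  stopifnot(inherits(fit, "lmm_fit"))
  n <- max(length(id), length(t))
  id <- rep_len(id, n); t <- rep_len(t, n)
  pos <- match(id, fit$blups$id)
  if (anyNA(pos)) stop("unknown subject id: ",
                       paste(unique(id[is.na(pos)]), collapse = ", "),
                       call. = FALSE)
  p <- length(fit$beta_hat)
  Xt <- if (fit$trajectory == "linear") matrix(t, ncol = 1) else
    spline_basis(t, trajectory_spec("bspline",
                                    spline_boundary = fit$spline_boundary))
  fixed <- fit$beta_hat[1] + drop(Xt %*% fit$beta_hat[2:(p - 1)]) +
    fit$beta_hat[p] * fit$subject_age[as.character(id)]
  unname(fixed + fit$blups$b0_hat[pos] + fit$blups$b1_hat[pos] * t)
}
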