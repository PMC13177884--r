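#' Serialize a fitted model as JSON
#'
#' Writes a compact JSON summary of an `lmm_fit`, `tvcox_fit`,
#' `twostage_result` or `joint_fit`: point estimates, standard errors,
#' log-likelihood and convergence diagnostics.
#'
#' @param fit A fitted object from this package.
#' @param path Output file; `NULL` returns the JSON string instead.
#' @return The path (invisibly), or the JSON string when `path` is `NULL`.
#' @export
write_fit_json <- function(fit, path = NULL) {
  x <- if (inherits(fit, "lmm_fit")) {
    list(type = "lmm", beta = as.list(fit$beta_hat),
         se_beta = as.list(fit$se_beta),
         D = fit$D_hat, sigma = fit$sigma_hat,
         loglik = fit$loglik, converged = fit$converged,
         method = fit$method)
  } else if (inherits(fit, "tvcox_fit")) {
    list(type = "tvcox", coef = as.list(fit$coef), se = as.list(fit$se),
         ci95 = fit$ci95, loglik = fit$loglik,
         converged = fit$converged, n_events = fit$n_events,
         ties = fit$ties)
  } else if (inherits(fit, "twostage_result")) {
    list(type = "twostage", converged = fit$converged,
         stage1 = if (!is.null(fit$stage1))
           jsonlite::fromJSON(write_fit_json(fit$stage1)),
         stage2 = if (!is.null(fit$stage2))
           jsonlite::fromJSON(write_fit_json(fit$stage2)))
  } else if (inherits(fit, "joint_fit")) {
    list(type = "jointml", estimates = as.list(fit$estimates),
         se = as.list(fit$se), ci95 = fit$ci95, loglik = fit$loglik,
         converged = fit$converged, hessian_pd = fit$hessian_pd,
         grad_rel = fit$grad_rel, n_nodes = fit$n_nodes)
  } else stop("unsupported fit object", call. = FALSE)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
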