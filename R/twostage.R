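#' Uncorrected two-stage estimation
#'
#' Stage 1 fits the linear mixed model to the observed longitudinal rows
#' ([fit_lmm()]). Stage 2 fits a time-varying Cox model ([fit_tvcox()]) on a
#' counting-process table whose covariate for each at-risk subject at each
#' distinct event time is the stage-1 BLUP prediction
#' \eqn{\hat m_i(t)} ([predict_blup()]), extrapolated past the subject's
#' last measurement where needed. The reported stage-2 standard errors are
#' the naive plug-in ones: first-stage estimation uncertainty is not
#' propagated, by definition of the uncorrected approach.
#'
#' If stage 1 fails to converge, stage 2 is skipped and the composite result
#' is flagged non-converged.
#'
#' @param dataset A `sim_dataset`, or a list with elements `longitudinal`
#'   and `survival` (e.g. from [read_dataset()]).
#' @param trajectory Fixed time trend for stage 1: `"linear"`, `"bspline"`,
#'   or `NULL` to take it from the dataset's generating config (falling back
#'   to linear).
#' @param method Stage-1 likelihood: `"ML"` (default) or `"REML"`.
#' @param covariates Stage-2 covariate columns (see [fit_tvcox()]).
#' @param control Passed to [fit_tvcox()].
#' @return Object of class `twostage_result`: `stage1` (`lmm_fit`),
#'   `stage2` (`tvcox_fit` or `NULL`), `converged`.
#' @examples
#' d <- generate_dataset(scenario_config(n_subjects = 60, seed = 4), 1)
#' r <- run_two_stage(d)
#' r$stage2$coef
#' @export
run_two_stage <- function(dataset, trajectory = NULL, method = "ML",
                          covariates = c("value", "age", "sex"),
                          control = list()) {
  if (is.null(trajectory))
    trajectory <- if (!is.null(dataset$config)) dataset$config$trajectory$kind
      else "linear"
  boundary <- if (!is.null(dataset$config))
    dataset$config$trajectory$spline_boundary else c(0, 400)
  stage1 <- tryCatch(
    fit_lmm(dataset$longitudinal, dataset$survival, trajectory = trajectory,
            method = method, spline_boundary = boundary),
    error = function(e) NULL)
  if (is.null(stage1) || !stage1$converged) {
    return(structure(list(stage1 = stage1, stage2 = NULL, converged = FALSE),
                     class = "twostage_result"))
  }
  pred <- function(id, t) predict_blup(stage1, id, t)
  stage2 <- tryCatch({
    cp <- build_counting_process(dataset$longitudinal, dataset$survival,
                                 covariate_source = "supplied_function",
                                 predict_fn = pred)
    fit_tvcox(cp, covariates = covariates, control = control)
  }, error = function(e) NULL)
  structure(
    list(stage1 = stage1, stage2 = stage2,
         converged = !is.null(stage2) && stage2$converged),
    class = "twostage_result")
}

#' @export
print.twostage_result <- function(x, ...) {
  cat("<twostage_result> converged:", x$converged, "\n")
  if (!is.null(x$stage2)) {
    cat("stage-2 survival coefficients (naive SEs):\n")
    print(round(cbind(coef = x$stage2$coef, se = x$stage2$se), 5))
  } else cat("stage 2 not fitted\n")
  invisible(x)
}
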