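#' Run one scenario of the simulation study
#'
#' For each replicate: generate a dataset, fit each requested method, and
#' record term-level estimates with Wald confidence intervals. A method that
#' crashes on a replicate is coded as missing (its rows carry `NA`
#' estimates and `converged = FALSE`) rather than aborting the run; fits
#' that produce estimates without meeting their convergence criteria are
#' retained with `converged = FALSE` so that unconditional summaries remain
#' possible. Fully reproducible: replicate `r` uses the stream
#' `config$seed + r`.
#'
#' Methods:
#' \describe{
#'   \item{`tvcox`}{Time-varying Cox on observed LOCF biomarker values.}
#'   \item{`twostage`}{Uncorrected two-stage plug-in ([run_two_stage()]).}
#'   \item{`jointml`}{Joint maximum likelihood ([fit_joint()]).}
#'   \item{`tvcox_truth`}{Diagnostic oracle: time-varying Cox with the
#'     covariate set to the *true* latent trajectory at event times,
#'     isolating the measurement-error/step-function bias of `tvcox`.}
#' }
#'
#' @param config A [scenario_config()].
#' @param methods Character vector of methods to run.
#' @param reps Number of replicates (default `config$n_reps`).
#' @param joint_control Control list passed to [fit_joint()].
#' @return Object of class `scenario_results`: list with `results` (tidy
#'   data frame: scenario, rep, method, term, estimate, se, lower, upper,
#'   converged, n_events, n_obs) and `config`.
#' @export
run_scenario <- function(config,
                         methods = c("tvcox", "twostage", "jointml"),
                         reps = NULL, joint_control = list()) {
  stopifnot(inherits(config, "scenario_config"))
  known <- c("tvcox", "twostage", "jointml", "tvcox_truth")
  if (!all(methods %in% known))
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "), call. = FALSE)
  reps <- reps %||% config$n_reps
  out <- vector("list", reps * length(methods))
  k <- 0L
  for (r in seq_len(reps)) {
    d <- generate_dataset(config, r)
    n_events <- sum(d$survival$event)
    n_obs <- nrow(d$longitudinal)
    for (m in methods) {
      k <- k + 1L
      rows <- tryCatch(fit_one_method(d, m, joint_control),
                       error = function(e) NULL)
      if (is.null(rows))
        rows <- data.frame(term = "alpha", estimate = NA_real_,
                           se = NA_real_, lower = NA_real_, upper = NA_real_,
                           converged = FALSE)
      rows$scenario <- config$label
      rows$rep <- r
      rows$method <- m
      rows$n_events <- n_events
      rows$n_obs <- n_obs
      out[[k]] <- rows
    }
  }
  res <- do.call(rbind, out)
  res <- res[c("scenario", "rep", "method", "term", "estimate", "se",
               "lower", "upper", "converged", "n_events", "n_obs")]
  rownames(res) <- NULL
  structure(list(results = res, config = config), class = "scenario_results")
}

fit_one_method <- function(d, method, joint_control = list()) {
  if (method == "tvcox") {
    cp <- build_counting_process(d$longitudinal, d$survival)
    f <- fit_tvcox(cp)
    tidy_surv_fit(f$coef, f$se, f$converged)
  } else if (method == "tvcox_truth") {
    truth <- d$truth
    tr <- d$config$trajectory
    pred <- function(id, t) {
      i <- match(id, truth$id)
      trajectory_fixed(tr, truth$age[i], t) + truth$b0[i] + truth$b1[i] * t
    }
    cp <- build_counting_process(d$longitudinal, d$survival,
                                 covariate_source = "supplied_function",
                                 predict_fn = pred)
    f <- fit_tvcox(cp)
    tidy_surv_fit(f$coef, f$se, f$converged)
  } else if (method == "twostage") {
    f <- run_two_stage(d)
    if (is.null(f$stage2))
      return(data.frame(term = c("alpha", "gamma_age", "gamma_sex"),
                        estimate = NA_real_, se = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        converged = FALSE))
    tidy_surv_fit(f$stage2$coef, f$stage2$se, f$converged)
  } else {
    f <- fit_joint(d, control = joint_control)
    keep <- c("alpha", "gamma_age", "gamma_sex", "phi", "sigma",
              names(f$estimates)[seq_along(f$params_hat$beta)])
    data.frame(term = keep,
               estimate = unname(f$estimates[keep]),
               se = unname(f$se[keep]),
               lower = unname(f$ci95[keep, "lower"]),
               upper = unname(f$ci95[keep, "upper"]),
               converged = f$converged)
  }
}

tidy_surv_fit <- function(coef, se, converged) {
  term <- c(value = "alpha", age = "gamma_age", sex = "gamma_sex")[names(coef)]
  z <- stats::qnorm(0.975)
  data.frame(term = unname(term), estimate = unname(coef), se = unname(se),
             lower = unname(coef - z * se), upper = unname(coef + z * se),
             converged = converged)
}

## generating truth for each reported term
truth_from_config <- function(config) {
  tr <- config$trajectory
  beta_truth <- if (tr$kind == "linear")
    c("(Intercept)" = tr$beta0, time = tr$beta_time, age = tr$beta_age)
  else c("(Intercept)" = tr$beta0,
         stats::setNames(tr$beta_spline, paste0("spline", 1:3)),
         age = tr$beta_age)
  c(alpha = config$survival$alpha,
    gamma_age = config$survival$gamma_age,
    gamma_sex = config$survival$gamma_sex,
    phi = config$survival$phi, sigma = config$sigma_eps,
    beta_truth)
}

#' Summarize scenario results into the study's evaluation metrics
#'
#' Computes, per method and term: the median estimate, bias of the median
#' (median minus generating truth), mean-based bias, empirical SD, 95%
#' confidence-interval coverage of the truth, convergence rate, mean event
#' and observation counts, and the observation-to-event ratio (total
#' longitudinal observations divided by total events across replicates).
#'
#' Conditioning modes:
#' \describe{
#'   \item{`converged_only`}{Only converged fits contribute to estimate
#'     summaries; a method with fewer than `min_display` converged
#'     replicates is flagged as below the display threshold.}
#'   \item{`unconditional`}{All fits with non-missing estimates contribute,
#'     converged or not.}
#'   \item{`all_methods_converged`}{Restricts to replicates on which every
#'     method in `results` converged.}
#' }
#'
#' @param scenario_results A `scenario_results` object from
#'   [run_scenario()], or its `results` data frame together with `config`.
#' @param mode Conditioning mode (see above).
#' @param min_display Display-rule threshold on the number of converged
#'   replicates (default 50).
#' @param config Scenario configuration (only needed when passing a raw
#'   data frame).
#' @return Data frame of class `eval_summary`, one row per method x term.
#' @export
summarize_results <- function(scenario_results,
                              mode = c("converged_only", "unconditional",
                                       "all_methods_converged"),
                              min_display = 50L, config = NULL) {
  mode <- match.arg(mode)
  if (inherits(scenario_results, "scenario_results")) {
    res <- scenario_results$results
    config <- scenario_results$config
  } else {
    res <- scenario_results
    if (is.null(config)) stop("`config` required with a raw results table",
                              call. = FALSE)
  }
  if (nrow(res) == 0L) stop("empty results", call. = FALSE)
  truth <- truth_from_config(config)

  ## method-level convergence per rep (a method converged on a rep iff its
  ## rows say so and estimates are present)
  conv <- stats::aggregate(converged ~ rep + method, data = res,
                           FUN = function(x) all(x))
  if (mode == "all_methods_converged") {
    by_rep <- tapply(conv$converged, conv$rep, all)
    keep_reps <- as.integer(names(by_rep))[by_rep]
  }

  meta <- res[!duplicated(res[c("rep", "method")]),
              c("rep", "method", "n_events", "n_obs")]

  out <- list(); k <- 0L
  for (m in unique(res$method)) {
    rm_ <- res[res$method == m, ]
    conv_m <- conv[conv$method == m, ]
    n_reps <- nrow(conv_m)
    n_conv <- sum(conv_m$converged)
    keep <- switch(mode,
                   converged_only = conv_m$rep[conv_m$converged],
                   unconditional = conv_m$rep,
                   all_methods_converged = keep_reps)
    meta_m <- meta[meta$method == m, ]
    for (tm in unique(rm_$term)) {
      rt <- rm_[rm_$term == tm & rm_$rep %in% keep & !is.na(rm_$estimate), ]
      tv <- if (tm %in% names(truth)) truth[[tm]] else NA_real_
      covered <- mean(rt$lower <= tv & tv <= rt$upper, na.rm = TRUE)
      k <- k + 1L
      out[[k]] <- data.frame(
        scenario = config$label, method = m, term = tm, mode = mode,
        n_reps = n_reps, n_converged = n_conv,
        convergence_rate = 100 * n_conv / n_reps,
        n_used = nrow(rt),
        truth = tv,
        median_est = stats::median(rt$estimate),
        bias_median = stats::median(rt$estimate) - tv,
        bias_mean = mean(rt$estimate) - tv,
        emp_sd = stats::sd(rt$estimate),
        coverage = 100 * covered,
        mean_events = mean(meta_m$n_events),
        mean_obs = mean(meta_m$n_obs),
        obs_event_ratio = sum(meta_m$n_obs) / sum(meta_m$n_events),
        below_display_threshold = n_conv < min_display)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("eval_summary", "data.frame")
  out
}

#' Run the full simulation study over several settings
#'
#' Iterates [build_scenarios()] x [run_scenario()] x [summarize_results()]
#' and writes tidy CSV tables plus a JSON manifest (seed, settings, counts)
#' into `out_dir`. Failures of individual scenarios are logged into the
#' manifest and do not abort the study.
#'
#' @param settings Character vector of setting labels (see
#'   [build_scenarios()]).
#' @param out_dir Output directory.
#' @param methods Methods to run (see [run_scenario()]).
#' @param reps Replicates per scenario (default: each config's `n_reps`).
#' @param seed Base seed installed into every scenario configuration.
#' @param modes Conditioning modes to summarize.
#' @param base Base configuration passed to [build_scenarios()].
#' @param joint_control Control list for [fit_joint()].
#' @return Invisibly, a list with `summaries` (combined data frame) and
#'   `manifest`.
#' @export
run_study <- function(settings, out_dir,
                      methods = c("tvcox", "twostage", "jointml"),
                      reps = NULL, seed = 1L,
                      modes = c("converged_only", "unconditional"),
                      base = base_config(), joint_control = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  raw_files <- character()
  errors <- list()
  for (s in settings) {
    cfgs <- build_scenarios(s, base = base)
    for (cfg in cfgs) {
      cfg$seed <- as.integer(seed)
      r <- tryCatch(
        run_scenario(cfg, methods = methods, reps = reps,
                     joint_control = joint_control),
        error = function(e) e)
      if (inherits(r, "error")) {
        errors[[cfg$label]] <- conditionMessage(r)
        next
      }
      f <- file.path(out_dir, paste0("results_", cfg$label, ".csv"))
      utils::write.csv(r$results, f, row.names = FALSE)
      raw_files <- c(raw_files, f)
      for (md in modes)
        summaries[[paste(cfg$label, md)]] <- summarize_results(r, mode = md)
    }
  }
  summary_df <- do.call(rbind, summaries)
  rownames(summary_df) <- NULL
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(settings = settings, methods = methods, seed = seed,
                   reps = reps, modes = modes,
                   n_scenarios = length(raw_files),
                   files = basename(raw_files),
                   errors = errors,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summaries = summary_df, manifest = manifest))
}
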