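## End-to-end pipeline: prep -> growth mixture -> four survival fits ->
## AICc comparison -> diagnostics, with every artefact written under a run
## directory. Fully determined by (config$seed, input).

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain data - either simulate a cohort from the default
#' generative truth or read record + longevity CSVs; (2) C/N screening and
#' series assembly, with the per-individual ashore/at-sea KS comparison;
#' (3) the constrained growth mixture; (4) the joint change-point/Weibull
#' model and its null, random-effect and mixture-group competitors; (5) the
#' AICc comparison table; (6) diagnostics (Kaplan-Meier, empirical hazard,
#' Weibull probability plot, posterior-predictive KS, predictor
#' correlations). Artefacts (CSV, JSON summary, optional PNG figures) are
#' written under `outdir`. Re-running with the same config and input gives
#' byte-identical JSON summaries.
#'
#' @param config A [default_config()] list.
#' @param input `"simulate"`, or a list with elements `records` and
#'   `longevity` (paths to CSVs).
#' @param outdir Run directory (created if needed).
#' @param n_individuals Cohort size when simulating.
#' @return Invisibly, a list with all stage results (`series`, `fits`,
#'   `comparison`, `diagnostics`, `summary`, paths).
#' @export
run_pipeline <- function(config = default_config(), input = "simulate",
                         outdir = tempfile("isojoint_run_"),
                         n_individuals = 50) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] seed=", config$seed)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage: data
  truth <- NULL
  if (identical(input, "simulate")) {
    sim <- stage("simulate", simulate_cohort(
      n_individuals, frac_bad = 0.05, cn_good_range = config$cn_bounds,
      quarters_per_year = config$quarters_per_year, seed = config$seed))
    records <- sim$records
    longev <- sim$longevities
    truth <- sim$truth
    write_dentin_csv(records, file.path(outdir, "records.csv"))
    write_longevity_csv(longev, file.path(outdir, "longevity.csv"))
    truth_json <- list(
      mu_re = truth$pop$mu_re, sigma_re = truth$pop$sigma_re,
      sigma_obs = truth$pop$sigma_obs, theta = truth$pop$theta,
      shape = truth$pop$shape,
      individual = data.frame(
        individual_id = truth$ids,
        t(vapply(truth$params, function(p) unlist(p), numeric(4)))))
    jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    records <- stage("read", read_dentin_csv(input$records))
    longev <- stage("read", read_longevity_csv(input$longevity))
  }

  ## stage: prep
  prep <- stage("prep", {
    flt <- filter_cn(records, config$cn_bounds[1], config$cn_bounds[2])
    series <- assemble_series(flt$kept, longev, config$quarters_per_year)
    ks <- ashore_vs_atsea_cohort(flt$kept)
    list(filter = flt, series = series, ashore_ks = ks)
  })
  series <- prep$series
  utils::write.csv(series_to_df(series), file.path(outdir, "series.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cn_bounds = config$cn_bounds, qc = prep$filter$report,
         ashore_vs_atsea = list(
           n_tested = nrow(prep$ashore_ks),
           n_significant = attr(prep$ashore_ks, "n_significant"))),
    file.path(outdir, "qc_report.json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)

  ## stage: growth mixture
  mix_mcmc <- config$mcmc
  mix_mcmc$seed <- config$mcmc$seed + 1L
  mix <- stage("fit-mixture",
               fit_growth_mixture(series, mcmc = mix_mcmc))
  write_posterior_csv(drop_vector_params(mix$samples, "cls1"),
                      file.path(outdir, "mixture_posterior.csv"))
  utils::write.csv(data.frame(individual_id = mix$ids,
                              class_prob = unname(mix$class_prob),
                              class = unname(classify_mixture(mix))),
                   file.path(outdir, "class_prob.csv"), row.names = FALSE)

  ## stage: survival fits
  fits <- stage("fit-survival", {
    mc <- function(offset) {
      m <- config$mcmc
      m$seed <- config$mcmc$seed + offset
      m
    }
    list(joint = fit_joint(series, config$priors, mc(2L)),
         null = fit_null(vapply(series, `[[`, numeric(1), "longevity"),
                         config$priors, mc(3L)),
         random = fit_random(series, config$priors, mc(4L)),
         mixture = fit_mixture_aft(
           series, groups = assign_groups(series, "mixture_fit",
                                          mixture_fit = mix),
           priors = config$priors, mcmc = mc(5L)))
  })
  for (nm in names(fits)) {
    write_posterior_csv(drop_vector_params(fits[[nm]]$samples,
                                           c("b", "eta", "dev")),
                        file.path(outdir, paste0("posterior_", nm, ".csv")))
  }

  ## stage: comparison
  comparison <- stage("compare", compare_models(fits))
  utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                   row.names = FALSE)

  ## stage: diagnostics
  diag <- stage("diagnose", {
    times <- unname(vapply(series, `[[`, numeric(1), "longevity"))
    km <- kaplan_meier(times)
    hz <- empirical_hazard(times)
    wpp <- weibull_probability_plot(times)
    pp <- posterior_predict_longevity(fits$joint, ndraw = 100,
                                      seed = config$seed + 10L)
    gof <- ks_gof(times, pp)
    corr <- predictor_correlations(fits$joint$b_mean)
    list(km = km, hazard = hz, weibull_plot = wpp, gof = gof,
         correlations = corr)
  })

  summary_obj <- list(
    seed = config$seed,
    n_individuals = length(series),
    n_observations = nrow(series_to_df(series)),
    qc = prep$filter$report,
    mixture = list(w = mix$point$w, sigma_m = mix$point$sigma_m,
                   converged = mix$converged),
    joint = posterior_summary(
      fits$joint, c("v", "theta0", "theta0c", sprintf("theta[%d]", 1:4),
                    "sigma_obs")),
    comparison = as.data.frame(unclass(comparison)),
    gof = diag$gof,
    weibull_plot = list(slope = diag$weibull_plot$slope,
                        r_squared = diag$weibull_plot$r_squared),
    predictor_correlations = diag$correlations,
    converged = vapply(fits, `[[`, logical(1), "converged"))
  jsonlite::write_json(summary_obj, file.path(outdir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "columns")

  if (isTRUE(config$make_plots)) {
    stage("figures", write_pipeline_figures(outdir, series, mix, diag))
  }

  invisible(list(outdir = outdir, records = records, series = series,
                 truth = truth, mixture = mix, fits = fits,
                 comparison = comparison, diagnostics = diag,
                 summary = summary_obj))
}

## drop high-dimensional per-individual parameter blocks before writing CSV
drop_vector_params <- function(samples, prefixes) {
  df <- draws_to_df(samples)
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")\\[")
  df[, !grepl(pat, names(df)), drop = FALSE]
}

write_pipeline_figures <- function(outdir, series, mix, diag) {
  png_dev <- function(name) {
    grDevices::png(file.path(outdir, name), width = 900, height = 600)
  }
  ## spaghetti plot of the series with mixture component means
  png_dev("spaghetti.png")
  df <- series_to_df(series)
  plot(df$age, df$d13c, type = "n", xlab = "age (yr)",
       ylab = expression(delta^13 * C ~ "(‰)"),
       main = "Dentin isotope trajectories")
  for (s in series) graphics::lines(s$ages, s$values,
                                    col = grDevices::grey(0.6, 0.5))
  ac <- mix$age_classes
  graphics::lines(ac - 0.5, mix$point$mu1, col = "firebrick", lwd = 2)
  graphics::lines(ac - 0.5, mix$point$mu2, col = "navy", lwd = 2)
  graphics::legend("bottomright", c("Subantarctic mean", "Antarctic mean"),
                   col = c("firebrick", "navy"), lwd = 2, bty = "n")
  grDevices::dev.off()

  ## KM + hazard
  png_dev("survival.png")
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  km <- diag$km
  plot(stats::stepfun(km$time, c(1, km$surv)), do.points = FALSE,
       xlab = "age (yr)", ylab = "S(t)", main = "Kaplan-Meier")
  graphics::lines(km$time, km$lower, lty = 2)
  graphics::lines(km$time, km$upper, lty = 2)
  hb <- diag$hazard$bins
  plot(hb$mid, hb$hazard, pch = 16, xlab = "age (yr)", ylab = "hazard",
       main = "Empirical hazard")
  graphics::lines(hb$mid, hb$smooth, lwd = 2)
  graphics::lines(hb$mid, hb$lower, lty = 2)
  graphics::lines(hb$mid, hb$upper, lty = 2)
  grDevices::dev.off()

  ## Weibull probability plot
  png_dev("weibull_plot.png")
  wp <- diag$weibull_plot
  plot(wp$points$log_t, wp$points$log_neg_log_s, pch = 16,
       xlab = "log t", ylab = "log(-log S)",
       main = sprintf("Weibull probability plot (slope = %.2f, R2 = %.3f)",
                      wp$slope, wp$r_squared))
  graphics::abline(wp$intercept, wp$slope)
  grDevices::dev.off()
  invisible(NULL)
}
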