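#' Pipeline configuration
#'
#' Collects every tunable parameter of the full analysis into one validated
#' list that is echoed into the run report (provenance). Unknown keys are
#' rejected. All randomness (simulation, shuffle nulls, permutation tests)
#' derives from the single `seed`.
#'
#' @param params a [gt_params()] object used when no `session` is supplied.
#' @param session an existing `pm_session` or a [write_session()] directory
#'   path; `NULL` simulates from `params`.
#' @param seed root RNG seed.
#' @param trace `"dff"` or `"events"`.
#' @param n_shuffles shuffles for the influence null.
#' @param pre_len,post_len influence windows (frames).
#' @param exclude_radius proximity exclusion (um).
#' @param bin_width distance-profile bin width (um).
#' @param map_bin_size centered-map bin size (um).
#' @param noise_split near/far distance split (um).
#' @param speed_window prestimulus speed window (frames).
#' @param tuning_shuffles shuffles for the BF shuffle test.
#' @param analyses which downstream stages to run.
#' @return a `pm_config` list.
#' @export
pm_config <- function(params = gt_params(), session = NULL, seed = 1,
                      trace = "dff", n_shuffles = 1000,
                      pre_len = 10, post_len = 10, exclude_radius = 25,
                      bin_width = 50, map_bin_size = 20, noise_split = 125,
                      speed_window = 20, tuning_shuffles = 500,
                      analyses = c("maps", "axis", "state", "noisecorr",
                                   "tuning")) {
  cfg <- list(params = params, session = session, seed = as.integer(seed),
              trace = trace, n_shuffles = n_shuffles, pre_len = pre_len,
              post_len = post_len, exclude_radius = exclude_radius,
              bin_width = bin_width, map_bin_size = map_bin_size,
              noise_split = noise_split, speed_window = speed_window,
              tuning_shuffles = tuning_shuffles, analyses = analyses)
  class(cfg) <- "pm_config"
  cfg
}

#' Run the full influence-mapping pipeline on one session
#'
#' Orchestrates simulate (or load) -> validate -> preprocess -> influence ->
#' enabled downstream analyses, in dependency order, and assembles a run
#' report. Identical config and seed give identical reports. A failing
#' downstream stage is caught and recorded in `report$failures` instead of
#' aborting the run.
#'
#' @param config a [pm_config()].
#' @return a `pm_report` list: `session_summary`, `influence` (fractions and
#'   records), `distance_table`, `profile`, `dog_fit`, `maps`, `axis`,
#'   `state`, `noisecorr`, `tuning`, `config`, `warnings`, `failures`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pm_config"))
  failures <- list(); warns <- character(0)
  session <- config$session
  if (is.null(session)) {
    session <- generate_session(config$params)
  } else if (is.character(session)) {
    session <- read_session(session)
  }
  v <- validate_session(session)
  if (!v$ok) stop("session failed validation: ",
                  paste(v$errors, collapse = "; "))
  warns <- c(warns, v$warnings)

  act <- preprocess_session(session)
  infl <- influence_map(session, act, trace = config$trace,
                        pre_len = config$pre_len, post_len = config$post_len,
                        n_shuffles = config$n_shuffles, seed = config$seed,
                        exclude_radius = config$exclude_radius)
  ret <- infl$records[!infl$records$excluded, , drop = FALSE]
  influence_summary <- list(
    n_targets = sum(!infl$targets$control),
    n_successful = sum(infl$targets$successful & !infl$targets$control),
    n_control_successful = sum(infl$targets$successful & infl$targets$control),
    n_retained_pairs = nrow(ret),
    frac_positive = mean(ret$sig_class == "positive"),
    frac_negative = mean(ret$sig_class == "negative"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e); NULL
    })
  }
  report <- list(session_summary = list(
    area_tag = session$area_tag, n_neurons = nrow(session$f_raw),
    n_frames = ncol(session$f_raw), n_som = sum(session$labels$cell_type == "SOM"),
    n_stimulations = nrow(session$stim_table)),
    influence = c(influence_summary, list(records = infl$records,
                                          targets = infl$targets)))

  if ("maps" %in% config$analyses) {
    report$distance_table <- stage("maps", distance_distributions(infl$records)$summary)
    report$profile <- stage("maps", distance_binned_influence(
      infl$records, bin_width = config$bin_width))
    report$dog_fit <- stage("maps", tryCatch(
      fit_center_surround(distance_binned_influence(infl$records,
                                                    bin_width = 20)),
      error = function(e) NULL))
    report$maps <- stage("maps", list(
      positive = centered_influence_map(infl$records, session$positions,
                                        "positive", "NonSOM",
                                        config$map_bin_size),
      negative = centered_influence_map(infl$records, session$positions,
                                        "negative", "NonSOM",
                                        config$map_bin_size)))
  }
  if ("axis" %in% config$analyses) {
    ax <- stage("axis", stimulus_axes(session, infl))
    report$axis <- if (!is.null(ax)) list(
      weights = ax$weights, projections = ax$projections,
      mean_weight = mean(ax$weights$weight),
      by_distance = weights_by_distance(ax$weights)) else NULL
  }
  if ("state" %in% config$analyses) {
    report$state <- stage("state", {
      sp <- prestim_speed(session$run_speed,
                          infl$aligned$stim_table$onset_frame,
                          config$speed_window)
      qa <- assign_quartiles(sp)
      list(quartiles = qa,
           influence_by_quartile = influence_by_quartile(infl, qa)$summary,
           activity_by_quartile = activity_by_quartile(
             infl, qa, session$labels$cell_type)$summary)
    })
  }
  if ("noisecorr" %in% config$analyses) {
    report$noisecorr <- stage("noisecorr", {
      nt <- noise_correlation_table(session, infl, config$noise_split)
      list(table = correlation_influence_relation(nt, infl$records,
                                                  config$noise_split),
           records = nt)
    })
  }
  if ("tuning" %in% config$analyses && nrow(session$tone_table) > 0) {
    report$tuning <- stage("tuning", {
      tt <- tuning_table(act$events, session$tone_table,
                         session$params$frame_rate, seed = config$seed)
      test <- tuning_shuffle_test(infl$records, tt,
                                  n_shuffles = config$tuning_shuffles,
                                  seed = config$seed)
      list(table = tt, test = test[c("observed_r", "p", "n_pairs",
                                     "n_shuffles", "seed")])
    })
  }
  report$config <- config
  report$warnings <- warns
  report$failures <- failures
  class(report) <- "pm_report"
  report
}

#' @export
print.pm_report <- function(x, ...) {
  s <- x$session_summary; i <- x$influence
  cat("<pm_report> ", s$area_tag, ": ", s$n_neurons, " neurons (",
      s$n_som, " SOM), ", s$n_stimulations, " stimulations\n", sep = "")
  cat("  successful targets: ", i$n_successful, "/", i$n_targets,
      "; retained pairs: ", i$n_retained_pairs, "\n", sep = "")
  cat("  positively influenced: ", round(100 * i$frac_positive, 2),
      "%; negatively influenced: ", round(100 * i$frac_negative, 2),
      "%\n", sep = "")
  if (length(x$failures) > 0)
    cat("  FAILED stages:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
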