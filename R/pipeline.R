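#' Run a figure-level analysis pipeline end to end
#'
#' Executes simulate -> quantify -> test for one named analysis on
#' synthetic data (or a user-supplied movie), writing a traces CSV, a
#' summary JSON with a provenance block (config hash, seed, package
#' version) and an overview plot. The run is fully determined by
#' `(config, params, seed)`.
#'
#' @param name one of `"sorting"`, `"recycling"`, `"nn"`, `"fusion"`,
#'   `"spatial"`, `"aggregation"`, `"divergence"`.
#' @param cfg an [analysis_config()].
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param sim_params optional simulator parameter object for the stage
#'   (defaults to the stage's standard protocol).
#' @param movie optional user [time_lapse_movie()] replacing the
#'   simulation (supported for `"sorting"`, `"aggregation"`).
#' @param write_plot write a PNG overview plot.
#' @return list of class `pipeline_run`: `name`, `summary`, `paths`,
#'   `provenance`.
#' @export
run_figure_pipeline <- function(name = c("sorting", "recycling", "nn",
                                         "fusion", "spatial",
                                         "aggregation", "divergence"),
                                cfg = analysis_config(), seed = 1L,
                                out_dir = tempfile("pipeline_"),
                                sim_params = NULL, movie = NULL,
                                write_plot = TRUE) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  message(sprintf("[%s] stage start (seed %d)", name, seed))
  res <- switch(name,
    sorting = .pipe_sorting(cfg, seed, sim_params, movie),
    recycling = .pipe_recycling(cfg, seed, sim_params),
    nn = .pipe_nn(cfg, seed, sim_params),
    fusion = .pipe_fusion(cfg, seed, sim_params),
    spatial = .pipe_spatial(cfg, seed, sim_params),
    aggregation = .pipe_aggregation(cfg, seed, sim_params, movie),
    divergence = .pipe_divergence(cfg, seed, sim_params))
  traces_path <- file.path(out_dir, paste0(name, "_traces.csv"))
  summary_path <- file.path(out_dir, paste0(name, "_summary.json"))
  write_results(res$traces, traces_path)
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  tmp <- tempfile(); writeLines(cfg_yaml, tmp)
  provenance <- list(
    pipeline = name, seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("endorecycle")))
  unlink(tmp)
  jsonlite::write_json(list(summary = res$summary, provenance = provenance),
                       summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  plot_path <- NULL
  if (write_plot && !is.null(res$plot_fun)) {
    plot_path <- file.path(out_dir, paste0(name, "_overview.png"))
    grDevices::png(plot_path, width = 700, height = 500)
    try(res$plot_fun(), silent = TRUE)
    grDevices::dev.off()
  }
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  structure(list(name = name, summary = res$summary,
                 paths = list(traces = traces_path, summary = summary_path,
                              plot = plot_path),
                 provenance = provenance),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run '%s' (seed %d, pkg %s)\n", x$name,
              x$provenance$seed, x$provenance$package_version))
  str(x$summary, give.head = FALSE)
  invisible(x)
}

.trace_to_results <- function(trace, metric, cell = "sim_cell_1",
                              cond = "simulated", exp = "sim") {
  results_table(exp, cell, cond, metric, trace$times_s, trace$values,
                trace$units)
}

.pipe_sorting <- function(cfg, seed, sim_params, movie) {
  if (is.null(movie)) {
    sp <- sim_params %||% sorting_sim_params()
    sim <- simulate_sorting_assay(sp, seed)
    movie <- sim$movie
  }
  trace <- endosomal_incorporation_trace(movie, "cargo", "marker", cfg)
  hm <- half_maximal_time(trace)
  slope <- tryCatch(exit_slope(trace, cfg), error = function(e) NULL)
  list(traces = .trace_to_results(trace, "pct_endosomal_in_marker"),
       summary = list(half_maximal_time_s = hm$time_s,
                      plateau_percent = hm$plateau,
                      exit_slope_pct_per_s = if (!is.null(slope))
                        slope$slope else NA),
       plot_fun = function() plot(trace, main = "sorting"))
}

.pipe_recycling <- function(cfg, seed, sim_params) {
  sp <- sim_params %||% recycling_sim_params()
  sim <- simulate_recycling_assay(sp, seed)
  trace <- plasma_membrane_recycling_trace(
    sim$movie, "cargo", cfg, cell_outline = sim$rois$cell_outline)
  plateau <- window_mean(trace, cfg$plateau_window_s[1L],
                         cfg$plateau_window_s[2L])
  hm <- half_maximal_time(trace)
  list(traces = .trace_to_results(trace, "pm_pct_increase"),
       summary = list(plateau_mean_percent = plateau,
                      half_maximal_time_s = hm$time_s),
       plot_fun = function() plot(trace, main = "recycling"))
}

.pipe_nn <- function(cfg, seed, sim_params) {
  sp <- sim_params %||% sorting_sim_params()
  sim <- simulate_sorting_assay(sp, seed)
  f <- sim$movie$n_frames
  det_a <- detect_vesicles(movie_frame(sim$movie, "cargo", f), cfg)
  det_b <- detect_vesicles(movie_frame(sim$movie, "marker", f), cfg)
  excl <- rasterize_roi(sp$pa_roi, sim$movie$height, sim$movie$width)
  det_a <- exclude_region(det_a, excl)
  frac <- nn_fraction(det_a, det_b, cfg, sim$movie$pixel_size_nm)
  cell <- matrix(TRUE, sim$movie$height, sim$movie$width)
  rand <- randomized_nn_fraction(det_a, cell, det_b, cfg,
                                 sim$movie$pixel_size_nm,
                                 n_iter = 100L, seed = seed,
                                 exclusion = excl)
  tr <- intensity_trace(0, frac, units = "percent")
  list(traces = .trace_to_results(tr, "nn_fraction_percent"),
       summary = list(nn_fraction_percent = frac,
                      randomized_percent = rand$mean_percent),
       plot_fun = NULL)
}

.pipe_fusion <- function(cfg, seed, sim_params) {
  sp <- sim_params %||% tirf_sim_params()
  sim <- simulate_tirf_fusion(sp, seed)
  events <- detect_fusion_events(sim$movie, "event", cfg,
                                 partner_channel = "partner")
  events <- classify_events(events, cfg)
  rate <- fusion_rate(events, sp$duration_s)
  cofrac <- tryCatch(cofusion_fraction(events), error = function(e) NA)
  tr <- intensity_trace(0, rate, units = "events/min")
  list(traces = .trace_to_results(tr, "fusion_rate_per_min"),
       summary = list(n_events = length(events),
                      fusion_rate_per_min = rate,
                      cofusion_percent = cofrac),
       plot_fun = NULL)
}

.pipe_spatial <- function(cfg, seed, sim_params) {
  sp <- sim_params %||% aggregation_sim_params(noise = FALSE)
  sim <- simulate_aggregation(sp, seed)
  img <- movie_frame(sim$movie, 1L, 1L)
  cell <- matrix(TRUE, nrow(img), ncol(img))
  disp <- dispersion(img, cell, sim$movie$pixel_size_nm)
  mask <- segment_endosomes(img, cfg)
  circ <- circularity(mask, cfg$min_object_px)
  tr <- intensity_trace(0, disp, units = "um")
  list(traces = .trace_to_results(tr, "dispersion_um"),
       summary = list(dispersion_um = disp,
                      mean_circularity = mean(circ$circularity),
                      n_objects = nrow(circ)),
       plot_fun = NULL)
}

.pipe_aggregation <- function(cfg, seed, sim_params, movie) {
  truth <- NULL
  if (is.null(movie)) {
    sp <- sim_params %||% aggregation_sim_params()
    sim <- simulate_aggregation(sp, seed)
    movie <- sim$movie; truth <- sim$truth
  }
  met <- aggregation_metrics(movie, 1L, cfg)
  pre <- met$frame < (truth$switch_frame %||% Inf)
  tr <- intensity_trace(met$time_s, met$n_vesicles, units = "vesicles")
  list(traces = .trace_to_results(tr, "vesicle_count"),
       summary = list(
         pre_switch_count = mean(met$n_vesicles[pre]),
         post_switch_count = mean(met$n_vesicles[!pre]),
         intensity_ratio = mean(met$mean_intensity[!pre], na.rm = TRUE) /
           mean(met$mean_intensity[pre], na.rm = TRUE)),
       plot_fun = function()
         plot(met$time_s, met$n_vesicles, type = "b",
              xlab = "time (s)", ylab = "vesicles"))
}

.pipe_divergence <- function(cfg, seed, sim_params) {
  sp <- sim_params %||% list(n_per_group = 15L, divergence_time_s = 50,
                             effect_size_sd = 5, noise_sd = 1,
                             times_s = seq(0, 100, by = 2.5))
  sim <- do.call(simulate_group_traces, c(sp, list(seed = seed)))
  div <- time_of_divergence(sim$a, sim$b, sim$times_s, alpha = cfg$alpha)
  tr <- intensity_trace(div$times_s, div$p_values, units = "p-value")
  list(traces = .trace_to_results(tr, "wilcoxon_p"),
       summary = list(divergence_time = if (div$diverged)
                        div$divergence_time_s else "none",
                      alpha = cfg$alpha,
                      true_divergence_time = sim$truth$divergence_time_s),
       plot_fun = function() {
         plot(div$times_s, div$p_values, log = "y", type = "b",
              xlab = "time (s)", ylab = "p")
         graphics::abline(h = cfg$alpha, lty = 2)
       })
}
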