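#' Read and validate a run configuration
#'
#' Configurations are human-readable YAML trees with the sections below;
#' unknown keys are rejected so that typos fail fast rather than being
#' silently ignored.
#'
#' \preformatted{
#' seed: 7
#' out_dir: out/
#' scene:
#'   kind: vesicles            # any make_geometry() kind
#'   params: {n: 30, r_range: [300, 500], extent: [8640, 8640]}
#'   density: 100              # fluorophores per micron
#'   tag_mode: double
#' plan:
#'   n_frames: 700
#'   frames_per_period_acq: 30
#'   mode: frexpan
#'   n_lead_frames: 100
#'   dose_on: 6
#'   dose_off: 3
#' detector: {shape: [192, 192], pixel_size: 45}
#' analysis:
#'   roi_size: 11
#'   max_rois: 120
#'   intensity_quantile: 0.8
#'   r2_gate_expan: 0.7
#'   r2_gate_noexpan: 0.4
#' noexpan_reference: shuttered   # shuttered | fpm | none
#' render_method: splat
#' write_tiff: false
#' }
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  validate_config(yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  known <- c("seed", "out_dir", "scene", "plan", "detector", "analysis",
             "noexpan_reference", "render_method", "write_tiff")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) stopf("unknown config key(s): %s",
                               paste(extra, collapse = ", "))
  for (sec in c("scene", "plan", "detector")) {
    if (is.null(cfg[[sec]])) stopf("config is missing the '%s' section", sec)
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$analysis <- cfg$analysis %||% list()
  cfg$noexpan_reference <- cfg$noexpan_reference %||% "shuttered"
  if (!cfg$noexpan_reference %in% c("shuttered", "fpm", "none"))
    stopf("noexpan_reference must be shuttered, fpm or none")
  cfg$render_method <- cfg$render_method %||% "integrate"
  cfg$write_tiff <- isTRUE(cfg$write_tiff)
  cfg
}

build_scene <- function(scene, seed) {
  params <- scene$params %||% list()
  if (identical(scene$kind, "vesicles") && is.null(params$seed))
    params$seed <- seed
  geom <- do.call(make_geometry, c(list(kind = scene$kind), params))
  field <- populate_dipoles(geom, density = scene$density,
                            tag_mode = scene$tag_mode %||% "double",
                            seed = seed)
  list(geom = geom, field = field)
}

build_plan <- function(plan) do.call(acquisition_plan, plan)

build_detector <- function(det) {
  det$shape <- unlist(det$shape)
  do.call(detector_model, det)
}

#' Run the full simulate-process-compare pipeline
#'
#' Simulates a FrExPAN acquisition (and, unless disabled, a matching
#' NoExPAN reference: either the same pulse scheme with the off-switch
#' beam shuttered, `"shuttered"`, or a plain FPM acquisition, `"fpm"`),
#' demultiplexes the readout frames, mean-normalizes, periodic-averages,
#' picks ROIs on the ExPAN stack, and compares ExPAN factors between the
#' two stacks.  All randomness derives from `cfg$seed`, so a
#' configuration determines every output.
#'
#' Artifacts written to `out_dir` (if set): `stats.json` (group
#' statistics plus provenance: configuration, seed, package version),
#' `rois.csv`, and, with `write_tiff`, the raw stacks and phase maps.
#'
#' @param cfg configuration list ([read_config()]) or YAML path
#' @param quiet suppress progress messages?
#' @return list with `stats` (an [compare_expan()] result or NULL),
#'   `rois`, `phase_map` (of the ExPAN periodic average), and the
#'   processed stacks
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cfg <- validate_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(cfg$seed)

  say("building scene (%s)", cfg$scene$kind)
  scn <- build_scene(cfg$scene, seed)
  plan_e <- build_plan(cfg$plan)
  det <- build_detector(cfg$detector)
  det$seed <- seed + 1L

  say("simulating ExPAN stack (%d frames)", plan_e$n_frames)
  sim_e <- simulate_stack(scn$field, plan_e, det,
                          render_method = cfg$render_method,
                          store_truth = FALSE)
  prep <- function(stack, n_cut) {
    raw_ro <- if (stack$frames_per_period > 0 && !is.null(stack$roles) &&
                  any(stack$roles == "switch"))
      demux_frexpan(stack, n_cut) else stack
    list(period = periodic_average(mean_normalize(raw_ro)),
         intensity = mean_image(raw_ro))
  }
  pe <- prep(sim_e$stack, plan_e$n_lead_frames)

  sim_n <- NULL; pn <- NULL
  if (cfg$noexpan_reference != "none") {
    plan_n <- cfg$plan
    if (cfg$noexpan_reference == "shuttered") {
      plan_n$dose_off <- 0
      plan_n$switch_brightness <- plan_e$switch_brightness / 4
    } else {
      plan_n$mode <- "fpm"; plan_n$n_lead_frames <- 0L
    }
    plan_n <- build_plan(plan_n)
    det_n <- det; det_n$seed <- seed + 2L
    say("simulating NoExPAN reference (%s)", cfg$noexpan_reference)
    sim_n <- simulate_stack(scn$field, plan_n, det_n,
                            render_method = cfg$render_method,
                            store_truth = FALSE)
    pn <- prep(sim_n$stack, plan_n$n_lead_frames)
  }

  an <- cfg$analysis
  say("picking ROIs")
  rois <- pick_rois(pe$period, intensity_image = pe$intensity,
                    roi_size = an$roi_size %||% 11L,
                    max_n = an$max_rois %||% 120L,
                    intensity_quantile = an$intensity_quantile %||% 0.8,
                    r2_gate = an$r2_gate_expan %||% 0.7)
  say("%d ROIs accepted", sum(rois$accepted))

  stats <- NULL
  if (!is.null(pn)) {
    stats <- compare_expan(pe$period, pn$period, rois,
                           r2_gate_expan = an$r2_gate_expan %||% 0.7,
                           r2_gate_noexpan = an$r2_gate_noexpan %||% 0.4)
    say("Cohen's d = %.2f, p = %.3g over %d ROIs",
        stats$cohens_d, stats$p_value, stats$n_rois)
  }
  pm <- fft_demodulate(pe$period)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_prov <- cfg; cfg_prov$out_dir <- NULL
    payload <- list(
      provenance = list(seed = seed, config = cfg_prov,
                        package_version = as.character(utils::packageVersion("frexpan")),
                        r_version = R.version.string),
      n_rois_accepted = sum(rois$accepted))
    if (!is.null(stats))
      payload$stats <- list(mean_f_expan = stats$mean_expan,
                            sd_f_expan = stats$sd_expan,
                            mean_f_noexpan = stats$mean_noexpan,
                            sd_f_noexpan = stats$sd_noexpan,
                            cohens_d = stats$cohens_d,
                            t_statistic = stats$t_statistic,
                            p_value = stats$p_value,
                            n_rois = stats$n_rois)
    jsonlite::write_json(payload, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(as.data.frame(rois), file.path(cfg$out_dir, "rois.csv"),
                     row.names = FALSE)
    if (cfg$write_tiff) {
      write_stack(sim_e$stack, file.path(cfg$out_dir, "expan_raw.tif"))
      if (!is.null(sim_n))
        write_stack(sim_n$stack, file.path(cfg$out_dir, "noexpan_raw.tif"))
      write_phase_map(pm, file.path(cfg$out_dir, "expan_phase.tif"),
                      file.path(cfg$out_dir, "expan_phase.png"))
    }
  }
  invisible(list(stats = stats, rois = rois, phase_map = pm,
                 expan_period = pe$period,
                 noexpan_period = if (!is.null(pn)) pn$period else NULL,
                 intensity_image = pe$intensity, config = cfg))
}
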