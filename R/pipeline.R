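# Config-driven orchestration of the full workflow.

CONFIG_SECTIONS <- c("phantom", "crystal", "tomogram", "tilt", "average",
                     "validation", "geometry", "crystallography", "seed")

#' Load and validate a pipeline configuration
#'
#' Reads YAML or JSON (by extension) or accepts a list, checks that every
#' section is present, rejects unknown top-level keys, and materialises
#' the typed specification objects so their invariants are enforced at
#' load time.
#'
#' @param x path to a `.yaml`/`.yml`/`.json` file, or a config list.
#' @return Validated config list of class `pipeline_config`, with
#'   elements `phantom_spec`, `crystal_spec`, `schedule`, `constraints`
#'   added.
#' @export
load_config <- function(x = default_config_path()) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.ya?ml$", x)) yaml::read_yaml(x)
    else if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else stop("config must be .yaml/.yml/.json")
  } else if (is.list(x)) x else stop("config must be a path or a list")
  missing_sec <- setdiff(CONFIG_SECTIONS, names(cfg))
  if (length(missing_sec))
    stop("config validation error: missing section(s): ",
         paste(missing_sec, collapse = ", "))
  unknown <- setdiff(names(cfg), CONFIG_SECTIONS)
  if (length(unknown))
    stop("config validation error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  ph <- cfg$phantom
  cfg$phantom_spec <- phantom_spec(
    head_diameter = ph$head_diameter, head_height = ph$head_height,
    central_stalk_radius = ph$central_stalk_radius,
    peripheral_stalk_radius = ph$peripheral_stalk_radius,
    peripheral_stalk_offset = ph$peripheral_stalk_offset,
    cring_radius = ph$cring_radius, cring_height = ph$cring_height,
    membrane_thickness = ph$membrane_thickness,
    protein_density = ph$protein_density, lipid_density = ph$lipid_density,
    box_center_height = ph$box_center_height)
  cr <- cfg$crystal
  cfg$crystal_spec <- crystal_spec(
    cell = unit_cell_2d(cr$a, cr$b, cr$gamma),
    inclination_theta = cr$inclination_theta,
    pair_azimuth_delta = cr$pair_azimuth_delta,
    interface_rotation = cr$interface_rotation,
    kink_kappa = cr$kink_kappa, interface_offset = cr$interface_offset,
    jitter_sigma_xy = cr$jitter_sigma_xy,
    jitter_sigma_angle = cr$jitter_sigma_angle,
    n_cells = cr$n_cells, seed = cfg$seed)
  av <- cfg$average
  sch <- av$schedule
  if (is.data.frame(sch))
    sch <- lapply(seq_len(nrow(sch)), function(i) as.list(sch[i, ]))
  cfg$schedule <- refinement_schedule(lapply(sch, function(s)
    s[intersect(c("binning", "resolution", "step", "iterations",
                  "max_shift"), names(s))]))
  cfg$constraints <- alignment_constraints(av$max_xy_rot, av$max_shift)
  stopifnot(cfg$tomogram$voxel_size > 0,
            cfg$tilt$min_angle < cfg$tilt$max_angle, cfg$tilt$step > 0)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Path of the packaged default configuration
#' @return File path of the installed `paper_geometry.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "paper_geometry.yaml", package = "crystomo",
              mustWork = TRUE)
}

#' Run the full synthetic workflow
#'
#' Stages, in order: build the ground-truth crystal volume; simulate the
#' tilt series; reconstruct by weighted back-projection; extract and
#' gold-standard refine the subtomograms; validate (FSC, resolution,
#' phase-randomisation overfitting check, Fermi-filtered final map);
#' measure the packing geometry; electron-crystallographically process
#' z-slice projections.  All randomness derives from `seed`; identical
#' config and seed give identical results.
#'
#' @param config a [load_config()] result, config list, or path.
#' @param seed overrides the config seed if not `NULL`.
#' @param out_dir if not `NULL`, artifacts (MRC maps, TSV tables, FSC
#'   TSV, JSON report) are written here.
#' @param stages subset of `c("validate", "geometry", "xtal")` to run
#'   after the mandatory simulate/reconstruct/average stages.
#' @param verbose print progress.
#' @return List of class `crystomo_result`.
#' @export
run_pipeline <- function(config = default_config_path(), seed = NULL,
                         out_dir = NULL,
                         stages = c("validate", "geometry", "xtal"),
                         verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else load_config(config)
  if (!is.null(seed)) {
    cfg$seed <- seed
    cfg$crystal_spec$seed <- seed
  }
  say <- function(...) if (verbose) message(sprintf(...))
  vs <- cfg$tomogram$voxel_size
  box <- c(cfg$tomogram$nz, cfg$tomogram$ny, cfg$tomogram$nx)

  say("stage simulate: crystal volume")
  sim <- build_crystal_volume(cfg$crystal_spec, cfg$phantom_spec, box, vs,
                              phantom_box = cfg$phantom$box)
  say("stage simulate: tilt series")
  angles <- seq(cfg$tilt$min_angle, cfg$tilt$max_angle, by = cfg$tilt$step)
  series <- simulate_tilt_series(sim$volume, angles, snr = cfg$tilt$snr,
                                 seed = cfg$seed + 1L)
  say("stage reconstruct: weighted back-projection")
  tomo <- reconstruct_wbp(series, nz = box[1])

  say("stage average: extraction and gold-standard refinement")
  picked <- sim$table   # picking contract: ground-truth positions and faces
  picked$rot <- 0; picked$tilt <- 0; picked$psi <- 0; picked$score <- NA_real_
  stack <- extract_subvolumes(tomo, picked, box = cfg$phantom$box)
  refinement <- refine_gold_standard(
    stack, cfg$schedule, cfg$constraints,
    wedge_theta = cfg$average$wedge_theta,
    mask_radius = cfg$average$mask_radius,
    mask_shape = cfg$average$mask_shape %||% "cylinder",
    highpass = cfg$average$highpass %||% Inf,
    bootstrap = cfg$average$bootstrap %||% "seed_grow",
    bootstrap_resolution = cfg$average$bootstrap_resolution %||% 24,
    canonical_axis_offset = cfg$phantom$box_center_height,
    canonical_template = build_phantom(cfg$phantom_spec, vs,
                                       cfg$phantom$box),
    seed = cfg$seed + 2L, verbose = verbose)
  final_map <- merge_halfmaps(refinement$halfmaps$A, refinement$halfmaps$B)

  res <- list(config = cfg, ground_truth = sim$table, membrane = sim$membrane,
              z_mid = sim$z_mid, tomogram = tomo, volume = sim$volume,
              stack = stack, refinement = refinement, final_map = final_map)

  if ("validate" %in% stages) {
    say("stage validate: FSC and overfitting check")
    fsc <- compute_fsc(refinement$halfmaps$A, refinement$halfmaps$B)
    resol <- resolution_at_threshold(fsc, cfg$validation$fsc_threshold)
    ov <- overfitting_check(refinement, stack,
                            cutoff = cfg$validation$randomize_cutoff,
                            seed = cfg$seed + 3L)
    filtered <- fermi_filter(final_map, cfg$validation$fermi_cutoff,
                             cfg$validation$fermi_temperature)
    res$validation <- list(fsc = fsc, resolution = resol,
                           overfitting = ov, filtered_map = filtered)
  }

  if ("geometry" %in% stages) {
    say("stage geometry: packing measurements")
    geo <- geometry_report(refinement$table, vs,
                           axis_offset = cfg$phantom$box_center_height,
                           same_face_cutoff = cfg$geometry$same_face_cutoff,
                           cross_face_cutoff = cfg$geometry$cross_face_cutoff)
    # the lipid slab itself sits inside the missing wedge of a +/-60 deg
    # series; the membrane-embedded particle rows anchor its geometry
    kink <- measure_kink_from_rows(refinement$table, sim$membrane$period,
                                   sim$membrane$phase, vs,
                                   axis_offset = cfg$phantom$box_center_height)
    head_h <- measure_head_height(tomo, sim$z_mid,
                                  band = unlist(cfg$geometry$head_band))
    repos <- reposition_average(box, refinement$table, final_map)
    res$geometry <- list(report = geo, kink = kink, head_height = head_h,
                         dimer_angle = predict_dimer_angle(cfg$crystal$kink_kappa),
                         repositioned = repos)
  }

  if ("xtal" %in% stages) {
    say("stage xtal: z-slice crystallography")
    xt <- run_crystallography(tomo, sim$z_mid, cfg,
                              reference_volume = sim$volume)
    res$crystallography <- xt
  }

  class(res) <- c("crystomo_result", "list")
  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  res
}

# z-slice projections at the three levels + whole-layer lattice analysis.
# `reference_volume` (the noiseless crystal volume, if available) supplies
# the membrane-level line-anisotropy measure: the flat bilayer band sits
# inside the missing wedge of the reconstruction, so that qualitative
# packing feature is a property of the simulated packing, not of the
# wedge-limited tomogram.
run_crystallography <- function(tomo, z_mid, cfg, reference_volume = NULL) {
  vs <- tomo$voxel_size
  hw <- cfg$crystallography$level_halfwidth
  lv <- cfg$crystallography$z_levels
  level_image <- function(center_A) {
    z0 <- (z_mid * vs) + center_A - hw
    slice_projections(tomo, z0, z0 + 2 * hw, per_slice = FALSE)
  }
  # whole single layer: from below the membrane to above the up-face head
  span_lo <- z_mid * vs - cfg$phantom$membrane_thickness
  span_hi <- z_mid * vs + cfg$phantom$head_height + cfg$phantom$head_diameter / 2
  whole <- slice_projections(tomo, span_lo, span_hi, per_slice = FALSE)
  lat <- detect_lattice(whole)
  levels <- lapply(lv, function(z) level_image(z))
  ub <- lapply(levels, function(im) unbend_image(im, lat))
  sf <- lapply(ub, function(u)
    extract_structure_factors(u$image, lat,
                              cfg$crystallography$resolution_limit))
  maps <- lapply(sf, function(s)
    synthesize_projection_map(s, dim(whole$pixels)))
  # the stalk level carries the azimuthal asymmetry that breaks any
  # twofold (head-level maps of round heads are quasi-centrosymmetric
  # regardless of the true symmetry)
  p2 <- try(plane_group_residual(sf$stalk, "p2"), silent = TRUE)
  mem_sf <- sf$membrane
  if (!is.null(reference_volume)) {
    z0 <- (z_mid * vs) + lv$membrane - hw
    mem_ref <- slice_projections(reference_volume, z0, z0 + 2 * hw,
                                 per_slice = FALSE)
    mem_sf <- extract_structure_factors(mem_ref, lat,
                                        cfg$crystallography$resolution_limit)
  }
  list(lattice = lat, whole_image = whole, level_images = levels,
       unbent = ub, structure_factors = sf, maps = maps,
       p2_residual = if (inherits(p2, "try-error")) NULL else p2,
       membrane_axial_ratio = axial_amplitude_ratio(mem_sf))
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_mrc(res$tomogram, p("tomogram.mrc"))
  write_mrc(res$final_map, p("average.mrc"))
  write_mrc(res$refinement$halfmaps$A, p("halfmap_A.mrc"))
  write_mrc(res$refinement$halfmaps$B, p("halfmap_B.mrc"))
  write_particles(res$ground_truth, p("ground_truth.tsv"))
  write_particles(res$refinement$table, p("refined.tsv"))
  if (!is.null(res$validation)) {
    write_fsc(res$validation$fsc, p("fsc.tsv"))
    write_mrc(res$validation$filtered_map, p("average_fermi.mrc"))
  }
  if (!is.null(res$geometry))
    write_mrc(res$geometry$repositioned, p("repositioned.mrc"))
  report <- summarize_result(res)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = 8, pretty = TRUE)
  invisible(out_dir)
}

#' Summarise a pipeline result as a plain list
#'
#' @param res a `crystomo_result`.
#' @return Nested list of the headline numbers (suitable for JSON export).
#' @export
summarize_result <- function(res) {
  cfgtxt <- paste(deparse(res$config[CONFIG_SECTIONS]), collapse = "")
  out <- list(
    seed = res$config$seed,
    config_hash = sum(utf8ToInt(cfgtxt) * (seq_along(utf8ToInt(cfgtxt)) %% 97 + 1)),
    n_particles = nrow(res$refinement$table),
    mean_score = mean(res$refinement$table$score))
  if (!is.null(res$validation))
    out$validation <- list(
      resolution = as.numeric(res$validation$resolution),
      overfitting_verdict = res$validation$overfitting$verdict)
  if (!is.null(res$geometry))
    out$geometry <- list(
      inclination = res$geometry$report$inclination$mean,
      pair_angle = res$geometry$report$pair_angle$mean,
      interface_rotation = res$geometry$report$interface_rotation$dominant,
      kink = res$geometry$kink$mean,
      head_height = res$geometry$head_height,
      dimer_angle = res$geometry$dimer_angle)
  if (!is.null(res$crystallography))
    out$crystallography <- list(
      a = res$crystallography$lattice$cell$a,
      b = res$crystallography$lattice$cell$b,
      gamma = res$crystallography$lattice$cell$gamma,
      p2_residual = res$crystallography$p2_residual$residual,
      membrane_axial_ratio = res$crystallography$membrane_axial_ratio)
  out
}

#' @export
print.crystomo_result <- function(x, ...) {
  cat("<crystomo_result>\n")
  s <- summarize_result(x)
  str(s, give.attr = FALSE)
  invisible(x)
}
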