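# Formats and configuration: track CSV, GeoJSON vector scenes, ASCII-grid
# stacks, JSON model serialisation, seasons, and the pipeline driver.

#' Read GPS tracks from CSV
#'
#' Expects columns `animal_id`, `timestamp` (ISO 8601), `x`, `y`. Rows are
#' sorted by animal and time; malformed rows (unparseable timestamp or
#' non-finite coordinates) are skipped with a count; duplicate
#' animal-timestamp rows keep the first occurrence.
#'
#' @param path CSV path.
#' @return tibble with parsed, sorted fixes.
#' @export
read_tracks <- function(path) {
  df <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                         progress = FALSE))
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) {
    warning("empty track file", call. = FALSE)
    return(tibble::tibble(animal_id = character(), timestamp = as.POSIXct(character()),
                          x = numeric(), y = numeric()))
  }
  if (!inherits(df$timestamp, "POSIXct"))
    df$timestamp <- as.POSIXct(as.character(df$timestamp), tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  bad <- is.na(df$timestamp) | !is.finite(df$x) | !is.finite(df$y) |
    is.na(df$animal_id)
  if (any(bad)) {
    message(sum(bad), " malformed row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  df <- dplyr::arrange(df, .data$animal_id, .data$timestamp)
  dup <- duplicated(df[c("animal_id", "timestamp")])
  if (any(dup)) {
    message(sum(dup), " duplicate timestamp row(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  tibble::as_tibble(df)
}

#' Write tracks to CSV
#' @param tracks track tibble.
#' @param path output path.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assign a biological season to timestamps
#'
#' May-June is spring, July-August summer, September-October fall,
#' January-February winter; other months return `NA` (excluded from seasonal
#' models).
#'
#' @param timestamp POSIXct (or parseable character) vector.
#' @return character vector of seasons or `NA`.
#' @export
assign_season <- function(timestamp) {
  if (is.character(timestamp))
    timestamp <- as.POSIXct(timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%d"))
  m <- as.integer(format(timestamp, "%m"))
  dplyr::case_when(
    m %in% 5:6 ~ "spring", m %in% 7:8 ~ "summer",
    m %in% 9:10 ~ "fall", m %in% 1:2 ~ "winter",
    TRUE ~ NA_character_)
}

# GeoJSON ---------------------------------------------------------------------

.geojson_feature <- function(geom_type, coords, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = geom_type, coordinates = coords))
}

.coords_list <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

#' Write a vector scene as GeoJSON
#'
#' One FeatureCollection; each feature carries `role` (town, trail, road,
#' railway, patch, transect, focal) in its properties.
#'
#' @param scene a [vector_scene()].
#' @param path output path.
#' @export
write_scene_geojson <- function(scene, path) {
  feats <- list()
  add_poly <- function(p, role) {
    ring <- rbind(p, p[1, , drop = FALSE])
    feats[[length(feats) + 1]] <<-
      .geojson_feature("Polygon", list(.coords_list(ring)), list(role = role))
  }
  add_line <- function(l, role) {
    feats[[length(feats) + 1]] <<-
      .geojson_feature("LineString", .coords_list(l), list(role = role))
  }
  for (p in scene$towns) add_poly(p, "town")
  for (cl in c("trail", "road", "railway"))
    for (l in scene$lines[[cl]]) add_line(l, cl)
  for (p in scene$patches) add_poly(p, "patch")
  for (l in scene$transects) add_line(l, "transect")
  if (!is.null(scene$focal)) add_poly(scene$focal, "focal")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vector scene from GeoJSON written by [write_scene_geojson()]
#' @param path GeoJSON path.
#' @return a [vector_scene()].
#' @export
read_scene_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  towns <- list(); patches <- list(); transects <- list(); focal <- NULL
  lines <- list(trail = list(), road = list(), railway = list())
  to_mat <- function(coords)
    do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  for (f in j$features) {
    role <- f$properties$role
    if (f$geometry$type == "Polygon") {
      m <- to_mat(f$geometry$coordinates[[1]])
      m <- m[-nrow(m), , drop = FALSE]   # drop closing vertex
      if (role == "town") towns[[length(towns) + 1]] <- m
      else if (role == "patch") patches[[length(patches) + 1]] <- m
      else if (role == "focal") focal <- m
    } else {
      m <- to_mat(f$geometry$coordinates)
      if (role %in% names(lines)) lines[[role]][[length(lines[[role]]) + 1]] <- m
      else if (role == "transect") transects[[length(transects) + 1]] <- m
    }
  }
  vector_scene(towns = towns, lines = lines, patches = patches,
               transects = transects, focal = focal)
}

# Stack and model serialisation ----------------------------------------------

#' Write a covariate stack to a directory
#'
#' One ASCII grid per layer plus the mask, and a JSON sidecar with grid
#' geometry, layer names, and the anthropogenic flags.
#'
#' @param stack a [covariate_stack()].
#' @param dir output directory (created).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack, nm, file.path(dir, paste0(nm, ".asc")))
  write_ascii_grid(stack, "mask", file.path(dir, "mask.asc"))
  meta <- list(origin = stack$origin, cell_size = stack$cell_size,
               n_rows = stack$n_rows, n_cols = stack$n_cols, crs = stack$crs,
               layers = names(stack$layers), anthropogenic = stack$anthropogenic)
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a covariate stack written by [write_stack()]
#' @param dir directory path.
#' @return a [covariate_stack()].
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- lapply(meta$layers, function(nm)
    read_ascii_grid(file.path(dir, paste0(nm, ".asc")))$matrix)
  names(layers) <- meta$layers
  mask <- read_ascii_grid(file.path(dir, "mask.asc"))$matrix == 1
  covariate_stack(origin = meta$origin, cell_size = meta$cell_size,
                  n_rows = meta$n_rows, n_cols = meta$n_cols, layers = layers,
                  anthropogenic = meta$anthropogenic, mask = mask,
                  crs = meta$crs)
}

#' Serialise a fitted model to JSON
#'
#' Works for `hmm_fit` and `ssf_fit`; everything needed to reuse the fit
#' (parameters, covariances, term names, likelihood) round-trips.
#'
#' @param fit an `hmm_fit` or `ssf_fit`.
#' @param path output path.
#' @export
write_model_json <- function(fit, path) {
  if (inherits(fit, "hmm_fit")) {
    obj <- list(type = "hmm_fit",
                mu = fit$params$mu, sigma = fit$params$sigma,
                kappa = fit$params$kappa, mean_angle = fit$params$mean_angle,
                beta = fit$params$beta, tcov_layers = fit$params$tcov_layers,
                loglik = fit$loglik, aic = fit$aic, npar = fit$npar,
                vcov = fit$vcov, se = fit$se, vcov_ok = fit$vcov_ok,
                convergence = fit$convergence, n_steps = fit$n_steps)
  } else if (inherits(fit, "ssf_fit")) {
    obj <- list(type = "ssf_fit", terms = fit$terms, beta = fit$beta,
                vcov_model = fit$vcov_model, vcov_robust = fit$vcov_robust,
                loglik = fit$loglik, qic = fit$qic, n_strata = fit$n_strata,
                n_clusters = fit$n_clusters, converged = fit$converged)
  } else stop("unsupported model type", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialised by [write_model_json()]
#' @param path JSON path.
#' @return a list mirroring the serialised fields (`hmm_fit` entries are
#'   rebuilt into an [hmm_params()] under `$params`).
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(j$type, "hmm_fit")) {
    j$params <- hmm_params(j$mu, j$sigma, j$kappa, j$mean_angle,
                           as.matrix(j$beta), j$tcov_layers)
  }
  j
}

# Pipeline --------------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Generates (or loads) the landscape and tracks, fits the movement HMM,
#' smooths state probabilities, builds used/available strata, fits the SSF,
#' simulates path ensembles per scenario, and summarises habitat use and
#' connectivity. Every stage writes its artifact plus a manifest (seed,
#' stage, inputs) into `out_dir`; a rerun with the same config reproduces
#' identical outputs.
#'
#' @param config named list (or YAML file path): see Details. Key entries:
#'   `seed` (master seed), `out_dir`, `landscape` (config list for
#'   [generate_landscape()]), `true_hmm`/`true_ssf` (generator truth),
#'   `n_animals`, `n_steps`, `scenarios` (character vector), `n_paths`,
#'   `steps_per_path`, `species`, `season`.
#' @return invisible list of in-memory results (`hmm_fit`, `ssf_fit`,
#'   `ensembles`, `summary` tibble).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1, out_dir = tempfile("movescape_run_"),
    landscape = list(n_rows = 80, n_cols = 120),
    true_hmm = NULL, true_ssf = NULL,
    n_animals = 8, n_steps = 240,
    scenarios = c("reference", "current"),
    n_paths = 100, steps_per_path = 240,
    species = "wolf", season = "summer",
    clip_buffer_m = 2500), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seasons <- cfg$season
  if (identical(cfg$species, "grizzly_bear") && "winter" %in% seasons) {
    message("winter excluded for grizzly bears (hibernation)")
    seasons <- setdiff(seasons, "winter")
  }
  manifest <- list(seed = cfg$seed, species = cfg$species, season = seasons,
                   stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- list(done = TRUE,
                                     seed = derive_seed(cfg$seed, name))
    value
  }

  # 1. landscape + ground-truth tracks
  land <- stage("landscape",
                generate_landscape(cfg$landscape, seed = derive_seed(cfg$seed, "landscape")))
  stack <- land$stack; scene <- land$scene
  write_stack(stack, file.path(cfg$out_dir, "stack"))
  write_scene_geojson(scene, file.path(cfg$out_dir, "scene.geojson"))
  true_hmm <- cfg$true_hmm %||% default_true_hmm()
  true_ssf <- cfg$true_ssf %||% default_true_ssf()
  tracks <- stage("tracks",
                  generate_labelled_tracks(stack, scene, true_hmm, true_ssf,
                                           n_animals = cfg$n_animals,
                                           n_steps = cfg$n_steps,
                                           seed = derive_seed(cfg$seed, "tracks")))
  write_tracks(dplyr::select(tracks, -"state", -"hour"),
               file.path(cfg$out_dir, "tracks.csv"))

  # 2. movement HMM and smoothed state probabilities
  steps <- build_steps(tracks, stack)
  hmm_fit <- stage("fit-hmm",
                   fit_hmm(steps, seed = derive_seed(cfg$seed, "hmm-init")))
  write_model_json(hmm_fit, file.path(cfg$out_dir, "hmm.json"))
  steps <- smoothed_state_probs(steps, hmm_fit)

  # 3. step selection
  spec <- ssf_design()
  strata <- sample_available_steps(steps, stack,
                                   seed = derive_seed(cfg$seed, "availability"))
  design <- assemble_design(strata, stack, scene, spec)
  ssf_fit <- stage("fit-ssf", fit_conditional_logit(design))
  write_model_json(ssf_fit, file.path(cfg$out_dir, "ssf.json"))

  # 4. scenario simulation
  scen_specs <- list(
    reference = scenario_spec("reference", overrides = list(
      mask = availability_mask(stack, land$landcover, land$slope, scene$towns,
                               scenario = "reference"))),
    current = scenario_spec("current"),
    future = scenario_spec("future"))
  ensembles <- list()
  for (sc in cfg$scenarios) {
    scfg <- sim_config(n_paths = cfg$n_paths, days = cfg$steps_per_path / 12,
                       seed = derive_seed(cfg$seed, paste0("simulate-", sc)))
    scfg$steps_per_path <- as.integer(cfg$steps_per_path)
    bundle <- scenario_bundle(stack, scene, ssf_fit, hmm_fit, spec,
                              scenario = scen_specs[[sc]], config = scfg)
    ensembles[[sc]] <- stage(paste0("simulate-", sc), simulate_ensemble(bundle))
  }

  # 5. summaries: UD, bins, validation, connectivity
  summary_rows <- list()
  ref_counts <- NULL
  uds <- list()
  for (sc in names(ensembles)) {
    ud <- utilization_distribution(ensembles[[sc]], stack,
                                   clip_buffer_m = cfg$clip_buffer_m)
    uds[[sc]] <- ud
    bm <- equal_area_bins(ud, mask = stack$mask)
    hq <- high_quality_proportion(bm, scene$focal, stack)
    n_patch <- patch_traversal_count(ensembles[[sc]], scene$patches[[1]],
                                     scene$patches[[2]])
    n_cross <- vapply(scene$transects, function(tr)
      transect_crossing_count(ensembles[[sc]], tr), 0L)
    summary_rows[[sc]] <- tibble::tibble(
      species = cfg$species, season = seasons[1], scenario = sc,
      hq_proportion = hq, n_patch = n_patch,
      n_transect = mean(n_cross))
  }
  summary <- dplyr::bind_rows(summary_rows)
  if ("reference" %in% summary$scenario) {
    ref <- summary[summary$scenario == "reference", ]
    summary$percent_intact <- vapply(seq_len(nrow(summary)), function(i)
      percent_intact(summary$hq_proportion[i], ref$hq_proportion), 0)
    ratio_to_ref <- function(n, n_ref, is_ref) {
      ifelse(is_ref, 1, ifelse(n_ref > 0, n / n_ref, NA_real_))
    }
    is_ref <- summary$scenario == "reference"
    summary$patch_connectivity <- ratio_to_ref(summary$n_patch, ref$n_patch, is_ref)
    summary$transect_connectivity <- ratio_to_ref(summary$n_transect,
                                                  ref$n_transect, is_ref)
  }
  # validation against the generating tracks under current conditions
  if ("current" %in% names(uds)) {
    bm_cur <- equal_area_bins(uds$current, mask = stack$mask)
    val <- spearman_validation(bm_cur, tracks, stack)
    summary$spearman_pooled <- val$rho[val$animal_id == "pooled"]
  }
  readr::write_csv(summary, file.path(cfg$out_dir, "connectivity.csv"),
                   progress = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stack = stack, scene = scene, tracks = tracks,
                 hmm_fit = hmm_fit, ssf_fit = ssf_fit, ensembles = ensembles,
                 summary = summary))
}

#' Default ground-truth movement parameters for the synthetic study
#'
#' Slow state: 50 m mean steps, weak directionality; fast state: 500 m mean
#' steps, concentrated turns. Transitions respond to time of day, town
#' distance, and trail density with unit-magnitude coefficients.
#' @export
default_true_hmm <- function() {
  hmm_params(mu = c(50, 500), sigma = c(50, 400), kappa = c(0.5, 2),
             mean_angle = c(0, 0),
             beta = matrix(c(-1,  1, -1,  1,
                             -1, -1,  1, -1), 2, 4, byrow = TRUE))
}

#' Default ground-truth selection coefficients for the synthetic study
#'
#' Selection for habitat quality, avoidance near towns and of high trail
#' density, stronger for the slow state (positive `:p_fast` interactions
#' relax the avoidance when travelling).
#' @export
default_true_ssf <- function() {
  c(habitat = 1.5, town_prox = -4, trail_density = -0.5,
    trail_density_sq = -0.05,
    "town_prox:p_fast" = 2, "trail_density:p_fast" = 0.3,
    "cos_ta" = 0.2)
}
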