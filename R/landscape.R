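# Synthetic valley landscapes: covariate layers, vector scenes (towns, linear
# features, habitat patches, transects), scenarios, and the availability mask.
# Everything is planar, in projected metres; the default grid uses 120 m cells.

#' Vector scene
#'
#' Container for the vector geometry the pipeline consumes: town polygons,
#' classed linear features, habitat-patch polygons, cross-valley transects,
#' and a focal-area polygon. Polygons are n x 2 matrices (implicitly closed),
#' polylines are n x 2 matrices.
#'
#' @param towns list of polygons.
#' @param lines named list with elements `trail`, `road`, `railway`, each a
#'   list of polylines (possibly empty).
#' @param patches list of at least two disjoint polygons.
#' @param transects list of polylines.
#' @param focal single polygon.
#' @return object of class `vector_scene`.
#' @export
vector_scene <- function(towns = list(), lines = list(trail = list(), road = list(), railway = list()),
                         patches = list(), transects = list(), focal = NULL) {
  for (cl in c("trail", "road", "railway"))
    if (is.null(lines[[cl]])) lines[[cl]] <- list()
  if (length(patches) >= 2) {
    for (i in seq_along(patches)) for (j in seq_along(patches)) {
      if (i >= j) next
      if (any(point_in_polygon(patches[[j]][, 1], patches[[j]][, 2], patches[[i]])) ||
          any(point_in_polygon(patches[[i]][, 1], patches[[i]][, 2], patches[[j]])))
        stop("habitat patches must be disjoint", call. = FALSE)
    }
  }
  structure(list(towns = towns, lines = lines, patches = patches,
                 transects = transects, focal = focal),
            class = "vector_scene")
}

#' Scenario specification
#'
#' @param name one of `"reference"`, `"current"`, `"future"`.
#' @param overrides named list of replacement layers (matrices) and/or a
#'   replacement `mask`; names must already exist in the stack.
#' @param zero_anthropogenic zero all anthropogenic selection and transition
#'   coefficients when simulating; forced `TRUE` for the reference scenario.
#' @export
scenario_spec <- function(name, overrides = list(),
                          zero_anthropogenic = identical(name, "reference")) {
  name <- match.arg(name, c("reference", "current", "future"))
  if (name == "reference" && !zero_anthropogenic)
    stop("reference scenario must zero anthropogenic coefficients", call. = FALSE)
  structure(list(name = name, overrides = overrides,
                 zero_anthropogenic = zero_anthropogenic),
            class = "scenario_spec")
}

# Gaussian smoothing of a matrix by separable convolution, edge-normalised so
# the border keeps the field's scale. Deterministic.
smooth_matrix <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma_cells))
  k <- exp(-((-hw:hw)^2) / (2 * sigma_cells^2))
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - hw); hi <- min(n, i + hw)
      kk <- k[(lo - i + hw + 1):(hi - i + hw + 1)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' Rasterize polygons onto the stack's grid
#'
#' A cell is covered when its centre falls inside any polygon.
#'
#' @param polys list of polygons.
#' @param stack grid source.
#' @return logical matrix.
#' @export
rasterize_polygons <- function(polys, stack) {
  out <- matrix(FALSE, stack$n_rows, stack$n_cols)
  if (length(polys) == 0) return(out)
  cc <- cell_centers(stack)
  inside <- rep(FALSE, nrow(cc))
  for (p in polys) inside <- inside | point_in_polygon(cc$x, cc$y, p)
  out[cbind(cc$row, cc$col)] <- inside
  out
}

#' Distance-to-town covariate layer
#'
#' Distance is from each cell centre to the nearest town polygon (zero
#' inside). Two transforms:
#' * `capped_linear`: `min(d, range_m) / range_m` — a distance-like covariate,
#'   0 at the town edge, 1 at and beyond the range;
#' * `exp_decay`: `exp(-d / range_m)` — a proximity-like covariate, 1 at the
#'   town edge decaying to 0.
#'
#' @param towns list of town polygons (empty allowed: constant "far" layer
#'   with a warning).
#' @param stack grid source.
#' @param mode `"capped_linear"` or `"exp_decay"`.
#' @param range_m decay range / asymptote distance in metres, in `[500, 5000]`.
#' @return numeric matrix.
#' @export
town_distance_layer <- function(towns, stack, mode = c("capped_linear", "exp_decay"),
                                range_m = 5000) {
  mode <- match.arg(mode)
  stopifnot(range_m >= 500, range_m <= 5000)
  if (length(towns) == 0) {
    warning("no towns: returning constant far-from-town layer")
    far <- if (mode == "capped_linear") 1 else 0
    return(matrix(far, stack$n_rows, stack$n_cols))
  }
  cc <- cell_centers(stack)
  segs <- polylines_to_segments(lapply(towns, function(p) rbind(p, p[1, ])))
  d <- dist_point_segments(cc$x, cc$y, segs)
  inside <- rep(FALSE, nrow(cc))
  for (p in towns) inside <- inside | point_in_polygon(cc$x, cc$y, p)
  d[inside] <- 0
  v <- if (mode == "capped_linear") pmin(d, range_m) / range_m else exp(-d / range_m)
  m <- matrix(0, stack$n_rows, stack$n_cols)
  m[cbind(cc$row, cc$col)] <- v
  m
}

#' Linear-feature density layer (km/km^2)
#'
#' For every cell centre, the total length of linear features inside the
#' circle of radius `radius_m`, divided by the circle area. Exact
#' circle-segment clipping, so a single straight line through a cell centre
#' gives `2r / (pi r^2)` exactly.
#'
#' @param lines list of polylines (pass trails + roads for the trail-road
#'   density used by the models).
#' @param stack grid source.
#' @param radius_m circle radius in metres; must exceed the cell size.
#' @return numeric matrix in km/km^2.
#' @export
line_density_layer <- function(lines, stack, radius_m = 500) {
  stopifnot(radius_m > stack$cell_size)
  m <- matrix(0, stack$n_rows, stack$n_cols)
  segs <- dedupe_segments(polylines_to_segments(lines))
  if (nrow(segs) == 0) return(m)
  cc <- cell_centers(stack)
  total <- numeric(nrow(cc))
  for (i in seq_len(nrow(segs))) {
    xlo <- min(segs[i, 1], segs[i, 3]) - radius_m
    xhi <- max(segs[i, 1], segs[i, 3]) + radius_m
    ylo <- min(segs[i, 2], segs[i, 4]) - radius_m
    yhi <- max(segs[i, 2], segs[i, 4]) + radius_m
    idx <- which(cc$x >= xlo & cc$x <= xhi & cc$y >= ylo & cc$y <= yhi)
    if (length(idx) == 0) next
    total[idx] <- total[idx] +
      .seg_len_in_circles(segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4],
                          cc$x[idx], cc$y[idx], radius_m)
  }
  dens <- (total / 1000) / (pi * (radius_m / 1000)^2)
  m[cbind(cc$row, cc$col)] <- dens
  m
}

#' Availability mask
#'
#' A cell is unavailable when it is barren/ice with slope above 35 degrees,
#' or (outside the reference scenario) when it lies inside a developed
#' polygon. Under the reference scenario the developed footprint is restored
#' to available habitat.
#'
#' @param stack grid source.
#' @param landcover integer matrix; codes in `barren_codes` are barren/ice.
#' @param slope_deg slope matrix in degrees.
#' @param developed_polygons list of town / development polygons.
#' @param scenario scenario name or [scenario_spec()]; `"reference"` skips the
#'   developed mask.
#' @param barren_codes landcover codes treated as barren/ice.
#' @param slope_limit_deg slope threshold in degrees.
#' @return logical matrix, `TRUE` = available.
#' @export
availability_mask <- function(stack, landcover, slope_deg, developed_polygons,
                              scenario = "current", barren_codes = 0L,
                              slope_limit_deg = 35) {
  name <- if (inherits(scenario, "scenario_spec")) scenario$name else scenario
  un <- (landcover %in% barren_codes) & (slope_deg > slope_limit_deg)
  un <- matrix(un, nrow(landcover), ncol(landcover))
  if (!identical(name, "reference") && length(developed_polygons) > 0)
    un <- un | rasterize_polygons(developed_polygons, stack)
  if (all(un)) stop("availability mask has no available cells", call. = FALSE)
  !un
}

#' Generate a synthetic valley landscape
#'
#' An east-west valley bounded by steep barren ridges, two towns on the
#' valley floor, a road / railway / trail network along the valley with
#' `trail_intensity` spur trails, a smooth habitat-quality field (Gaussian
#' random field plus a valley-bottom bonus), and the derived covariate
#' layers: `d_town` (capped-linear distance, 5 km), `town_prox` (exponential
#' decay, 500 m), `trail_density` (+ its square), `slope`, `elevation`,
#' `habitat`. Deterministic given `seed`.
#'
#' @param config named list of optional settings: `n_rows`, `n_cols`,
#'   `cell_size`, `town_frac_x` (two fractions along the valley),
#'   `town_half_m` (two half-widths in metres), `trail_intensity`
#'   (number of spur trails), `habitat_corr_cells` (random-field correlation
#'   length), `d_town_range_m`, `town_prox_range_m`, `density_radius_m`.
#' @param seed integer seed.
#' @return list with elements `stack` ([covariate_stack()]), `scene`
#'   ([vector_scene()]), `landcover`, `slope` (matrices).
#' @export
generate_landscape <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_rows = 120L, n_cols = 200L, cell_size = 120,
    town_frac_x = c(0.38, 0.66), town_half_m = c(900, 700),
    trail_intensity = 12, habitat_corr_cells = 6,
    d_town_range_m = 5000, town_prox_range_m = 500,
    density_radius_m = 500), config)
  nr <- as.integer(cfg$n_rows); nc <- as.integer(cfg$n_cols); cs <- cfg$cell_size
  if (nr < 50 || nc < 50) stop("grid must be at least 50 x 50 cells")
  W <- nc * cs; H <- nr * cs
  set.seed(seed)

  st <- covariate_stack(origin = c(0, 0), cell_size = cs, n_rows = nr, n_cols = nc)
  cc <- cell_centers(st)
  ymid <- H / 2
  valley_half <- 0.22 * H
  dvy <- abs(cc$y - ymid)

  # terrain: flat valley floor, flanks rising at a constant 42 degrees
  flank_deg <- 42
  elev <- 1400 + pmax(0, dvy - valley_half) * tan(flank_deg * pi / 180)
  elev_m <- matrix(0, nr, nc); elev_m[cbind(cc$row, cc$col)] <- elev
  slope <- matrix(0, nr, nc)
  slope[cbind(cc$row, cc$col)] <- ifelse(dvy > valley_half, flank_deg, 0)
  treeline_rise <- 700  # metres of rise before cover turns barren
  landcover <- matrix(1L, nr, nc)                      # 1 = forest
  landcover[elev_m > 1400 + treeline_rise] <- 0L       # 0 = barren / ice
  green <- smooth_matrix(matrix(stats::runif(nr * nc), nr, nc), 3) > 0.55
  landcover[green & elev_m < 1450] <- 2L               # 2 = open / green space

  # habitat quality: random field + valley-bottom bonus, rescaled to [0, 1]
  grf <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), cfg$habitat_corr_cells)
  grf <- (grf - min(grf)) / (max(grf) - min(grf))
  valley_bonus <- matrix(0, nr, nc)
  valley_bonus[cbind(cc$row, cc$col)] <- exp(-(dvy / valley_half)^2)
  habitat <- 0.55 * grf + 0.45 * valley_bonus

  # towns: rectangles on the valley floor
  towns <- lapply(seq_along(cfg$town_frac_x), function(i) {
    cx <- cfg$town_frac_x[i] * W; cy <- ymid
    h <- cfg$town_half_m[i]
    rbind(c(cx - h, cy - 0.7 * h), c(cx + h, cy - 0.7 * h),
          c(cx + h, cy + 0.7 * h), c(cx - h, cy + 0.7 * h))
  })
  for (p in towns)
    if (any(p[, 1] < 0 | p[, 1] > W | p[, 2] < 0 | p[, 2] > H))
      stop("town placement falls outside the grid", call. = FALSE)

  # linear features: meandering valley road, parallel railway, main trail,
  # plus seeded spur trails; intensity 0 means no human linear network at all
  xs <- seq(0.02 * W, 0.98 * W, by = 4 * cs)
  meander <- function(amp, phase) ymid + amp * sin(2 * pi * xs / (0.45 * W) + phase)
  railway <- cbind(xs, meander(0.04 * H, pi / 3) - 500)
  n_spur <- round(cfg$trail_intensity)
  if (n_spur > 0) {
    road <- list(cbind(xs, meander(0.045 * H, 0)))
    main_trail <- cbind(xs, meander(0.05 * H, pi / 1.5) + 450)
    sx <- stats::runif(n_spur, 0.05 * W, 0.95 * W)
    sy <- ymid + stats::runif(n_spur, -0.1 * H, 0.1 * H)
    ang <- stats::runif(n_spur, 0, 2 * pi)
    len <- stats::runif(n_spur, 1000, 3000)
    ex <- pmin(pmax(sx + len * cos(ang), 0.01 * W), 0.99 * W)
    ey <- pmin(pmax(sy + len * sin(ang), 0.01 * H), 0.99 * H)
    spurs <- lapply(seq_len(n_spur), function(i) rbind(c(sx[i], sy[i]), c(ex[i], ey[i])))
    trails <- c(list(main_trail), spurs)
  } else {
    road <- list()
    trails <- list()
  }

  patches <- list(
    rbind(c(0.02 * W, ymid - valley_half), c(0.10 * W, ymid - valley_half),
          c(0.10 * W, ymid + valley_half), c(0.02 * W, ymid + valley_half)),
    rbind(c(0.90 * W, ymid - valley_half), c(0.98 * W, ymid - valley_half),
          c(0.98 * W, ymid + valley_half), c(0.90 * W, ymid + valley_half)))
  transects <- lapply(cfg$town_frac_x, function(f)
    cbind(c(f * W, f * W), c(0, H)))
  focal <- rbind(
    c(cfg$town_frac_x[1] * W - 5000, ymid - valley_half),
    c(cfg$town_frac_x[2] * W + 5000, ymid - valley_half),
    c(cfg$town_frac_x[2] * W + 5000, ymid + valley_half),
    c(cfg$town_frac_x[1] * W - 5000, ymid + valley_half))

  scene <- vector_scene(towns = towns,
                        lines = list(trail = trails, road = road,
                                     railway = list(railway)),
                        patches = patches, transects = transects, focal = focal)

  trail_density <- line_density_layer(c(scene$lines$trail, scene$lines$road),
                                      st, radius_m = cfg$density_radius_m)
  layers <- list(
    habitat = habitat, elevation = elev_m, slope = slope,
    d_town = town_distance_layer(towns, st, "capped_linear", cfg$d_town_range_m),
    town_prox = town_distance_layer(towns, st, "exp_decay", cfg$town_prox_range_m),
    trail_density = trail_density,
    trail_density_sq = trail_density^2)
  mask <- availability_mask(st, landcover, slope, towns, scenario = "current")
  stack <- covariate_stack(
    origin = c(0, 0), cell_size = cs, n_rows = nr, n_cols = nc,
    layers = layers,
    anthropogenic = c("d_town", "town_prox", "trail_density", "trail_density_sq"),
    mask = mask)
  list(stack = stack, scene = scene, landcover = landcover, slope = slope)
}

#' Apply a future-development scenario to a landscape
#'
#' Expands the developed footprint with new town polygons (their cells become
#' unavailable) and adds informal trails to the formal network, recomputing
#' the trail-road density (and its square). Duplicate trail segments are
#' de-duplicated before the density computation; all other layers are left
#' unchanged (green spaces stay available).
#'
#' @param stack current-scenario [covariate_stack()].
#' @param scene current [vector_scene()].
#' @param new_town_polygons list of polygons to add to the developed footprint.
#' @param informal_trails list of polylines to add to the trail network.
#' @param density_radius_m radius for the recomputed density layer.
#' @return list with updated `stack` and `scene`.
#' @export
apply_future_development <- function(stack, scene, new_town_polygons = list(),
                                     informal_trails = list(),
                                     density_radius_m = 500) {
  W <- stack$n_cols * stack$cell_size; H <- stack$n_rows * stack$cell_size
  for (g in c(new_town_polygons, informal_trails))
    if (any(g[, 1] < stack$origin[1] | g[, 1] > stack$origin[1] + W |
            g[, 2] < stack$origin[2] | g[, 2] > stack$origin[2] + H))
      stop("new geometry falls outside the grid", call. = FALSE)
  scene2 <- scene
  scene2$towns <- c(scene$towns, new_town_polygons)
  scene2$lines$trail <- c(scene$lines$trail, informal_trails)
  stack2 <- stack
  if (length(new_town_polygons) > 0)
    stack2$mask <- stack$mask & !rasterize_polygons(new_town_polygons, stack)
  if (length(informal_trails) > 0) {
    dens <- line_density_layer(c(scene2$lines$trail, scene2$lines$road),
                               stack, radius_m = density_radius_m)
    stack2$layers$trail_density <- dens
    if ("trail_density_sq" %in% names(stack2$layers))
      stack2$layers$trail_density_sq <- dens^2
  }
  list(stack = validate_stack(stack2), scene = scene2)
}
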