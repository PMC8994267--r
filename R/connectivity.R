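# Habitat use and Merriam connectivity: utilization distributions from path
# ensembles, ten equal-area habitat bins, Spearman validation against GPS
# locations, high-quality habitat (bin rank >= 7) and percent-intact
# summaries, and unique-path patch-traversal / transect-crossing counts.

#' Utilization distribution from a path ensemble
#'
#' Counts simulated locations per grid cell after discarding locations within
#' `clip_buffer_m` of the study-area edge, then normalises by the retained
#' location count. The state filter keeps slow-only, fast-only, or all steps.
#'
#' @param ensemble a `path_ensemble` (or a tibble of locations with `x`, `y`
#'   and optionally `state`).
#' @param stack grid source.
#' @param state one of `"combined"`, `"slow"`, `"fast"`.
#' @param clip_buffer_m edge buffer excluded before counting.
#' @return object of class `utilization_distribution`: `ud` matrix summing to
#'   one, `state`, `scenario`, `n_locations`, grid geometry.
#' @export
utilization_distribution <- function(ensemble, stack, state = c("combined", "slow", "fast"),
                                     clip_buffer_m = 5000) {
  state <- match.arg(state)
  locs <- if (inherits(ensemble, "path_ensemble")) ensemble$steps else ensemble
  scen <- if (inherits(ensemble, "path_ensemble")) ensemble$scenario else NA_character_
  stopifnot(nrow(locs) > 0)
  if (state != "combined") {
    stopifnot("state" %in% names(locs))
    locs <- locs[locs$state == (state == "fast") * 1, , drop = FALSE]
  }
  W <- stack$n_cols * stack$cell_size; H <- stack$n_rows * stack$cell_size
  keep <- locs$x >= stack$origin[1] + clip_buffer_m &
    locs$x <= stack$origin[1] + W - clip_buffer_m &
    locs$y >= stack$origin[2] + clip_buffer_m &
    locs$y <= stack$origin[2] + H - clip_buffer_m
  locs <- locs[keep, , drop = FALSE]
  if (nrow(locs) == 0)
    stop("no locations retained after clipping the edge buffer", call. = FALSE)
  rc <- cell_of(stack, locs$x, locs$y)
  counts <- matrix(0, stack$n_rows, stack$n_cols)
  tab <- table(factor(rc[, 1], levels = 1:stack$n_rows),
               factor(rc[, 2], levels = 1:stack$n_cols))
  counts[] <- as.numeric(tab)
  structure(list(ud = counts / sum(counts), counts = counts, state = state,
                 scenario = scen, n_locations = nrow(locs),
                 origin = stack$origin, cell_size = stack$cell_size,
                 clip_buffer_m = clip_buffer_m),
            class = "utilization_distribution")
}

#' Ten equal-area habitat-use bins
#'
#' In-mask cells are sorted by UD value (ties broken by row-major cell index)
#' and partitioned into `n_bins` groups of equal cell count (within one
#' cell); rank 1 is lowest use, rank `n_bins` highest.
#'
#' @param ud a `utilization_distribution` (or bare matrix).
#' @param mask logical matrix of cells to bin (e.g. availability mask);
#'   default all cells.
#' @param n_bins number of bins.
#' @return object of class `bin_map`: `bins` (integer matrix, `NA` off-mask),
#'   `n_bins`, `mask`, grid geometry.
#' @export
equal_area_bins <- function(ud, mask = NULL, n_bins = 10) {
  m <- if (inherits(ud, "utilization_distribution")) ud$ud else ud
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  idx <- which(t(mask))          # row-major cell order for the tie-break
  if (length(idx) < n_bins) stop("fewer in-mask cells than bins", call. = FALSE)
  vals <- t(m)[idx]
  ord <- idx[order(vals, idx)]   # ascending use, ties by row-major index
  k <- length(ord)
  sizes <- rep(floor(k / n_bins), n_bins)
  extra <- k - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ranks <- rep(seq_len(n_bins), times = sizes)
  bins_t <- matrix(NA_integer_, ncol(m), nrow(m))   # transposed workspace
  bins_t[ord] <- ranks
  bins <- t(bins_t)
  structure(list(bins = bins, n_bins = n_bins, mask = mask,
                 origin = if (inherits(ud, "utilization_distribution")) ud$origin else NULL,
                 cell_size = if (inherits(ud, "utilization_distribution")) ud$cell_size else NULL),
            class = "bin_map")
}

# Bin rank at point locations (NA outside mask/grid).
bin_at <- function(binmap, stack, x, y) {
  rc <- cell_of(stack, x, y)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- binmap$bins[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Spearman validation of predicted habitat use
#'
#' Tallies the proportion of GPS locations in each use bin and correlates it
#' with bin rank (Spearman). Computed pooled, and per animal when an
#' `animal_id` column is present.
#'
#' @param binmap a [equal_area_bins()] result.
#' @param locations tibble with `x`, `y` (and optionally `animal_id`).
#' @param stack grid source.
#' @return tibble with `animal_id` (`"pooled"` first), `rho`, `n_locations`.
#' @export
spearman_validation <- function(binmap, locations, stack) {
  b <- bin_at(binmap, stack, locations$x, locations$y)
  ok <- !is.na(b)
  if (!any(ok)) stop("no locations fall inside the binned area", call. = FALSE)
  rho_of <- function(bins) {
    prop <- as.numeric(table(factor(bins, levels = seq_len(binmap$n_bins)))) / length(bins)
    if (length(unique(bins)) < 2) {
      warning("all locations in a single bin: rho undefined", call. = FALSE)
      return(NA_real_)
    }
    suppressWarnings(stats::cor(prop, seq_len(binmap$n_bins), method = "spearman"))
  }
  out <- tibble::tibble(animal_id = "pooled", rho = rho_of(b[ok]),
                        n_locations = sum(ok))
  if ("animal_id" %in% names(locations)) {
    per <- locations[ok, , drop = FALSE]
    per$bin <- b[ok]
    pa <- per %>% dplyr::group_by(.data$animal_id) %>%
      dplyr::summarise(rho = rho_of(.data$bin), n_locations = dplyr::n(),
                       .groups = "drop")
    out <- dplyr::bind_rows(out, pa)
  }
  out
}

#' High-quality habitat proportion within a focal area
#'
#' Proportion of in-mask focal cells with bin rank at or above `threshold`
#' (rank >= 7 defines high-quality habitat).
#'
#' @param binmap a [equal_area_bins()] result.
#' @param focal focal-area polygon.
#' @param stack grid source.
#' @param threshold minimum high-quality rank.
#' @return scalar proportion.
#' @export
high_quality_proportion <- function(binmap, focal, stack, threshold = 7) {
  cc <- cell_centers(stack)
  inside <- point_in_polygon(cc$x, cc$y, focal)
  if (!any(inside)) stop("focal polygon does not intersect the grid", call. = FALSE)
  b <- binmap$bins[cbind(cc$row, cc$col)]
  sel <- inside & !is.na(b)
  if (!any(sel)) stop("no in-mask cells inside the focal polygon", call. = FALSE)
  mean(b[sel] >= threshold)
}

#' Percent intact habitat relative to reference conditions
#'
#' `100 * proportion_scenario / proportion_reference`.
#'
#' @param prop_scenario,prop_reference high-quality proportions.
#' @return percentage (`NA` with a warning when the reference proportion is 0).
#' @export
percent_intact <- function(prop_scenario, prop_reference) {
  if (prop_reference == 0) {
    warning("reference proportion is zero: percent intact undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * prop_scenario / prop_reference
}

#' Count unique paths traversing between two habitat patches
#'
#' A path counts once if it has at least one location in each patch, in
#' either order.
#'
#' @param ensemble a `path_ensemble` (or location tibble with `path_id`).
#' @param patch_a,patch_b disjoint polygons.
#' @return integer count of unique paths.
#' @export
patch_traversal_count <- function(ensemble, patch_a, patch_b) {
  locs <- if (inherits(ensemble, "path_ensemble")) ensemble$steps else ensemble
  if (any(point_in_polygon(patch_b[, 1], patch_b[, 2], patch_a)) ||
      any(point_in_polygon(patch_a[, 1], patch_a[, 2], patch_b)))
    stop("patches must be disjoint", call. = FALSE)
  in_a <- point_in_polygon(locs$x, locs$y, patch_a)
  in_b <- point_in_polygon(locs$x, locs$y, patch_b)
  hit <- tibble::tibble(path_id = locs$path_id, in_a = in_a, in_b = in_b) %>%
    dplyr::group_by(.data$path_id) %>%
    dplyr::summarise(both = any(.data$in_a) && any(.data$in_b), .groups = "drop")
  sum(hit$both)
}

#' Count unique paths crossing a transect
#'
#' A path counts once if any of its step segments intersects any segment of
#' the transect polyline (endpoint touches count).
#'
#' @param ensemble a `path_ensemble` (or location tibble with `path_id`,
#'   ordered by step within path).
#' @param transect polyline matrix (n x 2, n >= 2) with positive length.
#' @return integer count of unique paths.
#' @export
transect_crossing_count <- function(ensemble, transect) {
  locs <- if (inherits(ensemble, "path_ensemble")) ensemble$steps else ensemble
  transect <- as.matrix(transect)
  tsegs <- polylines_to_segments(list(transect))
  if (nrow(tsegs) == 0 ||
      all((tsegs[, 1] == tsegs[, 3]) & (tsegs[, 2] == tsegs[, 4])))
    stop("degenerate zero-length transect", call. = FALSE)
  same_path <- locs$path_id[-1] == locs$path_id[-nrow(locs)]
  x1 <- locs$x[-nrow(locs)][same_path]; y1 <- locs$y[-nrow(locs)][same_path]
  x2 <- locs$x[-1][same_path]; y2 <- locs$y[-1][same_path]
  pid <- locs$path_id[-1][same_path]
  crossed <- rep(FALSE, length(x1))
  for (i in seq_len(nrow(tsegs))) {
    qx1 <- tsegs[i, 1]; qy1 <- tsegs[i, 2]; qx2 <- tsegs[i, 3]; qy2 <- tsegs[i, 4]
    d1 <- (qx2 - qx1) * (y1 - qy1) - (qy2 - qy1) * (x1 - qx1)
    d2 <- (qx2 - qx1) * (y2 - qy1) - (qy2 - qy1) * (x2 - qx1)
    d3 <- (x2 - x1) * (qy1 - y1) - (y2 - y1) * (qx1 - x1)
    d4 <- (x2 - x1) * (qy2 - y1) - (y2 - y1) * (qx2 - x1)
    crossed <- crossed | (d1 * d2 <= 0 & d3 * d4 <= 0 &
                            !(d1 == 0 & d2 == 0 & d3 == 0 & d4 == 0))
  }
  length(unique(pid[crossed]))
}

#' Write a utilization distribution or bin map as an ASCII grid
#'
#' @param x a `utilization_distribution` or `bin_map` (must carry grid
#'   geometry).
#' @param path output file path.
#' @export
write_ud_grid <- function(x, path) {
  m <- if (inherits(x, "utilization_distribution")) x$ud else x$bins
  if (is.null(x$origin) || is.null(x$cell_size))
    stop("object carries no grid geometry", call. = FALSE)
  st <- covariate_stack(origin = x$origin, cell_size = x$cell_size,
                        n_rows = nrow(m), n_cols = ncol(m),
                        layers = list(values = m * 1),
                        mask = !is.na(m))
  write_ascii_grid(st, "values", path)
}

#' Merriam connectivity ratio
#'
#' `n_traverse / n_reference`, with a binomial delta-method CI on the log
#' ratio when the ensemble size is supplied. Fewer than ten reference paths
#' make the ratio unreliable (flagged).
#'
#' @param n_traverse traversal/crossing count under the scenario.
#' @param n_reference count under reference conditions.
#' @param n_paths paths per ensemble (for the CI); optional.
#' @param level confidence level.
#' @return tibble: `ratio`, `conf.low`, `conf.high`, `n_traverse`,
#'   `n_reference`.
#' @export
connectivity_ratio <- function(n_traverse, n_reference, n_paths = NULL,
                               level = 0.95) {
  stopifnot(n_traverse >= 0, n_reference >= 0)
  if (n_reference == 0) {
    warning("zero reference paths: connectivity undefined", call. = FALSE)
    return(tibble::tibble(ratio = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, n_traverse = n_traverse,
                          n_reference = n_reference))
  }
  if (n_reference < 10)
    warning("fewer than ten reference paths: ratio unreliable", call. = FALSE)
  ratio <- n_traverse / n_reference
  lo <- hi <- NA_real_
  if (!is.null(n_paths) && n_traverse > 0) {
    se_log <- sqrt((1 - n_traverse / n_paths) / n_traverse +
                     (1 - n_reference / n_paths) / n_reference)
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- ratio * exp(-z * se_log); hi <- ratio * exp(z * se_log)
  }
  tibble::tibble(ratio = ratio, conf.low = lo, conf.high = hi,
                 n_traverse = n_traverse, n_reference = n_reference)
}
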