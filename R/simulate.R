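# Individual-based path simulation: at every 2-h step the animal's state is
# resampled from the covariate-dependent transition row, 20 candidate steps
# are drawn from the state-specific gamma / von Mises laws, candidates
# crossing unavailable habitat (checked at four equidistant points along the
# segment) are rejected, and one survivor is chosen by softmax on the SSF
# linear predictor with the candidate's binary state standing in for p_Fast.

#' Simulation configuration
#'
#' @param n_paths number of paths.
#' @param days days per path.
#' @param fixes_per_day fixes per day (2-h interval = 12).
#' @param n_candidates candidate steps per move.
#' @param fractions checkpoints along a proposed step, as fractions of its
#'   length, all of which must be available.
#' @param boundary_threshold terminate a path when the proportion of proposed
#'   candidate endpoints falling outside the study area exceeds this.
#' @param boundary_rule `"cumulative"` (running proportion over the whole
#'   path) or `"per_step"`.
#' @param clip_buffer_m outer buffer excluded when summarising use.
#' @param max_redraw candidate-set redraws when all 20 are rejected.
#' @param stuck_limit consecutive held steps before the path is flagged stuck.
#' @param seed master seed.
#' @export
sim_config <- function(n_paths = 1000, days = 60, fixes_per_day = 12,
                       n_candidates = 20, fractions = c(0.25, 0.5, 0.75, 1),
                       boundary_threshold = 0.40,
                       boundary_rule = c("cumulative", "per_step"),
                       clip_buffer_m = 5000, max_redraw = 5, stuck_limit = 10,
                       seed = 1) {
  boundary_rule <- match.arg(boundary_rule)
  stopifnot(n_paths >= 1, n_candidates >= 1,
            boundary_threshold > 0, boundary_threshold < 1)
  structure(list(n_paths = as.integer(n_paths), days = days,
                 fixes_per_day = fixes_per_day,
                 steps_per_path = as.integer(days * fixes_per_day),
                 fix_h = 24 / fixes_per_day,
                 n_candidates = as.integer(n_candidates),
                 fractions = fractions,
                 boundary_threshold = boundary_threshold,
                 boundary_rule = boundary_rule,
                 clip_buffer_m = clip_buffer_m,
                 max_redraw = as.integer(max_redraw),
                 stuck_limit = as.integer(stuck_limit),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Derive a named substream seed from a master seed
#'
#' Every source of randomness in the pipeline draws its seed from the master
#' seed through a named substream, so reruns are reproducible and streams do
#' not collide.
#'
#' @param master integer master seed.
#' @param name substream name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) * 131))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483587) + 1L
}

#' Scenario-adjusted model coefficients
#'
#' Under the reference scenario (or any scenario with `zero_anthropogenic`),
#' every anthropogenic SSF term -- and its `p_fast` / `c_hour` interactions --
#' is set to zero, and the anthropogenic HMM transition coefficients (columns
#' named after anthropogenic layers) are zeroed too. Current and future
#' scenarios return the fitted coefficients unchanged (their landscapes
#' differ instead). Zeroing is idempotent.
#'
#' @param ssf_beta named SSF coefficient vector (or `ssf_fit`).
#' @param hmm an [hmm_params()] (or `hmm_fit`).
#' @param scenario a [scenario_spec()] or scenario name.
#' @param spec the [ssf_design()] naming the anthropogenic terms.
#' @param anthropogenic_layers layer names whose transition coefficients are
#'   anthropogenic.
#' @return list with `ssf_beta` and `hmm` (an `hmm_params`).
#' @export
scenario_coefficients <- function(ssf_beta, hmm, scenario, spec,
                                  anthropogenic_layers = c("d_town", "trail_density")) {
  if (inherits(ssf_beta, "ssf_fit")) ssf_beta <- ssf_beta$beta
  if (inherits(hmm, "hmm_fit")) hmm <- hmm$params
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  if (scenario$zero_anthropogenic) {
    zap <- c(spec$anthropogenic,
             paste0(spec$anthropogenic, ":p_fast"),
             paste0(spec$anthropogenic, ":c_hour"))
    ssf_beta[names(ssf_beta) %in% zap] <- 0
    zap_t <- intersect(colnames(hmm$beta), anthropogenic_layers)
    hmm$beta[, zap_t] <- 0
  }
  list(ssf_beta = ssf_beta, hmm = hmm)
}

# Align a named coefficient vector onto term names, filling zeros.
.beta_at <- function(beta, terms) {
  out <- stats::setNames(rep(0, length(terms)), terms)
  hit <- intersect(names(beta), terms)
  out[hit] <- beta[hit]
  out
}

#' Build a scenario bundle for the simulator
#'
#' Assembles everything one simulated path needs: the scenario's layers and
#' availability mask, the (scenario-adjusted) SSF coefficients split into
#' endpoint / on-off / movement parts with their state and time interactions,
#' the transition model, precomputed distance-to-feature rasters, and the
#' simulation configuration.
#'
#' @param stack [covariate_stack()].
#' @param scene [vector_scene()].
#' @param ssf_beta named SSF coefficient vector (or `ssf_fit`).
#' @param hmm an [hmm_params()] (or `hmm_fit`).
#' @param spec the [ssf_design()].
#' @param scenario a [scenario_spec()] or scenario name; overrides are
#'   applied, and coefficients zeroed via [scenario_coefficients()].
#' @param config a [sim_config()].
#' @return list of class `scenario_bundle`.
#' @export
scenario_bundle <- function(stack, scene, ssf_beta, hmm, spec,
                            scenario = "current", config = sim_config()) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  extra <- setdiff(names(scenario$overrides), c(names(stack$layers), "mask"))
  if (length(extra))
    stop("scenario overrides unknown layers: ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (nm in setdiff(names(scenario$overrides), "mask"))
    stack$layers[[nm]] <- scenario$overrides[[nm]]
  if ("mask" %in% names(scenario$overrides)) stack$mask <- scenario$overrides$mask
  co <- scenario_coefficients(ssf_beta, hmm, scenario, spec)
  beta <- co$ssf_beta; hmm <- co$hmm

  sq_terms <- if (length(spec$quadratic)) paste0(spec$quadratic, "_sq") else character()
  layer_terms <- unique(c(spec$endpoint, sq_terms, hmm$tcov_layers))
  end_layers <- list()
  for (nm in layer_terms) {
    if (nm %in% names(stack$layers)) {
      end_layers[[nm]] <- stack$layers[[nm]]
    } else if (nm %in% sq_terms) {
      end_layers[[nm]] <- stack$layers[[sub("_sq$", "", nm)]]^2
    } else stop("layer '", nm, "' not in stack", call. = FALSE)
  }
  cc <- cell_centers(stack)
  onoff <- lapply(spec$onoff, function(cl) {
    segs <- polylines_to_segments(scene$lines[[cl]])
    cd <- matrix(Inf, stack$n_rows, stack$n_cols)
    if (nrow(segs) > 0)
      cd[cbind(cc$row, cc$col)] <- dist_point_segments(cc$x, cc$y, segs)
    tm <- paste0("on_", cl)
    list(segs = segs, cdist = cd,
         beta = unname(.beta_at(beta, tm)),
         beta_state = unname(.beta_at(beta, paste0(tm, ":p_fast"))),
         beta_chour = unname(.beta_at(beta, paste0(tm, ":c_hour"))))
  })
  mv <- c("step_length_km", "cos_ta")
  bundle <- list(
    grid = list(x0 = stack$origin[1], y0 = stack$origin[2],
                cs = stack$cell_size, nr = stack$n_rows, nc = stack$n_cols),
    mask = stack$mask,
    end_layers = end_layers,
    beta_end = unname(.beta_at(beta, layer_terms)),
    beta_end_state = unname(.beta_at(beta, paste0(layer_terms, ":p_fast"))),
    beta_end_chour = unname(.beta_at(beta, paste0(layer_terms, ":c_hour"))),
    tcov_idx = match(hmm$tcov_layers, layer_terms),
    onoff = onoff, buffer = spec$buffer_m,
    beta_move = unname(.beta_at(beta, mv)),
    beta_move_state = unname(.beta_at(beta, paste0(mv, ":p_fast"))),
    beta_move_chour = unname(.beta_at(beta, paste0(mv, ":c_hour"))),
    hmm = list(mu = hmm$mu, sigma = hmm$sigma, kappa = hmm$kappa,
               mang = hmm$mean_angle, beta = unname(hmm$beta)),
    config = list(n_cand = config$n_candidates, fracs = config$fractions,
                  boundary_threshold = config$boundary_threshold,
                  boundary_cumulative = config$boundary_rule == "cumulative",
                  max_redraw = config$max_redraw,
                  stuck_limit = config$stuck_limit, fix_h = config$fix_h),
    scenario = scenario$name, spec = spec, sim_config = config,
    stack = stack, scene = scene, ssf_beta = beta, hmm_params = hmm)
  class(bundle) <- "scenario_bundle"
  bundle
}

#' Seed path start points in high-quality habitat
#'
#' Uniform draws among top-third cells of the habitat map, uniform position
#' within the cell, start hour uniform over the fix times.
#'
#' @param map a `habitat_map` from [predict_habitat_map()].
#' @param n_paths number of starts.
#' @param seed integer seed.
#' @param fixes_per_day fix schedule defining the possible start hours.
#' @return tibble with `x`, `y`, `hour`.
#' @export
seed_start_points <- function(map, n_paths, seed = 1, fixes_per_day = 12) {
  cells <- which(map$top_third, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("empty top-third mask", call. = FALSE)
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n_paths, replace = TRUE), , drop = FALSE]
  cs <- map$cell_size %||% 120
  x0 <- map$origin %||% c(0, 0)
  tibble::tibble(
    x = x0[1] + (pick[, 2] - 1) * cs + stats::runif(n_paths) * cs,
    y = x0[2] + (pick[, 1] - 1) * cs + stats::runif(n_paths) * cs,
    hour = sample(seq(0, 24 - 24 / fixes_per_day, by = 24 / fixes_per_day),
                  n_paths, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# R-side linear predictor for one candidate step (mirrors the C++ scoring;
# used by propose/select and in audits).
.candidate_eta <- function(bundle, x_end, y_end, state, c_hour, len_m, turn) {
  rc <- cell_of(list(origin = c(bundle$grid$x0, bundle$grid$y0),
                     cell_size = bundle$grid$cs, n_rows = bundle$grid$nr,
                     n_cols = bundle$grid$nc), x_end, y_end)
  eta <- rep(NA_real_, length(x_end))
  ok <- !is.na(rc[, 1])
  if (!any(ok)) return(eta)
  e <- rep(0, sum(ok))
  for (j in seq_along(bundle$end_layers)) {
    b <- bundle$beta_end[j] + state[ok] * bundle$beta_end_state[j] +
      c_hour * bundle$beta_end_chour[j]
    e <- e + b * bundle$end_layers[[j]][cbind(rc[ok, 1], rc[ok, 2])]
  }
  for (cl in bundle$onoff) {
    bsum <- cl$beta + state[ok] * cl$beta_state + c_hour * cl$beta_chour
    if (all(bsum == 0)) next
    on <- dist_point_segments(x_end[ok], y_end[ok], cl$segs) <= bundle$buffer
    e <- e + bsum * on
  }
  e <- e + (bundle$beta_move[1] + state[ok] * bundle$beta_move_state[1] +
              c_hour * bundle$beta_move_chour[1]) * (len_m[ok] / 1000)
  e <- e + (bundle$beta_move[2] + state[ok] * bundle$beta_move_state[2] +
              c_hour * bundle$beta_move_chour[2]) * cos(turn[ok])
  eta[ok] <- e
  eta
}

#' Propose candidate steps
#'
#' Draws `n` candidates: state from the current state's transition row,
#' length from that state's gamma law, turn angle from its von Mises law,
#' endpoint projected from the current bearing. Scores each candidate with
#' the SSF linear predictor (binary candidate state in the `p_fast`
#' interactions).
#'
#' @param bundle a [scenario_bundle()].
#' @param x,y current location.
#' @param hour hour of day at the step start.
#' @param state current state (0 slow, 1 fast).
#' @param bearing current bearing in radians.
#' @param n number of candidates.
#' @return tibble: `state`, `length`, `turn`, `x_end`, `y_end`, `eta`,
#'   `outside`, `rejected`.
#' @export
propose_candidates <- function(bundle, x, y, hour, state, bearing, n = 20) {
  hp <- bundle$hmm
  rc <- cell_of(bundle$stack, x, y)
  tc <- vapply(bundle$tcov_idx,
               function(j) bundle$end_layers[[j]][rc[1, 1], rc[1, 2]], 0)
  G <- transition_matrix(hp$beta, c(cos_hour(hour), tc))
  p_switch <- if (state == 0) G[1, 2] else G[2, 1]
  st <- ifelse(stats::runif(n) < p_switch, 1 - state, state)
  shape <- (hp$mu / hp$sigma)^2; scale <- hp$sigma^2 / hp$mu
  len <- stats::rgamma(n, shape = shape[st + 1], scale = scale[st + 1])
  turn <- vapply(st, function(s) rvonmises_cpp(1, hp$mang[s + 1], hp$kappa[s + 1]), 0)
  xe <- x + len * cos(bearing + turn)
  ye <- y + len * sin(bearing + turn)
  outside <- is.na(cell_of(bundle$stack, xe, ye)[, 1])
  rejected <- outside | !vapply(seq_len(n), function(i)
    reject_step(bundle$stack, x, y, xe[i], ye[i],
                fractions = bundle$config$fracs), TRUE)
  eta <- .candidate_eta(bundle, xe, ye, st, cos_hour(hour), len, turn)
  tibble::tibble(state = st, length = len, turn = turn, x_end = xe,
                 y_end = ye, eta = eta, outside = outside, rejected = rejected)
}

#' Accept or reject a proposed step
#'
#' Evaluates the availability mask at the given fractions along the segment
#' (by default 0.25, 0.5, 0.75, 1.0); the step is accepted only if every
#' checkpoint is in available habitat and inside the grid.
#'
#' @param stack [covariate_stack()] (its mask is used).
#' @param x1,y1,x2,y2 step segment endpoints.
#' @param fractions checkpoint fractions along the segment.
#' @return `TRUE` to accept.
#' @export
reject_step <- function(stack, x1, y1, x2, y2, fractions = c(0.25, 0.5, 0.75, 1)) {
  px <- x1 + fractions * (x2 - x1)
  py <- y1 + fractions * (y2 - y1)
  all(is_available(stack, px, py))
}

#' Select one surviving candidate by softmax
#'
#' @param eta linear predictors of the surviving candidates.
#' @return index of the chosen candidate.
#' @export
select_step <- function(eta) {
  if (length(eta) == 0) stop("no surviving candidates", call. = FALSE)
  w <- exp(eta - max(eta))
  sample.int(length(eta), 1, prob = w / sum(w))
}

#' Simulate one movement path
#'
#' @param bundle a [scenario_bundle()].
#' @param start list or tibble row with `x`, `y`, `hour`; optional `state`
#'   (default: drawn from the stationary distribution there) and `bearing`
#'   (default: uniform on the circle).
#' @param n_steps number of steps (defaults to the bundle's config).
#' @param seed optional integer seed (set before any draw).
#' @return tibble with `step`, `x`, `y`, `hour`, `state`; attributes
#'   `reason`, `n_proposed`, `n_outside`, `n_holds`.
#' @export
simulate_path <- function(bundle, start, n_steps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_steps <- n_steps %||% bundle$sim_config$steps_per_path
  hp <- bundle$hmm
  rc <- cell_of(bundle$stack, start$x, start$y)
  if (is.na(rc[1, 1])) stop("start outside grid", call. = FALSE)
  state <- start[["state"]] %||% {
    tc <- vapply(bundle$tcov_idx,
                 function(j) bundle$end_layers[[j]][rc[1, 1], rc[1, 2]], 0)
    pf <- stationary_probs(hp$beta, c(cos_hour(start$hour), tc))[["fast"]]
    as.integer(stats::runif(1) < pf)
  }
  bearing <- start[["bearing"]] %||% stats::runif(1, -pi, pi)
  res <- simulate_path_cpp(start$x, start$y, as.integer(state), start$hour,
                           bearing, as.integer(n_steps), unclass(bundle))
  out <- tibble::as_tibble(as.data.frame(res$path))
  out$step <- seq_len(nrow(out)) - 1L
  out <- out[, c("step", "x", "y", "hour", "state")]
  attr(out, "reason") <- res$reason
  attr(out, "n_proposed") <- res$n_proposed
  attr(out, "n_outside") <- res$n_outside
  attr(out, "n_holds") <- res$n_holds
  out
}

#' Simulate a path ensemble
#'
#' Seeds `n_paths` start points in the scenario's top-third habitat, then
#' simulates each path on its own derived seed substream, so the ensemble is
#' reproducible from the master seed alone.
#'
#' @param bundle a [scenario_bundle()].
#' @param config optional [sim_config()] (defaults to the bundle's).
#' @param map optional `habitat_map` for seeding (default: computed from the
#'   bundle at `p_fast = 0.5`, `c_hour = 0`).
#' @return object of class `path_ensemble`: `steps` (tibble: `path_id`,
#'   `step`, `x`, `y`, `hour`, `state`), `scenario`, `seed`, `terminations`
#'   (tibble), `config`.
#' @export
simulate_ensemble <- function(bundle, config = NULL, map = NULL) {
  config <- config %||% bundle$sim_config
  if (is.null(map)) {
    map <- predict_habitat_map(bundle$ssf_beta, bundle$stack, bundle$scene,
                               bundle$spec, p_fast = 0.5, c_hour = 0)
    map$origin <- bundle$stack$origin
    map$cell_size <- bundle$stack$cell_size
  }
  map$top_third <- map$top_third & bundle$mask
  if (!any(map$top_third))
    stop("no available high-quality start cells", call. = FALSE)
  starts <- seed_start_points(map, config$n_paths,
                              seed = derive_seed(config$seed, "starts"),
                              fixes_per_day = config$fixes_per_day)
  paths <- vector("list", config$n_paths)
  reasons <- character(config$n_paths)
  for (i in seq_len(config$n_paths)) {
    p <- simulate_path(bundle, starts[i, ], n_steps = config$steps_per_path,
                       seed = derive_seed(config$seed, paste0("path-", i)))
    reasons[i] <- attr(p, "reason")
    p$path_id <- i
    paths[[i]] <- p
  }
  steps <- dplyr::bind_rows(paths)[, c("path_id", "step", "x", "y", "hour", "state")]
  structure(list(steps = steps, scenario = bundle$scenario,
                 seed = config$seed,
                 terminations = tibble::tibble(path_id = seq_len(config$n_paths),
                                               reason = reasons),
                 config = config),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat("<path_ensemble> scenario:", x$scenario, "-",
      length(unique(x$steps$path_id)), "paths,", nrow(x$steps), "locations\n")
  print(table(x$terminations$reason))
  invisible(x)
}

#' Generate ground-truth labelled tracks
#'
#' Drives the path simulator with *known* movement and selection parameters
#' and keeps the hidden state, producing CSV-ready telemetry with ground
#' truth for parameter-recovery checks. Paths start in the top third of the
#' true selection surface.
#'
#' @param stack,scene landscape.
#' @param true_hmm an [hmm_params()].
#' @param true_ssf named SSF coefficient vector (zeros give uniform
#'   selection among candidates).
#' @param n_animals number of tracks.
#' @param n_steps steps per track.
#' @param spec an [ssf_design()] describing how `true_ssf` maps to layers.
#' @param fix_interval_h fix interval in hours.
#' @param start POSIXct timestamp of the first fix.
#' @param starts optional tibble of start points (`x`, `y`, `hour`), one per
#'   animal, overriding the top-third seeding.
#' @param seed integer seed.
#' @return tibble: `animal_id`, `timestamp`, `x`, `y`, `hour`, `state`
#'   (0 slow / 1 fast, the true label).
#' @export
generate_labelled_tracks <- function(stack, scene, true_hmm, true_ssf,
                                     n_animals, n_steps,
                                     spec = ssf_design(), fix_interval_h = 2,
                                     start = as.POSIXct("2022-07-01 00:00:00", tz = "UTC"),
                                     starts = NULL, seed = 1) {
  config <- sim_config(n_paths = n_animals, days = 1,
                       fixes_per_day = 24 / fix_interval_h, seed = seed)
  config$steps_per_path <- as.integer(n_steps)
  bundle <- scenario_bundle(stack, scene, true_ssf, true_hmm, spec,
                            scenario = "current", config = config)
  if (is.null(starts)) {
    map <- predict_habitat_map(true_ssf, stack, scene, spec, p_fast = 0.5, c_hour = 0)
    map$top_third <- map$top_third & stack$mask
    if (!any(map$top_third))
      stop("no available high-quality start cells", call. = FALSE)
    starts <- seed_start_points(map, n_animals,
                                seed = derive_seed(seed, "track-starts"),
                                fixes_per_day = config$fixes_per_day)
  }
  stopifnot(nrow(starts) == n_animals)
  purrr::map_dfr(seq_len(n_animals), function(i) {
    st <- starts[i, ]
    p <- simulate_path(bundle, st, n_steps = n_steps,
                       seed = derive_seed(seed, paste0("track-", i)))
    tibble::tibble(
      animal_id = sprintf("A%02d", i),
      timestamp = start + (st$hour + (p$step) * fix_interval_h) * 3600,
      x = p$x, y = p$y, hour = p$hour, state = as.integer(p$state))
  })
}
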