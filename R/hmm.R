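# Two-state hidden Markov movement model: gamma step lengths, von Mises turn
# angles, logit-linear transition probabilities in time of day (cosine of
# hour), distance to town, and trail-road density. State 1 = slow
# (foraging/resting), state 2 = fast (travelling/hunting).

#' Two-state movement-model parameters
#'
#' @param mu,sigma gamma step-length mean and sd in metres, length 2
#'   (slow, fast); `mu[2] > mu[1]` is required for identifiability.
#' @param kappa von Mises turn-angle concentrations, length 2, `>= 0`.
#' @param mean_angle von Mises mean turn angles in radians, length 2.
#' @param beta transition-coefficient matrix, 2 rows (slow->fast, fast->slow)
#'   by `2 + length(tcov_layers)` columns: intercept, `c_hour`, then one per
#'   transition covariate layer.
#' @param tcov_layers names of the covariate layers (beyond `c_hour`) that
#'   drive transitions; defaults to town distance and trail-road density.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, kappa, mean_angle = c(0, 0),
                       beta = NULL,
                       tcov_layers = c("d_town", "trail_density")) {
  if (is.null(beta)) beta <- matrix(0, 2, 2 + length(tcov_layers))
  stopifnot(length(mu) == 2, length(sigma) == 2, length(kappa) == 2,
            length(mean_angle) == 2, is.matrix(beta), nrow(beta) == 2,
            ncol(beta) == 2 + length(tcov_layers))
  if (any(mu <= 0) || any(sigma <= 0)) stop("mu and sigma must be positive")
  if (any(kappa < 0)) stop("kappa must be non-negative")
  if (!all(is.finite(kappa))) stop("kappa must be finite")
  if (mu[2] <= mu[1]) stop("mu[fast] must exceed mu[slow]")
  dimnames(beta) <- list(c("slow_to_fast", "fast_to_slow"),
                         c("(Intercept)", "c_hour", tcov_layers))
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 kappa = as.numeric(kappa), mean_angle = as.numeric(mean_angle),
                 beta = beta, tcov_layers = tcov_layers),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> slow/fast gamma mean:", round(x$mu, 1), " sd:",
      round(x$sigma, 1), "\n  kappa:", round(x$kappa, 3),
      " mean angle:", round(x$mean_angle, 3), "\n")
  cat("  transition coefficients:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Cosine-of-hour covariate
#'
#' `cos(2*pi*h/24)`: midnight (h = 0) maps to 1 (night), noon to -1 (day).
#' @param hour hour of day in `[0, 24)`, fractional allowed.
#' @export
cos_hour <- function(hour) cos(2 * pi * hour / 24)

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi)
  w[w <= 0] <- w[w <= 0] + 2 * pi
  w - pi
}

#' Build a step series from a track
#'
#' Converts a regularised GPS track into steps: Euclidean lengths, signed
#' turn angles (change in bearing, `NA` for the first step of each contiguous
#' segment), hour-of-day covariate, and transition covariates extracted from
#' the stack at each step's start. Inter-fix gaps outside the nominal interval
#' (2 h within a tolerance) break the track into independent segments. Fixes
#' outside the grid drop their steps (count reported via message).
#'
#' @param track tibble with `animal_id`, `timestamp` (POSIXct or ISO 8601
#'   character), `x`, `y` (metres).
#' @param stack [covariate_stack()] holding the transition covariate layers.
#' @param tcov_layers layer names extracted at step starts.
#' @param fix_interval_h nominal fix interval in hours.
#' @param tol_min tolerance around the nominal interval, in minutes.
#' @return tibble, one row per step: `animal_id`, `seg_id`, `t`, `x`, `y`,
#'   `x_end`, `y_end`, `l` (m), `bearing`, `theta`, `hour`, `c_hour`, plus one
#'   column per transition covariate layer.
#' @export
build_steps <- function(track, stack, tcov_layers = c("d_town", "trail_density"),
                        fix_interval_h = 2, tol_min = 15) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(track)))
  tr <- dplyr::arrange(track, .data$animal_id, .data$timestamp)
  if (is.character(tr$timestamp))
    tr$timestamp <- as.POSIXct(tr$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  out <- tr %>%
    dplyr::group_by(.data$animal_id) %>%
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < 2) return(tibble::tibble())
      dt_h <- as.numeric(difftime(d$timestamp[-1], d$timestamp[-n], units = "hours"))
      ok_gap <- abs(dt_h - fix_interval_h) <= tol_min / 60
      # segment id increments whenever a gap breaks the 2-h cadence
      seg <- cumsum(c(1, !ok_gap[-length(ok_gap)] * 1))
      x1 <- d$x[-n]; y1 <- d$y[-n]; x2 <- d$x[-1]; y2 <- d$y[-1]
      l <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      bearing <- atan2(y2 - y1, x2 - x1)
      theta <- rep(NA_real_, n - 1)
      same_seg <- c(FALSE, seg[-1] == seg[-(n - 1)])
      theta[same_seg] <- wrap_angle(bearing[same_seg] - bearing[which(same_seg) - 1])
      hr <- as.numeric(format(d$timestamp[-n], "%H")) +
        as.numeric(format(d$timestamp[-n], "%M")) / 60
      keep_gap <- ok_gap
      tibble::tibble(seg_id = seg, step_idx = seq_len(n - 1), t = d$timestamp[-n],
                     x = x1, y = y1, x_end = x2, y_end = y2,
                     l = l, bearing = bearing, theta = theta,
                     hour = hr, keep = keep_gap)
    }) %>%
    dplyr::ungroup()
  if (nrow(out) == 0) return(out)
  out <- dplyr::filter(out, .data$keep) %>% dplyr::select(-"keep")
  out$c_hour <- cos_hour(out$hour)
  in_grid <- !is.na(cell_of(stack, out$x, out$y)[, 1]) &
    !is.na(cell_of(stack, out$x_end, out$y_end)[, 1])
  n_drop <- sum(!in_grid)
  if (n_drop > 0) {
    message(n_drop, " step(s) dropped: fix outside the covariate grid")
    out <- out[in_grid, , drop = FALSE]
  }
  if (nrow(out) == 0) return(dplyr::select(out, -"step_idx"))
  for (nm in tcov_layers) out[[nm]] <- extract_layer(stack, nm, out$x, out$y)
  # dropped steps or animal changes break segments: re-key and reset the turn
  # angle at every new segment start
  key <- paste(out$animal_id, out$seg_id)
  brk <- c(TRUE, diff(out$step_idx) != 1 | key[-1] != key[-length(key)])
  out$seg_id <- cumsum(brk)
  out$theta[brk] <- NA_real_
  dplyr::select(out, -"step_idx")
}

# Design matrix of transition covariates (c_hour first, then layers) and
# segment-start indicator, shared by likelihood and smoothing wrappers.
.hmm_X <- function(steps, tcov_layers) {
  X <- cbind(c_hour = steps$c_hour)
  for (nm in tcov_layers) {
    if (!nm %in% names(steps))
      stop("step series lacks transition covariate '", nm, "'", call. = FALSE)
    X <- cbind(X, steps[[nm]])
  }
  colnames(X) <- c("c_hour", tcov_layers)
  if (any(!is.finite(X))) stop("non-finite transition covariates", call. = FALSE)
  X
}

.seg_start <- function(steps) {
  as.integer(c(1L, diff(steps$seg_id) != 0))
}

#' Covariate-dependent transition probability matrix
#'
#' Row 1 is the slow state, row 2 the fast state;
#' `logit P(slow -> fast) = beta[1, ] %*% c(1, x)` and likewise for
#' fast -> slow.
#'
#' @param beta 2 x (1 + k) coefficient matrix.
#' @param x covariate vector of length k (order matching `beta` columns after
#'   the intercept).
#' @return 2 x 2 matrix with rows summing to one.
#' @export
transition_matrix <- function(beta, x) {
  if (length(x) != ncol(beta) - 1) stop("covariate length mismatch")
  if (any(!is.finite(x))) stop("non-finite covariates")
  eta <- as.numeric(beta %*% c(1, x))
  g_sf <- stats::plogis(eta[1]); g_fs <- stats::plogis(eta[2])
  matrix(c(1 - g_sf, g_fs, g_sf, 1 - g_fs), 2, 2,
         dimnames = list(c("slow", "fast"), c("slow", "fast")))
}

#' Stationary state distribution at given covariates
#'
#' Solves `pi %*% Gamma(x) = pi` for the two-state chain:
#' `pi_fast = g_sf / (g_sf + g_fs)`.
#'
#' @inheritParams transition_matrix
#' @return named numeric vector `c(slow = , fast = )`.
#' @export
stationary_probs <- function(beta, x) {
  G <- transition_matrix(beta, x)
  g_sf <- G[1, 2]; g_fs <- G[2, 1]
  if (g_sf + g_fs == 0) {
    warning("degenerate (absorbing) transition matrix; returning limit 0.5/0.5")
    return(c(slow = 0.5, fast = 0.5))
  }
  pf <- g_sf / (g_sf + g_fs)
  c(slow = 1 - pf, fast = pf)
}

#' Forward-algorithm log-likelihood
#'
#' Scaled forward recursion over the two states with per-step transition
#' matrices; gamma x von Mises emissions; a missing first turn angle
#' contributes its length density only; the initial distribution of each
#' segment is the stationary distribution at that segment's first covariates.
#' Step lengths are floored at `len_floor` metres (stationary GPS jitter).
#'
#' @param steps step series from [build_steps()].
#' @param params an [hmm_params()].
#' @param len_floor minimum step length in metres.
#' @return log-likelihood (scalar).
#' @export
forward_loglik <- function(steps, params, len_floor = 1) {
  stopifnot(inherits(params, "hmm_params"), nrow(steps) > 0)
  X <- .hmm_X(steps, params$tcov_layers)
  hmm_loglik_cpp(pmax(steps$l, len_floor), steps$theta, X, .seg_start(steps),
                 params$mu, params$sigma, params$kappa, params$mean_angle,
                 params$beta)
}

# working-scale packing: log mu (2), log sigma (2), log kappa (2),
# mean angle (2), beta rows (slow->fast then fast->slow)
.pack <- function(p) {
  c(log(p$mu), log(p$sigma), log(pmax(p$kappa, 1e-6)), p$mean_angle,
    as.numeric(t(p$beta)))
}

.unpack <- function(w, tcov_layers) {
  nb <- 2 + length(tcov_layers)
  beta <- matrix(w[8 + seq_len(2 * nb)], 2, nb, byrow = TRUE)
  list(mu = exp(w[1:2]), sigma = exp(w[3:4]), kappa = exp(w[5:6]),
       mean_angle = wrap_angle(w[7:8]), beta = beta)
}

.wnames <- function(tcov_layers) {
  cn <- c("(Intercept)", "c_hour", tcov_layers)
  c("log_mu_slow", "log_mu_fast", "log_sigma_slow", "log_sigma_fast",
    "log_kappa_slow", "log_kappa_fast", "mean_angle_slow", "mean_angle_fast",
    paste0("slow_to_fast:", cn), paste0("fast_to_slow:", cn))
}

#' Fit the two-state movement HMM
#'
#' Maximises the pooled forward log-likelihood across all segments by
#' quasi-Newton (BFGS) on the working scale (log means/sds/concentrations,
#' unconstrained transition coefficients), from a data-informed start plus
#' seeded random restarts, keeping the best optimum. States are relabelled
#' post-fit so the fast state has the larger mean step length. The covariance
#' is the inverse numerical Hessian on the working scale.
#'
#' @param steps pooled step series from [build_steps()] (one or many animals).
#' @param tcov_layers transition covariate layer names (beyond `c_hour`).
#' @param inits optional [hmm_params()] start.
#' @param n_restarts number of seeded random restarts around the start.
#' @param seed integer seed for the restarts.
#' @param len_floor minimum step length in metres.
#' @return object of class `hmm_fit`: `params` ([hmm_params()]), `loglik`,
#'   `aic`, `npar`, `vcov` (working scale), `se` (named), `convergence`,
#'   `vcov_ok`, `n_steps`.
#' @export
fit_hmm <- function(steps, tcov_layers = c("d_town", "trail_density"),
                    inits = NULL, n_restarts = 3, seed = 1, len_floor = 1) {
  stopifnot(nrow(steps) >= 3)
  X <- .hmm_X(steps, tcov_layers)
  l <- pmax(steps$l, len_floor)
  if (any(steps$l < len_floor))
    message(sum(steps$l < len_floor), " step length(s) floored at ", len_floor, " m")
  theta <- steps$theta
  ss <- .seg_start(steps)
  nb <- 2 + length(tcov_layers)

  negll <- function(w) {
    p <- .unpack(w, tcov_layers)
    -hmm_loglik_cpp(l, theta, X, ss, p$mu, p$sigma, p$kappa, p$mean_angle, p$beta)
  }

  if (is.null(inits)) {
    med <- stats::median(l)
    lo <- l[l <= med]; hi <- l[l > med]
    inits <- hmm_params(
      mu = sort(c(max(mean(lo), len_floor), max(mean(hi), 2 * mean(lo) + 1))),
      sigma = c(max(stats::sd(lo), 1), max(stats::sd(hi), 2)),
      kappa = c(0.5, 0.5), mean_angle = c(0, 0),
      beta = cbind(c(-1, -1), matrix(0, 2, nb - 1)),
      tcov_layers = tcov_layers)
  }
  w0 <- .pack(inits)

  starts <- list(w0)
  if (n_restarts > 1) {
    set.seed(seed)
    for (i in seq_len(n_restarts - 1))
      starts[[i + 1]] <- w0 + stats::rnorm(length(w0), 0, 0.4)
  }
  best <- NULL
  for (w in starts) {
    op <- tryCatch(
      stats::optim(w, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("HMM optimisation failed from every start")
  converged <- best$convergence == 0

  p <- .unpack(best$par, tcov_layers)
  # enforce mu_fast > mu_slow by relabelling (swap emissions and beta rows)
  if (p$mu[1] > p$mu[2]) {
    p$mu <- rev(p$mu); p$sigma <- rev(p$sigma); p$kappa <- rev(p$kappa)
    p$mean_angle <- rev(p$mean_angle); p$beta <- p$beta[2:1, , drop = FALSE]
    best$par <- .pack(c(p, list(tcov_layers = tcov_layers)))
  }
  params <- hmm_params(p$mu, p$sigma, p$kappa, p$mean_angle, p$beta, tcov_layers)

  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vcov <- NULL; vcov_ok <- FALSE
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc))) {
      vcov <- (vc + t(vc)) / 2
      vcov_ok <- all(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values > -1e-8)
    }
  }
  wn <- .wnames(tcov_layers)
  if (!is.null(vcov)) dimnames(vcov) <- list(wn, wn)
  se <- if (vcov_ok) stats::setNames(sqrt(pmax(diag(vcov), 0)), wn)
        else stats::setNames(rep(NA_real_, length(wn)), wn)

  npar <- length(best$par)
  ll <- -best$value
  structure(list(params = params, loglik = ll, npar = npar,
                 aic = -2 * ll + 2 * npar, vcov = vcov, se = se,
                 vcov_ok = vcov_ok, convergence = converged,
                 n_steps = nrow(steps), tcov_layers = tcov_layers),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> logLik =", round(x$loglik, 2), " AIC =", round(x$aic, 2),
      " (", x$npar, "parameters,", x$n_steps, "steps )\n")
  if (!x$convergence) cat("  WARNING: optimiser did not report convergence\n")
  if (!x$vcov_ok) cat("  NOTE: covariance unavailable (Hessian not PD)\n")
  print(x$params)
  invisible(x)
}

#' Smoothed state probabilities (p_Fast)
#'
#' Forward-backward smoothing: for every step, the posterior probability of
#' the fast state given the whole series.
#'
#' @param steps step series used in the fit.
#' @param fit an `hmm_fit` (or [hmm_params()]).
#' @param len_floor minimum step length in metres.
#' @return the step tibble with columns `p_fast` and `p_slow` appended.
#' @export
smoothed_state_probs <- function(steps, fit, len_floor = 1) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  stopifnot(inherits(params, "hmm_params"))
  X <- .hmm_X(steps, params$tcov_layers)
  P <- hmm_posterior_cpp(pmax(steps$l, len_floor), steps$theta, X,
                         .seg_start(steps), params$mu, params$sigma,
                         params$kappa, params$mean_angle, params$beta)
  dplyr::mutate(steps, p_slow = P[, 1], p_fast = P[, 2])
}

#' Compare town-distance decay specifications by AIC
#'
#' Fits one HMM per candidate town-covariate transform (capped-linear
#' distance or exponential decay at a given range) and ranks them by AIC.
#' Non-converged candidates are excluded with a warning.
#'
#' @param tracks track tibble (one or many animals).
#' @param stack [covariate_stack()]; its `d_town` layer is replaced per
#'   candidate.
#' @param towns list of town polygons used to rebuild the distance layer.
#' @param specs list of `list(mode =, range_m =)` candidates; modes as in
#'   [town_distance_layer()].
#' @param ... passed to [fit_hmm()].
#' @return list with `table` (tibble: mode, range_m, loglik, aic, delta_aic,
#'   converged), `best_index`, and `best_fit`.
#' @export
decay_model_selection <- function(tracks, stack, towns, specs, ...) {
  stopifnot(length(specs) >= 1)
  fits <- vector("list", length(specs))
  rows <- purrr::imap_dfr(specs, function(sp, i) {
    st2 <- stack
    st2$layers$d_town <- town_distance_layer(towns, stack, mode = sp$mode,
                                             range_m = sp$range_m)
    steps <- build_steps(tracks, st2)
    f <- fit_hmm(steps, ...)
    fits[[as.integer(i)]] <<- f
    tibble::tibble(mode = sp$mode, range_m = sp$range_m,
                   loglik = f$loglik, aic = f$aic, converged = f$convergence)
  })
  if (any(!rows$converged)) {
    warning(sum(!rows$converged), " candidate(s) excluded: no convergence")
  }
  ok <- which(rows$converged)
  if (length(ok) == 0) stop("no decay candidate converged")
  rows$delta_aic <- rows$aic - min(rows$aic[ok])
  best <- ok[which.min(rows$aic[ok])]
  list(table = rows, best_index = best, best_fit = fits[[best]])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the working-scale parameter estimates of an HMM fit
#' @param x an `hmm_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.hmm_fit <- function(x, ...) {
  wn <- .wnames(x$tcov_layers)
  est <- .pack(x$params)
  tibble::tibble(term = wn, estimate = est, std.error = unname(x$se[wn]))
}

#' One-row fit summary of an HMM fit
#' @param x an `hmm_fit`.
#' @param ... unused.
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, npar = x$npar,
                 n_steps = x$n_steps, converged = x$convergence)
}
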