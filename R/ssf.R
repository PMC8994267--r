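# Step selection: used/available strata (1 used + 20 available per observed
# step), state-interacted conditional logistic regression maximised by Newton
# iterations on the stratum-softmax likelihood, cluster-robust (sandwich)
# covariance over animals, QIC backward selection, relative selection
# strength, and habitat prediction maps.

#' Step-selection design specification
#'
#' Terms follow a fixed naming convention shared with the path simulator:
#' endpoint layers by name, squared terms as `<name>_sq`, on/off linear
#' features as `on_<class>`, movement terms `step_length_km` and `cos_ta`,
#' and interactions as `<term>:p_fast` / `<term>:c_hour`.
#'
#' @param endpoint endpoint covariate layer names.
#' @param quadratic subset of `endpoint` that also enter squared.
#' @param onoff linear-feature classes with on/off indicators
#'   (within `buffer_m` of the feature).
#' @param movement movement terms (step length in km, cosine of turn angle).
#' @param anthropogenic terms flagged as development covariates; their
#'   coefficients (and interactions) are zeroed under the reference scenario.
#' @param interact_p_fast,interact_c_hour terms interacted with the fast-state
#'   probability and the time-of-day covariate. Default: all anthropogenic and
#'   movement terms.
#' @param buffer_m on/off buffer distance in metres.
#' @return object of class `ssf_design`.
#' @export
ssf_design <- function(endpoint = c("habitat", "town_prox", "trail_density"),
                       quadratic = "trail_density",
                       onoff = c("trail", "road", "railway"),
                       movement = c("step_length_km", "cos_ta"),
                       anthropogenic = NULL,
                       interact_p_fast = NULL, interact_c_hour = NULL,
                       buffer_m = 30) {
  stopifnot(all(quadratic %in% endpoint))
  onoff_terms <- if (length(onoff)) paste0("on_", onoff) else character()
  sq_terms <- if (length(quadratic)) paste0(quadratic, "_sq") else character()
  if (is.null(anthropogenic))
    anthropogenic <- intersect(
      c("town_prox", "d_town", "trail_density", sq_terms, onoff_terms),
      c(endpoint, sq_terms, onoff_terms))
  if (is.null(interact_p_fast)) interact_p_fast <- c(anthropogenic, movement)
  if (is.null(interact_c_hour)) interact_c_hour <- c(anthropogenic, movement)
  main <- c(endpoint, sq_terms, onoff_terms, movement)
  bad <- setdiff(c(interact_p_fast, interact_c_hour, anthropogenic), main)
  if (length(bad))
    stop("interaction/anthropogenic terms not among main effects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(endpoint = endpoint, quadratic = quadratic, onoff = onoff,
                 movement = movement, anthropogenic = anthropogenic,
                 interact_p_fast = interact_p_fast,
                 interact_c_hour = interact_c_hour, buffer_m = buffer_m),
            class = "ssf_design")
}

ssf_term_names <- function(spec) {
  main <- c(spec$endpoint,
            if (length(spec$quadratic)) paste0(spec$quadratic, "_sq"),
            if (length(spec$onoff)) paste0("on_", spec$onoff),
            spec$movement)
  c(main, if (length(spec$interact_p_fast)) paste0(spec$interact_p_fast, ":p_fast"),
    if (length(spec$interact_c_hour)) paste0(spec$interact_c_hour, ":c_hour"))
}

#' Sample available steps for each observed step
#'
#' Draws `n_avail` (length, turn angle) pairs per observed step independently
#' with replacement from the pooled empirical marginals of the observed
#' steps, projecting endpoints from the step's start and the animal's prior
#' bearing. Available steps inherit the used step's `p_fast`, `c_hour`, and
#' hour (state and time belong to the decision moment, not the candidate).
#' Endpoints outside the grid are redrawn up to `max_redraw` times, after
#' which the stratum is dropped. Steps without a prior bearing (segment
#' starts) are skipped.
#'
#' @param steps step series with a `p_fast` column (see
#'   [smoothed_state_probs()]).
#' @param stack grid source (bounds check).
#' @param n_avail available steps per stratum.
#' @param seed integer seed.
#' @param max_redraw redraw attempts for out-of-grid endpoints.
#' @return tibble, 1 used + `n_avail` available rows per stratum: `stratum`,
#'   `animal_id`, `used`, `x`, `y`, `x_end`, `y_end`, `step_length_km`,
#'   `cos_ta`, `p_fast`, `c_hour`, `hour`. Attributes `n_skipped`
#'   (no prior bearing) and `n_dropped` (out-of-grid redraw exhausted).
#' @export
sample_available_steps <- function(steps, stack, n_avail = 20, seed = 1,
                                   max_redraw = 10) {
  stopifnot("p_fast" %in% names(steps), nrow(steps) > 0)
  set.seed(seed)
  pool_l <- steps$l
  pool_theta <- steps$theta[!is.na(steps$theta)]
  stopifnot(length(pool_l) > 0, length(pool_theta) > 0)

  # prior bearing: bearing of the previous step within the same segment
  prior_bearing <- c(NA_real_, steps$bearing[-nrow(steps)])
  prior_bearing[.seg_start(steps) == 1] <- NA_real_
  usable <- !is.na(prior_bearing)
  n_skipped <- sum(!usable)
  obs <- steps[usable, , drop = FALSE]
  pb <- prior_bearing[usable]
  n <- nrow(obs)
  if (n == 0) stop("no steps with a defined prior bearing", call. = FALSE)

  draw <- function(k) {
    list(l = sample(pool_l, k, replace = TRUE),
         th = sample(pool_theta, k, replace = TRUE))
  }
  L <- matrix(0, n, n_avail); TH <- matrix(0, n, n_avail)
  d <- draw(n * n_avail)
  L[] <- d$l; TH[] <- d$th
  ex <- obs$x + L * cos(pb + TH)
  ey <- obs$y + L * sin(pb + TH)
  bad <- is.na(cell_of(stack, ex, ey)[, 1])
  dim(bad) <- dim(ex)
  tries <- 0
  while (any(bad) && tries < max_redraw) {
    k <- sum(bad)
    d <- draw(k)
    L[bad] <- d$l; TH[bad] <- d$th
    ex[bad] <- obs$x[row(bad)[bad]] + d$l * cos(pb[row(bad)[bad]] + d$th)
    ey[bad] <- obs$y[row(bad)[bad]] + d$l * sin(pb[row(bad)[bad]] + d$th)
    bad <- is.na(cell_of(stack, ex, ey)[, 1])
    dim(bad) <- dim(ex)
    tries <- tries + 1
  }
  drop_stratum <- apply(bad, 1, any)
  n_dropped <- sum(drop_stratum)
  if (n_dropped > 0)
    message(n_dropped, " stratum/strata dropped: endpoints outside grid after ",
            max_redraw, " redraws")
  keep <- which(!drop_stratum)
  used <- tibble::tibble(
    stratum = seq_along(keep), animal_id = obs$animal_id[keep], used = 1L,
    x = obs$x[keep], y = obs$y[keep],
    x_end = obs$x_end[keep], y_end = obs$y_end[keep],
    step_length_km = obs$l[keep] / 1000, cos_ta = cos(obs$theta[keep]),
    p_fast = obs$p_fast[keep], c_hour = obs$c_hour[keep], hour = obs$hour[keep])
  avail <- tibble::tibble(
    stratum = rep(seq_along(keep), each = n_avail),
    animal_id = rep(obs$animal_id[keep], each = n_avail), used = 0L,
    x = rep(obs$x[keep], each = n_avail), y = rep(obs$y[keep], each = n_avail),
    x_end = as.numeric(t(ex[keep, , drop = FALSE])),
    y_end = as.numeric(t(ey[keep, , drop = FALSE])),
    step_length_km = as.numeric(t(L[keep, , drop = FALSE])) / 1000,
    cos_ta = cos(as.numeric(t(TH[keep, , drop = FALSE]))),
    p_fast = rep(obs$p_fast[keep], each = n_avail),
    c_hour = rep(obs$c_hour[keep], each = n_avail),
    hour = rep(obs$hour[keep], each = n_avail))
  out <- dplyr::arrange(dplyr::bind_rows(used, avail), .data$stratum,
                        dplyr::desc(.data$used))
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Assemble the SSF design matrix
#'
#' One row per candidate step: endpoint covariates extracted from the stack,
#' squared terms, on/off indicators (endpoint within `buffer_m` of the
#' feature class), movement terms, and the design's interactions with `p_fast`
#' and `c_hour`.
#'
#' @param strata output of [sample_available_steps()].
#' @param stack [covariate_stack()].
#' @param scene [vector_scene()] providing the linear features.
#' @param spec an [ssf_design()].
#' @return list of class `ssf_data`: `X` (matrix, one column per term),
#'   `stratum`, `cluster`, `used`, `terms`.
#' @export
assemble_design <- function(strata, stack, scene, spec) {
  missing <- setdiff(spec$endpoint, names(stack$layers))
  if (length(missing))
    stop("missing layers: ", paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(strata)
  cols <- list()
  for (nm in spec$endpoint)
    cols[[nm]] <- extract_layer(stack, nm, strata$x_end, strata$y_end)
  for (nm in spec$quadratic)
    cols[[paste0(nm, "_sq")]] <- cols[[nm]]^2
  for (cl in spec$onoff) {
    segs <- polylines_to_segments(scene$lines[[cl]])
    d <- dist_point_segments(strata$x_end, strata$y_end, segs)
    cols[[paste0("on_", cl)]] <- as.numeric(d <= spec$buffer_m)
  }
  cols$step_length_km <- strata$step_length_km
  cols$cos_ta <- strata$cos_ta
  X <- do.call(cbind, cols[c(spec$endpoint,
                             if (length(spec$quadratic)) paste0(spec$quadratic, "_sq"),
                             if (length(spec$onoff)) paste0("on_", spec$onoff),
                             spec$movement)])
  for (nm in spec$interact_p_fast) {
    X <- cbind(X, X[, nm] * strata$p_fast)
    colnames(X)[ncol(X)] <- paste0(nm, ":p_fast")
  }
  for (nm in spec$interact_c_hour) {
    X <- cbind(X, X[, nm] * strata$c_hour)
    colnames(X)[ncol(X)] <- paste0(nm, ":c_hour")
  }
  if (any(!is.finite(X)))
    stop("non-finite design values (endpoint outside grid?)", call. = FALSE)
  structure(list(X = X, stratum = strata$stratum,
                 cluster = as.character(strata$animal_id),
                 used = strata$used == 1L, terms = colnames(X)),
            class = "ssf_data")
}

# Conditional (stratum-softmax) log-likelihood, per-stratum scores (aligned
# with the used rows) and observed information at beta. Strata are re-keyed to
# integers so rowsum/tapply order numerically.
.clogit_parts <- function(X, stratum, used, beta) {
  g <- as.integer(factor(stratum, levels = unique(stratum)))
  eta <- as.numeric(X %*% beta)
  emax <- as.numeric(tapply(eta, g, max))          # ordered 1..S
  w <- exp(eta - emax[g])
  denom <- as.numeric(rowsum(w, g))                # ordered 1..S
  p <- w / denom[g]
  ll <- sum(eta[used]) - sum(log(denom) + emax)
  xb <- rowsum(X * p, g)                           # stratum-wise E[x], 1..S
  U <- X[used, , drop = FALSE] - xb[g[used], , drop = FALSE]
  A <- crossprod(X, X * p) - crossprod(xb)         # sum_s Var_s(x)
  list(ll = ll, U = U, A = A, p = p)
}

#' Fit the conditional logistic step selection function
#'
#' Maximises the stratum-conditional likelihood
#' `sum_s [eta_used - log sum_i exp(eta_i)]` (a softmax over the 21
#' candidates of each stratum) by Newton iterations to a gradient norm below
#' `tol`, then computes the cluster sandwich covariance over animals.
#' Columns constant within every stratum carry no information; their
#' coefficients are fixed at zero and flagged.
#'
#' @param data an `ssf_data` from [assemble_design()], or a tibble with the
#'   candidate rows plus `stratum`, `cluster`/`animal_id`, `used` columns (all
#'   remaining numeric columns become terms).
#' @param tol Newton convergence tolerance on the max absolute score.
#' @param max_iter Newton iteration cap.
#' @return object of class `ssf_fit`: `beta`, `vcov_model`, `vcov_robust`,
#'   `se_robust`, `loglik`, `qic`, `n_strata`, `n_clusters`, `converged`,
#'   `separation`, `aliased`, `terms`, plus per-stratum scores and cluster
#'   ids for downstream variance work.
#' @export
fit_conditional_logit <- function(data, tol = 1e-8, max_iter = 50) {
  if (!inherits(data, "ssf_data")) data <- as_ssf_data(data)
  X <- data$X; stratum <- data$stratum; used <- data$used
  stopifnot(sum(used) == length(unique(stratum)))
  # aliased columns: constant within every stratum
  rng <- apply(X, 2, function(col) {
    max(tapply(col, stratum, function(v) diff(range(v))))
  })
  aliased <- rng < 1e-12
  Xa <- X[, !aliased, drop = FALSE]
  p <- ncol(Xa)
  beta <- rep(0, p)
  converged <- FALSE; separation <- FALSE
  ll <- -Inf
  if (p > 0) {
    for (it in seq_len(max_iter)) {
      parts <- .clogit_parts(Xa, stratum, used, beta)
      sc <- colSums(parts$U)
      if (max(abs(sc)) < tol) { converged <- TRUE; ll <- parts$ll; break }
      step <- tryCatch(solve(parts$A, sc), error = function(e) NULL)
      if (is.null(step)) { separation <- TRUE; break }
      # dampen huge steps (separation guard)
      if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
      beta <- beta + step
      ll <- parts$ll
      if (max(abs(beta)) > 50) { separation <- TRUE; break }
    }
    parts <- .clogit_parts(Xa, stratum, used, beta)
    ll <- parts$ll
  } else {
    parts <- list(U = matrix(0, length(unique(stratum)), 0),
                  A = matrix(0, 0, 0))
    ll <- -sum(log(as.numeric(table(stratum))))
    converged <- TRUE
  }
  if (separation)
    warning("possible complete separation: coefficients diverging", call. = FALSE)

  full_beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  full_beta[!aliased] <- beta
  cluster_of_stratum <- data$cluster[used]
  vc_model <- matrix(NA_real_, ncol(X), ncol(X),
                     dimnames = list(colnames(X), colnames(X)))
  vc_rob <- vc_model
  if (p > 0 && !separation) {
    Ai <- tryCatch(solve(parts$A), error = function(e) NULL)
    if (!is.null(Ai)) {
      Uc <- rowsum(parts$U, cluster_of_stratum)
      M <- crossprod(Uc)
      vr <- Ai %*% M %*% Ai
      vc_model[!aliased, !aliased] <- Ai
      vc_rob[!aliased, !aliased] <- (vr + t(vr)) / 2
    }
  }
  n_clusters <- length(unique(data$cluster))
  if (n_clusters < 2)
    warning("single cluster: robust covariance undefined", call. = FALSE)
  fit <- structure(list(
    beta = full_beta, vcov_model = vc_model, vcov_robust = vc_rob,
    se_robust = sqrt(pmax(diag(vc_rob), 0)), loglik = ll,
    n_strata = length(unique(stratum)), n_clusters = n_clusters,
    converged = converged, separation = separation, aliased = aliased,
    terms = colnames(X), scores = parts$U,
    cluster_of_stratum = cluster_of_stratum,
    info = parts$A, info_terms = colnames(X)[!aliased]),
    class = "ssf_fit")
  fit$qic <- qic(fit)
  fit
}

# Coerce a candidate-level tibble to the ssf_data structure.
as_ssf_data <- function(df) {
  stopifnot(all(c("stratum", "used") %in% names(df)))
  cl <- if ("cluster" %in% names(df)) df$cluster else df$animal_id
  drop <- intersect(c("stratum", "used", "cluster", "animal_id"), names(df))
  X <- as.matrix(df[setdiff(names(df), drop)])
  structure(list(X = X, stratum = df$stratum, cluster = as.character(cl),
                 used = df$used == 1, terms = colnames(X)),
            class = "ssf_data")
}

#' Cluster-robust sandwich covariance of an SSF fit
#'
#' `A^{-1} M A^{-1}` with `A` the observed information of the independence
#' (conditional-logit) model and `M` the outer-product sum of cluster score
#' totals.
#'
#' @param fit an `ssf_fit`.
#' @param clusters optional replacement cluster assignment, one per stratum.
#' @return covariance matrix over all terms (zero-information terms `NA`).
#' @export
robust_cluster_vcov <- function(fit, clusters = NULL) {
  cl <- if (is.null(clusters)) fit$cluster_of_stratum else as.character(clusters)
  stopifnot(length(cl) == nrow(fit$scores))
  if (length(unique(cl)) < 2) {
    warning("single cluster: robust covariance undefined", call. = FALSE)
    return(matrix(NA_real_, length(fit$beta), length(fit$beta),
                  dimnames = list(fit$terms, fit$terms)))
  }
  Ai <- solve(fit$info)
  Uc <- rowsum(fit$scores, cl)
  vr <- Ai %*% crossprod(Uc) %*% Ai
  out <- matrix(NA_real_, length(fit$beta), length(fit$beta),
                dimnames = list(fit$terms, fit$terms))
  out[fit$info_terms, fit$info_terms] <- (vr + t(vr)) / 2
  out
}

#' Quasi-likelihood information criterion
#'
#' `QIC = -2 Q + 2 trace(A V_robust)` with `Q` the independence-model
#' conditional log-likelihood, `A` its observed information and `V_robust`
#' the cluster sandwich covariance.
#'
#' @param fit an `ssf_fit`.
#' @return scalar QIC.
#' @export
qic <- function(fit) {
  vr <- fit$vcov_robust[fit$info_terms, fit$info_terms, drop = FALSE]
  if (length(vr) == 0) return(-2 * fit$loglik)
  if (any(!is.finite(vr))) return(NA_real_)
  -2 * fit$loglik + 2 * sum(diag(fit$info %*% vr))
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat("<ssf_fit> ", x$n_strata, " strata, ", x$n_clusters, " clusters; QIC = ",
      round(x$qic, 2), "\n", sep = "")
  if (x$separation) cat("  WARNING: possible separation\n")
  print(tidy(x), n = length(x$beta))
  invisible(x)
}

#' @rdname tidy.hmm_fit
#' @export
tidy.ssf_fit <- function(x, ...) {
  tibble::tibble(term = x$terms, estimate = unname(x$beta),
                 std.error = unname(x$se_robust),
                 statistic = unname(x$beta / x$se_robust),
                 p.value = 2 * stats::pnorm(-abs(unname(x$beta / x$se_robust))))
}

#' @rdname glance.hmm_fit
#' @export
glance.ssf_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, QIC = x$qic, n_strata = x$n_strata,
                 n_clusters = x$n_clusters, converged = x$converged)
}

# Terms protected from removal while a dependent term remains: a main effect
# with a live interaction, a linear term with a live quadratic.
.protected_terms <- function(terms) {
  base <- sub(":(p_fast|c_hour)$", "", terms)
  prot <- unique(base[base != terms])             # interaction parents
  sq <- terms[grepl("_sq$", terms)]
  prot <- union(prot, sub("_sq$", "", sq))        # quadratic parents
  intersect(prot, terms)
}

#' QIC backward stepwise selection
#'
#' Iteratively removes the single term whose removal lowers QIC the most,
#' honouring hierarchy (no main effect leaves while its interaction or
#' quadratic remains), stopping when no removal lowers QIC. A candidate whose
#' refit fails is retained.
#'
#' @param data an `ssf_data` (full model).
#' @param ... passed to [fit_conditional_logit()].
#' @return list: `fit` (final `ssf_fit`), `terms` (retained), `trace`
#'   (tibble: step, removed term, QIC).
#' @export
qic_backward_selection <- function(data, ...) {
  if (!inherits(data, "ssf_data")) data <- as_ssf_data(data)
  cur <- data
  fit <- fit_conditional_logit(cur, ...)
  trace <- tibble::tibble(step = 0L, removed = NA_character_, qic = fit$qic)
  step <- 0L
  repeat {
    cand <- setdiff(cur$terms, .protected_terms(cur$terms))
    if (length(cand) == 0 || length(cur$terms) == 1) break
    qics <- vapply(cand, function(tm) {
      sub <- cur
      keep <- cur$terms != tm
      sub$X <- cur$X[, keep, drop = FALSE]; sub$terms <- cur$terms[keep]
      f <- tryCatch(fit_conditional_logit(sub, ...), error = function(e) NULL)
      if (is.null(f) || !is.finite(f$qic)) Inf else f$qic
    }, 0)
    if (min(qics) >= fit$qic) break
    drop_tm <- cand[which.min(qics)]
    keep <- cur$terms != drop_tm
    cur$X <- cur$X[, keep, drop = FALSE]; cur$terms <- cur$terms[keep]
    fit <- fit_conditional_logit(cur, ...)
    step <- step + 1L
    trace <- dplyr::bind_rows(trace,
      tibble::tibble(step = step, removed = drop_tm, qic = fit$qic))
  }
  list(fit = fit, terms = cur$terms, trace = trace)
}

#' Relative selection strength between two covariate profiles
#'
#' `RSS = exp(beta' (x1 - x0))`, with a delta-method CI on the robust
#' covariance.
#'
#' @param fit an `ssf_fit`.
#' @param x1,x0 named numeric vectors (missing terms treated as equal in both
#'   profiles).
#' @param level confidence level.
#' @return tibble with `rss`, `conf.low`, `conf.high`, `log_rss`, `se_log`.
#' @export
relative_selection_strength <- function(fit, x1, x0, level = 0.95) {
  d <- stats::setNames(rep(0, length(fit$terms)), fit$terms)
  d[names(x1)] <- d[names(x1)] + x1
  d[names(x0)] <- d[names(x0)] - x0
  lr <- sum(fit$beta * d)
  ok <- fit$terms[!is.na(diag(fit$vcov_robust))]
  se <- sqrt(as.numeric(t(d[ok]) %*% fit$vcov_robust[ok, ok] %*% d[ok]))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(rss = exp(lr), conf.low = exp(lr - z * se),
                 conf.high = exp(lr + z * se), log_rss = lr, se_log = se)
}

#' Predict a habitat-selection map
#'
#' Per-cell linear predictor using endpoint covariates only (movement terms
#' excluded), with `p_fast` and `c_hour` held at supplied values, normalised
#' as a probability surface over available cells (softmax without movement
#' kernel). The top-third mask marks the highest-eta third of available
#' cells; ties break by row-major cell index.
#'
#' @param fit an `ssf_fit` (or named coefficient vector).
#' @param stack [covariate_stack()].
#' @param scene [vector_scene()] for the on/off features.
#' @param spec the [ssf_design()] used to fit.
#' @param p_fast,c_hour held-constant values of the state and time covariates.
#' @param scenario optional [scenario_spec()]; its layer/mask overrides are
#'   applied and, if `zero_anthropogenic`, anthropogenic terms are zeroed.
#' @return list of class `habitat_map`: `eta` (matrix), `prob` (normalised,
#'   `NA` off-mask), `top_third` (logical matrix), `mask`.
#' @export
predict_habitat_map <- function(fit, stack, scene, spec, p_fast = 0,
                                c_hour = 0, scenario = NULL) {
  beta <- if (inherits(fit, "ssf_fit")) fit$beta else fit
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_spec"))
    extra <- setdiff(names(scenario$overrides), c(names(stack$layers), "mask"))
    if (length(extra))
      stop("scenario overrides unknown layers: ", paste(extra, collapse = ", "),
           call. = FALSE)
    for (nm in setdiff(names(scenario$overrides), "mask"))
      stack$layers[[nm]] <- scenario$overrides[[nm]]
    if ("mask" %in% names(scenario$overrides))
      stack$mask <- scenario$overrides$mask
    if (scenario$zero_anthropogenic) {
      zap <- c(spec$anthropogenic,
               paste0(spec$anthropogenic, ":p_fast"),
               paste0(spec$anthropogenic, ":c_hour"))
      beta[names(beta) %in% zap] <- 0
    }
  }
  cc <- cell_centers(stack)
  vals <- list()
  for (nm in spec$endpoint) vals[[nm]] <- extract_layer(stack, nm, cc$x, cc$y)
  for (nm in spec$quadratic) vals[[paste0(nm, "_sq")]] <- vals[[nm]]^2
  for (cl in spec$onoff) {
    segs <- polylines_to_segments(scene$lines[[cl]])
    vals[[paste0("on_", cl)]] <-
      as.numeric(dist_point_segments(cc$x, cc$y, segs) <= spec$buffer_m)
  }
  eta <- rep(0, nrow(cc))
  for (nm in names(vals)) {
    b <- 0
    if (nm %in% names(beta)) b <- b + beta[[nm]]
    ipf <- paste0(nm, ":p_fast"); ich <- paste0(nm, ":c_hour")
    if (ipf %in% names(beta)) b <- b + beta[[ipf]] * p_fast
    if (ich %in% names(beta)) b <- b + beta[[ich]] * c_hour
    eta <- eta + b * vals[[nm]]
  }
  eta_m <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  eta_m[cbind(cc$row, cc$col)] <- eta
  avail <- stack$mask
  w <- exp(eta_m - max(eta_m[avail]))
  w[!avail] <- NA
  prob <- w / sum(w[avail])
  # top third of available cells by eta, ties by row-major cell index
  idx <- which(avail[cbind(cc$row, cc$col)])
  cell_index <- (cc$row - 1) * stack$n_cols + cc$col
  ord <- idx[order(-eta[idx], cell_index[idx])]
  k <- round(length(idx) / 3)
  top <- matrix(FALSE, stack$n_rows, stack$n_cols)
  top[cbind(cc$row[ord[seq_len(k)]], cc$col[ord[seq_len(k)]])] <- TRUE
  structure(list(eta = eta_m, prob = prob, top_third = top, mask = avail,
                 p_fast = p_fast, c_hour = c_hour,
                 origin = stack$origin, cell_size = stack$cell_size),
            class = "habitat_map")
}

#' Simulate choice strata from a known selection coefficient vector
#'
#' Ground-truth generator for the conditional-logit machinery: each stratum
#' has `n_avail + 1` candidates with standard-normal covariates (plus optional
#' cluster-level random coefficient noise), and the used candidate is drawn
#' from the softmax under `beta`.
#'
#' @param n_strata number of strata.
#' @param beta named true coefficient vector.
#' @param n_avail available candidates per stratum.
#' @param n_clusters number of animals (strata split evenly).
#' @param cluster_sd sd of cluster-level random coefficient deviations.
#' @param seed integer seed.
#' @return tibble with `stratum`, `cluster`, `used`, and one column per term.
#' @export
simulate_choice_strata <- function(n_strata, beta, n_avail = 20,
                                   n_clusters = 20, cluster_sd = 0, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  m <- n_avail + 1
  cl <- rep_len(seq_len(n_clusters), n_strata)
  rows <- n_strata * m
  X <- matrix(stats::rnorm(rows * p), rows, p,
              dimnames = list(NULL, names(beta)))
  stratum <- rep(seq_len(n_strata), each = m)
  bmat <- matrix(rep(beta, n_clusters), n_clusters, p, byrow = TRUE)
  if (cluster_sd > 0)
    bmat <- bmat + matrix(stats::rnorm(n_clusters * p, 0, cluster_sd), n_clusters, p)
  eta <- rowSums(X * bmat[rep(cl, each = m), , drop = FALSE])
  used <- integer(rows)
  for (s in seq_len(n_strata)) {
    i0 <- (s - 1) * m
    e <- eta[i0 + seq_len(m)]
    pr <- exp(e - max(e)); pr <- pr / sum(pr)
    used[i0 + sample.int(m, 1, prob = pr)] <- 1L
  }
  out <- tibble::as_tibble(as.data.frame(X))
  dplyr::bind_cols(tibble::tibble(stratum = stratum,
                                  cluster = paste0("a", cl[stratum]),
                                  used = used), out)
}
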