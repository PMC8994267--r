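test_that("step construction gets lengths, turn angles, and the hour covariate right", {
  st <- flat_stack(50, 50)
  ts <- as.POSIXct("2022-07-01 00:00:00", tz = "UTC") + seq(0, by = 7200, length.out = 5)
  # east, east, north, then reverse: turns 0, +pi/2, pi
  track <- tibble::tibble(animal_id = "a", timestamp = ts,
                          x = c(1000, 1500, 2000, 2000, 2000),
                          y = c(1000, 1000, 1000, 1500, 1000))
  s <- build_steps(track, st)
  expect_equal(nrow(s), 4)
  expect_equal(s$l, c(500, 500, 500, 500))
  expect_equal(s$theta, c(NA, 0, pi / 2, pi))
  expect_equal(s$hour, c(0, 2, 4, 6))
  # day = -1, night = +1
  expect_equal(cos_hour(12), -1)
  expect_equal(cos_hour(0), 1)
  expect_equal(s$c_hour[1], 1)
})

test_that("gaps in the fix schedule break the series into segments", {
  st <- flat_stack(50, 50)
  ts <- as.POSIXct("2022-07-01 00:00:00", tz = "UTC") +
    c(0, 7200, 14400, 14400 + 6 * 3600, 14400 + 6 * 3600 + 7200, 14400 + 6 * 3600 + 14400)
  track <- tibble::tibble(animal_id = "a", timestamp = ts,
                          x = 1000 + 200 * (0:5), y = rep(1000, 6))
  s <- build_steps(track, st)
  # the 6-h gap step is dropped; two segments remain
  expect_equal(nrow(s), 4)
  expect_equal(length(unique(s$seg_id)), 2)
  # first step of each segment has no turn angle
  expect_equal(sum(is.na(s$theta)), 2)
})

test_that("transition matrix and stationary distribution match logistic closed forms", {
  b0 <- matrix(0, 2, 4)
  G <- transition_matrix(b0, c(0, 0, 0))
  expect_equal(unname(G), matrix(0.5, 2, 2))
  b <- matrix(c(-2, 0, 0, 0, -2, 0, 0, 0), 2, 4, byrow = TRUE)
  G2 <- transition_matrix(b, c(0, 0, 0))
  expect_equal(G2[1, 2], plogis(-2), tolerance = 1e-12)
  expect_equal(G2[1, 2], 0.11920, tolerance = 1e-4)
  expect_equal(rowSums(G2), c(slow = 1, fast = 1))
  # a -0.98 town-distance coefficient raises the slow->fast logit by 0.98
  # when distance drops by one unit
  bt <- matrix(c(-1, 0, -0.98, 0, -1, 0, 0, 0), 2, 4, byrow = TRUE)
  l1 <- qlogis(transition_matrix(bt, c(0, 1, 0))[1, 2])
  l0 <- qlogis(transition_matrix(bt, c(0, 0, 0))[1, 2])
  expect_equal(l0 - l1, 0.98, tolerance = 1e-10)
  expect_error(transition_matrix(b0, c(0, NA, 0)), "non-finite")

  expect_equal(unname(stationary_probs(b0, c(0, 0, 0))), c(0.5, 0.5))
  # g_sf = 0.2, g_fs = 0.1 -> pi_fast = 2/3
  b3 <- matrix(c(qlogis(0.2), 0, 0, 0, qlogis(0.1), 0, 0, 0), 2, 4, byrow = TRUE)
  expect_equal(stationary_probs(b3, c(0, 0, 0))[["fast"]], 2 / 3, tolerance = 1e-12)
  # pi solves pi G = pi for random coefficients
  set.seed(5)
  for (i in 1:20) {
    bb <- matrix(rnorm(8), 2, 4)
    x <- rnorm(3)
    p <- stationary_probs(bb, x)
    G <- transition_matrix(bb, x)
    expect_lt(max(abs(p %*% G - p)), 1e-12)
  }
})

test_that("forward likelihood equals exhaustive state-sequence enumeration", {
  params <- test_params()
  for (seed in 1:10) {
    T <- sample(2:8, 1)
    s <- random_steps(T, seed)
    expect_equal(forward_loglik(s, params), bf_forward_loglik(s, params),
                 tolerance = 1e-10)
  }
})

test_that("likelihood limit cases: single step, flat turn angles, label symmetry", {
  params <- test_params()
  # T = 1 with symmetric transitions: log(0.5 f_slow + 0.5 f_fast)
  p1 <- hmm_params(params$mu, params$sigma, params$kappa, params$mean_angle,
                   matrix(0, 2, 4))
  s1 <- random_steps(1, 3)
  f <- dgamma_musd(max(s1$l, 1), p1$mu, p1$sigma)
  expect_equal(forward_loglik(s1, p1), log(0.5 * f[1] + 0.5 * f[2]),
               tolerance = 1e-12)
  # kappa = 0 in both states: angles contribute log(1/2pi) each
  s <- random_steps(6, 4)
  pk <- hmm_params(params$mu, params$sigma, c(0, 0), c(0, 0), params$beta)
  pk_len_only <- pk
  s_noang <- s; s_noang$theta <- NA_real_
  expect_equal(forward_loglik(s, pk),
               forward_loglik(s_noang, pk_len_only) + 5 * log(1 / (2 * pi)),
               tolerance = 1e-10)
  # swapping state labels leaves the likelihood unchanged
  swapped <- hmm_params(params$mu, params$sigma, params$kappa,
                        params$mean_angle, params$beta)
  swapped$mu <- rev(params$mu); swapped$sigma <- rev(params$sigma)
  swapped$kappa <- rev(params$kappa); swapped$mean_angle <- rev(params$mean_angle)
  swapped$beta <- params$beta[2:1, ]
  expect_equal(forward_loglik(s, params), forward_loglik(s, swapped),
               tolerance = 1e-12)
  # track ordering does not matter (segments are independent blocks)
  s2 <- random_steps(6, 5); s2$animal_id <- "b"; s2$seg_id <- 2L
  both <- dplyr::bind_rows(s, s2)
  both_rev <- dplyr::bind_rows(s2, s)
  expect_equal(forward_loglik(both, params), forward_loglik(both_rev, params),
               tolerance = 1e-12)
  expect_equal(forward_loglik(both, params),
               forward_loglik(s, params) + forward_loglik(s2, params),
               tolerance = 1e-12)
})

test_that("smoothed probabilities sum to one and track well-separated states", {
  land <- open_land()
  # near-disjoint length supports
  hp <- hmm_params(mu = c(20, 2000), sigma = c(5, 200), kappa = c(1, 1),
                   beta = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0), 2, 4, byrow = TRUE))
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  tr <- generate_labelled_tracks(land$stack, land$scene, hp, c(habitat = 0),
                                 n_animals = 2, n_steps = 300,
                                 starts = tibble::tibble(x = rep(W / 2, 2),
                                                         y = rep(H / 2, 2),
                                                         hour = 0),
                                 seed = 12)
  steps <- build_steps(tr, land$stack)
  sp <- smoothed_state_probs(steps, hp)
  expect_true(all(abs(sp$p_slow + sp$p_fast - 1) < 1e-12))
  # true state of step t is the state at the landing fix
  truth <- tr %>% dplyr::group_by(animal_id) %>%
    dplyr::mutate(s_next = dplyr::lead(state)) %>%
    dplyr::slice(-dplyr::n()) %>% dplyr::ungroup()
  expect_gt(mean((sp$p_fast > 0.5) == (truth$s_next == 1)), 0.99)
  # uninformative emissions: p_fast equals the stationary probability
  hp_flat <- hmm_params(mu = c(100, 101), sigma = c(50, 50), kappa = c(0, 0),
                        beta = matrix(c(qlogis(0.3), 0, 0, 0,
                                        qlogis(0.2), 0, 0, 0), 2, 4, byrow = TRUE))
  s_flat <- steps
  s_flat$l <- rep(100.5, nrow(steps))   # identical emissions in both states
  s_flat$theta[!is.na(s_flat$theta)] <- 0
  sp2 <- smoothed_state_probs(s_flat, hp_flat)
  pi_f <- 0.3 / (0.3 + 0.2)
  expect_true(all(abs(sp2$p_fast - pi_f) < 0.02))
})

test_that("fitting recovers parameters and the AIC bookkeeping holds", {
  land <- open_land()
  hp <- default_true_hmm()
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  tr <- generate_labelled_tracks(land$stack, land$scene, hp, c(habitat = 0),
                                 n_animals = 8, n_steps = 400,
                                 starts = tibble::tibble(x = rep(W / 2, 8),
                                                         y = rep(H / 2, 8),
                                                         hour = 0),
                                 seed = 31)
  steps <- suppressMessages(build_steps(tr, land$stack))
  fit <- suppressMessages(fit_hmm(steps, n_restarts = 1, seed = 2))
  expect_true(fit$convergence)
  expect_lt(max(abs(fit$params$mu - hp$mu) / hp$mu), 0.15)
  expect_lt(max(abs(fit$params$sigma - hp$sigma) / hp$sigma), 0.15)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_equal(fit$npar, 16)
  # transition coefficient signs recovered
  expect_true(all(sign(fit$params$beta[, -1]) == sign(hp$beta[, -1])))
  # identifiability ordering enforced
  expect_gt(fit$params$mu[2], fit$params$mu[1])
  # tidy/glance expose the fit
  td <- tidy(fit)
  expect_equal(nrow(td), 16)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(glance(fit)$AIC, fit$aic)
})

test_that("decay-spec comparison ranks by AIC and is stable for duplicates", {
  land <- open_land()
  hp <- default_true_hmm()
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  tr <- generate_labelled_tracks(land$stack, land$scene, hp, c(habitat = 0),
                                 n_animals = 6, n_steps = 300,
                                 starts = tibble::tibble(x = rep(W / 2, 6),
                                                         y = rep(H / 2, 6),
                                                         hour = 0),
                                 seed = 33)
  specs <- list(list(mode = "capped_linear", range_m = 5000),
                list(mode = "capped_linear", range_m = 5000),
                list(mode = "exp_decay", range_m = 500))
  sel <- suppressMessages(
    decay_model_selection(tr, land$stack, land$scene$towns, specs,
                          n_restarts = 1, seed = 2))
  expect_equal(nrow(sel$table), 3)
  expect_equal(min(sel$table$delta_aic), 0)
  # identical duplicate specs give identical AIC
  expect_equal(sel$table$aic[1], sel$table$aic[2], tolerance = 1e-6)
  # the generating transform (capped linear, 5 km) wins
  expect_equal(sel$table$mode[sel$best_index], "capped_linear")
  # a single candidate trivially has delta AIC 0
  one <- suppressMessages(
    decay_model_selection(tr, land$stack, land$scene$towns, specs[1],
                          n_restarts = 1, seed = 2))
  expect_equal(one$table$delta_aic, 0)
})
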