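# bundle on the small landscape, default truth
.bundle <- function(land = small_land(), beta = default_true_ssf(),
                    hmm = default_true_hmm(), scenario = "current",
                    config = sim_config(n_paths = 5, seed = 99)) {
  scenario_bundle(land$stack, land$scene, beta, hmm, ssf_design(),
                  scenario = scenario, config = config)
}

test_that("reference scenarios zero every anthropogenic coefficient, idempotently", {
  spec <- ssf_design()
  beta <- default_true_ssf()
  hmm <- default_true_hmm()
  ref <- scenario_coefficients(beta, hmm, "reference", spec)
  anth <- c(spec$anthropogenic, paste0(spec$anthropogenic, ":p_fast"),
            paste0(spec$anthropogenic, ":c_hour"))
  expect_true(all(ref$ssf_beta[names(ref$ssf_beta) %in% anth] == 0))
  expect_true(all(ref$hmm$beta[, c("d_town", "trail_density")] == 0))
  # non-anthropogenic terms survive
  expect_equal(ref$ssf_beta[["habitat"]], beta[["habitat"]])
  expect_equal(ref$hmm$beta[, "c_hour"], hmm$beta[, "c_hour"])
  # current: identity
  cur <- scenario_coefficients(beta, hmm, "current", spec)
  expect_identical(cur$ssf_beta, beta)
  expect_identical(cur$hmm$beta, hmm$beta)
  # idempotent
  ref2 <- scenario_coefficients(ref$ssf_beta, ref$hmm, "reference", spec)
  expect_identical(ref2$ssf_beta, ref$ssf_beta)
  expect_error(scenario_coefficients(beta, hmm, "urban", spec))
})

test_that("start seeding stays in the mask, is reproducible, and is uniform", {
  land <- small_land()
  map <- predict_habitat_map(default_true_ssf(), land$stack, land$scene,
                             ssf_design(), p_fast = 0.5)
  s1 <- seed_start_points(map, 500, seed = 4)
  s2 <- seed_start_points(map, 500, seed = 4)
  expect_identical(s1, s2)
  rc <- cell_of(land$stack, s1$x, s1$y)
  expect_true(all(map$top_third[cbind(rc[, 1], rc[, 2])]))
  expect_true(all(s1$hour %in% seq(0, 22, 2)))
  # uniformity over top-third cells (chi-square on a coarse partition)
  s3 <- seed_start_points(map, 20000, seed = 5)
  rc3 <- cell_of(land$stack, s3$x, s3$y)
  cellid <- (rc3[, 1] - 1) * land$stack$n_cols + rc3[, 2]
  topid <- which(t(map$top_third))
  expect_true(all(cellid %in% topid))
  counts <- table(factor(cellid, levels = topid))
  grp <- rep_len(1:20, length(topid))           # pool cells into 20 groups
  pooled <- tapply(as.numeric(counts), grp, sum)
  p <- stats::chisq.test(pooled)$p.value
  expect_gt(p, 0.01)
  # empty mask errors
  map$top_third[] <- FALSE
  expect_error(seed_start_points(map, 5, seed = 1), "empty top-third")
})

test_that("candidate proposal follows the transition row and scores 20 candidates", {
  land <- open_land()
  b <- .bundle(land)
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  set.seed(6)
  cand <- propose_candidates(b, W / 2, H / 2, hour = 0, state = 0, bearing = 0)
  expect_equal(nrow(cand), 20)
  # empirical switch fraction matches the transition probability
  rc <- cell_of(land$stack, W / 2, H / 2)
  x <- c(cos_hour(0),
         land$stack$layers$d_town[rc[1], rc[2]],
         land$stack$layers$trail_density[rc[1], rc[2]])
  p_sf <- transition_matrix(default_true_hmm()$beta, x)[1, 2]
  set.seed(7)
  big <- propose_candidates(b, W / 2, H / 2, hour = 0, state = 0, bearing = 0,
                            n = 20000)
  se <- sqrt(p_sf * (1 - p_sf) / 20000)
  expect_lt(abs(mean(big$state) - p_sf), 3 * se)
  # per-state lengths come from the right gamma law
  hp <- default_true_hmm()
  m_slow <- mean(big$length[big$state == 0])
  expect_lt(abs(m_slow - hp$mu[1]) / hp$mu[1], 0.05)
})

test_that("step rejection checks the four along-step locations", {
  st <- flat_stack(10, 10)
  expect_true(reject_step(st, 200, 200, 800, 800))
  # block only the midpoint cell: fraction 0.5 hits it
  st2 <- st
  mid <- cell_of(st, 500, 500)
  st2$mask[mid[1, 1], mid[1, 2]] <- FALSE
  expect_false(reject_step(st2, 200, 200, 800, 800))
  # endpoint in unavailable habitat
  st3 <- st
  endc <- cell_of(st, 800, 800)
  st3$mask[endc[1, 1], endc[1, 2]] <- FALSE
  expect_false(reject_step(st3, 200, 200, 800, 800))
  # endpoint outside the grid
  expect_false(reject_step(st, 200, 200, 5000, 200))
  # origin cell unavailability alone does not reject (origin is known used)
  st4 <- st
  orig <- cell_of(st, 200, 200)
  st4$mask[orig[1, 1], orig[1, 2]] <- FALSE
  expect_true(reject_step(st4, 200, 200, 800, 800))
})

test_that("softmax selection is shift-invariant and matches its law", {
  set.seed(8)
  # single survivor always chosen
  expect_equal(select_step(2.5), 1)
  # uniform eta: empirical frequencies match 1/20 within 3 MC SE
  draws <- replicate(20000, select_step(rep(0, 20)))
  freq <- as.numeric(table(factor(draws, levels = 1:20))) / 20000
  se <- sqrt(0.05 * 0.95 / 20000)
  expect_true(all(abs(freq - 0.05) < 4 * se))
  # shifting eta by a constant yields the same selection under the same seed
  set.seed(9); a <- replicate(200, select_step(c(0.2, 1, -1)))
  set.seed(9); b <- replicate(200, select_step(c(5.2, 6, 4)))
  expect_identical(a, b)
  expect_error(select_step(numeric(0)), "no surviving")
})

test_that("paths are deterministic, complete on open terrain, and honour barriers", {
  land <- open_land()
  b <- .bundle(land)
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  start <- list(x = W / 2, y = H / 2, hour = 0)
  p1 <- simulate_path(b, start, n_steps = 720, seed = 11)
  p2 <- simulate_path(b, start, n_steps = 720, seed = 11)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "reason"), "completed")
  expect_equal(nrow(p1), 721)
  expect_true(all(p1$hour == (p1$step * 2) %% 24))

  # closed basin: an available square surrounded by unavailable cells
  land2 <- small_land()
  st <- land2$stack
  st$mask[] <- FALSE
  st$mask[20:40, 40:70] <- TRUE
  basin <- scenario_bundle(st, land2$scene, default_true_ssf(),
                           default_true_hmm(), ssf_design(),
                           config = sim_config(n_paths = 1, seed = 1))
  bx <- st$origin[1] + c(39, 70) * st$cell_size   # x range of basin cols 40:70
  by <- st$origin[2] + c(19, 40) * st$cell_size
  ps <- simulate_path(basin, list(x = mean(bx), y = mean(by), hour = 0),
                      n_steps = 300, seed = 12)
  rc <- cell_of(st, ps$x, ps$y)
  expect_true(all(st$mask[cbind(rc[, 1], rc[, 2])]))

  # post-hoc audit: every accepted step's four checkpoints are available
  for (i in 2:nrow(ps)) {
    if (ps$x[i] == ps$x[i - 1] && ps$y[i] == ps$y[i - 1]) next  # held position
    expect_true(reject_step(st, ps$x[i - 1], ps$y[i - 1], ps$x[i], ps$y[i]))
  }
})

test_that("per-state step lengths and turns from free simulation match their laws", {
  # grid large enough that 250-step excursions never feel the boundary
  land <- generate_landscape(list(n_rows = 200, n_cols = 200), seed = 51)
  land$stack$mask[] <- TRUE
  hp <- default_true_hmm()
  b <- scenario_bundle(land$stack, land$scene, c(habitat = 0), hp, ssf_design(),
                       config = sim_config(n_paths = 1, seed = 2))
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  paths <- lapply(1:40, function(i)
    simulate_path(b, list(x = W / 2, y = H / 2, hour = 0), n_steps = 250,
                  seed = 400 + i))
  d <- dplyr::bind_rows(lapply(paths, function(p) {
    dx <- diff(p$x); dy <- diff(p$y)
    br <- atan2(dy, dx)
    tibble::tibble(l = sqrt(dx^2 + dy^2), s = p$state[-1],
                   turn = c(NA, movescape:::wrap_angle(diff(br))))
  }))
  d <- d[d$l > 0, ]
  pvm <- function(q, k) vapply(q, function(qi)
    stats::integrate(dvm_r, -pi, qi, m = 0, k = k)$value, 0)
  for (s in 0:1) {
    ls <- d$l[d$s == s]
    ks <- stats::ks.test(ls, function(q)
      pgamma(q, shape = (hp$mu[s + 1] / hp$sigma[s + 1])^2,
             scale = hp$sigma[s + 1]^2 / hp$mu[s + 1]))
    expect_gt(ks$p.value, 0.01)
    turns <- d$turn[d$s == s & !is.na(d$turn)]
    kst <- stats::ks.test(turns, function(q) pvm(q, hp$kappa[s + 1]))
    expect_gt(kst$p.value, 0.01)
  }
})

test_that("ensembles are reproducible and scenario-consistent under zeroed effects", {
  land <- small_land()
  cfg <- sim_config(n_paths = 30, seed = 123)
  cfg$steps_per_path <- 150L
  b1 <- .bundle(land, config = cfg)
  e1 <- simulate_ensemble(b1)
  e2 <- simulate_ensemble(.bundle(land, config = cfg))
  expect_identical(e1$steps, e2$steps)
  expect_s3_class(e1, "path_ensemble")
  expect_equal(nrow(e1$terminations), 30)

  # anthropogenic beta = 0 + reference mask: "current" ensemble identical to
  # the reference ensemble under a shared master seed
  beta0 <- default_true_ssf()
  anth <- c("town_prox", "trail_density", "trail_density_sq")
  beta0[names(beta0) %in% c(anth, paste0(anth, ":p_fast"))] <- 0
  hmm0 <- default_true_hmm()
  hmm0$beta[, c("d_town", "trail_density")] <- 0
  ref_mask <- land$stack$mask | rasterize_polygons(land$scene$towns, land$stack)
  cur <- scenario_bundle(land$stack, land$scene, beta0, hmm0, ssf_design(),
                         scenario = scenario_spec("current",
                                                  overrides = list(mask = ref_mask),
                                                  zero_anthropogenic = FALSE),
                         config = cfg)
  ref <- scenario_bundle(land$stack, land$scene, default_true_ssf(),
                         default_true_hmm(), ssf_design(),
                         scenario = scenario_spec("reference",
                                                  overrides = list(mask = ref_mask)),
                         config = cfg)
  ec <- simulate_ensemble(cur)
  er <- simulate_ensemble(ref)
  expect_identical(ec$steps, er$steps)
})

test_that("stronger town avoidance lowers occupancy near town", {
  land <- small_land()
  cfg <- sim_config(n_paths = 40, seed = 7)
  cfg$steps_per_path <- 200L
  beta_weak <- default_true_ssf(); beta_weak["town_prox"] <- 0
  beta_strong <- default_true_ssf(); beta_strong["town_prox"] <- -8
  occupancy <- function(beta) {
    e <- simulate_ensemble(.bundle(land, beta = beta, config = cfg))
    near <- extract_layer(land$stack, "d_town", e$steps$x, e$steps$y) < 1
    mean(near, na.rm = TRUE)
  }
  expect_gt(occupancy(beta_weak), occupancy(beta_strong))
})
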