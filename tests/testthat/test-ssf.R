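# helper: steps with smoothed p_fast on the small open landscape
.ssf_steps <- function(n_animals = 4, n_steps = 250, seed = 14) {
  land <- open_land()
  hp <- default_true_hmm()
  W <- land$stack$n_cols * land$stack$cell_size
  H <- land$stack$n_rows * land$stack$cell_size
  tr <- generate_labelled_tracks(land$stack, land$scene, hp, c(habitat = 0),
                                 n_animals = n_animals, n_steps = n_steps,
                                 starts = tibble::tibble(x = rep(W / 2, n_animals),
                                                         y = rep(H / 2, n_animals),
                                                         hour = 0),
                                 seed = seed)
  steps <- suppressMessages(build_steps(tr, land$stack))
  smoothed_state_probs(steps, hp)
}

test_that("strata have 1 used + 20 available sharing the decision context", {
  land <- open_land()
  steps <- .ssf_steps()
  strata <- suppressMessages(sample_available_steps(steps, land$stack, seed = 3))
  counts <- table(strata$stratum)
  expect_true(all(counts == 21))
  expect_true(all(tapply(strata$used, strata$stratum, sum) == 1))
  # p_fast and c_hour constant within stratum
  expect_true(all(tapply(strata$p_fast, strata$stratum,
                         function(v) diff(range(v))) == 0))
  expect_true(all(tapply(strata$c_hour, strata$stratum,
                         function(v) diff(range(v))) == 0))
  # available lengths are resamples of observed lengths
  avail_l <- strata$step_length_km[strata$used == 0] * 1000
  nearest <- vapply(avail_l[1:200], function(v) min(abs(steps$l - v)), 0)
  expect_true(all(nearest < 1e-9))
  # deterministic given the seed
  strata2 <- suppressMessages(sample_available_steps(steps, land$stack, seed = 3))
  expect_identical(strata, strata2)
  # first steps of segments are skipped
  expect_equal(attr(strata, "n_skipped"), sum(is.na(steps$theta)))
})

test_that("the design matrix applies the 30 m on/off buffer and interactions", {
  st <- flat_stack(50, 50)
  trail <- rbind(c(0, 3000), c(6000, 3000))
  scene <- vector_scene(lines = list(trail = list(trail), road = list(),
                                     railway = list()))
  spec <- ssf_design(endpoint = c("habitat", "trail_density"),
                     quadratic = "trail_density", onoff = "trail")
  strata <- tibble::tibble(
    stratum = c(1, 1, 1), animal_id = "a", used = c(1L, 0L, 0L),
    x = 1000, y = 1000,
    x_end = c(1000, 2000, 3000), y_end = c(3025, 3035, 2970),
    step_length_km = c(0.5, 1, 2), cos_ta = c(1, 0, -1),
    p_fast = 0.25, c_hour = -1, hour = 12)
  d <- assemble_design(strata, st, scene, spec)
  expect_equal(unname(d$X[, "on_trail"]), c(1, 0, 1))   # 25 m in, 35 m out, 30 m in
  expect_equal(d$X[, "trail_density_sq"], d$X[, "trail_density"]^2)
  expect_equal(d$X[, "trail_density:p_fast"], d$X[, "trail_density"] * 0.25)
  expect_equal(d$X[, "trail_density:c_hour"], d$X[, "trail_density"] * -1)
  expect_equal(d$X[, "step_length_km:p_fast"], d$X[, "step_length_km"] * 0.25)
  # p_fast = 0 zeroes every p_fast interaction column
  strata0 <- dplyr::mutate(strata, p_fast = 0)
  d0 <- assemble_design(strata0, st, scene, spec)
  expect_true(all(d0$X[, grepl(":p_fast", colnames(d0$X))] == 0))
  # missing layers are named in the error
  spec_bad <- ssf_design(endpoint = c("habitat", "snow"), quadratic = character(),
                         onoff = character())
  expect_error(assemble_design(strata, st, scene, spec_bad), "snow")
})

test_that("conditional logit matches survival::clogit and its own softmax oracle", {
  beta_true <- c(x1 = 0.8, x2 = -0.5, x3 = 0.3)
  df <- simulate_choice_strata(300, beta_true, n_avail = 10, seed = 5)
  fit <- fit_conditional_logit(df)
  expect_true(fit$converged)
  # independent softmax log-likelihood at beta-hat
  eta <- as.matrix(df[names(beta_true)]) %*% fit$beta
  ll <- sum(tapply(seq_len(nrow(df)), df$stratum, function(i)
    eta[i][df$used[i] == 1] - log(sum(exp(eta[i])))))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
  # survival::clogit as the independent fitting oracle
  sv <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), used) ~ x1 + x2 + x3 +
      survival::strata(stratum),
    data = df, method = "breslow")
  expect_equal(unname(fit$beta), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(diag(fit$vcov_model)), unname(diag(vcov(sv))),
               tolerance = 1e-5)
})

test_that("conditional logit recovers a known coefficient within robust error", {
  beta_true <- c(x1 = 1.0)
  df <- simulate_choice_strata(2000, beta_true, n_avail = 20, seed = 6)
  fit <- fit_conditional_logit(df)
  expect_lt(abs(fit$beta["x1"] - 1.0), 2 * fit$se_robust["x1"])
  # likelihood is invariant to within-stratum candidate order
  perm <- df[order(df$stratum, stats::runif(nrow(df))), ]
  fit2 <- fit_conditional_logit(perm)
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-8)
  # a stratum-constant covariate is aliased to zero and others are unchanged
  df3 <- dplyr::mutate(df, const = as.numeric(stratum %% 7))
  fit3 <- fit_conditional_logit(df3)
  expect_equal(unname(fit3$beta["const"]), 0)
  expect_true(fit3$aliased["const"])
  expect_equal(unname(fit3$beta["x1"]), unname(fit$beta["x1"]), tolerance = 1e-10)
})

test_that("cluster sandwich variance behaves under permutation and independence", {
  beta_true <- c(x1 = 0.6, x2 = -0.4)
  df <- simulate_choice_strata(2000, beta_true, n_avail = 10,
                               n_clusters = 2000, seed = 7)
  fit <- fit_conditional_logit(df)
  # with one independent stratum per cluster the sandwich is close to the
  # model covariance
  ratio <- fit$se_robust / sqrt(diag(fit$vcov_model))
  expect_true(all(ratio > 0.8 & ratio < 1.2))
  # consistent relabelling of clusters leaves the covariance unchanged
  cl <- fit$cluster_of_stratum
  relab <- paste0("z", as.integer(factor(cl)))
  expect_equal(robust_cluster_vcov(fit, relab), fit$vcov_robust,
               tolerance = 1e-12)
  # a single cluster is flagged
  expect_warning(v1 <- robust_cluster_vcov(fit, rep("one", length(cl))),
                 "single cluster")
  expect_true(all(is.na(v1)))
})

test_that("QIC backward selection honours hierarchy and drops noise terms", {
  # hierarchy: quadratic and interactions protect their parents
  expect_identical(
    sort(movescape:::.protected_terms(c("a", "a_sq", "b", "b:p_fast", "c"))),
    c("a", "b"))
  set.seed(8)
  dropped <- 0L
  for (r in 1:6) {
    df <- simulate_choice_strata(400, c(x1 = 1.0, x2 = -0.8), n_avail = 10,
                                 seed = 100 + r)
    df$noise <- rnorm(nrow(df))
    sel <- qic_backward_selection(as_ssf_data(df))
    if (!"noise" %in% sel$terms) dropped <- dropped + 1L
    expect_true(all(c("x1", "x2") %in% sel$terms))
    expect_true(all(diff(sel$trace$qic) < 0))   # each removal lowered QIC
  }
  expect_gte(dropped, 4)
})

test_that("QIC never proposes a protected linear term while its square is present", {
  df <- simulate_choice_strata(300, c(x1 = 0.5), n_avail = 10, seed = 9)
  df$x1_sq <- df$x1^2
  sel <- qic_backward_selection(as_ssf_data(df))
  expect_false("x1_sq" %in% sel$terms && !"x1" %in% sel$terms)
})

test_that("relative selection strength follows the closed form", {
  df <- simulate_choice_strata(300, c(x1 = 1), n_avail = 10, seed = 10)
  fit <- fit_conditional_logit(df)
  same <- relative_selection_strength(fit, c(x1 = 2), c(x1 = 2))
  expect_equal(same$rss, 1)
  # a single coefficient of -8.99 gives exp(-8.99) per unit difference
  fit2 <- fit
  fit2$beta["x1"] <- -8.99
  r <- relative_selection_strength(fit2, c(x1 = 1), c(x1 = 0))
  expect_equal(r$rss, exp(-8.99))
  expect_equal(r$rss, 1.24e-4, tolerance = 1e-2)
  # reciprocity
  a <- relative_selection_strength(fit, c(x1 = 1.7), c(x1 = 0.2))
  b <- relative_selection_strength(fit, c(x1 = 0.2), c(x1 = 1.7))
  expect_equal(a$rss * b$rss, 1, tolerance = 1e-12)
})

test_that("habitat maps normalise, cover a third, and respond monotonically", {
  land <- small_land()
  spec <- ssf_design()
  # beta = 0: uniform map over available cells, top third by tie-break
  map0 <- predict_habitat_map(c(habitat = 0), land$stack, land$scene, spec)
  n_avail <- sum(land$stack$mask)
  expect_equal(sum(map0$prob[land$stack$mask]), 1, tolerance = 1e-12)
  expect_true(all(is.na(map0$prob[!land$stack$mask])))
  expect_equal(sum(map0$top_third), round(n_avail / 3))
  u <- unique(map0$prob[land$stack$mask])
  expect_equal(length(u), 1)
  # adding a constant to eta leaves the normalised map unchanged
  beta <- default_true_ssf()
  m1 <- predict_habitat_map(beta, land$stack, land$scene, spec, p_fast = 0.3,
                            c_hour = -1)
  stack2 <- land$stack
  stack2$layers$ones <- matrix(1, stack2$n_rows, stack2$n_cols)
  spec2 <- ssf_design(endpoint = c(spec$endpoint, "ones"))
  m2 <- predict_habitat_map(c(beta, ones = 5), stack2, land$scene, spec2,
                            p_fast = 0.3, c_hour = -1)
  expect_equal(m2$prob, m1$prob, tolerance = 1e-10)
  # raising a favoured covariate in one cell raises its normalised value
  stack3 <- land$stack
  rc <- which(land$stack$mask, arr.ind = TRUE)[50, ]
  stack3$layers$habitat[rc[1], rc[2]] <- stack3$layers$habitat[rc[1], rc[2]] + 0.5
  m3 <- predict_habitat_map(beta, stack3, land$scene, spec, p_fast = 0.3,
                            c_hour = -1)
  expect_gt(m3$prob[rc[1], rc[2]], m1$prob[rc[1], rc[2]])
  # the reference scenario zeroes anthropogenic terms: town proximity stops
  # depressing the map
  ref <- scenario_spec("reference")
  mref <- predict_habitat_map(beta, land$stack, land$scene, spec, p_fast = 0,
                              c_hour = 0, scenario = ref)
  town_cells <- land$stack$layers$town_prox > 0.5 & land$stack$mask
  if (any(town_cells)) {
    mcur <- predict_habitat_map(beta, land$stack, land$scene, spec, p_fast = 0,
                                c_hour = 0)
    expect_gt(mean(mref$prob[town_cells]), mean(mcur$prob[town_cells]))
  }
})
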