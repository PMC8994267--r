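# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (enumeration, closed forms, base-R densities) and
# never call the code paths they check.

# --- small landscapes (built once per test run) ------------------------------

.fixture_env <- new.env(parent = emptyenv())

small_land <- function() {
  if (is.null(.fixture_env$land))
    .fixture_env$land <- generate_landscape(list(n_rows = 80, n_cols = 120),
                                            seed = 42)
  .fixture_env$land
}

# same landscape with every cell available (towns are covariates only)
open_land <- function() {
  if (is.null(.fixture_env$open)) {
    land <- small_land()
    land$stack$mask[] <- TRUE
    .fixture_env$open <- land
  }
  .fixture_env$open
}

# bare stack with constant layers, useful for geometric unit tests
flat_stack <- function(nr = 10, nc = 10, cs = 120, mask = NULL) {
  covariate_stack(origin = c(0, 0), cell_size = cs, n_rows = nr, n_cols = nc,
                  layers = list(habitat = matrix(0.5, nr, nc),
                                d_town = matrix(1, nr, nc),
                                trail_density = matrix(0, nr, nc)),
                  mask = mask)
}

# --- independent densities ----------------------------------------------------

dvm_r <- function(x, m, k) exp(k * cos(x - m)) / (2 * pi * besselI(k, 0))

dgamma_musd <- function(x, mu, sd)
  dgamma(x, shape = (mu / sd)^2, scale = sd^2 / mu)

# --- brute-force forward likelihood by state-sequence enumeration -------------

bf_forward_loglik <- function(steps, params, len_floor = 1) {
  l <- pmax(steps$l, len_floor)
  theta <- steps$theta
  X <- cbind(steps$c_hour,
             as.matrix(steps[params$tcov_layers]))
  T <- length(l)
  dens <- function(t, s) {
    d <- dgamma_musd(l[t], params$mu[s], params$sigma[s])
    if (!is.na(theta[t]))
      d <- d * dvm_r(theta[t], params$mean_angle[s], params$kappa[s])
    d
  }
  gam <- function(t) {
    eta <- params$beta %*% c(1, X[t, ])
    g_sf <- plogis(eta[1]); g_fs <- plogis(eta[2])
    matrix(c(1 - g_sf, g_fs, g_sf, 1 - g_fs), 2, 2)
  }
  # initial distribution: stationary at the first step's covariates
  G1 <- gam(1)
  pf <- G1[1, 2] / (G1[1, 2] + G1[2, 1])
  delta <- c(1 - pf, pf)
  seqs <- as.matrix(expand.grid(rep(list(1:2), T)))
  tot <- 0
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    p <- delta[s[1]] * dens(1, s[1])
    if (T > 1) for (t in 2:T) p <- p * gam(t)[s[t - 1], s[t]] * dens(t, s[t])
    tot <- tot + p
  }
  log(tot)
}

# random single-segment step series with covariates, for likelihood tests
random_steps <- function(T, seed) {
  set.seed(seed)
  tibble::tibble(
    animal_id = "a", seg_id = 1L,
    l = rgamma(T, 2, 0.01),
    theta = c(NA, runif(T - 1, -pi, pi)),
    hour = sample(seq(0, 22, 2), T, replace = TRUE),
    c_hour = NA_real_,
    d_town = runif(T), trail_density = runif(T, 0, 3)) %>%
    dplyr::mutate(c_hour = cos_hour(hour))
}

test_params <- function() {
  hmm_params(mu = c(80, 600), sigma = c(70, 450), kappa = c(0.4, 1.5),
             mean_angle = c(0.1, -0.05),
             beta = matrix(c(-0.8, 0.9, -1.1, 0.6,
                             -1.2, -0.7, 0.8, -0.4), 2, 4, byrow = TRUE))
}

# --- simple rectangular helpers ----------------------------------------------

rect <- function(x1, y1, x2, y2)
  rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2))

# fake ensemble from a list of coordinate matrices (one per path)
fake_ensemble <- function(paths, scenario = "current") {
  steps <- purrr::imap_dfr(paths, function(m, i) {
    tibble::tibble(path_id = as.integer(i), step = seq_len(nrow(m)) - 1L,
                   x = m[, 1], y = m[, 2], hour = 0,
                   state = rep_len(c(0, 1), nrow(m)))
  })
  structure(list(steps = steps, scenario = scenario, seed = 0,
                 terminations = tibble::tibble(
                   path_id = unique(steps$path_id), reason = "completed"),
                 config = NULL),
            class = "path_ensemble")
}
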