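# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Long tibble of a matrix on a stack-like geometry.
.grid_tbl <- function(m, origin, cell_size) {
  g <- expand.grid(col = seq_len(ncol(m)), row = seq_len(nrow(m)))
  tibble::tibble(x = origin[1] + (g$col - 0.5) * cell_size,
                 y = origin[2] + (g$row - 0.5) * cell_size,
                 value = m[cbind(g$row, g$col)])
}

#' Plot one layer of a covariate stack
#'
#' @param stack a [covariate_stack()].
#' @param layer layer name (or `"mask"`).
#' @param scene optional [vector_scene()] overlaid (towns, linear features).
#' @return a ggplot.
#' @export
plot_layer <- function(stack, layer, scene = NULL) {
  m <- if (identical(layer, "mask")) stack$mask * 1 else stack$layers[[layer]]
  if (is.null(m)) stop("no layer named '", layer, "'", call. = FALSE)
  d <- .grid_tbl(m, stack$origin, stack$cell_size)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = layer) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
  if (!is.null(scene)) {
    for (tp in scene$towns) {
      td <- tibble::tibble(x = c(tp[, 1], tp[1, 1]), y = c(tp[, 2], tp[1, 2]))
      p <- p + ggplot2::geom_path(data = td, ggplot2::aes(.data$x, .data$y),
                                  inherit.aes = FALSE, colour = "red")
    }
    for (cl in c("trail", "road", "railway"))
      for (l in scene$lines[[cl]]) {
        ld <- tibble::tibble(x = l[, 1], y = l[, 2])
        p <- p + ggplot2::geom_path(data = ld, ggplot2::aes(.data$x, .data$y),
                                    inherit.aes = FALSE, colour = "grey30",
                                    linewidth = 0.3)
      }
  }
  p
}

#' @rdname plot_layer
#' @param object,x result object.
#' @param ... unused.
#' @export
autoplot.utilization_distribution <- function(object, ...) {
  d <- .grid_tbl(log10(object$ud + 1e-12), object$origin, object$cell_size)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 use") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Utilization distribution (", object$state,
                                 ", ", object$scenario, ")"),
                  x = "easting (m)", y = "northing (m)")
}

#' @rdname plot_layer
#' @export
autoplot.habitat_map <- function(object, ...) {
  d <- .grid_tbl(object$eta, object$origin, object$cell_size)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "selection eta") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' @rdname plot_layer
#' @param n_paths number of paths displayed.
#' @export
autoplot.path_ensemble <- function(object, n_paths = 50, ...) {
  ids <- utils::head(unique(object$steps$path_id), n_paths)
  d <- object$steps[object$steps$path_id %in% ids, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, group = .data$path_id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Simulated paths:", object$scenario),
                  x = "easting (m)", y = "northing (m)")
}

#' Stationary state probabilities across a covariate sweep
#'
#' Sweeps one transition covariate over `range` holding the others at
#' `at`, and plots the stationary probability of each state, mirroring how
#' fitted movement models are usually displayed.
#'
#' @param fit an `hmm_fit` or [hmm_params()].
#' @param covariate covariate name (one of `c_hour` plus the transition
#'   layers).
#' @param range length-2 numeric sweep range.
#' @param at named list of values for the held covariates (default 0).
#' @return a ggplot.
#' @export
plot_stationary <- function(fit, covariate = "d_town", range = c(0, 1),
                            at = list()) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  covs <- c("c_hour", params$tcov_layers)
  stopifnot(covariate %in% covs)
  base <- stats::setNames(rep(0, length(covs)), covs)
  for (nm in names(at)) base[nm] <- at[[nm]]
  xs <- seq(range[1], range[2], length.out = 100)
  d <- purrr::map_dfr(xs, function(v) {
    x <- base; x[covariate] <- v
    p <- stationary_probs(params$beta, unname(x))
    tibble::tibble(value = v, state = c("slow", "fast"), prob = unname(p))
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$prob,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = covariate, y = "stationary probability") +
    ggplot2::ylim(0, 1)
}
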