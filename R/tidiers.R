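#' Tidy methods for flyAL result objects
#'
#' `tidy()` returns a long tibble of the object's primary quantities;
#' `glance()` returns a one-row summary.
#'
#' @param x a flyAL result object.
#' @param ... unused.
#' @return A tibble.
#' @name flyal-tidiers
NULL

#' @rdname flyal-tidiers
#' @export
tidy.al_response <- function(x, ...) {
  dplyr::bind_rows(
    response_to_tibble(x$pn) |> dplyr::mutate(cell_class = "uPN"),
    response_to_tibble(x$orn) |> dplyr::mutate(cell_class = "ORN"))
}

#' @rdname flyal-tidiers
#' @export
glance.al_response <- function(x, ...) {
  tibble::tibble(
    n_glomeruli = nrow(x$pn), n_odors = ncol(x$pn),
    mean_pn_rate = mean(x$pn, na.rm = TRUE),
    mean_orn_rate = mean(x$orn, na.rm = TRUE),
    mean_orn_baseline =
      mean(x$baseline_rates[x$roster$cell_class == "ORN"]))
}

#' @rdname flyal-tidiers
#' @export
tidy.al_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading") |>
    dplyr::mutate(glomerulus = sub(":.*$", "", .data$feature))
}

#' @rdname flyal-tidiers
#' @export
glance.al_pca <- function(x, ...) {
  tibble::tibble(n_obs = nrow(x$scores), n_features = nrow(x$loadings),
                 pc1_variance = x$variance_fraction[1],
                 pc2_variance = x$variance_fraction[2])
}

#' @rdname flyal-tidiers
#' @export
tidy.volume_synapse_model <- function(x, ...) {
  tibble::tibble(term = c("a", "d", "sigma"),
                 estimate = c(x$a, x$d, x$sigma))
}

#' @rdname flyal-tidiers
#' @export
glance.volume_synapse_model <- function(x, ...) {
  tibble::tibble(a = x$a, d = x$d, sigma = x$sigma, n = x$n)
}

#' @rdname flyal-tidiers
#' @export
tidy.latent_inference <- function(x, ...) {
  tibble::tibble(r_latent = x$grid, r2_latent = x$grid^2,
                 posterior = x$posterior)
}

#' @rdname flyal-tidiers
#' @export
glance.latent_inference <- function(x, ...) {
  tibble::tibble(median_r2_latent = x$median, ci90_low = x$ci90[1],
                 ci90_high = x$ci90[2], n_individuals = x$N,
                 n_sims = x$n_sims)
}

#' @rdname flyal-tidiers
#' @export
tidy.repeatability_estimate <- function(x, ...) {
  tibble::tibble(source = x$source, sample = x$samples)
}

#' @rdname flyal-tidiers
#' @export
glance.repeatability_estimate <- function(x, ...) {
  tibble::tibble(source = x$source, r2 = x$r2,
                 n_signal_pcs = x$n_signal_pcs,
                 n_boot = length(x$samples))
}

#' Plot methods for flyAL result objects
#'
#' `autoplot.al_response()` draws the glomerulus-by-odor PN rate heatmap;
#' `autoplot.al_pca()` the loading heatmap of the leading components
#' (glomerulus-blocked, the view in which glomerular organization is
#' visible); `autoplot.latent_inference()` the posterior over the latent
#' squared correlation; `autoplot.al_simulation()` a spike raster.
#'
#' @param object a flyAL result object.
#' @param n_pcs number of components to show.
#' @param max_neurons cap on raster rows.
#' @param ... unused.
#' @return A ggplot object.
#' @name flyal-autoplot
NULL

#' @rdname flyal-autoplot
#' @export
autoplot.al_response <- function(object, ...) {
  response_to_tibble(object$pn) |>
    ggplot2::ggplot(ggplot2::aes(.data$odor, .data$glomerulus,
                                 fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "PN rate (Hz)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname flyal-autoplot
#' @export
autoplot.al_pca <- function(object, n_pcs = 5, ...) {
  tidy(object) |>
    dplyr::filter(.data$component %in% paste0("PC", seq_len(n_pcs))) |>
    ggplot2::ggplot(ggplot2::aes(.data$feature, .data$component,
                                 fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  mid = "white") +
    ggplot2::labs(x = "glomerulus:odor feature", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       size = 5))
}

#' @rdname flyal-autoplot
#' @export
autoplot.latent_inference <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$r2_latent, .data$posterior)) +
    ggplot2::geom_col(width = 0.01, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$median, color = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$ci90, linetype = "dashed") +
    ggplot2::labs(x = expression(R^2 ~ "latent"), y = "posterior weight") +
    ggplot2::theme_minimal()
}

#' @rdname flyal-autoplot
#' @export
autoplot.al_simulation <- function(object, max_neurons = 100, ...) {
  ids <- names(object$spikes)
  if (length(ids) > max_neurons) ids <- ids[seq_len(max_neurons)]
  df <- tibble::tibble(
    neuron = rep(ids, lengths(object$spikes[ids])),
    time_ms = unlist(object$spikes[ids], use.names = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms,
                                   factor(.data$neuron, levels = ids))) +
    ggplot2::geom_point(shape = "|", size = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Heatmap-style plot of a validation report
#'
#' @param report a `validation_report` from [validate_al_model()].
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(.data$value, .data$criterion,
                               color = .data$pass)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#1b7837",
                                           `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "score", y = NULL) +
    ggplot2::theme_minimal()
}
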