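#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.frc_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.frc_curve <- function(x, ...) {
  res <- suppressWarnings(resolution_from_frc(x))
  tibble::tibble(crossing_freq_invA = res$crossing_freq_invA,
                 resolution_A = res$resolution_A,
                 n_rings = nrow(x))
}

#' Plot an FRC curve against its half-bit threshold
#'
#' @param object an `frc_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.frc_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ring_freq_invA)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$correlation, colour = "FRC")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold, colour = "half-bit threshold"),
                       linetype = "dashed") +
    ggplot2::labs(x = expression("spatial frequency (" * ring(A)^-1 * ")"),
                  y = "correlation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.radial_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.radial_profile <- function(x, ...) {
  pk <- attr(x, "peaks")
  tibble::tibble(n_points = nrow(x), r_max_invA = max(x$r_invA),
                 n_peaks = if (is.null(pk)) NA_integer_ else nrow(pk))
}

#' Plot a radial intensity profile (log scale), with ring markers if present
#'
#' @param object a `radial_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.radial_profile <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r_invA, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression("radius (" * ring(A)^-1 * ")"), y = "intensity") +
    ggplot2::theme_minimal()
  pk <- attr(object, "peaks")
  if (!is.null(pk)) {
    p <- p + ggplot2::geom_vline(data = pk,
                                 ggplot2::aes(xintercept = .data$r_invA),
                                 linetype = "dotted", colour = "grey50")
  }
  p
}

#' @exportS3Method generics::tidy
tidy.distortion_model <- function(x, ...) {
  tibble::tibble(term = c("M", "k"), estimate = c(x$M, x$k),
                 units = c("dimensionless", "A^2"))
}

#' @exportS3Method generics::glance
glance.distortion_model <- function(x, ...) {
  tibble::tibble(M = x$M, k = x$k,
                 fit_residual = attr(x, "fit_residual") %||% NA_real_,
                 linearity_r2 = attr(x, "linearity_r2") %||% NA_real_)
}

#' @export
print.distortion_model <- function(x, ...) {
  cat(sprintf("<distortion_model> s = M r (1 + k r^2) with M = %.5f, k = %.5g A^2\n",
              x$M, x$k))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aberration_set <- function(x, ...) {
  tibble::tibble(
    term = c("defocus", "Cs", "astigmatism", "astig_azimuth"),
    estimate = c(x$defocus_nm, x$cs_mm, x$astig_nm, x$astig_azimuth_rad),
    units = c("nm", "mm", "nm", "rad")
  )
}

#' @exportS3Method generics::glance
glance.reconstruction_state <- function(x, ...) {
  eh <- x$error_history
  tibble::tibble(
    iterations = length(eh),
    final_error = if (length(eh)) eh[length(eh)] else NA_real_,
    n_slices = length(x$object$slices),
    n_probe_modes = length(x$probe$modes),
    pixel_size_pm = x$pixel_size_pm
  )
}

#' @exportS3Method generics::tidy
tidy.reconstruction_state <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$error_history),
                 fourier_error = x$error_history)
}

#' Plot the error history of a reconstruction
#'
#' @param object a `reconstruction_state`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reconstruction_state <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fourier_error)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "Fourier amplitude error") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
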