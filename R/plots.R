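# ggplot2 methods for the result types.

#' Plot a positional property profile
#'
#' Line plot of the positional mean with a +/- SEM ribbon; position 1 is
#' the cytosolic edge of the hydrophobic core.
#'
#' @param object A `tmd_profile` from [positional_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position (1 = cytosolic core edge)", y = "mean property") +
    ggplot2::theme_minimal()
}

#' Plot a residue-frequency matrix
#'
#' Heat-map analogue of the positional abundance matrices: residues by
#' aligned position, shaded by frequency.
#'
#' @param object A `tmd_freq` from [frequency_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmd_freq <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position,
                               y = factor(.data$residue, levels = rev(AA_ALPHABET)),
                               fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "frequency") +
    ggplot2::labs(x = "position (1 = cytosolic core edge)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a hydrophobic-length distribution
#'
#' @param object A `tmd_lengths` from [length_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmd_lengths <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "mean"), linetype = "dashed") +
    ggplot2::labs(x = "hydrophobic length (residues)", y = "proteins") +
    ggplot2::theme_minimal()
}

#' Plot leaflet-preference ratios
#'
#' Bars of the mean (outer - inner)/(outer + inner) abundance ratio per
#' residue with SEM error bars; positive values mark outer-leaflet
#' enrichment.
#'
#' @param object A `tmd_leaflet` from [leaflet_preference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmd_leaflet <- function(object, ...) {
  dat <- filter(object, !is.na(.data$ratio))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$residue, y = .data$ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ratio - .data$sem,
                                        ymax = .data$ratio + .data$sem),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(y = "leaflet preference (outer - inner)/(outer + inner)") +
    ggplot2::theme_minimal()
}

#' Plot an MCC threshold-scan curve
#'
#' @param object A `tmd_threshold_scan` from [threshold_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmd_threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$threshold, y = .data$mcc)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "classification threshold", y = "MCC") +
    ggplot2::theme_minimal()
}
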