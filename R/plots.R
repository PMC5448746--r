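# Plot helpers for trait profiles (sensitivity-style overlays over Dns and
# fnum choices). ggplot2 is optional; base graphics are the fallback.

#' Plot a trait profile
#'
#' Step plot of the profile's main value column against its interval axis
#' (height, hill-axis distance or azimuth sector).
#'
#' @param profile a `trait_profile`.
#' @param value column to plot; defaults to the mode's main quantity.
#' @return a ggplot object when ggplot2 is installed, otherwise plots to the
#'   active device and returns `NULL` invisibly.
#' @export
plot_profile <- function(profile, value = NULL) {
  mode <- attr(profile, "mode")
  axis <- if ("z_lo" %in% names(profile)) "z_lo"
          else if ("r_lo" %in% names(profile)) "r_lo" else "az_lo"
  value <- value %||% switch(mode,
    "planar-z" = "area_density", "cylindrical" = "area_density",
    "azimuth" = "azimuth_density", "light-z" = "lid",
    "inclination-z" = "inclination", "inclination-radial" = "inclination",
    "area")
  df <- as.data.frame(profile)
  xlab <- switch(axis, z_lo = "height z (cm)", r_lo = "distance to hill axis (cm)",
                 az_lo = "azimuth (rad)")
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[axis]], y = .data[[value]])) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::labs(x = xlab, y = value, title = sprintf("%s profile", mode)) +
      ggplot2::theme_minimal()
  } else {
    plot(df[[axis]], df[[value]], type = "s", xlab = xlab, ylab = value,
         main = sprintf("%s profile", mode))
    invisible(NULL)
  }
}

#' Overlay area profiles across section spacings and fragment numbers
#'
#' Recomputes the vertical (or radial) leaf-area density for every
#' combination of `Dns` and `fnum` and overlays them, reproducing the
#' classic sensitivity picture: coarse fragments with fine sections make the
#' profile ragged.
#'
#' @param arch a reconstructed [digital_architecture()].
#' @param Dns section spacings to compare (cm).
#' @param fnum fragment numbers to compare.
#' @param mode `"z"` or `"radial"`.
#' @return list with `data` (long data.frame: `Dns`, `fnum`, interval axis,
#'   density) and `plot` (ggplot or `NULL`).
#' @export
profile_sensitivity <- function(arch, Dns = c(10, 5, 1), fnum = c(10, 100),
                                mode = c("z", "radial")) {
  mode <- match.arg(mode)
  frs <- lapply(fnum, function(f) fragment_canopy(arch, f))
  rows <- list()
  for (fi in seq_along(fnum)) for (d in Dns) {
    p <- if (mode == "z") area_profile_z(frs[[fi]], Dns = d, ctx = arch$context)
         else area_profile_radial(frs[[fi]], Dns = d, ctx = arch$context)
    axis <- if (mode == "z") p$z_lo else p$r_lo
    rows[[length(rows) + 1L]] <- data.frame(Dns = d, fnum = fnum[fi],
                                            pos = axis, density = p$area_density)
  }
  df <- do.call(rbind, rows)
  pl <- NULL
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$density,
                                           colour = factor(.data$Dns))) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::facet_wrap(~fnum, labeller = ggplot2::label_both) +
      ggplot2::labs(x = if (mode == "z") "height z (cm)" else "distance to hill axis (cm)",
                    y = "leaf area density", colour = "Dns (cm)") +
      ggplot2::theme_minimal()
  }
  list(data = df, plot = pl)
}
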