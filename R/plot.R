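#' Laminar heatmap (channels x time), warm colours = current sink
#'
#' Displays a CSD (or MUA) matrix with depth on the y axis and time on
#' the x axis.  Following the field's convention, current sinks (negative
#' CSD) are drawn in warm colours and sources in cool colours; pass
#' `warm_sink = FALSE` for plain sign-to-colour mapping.
#'
#' @param values `lam_csd` object or channel x time matrix.
#' @param time Time base in ms.
#' @param depths Optional per-channel depths (mm) for the y axis.
#' @param warm_sink Map sinks to warm colours (default TRUE).
#' @param main Plot title.
#' @return Invisibly, the plotted matrix.
#' @export
plot_laminar_heatmap <- function(values, time, depths = NULL,
                                 warm_sink = TRUE, main = "") {
  m <- as_csd_values(values)
  stopifnot(ncol(m) == length(time))
  z <- if (warm_sink) -m else m
  if (is.null(depths)) depths <- seq_len(nrow(m))
  lim <- max(abs(z), na.rm = TRUE)
  pal <- colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(255)
  image(x = time, y = depths, z = t(z), zlim = c(-lim, lim), col = pal,
        xlab = "time (ms)", ylab = "depth (channel)", useRaster = TRUE)
  title(main)
  invisible(z)
}
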