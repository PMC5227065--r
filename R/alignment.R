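#' Locate the layer-4C/5 boundary from the stimulus-evoked CSD
#'
#' The border between layer 4C and layer 5 is estimated as the polarity
#' reversal of the early evoked CSD: current sinks in layer 4C above the
#' boundary, current sources in the deep layers below, around 40 ms after
#' stimulus onset.  The CSD is time-averaged in the search window and the
#' sign transition adjacent to the strongest sink is selected when several
#' transitions exist.
#'
#' Channel 1 is the deepest contact, so "above" means a larger channel
#' index.  The boundary is placed at the midpoint between the two
#' straddling channels; `boundary_channel` is the first channel below the
#' reversal (the deep-side channel).
#'
#' @param csd A `lam_csd` object or channel x time matrix from a full-field
#'   (for example checkerboard) stimulus response.
#' @param time Time base in ms relative to stimulus onset.
#' @param search_time Center of the search window in ms (default 40).
#' @param search_halfwidth Half-width of the search window in ms (default 10).
#' @return List with `boundary_channel` (integer, deep side),
#'   `boundary_depth_index` (boundary_channel + 0.5) and the window-averaged
#'   `profile` used.
#' @export
find_reversal <- function(csd, time, search_time = 40, search_halfwidth = 10) {
  values <- as_csd_values(csd)
  stopifnot(ncol(values) == length(time))
  cols <- win_idx(time, search_time + c(-1, 1) * search_halfwidth)
  if (!length(cols)) stop("search window contains no time samples")
  p <- rowMeans(values[, cols, drop = FALSE])
  ok <- which(!is.na(p))
  # transitions between adjacent valid channels: source (+) below, sink (-) above
  cand <- integer(0)
  for (i in ok) {
    if ((i + 1L) %in% ok && p[i] > 0 && p[i + 1L] < 0) cand <- c(cand, i)
  }
  if (!length(cand)) stop("no polarity reversal found in the search window")
  sink_ch <- ok[which.min(p[ok])]
  # the reversal adjacent to the strongest sink: walk down the contiguous
  # sink region containing it and take the transition at its lower edge
  j <- sink_ch
  while ((j - 1L) %in% ok && p[j - 1L] < 0) j <- j - 1L
  b <- if ((j - 1L) %in% cand) j - 1L else {
    # no source directly below the sink region: nearest transition
    cand[which.min(pmin(abs(cand - sink_ch), abs(cand + 1L - sink_ch)))]
  }
  list(boundary_channel = b,
       boundary_depth_index = b + 0.5,
       profile = p)
}

#' Assign channels to laminar compartments by depth from the 4C/5 boundary
#'
#' Depth bands relative to the boundary: 0.05-0.55 mm below = deep layers,
#' 0.05-0.55 mm above = layer 4, 0.65-1.15 mm above = superficial layers.
#' Each band is closed at its lower printed bound and open at the upper, so
#' every depth maps to at most one compartment; depths outside all bands
#' (including the 0.55-0.65 mm gap and channels below the deep band, where
#' layer 6 sits) are `"unassigned"`.
#'
#' @param rel_depth Numeric vector of signed depths in mm relative to the
#'   4C/5 boundary; positive = above the boundary (towards the surface).
#' @return Character vector of labels in
#'   `c("deep", "layer4", "superficial", "unassigned")`.
#' @export
assign_compartments <- function(rel_depth) {
  stopifnot(is.numeric(rel_depth))
  below <- -rel_depth   # distance below the boundary
  out <- rep("unassigned", length(rel_depth))
  out[below >= 0.05 & below < 0.55] <- "deep"
  out[rel_depth >= 0.05 & rel_depth < 0.55] <- "layer4"
  out[rel_depth >= 0.65 & rel_depth < 1.15] <- "superficial"
  out
}

#' Build a per-channel alignment from a boundary channel
#'
#' @param boundary_channel Integer index of the first channel below the
#'   4C/5 polarity reversal (deep side).
#' @param n_channels Number of probe contacts.
#' @param spacing Contact spacing in mm.
#' @return `lam_alignment`: `boundary_channel`, `rel_depth` per channel
#'   (mm, positive = superficial-ward, strictly increasing) and
#'   `compartment` labels.
#' @export
alignment_result <- function(boundary_channel, n_channels = 24L, spacing = 0.1) {
  stopifnot(boundary_channel >= 1, boundary_channel < n_channels)
  rel_depth <- (seq_len(n_channels) - boundary_channel - 0.5) * spacing
  structure(list(boundary_channel = as.integer(boundary_channel),
                 rel_depth = rel_depth,
                 compartment = assign_compartments(rel_depth),
                 spacing = spacing),
            class = "lam_alignment")
}

#' @export
print.lam_alignment <- function(x, ...) {
  cat(sprintf("<lam_alignment> boundary below channel %d; %d channels (%s)\n",
              x$boundary_channel + 1L, length(x$rel_depth),
              paste(sprintf("%s:%d", names(table(x$compartment)),
                            as.integer(table(x$compartment))), collapse = ", ")))
  invisible(x)
}

#' Co-register laminar profiles from several penetrations
#'
#' Maps each penetration's per-channel profile onto the common grid of
#' depths relative to its own 4C/5 boundary (0.1 mm steps) and averages
#' across penetrations.  Depths covered by fewer penetrations carry the
#' contributing count.
#'
#' @param profiles List of per-channel numeric vectors, or matrices
#'   (channel x time with a shared time base) - one per penetration.
#' @param alignments List of [alignment_result()] objects (same length).
#' @return List with `rel_depth` (common grid), `mean` (vector, or
#'   depth x time matrix when the inputs are matrices) and `n`
#'   (penetrations contributing at each depth).
#' @export
align_penetrations <- function(profiles, alignments) {
  if (!length(profiles)) stop("no penetrations supplied")
  if (length(profiles) != length(alignments))
    stop("`profiles` and `alignments` must have the same length")
  is_mat <- is.matrix(profiles[[1]])
  key <- function(d) as.integer(round(d * 100))  # 0.01 mm integer grid
  keys <- lapply(alignments, function(a) key(a$rel_depth))
  grid <- sort(unique(unlist(keys)))
  if (is_mat) {
    nt <- ncol(profiles[[1]])
    acc <- matrix(0, length(grid), nt)
  } else {
    acc <- numeric(length(grid))
  }
  n <- integer(length(grid))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    if (is_mat && !identical(ncol(pr), ncol(profiles[[1]])))
      stop("matrix profiles must share a time base")
    pos <- match(keys[[i]], grid)
    if (is_mat) {
      miss <- apply(pr, 1, function(r) all(is.na(r)))
      pr[is.na(pr)] <- 0
      acc[pos[!miss], ] <- acc[pos[!miss], , drop = FALSE] + pr[!miss, , drop = FALSE]
      n[pos[!miss]] <- n[pos[!miss]] + 1L
    } else {
      miss <- is.na(pr)
      acc[pos[!miss]] <- acc[pos[!miss]] + pr[!miss]
      n[pos[!miss]] <- n[pos[!miss]] + 1L
    }
  }
  div <- ifelse(n == 0, NA_real_, n)
  out <- if (is_mat) sweep(acc, 1, div, "/") else acc / div
  list(rel_depth = grid / 100, mean = out, n = n)
}
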