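#' Reference geometry of the carbon-flow triangle
#'
#' The three energy channels of the soil food web — bacterial,
#' fungal and root (plant) — are mapped into a fixed equilateral triangle
#' with base (0,0)–(100,0) and apex (50, 86.6) (86.6 = 50 * sqrt(3) to one
#' decimal, the convention used for this plot). The reference frame is
#' seven landmarks: the 3 vertices, the 3 side midpoints and the centroid.
#'
#' @param corners Character vector of length 3 naming which channel sits
#'   at each vertex, in vertex order (0,0), (100,0), (50,86.6). Default
#'   `c("BF", "FF", "PP")`.
#' @return List with `vertices` (3 x 2, rownames = channel), `midpoints`
#'   (3 x 2), `centroid` (length 2).
#' @export
triangle_geometry <- function(corners = c("BF", "FF", "PP")) {
  if (length(corners) != 3L || anyDuplicated(corners)) {
    stop("corners must be 3 distinct channel labels", call. = FALSE)
  }
  v <- rbind(c(0, 0), c(100, 0), c(50, 86.6))
  dimnames(v) <- list(corners, c("x", "y"))
  mid <- (v[c(1, 2, 3), ] + v[c(2, 3, 1), ]) / 2
  rownames(mid) <- paste(corners[c(1, 2, 3)], corners[c(2, 3, 1)],
                         sep = "-")
  list(vertices = v, midpoints = mid, centroid = colMeans(v))
}

#' Channel proportions from metabolic footprints
#'
#' Relative metabolic footprints of the bacterivorous, fungivorous and
#' plant-parasitic nematodes — the three decomposition/energy channels.
#' Omnivorous-predatory footprints sit above the channels and are
#' excluded.
#'
#' @param nmf_bf,nmf_ff,nmf_pp Group metabolic footprints (>= 0);
#'   vectorised.
#' @return `data.frame` with `p_bf`, `p_ff`, `p_pp` summing to 1 per row;
#'   all-`NA` rows where the three footprints are all zero.
#' @export
channel_proportions <- function(nmf_bf, nmf_ff, nmf_pp) {
  if (any(c(nmf_bf, nmf_ff, nmf_pp) < 0)) {
    stop("footprints must be >= 0", call. = FALSE)
  }
  total <- nmf_bf + nmf_ff + nmf_pp
  und <- total == 0
  total[und] <- NA_real_
  data.frame(p_bf = nmf_bf / total, p_ff = nmf_ff / total,
             p_pp = nmf_pp / total)
}

#' Map channel proportions into the carbon-flow triangle
#'
#' Barycentric combination of the triangle vertices: with the default
#' corner assignment, `(x, y) = p_bf*(0,0) + p_ff*(100,0) +
#' p_pp*(50,86.6)`. The mapping is affine, so treatment means of
#' proportions map to the mean of the mapped points.
#'
#' @param p_bf,p_ff,p_pp Channel proportions, each >= 0, summing to 1
#'   within 1e-9; vectorised.
#' @param corners Corner assignment, as in [triangle_geometry()].
#' @return `data.frame` with `p_bf`, `p_ff`, `p_pp`, `x`, `y`; the corner
#'   assignment is recorded in the `"corners"` attribute.
#' @export
ternary_point <- function(p_bf, p_ff, p_pp, corners = c("BF", "FF", "PP")) {
  p <- cbind(p_bf, p_ff, p_pp)
  ok <- !apply(is.na(p), 1L, any)
  if (any(p[ok, ] < 0)) stop("proportions must be >= 0", call. = FALSE)
  if (any(abs(rowSums(p[ok, , drop = FALSE]) - 1) > 1e-9)) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  geom <- triangle_geometry(corners)
  # column i of p weights the vertex whose label is corners[i]
  bary <- p[, match(corners, c("BF", "FF", "PP")), drop = FALSE]
  xy <- bary %*% geom$vertices
  out <- data.frame(p_bf = p[, 1L], p_ff = p[, 2L], p_pp = p[, 3L],
                    x = xy[, 1L], y = xy[, 2L])
  attr(out, "corners") <- corners
  out
}

#' Per-sample and per-treatment carbon-flow map
#'
#' Computes channel proportions from a faunal-profile table
#' ([compute_footprints()]), maps every sample into the triangle, and adds
#' one mean point per treatment (the mean of the per-sample proportions,
#' mapped).
#'
#' @param footprints A `faunal_profile` (or any data.frame with `NMF_BF`,
#'   `NMF_FF`, `NMF_PP` and optionally `treatment`).
#' @param corners Corner assignment, as in [triangle_geometry()].
#' @return Object of class `ternary_map`: a `data.frame` of points with a
#'   `kind` column (`"sample"` or `"treatment_mean"`); geometry and corner
#'   assignment in attributes.
#' @export
carbon_flow_map <- function(footprints, corners = c("BF", "FF", "PP")) {
  pr <- channel_proportions(footprints$NMF_BF, footprints$NMF_FF,
                            footprints$NMF_PP)
  pts <- ternary_point(pr$p_bf, pr$p_ff, pr$p_pp, corners)
  pts <- cbind(kind = "sample",
               label = if ("sample_id" %in% names(footprints))
                 footprints$sample_id else rownames(footprints),
               treatment = if ("treatment" %in% names(footprints))
                 footprints$treatment else NA_character_,
               pts)
  if ("treatment" %in% names(footprints)) {
    means <- lapply(split(pr, footprints$treatment), colMeans,
                    na.rm = TRUE)
    mp <- do.call(rbind, means)
    mpts <- ternary_point(mp[, "p_bf"], mp[, "p_ff"], mp[, "p_pp"],
                          corners)
    pts <- rbind(pts, cbind(kind = "treatment_mean",
                            label = rownames(mp),
                            treatment = rownames(mp), mpts))
  }
  rownames(pts) <- NULL
  attr(pts, "geometry") <- triangle_geometry(corners)
  attr(pts, "corners") <- corners
  class(pts) <- c("ternary_map", "data.frame")
  pts
}

#' Plot a carbon-flow ternary map
#'
#' Scatter of mapped points inside the reference triangle, with sides,
#' midlines and centroid drawn; axes are suppressed as is customary for
#' ternary diagrams.
#'
#' @param x A `ternary_map` from [carbon_flow_map()].
#' @param ... Passed to [graphics::points()].
#' @return `x`, invisibly.
#' @export
plot.ternary_map <- function(x, ...) {
  g <- attr(x, "geometry")
  v <- g$vertices
  graphics::plot(NA, xlim = c(-5, 105), ylim = c(-8, 95), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::polygon(v[, 1L], v[, 2L])
  for (i in 1:3) {
    graphics::segments(v[i, 1L], v[i, 2L],
                       g$midpoints[c(2, 3, 1)[i], 1L],
                       g$midpoints[c(2, 3, 1)[i], 2L],
                       lty = 3, col = "grey60")
  }
  graphics::text(v[, 1L], v[, 2L] + c(-5, -5, 5), rownames(v))
  samp <- x$kind == "sample"
  cols <- as.integer(factor(x$treatment)) + 1L
  graphics::points(x$x[samp], x$y[samp], pch = 1, col = cols[samp], ...)
  graphics::points(x$x[!samp], x$y[!samp], pch = 17, col = cols[!samp],
                   cex = 1.4)
  invisible(x)
}
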