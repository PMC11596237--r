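#' Per-taxon nematode metabolic footprint
#'
#' Carbon use of `N` individuals of a taxon with fresh body mass `W` (µg)
#' and c-p value `m`, combining a production term `0.1 * W / m` and a
#' respiration term `0.273 * W^0.75`:
#' \deqn{NMF = N (0.1 \, W / m + 0.273 \, W^{0.75}).}
#'
#' @param n Abundance (individuals, typically per 100 g dry soil), >= 0.
#' @param w Fresh body mass per individual in µg, > 0.
#' @param m c-p value in 1..5.
#' @return Footprint in carbon-flux-scaled units; vectorised.
#' @examples
#' metabolic_footprint(10, 1, 2)  # 3.23
#' @export
metabolic_footprint <- function(n, w, m) {
  if (any(n < 0)) stop("abundance must be >= 0", call. = FALSE)
  if (any(w <= 0)) stop("body mass must be > 0", call. = FALSE)
  if (any(m < 1 | m > 5)) stop("c-p value must lie in 1..5", call. = FALSE)
  n * (0.1 * (w / m) + 0.273 * w^0.75)
}

#' Metabolic footprints by trophic group
#'
#' Per-sample sums of per-taxon footprints for each feeding guild and
#' their total. Footprints are additive over taxa and homogeneous of
#' degree 1 in abundance, so the total equals the sum of the four groups
#' exactly.
#'
#' @param table Annotated nematode [community_table()] in counts per 100 g
#'   dry soil.
#' @param traits Trait table with c-p values and body masses.
#' @return `data.frame`: `sample_id`, `NMF_BF`, `NMF_FF`, `NMF_PP`,
#'   `NMF_OP`, `NMF_total`.
#' @export
group_footprints <- function(table, traits) {
  stopifnot(inherits(table, "community_table"))
  tr <- match_traits(colnames(table$abundance), traits, organism = "nematode")
  # footprint of one individual of each taxon; abundance scales it
  per_ind <- metabolic_footprint(1, tr$mass_ug, tr$cp)
  fp <- sweep(table$abundance, 2L, per_ind, `*`)
  groups <- c("BF", "FF", "PP", "OP")
  out <- sapply(groups, function(g) {
    cols <- tr$trophic == g
    if (!any(cols)) return(rep(0, nrow(fp)))
    rowSums(fp[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(fp),
                dimnames = list(NULL, paste0("NMF_", groups)))
  data.frame(sample_id = rownames(table$abundance), out,
             NMF_total = rowSums(out), stringsAsFactors = FALSE)
}

# Membership masks for the enrichment (e), basal (b) and structural (s)
# faunal components. Literal scheme: e = {BF cp1, FF cp2},
# b = {BF cp2, FF cp2} (FF cp2 belongs to both e and b),
# s = {BF 3-5, FF 3-5, OP 3-5, PP 2-5}. The ferris2001 preset drops PP
# from s (structure built from free-living guilds only).
#' @keywords internal
component_masks <- function(tr, include_pp_in_s = TRUE) {
  e <- (tr$trophic == "BF" & tr$cp == 1L) |
       (tr$trophic == "FF" & tr$cp == 2L)
  b <- (tr$trophic == "BF" & tr$cp == 2L) |
       (tr$trophic == "FF" & tr$cp == 2L)
  s <- (tr$trophic %in% c("BF", "FF", "OP") & tr$cp >= 3L)
  if (include_pp_in_s) s <- s | (tr$trophic == "PP" & tr$cp >= 2L)
  list(e = e, b = b, s = s)
}

#' @keywords internal
resolve_weights <- function(weights) {
  if (is.null(weights)) {
    list(w = rep(1, 5), include_pp_in_s = TRUE)
  } else if (identical(weights, "ferris2001")) {
    list(w = c(3.2, 0.8, 1.8, 3.2, 5.0), include_pp_in_s = FALSE)
  } else if (is.numeric(weights) && length(weights) == 5L) {
    if (any(weights <= 0)) stop("component weights must be > 0",
                                call. = FALSE)
    list(w = unname(weights), include_pp_in_s = TRUE)
  } else {
    stop("weights must be NULL, \"ferris2001\", or 5 positive numbers ",
         "(one per c-p class)", call. = FALSE)
  }
}

#' Enrichment, basal and structural faunal components
#'
#' Per-sample component sums `e`, `b`, `s` feeding the enrichment and
#' structure indices. By default the (unweighted) literal memberships are
#' used; `weights = "ferris2001"` applies the conventional c-p class
#' weights (cp1: 3.2, cp2: 0.8, cp3: 1.8, cp4: 3.2, cp5: 5.0) and builds
#' `s` from the free-living guilds only (PP excluded). A numeric vector of
#' five positive weights (one per c-p class) is also accepted.
#'
#' @inheritParams group_footprints
#' @param weights `NULL` (all 1), `"ferris2001"`, or numeric length 5.
#' @return `data.frame`: `sample_id`, `e`, `b`, `s`.
#' @export
faunal_components <- function(table, traits, weights = NULL) {
  stopifnot(inherits(table, "community_table"))
  tr <- match_traits(colnames(table$abundance), traits, organism = "nematode")
  ws <- resolve_weights(weights)
  masks <- component_masks(tr, include_pp_in_s = ws$include_pp_in_s)
  wt <- ws$w[tr$cp]  # per-taxon weight by c-p class
  comp <- function(mask) {
    if (!any(mask)) return(rep(0, nrow(table$abundance)))
    rowSums(sweep(table$abundance[, mask, drop = FALSE], 2L, wt[mask], `*`))
  }
  data.frame(sample_id = rownames(table$abundance),
             e = comp(masks$e), b = comp(masks$b), s = comp(masks$s),
             stringsAsFactors = FALSE)
}

#' Enrichment index
#'
#' `EI = 100 * e / (e + b)`.
#'
#' @param e,b Enrichment and basal component sums (>= 0).
#' @return EI in `[0, 100]`; `NA` when e + b = 0.
#' @export
enrichment_index <- function(e, b) {
  if (any(c(e, b) < 0)) stop("components must be >= 0", call. = FALSE)
  ifelse(e + b == 0, NA_real_, 100 * e / (e + b))
}

#' Structure index
#'
#' `SI = 100 * s / (s + b)`.
#'
#' @param s,b Structural and basal component sums (>= 0).
#' @return SI in `[0, 100]`; `NA` when s + b = 0.
#' @export
structure_index <- function(s, b) {
  if (any(c(s, b) < 0)) stop("components must be >= 0", call. = FALSE)
  ifelse(s + b == 0, NA_real_, 100 * s / (s + b))
}

#' Enrichment and structural footprints
#'
#' `Fe` sums the (unweighted) per-taxon metabolic footprints over the
#' enrichment-component taxa, `Fs` over the structural-component taxa,
#' using the same memberships as [faunal_components()].
#'
#' @inheritParams faunal_components
#' @return `data.frame`: `sample_id`, `Fe`, `Fs`.
#' @export
component_footprints <- function(table, traits, weights = NULL) {
  stopifnot(inherits(table, "community_table"))
  tr <- match_traits(colnames(table$abundance), traits, organism = "nematode")
  ws <- resolve_weights(weights)
  masks <- component_masks(tr, include_pp_in_s = ws$include_pp_in_s)
  per_ind <- metabolic_footprint(1, tr$mass_ug, tr$cp)
  fp <- sweep(table$abundance, 2L, per_ind, `*`)
  fsum <- function(mask) {
    if (!any(mask)) return(rep(0, nrow(fp)))
    rowSums(fp[, mask, drop = FALSE])
  }
  data.frame(sample_id = rownames(table$abundance),
             Fe = fsum(masks$e), Fs = fsum(masks$s),
             stringsAsFactors = FALSE)
}

#' Functional metabolic footprint rhombus
#'
#' Centered on the faunal-profile point (SI, EI), the functional footprint
#' is the quadrilateral through
#' `(SI, EI - 0.5 Fe/k)`, `(SI + 0.5 Fs/k, EI)`, `(SI, EI + 0.5 Fe/k)`,
#' `(SI - 0.5 Fs/k, EI)` — a rhombus with perpendicular diagonals `Fe/k`
#' and `Fs/k`. Its area, computed by the shoelace formula, equals
#' `0.5 * (Fe/k) * (Fs/k)` and measures the food web's metabolic balance.
#'
#' @param si,ei Structure and enrichment indices (defined, i.e. not NA).
#' @param fe,fs Enrichment and structural footprints (>= 0).
#' @param k Transformation constant scaling footprints onto the index
#'   plane; default 100.
#' @return List with `vertices` (4 x 2 matrix, in the order above) and
#'   `area`.
#' @export
functional_footprint <- function(si, ei, fe, fs, k = 100) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (any(c(fe, fs) < 0)) stop("footprints must be >= 0", call. = FALSE)
  if (is.na(si) || is.na(ei)) {
    return(list(vertices = matrix(NA_real_, 4, 2,
                                  dimnames = list(NULL, c("x", "y"))),
                area = NA_real_))
  }
  v <- rbind(c(si, ei - 0.5 * fe / k),
             c(si + 0.5 * fs / k, ei),
             c(si, ei + 0.5 * fe / k),
             c(si - 0.5 * fs / k, ei))
  colnames(v) <- c("x", "y")
  list(vertices = v, area = shoelace_area(v))
}

# Shoelace (surveyor's) polygon area. Vertices are centred first: the
# area is translation-invariant and centring avoids cancellation when the
# polygon is small relative to its distance from the origin.
#' @keywords internal
shoelace_area <- function(v) {
  x <- v[, 1L] - mean(v[, 1L]); y <- v[, 2L] - mean(v[, 2L])
  j <- c(seq_len(nrow(v))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Faunal-profile quadrant
#'
#' Position of a sample in the EI-by-SI plane. Quadrant A (EI > 50,
#' SI <= 50): enriched but unstructured, N-mediated disturbance; B (both
#' > 50): enriched and structured, maturing; C (EI <= 50, SI > 50):
#' structured, fungal-channel decomposition; D (both <= 50): depleted,
#' degraded.
#'
#' @param ei,si Enrichment and structure indices in `[0, 100]`.
#' @return `"A"`, `"B"`, `"C"` or `"D"`; `NA` if either index is
#'   undefined. Vectorised.
#' @export
faunal_quadrant <- function(ei, si) {
  ifelse(is.na(ei) | is.na(si), NA_character_,
         ifelse(ei > 50,
                ifelse(si > 50, "B", "A"),
                ifelse(si > 50, "C", "D")))
}

#' Full per-sample footprint and faunal-profile table
#'
#' One call assembling, per sample: group metabolic footprints, faunal
#' components e/b/s, EI, SI, Fe, Fs, the functional-footprint area and
#' rhombus vertices, and the quadrant classification.
#'
#' @inheritParams faunal_components
#' @param k Transformation constant for the functional footprint.
#' @return Object of class `faunal_profile`: a `data.frame` with sample
#'   metadata, `NMF_*`, `e`, `b`, `s`, `EI`, `SI`, `Fe`, `Fs`, `F_area`,
#'   `quadrant` and the 8 vertex coordinates `v1_x` .. `v4_y`. The
#'   component scheme and `k` are attached as attributes.
#' @export
compute_footprints <- function(table, traits, weights = NULL, k = 100) {
  gf <- group_footprints(table, traits)
  comp <- faunal_components(table, traits, weights)
  cf <- component_footprints(table, traits, weights)
  ei <- enrichment_index(comp$e, comp$b)
  si <- structure_index(comp$s, comp$b)
  geom <- lapply(seq_along(ei), function(i) {
    functional_footprint(si[i], ei[i], cf$Fe[i], cf$Fs[i], k)
  })
  verts <- t(vapply(geom, function(g) as.vector(t(g$vertices)),
                    numeric(8L)))
  colnames(verts) <- paste0(rep(paste0("v", 1:4), each = 2L),
                            c("_x", "_y"))
  out <- cbind(sample_frame(table),
               gf[-1L], comp[-1L],
               EI = ei, SI = si, Fe = cf$Fe, Fs = cf$Fs,
               F_area = vapply(geom, `[[`, numeric(1L), "area"),
               quadrant = faunal_quadrant(ei, si),
               as.data.frame(verts))
  attr(out, "weights") <- if (is.null(weights)) "unweighted" else
    if (identical(weights, "ferris2001")) "ferris2001" else "custom"
  attr(out, "k") <- k
  class(out) <- c("faunal_profile", "data.frame")
  out
}

#' Plot a faunal profile
#'
#' Draws the EI-by-SI plane with the 50/50 quadrant lines and, for every
#' sample, the functional-footprint rhombus centred on its (SI, EI) point.
#'
#' @param x A `faunal_profile` from [compute_footprints()].
#' @param col Colours, recycled over samples (default: by treatment when
#'   available).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.faunal_profile <- function(x, col = NULL, ...) {
  if (is.null(col)) {
    col <- if ("treatment" %in% names(x)) {
      as.integer(factor(x$treatment)) + 1L
    } else "steelblue"
  }
  col <- rep_len(col, nrow(x))
  graphics::plot(x$SI, x$EI, xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "Structure index (SI)",
                 ylab = "Enrichment index (EI)",
                 pch = 19, col = col, ...)
  graphics::abline(h = 50, v = 50, lty = 2, col = "grey50")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$EI[i]) || is.na(x$SI[i])) next
    graphics::polygon(c(x$v1_x[i], x$v2_x[i], x$v3_x[i], x$v4_x[i]),
                      c(x$v1_y[i], x$v2_y[i], x$v3_y[i], x$v4_y[i]),
                      border = col[i])
  }
  invisible(x)
}
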