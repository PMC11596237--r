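#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats, with the convention
#' \eqn{0 \cdot \ln 0 = 0}.
#'
#' @param p Probability vector (relative abundances): entries >= 0 summing
#'   to 1 within 1e-9.
#' @return H >= 0.
#' @examples
#' shannon_index(rep(0.25, 4))  # log(4)
#' @export
shannon_index <- function(p) {
  check_probability(p)
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Dominance index
#'
#' Simpson's dominance \eqn{\lambda = \sum_i p_i^2}; 1 for a single-taxon
#' community, 1/S at the uniform distribution over S taxa.
#'
#' @inheritParams shannon_index
#' @return lambda in (0, 1].
#' @export
dominance_index <- function(p) {
  check_probability(p)
  sum(p^2)
}

#' @keywords internal
check_probability <- function(p) {
  if (any(p < 0)) stop("probabilities must be >= 0", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  invisible(p)
}

#' Free-living maturity index
#'
#' Abundance-weighted mean c-p value over free-living nematodes (BF, FF and
#' OP guilds; plant parasites are excluded). Higher values indicate a more
#' structured, less disturbed community.
#'
#' @param abundance Named non-negative vector of nematode abundances, names
#'   are taxon ids.
#' @param traits Trait table annotating those taxa.
#' @return MI in `[1, 5]`, or `NA` (explicit undefined flag) when the
#'   sample holds no free-living individuals.
#' @export
maturity_index <- function(abundance, traits) {
  weighted_cp(abundance, traits, trophic = c("BF", "FF", "OP"))
}

#' Plant-parasitic index
#'
#' Abundance-weighted mean c-p value over plant-parasitic (PP) taxa only.
#'
#' @inheritParams maturity_index
#' @return PPI in `[1, 5]`, or `NA` when no plant parasites are present.
#' @export
plant_parasitic_index <- function(abundance, traits) {
  weighted_cp(abundance, traits, trophic = "PP")
}

#' @keywords internal
weighted_cp <- function(abundance, traits, trophic) {
  if (any(abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  tr <- match_traits(names(abundance), traits, organism = "nematode")
  keep <- tr$trophic %in% trophic
  total <- sum(abundance[keep])
  if (total == 0) return(NA_real_)
  sum(tr$cp[keep] * abundance[keep]) / total
}

#' Nematode channel ratio
#'
#' NCR = BF / (BF + FF): the share of the microbivorous community feeding
#' through the bacterial decomposition channel. 1 means a purely bacterial
#' channel, 0 purely fungal.
#'
#' @param bf,ff Total bacterivorous and fungivorous abundances (>= 0).
#' @return NCR in `[0, 1]`; `NA` when BF + FF = 0.
#' @export
channel_ratio <- function(bf, ff) {
  if (any(c(bf, ff) < 0)) stop("abundances must be >= 0", call. = FALSE)
  ifelse(bf + ff == 0, NA_real_, bf / (bf + ff))
}

#' Wasilewska index
#'
#' WI = (BF + FF) / PP: microbivorous relative to plant-parasitic
#' abundance; values above 1 indicate the beneficial microbivores outweigh
#' the root herbivores.
#'
#' @param bf,ff,pp Trophic-group abundance totals (>= 0).
#' @return WI >= 0; `NA` when PP = 0.
#' @export
wasilewska_index <- function(bf, ff, pp) {
  if (any(c(bf, ff, pp) < 0)) stop("abundances must be >= 0", call. = FALSE)
  ifelse(pp == 0, NA_real_, (bf + ff) / pp)
}

#' Chao1 richness estimator
#'
#' Classic Chao1: \eqn{S_{obs} + F_1^2 / (2 F_2)} where \eqn{F_1}
#' and \eqn{F_2} are the singleton and doubleton counts, with the fallback
#' \eqn{S_{obs} + F_1 (F_1 - 1) / 2} when there are no doubletons. The
#' bias-corrected variant \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} is
#' available via `bias_corrected = TRUE`.
#'
#' @param counts Non-negative integer count vector for one sample.
#' @param bias_corrected Use the bias-corrected estimator instead of the
#'   classic one.
#' @return Estimated richness, always >= observed richness.
#' @export
chao1_index <- function(counts, bias_corrected = FALSE) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("Chao1 requires integer counts", call. = FALSE)
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Per-sample nematode ecological indices
#'
#' Computes, for every sample of an annotated nematode community table:
#' Shannon diversity `H` (nats) and dominance `lambda` over genus relative
#' abundances, the free-living maturity index `MI`, the plant-parasitic
#' index `PPI` and their ratio `PPI_MI`, the channel ratio `NCR`, the
#' Wasilewska index `WI`, and (when the abundances are integer-valued)
#' the Chao1 richness estimate.
#'
#' Undefined indices (empty sample, no free-living or no plant-parasitic
#' individuals, BF + FF = 0, PP = 0) are reported as `NA` — an explicit
#' missing flag, never silently 0.
#'
#' @param table Nematode [community_table()] in counts.
#' @param traits Trait table annotating every taxon in `table`.
#' @return A `data.frame` with one row per sample: `sample_id`, any
#'   `treatment`/`replicate` metadata, then `H`, `lambda`, `MI`, `PPI`,
#'   `PPI_MI`, `NCR`, `WI`, `chao1`.
#' @export
compute_indices <- function(table, traits) {
  stopifnot(inherits(table, "community_table"))
  ab <- table$abundance
  troph <- aggregate_trophic(table, traits)
  integer_counts <- all(abs(ab - round(ab)) <= 1e-8)
  if (!integer_counts) {
    warning("non-integer abundances: Chao1 reported as NA", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(ab)), function(i) {
    x <- stats::setNames(ab[i, ], colnames(ab))
    total <- sum(x)
    if (total > 0) {
      p <- x[x > 0] / total
      h <- shannon_index(p)
      lam <- dominance_index(p)
    } else {
      h <- NA_real_
      lam <- NA_real_
    }
    mi <- maturity_index(x, traits)
    ppi <- plant_parasitic_index(x, traits)
    data.frame(
      H = h, lambda = lam, MI = mi, PPI = ppi,
      PPI_MI = if (is.na(mi) || is.na(ppi)) NA_real_ else ppi / mi,
      NCR = channel_ratio(troph$BF[i], troph$FF[i]),
      WI = wasilewska_index(troph$BF[i], troph$FF[i], troph$PP[i]),
      chao1 = if (integer_counts) chao1_index(x) else NA_real_)
  })
  cbind(sample_frame(table), do.call(rbind, rows))
}

# sample_id (+ treatment/replicate when present) frame for result tables
#' @keywords internal
sample_frame <- function(table) {
  md <- table$metadata
  keep <- intersect(c("sample_id", "treatment", "replicate"), names(md))
  md[keep]
}
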