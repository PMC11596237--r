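#' Assemble a pipeline run configuration
#'
#' Collects inputs (either a [synthetic_config()] to simulate, or file
#' paths to community/trait/metadata tables) and every analysis threshold
#' in one serializable list which is echoed verbatim into the output
#' bundle. No stage has hidden defaults: everything tunable is here.
#'
#' @param synthetic Optional [synthetic_config()]; when given, inputs are
#'   simulated.
#' @param nematodes,bacteria,fungi,traits,metadata File paths used when
#'   `synthetic` is `NULL` (bacteria/fungi/metadata optional).
#' @param microbial_unit Declared unit of microbial tables read from
#'   disk: `"raw_count"` or `"relative"` (either is accepted; the unit is
#'   recorded in the bundle).
#' @param weights Component weighting for EI/SI (see
#'   [faunal_components()]).
#' @param k Functional-footprint transformation constant.
#' @param method Correlation method for the network stage.
#' @param r_min,p_max,adjust,min_prevalence Network thresholds (see
#'   [cooccurrence_network()]).
#' @param network_grouping `"pooled"` (one network over all samples,
#'   default) or `"per_treatment"` (one per treatment; requires >= 4
#'   replicates).
#' @param alpha Significance level for treatment comparisons.
#' @param top_k Keystone taxa reported per network.
#' @return List of class `foodweb_config`.
#' @export
foodweb_config <- function(synthetic = synthetic_config(),
                           nematodes = NULL, bacteria = NULL,
                           fungi = NULL, traits = NULL, metadata = NULL,
                           microbial_unit = c("raw_count", "relative"),
                           weights = NULL, k = 100,
                           method = c("spearman", "pearson"),
                           r_min = 0.6, p_max = 0.05,
                           adjust = c("none", "BH"),
                           min_prevalence = 3L,
                           network_grouping = c("pooled",
                                                "per_treatment"),
                           alpha = 0.05, top_k = 5L) {
  structure(list(synthetic = synthetic, nematodes = nematodes,
                 bacteria = bacteria, fungi = fungi, traits = traits,
                 metadata = metadata,
                 microbial_unit = match.arg(microbial_unit),
                 weights = weights, k = k, method = match.arg(method),
                 r_min = r_min, p_max = p_max,
                 adjust = match.arg(adjust),
                 min_prevalence = min_prevalence,
                 network_grouping = match.arg(network_grouping),
                 alpha = alpha, top_k = top_k),
            class = "foodweb_config")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [foodweb_config()]; a `synthetic:` block is
#' forwarded to [synthetic_config()].
#'
#' @param path Path to a YAML file.
#' @return A `foodweb_config`.
#' @export
read_foodweb_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  do.call(foodweb_config, y)
}

#' @keywords internal
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full micro-food-web analysis pipeline
#'
#' Orchestrates every stage over one data set: ingest or simulate
#' (core_data / synthetic_data), per-sample ecological indices, metabolic
#' footprints and faunal profile, carbon-flow ternary mapping,
#' co-occurrence network(s) with keystone ranking, and treatment
#' comparisons (ANOVA + LSD letters). Deterministic given the config
#' (which carries the seed for synthetic runs).
#'
#' When `out_dir` is given, the bundle is written there: CSV tables per
#' stage, network files (GraphML/CSV/JSON), and `summary.json` holding
#' the echoed config, per-treatment means, network link counts and
#' ANOVA results. Outputs are staged in a temporary directory and only
#' moved into `out_dir` on success, so a failing run leaves no partial
#' bundle.
#'
#' @param config A [foodweb_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `foodweb_run`: list with `indices`,
#'   `footprints`, `ternary`, `networks` (+ `keystones`), `comparisons`,
#'   `summary`, `config`, `data`.
#' @export
run_foodweb <- function(config = foodweb_config(), out_dir = NULL) {
  stopifnot(inherits(config, "foodweb_config"))

  dat <- stage("core_data", {
    if (!is.null(config$synthetic)) {
      simulate_foodweb(config$synthetic)
    } else {
      if (is.null(config$nematodes) || is.null(config$traits)) {
        stop("need nematode community and trait tables")
      }
      traits <- read_trait_table(config$traits)
      md <- if (!is.null(config$metadata))
        read_delimited(config$metadata) else NULL
      list(
        nematodes = read_community_table(config$nematodes,
                                         unit = "count_per_100g_dry",
                                         metadata = md),
        bacteria = if (!is.null(config$bacteria))
          read_community_table(config$bacteria,
                               unit = config$microbial_unit,
                               metadata = md) else NULL,
        fungi = if (!is.null(config$fungi))
          read_community_table(config$fungi,
                               unit = config$microbial_unit,
                               metadata = md) else NULL,
        traits = traits, metadata = md)
    }
  })

  idx <- stage("indices", compute_indices(dat$nematodes, dat$traits))
  fp <- stage("footprints",
              compute_footprints(dat$nematodes, dat$traits,
                                 weights = config$weights, k = config$k))
  tern <- stage("carbon_flow", carbon_flow_map(fp))

  nets <- stage("network", {
    tables <- Filter(Negate(is.null),
                     list(dat$bacteria, dat$fungi, dat$nematodes))
    build_one <- function(tbls) {
      do.call(cooccurrence_network,
              c(tbls, list(traits = dat$traits, method = config$method,
                           r_min = config$r_min, p_max = config$p_max,
                           adjust = config$adjust,
                           min_prevalence = config$min_prevalence)))
    }
    if (config$network_grouping == "pooled") {
      list(pooled = build_one(tables))
    } else {
      trts <- unique(dat$nematodes$metadata$treatment)
      nets <- lapply(trts, function(tt) {
        keep <- dat$nematodes$metadata$treatment == tt
        build_one(lapply(tables, function(tb) {
          community_table(tb$abundance[keep, , drop = FALSE],
                          metadata = tb$metadata[keep, , drop = FALSE],
                          unit = tb$unit)
        }))
      })
      stats::setNames(nets, trts)
    }
  })
  keys <- lapply(nets, function(nw)
    keystone_taxa(nw, network_centrality(nw, "degree"),
                  top_k = config$top_k))

  comps <- stage("treatment_stats", {
    if (!"treatment" %in% names(idx)) {
      list()
    } else {
      c(compare_treatments(idx, alpha = config$alpha),
        compare_treatments(
          fp, columns = c("NMF_BF", "NMF_FF", "NMF_PP", "NMF_OP",
                          "NMF_total", "EI", "SI", "Fe", "Fs", "F_area"),
          alpha = config$alpha))
    }
  })

  summ <- stage("report", {
    index_cols <- c("H", "lambda", "MI", "PPI", "PPI_MI", "NCR", "WI",
                    "chao1")
    fp_cols <- c("NMF_BF", "NMF_FF", "NMF_PP", "NMF_OP", "NMF_total",
                 "EI", "SI", "Fe", "Fs", "F_area")
    by_trt <- function(df, cols) {
      if (!"treatment" %in% names(df)) return(NULL)
      lapply(split(df[cols], df$treatment),
             function(d) lapply(as.list(colMeans(d, na.rm = TRUE)),
                                unname))
    }
    list(config = serialize_config(config),
         n_samples = nrow(dat$nematodes$abundance),
         treatment_means = list(indices = by_trt(idx, index_cols),
                                footprints = by_trt(fp, fp_cols)),
         networks = lapply(nets, function(nw) c(nw$summary, nw$params)),
         keystones = lapply(keys, function(k) k$taxon),
         anova = lapply(comps, function(cm)
           list(F = cm$F, p = cm$p,
                letters = stats::setNames(as.list(cm$table$letter),
                                          cm$table$group))))
  })

  run <- structure(list(indices = idx, footprints = fp, ternary = tern,
                        networks = nets, keystones = keys,
                        comparisons = comps, summary = summ,
                        config = config, data = dat),
                   class = "foodweb_run")
  if (!is.null(out_dir)) write_bundle(run, out_dir)
  run
}

# Config as plain lists for the JSON echo (drop the bulky trait table,
# keep its size; matrices become named lists of columns).
#' @keywords internal
serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    sy <- unclass(out$synthetic)
    sy$traits <- list(n_taxa = nrow(sy$traits),
                      n_nematode = sum(sy$traits$group == "nematode"))
    sy$multipliers <- apply(sy$multipliers, 2L, as.list,
                            simplify = FALSE)
    out$synthetic <- sy
  }
  out$weights <- if (is.null(out$weights)) "unweighted" else
    if (identical(out$weights, "ferris2001")) "ferris2001" else
      as.list(out$weights)
  out
}

#' @keywords internal
write_bundle <- function(run, out_dir) {
  staging <- tempfile("foodweb_bundle_")
  dir.create(staging, recursive = TRUE)
  write_delimited(run$indices, file.path(staging, "indices.csv"))
  write_delimited(as.data.frame(run$footprints),
                  file.path(staging, "footprints.csv"))
  write_delimited(as.data.frame(run$ternary),
                  file.path(staging, "ternary.csv"))
  geom <- attr(run$ternary, "geometry")
  ref <- data.frame(
    landmark = c(rownames(geom$vertices), rownames(geom$midpoints),
                 "centroid"),
    x = c(geom$vertices[, 1L], geom$midpoints[, 1L], geom$centroid[1L]),
    y = c(geom$vertices[, 2L], geom$midpoints[, 2L], geom$centroid[2L]))
  write_delimited(ref, file.path(staging, "ternary_reference.csv"))
  for (nm in names(run$networks)) {
    write_network(run$networks[[nm]], staging,
                  name = paste0("network_", nm))
  }
  if (length(run$comparisons) > 0L) {
    comp_tab <- do.call(rbind, lapply(names(run$comparisons), function(v) {
      cbind(variable = v, run$comparisons[[v]]$table)
    }))
    write_delimited(comp_tab, file.path(staging, "comparisons.csv"))
  }
  jsonlite::write_json(run$summary, file.path(staging, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f),
              overwrite = TRUE)
  }
  unlink(staging, recursive = TRUE)
  invisible(out_dir)
}

#' @export
print.foodweb_run <- function(x, ...) {
  cat("foodweb_run:", nrow(x$indices), "samples\n")
  if ("treatment" %in% names(x$indices)) {
    cat("treatments:",
        paste(unique(x$indices$treatment), collapse = ", "), "\n")
  }
  cat("networks:", paste(names(x$networks), collapse = ", "), "\n")
  for (nm in names(x$networks)) {
    s <- x$networks[[nm]]$summary
    cat(sprintf("  %s: %d links (%d+, %d-)\n", nm, s$total_links,
                s$positive_links, s$negative_links))
  }
  invisible(x)
}

#' @export
summary.foodweb_run <- function(object, ...) object$summary
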