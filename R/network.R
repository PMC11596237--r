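#' Pairwise correlation matrices for co-occurrence analysis
#'
#' Correlation coefficient and p-value for every pair of taxa across
#' samples. Spearman rank correlation is the default (robust against the
#' skewed, non-normal distributions typical of abundance data); Pearson is
#' available. P-values come from [stats::cor.test()]: for small untied
#' samples the Spearman p is exact (permutation null), otherwise the
#' standard asymptotic approximation is used.
#'
#' Taxa with zero variance across samples carry no correlation signal and
#' are excluded with a warning.
#'
#' @param mat Samples-by-taxa numeric matrix (>= 4 samples), or a
#'   [community_table()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `r` (symmetric, unit diagonal), `p` (symmetric,
#'   diagonal 0), `dropped` (zero-variance taxa), `method`.
#' @export
pairwise_correlation <- function(mat, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (inherits(mat, "community_table")) mat <- mat$abundance
  mat <- as.matrix(mat)
  if (nrow(mat) < 4L) {
    stop("need >= 4 samples for pairwise correlation (got ", nrow(mat),
         ")", call. = FALSE)
  }
  v <- apply(mat, 2L, stats::var)
  dropped <- colnames(mat)[v == 0]
  if (length(dropped) > 0L) {
    warning("excluding zero-variance taxa: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    mat <- mat[, v > 0, drop = FALSE]
  }
  m <- ncol(mat)
  r <- suppressWarnings(stats::cor(mat, method = method))
  p <- matrix(0, m, m, dimnames = dimnames(r))
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        pv <- suppressWarnings(
          stats::cor.test(mat[, i], mat[, j], method = method))$p.value
        p[i, j] <- p[j, i] <- pv
      }
    }
  }
  list(r = r, p = p, dropped = dropped, method = method)
}

#' Build a signed co-occurrence network
#'
#' Keeps every taxon pair whose correlation passes both thresholds:
#' `|r| >= r_min` and (optionally BH-adjusted) `p <= p_max`. Edges carry
#' the correlation, its p-value and its sign; the summary counts satisfy
#' `total_links = positive_links + negative_links`.
#'
#' @param r,p Symmetric matrices from [pairwise_correlation()] (or a list
#'   with elements `r` and `p` passed as `r`).
#' @param r_min Minimum absolute correlation, in `[0, 1]`; default 0.6.
#' @param p_max Significance threshold; default 0.05.
#' @param adjust `"none"` (default, mirroring common co-occurrence
#'   practice) or `"BH"` (Benjamini-Hochberg over all tested pairs).
#' @param node_info Optional `data.frame` keyed by `taxon` adding labels
#'   (organism group, trophic group) to the nodes.
#' @return Object of class `cooccurrence_network`: list with `graph`
#'   (igraph, edge attributes `r`, `p`, `sign`), `edges` (data.frame),
#'   `nodes` (data.frame), `summary` (total/positive/negative links) and
#'   `params`.
#' @export
build_cooccurrence_network <- function(r, p = NULL, r_min = 0.6,
                                       p_max = 0.05,
                                       adjust = c("none", "BH"),
                                       node_info = NULL) {
  adjust <- match.arg(adjust)
  if (is.list(r) && is.null(p)) { p <- r$p; r <- r$r }
  if (r_min < 0 || r_min > 1) stop("r_min must lie in [0, 1]",
                                   call. = FALSE)
  if (p_max <= 0 || p_max > 1) stop("p_max must lie in (0, 1]",
                                    call. = FALSE)
  taxa <- colnames(r)
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  pv <- p[ut]
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  keep <- abs(r[ut]) >= r_min & pv <= p_max
  edges <- data.frame(source = taxa[idx[keep, 1L]],
                      target = taxa[idx[keep, 2L]],
                      r = r[ut][keep], p = pv[keep],
                      sign = ifelse(r[ut][keep] > 0, "positive",
                                    "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = taxa)
  nodes <- data.frame(taxon = taxa, degree = igraph::degree(g),
                      stringsAsFactors = FALSE)
  if (!is.null(node_info)) {
    nodes <- merge(nodes, node_info, by = "taxon", all.x = TRUE,
                   sort = FALSE)
  }
  rownames(nodes) <- NULL
  structure(list(
    graph = g, edges = edges, nodes = nodes,
    summary = list(total_links = nrow(edges),
                   positive_links = sum(edges$sign == "positive"),
                   negative_links = sum(edges$sign == "negative")),
    params = list(r_min = r_min, p_max = p_max, adjust = adjust)),
    class = "cooccurrence_network")
}

#' One-call co-occurrence network from community tables
#'
#' Column-binds the supplied community tables over shared samples, applies
#' a prevalence filter (taxa present in fewer than `min_prevalence`
#' samples are removed — correlations over near-constant vectors are
#' meaningless), computes pairwise correlations and thresholds the edges.
#'
#' @param ... One or more [community_table()] objects (e.g. bacteria,
#'   fungi, nematodes) sharing sample ids.
#' @param traits Optional trait table used to label nodes.
#' @inheritParams pairwise_correlation
#' @inheritParams build_cooccurrence_network
#' @param min_prevalence Minimum number of samples a taxon must occur in;
#'   default 3.
#' @return A `cooccurrence_network`.
#' @export
cooccurrence_network <- function(..., traits = NULL,
                                 method = c("spearman", "pearson"),
                                 r_min = 0.6, p_max = 0.05,
                                 adjust = c("none", "BH"),
                                 min_prevalence = 3L) {
  tables <- list(...)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1L), "community_table")))
  ids <- rownames(tables[[1L]]$abundance)
  mats <- lapply(tables, function(t) {
    if (!identical(rownames(t$abundance), ids)) {
      stop("community tables must share identical sample ids/order",
           call. = FALSE)
    }
    t$abundance
  })
  mat <- do.call(cbind, mats)
  prevalent <- colSums(mat > 0) >= min_prevalence
  mat <- mat[, prevalent, drop = FALSE]
  pc <- pairwise_correlation(mat, method = match.arg(method))
  node_info <- if (!is.null(traits)) {
    data.frame(taxon = traits$taxon, group = traits$group,
               trophic = traits$trophic, stringsAsFactors = FALSE)
  } else NULL
  net <- build_cooccurrence_network(pc$r, pc$p, r_min = r_min,
                                    p_max = p_max,
                                    adjust = match.arg(adjust),
                                    node_info = node_info)
  net$params$method <- pc$method
  net$params$min_prevalence <- min_prevalence
  net
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(paste0("cooccurrence_network: %d nodes, %d links ",
                     "(%d positive, %d negative)\n"),
              nrow(x$nodes), x$summary$total_links,
              x$summary$positive_links, x$summary$negative_links))
  cat(sprintf("thresholds: |r| >= %g, p <= %g (adjust: %s)\n",
              x$params$r_min, x$params$p_max, x$params$adjust))
  invisible(x)
}

#' @export
summary.cooccurrence_network <- function(object, ...) {
  c(object$summary, object$params)
}

#' Node centrality scores
#'
#' Degree, betweenness or eigenvector centrality of the network nodes.
#' Node importance (size in the usual visualisation) is proportional to
#' the score; the top-ranked node is the network's keystone candidate.
#'
#' @param net A `cooccurrence_network`.
#' @param measure `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @return Named numeric vector of scores >= 0 (isolated nodes score 0
#'   under degree). Eigenvector centrality on an edgeless graph is
#'   undefined and returns all `NA`.
#' @export
network_centrality <- function(net, measure = c("degree", "betweenness",
                                                "eigenvector")) {
  measure <- match.arg(measure)
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  switch(measure,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE),
    eigenvector = {
      if (igraph::ecount(g) == 0L) {
        warning("eigenvector centrality undefined on an edgeless graph",
                call. = FALSE)
        stats::setNames(rep(NA_real_, igraph::vcount(g)),
                        igraph::V(g)$name)
      } else {
        igraph::eigen_centrality(g)$vector
      }
    })
}

#' Keystone taxa
#'
#' Top-`k` taxa by centrality score; ties are broken lexicographically by
#' taxon id so the ranking is deterministic.
#'
#' @param net A `cooccurrence_network`.
#' @param scores Named scores from [network_centrality()]; computed with
#'   the default degree measure when omitted.
#' @param top_k How many taxa to return (>= 1).
#' @return `data.frame` with `taxon`, `score`, ranked.
#' @export
keystone_taxa <- function(net, scores = NULL, top_k = 5L) {
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (is.null(scores)) scores <- network_centrality(net, "degree")
  ord <- order(-scores, names(scores))
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(taxon = names(scores)[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Write a network to disk
#'
#' Emits GraphML (via igraph), an edge-list CSV (`source`, `target`, `r`,
#' `p`, `sign`), a node table CSV (taxon, labels, degree) and a JSON
#' summary of link counts and thresholds.
#'
#' @param net A `cooccurrence_network`.
#' @param dir Output directory (created if absent).
#' @param name Basename for the four files.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_network <- function(net, dir, name = "network") {
  stopifnot(inherits(net, "cooccurrence_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(graphml = file.path(dir, paste0(name, ".graphml")),
             edges = file.path(dir, paste0(name, "_edges.csv")),
             nodes = file.path(dir, paste0(name, "_nodes.csv")),
             summary = file.path(dir, paste0(name, "_summary.json")))
  igraph::write_graph(net$graph, paths["graphml"], format = "graphml")
  write_delimited(net$edges, paths["edges"])
  write_delimited(net$nodes, paths["nodes"])
  jsonlite::write_json(c(net$summary, net$params), paths["summary"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
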