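#' Construct a community table
#'
#' A community table is a samples-by-taxa non-negative abundance matrix with
#' per-sample metadata and a declared unit. Nematode tables are expected in
#' individuals per 100 g dry soil ([normalize_per_100g_dry()]); microbial
#' tables may be raw read counts or relative abundances.
#'
#' @param abundance Numeric matrix, samples in rows (rownames are sample
#'   ids), taxa in columns (colnames are taxon ids). No missing cells, all
#'   entries >= 0.
#' @param metadata Optional `data.frame` with a `sample_id` column matching
#'   the matrix rownames, typically also `treatment` and `replicate`, plus
#'   soil covariates (SM, SOC, TN, TP, AP, pH, BD). If `NULL`, a minimal
#'   frame holding only `sample_id` is created.
#' @param unit One of `"count_per_100g_dry"`, `"raw_count"`, `"relative"`.
#'   Relative tables must have rows summing to 1 (tolerance 1e-9).
#' @return An object of class `community_table`: a list with elements
#'   `abundance`, `metadata`, `unit`.
#' @examples
#' m <- matrix(c(10, 5, 0, 2, 8, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("Acrobeles", "Aphelenchus",
#'                                              "Meloidogyne")))
#' community_table(m, unit = "count_per_100g_dry")
#' @export
community_table <- function(abundance,
                            metadata = NULL,
                            unit = c("count_per_100g_dry", "raw_count",
                                     "relative")) {
  unit <- match.arg(unit)
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- paste0("sample", seq_len(nrow(abundance)))
  }
  if (is.null(colnames(abundance))) {
    stop("abundance matrix must have taxon ids as column names",
         call. = FALSE)
  }
  if (anyNA(abundance)) stop("abundance matrix has missing cells",
                             call. = FALSE)
  if (any(abundance < 0)) {
    stop("negative abundance in sample(s): ",
         paste(rownames(abundance)[apply(abundance < 0, 1L, any)],
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rownames(abundance))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(abundance))) {
    stop("duplicate taxon ids", call. = FALSE)
  }
  if (unit == "relative") {
    rs <- rowSums(abundance)
    bad <- abs(rs - 1) > 1e-9
    if (any(bad)) {
      stop("relative-abundance rows must sum to 1; offending sample(s): ",
           paste(rownames(abundance)[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(abundance),
                           stringsAsFactors = FALSE)
  } else {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) {
      stop("metadata must have a sample_id column", call. = FALSE)
    }
    metadata$sample_id <- as.character(metadata$sample_id)
    if (anyDuplicated(metadata$sample_id)) {
      stop("duplicate sample ids in metadata", call. = FALSE)
    }
    idx <- match(rownames(abundance), metadata$sample_id)
    if (anyNA(idx)) {
      stop("metadata missing sample(s): ",
           paste(rownames(abundance)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    metadata <- metadata[idx, , drop = FALSE]
    rownames(metadata) <- NULL
    if ("SM" %in% names(metadata)) {
      sm <- metadata$SM
      if (any(!is.na(sm) & (sm < 0 | sm >= 1))) {
        stop("soil moisture fraction SM must lie in [0, 1)", call. = FALSE)
      }
    }
  }
  structure(list(abundance = abundance, metadata = metadata, unit = unit),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa (unit: %s)\n",
              nrow(x$abundance), ncol(x$abundance), x$unit))
  if ("treatment" %in% names(x$metadata)) {
    tab <- table(x$metadata$treatment)
    cat("treatments:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$abundance)

#' Read a community table from delimited text
#'
#' First column must be the sample id; remaining columns are taxa. Comma
#' vs tab dialect is chosen by extension (`.csv` vs `.tsv`/anything else).
#'
#' @param path Path to the matrix file.
#' @param unit Declared unit of the abundances (see [community_table()]).
#' @param metadata Optional path to a sample-metadata CSV/TSV keyed by
#'   `sample_id`, or a `data.frame`.
#' @return A [community_table()].
#' @export
read_community_table <- function(path,
                                 unit = c("count_per_100g_dry", "raw_count",
                                          "relative"),
                                 metadata = NULL) {
  unit <- match.arg(unit)
  df <- read_delimited(path)
  if (ncol(df) < 2L) stop("community table needs sample_id + >= 1 taxon",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  mat <- df[-1L]
  non_numeric <- !vapply(mat, is.numeric, logical(1L))
  if (any(non_numeric)) {
    stop("non-numeric abundance column(s): ",
         paste(names(mat)[non_numeric], collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(mat)
  rownames(mat) <- ids
  if (!is.null(metadata) && !is.data.frame(metadata)) {
    metadata <- read_delimited(metadata)
  }
  community_table(mat, metadata = metadata, unit = unit)
}

#' Write a community table to delimited text
#'
#' Writes the abundance matrix with a leading `sample_id` column so that
#' [read_community_table()] round-trips it exactly; the full numeric
#' precision is preserved.
#'
#' @param table A [community_table()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(sample_id = rownames(table$abundance),
                   table$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delimited(df, path)
}

#' Convert raw nematode counts to individuals per 100 g dry soil
#'
#' Field counts come from a known fresh-soil mass with a measured moisture
#' fraction; reporting per 100 g dry soil makes samples with different
#' moisture comparable.
#'
#' @param count Non-negative count(s) extracted from the soil aliquot.
#' @param fresh_mass_g Fresh mass of the aliquot in grams (> 0).
#' @param moisture_fraction Gravimetric moisture as a fraction in `[0, 1)`.
#' @return `count * 100 / (fresh_mass_g * (1 - moisture_fraction))`, i.e.
#'   individuals per 100 g dry soil. Vectorised over `count`.
#' @examples
#' normalize_per_100g_dry(50, 100, 0.20)  # 62.5
#' @export
normalize_per_100g_dry <- function(count, fresh_mass_g, moisture_fraction) {
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  if (any(fresh_mass_g <= 0)) stop("fresh_mass_g must be > 0", call. = FALSE)
  if (any(moisture_fraction < 0 | moisture_fraction >= 1)) {
    stop("moisture_fraction must lie in [0, 1)", call. = FALSE)
  }
  count * 100 / (fresh_mass_g * (1 - moisture_fraction))
}

#' Per-sample abundance totals by nematode trophic group
#'
#' Sums abundances over the four feeding guilds: bacterivorous (BF),
#' fungivorous (FF), plant-parasitic (PP) and omnivorous-predatory (OP).
#' Totals conserve abundance: their sum equals the row sum over nematode
#' taxa exactly.
#'
#' @param table A [community_table()] of nematode abundances.
#' @param traits Trait table ([read_trait_table()]) annotating every taxon
#'   in `table`; missing nematode annotations are an error.
#' @return A `data.frame` with columns `sample_id`, `BF`, `FF`, `PP`, `OP`.
#' @export
aggregate_trophic <- function(table, traits) {
  stopifnot(inherits(table, "community_table"))
  tr <- match_traits(colnames(table$abundance), traits, organism = "nematode")
  groups <- c("BF", "FF", "PP", "OP")
  out <- sapply(groups, function(g) {
    cols <- tr$trophic == g
    if (!any(cols)) return(rep(0, nrow(table$abundance)))
    rowSums(table$abundance[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(table$abundance),
                dimnames = list(NULL, groups))
  data.frame(sample_id = rownames(table$abundance), out,
             stringsAsFactors = FALSE)
}

# Shared delimited-text helpers: dialect by extension, UTF-8, header row.
#' @keywords internal
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

#' @keywords internal
write_delimited <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # print doubles at full precision so numeric round-trips are exact
  for (cn in names(df)) {
    if (is.double(df[[cn]])) {
      v <- formatC(df[[cn]], digits = 17, format = "g")
      v[is.na(df[[cn]])] <- "NA"
      df[[cn]] <- v
    }
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
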