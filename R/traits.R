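#' Read a taxon trait table
#'
#' Reads a delimited trait table annotating each genus with its organism
#' group, nematode trophic group, colonizer-persister (c-p) value and fresh
#' body mass. These annotations drive every downstream index: trophic
#' aggregation, maturity indices, metabolic footprints and the faunal
#' profile.
#'
#' The file must have a header with columns `taxon`, `group`, `trophic`,
#' `cp`, `mass_ug`. `group` is one of `bacteria`, `fungi`, `nematode`.
#' For nematodes, `trophic` is one of `BF` (bacterivorous), `FF`
#' (fungivorous), `PP` (plant-parasitic), `OP` (omnivorous-predatory),
#' `cp` is an integer in 1..5 and `mass_ug` is the fresh body weight of one
#' individual in micrograms. For microbes `trophic` must be `none` and
#' `cp`/`mass_ug` empty (NA).
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file, UTF-8,
#'   first row a header.
#' @return A `data.frame` with columns `taxon`, `group`, `trophic`, `cp`,
#'   `mass_ug`, one row per taxon, validated (unique taxa, c-p in range,
#'   positive masses).
#' @seealso [default_trait_fixture()] for a ready-made synthetic table,
#'   [aggregate_trophic()] for its first consumer.
#' @export
read_trait_table <- function(path) {
  df <- read_delimited(path)
  required <- c("taxon", "group", "trophic", "cp", "mass_ug")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$taxon <- as.character(df$taxon)
  df$group <- as.character(df$group)
  df$trophic <- as.character(df$trophic)
  df$cp <- suppressWarnings(as.integer(df$cp))
  df$mass_ug <- suppressWarnings(as.numeric(df$mass_ug))
  validate_traits(df)
}

#' @keywords internal
validate_traits <- function(df) {
  dup <- df$taxon[duplicated(df$taxon)]
  if (length(dup) > 0L) {
    stop("duplicate taxon id(s) in trait table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(df$group), c("bacteria", "fungi", "nematode"))
  if (length(bad_group) > 0L) {
    stop("unknown organism group(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  is_nema <- df$group == "nematode"
  bad_trophic <- df$trophic[is_nema & !df$trophic %in% c("BF", "FF", "PP", "OP")]
  if (length(bad_trophic) > 0L) {
    stop("nematode trophic group must be one of BF, FF, PP, OP; got: ",
         paste(unique(bad_trophic), collapse = ", "), call. = FALSE)
  }
  if (any(!is_nema & df$trophic != "none")) {
    bad <- df$taxon[!is_nema & df$trophic != "none"]
    stop("microbial taxa must have trophic 'none': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is_nema & (is.na(df$cp) | df$cp < 1L | df$cp > 5L))) {
    bad <- df$taxon[is_nema & (is.na(df$cp) | df$cp < 1L | df$cp > 5L)]
    stop("c-p value must be an integer in 1..5 for nematode taxa: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is_nema & !is.na(df$cp))) {
    stop("c-p values are defined for nematodes only", call. = FALSE)
  }
  if (any(is_nema & (is.na(df$mass_ug) | df$mass_ug <= 0))) {
    bad <- df$taxon[is_nema & (is.na(df$mass_ug) | df$mass_ug <= 0)]
    stop("body mass (mass_ug) must be > 0 for nematode taxa: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is_nema & !is.na(df$mass_ug))) {
    stop("body masses are defined for nematodes only", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a trait table
#'
#' Inverse of [read_trait_table()]; dialect (comma vs tab) follows the file
#' extension.
#'
#' @param traits Trait `data.frame` as returned by [read_trait_table()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  write_delimited(traits, path)
}

# Look up trait rows for a set of taxa, enforcing the annotation policy:
# unannotated nematode-table taxa are an error; unannotated microbial taxa
# are a warning and are treated as trophic 'none'.
#' @keywords internal
match_traits <- function(taxa, traits, organism = "nematode") {
  idx <- match(taxa, traits$taxon)
  if (anyNA(idx)) {
    missing <- taxa[is.na(idx)]
    if (organism == "nematode") {
      stop("nematode taxa missing from trait table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    warning("taxa missing from trait table treated as trophic 'none': ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(taxon = taxa,
                    group = NA_character_, trophic = "none",
                    cp = NA_integer_, mass_ug = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- !is.na(idx)
  out[ok, c("group", "trophic", "cp", "mass_ug")] <-
    traits[idx[ok], c("group", "trophic", "cp", "mass_ug")]
  out
}
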