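#' Synthetic taxon trait table
#'
#' A built-in trait fixture for simulation and examples: 26 nematode
#' genera spanning all four trophic groups and every c-p class used by
#' the enrichment/structure components (BF 1-5, FF 2-5, OP 3-5, PP 2-5),
#' plus 42 bacterial and 24 fungal genera. Genus names are real soil
#' taxa; the c-p values and fresh body masses are synthetic fixture
#' values chosen at realistic magnitudes (microbivores a fraction of a
#' µg, large omnivore-predators several µg), not measured trait data.
#'
#' @return Trait `data.frame` as from [read_trait_table()].
#' @export
default_trait_fixture <- function() {
  nema <- data.frame(
    taxon = c("Mesorhabditis", "Rhabditis", "Panagrolaimus",
              "Acrobeles", "Acrobeloides", "Eucephalobus", "Chiloplacus",
              "Cephalobus", "Plectus", "Wilsonema",
              "Prismatolaimus", "Teratocephalus", "Alaimus", "Isolaimium",
              "Bathyodontus",
              "Aphelenchus", "Aphelenchoides", "Filenchus",
              "Diphtherophora", "Tylencholaimus", "Dorylaimoides",
              "Paratylenchus", "Basiria", "Aglenchus",
              "Meloidogyne", "Pratylenchus", "Helicotylenchus",
              "Hoplolaimus", "Trichodorus", "Xiphinema",
              "Tripyla", "Mononchus", "Eudorylaimus", "Mesodorylaimus",
              "Aporcelaimellus", "Discolaimus"),
    group = "nematode",
    trophic = c(rep("BF", 15),
                rep("FF", 6),
                rep("PP", 9),
                rep("OP", 6)),
    cp = c(1L, 1L, 1L,
           2L, 2L, 2L, 2L, 2L, 2L, 2L,
           3L, 3L, 4L, 4L, 5L,
           2L, 2L, 2L, 3L, 4L, 5L,
           2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 5L,
           3L, 4L, 4L, 4L, 5L, 5L),
    mass_ug = c(0.25, 0.60, 0.52,
                0.32, 0.18, 0.40, 0.45, 0.35, 0.55, 0.12,
                0.38, 0.20, 0.30, 0.90, 1.10,
                0.28, 0.15, 0.14, 0.32, 0.35, 0.60,
                0.06, 0.12, 0.10, 0.25, 0.22, 0.40, 1.20, 0.45, 3.80,
                1.00, 3.50, 1.80, 1.20, 6.50, 3.00),
    stringsAsFactors = FALSE)
  bact <- data.frame(
    taxon = c("Nocardioides", "Massilia", "Arthrobacter", "Microvirga",
              "Blastococcus", "Nitrospira", "Bacillus", "Pirellula",
              "Pir4_lineage", "MND1", "RB41", "Subgroup_10",
              "Streptomyces", "Pseudomonas", "Sphingomonas", "Rhizobium",
              "Bradyrhizobium", "Mesorhizobium", "Flavobacterium",
              "Pedobacter", "Chitinophaga", "Gemmatimonas",
              "Solirubrobacter", "Rubrobacter", "Actinomadura",
              "Micromonospora", "Mycobacterium", "Paenibacillus",
              "Lysobacter", "Variovorax", "Ramlibacter", "Skermanella",
              "Geodermatophilus", "Kribbella", "Terrabacter", "Agromyces",
              "Devosia", "Hyphomicrobium", "Nitrosospira",
              "Steroidobacter", "Haliangium", "Opitutus"),
    group = "bacteria", trophic = "none",
    cp = NA_integer_, mass_ug = NA_real_, stringsAsFactors = FALSE)
  fung <- data.frame(
    taxon = c("Leohumicola", "Ascochyta", "Ramophialophora", "Lectera",
              "Alternaria", "Acremonium", "Leptosphaeria", "Articulospora",
              "Pyrenochaeta", "Volvariella", "Lecythophora", "Pterula",
              "Solicoccozyma", "Clitopilus", "Gibberella", "Metarhizium",
              "Entoloma", "Setophoma", "Chaetomium", "Glarea",
              "Fusarium", "Mortierella", "Penicillium", "Trichoderma"),
    group = "fungi", trophic = "none",
    cp = NA_integer_, mass_ug = NA_real_, stringsAsFactors = FALSE)
  validate_traits(rbind(nema, bact, fung))
}

#' Configuration for the community simulator
#'
#' Defines the simulated field design: an unreplanted control plus a
#' chronosequence of treatments, each with `n_replicates` plots. The
#' treatment effect enters as per-trophic-group multipliers on mean
#' nematode abundance; the defaults encode the study conditions the
#' package targets — the plant-parasitic footprint declines and the
#' omnivorous-predatory footprint rises along the chronosequence, the
#' fungivore footprint is highest in the control — together with soil
#' covariate trends (moisture declining, organic carbon and total
#' nitrogen rising, available phosphorus declining).
#'
#' Counts are drawn negative-binomially (mean `mu`, variance
#' `mu + dispersion * mu^2`); covariates get multiplicative log-normal
#' noise. Correlated taxon pairs are planted through a shared latent
#' log-normal factor (sign-flipped for negative pairs) so the
#' co-occurrence stage has known edges to find.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of it.
#' @param treatments Ordered treatment labels.
#' @param n_replicates Replicates per treatment (>= 2).
#' @param multipliers Numeric matrix, trophic groups (BF, FF, PP, OP) by
#'   treatment: per-treatment scaling of mean abundance.
#' @param dispersion Negative-binomial overdispersion (> 0).
#' @param n_correlated_pairs Number of planted correlated microbial
#'   pairs; signs alternate +, +, - so roughly a third are negative.
#' @param latent_sd Standard deviation of the shared latent factor for
#'   planted pairs.
#' @param covariate_trends `data.frame` of per-treatment covariate means
#'   (rows = treatments) for SM, SOC, TN, TP, AP, pH, BD.
#' @param traits Trait table to simulate from; defaults to
#'   [default_trait_fixture()].
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             treatments = c("CK", "Y2", "Y9", "Y18"),
                             n_replicates = 3L,
                             multipliers = NULL,
                             dispersion = 0.5,
                             n_correlated_pairs = 6L,
                             latent_sd = 0.8,
                             covariate_trends = NULL,
                             traits = default_trait_fixture()) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (is.null(multipliers)) {
    multipliers <- rbind(
      BF = c(1.0, 1.0, 1.0, 1.0),
      FF = c(1.6, 0.8, 0.8, 0.8),
      PP = c(1.0, 1.2, 0.5, 0.35),
      OP = c(0.4, 0.5, 1.2, 1.5))
    colnames(multipliers) <- c("CK", "Y2", "Y9", "Y18")
    multipliers <- multipliers[, treatments, drop = FALSE]
  }
  if (any(multipliers <= 0)) stop("multipliers must be > 0",
                                  call. = FALSE)
  if (!all(c("BF", "FF", "PP", "OP") %in% rownames(multipliers)) ||
      !identical(colnames(multipliers), treatments)) {
    stop("multipliers must be a (BF, FF, PP, OP) x treatments matrix",
         call. = FALSE)
  }
  if (is.null(covariate_trends)) {
    covariate_trends <- data.frame(
      treatment = c("CK", "Y2", "Y9", "Y18"),
      SM  = c(0.18, 0.16, 0.14, 0.12),
      SOC = c(7.5, 8.5, 11.0, 14.0),
      TN  = c(0.80, 0.95, 1.10, 1.30),
      TP  = c(0.85, 0.75, 0.80, 0.65),
      AP  = c(18.0, 14.0, 9.0, 7.0),
      pH  = c(8.40, 8.40, 8.40, 8.40),
      BD  = c(1.25, 1.25, 1.25, 1.25),
      stringsAsFactors = FALSE)
    covariate_trends <-
      covariate_trends[match(treatments, covariate_trends$treatment), ]
    if (anyNA(covariate_trends$treatment)) {
      stop("no default covariate trends for treatments outside ",
           "CK/Y2/Y9/Y18; supply covariate_trends", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), treatments = treatments,
                 n_replicates = as.integer(n_replicates),
                 multipliers = multipliers, dispersion = dispersion,
                 n_correlated_pairs = as.integer(n_correlated_pairs),
                 latent_sd = latent_sd,
                 covariate_trends = covariate_trends, traits = traits),
            class = "synthetic_config")
}

#' Simulate a study-shaped micro-food-web data set
#'
#' Draws nematode, bacterial and fungal genus abundance tables plus
#' sample metadata for the replicated multi-treatment design described by
#' a [synthetic_config()]. The same config (including seed) always
#' produces bit-identical output.
#'
#' Per-taxon baseline mean abundances are drawn once (log-normally,
#' around 20 per 100 g dry soil for nematode genera, 500 reads for
#' bacteria, 200 for fungi), scaled by the treatment multiplier of the
#' taxon's trophic group (nematodes) and by the latent pair factors, then
#' counts are drawn negative-binomially.
#'
#' @param config A [synthetic_config()].
#' @return List with `nematodes`, `bacteria`, `fungi` (each a
#'   [community_table()] sharing sample metadata), `metadata`
#'   (`data.frame`), `traits`, `planted_pairs` (`data.frame` of the
#'   planted correlated pairs with their signs) and `expected_mu` (the
#'   latent negative-binomial mean matrices, for diagnostics).
#' @export
simulate_foodweb <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  traits <- config$traits
  nema_tax <- traits[traits$group == "nematode", ]
  bact_tax <- traits$taxon[traits$group == "bacteria"]
  fung_tax <- traits$taxon[traits$group == "fungi"]

  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      treatment = config$treatments,
                      stringsAsFactors = FALSE)[, 2:1]
  meta$sample_id <- paste(meta$treatment, meta$replicate, sep = "_")
  n <- nrow(meta)
  cov <- config$covariate_trends[match(meta$treatment,
                                       config$covariate_trends$treatment),
                                 -1L, drop = FALSE]
  for (cn in names(cov)) {
    noise <- if (cn == "pH") stats::rnorm(n, 0, 0.05) else
      cov[[cn]] * (exp(stats::rnorm(n, 0, 0.05)) - 1)
    cov[[cn]] <- cov[[cn]] + noise
  }
  cov$SM <- pmin(pmax(cov$SM, 0), 0.999)
  meta <- cbind(meta[c("sample_id", "treatment", "replicate")], cov)
  rownames(meta) <- NULL

  size <- 1 / config$dispersion
  base_nema <- stats::setNames(
    stats::rlnorm(nrow(nema_tax), log(20), 0.8), nema_tax$taxon)
  base_bact <- stats::setNames(
    stats::rlnorm(length(bact_tax), log(500), 1.0), bact_tax)
  base_fung <- stats::setNames(
    stats::rlnorm(length(fung_tax), log(200), 1.0), fung_tax)

  # planted correlated pairs among microbial taxa; signs +, +, -, ...
  pairs <- NULL
  latent <- matrix(0, n, 0L)
  if (config$n_correlated_pairs > 0L) {
    pool <- c(bact_tax, fung_tax)
    need <- 2L * config$n_correlated_pairs
    if (need > length(pool)) stop("too many correlated pairs for the ",
                                  "available microbial taxa",
                                  call. = FALSE)
    chosen <- pool[seq_len(need)]
    pairs <- data.frame(
      taxon1 = chosen[seq(1L, need, by = 2L)],
      taxon2 = chosen[seq(2L, need, by = 2L)],
      sign = rep_len(c("positive", "positive", "negative"),
                     config$n_correlated_pairs),
      stringsAsFactors = FALSE)
    latent <- matrix(stats::rnorm(n * config$n_correlated_pairs, 0,
                                  config$latent_sd),
                     n, config$n_correlated_pairs)
  }

  draw <- function(mu_mat) {
    counts <- matrix(stats::rnbinom(length(mu_mat), size = size,
                                    mu = as.vector(mu_mat)),
                     nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
    counts
  }

  mult <- config$multipliers[nema_tax$trophic,
                             meta$treatment, drop = FALSE]
  mu_nema <- t(mult * base_nema[nema_tax$taxon])  # samples x taxa
  dimnames(mu_nema) <- list(meta$sample_id, nema_tax$taxon)

  mu_bact <- matrix(base_bact, n, length(bact_tax), byrow = TRUE,
                    dimnames = list(meta$sample_id, bact_tax))
  mu_fung <- matrix(base_fung, n, length(fung_tax), byrow = TRUE,
                    dimnames = list(meta$sample_id, fung_tax))
  if (!is.null(pairs)) {
    mu_all <- cbind(mu_bact, mu_fung)
    for (q in seq_len(nrow(pairs))) {
      flip <- if (pairs$sign[q] == "positive") 1 else -1
      mu_all[, pairs$taxon1[q]] <-
        mu_all[, pairs$taxon1[q]] * exp(latent[, q])
      mu_all[, pairs$taxon2[q]] <-
        mu_all[, pairs$taxon2[q]] * exp(flip * latent[, q])
    }
    mu_bact <- mu_all[, bact_tax, drop = FALSE]
    mu_fung <- mu_all[, fung_tax, drop = FALSE]
  }

  list(nematodes = community_table(draw(mu_nema), metadata = meta,
                                   unit = "count_per_100g_dry"),
       bacteria = community_table(draw(mu_bact), metadata = meta,
                                  unit = "raw_count"),
       fungi = community_table(draw(mu_fung), metadata = meta,
                               unit = "raw_count"),
       metadata = meta, traits = traits, planted_pairs = pairs,
       expected_mu = list(nematodes = mu_nema, bacteria = mu_bact,
                          fungi = mu_fung))
}
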