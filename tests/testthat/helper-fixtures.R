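# Small in-code fixtures shared across tests.

toy_traits <- function() {
  data.frame(
    taxon = c("bf1", "bf2", "bf2b", "bf3", "bf4", "bf5",
              "ff2", "ff3", "pp2", "pp3", "op4", "op5",
              "BacA", "BacB", "FunA"),
    group = c(rep("nematode", 12), "bacteria", "bacteria", "fungi"),
    trophic = c("BF", "BF", "BF", "BF", "BF", "BF",
                "FF", "FF", "PP", "PP", "OP", "OP",
                "none", "none", "none"),
    cp = c(1L, 2L, 2L, 3L, 4L, 5L, 2L, 3L, 2L, 3L, 4L, 5L,
           NA, NA, NA),
    mass_ug = c(0.5, 0.4, 0.3, 0.6, 0.8, 1.0, 0.25, 0.35, 0.1, 0.3,
                2.0, 4.0, NA, NA, NA),
    stringsAsFactors = FALSE)
}

toy_table <- function(abundance, taxa = NULL, ids = NULL,
                      unit = "count_per_100g_dry", metadata = NULL) {
  m <- as.matrix(abundance)
  if (!is.null(taxa)) colnames(m) <- taxa
  if (!is.null(ids)) rownames(m) <- ids
  community_table(m, metadata = metadata, unit = unit)
}

# All permutations of 1..n (for exact rank-permutation oracles).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact two-sided permutation p-value for a Spearman correlation.
perm_spearman_p <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  P <- all_perms(length(x))
  rhos <- apply(P, 1L, function(p) cor(x[p], y, method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
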