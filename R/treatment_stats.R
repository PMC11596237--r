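#' One-way ANOVA with protected LSD compact letters
#'
#' Classical one-way ANOVA across treatment groups followed, when the
#' omnibus test is significant at `alpha`, by Fisher's least significant
#' difference: pairwise t-tests on the pooled within-group mean square.
#' Group letters are assembled with the insert-and-absorb algorithm,
#' processing groups in descending mean order, so groups sharing a letter
#' are not significantly different by LSD. When the omnibus test is not
#' significant the LSD stage is skipped (protected LSD) and every group
#' shares the letter "a".
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; every group needs
#'   >= 2 observations.
#' @param alpha Significance level, default 0.05.
#' @return Object of class `group_comparison`: list with `table`
#'   (group, n, mean, se, letter — ordered by descending mean), `F`, `p`,
#'   `df`, `alpha`, and the pairwise LSD p-value matrix `pairwise_p`.
#' @examples
#' anova_lsd(c(1, 1.1, 0.9, 5, 5.1, 4.9, 9, 9.1, 8.9),
#'           rep(c("CK", "Y2", "Y9"), each = 3))
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  n_i <- table(groups)
  if (length(n_i) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(n_i < 2L)) {
    stop("every group needs >= 2 values; too few in: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "), call. = FALSE)
  }
  if (stats::var(values) == 0) {
    # constant response: no variation to test, all groups share a letter
    means <- tapply(values, groups, mean)
    g <- names(means)
    tab <- data.frame(group = g, n = as.integer(n_i[g]),
                      mean = unname(means[g]), se = 0, letter = "a",
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, F = NA_real_, p = NA_real_,
                          df = c(length(g) - 1L,
                                 length(values) - length(g)),
                          mse = 0, alpha = alpha,
                          pairwise_p = matrix(NA_real_, length(g),
                                              length(g),
                                              dimnames = list(g, g))),
                     class = "group_comparison"))
  }
  fit <- stats::lm(values ~ factor(groups))
  av <- stats::anova(fit)
  f_stat <- av$`F value`[1L]
  p_val <- av$`Pr(>F)`[1L]
  mse <- av$`Mean Sq`[2L]
  df_resid <- av$Df[2L]

  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  ord <- order(-means)
  g <- names(means)[ord]
  k <- length(g)

  pw <- matrix(NA_real_, k, k, dimnames = list(g, g))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      se_diff <- sqrt(mse * (1 / n_i[[g[i]]] + 1 / n_i[[g[j]]]))
      tt <- (means[[g[i]]] - means[[g[j]]]) / se_diff
      pw[i, j] <- pw[j, i] <- 2 * stats::pt(-abs(tt), df_resid)
    }
  }
  sig_pair <- !is.na(pw) & pw <= alpha
  if (is.na(p_val) || p_val > alpha) sig_pair[] <- FALSE  # protected LSD

  letters_vec <- insert_absorb_letters(g, sig_pair)
  tab <- data.frame(group = g,
                    n = as.integer(n_i[g]),
                    mean = unname(means[g]),
                    se = unname(sds[g] / sqrt(as.integer(n_i[g]))),
                    letter = letters_vec,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, F = f_stat, p = p_val, df = av$Df,
                 mse = mse, alpha = alpha, pairwise_p = pw),
            class = "group_comparison")
}

# Insert-and-absorb compact letter display. `g` is the group ordering
# (descending mean); `sig` a logical matrix over that ordering marking
# significantly different pairs. Each letter column is the set of groups
# allowed to share that letter; a significant pair splits every column
# containing both, and columns that become subsets of others are absorbed.
#' @keywords internal
insert_absorb_letters <- function(g, sig) {
  cols <- list(g)  # start: one column holding all groups
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (j <= i || !sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (g[i] %in% col && g[j] %in% col) {
          cols[[ci]] <- setdiff(col, g[j])
          cols <- c(cols, list(setdiff(col, g[i])))
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] %in% cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by the first (highest-mean) group they contain
  first <- vapply(cols, function(cl) min(match(cl, g)), numeric(1L))
  cols <- cols[order(first)]
  vapply(g, function(gr) {
    paste0(letters[which(vapply(cols, function(cl) gr %in% cl,
                                logical(1L)))], collapse = "")
  }, character(1L))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (alpha = %g)\n",
              x$df[1L], x$df[2L], x$F, x$p, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Treatment comparisons for a table of indices
#'
#' Runs [anova_lsd()] for each requested column of a per-sample result
#' table (indices or footprints) against its `treatment` column.
#'
#' @param df Per-sample `data.frame` with a `treatment` column.
#' @param columns Which numeric columns to compare; defaults to all
#'   numeric columns.
#' @param alpha Significance level.
#' @return Named list of `group_comparison` objects (columns whose groups
#'   are degenerate, e.g. all-NA, are skipped with a warning).
#' @export
compare_treatments <- function(df, columns = NULL, alpha = 0.05) {
  if (!"treatment" %in% names(df)) {
    stop("df must have a treatment column", call. = FALSE)
  }
  if (is.null(columns)) {
    columns <- names(df)[vapply(df, is.numeric, logical(1L))]
    columns <- setdiff(columns, c("replicate"))
    columns <- columns[!grepl("^v[1-4]_[xy]$", columns)]
  }
  out <- list()
  for (cl in columns) {
    res <- tryCatch(anova_lsd(df[[cl]], df$treatment, alpha = alpha),
                    error = function(e) {
                      warning("skipping ", cl, ": ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) out[[cl]] <- res
  }
  out
}
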