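# Group statistics: one-way ANOVA, LSD post-hoc letters, correlations.

# Insert-absorb compact letter display. `sig` is a symmetric logical
# matrix (TRUE = significantly different) with group names; `means` is
# used only to order letters so 'a' marks the highest-mean group.
compact_letters <- function(sig, means) {
  groups <- rownames(sig)
  ord <- groups[order(-means[groups])]
  letters_sets <- list(ord)  # start with one letter covering all groups
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      g1 <- ord[i]; g2 <- ord[j]
      if (!sig[g1, g2]) next
      # split every letter containing both members of a significant pair
      k <- 1L
      while (k <= length(letters_sets)) {
        s <- letters_sets[[k]]
        if (all(c(g1, g2) %in% s)) {
          letters_sets[[k]] <- setdiff(s, g1)
          letters_sets[[length(letters_sets) + 1L]] <- setdiff(s, g2)
        }
        k <- k + 1L
      }
      # absorb letters that are subsets of another letter
      keep <- rep(TRUE, length(letters_sets))
      for (a in seq_along(letters_sets)) {
        for (b in seq_along(letters_sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(letters_sets[[a]] %in% letters_sets[[b]]) &&
              (length(letters_sets[[a]]) < length(letters_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      letters_sets <- letters_sets[keep]
    }
  }
  # order letters by their highest-mean member, then assign a, b, c, ...
  firsts <- vapply(letters_sets, function(s) min(match(s, ord)), 0)
  letters_sets <- letters_sets[order(firsts)]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(letters_sets)) {
    for (g in letters_sets[[k]]) {
      out[g] <- paste0(out[g], letters[k])
    }
  }
  out[ord]
}

#' Group means, one-way ANOVA and LSD letter groups
#'
#' The standard summary for a replicated agronomy trial: per-group means
#' and SDs, the one-way ANOVA F test, and pairwise least-significant-
#' difference comparisons at `alpha` rendered as a compact letter display
#' (groups sharing a letter are not significantly different; 'a' marks
#' the highest mean).
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 groups, >= 2 replicates each).
#' @param alpha significance level for the LSD test (default 0.05).
#' @return List: `means` (data frame with `group`, `mean`, `sd`, `n`,
#'   `letters`), `anova` (`F`, `p`, dfs, `mse`), `pairwise` (data frame
#'   of differences and p-values).
#' @export
group_stats <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  n_by <- tapply(values, groups, length)
  if (any(n_by < 2)) stop("every group needs at least 2 replicates")
  within_var <- tapply(values, groups, var)
  if (all(within_var == 0)) {
    stop("zero within-group variance: LSD test undefined")
  }
  fit <- aov(values ~ groups)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  if (mse <= 0) stop("zero within-group variance: LSD test undefined")
  m_by <- tapply(values, groups, mean)
  s_by <- tapply(values, groups, sd)
  lv <- levels(groups)
  pairs <- t(combn(lv, 2))
  diffs <- m_by[pairs[, 1]] - m_by[pairs[, 2]]
  se <- sqrt(mse * (1 / n_by[pairs[, 1]] + 1 / n_by[pairs[, 2]]))
  tval <- diffs / se
  pval <- 2 * pt(-abs(tval), df_err)
  sig <- matrix(FALSE, nlevels(groups), nlevels(groups),
                dimnames = list(lv, lv))
  sig[pairs] <- pval < alpha
  sig <- sig | t(sig)
  letters_by <- compact_letters(sig, m_by)
  means <- data.frame(group = names(letters_by),
                      mean = as.numeric(m_by[names(letters_by)]),
                      sd = as.numeric(s_by[names(letters_by)]),
                      n = as.integer(n_by[names(letters_by)]),
                      letters = unname(letters_by),
                      stringsAsFactors = FALSE)
  list(means = means,
       anova = list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                    df_group = an[["Df"]][1], df_error = df_err, mse = mse),
       pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                             diff = as.numeric(diffs), se = as.numeric(se),
                             t = as.numeric(tval), p = as.numeric(pval),
                             significant = as.numeric(pval) < alpha,
                             stringsAsFactors = FALSE))
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric unit-diagonal Pearson correlations between metric columns.
#' Constant columns have no defined correlation and are reported as `NA`
#' with a warning.
#'
#' @param x data frame or matrix of metrics (>= 3 rows).
#' @return Correlation matrix with entries in `[-1, 1]` or `NA`.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("at least 3 paired observations are required")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("constant column(s), correlations reported as NA: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}
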