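# Cornell-style soil health scoring with PCA-derived indicator weights.

#' Score a soil indicator on the 0-100 CSHA scale
#'
#' Cumulative-normal scoring of an indicator value against the pooled
#' sample distribution (mean and SD of all plots and timepoints scored
#' together). `more`-is-better indicators score `100 * Phi(z)`,
#' `less`-is-better `100 * (1 - Phi(z))`, and `optimum` indicators (pH)
#' take a symmetric penalty around the target:
#' `100 * (1 - |2 * Phi((x - target)/sd) - 1|)`.
#'
#' @param x indicator values.
#' @param direction `"more"`, `"less"` or `"optimum"`.
#' @param mean,sd pooled scoring-population mean and SD (`sd > 0`). For
#'   `optimum` the mean is ignored in favour of `target`.
#' @param target optimum target value (pH default 7).
#' @return Scores in `[0, 100]`.
#' @examples
#' csha_normalize(5, "more", mean = 4, sd = 1)  # 84.13
#' @export
csha_normalize <- function(x, direction = c("more", "less", "optimum"),
                           mean, sd, target = 7) {
  direction <- match.arg(direction)
  if (is.na(sd) || sd <= 0) {
    stop("degenerate indicator: pooled SD must be > 0")
  }
  score <- switch(direction,
    more = 100 * pnorm((x - mean) / sd),
    less = 100 * (1 - pnorm((x - mean) / sd)),
    optimum = 100 * (1 - abs(2 * pnorm((x - target) / sd) - 1))
  )
  pmin(100, pmax(0, score))
}

#' PCA-derived indicator weights
#'
#' Indicators are standardized to zero mean and unit variance and
#' decomposed by principal components. Components with eigenvalue > 1
#' (Kaiser criterion) are retained, capped at `max_components` (three by
#' default, mirroring the scree-plot inflection typical for a 10-indicator
#' soil dataset). Each indicator's weight is the sum of the absolute
#' values of its loadings on the retained components -- eigenvector signs
#' are arbitrary, so absolute loadings keep weights non-negative.
#'
#' @param x numeric matrix or data frame, samples x indicators.
#' @param max_components cap on the number of retained components.
#' @return List: `weights` (named, >= 0), `eigenvalues`,
#'   `explained_variance` (percent), `n_retained`, `loadings` (retained
#'   columns).
#' @export
pca_weights <- function(x, max_components = 3) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  if (ncol(x) < 2) stop("PCA needs at least 2 indicators")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate indicator(s) with zero variance: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  n_ret <- min(max(sum(ev > 1), 1), max_components, length(ev))
  loadings <- p$rotation[, seq_len(n_ret), drop = FALSE]
  w <- rowSums(abs(loadings))
  list(weights = setNames(w, colnames(x)),
       eigenvalues = ev,
       explained_variance = 100 * ev / sum(ev),
       n_retained = n_ret,
       loadings = loadings)
}

#' Overall soil health score
#'
#' Weighted average of the individual indicator scores:
#' `sum(A_j w_j) / sum(w_j)`, in percent.
#'
#' @param scores indicator CSHA scores in `[0, 100]`.
#' @param weights non-negative weights, not all zero, same length.
#' @return Overall score in `[0, 100]`.
#' @examples
#' soil_health_score(c(80, 20), c(3, 1))  # 65
#' @export
soil_health_score <- function(scores, weights) {
  if (length(scores) != length(weights)) {
    stop("scores and weights have different lengths")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  sum(scores * weights) / sum(weights)
}

#' Full soil health assessment of an indicator table
#'
#' Scores every sample of a long-format indicator table against the
#' pooled distribution (all plots and timepoints together, so scores are
#' comparable across years), derives PCA weights from the sample x
#' indicator matrix, and returns overall scores.
#'
#' @param indicators long data frame with columns `plot`, `timepoint`,
#'   `indicator`, `value` (extra metadata columns such as `rotation` are
#'   carried through).
#' @param directions named character vector over indicators
#'   (`"more"`/`"less"`/`"optimum"`).
#' @param ph_target target value for `optimum` indicators.
#' @param max_components see [pca_weights()].
#' @return List of class `"soil_health_result"`: `scores` (long, with a
#'   `score` column), `overall` (one row per sample with the weighted
#'   score), `weights`, `pca`.
#' @export
soil_health_assessment <- function(indicators, directions,
                                   ph_target = 7, max_components = 3) {
  need <- c("plot", "timepoint", "indicator", "value")
  miss <- setdiff(need, names(indicators))
  if (length(miss)) stop("indicator table is missing column(s): ",
                         paste(miss, collapse = ", "))
  miss_dir <- setdiff(unique(indicators$indicator), names(directions))
  if (length(miss_dir)) {
    stop("no direction assigned for indicator(s): ",
         paste(miss_dir, collapse = ", "))
  }
  if (anyNA(indicators$value)) stop("indicator table contains missing values")
  # wide sample x indicator matrix
  sample_id <- interaction(indicators$plot, indicators$timepoint, drop = TRUE)
  ind_names <- unique(indicators$indicator)
  wide <- matrix(NA_real_, nrow = nlevels(sample_id), ncol = length(ind_names),
                 dimnames = list(levels(sample_id), ind_names))
  wide[cbind(match(as.character(sample_id), rownames(wide)),
             match(indicators$indicator, ind_names))] <- indicators$value
  if (anyNA(wide)) stop("every scored sample needs a value for every indicator")
  pooled_mean <- colMeans(wide)
  pooled_sd <- apply(wide, 2, sd)
  scores <- wide
  for (j in ind_names) {
    scores[, j] <- csha_normalize(wide[, j], directions[[j]],
                                  mean = pooled_mean[[j]],
                                  sd = pooled_sd[[j]], target = ph_target)
  }
  pca <- pca_weights(wide, max_components = max_components)
  overall_score <- apply(scores, 1, soil_health_score, weights = pca$weights)
  first <- !duplicated(sample_id)
  meta_cols <- setdiff(names(indicators), c("indicator", "value"))
  overall <- indicators[first, meta_cols, drop = FALSE]
  overall$score <- overall_score[match(as.character(sample_id[first]),
                                       rownames(scores))]
  rownames(overall) <- NULL
  long <- indicators
  long$score <- scores[cbind(match(as.character(sample_id), rownames(scores)),
                             match(indicators$indicator, ind_names))]
  out <- list(scores = long, overall = overall,
              weights = pca$weights, pca = pca)
  class(out) <- "soil_health_result"
  out
}
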