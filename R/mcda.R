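# Entropy-weighted TOPSIS comprehensive evaluation index (CEI).

#' Min-max normalize a decision matrix
#'
#' Positive (benefit) criteria map to `(x - min)/(max - min)`, negative
#' (cost) criteria to `(max - x)/(max - min)`, so 1 is always the best
#' observed level of a criterion and 0 the worst.
#'
#' @param x alternatives x criteria numeric matrix (>= 2 alternatives).
#' @param directions character vector per criterion, `"positive"` or
#'   `"negative"`, named after or aligned with the columns.
#' @return The normalized matrix `b` with entries in `[0, 1]`.
#' @export
normalize_matrix <- function(x, directions) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 alternatives are required")
  if (anyNA(x)) stop("decision matrix contains missing cells")
  if (!is.null(names(directions)) && !is.null(colnames(x))) {
    if (!setequal(names(directions), colnames(x))) {
      stop("directions must be named after the criteria")
    }
    directions <- directions[colnames(x)]
  }
  if (length(directions) != ncol(x)) {
    stop("one direction is required per criterion")
  }
  if (!all(directions %in% c("positive", "negative"))) {
    stop('directions must be "positive" or "negative"')
  }
  b <- x
  for (j in seq_len(ncol(x))) {
    r <- range(x[, j])
    if (diff(r) == 0) {
      stop("degenerate criterion (constant across alternatives): ",
           if (!is.null(colnames(x))) colnames(x)[j] else j)
    }
    b[, j] <- if (directions[j] == "positive") {
      (x[, j] - r[1]) / diff(r)
    } else {
      (r[2] - x[, j]) / diff(r)
    }
  }
  b
}

#' Entropy weights of evaluation criteria
#'
#' Information-entropy weighting over a normalized decision matrix. For
#' criterion `j` across the `m` alternatives: proportions
#' `f_ij = b_ij / sum_i b_ij`, entropy
#' `H_j = -(1/ln m) sum_i f_ij ln f_ij` (with `0 ln 0 := 0`), and weight
#' `W_j = (1 - H_j) / sum_k (1 - H_k)`. Whenever a column contains a zero
#' the shifted proportions `f_ij = (1 + b_ij) / sum_i (1 + b_ij)` are
#' used for that whole column, keeping every `f` positive while
#' preserving `sum_i f_ij = 1`. Criteria whose values spread more across
#' alternatives (lower entropy) receive more weight.
#'
#' @param b normalized matrix from [normalize_matrix()].
#' @return List: `weights` (sums to 1), `entropy` (`H_j`), `proportions`
#'   (`f_ij`).
#' @export
entropy_weights <- function(b) {
  b <- as.matrix(b)
  m <- nrow(b)
  if (m < 2) stop("entropy weighting needs at least 2 alternatives")
  if (anyNA(b)) stop("normalized matrix contains missing cells")
  if (any(b < 0)) stop("normalized values must be non-negative")
  f <- b
  for (j in seq_len(ncol(b))) {
    col <- b[, j]
    if (any(col == 0)) col <- 1 + col
    f[, j] <- col / sum(col)
  }
  plogp <- f * log(f)
  plogp[f == 0] <- 0
  H <- -colSums(plogp) / log(m)
  d <- 1 - H
  if (sum(d) <= 0) {
    stop("all criteria are maximally entropic; weights are undefined")
  }
  w <- d / sum(d)
  list(weights = w, entropy = H, proportions = f)
}

#' TOPSIS closeness coefficients (comprehensive evaluation index)
#'
#' Builds the weighted normalized matrix `z_ij = W_j b_ij`, takes the
#' per-criterion maxima/minima as the positive and negative ideal
#' solutions, measures each alternative's Euclidean distance to both, and
#' returns the closeness coefficient
#' `CEI_i = D_i^- / (D_i^+ + D_i^-)` in `[0, 1]` -- 1 for an alternative
#' sitting on the positive ideal, 0 on the negative ideal.
#'
#' @param b normalized matrix ([normalize_matrix()]).
#' @param weights criterion weights summing to 1
#'   ([entropy_weights()]`$weights`).
#' @return List of class `"cei_result"`: `cei` (named), `rank` (1 =
#'   best; ties share their minimum rank and are flagged in `ties`),
#'   `weighted` (`z`), `ideal_positive`, `ideal_negative`,
#'   `distance_positive`, `distance_negative`, `weights`.
#' @export
topsis_cei <- function(b, weights) {
  b <- as.matrix(b)
  if (length(weights) != ncol(b)) {
    stop("one weight is required per criterion")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  z <- sweep(b, 2, weights, `*`)
  z_pos <- apply(z, 2, max)
  z_neg <- apply(z, 2, min)
  d_pos <- sqrt(rowSums(sweep(z, 2, z_pos)^2))
  d_neg <- sqrt(rowSums(sweep(z, 2, z_neg)^2))
  if (all(d_pos + d_neg == 0)) {
    stop("degenerate decision matrix: all alternatives identical")
  }
  cei <- d_neg / (d_pos + d_neg)
  names(cei) <- rownames(b)
  rk <- rank(-cei, ties.method = "min")
  out <- list(cei = cei, rank = rk, ties = anyDuplicated(rk) > 0,
              weighted = z, ideal_positive = z_pos, ideal_negative = z_neg,
              distance_positive = d_pos, distance_negative = d_neg,
              weights = weights)
  class(out) <- "cei_result"
  out
}

#' Comprehensive evaluation index from a raw decision matrix
#'
#' One-call wrapper chaining [normalize_matrix()], [entropy_weights()]
#' and [topsis_cei()].
#'
#' @inheritParams normalize_matrix
#' @return A `"cei_result"` (see [topsis_cei()]) with the normalization
#'   (`normalized`), entropies and proportions attached.
#' @examples
#' x <- rbind(A = c(10, 3), B = c(6, 1), C = c(8, 2))
#' colnames(x) <- c("yield", "emissions")
#' cei(x, c(yield = "positive", emissions = "negative"))$cei
#' @export
cei <- function(x, directions) {
  b <- normalize_matrix(x, directions)
  ew <- entropy_weights(b)
  res <- topsis_cei(b, ew$weights)
  res$normalized <- b
  res$entropy <- ew$entropy
  res$proportions <- ew$proportions
  res$directions <- directions
  res
}
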