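# OTU-table rarefaction and alpha-diversity indices.

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample (column) without replacement to exactly `depth`
#' reads, deterministic given `seed`. Rarefaction equalizes sequencing
#' effort before diversity indices are compared; the default depth is the
#' minimum column sum, so no sample is dropped.
#'
#' @param counts taxa x samples matrix of non-negative integer counts.
#' @param depth target depth; defaults to the minimum sample depth.
#' @param seed integer seed for the subsampling.
#' @return A taxa x samples integer matrix with all column sums equal to
#'   `depth`.
#' @export
rarefy_table <- function(counts, depth = NULL, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("OTU counts must be non-negative integers")
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  if (is.null(depth)) depth <- min(totals)
  if (depth < 1) stop("rarefaction depth must be >= 1")
  short <- totals < depth
  if (any(short)) {
    stop("rarefaction depth ", depth, " exceeds the total count of sample(s): ",
         paste(colnames(counts)[short], collapse = ", "))
  }
  out <- with_stream_seed(seed, "rarefy", {
    # depth validity is checked above; silence vegan's advisory about
    # subsampling below the smallest observed count
    suppressWarnings(t(vegan::rrarefy(t(counts), sample = depth)))
  })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Alpha-diversity indices of one sample
#'
#' Computes the six standard within-sample diversity indices from a count
#' vector. Shannon `H = -sum p_i ln p_i` (natural log); richness
#' `S = #{c_i > 0}`; Simpson as the Gini--Simpson form `1 - sum p_i^2`
#' (the raw concentration `sum p_i^2` is also returned so either
#' convention is recoverable); Pielou `J = H / ln S` (`NA` when `S = 1`);
#' Chao1 `S + F1^2 / (2 F2)`, switching to the bias-corrected
#' `S + F1(F1 - 1) / (2 (F2 + 1))` when no doubletons are present; and
#' the abundance-based coverage estimator (ACE) with rare/abundant cutoff
#' `ace_cutoff`.
#'
#' @param counts non-negative integer counts, at least one positive.
#' @param ace_cutoff abundance threshold separating rare from abundant
#'   taxa in ACE (default 10).
#' @return Named list: `shannon`, `richness`, `simpson`,
#'   `simpson_concentration`, `pielou`, `chao1`, `ace`.
#' @examples
#' alpha_diversity(c(5, 5, 5, 5))$shannon  # log(4)
#' @export
alpha_diversity <- function(counts, ace_cutoff = 10) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero sample: no reads to summarize")
  c_pos <- counts[counts > 0]
  n <- sum(c_pos)
  p <- c_pos / n
  shannon <- -sum(p * log(p))
  s <- length(c_pos)
  conc <- sum(p^2)
  f1 <- sum(c_pos == 1)
  f2 <- sum(c_pos == 2)
  chao1 <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
  # ACE: rare taxa are those with <= ace_cutoff reads
  rare <- c_pos[c_pos <= ace_cutoff]
  s_abund <- sum(c_pos > ace_cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  ace <- if (s_rare == 0) {
    s_abund
  } else {
    c_ace <- 1 - sum(rare == 1) / n_rare
    if (c_ace <= 0) {
      NA_real_  # all rare taxa are singletons: coverage undefined
    } else {
      i <- seq_len(ace_cutoff)
      fi <- vapply(i, function(k) sum(rare == k), 0)
      g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
      if (n_rare == 1) g2 <- 0
      s_abund + s_rare / c_ace + sum(rare == 1) / c_ace * g2
    }
  }
  list(shannon = shannon,
       richness = s,
       simpson = 1 - conc,
       simpson_concentration = conc,
       pielou = if (s > 1) shannon / log(s) else NA_real_,
       chao1 = chao1,
       ace = ace)
}

#' Alpha diversity for every sample of an OTU table
#'
#' @param counts taxa x samples matrix.
#' @param meta optional data frame of sample metadata (one row per
#'   column of `counts`, matched by position) to carry through.
#' @param ace_cutoff see [alpha_diversity()].
#' @return Data frame with one row per sample and one column per index.
#' @export
alpha_diversity_table <- function(counts, meta = NULL, ace_cutoff = 10) {
  counts <- as.matrix(counts)
  res <- apply(counts, 2, function(x) {
    unlist(alpha_diversity(x, ace_cutoff = ace_cutoff))
  })
  out <- as.data.frame(t(res))
  out <- cbind(sample = colnames(counts), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(meta)) {
    if (nrow(meta) != ncol(counts)) {
      stop("meta must have one row per sample column")
    }
    out <- cbind(meta, out[setdiff(names(out), names(meta))])
  }
  out
}
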