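#' Alpha-diversity indices
#'
#' Observed species, bias-corrected Chao1, Shannon entropy and the
#' Gini-Simpson index for one sample's count vector.
#'
#' Chao1 uses the bias-corrected form
#' \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))} with \eqn{F_1} singletons and
#' \eqn{F_2} doubletons, so samples without doubletons are still defined.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @param base logarithm base for Shannon (default natural log).
#' @name alpha_diversity_indices
NULL

#' @rdname alpha_diversity_indices
#' @export
observed_species <- function(counts) {
  check_counts(counts, allow_zero = TRUE)
  sum(counts > 0)
}

#' @rdname alpha_diversity_indices
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha_diversity_indices
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname alpha_diversity_indices
#' @export
simpson <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  1 - sum(p^2)
}

check_counts <- function(counts, allow_zero = FALSE) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stopf("counts must be finite and non-negative")
  }
  if (!allow_zero && sum(counts) == 0) stopf("all counts are zero")
  invisible(counts)
}

#' Per-sample alpha-diversity table
#'
#' @param table an [abundance_table].
#' @inheritParams alpha_diversity_indices
#' @return data.frame: sample_id, observed_species, chao1, shannon, simpson.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$counts
  data.frame(
    sample_id = rownames(m),
    observed_species = apply(m, 1, observed_species),
    chao1 = apply(m, 1, chao1),
    shannon = apply(m, 1, shannon, base = base),
    simpson = apply(m, 1, simpson),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-sample phylum abundance ratio
#'
#' Ratio of summed counts of two phyla per sample, e.g. Firmicutes /
#' Bacteroidetes (F/B) or Firmicutes / Proteobacteria (F/P). Samples where
#' the denominator phylum is absent get `NA` rather than `Inf`.
#'
#' @param table an [abundance_table] with taxonomy (any rank resolution; it
#'   is aggregated to phylum internally).
#' @param numerator,denominator phylum names.
#' @return named numeric vector per sample.
#' @export
phylum_ratio <- function(table, numerator = "Firmicutes",
                         denominator = "Bacteroidetes") {
  phy <- aggregate_rank(table, "phylum")$counts
  for (p in c(numerator, denominator)) {
    if (!p %in% colnames(phy)) stopf("phylum '%s' absent from taxonomy", p)
  }
  num <- phy[, numerator]
  den <- phy[, denominator]
  out <- ifelse(den == 0, NA_real_, num / den)
  stats::setNames(out, rownames(phy))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the total sum of squared
#' distances \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} is partitioned into a
#' within-group component \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 /
#' n_g} and the remainder, giving the pseudo-F statistic
#' \deqn{F = \frac{(SS_T - SS_W)/(a - 1)}{SS_W/(n - a)}}
#' evaluated against `n_perm` random label permutations with
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). Perfectly separated
#' groups (zero within-group distance) give an infinite statistic and the
#' minimal attainable p.
#'
#' @param dist symmetric distance matrix (or `dist`) with zero diagonal.
#' @param groups group label per sample; >= 2 groups, each with >= 2
#'   samples.
#' @param n_perm number of permutations.
#' @param seed integer seed making the permutation stream reproducible.
#' @return list with `pseudo_f` and `p`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1L) {
  if (!inherits(dist, "dist")) {
    dist <- as.matrix(dist)
    if (!isSymmetric(unname(dist), tol = 1e-8) || any(abs(diag(dist)) > 1e-12)) {
      stopf("`dist` must be symmetric with a zero diagonal")
    }
  } else {
    dist <- as.matrix(dist)
  }
  groups <- as.factor(groups)
  n <- length(groups)
  if (nrow(dist) != n) stopf("length mismatch between `dist` and `groups`")
  tab <- table(groups)
  a <- length(tab)
  if (a < 2) stopf("need >= 2 groups")
  if (any(tab < 2)) stopf("singleton group: %s", names(tab)[tab < 2][1])
  d2 <- dist^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  pseudo_f_of <- function(g) {
    ss_w <- 0
    for (lev in levels(groups)) {
      idx <- which(g == lev)
      sub <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudo_f_of(groups)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pseudo_f_of(sample(groups)) >= f_obs
    }, logical(1)))
  })
  list(pseudo_f = f_obs, p = (1 + hits) / (1 + n_perm))
}

#' Euclidean sample distances on transformed relative abundances
#'
#' Helper for ordination-style PERMANOVA: Euclidean distance on relative
#' abundances (PCA geometry), optionally CLR-transformed with a
#' pseudocount.
#'
#' @param table an [abundance_table].
#' @param transform `"relative"` or `"clr"`.
#' @param pseudocount added before the CLR log.
#' @export
sample_distance <- function(table, transform = c("relative", "clr"),
                            pseudocount = 0.5) {
  transform <- match.arg(transform)
  m <- if (transform == "relative") {
    relative_abundance(table)
  } else {
    lp <- log(table$counts + pseudocount)
    sweep(lp, 1, rowMeans(lp))
  }
  stats::dist(m)
}
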