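#' Configuration of the weighted co-abundance network
#'
#' Defaults follow the conventional unsigned weighted-network workflow on
#' log-transformed relative abundances: Pearson correlation, scale-free fit
#' target R^2 = 0.85, minimum module size 25, branch-split sensitivity 3 and
#' eigengene merge height 0.25.
#'
#' @param correlation `"pearson"` or `"spearman"`.
#' @param network_type `"unsigned"` (|cor|^beta) or `"signed"`
#'   (((1+cor)/2)^beta).
#' @param power_grid candidate soft-threshold powers.
#' @param rsq_target scale-free fit R^2 at which a power is accepted.
#' @param min_module_size smallest allowed module before merging.
#' @param deep_split integer 0-4; larger values cut the dendrogram lower and
#'   split more aggressively.
#' @param merge_cut eigengene dissimilarity (1 - cor) below which modules
#'   are merged.
#' @param mad_keep_fraction fraction of OTUs kept by the MAD filter.
#' @param transform `"log1p_relative"` (log1p of counts-per-10k),
#'   `"hellinger"` or `"none"`.
#' @export
network_config <- function(correlation = c("pearson", "spearman"),
                           network_type = c("unsigned", "signed"),
                           power_grid = c(1:10, seq(12, 20, 2)),
                           rsq_target = 0.85,
                           min_module_size = 25,
                           deep_split = 3,
                           merge_cut = 0.25,
                           mad_keep_fraction = 0.5,
                           transform = c("log1p_relative", "hellinger", "none")) {
  assert_fraction(merge_cut, "merge_cut", lo = 0, hi = 1, lo_open = TRUE)
  assert_fraction(mad_keep_fraction, "mad_keep_fraction", lo = 0, hi = 1,
                  lo_open = TRUE)
  stopifnot(deep_split %in% 0:4, all(power_grid > 0))
  structure(list(
    correlation = match.arg(correlation),
    network_type = match.arg(network_type),
    power_grid = power_grid, rsq_target = rsq_target,
    min_module_size = as.integer(min_module_size),
    deep_split = as.integer(deep_split), merge_cut = merge_cut,
    mad_keep_fraction = mad_keep_fraction,
    transform = match.arg(transform)
  ), class = "network_config")
}

#' Transform counts for network construction
#'
#' @param table an [abundance_table] or counts matrix.
#' @param transform see [network_config()].
#' @param scale_factor library-size scaling for `log1p_relative`
#'   (counts-per-`scale_factor`).
#' @return samples x OTUs numeric matrix.
#' @export
transform_counts <- function(table, transform = "log1p_relative",
                             scale_factor = 1e4) {
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  switch(transform,
    log1p_relative = log1p(relative_abundance(m) * scale_factor),
    hellinger = sqrt(relative_abundance(m)),
    none = m,
    stopf("unknown transform '%s'", transform)
  )
}

#' Filter OTUs by median absolute deviation
#'
#' Ranks OTUs by per-OTU MAD (median of absolute deviations from the median,
#' unscaled) in descending order and keeps the top `keep_fraction`; ties at
#' the boundary are broken by original column order.
#'
#' @param m samples x OTUs matrix.
#' @param keep_fraction fraction in (0, 1].
#' @export
mad_filter <- function(m, keep_fraction = 0.5) {
  assert_fraction(keep_fraction, "keep_fraction", lo = 0, hi = 1, lo_open = TRUE)
  if (nrow(m) < 2) stopf("need >= 2 samples")
  mads <- apply(m, 2, function(x) stats::median(abs(x - stats::median(x))))
  n_keep <- max(1L, ceiling(keep_fraction * ncol(m)))
  ord <- order(-mads, seq_along(mads))
  keep <- sort(ord[seq_len(n_keep)])
  m[, keep, drop = FALSE]
}

#' Signed scale-free topology fit index
#'
#' Bins connectivities into `n_bins` equal-width bins, regresses
#' log10(frequency) on log10(mean connectivity) over non-empty bins, and
#' returns R^2 signed by the negated slope sign (positive for a decreasing,
#' power-law-like degree distribution).
#'
#' @param k non-negative connectivity vector.
#' @param n_bins number of bins.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (any(k < 0)) stopf("connectivities must be non-negative")
  if (diff(range(k)) == 0) stopf("scale-free fit undefined for constant k")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(ok) < 2) stopf("fewer than 2 usable bins")
  # simple regression: R^2 = cor^2 and the slope carries cor's sign
  r <- stats::cor(log10(kmean[ok]), log10(freq[ok]))
  unname(-sign(r) * r^2)
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned: \eqn{A_{ij} = |cor(x_i, x_j)|^\beta}; signed:
#' \eqn{((1 + cor)/2)^\beta}. Diagonal is 1.
#'
#' @param m samples x OTUs matrix (every OTU must vary).
#' @param power soft-threshold exponent beta > 0.
#' @param network_type,correlation see [network_config()].
#' @export
adjacency_matrix <- function(m, power, network_type = "unsigned",
                             correlation = "pearson") {
  if (power <= 0) stopf("`power` must be > 0")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance OTU '%s'; filter before building the network",
          colnames(m)[which(sds == 0)[1]])
  }
  cc <- stats::cor(m, method = correlation)
  a <- if (network_type == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  diag(a) <- 1
  a
}

#' Pick the soft-threshold power
#'
#' Evaluates the signed scale-free fit and mean connectivity for each power
#' in the grid and chooses the smallest power reaching `rsq_target` (or the
#' argmax of the fit if none does; the first grid element when the target is
#' vacuous at 0).
#'
#' @param m samples x OTUs matrix.
#' @param config a [network_config()].
#' @return list with `report` (data.frame power, sft_rsq, mean_k) and
#'   `power`.
#' @export
pick_soft_threshold <- function(m, config = network_config()) {
  if (ncol(m) < 3) stopf("need >= 3 OTUs")
  cc <- stats::cor(m, method = config$correlation)
  base <- if (config$network_type == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- NA
  rows <- lapply(config$power_grid, function(b) {
    a <- base^b
    k <- colSums(a, na.rm = TRUE)
    fit <- tryCatch(scale_free_fit(k), error = function(e) NA_real_)
    data.frame(power = b, sft_rsq = fit, mean_k = mean(k))
  })
  report <- do.call(rbind, rows)
  power <- if (config$rsq_target <= 0) {
    report$power[1]
  } else {
    hit <- which(!is.na(report$sft_rsq) & report$sft_rsq >= config$rsq_target)
    if (length(hit) > 0) {
      report$power[hit[1]]
    } else {
      report$power[which.max(report$sft_rsq)]
    }
  }
  list(report = report, power = power)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})} with
#' \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1.
#'
#' @param a symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-8)) stopf("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) stopf("adjacency outside [0, 1]")
  ao <- a
  diag(ao) <- 0
  l <- ao %*% ao
  k <- rowSums(ao)
  denom <- outer(k, k, pmin) + 1 - ao
  tom <- (l + ao) / denom
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

# Fixed colour vocabulary for module labels, assigned by decreasing module
# size; "grey" is reserved for unassigned taxa.
module_colours <- function() c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
  "brown4", "bisque4", "darkslateblue", "plum2", "thistle2", "thistle1",
  "salmon4", "palevioletred3", "navajowhite2", "maroon", "lightpink4",
  "lavenderblush3", "honeydew1", "darkseagreen4", "coral1"
)

# Map integer cluster ids to colour names ordered by decreasing size (ties
# by first-member index); 0 / NA stays "grey".
assign_colours <- function(cl) {
  lab <- rep("grey", length(cl))
  ids <- setdiff(unique(cl[!is.na(cl) & cl != 0]), integer(0))
  if (length(ids) == 0) return(lab)
  size <- vapply(ids, function(i) sum(cl == i, na.rm = TRUE), numeric(1))
  first <- vapply(ids, function(i) which(cl == i)[1], numeric(1))
  ord <- ids[order(-size, first)]
  pal <- module_colours()
  if (length(ord) > length(pal)) {
    pal <- c(pal, paste0("module", seq_len(length(ord) - length(pal))))
  }
  for (i in seq_along(ord)) lab[!is.na(cl) & cl == ord[i]] <- pal[i]
  lab
}

#' Detect modules by dynamic cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity followed
#' by a hybrid cut: a static cut at a height controlled by `deep_split`
#' (larger values cut lower), removal of clusters below `min_module_size`,
#' and a reassignment stage that attaches unassigned OTUs to the nearest
#' module when their average dissimilarity to its members is within the
#' module's own internal scatter. Remaining OTUs are labelled `"grey"`.
#' Module labels are colour names assigned by decreasing size.
#'
#' @param diss OTU x OTU dissimilarity matrix, typically `1 - TOM`.
#' @param config a [network_config()].
#' @return named character vector OTU -> module colour.
#' @export
detect_modules <- function(diss, config = network_config()) {
  diss <- as.matrix(diss)
  p <- ncol(diss)
  ids <- colnames(diss)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  if (p < config$min_module_size) {
    warning("fewer OTUs than min_module_size; all grey")
    return(stats::setNames(rep("grey", p), ids))
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  # Soft thresholding compresses dissimilarities towards 1, so branch joins
  # within modules and joins among unclustered taxa separate only on the
  # -log10(1 - h) scale: module joins sit orders of magnitude below the
  # noise band. Cut inside the widest gap of that scale; deep_split moves
  # the cut towards the noise band (more aggressive splitting).
  s <- sort(-log10(pmax(1 - hc$height, 1e-15)))
  gaps <- diff(s)
  gi <- which.max(gaps)
  frac <- c(0.1, 0.3, 0.5, 0.7, 0.9)[config$deep_split + 1]
  cut_h <- 1 - 10^(-(s[gi] + frac * gaps[gi]))
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < config$min_module_size])
  cl[cl %in% small] <- 0L

  # hybrid stage: pull borderline unassigned OTUs into a module when they
  # are closer to it than the module's own 95th-percentile internal scatter
  mods <- setdiff(unique(cl), 0L)
  grey <- which(cl == 0L)
  if (length(mods) > 0 && length(grey) > 0) {
    radius <- numeric(length(mods))
    avg <- matrix(NA_real_, length(grey), length(mods))
    for (j in seq_along(mods)) {
      members <- which(cl == mods[j])
      within <- rowMeans(diss[members, members, drop = FALSE]) *
        length(members) / (length(members) - 1)
      radius[j] <- stats::quantile(within, 0.95, names = FALSE)
      avg[, j] <- rowMeans(diss[grey, members, drop = FALSE])
    }
    best <- apply(avg, 1, which.min)
    ok <- avg[cbind(seq_along(grey), best)] <= radius[best]
    cl[grey[ok]] <- mods[best[ok]]
  }
  stats::setNames(assign_colours(cl), ids)
}

#' Module eigengene
#'
#' First principal component of the per-OTU standardised member submatrix,
#' rescaled to unit variance and sign-oriented so that it correlates
#' non-negatively with the mean member profile (falling back to the first
#' member when the mean profile is degenerate, e.g. for an anti-correlated
#' pair).
#'
#' @param m samples x OTUs matrix.
#' @param members OTU ids or column indices (>= 2).
#' @return list with `eigengene` (length-n vector, unit variance) and
#'   `variance_explained`.
#' @export
module_eigengene <- function(m, members) {
  sub <- m[, members, drop = FALSE]
  if (ncol(sub) < 2) stopf("need >= 2 member OTUs")
  sub <- scale(sub)
  sv <- svd(sub, nu = 1, nv = 0)
  eig <- sv$u[, 1]
  eig <- eig / stats::sd(eig)
  ref <- rowMeans(sub)
  if (stats::sd(ref) < 1e-10) ref <- sub[, 1]
  if (stats::cor(eig, ref) < 0) eig <- -eig
  list(eigengene = as.numeric(eig),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes of all modules in a partition
#'
#' @param m samples x OTUs matrix.
#' @param labels OTU -> module colour vector (aligned with columns of `m`).
#' @return list with `eigengenes` (samples x modules matrix, columns named
#'   `ME<colour>` ordered by decreasing module size) and
#'   `variance_explained`.
#' @export
module_eigengenes <- function(m, labels) {
  mods <- module_order(labels)
  if (length(mods) == 0) stopf("no non-grey modules")
  res <- lapply(mods, function(col) module_eigengene(m, which(labels == col)))
  me <- do.call(cbind, lapply(res, `[[`, "eigengene"))
  colnames(me) <- paste0("ME", mods)
  rownames(me) <- rownames(m)
  list(eigengenes = me,
       variance_explained = stats::setNames(
         vapply(res, `[[`, numeric(1), "variance_explained"), mods))
}

module_order <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0) return(character(0))
  size <- vapply(mods, function(col) sum(labels == col), numeric(1))
  first <- vapply(mods, function(col) which(labels == col)[1], numeric(1))
  mods[order(-size, first)]
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of module eigengenes under dissimilarity
#' 1 - cor; modules closer than `merge_cut` are merged, eigengenes are
#' recomputed and the procedure iterates until stable. Colours are
#' reassigned by decreasing merged-module size.
#'
#' @param m samples x OTUs matrix.
#' @param labels OTU -> module colour vector.
#' @param merge_cut merge height (default 0.25).
#' @return named character vector of merged module labels.
#' @export
merge_modules <- function(m, labels, merge_cut = 0.25) {
  labels <- as.character(labels)
  names(labels) <- colnames(m)
  repeat {
    mods <- module_order(labels)
    if (length(mods) < 2) break
    me <- module_eigengenes(m, labels)$eigengenes
    d <- 1 - stats::cor(me)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = merge_cut)
    if (max(grp) == length(mods)) break
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) > 1) {
        labels[labels %in% members] <- members[1]
      }
    }
  }
  # stable recolouring by merged size
  mods <- module_order(labels)
  cl <- integer(length(labels))
  for (i in seq_along(mods)) cl[labels == mods[i]] <- i
  stats::setNames(assign_colours(cl), names(labels))
}

#' Module-trait correlation, gene significance and module membership
#'
#' Pearson correlation of each module eigengene with each (numeric) trait,
#' with two-sided p-values from the t statistic on n - 2 df; per-OTU gene
#' significance GS (OTU-trait correlation) and module membership MM
#' (OTU-eigengene correlation for its own module); and per-module
#' correlation of |MM| with |GS| over members. No multiple-testing
#' correction is applied to the module-trait p-values by default, matching
#' the p < alpha selection convention; set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param m samples x OTUs matrix.
#' @param labels OTU -> module colour vector.
#' @param traits data.frame of numeric traits (binary traits coded 0/1),
#'   rows aligned with rows of `m`.
#' @param alpha significance level for module selection.
#' @param adjust p-adjustment method for module-trait p-values ("none" or
#'   any method of [stats::p.adjust]).
#' @return object of class `module_trait_result`: `module_trait` (module,
#'   trait, r, p), `significant` (subset with p < alpha), `otu_stats` (otu,
#'   module, MM, one GS column per trait), `mm_gs` (module, trait, r, p),
#'   `eigengenes`.
#' @export
module_trait <- function(m, labels, traits, alpha = 0.05, adjust = "none") {
  traits <- as.data.frame(traits)
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[, num, drop = FALSE]
  if (ncol(traits) == 0) stopf("no numeric traits")
  if (any(vapply(traits, function(x) stats::sd(x) == 0, logical(1)))) {
    stopf("constant trait")
  }
  n <- nrow(m)
  me <- module_eigengenes(m, labels)
  mods <- sub("^ME", "", colnames(me$eigengenes))

  r_mt <- stats::cor(me$eigengenes, as.matrix(traits))
  p_mt <- matrix(cor_pvalue(r_mt, n), nrow(r_mt), ncol(r_mt),
                 dimnames = dimnames(r_mt))
  mt <- expand.grid(module = mods, trait = colnames(traits),
                    stringsAsFactors = FALSE)
  mt$r <- r_mt[cbind(match(paste0("ME", mt$module), rownames(r_mt)),
                     match(mt$trait, colnames(r_mt)))]
  mt$p <- p_mt[cbind(match(paste0("ME", mt$module), rownames(p_mt)),
                     match(mt$trait, colnames(p_mt)))]
  if (adjust != "none") mt$p <- stats::p.adjust(mt$p, method = adjust)

  gs <- stats::cor(m, as.matrix(traits))
  colnames(gs) <- paste0("GS_", colnames(traits))
  mm <- rep(NA_real_, ncol(m))
  for (col in mods) {
    idx <- which(labels == col)
    mm[idx] <- stats::cor(m[, idx, drop = FALSE],
                          me$eigengenes[, paste0("ME", col)])
  }
  otu_stats <- data.frame(otu = colnames(m), module = labels, MM = mm,
                          gs, row.names = NULL, stringsAsFactors = FALSE)

  mm_gs <- do.call(rbind, lapply(mods, function(col) {
    idx <- which(labels == col)
    do.call(rbind, lapply(colnames(traits), function(tr) {
      r <- stats::cor(abs(mm[idx]), abs(gs[idx, paste0("GS_", tr)]))
      data.frame(module = col, trait = tr, r = r,
                 p = cor_pvalue(r, length(idx)), stringsAsFactors = FALSE)
    }))
  }))

  structure(list(
    module_trait = mt,
    significant = mt[!is.na(mt$p) & mt$p < alpha, , drop = FALSE],
    otu_stats = otu_stats, mm_gs = mm_gs,
    eigengenes = me$eigengenes,
    variance_explained = me$variance_explained
  ), class = "module_trait_result")
}
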