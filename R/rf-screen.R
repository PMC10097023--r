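#' Random-forest importance ranking of genera
#'
#' Trains a regression random forest on genus-level relative abundances with
#' the binary group coded 0/1, reproducing the two conventional importance
#' panels: permutation importance (%IncMSE, mean out-of-bag increase in
#' squared error when a genus is permuted) and impurity importance
#' (IncNodePurity, total node-impurity decrease). Defaults follow 500 trees
#' with a maximum depth of 7 (implemented as a cap of 2^7 terminal nodes).
#'
#' @param features samples x genera numeric matrix or data.frame (relative
#'   abundances).
#' @param labels binary class per sample (factor, character or 0/1); both
#'   classes need >= 2 samples.
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param seed integer seed (mandatory: no silent default randomness).
#' @return object of class `importance_report`: `importances` (genus,
#'   perm_importance, impurity_importance, rank_perm, rank_imp) plus the
#'   forest parameters.
#' @export
rf_importances <- function(features, labels, n_trees = 500, max_depth = 7,
                           seed) {
  if (missing(seed)) stopf("`seed` is required")
  x <- as.data.frame(features)
  genera <- colnames(x)
  colnames(x) <- make.names(genera, unique = TRUE)
  y <- if (is.numeric(labels)) labels else as.numeric(as.factor(labels)) - 1
  if (length(unique(y)) < 2) stopf("labels contain a single class")
  if (min(table(y)) < 2) stopf("each class needs >= 2 samples")
  fit <- with_seed(seed, {
    # regression on the 0/1 outcome is intentional (%IncMSE convention), so
    # silence randomForest's few-unique-values advisory
    suppressWarnings(randomForest::randomForest(
      x = x, y = as.numeric(y), ntree = n_trees,
      maxnodes = 2^max_depth, importance = TRUE
    ))
  })
  imp <- randomForest::importance(fit)
  out <- data.frame(
    genus = genera,
    perm_importance = unname(imp[, "%IncMSE"]),
    impurity_importance = unname(imp[, "IncNodePurity"]),
    stringsAsFactors = FALSE
  )
  out$rank_perm <- rank(-out$perm_importance, ties.method = "first")
  out$rank_imp <- rank(-out$impurity_importance, ties.method = "first")
  structure(list(importances = out, n_trees = n_trees, max_depth = max_depth,
                 seed = seed), class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %d genera, %d trees, depth %d\n",
              nrow(x$importances), x$n_trees, x$max_depth))
  print(utils::head(x$importances[order(x$importances$rank_perm), ], 10))
  invisible(x)
}

#' Top-k genera by an importance measure
#'
#' Descending by the chosen measure; ties broken by the other measure, then
#' by genus name.
#'
#' @param report an `importance_report`.
#' @param k list length.
#' @param measure `"permutation"` or `"impurity"`.
#' @return character vector of genus names.
#' @export
top_k <- function(report, k = 10, measure = c("permutation", "impurity")) {
  measure <- match.arg(measure)
  assert_count(k, "k")
  imp <- report$importances
  ord <- if (measure == "permutation") {
    order(-imp$perm_importance, -imp$impurity_importance, imp$genus)
  } else {
    order(-imp$impurity_importance, -imp$perm_importance, imp$genus)
  }
  imp$genus[ord][seq_len(min(k, nrow(imp)))]
}

#' Core-genus intersection rule
#'
#' Genera appearing in both random-forest top-k lists and among the hub
#' genera: `(top_perm` \eqn{\cap} `top_imp)` \eqn{\cap} `hub_genera`,
#' reported in hub-ranking order. The union of the two forest lists is
#' attached for inspection.
#'
#' @param hub_genera genus annotations of the top hub OTUs, in hub order.
#' @param top_perm,top_imp top-k genus lists from the two importance
#'   measures.
#' @return character vector of core genera (attribute `rf_union` carries
#'   the union of the two forest lists); empty with a warning when the
#'   lists are disjoint.
#' @export
core_intersection <- function(hub_genera, top_perm, top_imp) {
  if (length(hub_genera) == 0 || length(top_perm) == 0 || length(top_imp) == 0) {
    stopf("all three lists must be non-empty")
  }
  rf_both <- intersect(top_perm, top_imp)
  hubs <- unique(hub_genera[!is.na(hub_genera)])
  core <- hubs[hubs %in% rf_both]
  if (length(core) == 0) warning("no genus shared by hubs and both RF lists")
  attr(core, "rf_union") <- union(top_perm, top_imp)
  core
}
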