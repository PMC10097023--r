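write_stage_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# longicore %s", utils::packageVersion("longicore")), con)
  if (!is.null(seed)) writeLines(sprintf("# seed = %s", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full core-microbiota discovery chain
#'
#' Orchestrates transform -> MAD filter -> soft threshold -> adjacency ->
#' TOM -> module detection -> merging -> module-trait correlation ->
#' selection at p < alpha, then for each selected module: weighted-network
#' export, MNC hub extraction, dual random-forest importance ranking on the
#' module's genera, and the core-genus intersection. Every random stage is
#' seeded from the global seed.
#'
#' @param abundance an [abundance_table] with taxonomy.
#' @param traits trait data.frame (`sample_id` plus numeric traits; binary
#'   traits coded 0/1) aligned by sample id.
#' @param trait name of the trait column used for module selection and RF
#'   labels.
#' @param config a [network_config()].
#' @param hub_k number of hub OTUs per module.
#' @param hub_edges_per_node density of the exported module network (top
#'   `hub_edges_per_node * module size` edges).
#' @param rf_n_trees,rf_max_depth random-forest parameters.
#' @param alpha module-trait significance level.
#' @param seed global seed.
#' @param output_dir if non-NULL, stage TSVs are written there.
#' @return a `discovery_report` list: `power`, `soft_threshold_report`,
#'   `modules` (OTU -> colour), `module_sizes`, `module_trait`,
#'   `selected_modules`, and per selected module `results` (network, hubs,
#'   rf report, top-k lists, core genera).
#' @export
run_discovery <- function(abundance, traits, trait = "longevity",
                          config = network_config(), hub_k = 10,
                          hub_edges_per_node = 3,
                          rf_n_trees = 500, rf_max_depth = 7,
                          alpha = 0.05, seed = 1L, output_dir = NULL) {
  stopifnot(inherits(abundance, "abundance_table"))
  assert_fraction(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  traits <- traits[match(rownames(abundance$counts), traits$sample_id), ,
                   drop = FALSE]
  if (any(is.na(traits$sample_id))) stopf("trait table missing samples")
  if (!trait %in% names(traits)) stopf("trait '%s' not in trait table", trait)

  m <- transform_counts(abundance, config$transform)
  m <- mad_filter(m, config$mad_keep_fraction)
  m <- m[, apply(m, 2, stats::sd) > 0, drop = FALSE]

  sft <- pick_soft_threshold(m, config)
  a <- adjacency_matrix(m, sft$power, config$network_type, config$correlation)
  tom <- tom_similarity(a)
  dimnames(tom) <- dimnames(a)
  labels <- detect_modules(1 - tom, config)
  labels <- if (any(labels != "grey")) {
    merge_modules(m, labels, config$merge_cut)
  } else {
    labels
  }

  report <- list(
    trait = trait, seed = seed, power = sft$power,
    soft_threshold_report = sft$report, modules = labels,
    module_sizes = sort(table(labels[labels != "grey"]), decreasing = TRUE),
    module_trait = NULL, selected_modules = character(0), results = list()
  )
  class(report) <- "discovery_report"

  if (all(labels == "grey")) {
    warning("no modules detected; empty selection")
    return(report)
  }

  tr_num <- traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE]
  mt <- module_trait(m, labels, tr_num, alpha = alpha)
  report$module_trait <- mt
  sel <- mt$significant
  sel <- sel$module[sel$trait == trait]
  report$selected_modules <- sel
  if (length(sel) == 0) {
    warning("no module passes alpha; empty selection")
  }

  genus_map <- NULL
  if (!is.null(abundance$taxonomy)) {
    genus_map <- stats::setNames(abundance$taxonomy$genus,
                                 abundance$taxonomy$otu_id)
  }
  genus_tab <- aggregate_rank(abundance, "genus")
  genus_rel <- relative_abundance(genus_tab)

  for (i in seq_along(sel)) {
    col <- sel[i]
    size <- sum(labels == col)
    net <- export_module_network(tom, labels, col,
                                 n_top_edges = hub_edges_per_node * size,
                                 genus = genus_map)
    hubs <- top_hubs(net, hub_k)
    mod_genera <- unique(genus_map[names(labels)[labels == col]])
    mod_genera <- setdiff(mod_genera[!is.na(mod_genera)], "unclassified")
    feat <- genus_rel[, intersect(colnames(genus_rel), mod_genera),
                      drop = FALSE]
    res <- list(module = col, network = net, hubs = hubs)
    if (ncol(feat) >= 2) {
      rf <- rf_importances(feat, traits[[trait]], n_trees = rf_n_trees,
                           max_depth = rf_max_depth,
                           seed = derive_seed(seed, i))
      tp <- top_k(rf, 10, "permutation")
      ti <- top_k(rf, 10, "impurity")
      hub_genera <- hubs$genus[!duplicated(hubs$genus) & !is.na(hubs$genus)]
      res$rf <- rf
      res$top_perm <- tp
      res$top_imp <- ti
      res$core_genera <- core_intersection(hub_genera, tp, ti)
    }
    report$results[[col]] <- res
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_tsv(sft$report, file.path(output_dir, "soft_threshold.tsv"),
                    seed)
    if (!is.null(report$module_trait)) {
      write_stage_tsv(mt$module_trait,
                      file.path(output_dir, "module_trait.tsv"), seed)
      write_stage_tsv(mt$otu_stats,
                      file.path(output_dir, "module_assignment.tsv"), seed)
      write_stage_tsv(data.frame(sample_id = rownames(mt$eigengenes),
                                 mt$eigengenes, check.names = FALSE),
                      file.path(output_dir, "eigengenes.tsv"), seed)
    }
    for (col in names(report$results)) {
      res <- report$results[[col]]
      write_network(res$network,
                    edge_path = file.path(output_dir,
                                          paste0("edges_", col, ".tsv")),
                    node_path = file.path(output_dir,
                                          paste0("nodes_", col, ".tsv")),
                    sif_path = file.path(output_dir, paste0(col, ".sif")))
      write_stage_tsv(res$hubs, file.path(output_dir,
                                          paste0("hubs_", col, ".tsv")), seed)
      if (!is.null(res$rf)) {
        write_stage_tsv(res$rf$importances,
                        file.path(output_dir,
                                  paste0("rf_importance_", col, ".tsv")), seed)
        write_stage_tsv(data.frame(genus = as.character(res$core_genera)),
                        file.path(output_dir,
                                  paste0("core_genera_", col, ".tsv")), seed)
      }
    }
  }
  report
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("<discovery_report> power = %s, %d modules, selected: %s\n",
              x$power, length(x$module_sizes),
              if (length(x$selected_modules)) {
                paste(x$selected_modules, collapse = ", ")
              } else {
                "(none)"
              }))
  for (col in names(x$results)) {
    core <- x$results[[col]]$core_genera
    if (!is.null(core)) {
      cat(sprintf("  %s core genera: %s\n", col,
                  paste(as.character(core), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Composite strain scoring workflow
#'
#' KMO adequacy check (warns when <= 0.6), principal components of the
#' indicator correlation matrix and the explained-variance-weighted
#' composite score with ranking; optionally written as two TSV reports
#' (load-factor table and ranked scores).
#'
#' @param table a `strain_property_table` (or path to a TSV with columns
#'   strain, source, gi_survival, self_aggregation, hydrophobicity).
#' @param cum_threshold cumulative-variance threshold for component
#'   retention.
#' @param kmo_threshold adequacy gate (warning below).
#' @param output_dir if non-NULL, write `pca_loadings.tsv` and
#'   `strain_scores.tsv` there.
#' @return list: `kmo`, `pca` (a `pca_score`), `scores` (strain, source,
#'   f_sum, rank).
#' @export
run_strain_scoring <- function(table, cum_threshold = 0.90,
                               kmo_threshold = 0.6, output_dir = NULL) {
  if (is.character(table)) {
    table <- utils::read.delim(table, comment.char = "#",
                               stringsAsFactors = FALSE)
  }
  k <- kmo(table)
  if (k <= kmo_threshold) {
    warning(sprintf("KMO = %.3f <= %.1f: sampling adequacy is questionable",
                    k, kmo_threshold))
  }
  pca <- pca_components(table, cum_threshold = cum_threshold)
  scores <- composite_score(pca)
  df <- as.data.frame(table)
  if ("source" %in% names(df) && "strain" %in% names(df)) {
    scores$source <- df$source[match(scores$strain, df$strain)]
    scores <- scores[, c("strain", "source", "f_sum", "rank")]
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    m <- pca$n_retained
    loads <- data.frame(
      name = c("characteristic_root", "explained_variance_pct",
               rownames(pca$loadings)),
      rbind(pca$roots[seq_len(m)], 100 * pca$explained_variance[seq_len(m)],
            pca$loadings), check.names = FALSE
    )
    names(loads)[-1] <- colnames(pca$loadings)
    write_stage_tsv(loads, file.path(output_dir, "pca_loadings.tsv"))
    write_stage_tsv(scores, file.path(output_dir, "strain_scores.tsv"))
  }
  list(kmo = k, pca = pca, scores = scores)
}
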