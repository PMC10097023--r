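tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Construct a validated abundance table
#'
#' @param counts samples x OTUs matrix of non-negative integer counts, with
#'   sample and OTU ids as dimnames.
#' @param taxonomy data.frame with column `otu_id` and the seven rank
#'   columns kingdom..species (empty string for unassigned ranks); optional
#'   `lineage` column with the Greengenes-style string.
#' @return object of class `abundance_table` with elements `counts` and
#'   `taxonomy`.
#' @export
abundance_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("`counts` must carry sample ids (rows) and OTU ids (columns)")
  }
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicate sample id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  }
  if (anyDuplicated(colnames(counts))) {
    stopf("duplicate OTU id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  }
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stopf("counts must be finite numbers")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stopf("negative count for sample '%s', OTU '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (!"otu_id" %in% names(taxonomy)) stopf("taxonomy needs an `otu_id` column")
    unknown <- setdiff(taxonomy$otu_id, colnames(counts))
    if (length(unknown) > 0) {
      stopf("taxonomy references unknown OTU: %s", unknown[1])
    }
    missing <- setdiff(names(core_rank_cols()), names(taxonomy))
    if (length(missing) > 0 && "lineage" %in% names(taxonomy)) {
      taxonomy <- cbind(taxonomy["otu_id"], parse_lineage(taxonomy$lineage),
                        taxonomy["lineage"])
    }
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "abundance_table")
}

core_rank_cols <- function() stats::setNames(seq_along(tax_ranks), tax_ranks)

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d OTUs%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else ", taxonomy attached"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Parse Greengenes-style lineage strings
#'
#' Splits strings like `"k__Bacteria;p__Firmicutes;...;g__Lactobacillus;s__"`
#' into the seven canonical ranks, dropping the `x__` prefixes; missing or
#' empty ranks become `""`.
#'
#' @param lineage character vector.
#' @return data.frame with columns kingdom..species.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- sub("^\\s*[kpcofgs]__", "", trimws(p))
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- tax_ranks
  out
}

format_lineage <- function(taxonomy) {
  pre <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(taxonomy[, tax_ranks, drop = FALSE], 1, function(r) {
    paste0(pre, r, collapse = ";")
  })
}

#' Write / read abundance tables as TSV
#'
#' The dialect is tab-separated with `#` comment lines; the first column is
#' the identifier. Orientation on read is auto-detected by matching
#' identifiers against the taxonomy file (OTU ids), or forced via
#' `orientation`.
#'
#' @param table an [abundance_table].
#' @param path counts TSV path.
#' @param taxonomy_path two-column TSV (otu_id, lineage string); optional on
#'   read, written alongside when taxonomy is attached.
#' @param comment character vector of comment lines (e.g. seed provenance)
#'   written as `#`-prefixed header lines.
#' @export
write_abundance <- function(table, path, taxonomy_path = NULL, comment = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy)) {
    tax <- data.frame(otu_id = table$taxonomy$otu_id,
                      lineage = if ("lineage" %in% names(table$taxonomy)) {
                        table$taxonomy$lineage
                      } else {
                        format_lineage(table$taxonomy)
                      }, stringsAsFactors = FALSE)
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_abundance
#' @param orientation `"auto"`, `"samples_in_rows"` or `"otus_in_rows"`.
#' @export
read_abundance <- function(path, taxonomy_path = NULL,
                           orientation = c("auto", "samples_in_rows",
                                           "otus_in_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(df[, -1, drop = FALSE], 2,
                       function(x) any(is.na(suppressWarnings(as.numeric(x))))))[1]
    stopf("non-numeric counts in column '%s' of %s",
          colnames(df)[-1][bad], path)
  }
  rownames(mat) <- ids
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- utils::read.delim(taxonomy_path, comment.char = "#",
                             check.names = FALSE, stringsAsFactors = FALSE)
    names(tax)[1:2] <- c("otu_id", "lineage")
    taxonomy <- cbind(tax["otu_id"], parse_lineage(tax$lineage),
                      tax["lineage"])
  }
  if (orientation == "auto") {
    orientation <- if (!is.null(taxonomy) &&
                       mean(ids %in% taxonomy$otu_id) > 0.5) {
      "otus_in_rows"
    } else {
      "samples_in_rows"
    }
  }
  if (orientation == "otus_in_rows") mat <- t(mat)
  abundance_table(mat, taxonomy)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Counts are summed over OTUs sharing the rank label; OTUs with an empty
#' label are pooled into `"unclassified"`, so per-sample totals are conserved
#' exactly.
#'
#' @param table an [abundance_table] with taxonomy.
#' @param rank one of phylum, class, order, family, genus.
#' @return an [abundance_table] whose columns are taxa at `rank` (taxonomy
#'   dropped).
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$taxonomy)) stopf("table carries no taxonomy")
  if (!rank %in% tax_ranks[-c(1, 7)]) {
    stopf("unknown rank '%s' (use one of %s)", rank,
          paste(tax_ranks[-c(1, 7)], collapse = ", "))
  }
  lab <- table$taxonomy[[rank]]
  lab[is.na(lab) | lab == ""] <- "unclassified"
  agg <- t(rowsum(t(table$counts), group = lab))
  abundance_table(agg[, order(colnames(agg)), drop = FALSE])
}

#' Relative abundance matrix
#'
#' @param table an [abundance_table] or samples x taxa matrix.
#' @return matrix of per-sample fractions; rows sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stopf("sample '%s' has all-zero counts", rownames(m)[which(tot == 0)[1]])
  }
  sweep(m, 1, tot, `/`)
}

#' Presence-pattern overlap of OTUs between sample groups
#'
#' An OTU is "present" in a group when it has a nonzero count in at least
#' one of the group's samples. Each OTU present anywhere is assigned to
#' exactly one cell of the Venn partition: the combination of groups it is
#' present in, so the cells are disjoint and sum to the number of OTUs with
#' nonzero total.
#'
#' @param table an [abundance_table].
#' @param traits trait data.frame with `sample_id` and the grouping column.
#' @param group_field name of the grouping column.
#' @return named integer vector; names are `&`-joined group combinations.
#' @export
group_otu_overlap <- function(table, traits, group_field = "group") {
  stopifnot(inherits(table, "abundance_table"))
  g <- traits[[group_field]][match(rownames(table$counts), traits$sample_id)]
  if (any(is.na(g))) stopf("samples missing from trait table")
  groups <- sort(unique(g))
  if (length(groups) < 2) stopf("need at least 2 groups, got %d", length(groups))
  pres <- rowsum(table$counts, group = g) > 0    # groups x OTUs
  pres <- pres[groups, , drop = FALSE]
  combos <- unlist(lapply(seq_along(groups), function(k) {
    utils::combn(groups, k, paste, collapse = "&", simplify = FALSE)
  }))
  pattern <- apply(pres, 2, function(col) paste(groups[col], collapse = "&"))
  counts <- table(factor(pattern[pattern != ""], levels = combos))
  out <- as.integer(counts)
  names(out) <- combos
  out
}
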