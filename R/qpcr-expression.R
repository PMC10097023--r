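#' 2^-ddCt relative expression
#'
#' Per sample and target: \eqn{\Delta Ct = Ct_{target} - Ct_{reference}};
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}} (mean
#' over the control group for the same target, arithmetic by default,
#' median optionally); fold change \eqn{= E^{-\Delta\Delta Ct}} with
#' amplification efficiency E = 2. By construction the geometric mean of
#' the control group's folds is exactly 1 for every target (with mean
#' centring).
#'
#' @param ct a `ct_table` data.frame: sample, group, target, ct_target,
#'   ct_reference.
#' @param control_group label of the control group.
#' @param center `"mean"` or `"median"` centring of control dCt.
#' @param efficiency amplification efficiency (default 2).
#' @return the input with columns `dct`, `ddct` and `fold` appended.
#' @export
relative_expression <- function(ct, control_group, center = c("mean", "median"),
                                efficiency = 2) {
  center <- match.arg(center)
  ct <- as.data.frame(ct)
  need <- c("sample", "group", "target", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stopf("ct table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(is.na(ct$ct_reference))) {
    stopf("missing reference Ct for sample '%s'",
          ct$sample[is.na(ct$ct_reference)][1])
  }
  if (any(is.na(ct$ct_target))) {
    stopf("missing target Ct for sample '%s'", ct$sample[is.na(ct$ct_target)][1])
  }
  if (any(ct$ct_target < 5 | ct$ct_target > 40)) {
    warning("Ct values outside the typical 5-40 cycle range")
  }
  if (!control_group %in% ct$group) {
    stopf("control group '%s' absent", control_group)
  }
  ct$dct <- ct$ct_target - ct$ct_reference
  fun <- if (center == "mean") mean else stats::median
  ctrl <- ct[ct$group == control_group, , drop = FALSE]
  base <- tapply(ctrl$dct, ctrl$target, fun)
  missing_t <- setdiff(unique(ct$target), names(base))
  if (length(missing_t) > 0) {
    stopf("control group empty for target '%s'", missing_t[1])
  }
  ct$ddct <- ct$dct - as.vector(base[ct$target])
  ct$fold <- efficiency^(-ct$ddct)
  ct
}

#' Group summaries of relative expression
#'
#' Per (group, target): mean and sd of fold change, percent change of the
#' group mean versus the control-group mean, and a two-sample Wilcoxon
#' rank-sum p-value against the control group.
#'
#' @param folds output of [relative_expression()].
#' @param control_group control group label.
#' @param test `"wilcox"` or `"t"`.
#' @return data.frame: group, target, n, mean_fold, sd_fold,
#'   percent_change, p_vs_control.
#' @export
expression_summary <- function(folds, control_group, test = c("wilcox", "t")) {
  test <- match.arg(test)
  out <- do.call(rbind, lapply(split(folds, folds[c("group", "target")],
                                     drop = TRUE), function(d) {
    ctrl <- folds$fold[folds$group == control_group &
                       folds$target == d$target[1]]
    p <- if (d$group[1] == control_group) {
      NA_real_
    } else if (test == "wilcox") {
      suppressWarnings(stats::wilcox.test(d$fold, ctrl)$p.value)
    } else {
      stats::t.test(d$fold, ctrl)$p.value
    }
    data.frame(
      group = d$group[1], target = d$target[1], n = nrow(d),
      mean_fold = mean(d$fold), sd_fold = stats::sd(d$fold),
      percent_change = 100 * (mean(d$fold) - mean(ctrl)) / mean(ctrl),
      p_vs_control = p, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$target, out$group), , drop = FALSE]
}
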