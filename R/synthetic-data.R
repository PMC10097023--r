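#' Core genus names used for readable planted designs
#'
#' The five genera used to label the planted trait-linked taxa when a design
#' is built with [core_recovery_design()]: Alistipes, Bacteroides, Blautia,
#' Lachnospiraceae NK4A136 group and Lactobacillus.
#' @export
core_genera <- c(
  "Alistipes", "Bacteroides", "Blautia",
  "Lachnospiraceae NK4A136 group", "Lactobacillus"
)

core_genus_lineage <- c(
  "Alistipes" = "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Rikenellaceae;g__Alistipes;s__",
  "Bacteroides" = "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__",
  "Blautia" = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Blautia;s__",
  "Lachnospiraceae NK4A136 group" = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Lachnospiraceae NK4A136 group;s__",
  "Lactobacillus" = "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__"
)

#' Describe a synthetic amplicon cohort
#'
#' A design specifies correlated OTU blocks (latent-factor modules), an
#' optional module whose latent factor is correlated with a binary longevity
#' trait, optional genera with an extra class-mean shift, and the count model
#' used to turn latent profiles into overdispersed counts. Defaults emulate a
#' cohort of 135 stool samples with a few thousand OTUs.
#'
#' @param n_samples number of samples.
#' @param n_otus total number of OTUs; OTUs not claimed by a module are
#'   background noise with 60--90\% zeros.
#' @param modules data.frame with columns `size` and `latent_corr` (loading
#'   of each member OTU on the module's latent factor, in (0, 1]).
#' @param trait_module index of the module whose latent factor is linked to
#'   the binary trait, or `NA` for none.
#' @param trait_effect target correlation between the trait-module latent
#'   factor and the (standardised) binary trait; 0 gives a null design.
#' @param discriminative_genera named numeric vector, genus -> standardised
#'   mean difference added to that genus' OTUs in trait==1 samples. `NULL`
#'   for none.
#' @param count_model `"lognormal"` (latent Gaussian -> exp -> Poisson) or
#'   `"negative_binomial"`.
#' @param dispersion NB dispersion (1/size); ignored for the lognormal model.
#' @param background_zeros length-2 range of per-OTU zero fractions for
#'   background OTUs.
#' @param seed integer seed; the design is fully reproducible.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_samples = 135, n_otus = 2000,
                             modules = data.frame(
                               size = c(80, 60, 50, 40, 30),
                               latent_corr = 0.8
                             ),
                             trait_module = 1, trait_effect = 0.5,
                             discriminative_genera = NULL,
                             count_model = c("lognormal", "negative_binomial"),
                             dispersion = 0.5,
                             background_zeros = c(0.6, 0.9),
                             seed = 1L) {
  assert_count(n_samples, "n_samples", min = 4)
  assert_count(n_otus, "n_otus", min = 1)
  modules <- as.data.frame(modules)
  if (!all(c("size", "latent_corr") %in% names(modules))) {
    stopf("`modules` needs columns `size` and `latent_corr`")
  }
  if (nrow(modules) > 0) {
    if (any(modules$size < 1)) stopf("module sizes must be >= 1")
    if (any(modules$latent_corr <= 0 | modules$latent_corr > 1)) {
      stopf("`latent_corr` must be in (0, 1]")
    }
    if (sum(modules$size) > n_otus) {
      stopf("invalid design: module sizes sum to %d > n_otus = %d",
            sum(modules$size), n_otus)
    }
  }
  if (!is.na(trait_module)) {
    if (nrow(modules) == 0 || trait_module < 1 || trait_module > nrow(modules)) {
      stopf("`trait_module` must index a row of `modules`")
    }
  }
  if (abs(trait_effect) > 1) stopf("`trait_effect` must be in [-1, 1]")
  if (!is.null(discriminative_genera) &&
      (is.null(names(discriminative_genera)) || !is.numeric(discriminative_genera))) {
    stopf("`discriminative_genera` must be a named numeric vector")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_otus = as.integer(n_otus),
    modules = modules, trait_module = trait_module,
    trait_effect = trait_effect,
    discriminative_genera = discriminative_genera,
    count_model = match.arg(count_model), dispersion = dispersion,
    background_zeros = background_zeros, seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' Study-style design with five planted core genera
#'
#' Convenience wrapper for the end-to-end recovery setting: one trait-linked
#' module whose first half is annotated to the five core genera
#' ([core_genera], with a boosted latent loading and a class-mean shift) and
#' whose second half is filler genera, plus unlinked modules and background
#' noise.
#'
#' @inheritParams synthetic_design
#' @param core_effect standardised mean difference planted for the five core
#'   genera.
#' @export
core_recovery_design <- function(n_samples = 135, n_otus = 800,
                                 trait_effect = 0.5, core_effect = 0.8,
                                 seed = 1L) {
  synthetic_design(
    n_samples = n_samples, n_otus = n_otus,
    modules = data.frame(size = c(60, 50, 40, 30), latent_corr = 0.8),
    trait_module = 1, trait_effect = trait_effect,
    discriminative_genera = stats::setNames(rep(core_effect, 5), core_genera),
    seed = seed
  )
}

#' Generate a synthetic abundance table, trait table and ground truth
#'
#' Samples a balanced binary longevity trait, module latent factors (the
#' trait module's factor correlated `trait_effect` with the standardised
#' trait), per-OTU latent profiles with loading `latent_corr` on their
#' module's factor, and overdispersed counts via a lognormal-Poisson (or
#' negative-binomial) model. Background OTUs are independent and sparse.
#' OTUs of genera named in `discriminative_genera` get an extra mean shift
#' in trait==1 samples and, inside the trait module, a boosted loading so
#' they sit at the module core.
#'
#' @param design a [synthetic_design()].
#' @return list with `abundance` ([abundance_table]), `traits` (trait
#'   data.frame: sample_id, age, sex, group, longevity), and `ground_truth`
#'   (named character vector OTU -> planted module label, "background" for
#'   noise OTUs).
#' @export
generate_abundance <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    n <- design$n_samples
    p <- design$n_otus
    mods <- design$modules
    k <- nrow(mods)

    trait <- sample(rep(c(0L, 1L), length.out = n))
    t_std <- as.numeric(scale(trait))

    sample_ids <- sprintf("S%03d", seq_len(n))
    age <- ifelse(trait == 1L, round(stats::runif(n, 90, 105)),
                  round(stats::runif(n, 55, 89)))
    traits <- data.frame(
      sample_id = sample_ids, age = age,
      sex = sample(c("F", "M"), n, replace = TRUE),
      group = ifelse(trait == 1L, "LG", "YG"),
      longevity = trait, stringsAsFactors = FALSE
    )

    # planted module membership, in OTU-index order
    truth <- rep("background", p)
    member_of <- integer(0)
    if (k > 0) {
      member_of <- rep(seq_len(k), mods$size)
      truth[seq_along(member_of)] <- paste0("M", member_of)
    }

    # taxonomy: genus blocks of 10 OTUs; trait-module OTUs of discriminative
    # genera are aliased to those genus names (first half of the module)
    genus <- paste0("Genus_", sprintf("%03d", (seq_len(p) - 1) %/% 10 + 1))
    loading <- rep(NA_real_, p)
    if (k > 0) loading[seq_along(member_of)] <- mods$latent_corr[member_of]
    shift <- rep(0, p)
    dg <- design$discriminative_genera
    if (!is.null(dg) && !is.na(design$trait_module)) {
      tm_idx <- which(truth == paste0("M", design$trait_module))
      n_core <- min(length(tm_idx), max(length(dg) * 5L, length(tm_idx) %/% 2L))
      core_idx <- tm_idx[seq_len(n_core)]
      genus[core_idx] <- rep(names(dg), length.out = n_core)
      shift[core_idx] <- dg[genus[core_idx]]
      loading[core_idx] <- pmin(0.95, loading[core_idx] + 0.1)
    } else if (!is.null(dg)) {
      for (g in names(dg)) shift[genus == g] <- dg[[g]]
    }

    # latent profiles
    x <- matrix(stats::rnorm(n * p), n, p)
    if (k > 0) {
      z <- matrix(stats::rnorm(n * k), n, k)
      if (!is.na(design$trait_module) && design$trait_effect != 0) {
        te <- design$trait_effect
        j <- design$trait_module
        z[, j] <- te * t_std + sqrt(1 - te^2) * z[, j]
      }
      idx <- seq_along(member_of)
      l <- loading[idx]
      x[, idx] <- sweep(z[, member_of, drop = FALSE], 2, l, `*`) +
        sweep(x[, idx, drop = FALSE], 2, sqrt(1 - l^2), `*`)
    }
    x <- x + outer(trait, shift)

    # counts
    base <- stats::runif(p, log(2), log(40))
    if (k > 0) base[seq_along(member_of)] <- stats::runif(length(member_of),
                                                          log(8), log(60))
    mu <- exp(sweep(x, 2, base, `+`))
    counts <- if (design$count_model == "lognormal") {
      matrix(stats::rpois(n * p, lambda = mu), n, p)
    } else {
      matrix(stats::rnbinom(n * p, mu = mu, size = 1 / design$dispersion), n, p)
    }

    # background sparsity
    bg <- which(truth == "background")
    if (length(bg) > 0) {
      zf <- stats::runif(length(bg), design$background_zeros[1],
                         design$background_zeros[2])
      keep <- matrix(stats::rbinom(n * length(bg), 1L, rep(1 - zf, each = n)),
                     n, length(bg))
      counts[, bg] <- counts[, bg, drop = FALSE] * keep
    }

    otu_ids <- sprintf("OTU_%04d", seq_len(p))
    dimnames(counts) <- list(sample_ids, otu_ids)
    taxonomy <- make_taxonomy(otu_ids, genus)
    names(truth) <- otu_ids
    list(
      abundance = abundance_table(counts, taxonomy),
      traits = traits,
      ground_truth = truth
    )
  })
}

# Build a 7-rank taxonomy frame from genus labels; core genera get their
# canonical lineages, synthetic genera cycle through four common phyla.
make_taxonomy <- function(otu_ids, genus) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria")
  classes <- c("Clostridia", "Bacteroidia", "Gammaproteobacteria", "Actinobacteria")
  ugen <- unique(genus)
  lineage_of <- stats::setNames(vapply(seq_along(ugen), function(i) {
    g <- ugen[i]
    if (g %in% names(core_genus_lineage)) return(core_genus_lineage[[g]])
    j <- (i - 1) %% 4 + 1
    sprintf("k__Bacteria;p__%s;c__%s;o__Order_%02d;f__Family_%02d;g__%s;s__",
            phyla[j], classes[j], j, (i - 1) %% 20 + 1, g)
  }, character(1)), ugen)
  lin <- unname(lineage_of[genus])
  ranks <- parse_lineage(lin)
  cbind(data.frame(otu_id = otu_ids, stringsAsFactors = FALSE), ranks,
        data.frame(lineage = lin, stringsAsFactors = FALSE))
}

#' Generate a synthetic probiotic strain-property table
#'
#' Three indicators (gastrointestinal survival, self-aggregation,
#' hydrophobicity, all percentages) are driven by one common latent factor
#' plus independent noise, so their correlation matrix is factor-dominated
#' and sampling adequacy (KMO) is high for small `noise_sd`.
#'
#' @param n_strains number of strains (>= 3).
#' @param factor_loadings length-3 loadings of the indicators on the common
#'   factor.
#' @param noise_sd independent noise standard deviation on the latent scale.
#' @param seed integer seed.
#' @return a `strain_property_table` data.frame: strain, source (CE/GE),
#'   gi_survival, self_aggregation, hydrophobicity.
#' @export
generate_strain_properties <- function(n_strains = 14,
                                       factor_loadings = c(1, 1, 1),
                                       noise_sd = 0.5, seed = 1L) {
  if (n_strains < 3) stopf("`n_strains` must be >= 3 (PCA undefined below)")
  stopifnot(length(factor_loadings) == 3, noise_sd >= 0)
  with_seed(seed, {
    f <- stats::rnorm(n_strains)
    lat <- outer(f, factor_loadings) +
      noise_sd * matrix(stats::rnorm(3 * n_strains), n_strains, 3)
    # map latent values onto realistic percentage scales
    centre <- c(55, 50, 60)
    spread <- c(15, 14, 12)
    pct <- pmin(pmax(sweep(sweep(lat, 2, spread, `*`), 2, centre, `+`), 0), 100)
    out <- data.frame(
      strain = sprintf("STR%02d", seq_len(n_strains)),
      source = rep(c("CE", "GE"), length.out = n_strains),
      gi_survival = pct[, 1], self_aggregation = pct[, 2],
      hydrophobicity = pct[, 3], stringsAsFactors = FALSE
    )
    class(out) <- c("strain_property_table", "data.frame")
    out
  })
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' The reference gene has a fixed baseline Ct; each target's Ct in the
#' treatment group is shifted by `-log2(fold change)` relative to the control
#' baseline, plus Gaussian noise, so the downstream 2^-ddCt computation
#' recovers the planted fold changes (exactly when `ct_noise_sd = 0`).
#'
#' @param n_per_group samples per group.
#' @param true_fold_changes named positive numeric vector, target -> fold
#'   change of treatment vs control.
#' @param ct_noise_sd Gaussian noise sd on target Ct values (cycles).
#' @param seed integer seed.
#' @param groups labels for (control, treatment).
#' @return a `ct_table` data.frame: sample, group, target, ct_target,
#'   ct_reference.
#' @export
generate_ct_table <- function(n_per_group, true_fold_changes,
                              ct_noise_sd = 0, seed = 1L,
                              groups = c("control", "treatment")) {
  assert_count(n_per_group, "n_per_group")
  if (is.null(names(true_fold_changes)) || any(true_fold_changes <= 0)) {
    stopf("`true_fold_changes` must be a named vector of positive numbers")
  }
  stopifnot(length(groups) == 2)
  with_seed(seed, {
    targets <- names(true_fold_changes)
    ref_ct <- 15
    base_ct <- stats::setNames(20 + 2 * seq_along(targets), targets)
    rows <- expand.grid(rep = seq_len(n_per_group), group = groups,
                        target = targets, stringsAsFactors = FALSE)
    shift <- ifelse(rows$group == groups[2],
                    -log2(true_fold_changes[rows$target]), 0)
    out <- data.frame(
      sample = sprintf("%s_%02d", rows$group, rows$rep),
      group = rows$group, target = rows$target,
      ct_target = base_ct[rows$target] + shift +
        stats::rnorm(nrow(rows), 0, ct_noise_sd),
      ct_reference = ref_ct,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
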