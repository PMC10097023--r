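test_that("generation is deterministic under a fixed seed", {
  d <- synthetic_design(n_samples = 40, n_otus = 120,
                        modules = data.frame(size = 30, latent_corr = 0.8),
                        seed = 42)
  g1 <- generate_abundance(d)
  g2 <- generate_abundance(d)
  expect_identical(g1$abundance$counts, g2$abundance$counts)
  expect_identical(g1$traits, g2$traits)
  expect_identical(g1$ground_truth, g2$ground_truth)

  s1 <- generate_strain_properties(10, seed = 7)
  s2 <- generate_strain_properties(10, seed = 7)
  expect_identical(s1, s2)

  c1 <- generate_ct_table(5, c(g = 2), ct_noise_sd = 0.3, seed = 3)
  c2 <- generate_ct_table(5, c(g = 2), ct_noise_sd = 0.3, seed = 3)
  expect_identical(c1, c2)
})

test_that("invalid designs are rejected", {
  expect_error(synthetic_design(n_otus = 50,
                                modules = data.frame(size = c(30, 30),
                                                     latent_corr = 0.8)),
               "invalid design")
  expect_error(synthetic_design(modules = data.frame(size = 10,
                                                     latent_corr = 1.2)),
               "latent_corr")
  expect_error(generate_strain_properties(2), ">= 3")
  expect_error(generate_ct_table(5, c(g = -1)), "positive")
})

test_that("planted modules are more correlated than background", {
  d <- synthetic_design(n_samples = 100, n_otus = 200,
                        modules = data.frame(size = 50, latent_corr = 0.9),
                        trait_module = NA, trait_effect = 0, seed = 11)
  g <- generate_abundance(d)
  m <- transform_counts(g$abundance)
  keep <- apply(m, 2, sd) > 0
  m <- m[, keep]
  truth <- g$ground_truth[colnames(m)]
  cc <- cor(m)
  diag(cc) <- NA
  in_mod <- truth == "M1"
  mean_within <- mean(abs(cc[in_mod, in_mod]), na.rm = TRUE)
  mean_bg <- mean(abs(cc[!in_mod, !in_mod]), na.rm = TRUE)
  expect_gt(mean_within, mean_bg)
  # counts are valid
  expect_true(all(g$abundance$counts >= 0))
  expect_true(all(g$abundance$counts == floor(g$abundance$counts)))
})

test_that("null designs plant no trait association", {
  # eigengene of the planted block is uncorrelated with the trait when
  # trait_effect = 0: |r| stays below 3/sqrt(n) in almost all seeds, and the
  # eigengene-trait p-values are close to uniform
  n <- 60
  rs <- ps <- numeric(120)
  for (s in seq_along(rs)) {
    d <- synthetic_design(n_samples = n, n_otus = 60,
                          modules = data.frame(size = 25, latent_corr = 0.8),
                          trait_module = 1, trait_effect = 0, seed = 1000 + s)
    g <- generate_abundance(d)
    m <- transform_counts(g$abundance)
    eg <- module_eigengene(m, names(g$ground_truth)[g$ground_truth == "M1"])
    rs[s] <- cor(eg$eigengene, g$traits$longevity)
    ps[s] <- cor.test(eg$eigengene, g$traits$longevity)$p.value
  }
  expect_gte(mean(abs(rs) < 3 / sqrt(n)), 0.97)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("eigengene-trait correlation grows with the planted effect", {
  mean_abs_r <- sapply(c(0.2, 0.6), function(te) {
    mean(sapply(1:8, function(s) {
      d <- synthetic_design(n_samples = 80, n_otus = 80,
                            modules = data.frame(size = 30, latent_corr = 0.8),
                            trait_module = 1, trait_effect = te, seed = s)
      g <- generate_abundance(d)
      m <- transform_counts(g$abundance)
      eg <- module_eigengene(m, names(g$ground_truth)[g$ground_truth == "M1"])
      abs(cor(eg$eigengene, g$traits$longevity))
    }))
  })
  expect_gt(mean_abs_r[2], mean_abs_r[1])
})

test_that("strain indicators approach a rank-one factor as noise vanishes", {
  tiny <- generate_strain_properties(14, noise_sd = 1e-3, seed = 5)
  ev <- eigen(cor(tiny[, c("gi_survival", "self_aggregation",
                           "hydrophobicity")]))$values
  expect_gt(ev[1], 2.99)
  # stated generator condition: unit loadings, noise 0.5, 14 strains
  tab <- generate_strain_properties(14, c(1, 1, 1), noise_sd = 0.5, seed = 21)
  expect_gt(kmo(tab), 0.6)
})

test_that("ct tables encode the planted fold changes", {
  ct <- generate_ct_table(4, c(a = 1, b = 4), ct_noise_sd = 0, seed = 1)
  fx <- relative_expression(ct, "control")
  expect_equal(unique(fx$fold[fx$group == "treatment" & fx$target == "a"]), 1)
  expect_equal(unique(fx$fold[fx$group == "treatment" & fx$target == "b"]), 4)
  # with noise the group mean stays near the planted value
  ct2 <- generate_ct_table(12, c(g = 2), ct_noise_sd = 0.2, seed = 9)
  fx2 <- relative_expression(ct2, "control")
  m <- mean(fx2$fold[fx2$group == "treatment"])
  expect_gt(m, 1.6)
  expect_lt(m, 2.5)
})
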