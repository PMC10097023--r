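test_that("MAD filter keeps the most variable OTUs with deterministic ties", {
  m <- cbind(const = rep(5, 10), vary = c(1:9, 30))
  expect_equal(colnames(mad_filter(m, 0.5)), "vary")
  expect_equal(mad_filter(m, 1.0), m)

  set.seed(3)
  r <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(NULL, letters[1:10]))
  got <- colnames(mad_filter(r, 0.4))
  mads <- apply(r, 2, function(x) median(abs(x - median(x))))
  want <- sort(colnames(r)[order(-mads, seq_len(10))][1:4])
  expect_equal(got, want)
})

test_that("scale-free fit is 1 for an exact power law and signed by slope", {
  k <- rep(c(1, 2, 4, 8), times = c(1600, 400, 100, 25))
  expect_equal(scale_free_fit(k, n_bins = 8), 1, tolerance = 1e-12)
  # increasing frequency with k gives a negative signed fit
  k_inc <- rep(c(1, 2, 4, 8), times = c(25, 100, 400, 1600))
  expect_lt(scale_free_fit(k_inc, n_bins = 8), 0)
  expect_error(scale_free_fit(rep(2, 50)), "constant")

  # independent regression oracle on random connectivities
  set.seed(9)
  k_r <- rexp(500, 0.2)
  breaks <- seq(min(k_r), max(k_r), length.out = 11)
  bin <- cut(k_r, breaks, include.lowest = TRUE)
  fr <- as.numeric(table(bin)) / length(k_r)
  km <- tapply(k_r, bin, mean)
  ok <- fr > 0 & km > 0
  fit <- lm(log10(fr[ok]) ~ log10(km[ok]))
  want <- -sign(coef(fit)[2]) * summary(fit)$r.squared
  expect_equal(scale_free_fit(k_r), unname(want), tolerance = 1e-10)
})

test_that("adjacency implements the soft-threshold formulas", {
  x <- c(1, 2, 3, 4)
  m <- cbind(a = x, b = 2 * x + 1)               # cor exactly 1
  expect_equal(unname(adjacency_matrix(m, 7)[1, 2]), 1)

  u <- c(1, -1, 0)
  v <- c(-1, 0, 1)                               # cor exactly -0.5
  m2 <- cbind(a = u, b = v)
  expect_equal(unname(adjacency_matrix(m2, 2)[1, 2]), 0.25)
  expect_equal(unname(adjacency_matrix(m2, 2, "signed")[1, 2]), 0.25^2)

  set.seed(4)
  m3 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(adjacency_matrix(m3, 1), abs(cor(m3)))
  m3[, 2] <- 1
  expect_error(adjacency_matrix(m3, 2), "zero-variance OTU 'b'")
})

test_that("TOM matches hand evaluation and the brute-force oracle", {
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1)
  expect_equal(tom[1, 3], 0)
  expect_equal(unname(diag(tom)), rep(1, 3))

  expect_equal(tom_similarity(diag(4)), diag(4))
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")

  set.seed(12)
  for (i in 1:20) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
})

test_that("soft-threshold selection honours the target and connectivity decreases in beta", {
  set.seed(5)
  f <- rnorm(150)
  m <- cbind(sapply(1:30, function(i) 0.9 * f + sqrt(0.19) * rnorm(150)),
             matrix(rnorm(150 * 170), 150, 170))
  colnames(m) <- paste0("O", seq_len(ncol(m)))
  cfg <- network_config(power_grid = c(1:10, 12, 14))
  sft <- pick_soft_threshold(m, cfg)
  expect_true(sft$power %in% cfg$power_grid)
  expect_lte(sft$power, 8)
  expect_gte(sft$report$sft_rsq[sft$report$power == sft$power], 0.85)
  expect_true(all(diff(sft$report$mean_k) < 0))

  cfg0 <- network_config(power_grid = c(3, 5, 7), rsq_target = 0)
  expect_equal(pick_soft_threshold(m, cfg0)$power, 3)
})

test_that("module eigengenes summarise members with the documented orientation", {
  x <- rnorm(20)
  m <- cbind(a = x, b = 2 * x + 3, c = 0.5 * x - 1)   # identical profiles
  eg <- module_eigengene(m, c("a", "b", "c"))
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengene, x)), 1, tolerance = 1e-12)
  expect_gte(cor(eg$eigengene, x), 0)
  expect_equal(sd(eg$eigengene), 1, tolerance = 1e-12)

  m2 <- cbind(a = x, b = -x)                          # anti-correlated pair
  eg2 <- module_eigengene(m2, c("a", "b"))
  expect_equal(eg2$variance_explained, 1, tolerance = 1e-12)
  expect_gte(cor(eg2$eigengene, x), 0)                # first-member fallback
  expect_error(module_eigengene(m2, "a"), ">= 2")

  # variance explained equals the leading eigenvalue share of the
  # correlation matrix (independent eigen-decomposition oracle)
  set.seed(6)
  m3 <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, letters[1:6]))
  eg3 <- module_eigengene(m3, letters[1:6])
  ev <- eigen(cor(m3))$values
  expect_equal(eg3$variance_explained, ev[1] / sum(ev), tolerance = 1e-10)
})

test_that("planted blocks are detected as pure modules and noise stays grey", {
  set.seed(2)
  n <- 60
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  m <- cbind(sapply(1:30, function(i) sqrt(0.9) * z1 + sqrt(0.1) * rnorm(n)),
             sapply(1:30, function(i) sqrt(0.9) * z2 + sqrt(0.1) * rnorm(n)))
  colnames(m) <- paste0("V", 1:60)
  lab <- detect_modules(1 - tom_similarity(adjacency_matrix(m, 6)),
                        network_config())
  truth <- rep(c("b1", "b2"), each = 30)
  expect_equal(length(setdiff(unique(lab), "grey")), 2)
  purity <- mean(sapply(split(truth, lab), function(tt) max(table(tt)) /
                                                        length(tt)))
  expect_gte(purity, 0.95)

  # order invariance up to relabelling
  perm <- sample(60)
  lab_p <- detect_modules(1 - tom_similarity(adjacency_matrix(m[, perm], 6)),
                          network_config())[colnames(m)]
  map <- tapply(lab_p, lab, function(v) names(which.max(table(v))))
  expect_equal(unname(lab_p), as.character(map[lab]))

  # independent OTUs stay grey
  set.seed(7)
  noise <- matrix(rnorm(50 * 120), 50, 120,
                  dimnames = list(NULL, paste0("N", 1:120)))
  lab_n <- detect_modules(1 - tom_similarity(adjacency_matrix(noise, 6)),
                          network_config())
  expect_gte(mean(lab_n == "grey"), 0.9)

  # fewer OTUs than the minimum size: everything grey, with a warning
  tiny <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, paste0("t", 1:5)))
  expect_warning(lab_t <- detect_modules(1 - tom_similarity(
    adjacency_matrix(tiny, 2)), network_config()), "grey")
  expect_true(all(lab_t == "grey"))
})

test_that("module merging collapses duplicate modules and keeps orthogonal ones", {
  set.seed(8)
  n <- 40
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  m <- cbind(sapply(1:10, function(i) z1 + 0.1 * rnorm(n)),
             sapply(1:10, function(i) z1 + 0.1 * rnorm(n)),
             sapply(1:10, function(i) z2 + 0.1 * rnorm(n)))
  colnames(m) <- paste0("V", 1:30)
  lab <- setNames(rep(c("blue", "brown", "turquoise"), each = 10),
                  colnames(m))
  merged <- merge_modules(m, lab, 0.25)
  # the two copies of z1 merge; the z2 module stays separate
  expect_equal(length(unique(merged[1:20])), 1)
  expect_equal(length(setdiff(unique(merged), "grey")), 2)

  # enumeration-order invariance
  lab2 <- setNames(rep(c("turquoise", "blue", "brown"), each = 10),
                   colnames(m))
  merged2 <- merge_modules(m, lab2, 0.25)
  expect_equal(unname(merged2), unname(merged))
})

test_that("module-trait statistics match the correlation-test oracle", {
  set.seed(10)
  n <- 50
  z <- rnorm(n)
  m <- cbind(sapply(1:12, function(i) 0.9 * z + sqrt(0.19) * rnorm(n)),
             sapply(1:12, function(i) rnorm(n)))
  colnames(m) <- paste0("V", 1:24)
  lab <- setNames(rep(c("turquoise", "blue"), each = 12), colnames(m))
  traits <- data.frame(longevity = rbinom(n, 1, 0.5), age = rnorm(n, 70, 8))

  res <- module_trait(m, lab, traits)
  for (i in seq_len(nrow(res$module_trait))) {
    row <- res$module_trait[i, ]
    ct <- cor.test(res$eigengenes[, paste0("ME", row$module)],
                   traits[[row$trait]])
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  }

  # trait identical to an eigengene: r = 1, vanishing p
  tr2 <- data.frame(me = res$eigengenes[, "MEturquoise"])
  res2 <- module_trait(m, lab, tr2)
  r_self <- res2$module_trait$r[res2$module_trait$module == "turquoise"]
  expect_equal(r_self, 1, tolerance = 1e-10)
  expect_lt(res2$module_trait$p[res2$module_trait$module == "turquoise"],
            1e-12)

  # flipping the binary coding negates r and preserves p
  flipped <- data.frame(longevity = 1 - traits$longevity)
  res3 <- module_trait(m, lab, flipped)
  ref <- res$module_trait[res$module_trait$trait == "longevity", ]
  expect_equal(res3$module_trait$r, -ref$r, tolerance = 1e-12)
  expect_equal(res3$module_trait$p, ref$p, tolerance = 1e-12)

  expect_error(module_trait(m, lab, data.frame(x = rep(1, n))), "constant")
})
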