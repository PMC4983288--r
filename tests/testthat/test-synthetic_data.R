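small_cfg <- function(...) {
  sim_config(n_accessions = 40, n_markers = 120,
             linkage_groups = c("Mrg01", "Mrg02", "Mrg03"),
             lg_lengths_cM = c(100, 80, 60), unmapped_frac = 0.1,
             subgroups_per_group = 2, ...)
}

test_that("the noiseless limit reproduces bulk frequencies exactly", {
  cfg <- small_cfg(fst_group = 0, fst_subgroup = 0, signal_bias_a = 0,
                   signal_gain_b = 1, signal_sd = 0)
  sim <- simulate_genotypes(cfg, seed = 101)
  ratio <- sim$signals$X / (sim$signals$X + sim$signals$Y)
  expect_equal(ratio, sim$truth$bulk_freq, tolerance = 1e-12)
  ## frequencies on the 1/(2*plants) grid
  expect_true(all(abs(sim$truth$bulk_freq * 20 -
                        round(sim$truth$bulk_freq * 20)) < 1e-12))
})

test_that("generation is deterministic under a seed, global RNG untouched", {
  cfg <- small_cfg()
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_genotypes(cfg, seed = 7)
  expect_identical(.Random.seed, before)
  s2 <- simulate_genotypes(cfg, seed = 7)
  expect_identical(s1$signals$X, s2$signals$X)
  expect_identical(s1$map, s2$map)
  s3 <- simulate_genotypes(cfg, seed = 8)
  expect_false(identical(s1$signals$X, s3$signals$X))
  p1 <- simulate_phenotypes(s1$truth, seed = 7)
  p2 <- simulate_phenotypes(s2$truth, seed = 7)
  expect_identical(p1$pheno, p2$pheno)
})

test_that("structure is recoverable from PC1 in nearly every seed", {
  hits <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(n_accessions = 40, n_markers = 100,
                      linkage_groups = "Mrg01", lg_lengths_cM = 100,
                      unmapped_frac = 0, subgroups_per_group = 2,
                      fst_group = 0.15, fst_subgroup = 0.02)
    sim <- simulate_genotypes(cfg, seed = seed)
    qc <- qc_pipeline(sim$signals)
    pc <- pca_ratios(qc$ratios, 1)
    g <- as.integer(factor(sim$truth$groups[rownames(qc$ratios$ratio)]))
    if (abs(cor(pc$scores[, 1], g)) > 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("Fv/Fm draws live in [0, 0.77] and follow the truth", {
  cfg <- small_cfg()
  sim <- simulate_genotypes(cfg, seed = 5)
  ph <- simulate_phenotypes(sim$truth, seed = 6)
  fv <- ph$pheno[ph$pheno$trait == "fvfm", ]
  expect_true(all(fv$value >= 0 & fv$value <= 0.77))
  expect_equal(sort(unique(fv$condition)), c("optimal", "sub-optimal"))
  ## 5 experiments x 6 plants per accession
  expect_equal(nrow(fv), 40 * 30)
  expect_true(all(ph$truth$tolerance_prob > 0 &
                    ph$truth$tolerance_prob < 1))
})

test_that("flat truth gives equal tolerance probabilities everywhere", {
  cfg <- small_cfg(h2_polygenic = 0, liability_scale = 0,
                   logit_intercept = 0.4)
  sim <- simulate_genotypes(cfg, seed = 11)
  ph <- simulate_phenotypes(sim$truth, seed = 12)
  expect_equal(unname(diff(range(ph$truth$tolerance_prob))), 0)
})

test_that("non-overlapping Fv/Fm mixtures binarize to the true states", {
  cfg <- small_cfg(fvfm_beta_tol = c(200, 1), fvfm_beta_sus = c(1, 200))
  sim <- simulate_genotypes(cfg, seed = 13)
  ph <- simulate_phenotypes(sim$truth, seed = 14)
  fv <- ph$pheno[ph$pheno$trait == "fvfm", ]
  sc <- binarize_fvfm(fv$value, 0.38)
  ## tolerant component is concentrated just under 0.77, susceptible
  ## just above 0: binarized scores are exactly the plant states
  expect_true(all(fv$value[sc == 1] > 0.7))
  expect_true(all(fv$value[sc == 0] < 0.05))
})

test_that("a planted QTL appears in the phenotype truth with its effect", {
  cfg <- small_cfg(qtl = data.frame(marker = NA_character_,
                                    var_explained = 0.25),
                   h2_polygenic = 0.3)
  sim <- simulate_genotypes(cfg, seed = 15)
  ph <- simulate_phenotypes(sim$truth, seed = 16)
  expect_equal(nrow(ph$truth$qtl), 1)
  expect_true(ph$truth$qtl$marker %in% sim$map$marker)
  x <- sim$truth$bulk_freq[, ph$truth$qtl$marker]
  expect_equal(ph$truth$qtl$beta, sqrt(0.25) / sd(x), tolerance = 1e-12)
  ## the QTL marker correlates with the liability
  expect_gt(abs(cor(x, ph$truth$liability)), 0.3)
})

test_that("the latent AR(1) coupling induces LD that falls with distance", {
  cfg <- sim_config(n_accessions = 100, n_markers = 80,
                    linkage_groups = "Mrg01", lg_lengths_cM = 100,
                    unmapped_frac = 0, fst_group = 0, fst_subgroup = 0,
                    fst_accession = 0, ld_scale_cM = 10)
  sim <- simulate_genotypes(cfg, seed = 17)
  f <- sim$truth$bulk_freq
  mp <- sim$map[order(sim$map$position_cM), ]
  cc <- cor(f[, mp$marker])
  d <- abs(outer(mp$position_cM, mp$position_cM, "-"))
  near <- d > 0 & d < 2; far <- d > 40
  expect_gt(mean(cc[near]^2), mean(cc[far]^2) + 0.2)
})
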