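test_that("auroc matches hand-computed and boundary cases", {
  expect_equal(auroc(c(3, 2, 1, 2.5), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rank-based auroc equals brute force over random tied instances", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(10:500, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # many ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
})

test_that("auroc respects negation and monotone-transform invariance", {
  set.seed(203)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, plogis(scores))
  a <- auroc(scores, labels)
  expect_equal(auroc(-scores, labels), 1 - a)
  expect_equal(auroc(exp(2 * scores) + 5, labels), a)
})

test_that("threshold_variants selects by p with the P = 0 convention", {
  ss <- rand_sumstats(5, seed = 3)
  ss$pvalue <- c(0.001, 0.02, 0.04, 0.2, 0.6)
  expect_length(threshold_variants(ss, 1), 5)
  expect_length(threshold_variants(ss, 0), 0)
  expect_length(threshold_variants(ss, 0.05), 3)
})

test_that("scoring is a weighted allele sum with orientation handling", {
  G <- matrix(c(0, 2, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("v1", "v2")))
  w <- structure(data.frame(variant_id = c("v1", "v2"),
                            effect_allele = c("A", "C"),
                            weight = c(0.5, -0.25)),
                 class = c("prs_weights", "data.frame"))
  expect_equal(as.vector(score_prs(G, w)), c(-0.5, 0.25))
  # single variant with weight 1: the score is the dosage
  w1 <- w[1, , drop = FALSE]; w1$weight <- 1
  expect_equal(as.vector(score_prs(G, w1)), G[, "v1"])
  # all-zero weights give a zero vector
  w0 <- w; w0$weight <- 0
  expect_equal(as.vector(score_prs(G, w0)), c(0, 0))
  # linearity in weights
  wa <- w; wa$weight <- c(0.2, 0.3)
  wb <- w; wb$weight <- c(-0.1, 0.5)
  wsum <- w; wsum$weight <- wa$weight + wb$weight
  expect_equal(score_prs(G, wsum)[1:2], (score_prs(G, wa) + score_prs(G, wb))[1:2])
})

test_that("allele flips and missing variants are handled in scoring", {
  G <- matrix(c(0, 2, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("v1", "v2")))
  ea <- c(v1 = "A", v2 = "C"); oa <- c(v1 = "G", v2 = "T")
  # weight on the other allele: dosage flips to 2 - x
  w <- structure(data.frame(variant_id = "v1", effect_allele = "G", weight = 1),
                 class = c("prs_weights", "data.frame"))
  s <- score_prs(G, w, effect_alleles = ea, other_alleles = oa)
  expect_equal(as.vector(s), 2 - G[, "v1"])
  # unmatchable allele and absent variant are skipped and counted
  w2 <- structure(data.frame(variant_id = c("v1", "v2", "v9"),
                             effect_allele = c("A", "G", "A"),
                             weight = c(1, 1, 1)),
                  class = c("prs_weights", "data.frame"))
  s2 <- score_prs(G, w2, effect_alleles = ea, other_alleles = oa)
  expect_equal(attr(s2, "n_missing"), 1L)
  expect_equal(attr(s2, "n_mismatched"), 1L)
  expect_equal(attr(s2, "n_used"), 1L)
  expect_error(score_prs(G, w2[3, ]), "no usable")
})

test_that("clumping keeps all variants under linkage equilibrium", {
  cfg <- sim_config(n_variants = 100, n_causal = 5, n_train = 800,
                    n_target = 200, seed = 21)
  ds <- simulate_population(cfg)
  ss <- run_gwas(ds, "consortium")
  kept <- clump(ss, ds$genotypes, r2_threshold = 0.1)
  expect_setequal(kept, ss$variant_id)
})

test_that("clumping keeps the most significant of a correlated pair", {
  set.seed(22)
  x <- rbinom(500, 2, 0.3)
  G <- cbind(v1 = x, v2 = x) # perfect LD
  ss <- as_sumstats(data.frame(
    variant_id = c("v1", "v2"), chrom = "1", pos = c(1000, 2000),
    effect_allele = "A", other_allele = "G",
    beta = c(0.5, 0.3), se = c(0.087, 0.078))) # p = 1e-8-ish and 1e-4-ish
  ss$pvalue <- c(1e-8, 1e-4)
  kept <- clump(ss, G, r2_threshold = 0.1)
  expect_equal(as.vector(kept), "v1")
})

test_that("block-LD clumping retains exactly one representative per block", {
  cfg <- sim_config(n_variants = 100, n_causal = 10, h2 = 0.4,
                    n_train = 1500, n_target = 500,
                    ld_blocks = list(size = 10, r = 0.95), seed = 23)
  ds <- simulate_population(cfg)
  ss <- run_gwas(ds, "consortium")
  kept <- clump(ss, ds$genotypes, r2_threshold = 0.1)
  block <- (match(kept, ds$variants$variant_id) - 1) %/% 10
  expect_length(kept, 10)
  expect_equal(sort(unique(block)), 0:9)
})

test_that("variants missing from the reference pass through unclumped", {
  cfg <- sim_config(n_variants = 50, n_causal = 5, n_train = 500,
                    n_target = 200, seed = 24)
  ds <- simulate_population(cfg)
  ss <- run_gwas(ds, "consortium")
  ref <- ds$genotypes[, 1:40]
  kept <- clump(ss, ref, r2_threshold = 0.1)
  expect_equal(attr(kept, "n_missing_reference"), 10L)
  expect_true(all(ss$variant_id[41:50] %in% kept))
})

test_that("or_per_sd recovers a known log-odds slope and flags separation", {
  set.seed(25)
  s <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(-0.5 + 0.5 * s))
  fit <- or_per_sd(s, y)
  expect_equal(fit$flag, "ok")
  expect_lt(abs(fit$or - exp(0.5)), 0.1)
  # independent scores: OR near 1
  y0 <- rbinom(5000, 1, 0.4)
  expect_lt(abs(or_per_sd(s, y0)$or - 1), 0.1)
  # near-perfect separation diverges and is flagged
  ysep <- as.integer(s > 0)
  fsep <- or_per_sd(s + rnorm(5000, sd = 1e-4), ysep)
  expect_true(fsep$flag %in% c("separation", "nonconvergence"))
  expect_error(or_per_sd(rep(1, 10), rep(c(0, 1), 5)), "constant")
})

test_that("evaluate_prs reports per-group metrics and non-evaluable groups", {
  set.seed(26)
  n <- 400
  part <- rep(c("overlap", "target_only"), each = n / 2)
  y <- rbinom(n, 1, 0.3)
  s <- y + rnorm(n)
  ev <- evaluate_prs(s, y, part)
  expect_equal(ev$group, c("total", "overlap", "non_overlap"))
  expect_equal(ev$n, c(400, 200, 200))
  expect_true(all(ev$evaluable))
  expect_equal(ev$n_cases[1], sum(y))
  # identical score distributions: groups agree within Monte-Carlo noise
  expect_lt(abs(ev$auroc[2] - ev$auroc[3]), 0.1)
  # no overlap samples: overlap group marked not evaluable
  ev2 <- evaluate_prs(s, y, rep("target_only", n))
  expect_false(ev2$evaluable[ev2$group == "overlap"])
  expect_true(is.na(ev2$auroc[ev2$group == "overlap"]))
})

test_that("overlap contamination inflates the overlap-group AUROC", {
  run <- overlap_study_run(1)
  expect_gt(run$unadj_ov, run$unadj_non)
})

test_that("build_prs_ct selects a threshold by total-target AUROC", {
  cfg <- sim_config(n_variants = 300, n_causal = 15, h2 = 0.5,
                    n_train = 2000, n_target = 600, overlap_fraction = 0,
                    seed = 27)
  ds <- simulate_population(cfg)
  ss <- run_gwas(ds, "consortium")
  tgt <- partition_indices(ds, "target")
  prs <- build_prs_ct(ss, ds$genotypes[tgt, ], ds$phenotype[tgt])
  expect_true(prs$best_p %in% prs$grid$p_max)
  expect_equal(max(prs$grid$auroc, na.rm = TRUE),
               auroc(prs$scores, ds$phenotype[tgt]))
  expect_equal(prs$grid$n_variants[prs$grid$p_max == 1], 300L)
})
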