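test_that("ivw_meta combines estimates with inverse-variance weights", {
  m <- ivw_meta(0.0866667, 0.0516398, 0.30, 0.20)
  expect_equal(m$b, 0.10, tolerance = 1e-4)
  expect_equal(m$se, 0.05, tolerance = 1e-4)
  # equal inputs: same estimate, se shrinks by sqrt(2)
  m2 <- ivw_meta(0.2, 0.1, 0.2, 0.1)
  expect_equal(m2$b, 0.2)
  expect_equal(m2$se, 0.1 / sqrt(2))
  # an uninformative study changes nothing
  m3 <- ivw_meta(0.2, 0.1, 0.9, 1e6)
  expect_equal(m3$b, 0.2, tolerance = 1e-6)
  expect_equal(m3$se, 0.1, tolerance = 1e-6)
  expect_error(ivw_meta(0.1, 0, 0.1, 0.1), "positive")
})

test_that("ivw_inverse recovers the remainder and flags unstable variants", {
  inv <- ivw_inverse(0.10, 0.05, 0.30, 0.20)
  expect_false(inv$unstable)
  expect_equal(inv$b, 0.0866667, tolerance = 1e-6)
  expect_equal(inv$se, 0.0516398, tolerance = 1e-6)
  # removing an uninformative overlap is a no-op
  inv2 <- ivw_inverse(0.1, 0.1, 5, 1e9)
  expect_equal(inv2$b, 0.1, tolerance = 1e-6)
  expect_equal(inv2$se, 0.1, tolerance = 1e-6)
  # equal precision: zero remainder precision, inversion undefined
  inv3 <- ivw_inverse(0.1, 0.1, 0.1, 0.1)
  expect_true(inv3$unstable)
  expect_true(is.na(inv3$b))
})

test_that("z_meta and z_inverse implement sqrt(n)-weighted combination", {
  expect_equal(z_meta(2.0, 100, 2.49559, 900), 3.0, tolerance = 1e-4)
  # equal z from both studies combines to z (sqrt(n) + sqrt(m))/sqrt(n + m)
  expect_equal(z_meta(1.3, 250, 1.3, 700),
               1.3 * (sqrt(250) + sqrt(700)) / sqrt(950))
  expect_equal(z_meta(0, 10, 0, 20), 0)
  inv <- z_inverse(3.0, 1000, 2.0, 100)
  expect_equal(inv$n, 900)
  expect_equal(inv$z, 2.49559, tolerance = 1e-4)
  expect_equal(z_inverse(0, 100, 0, 40)$z, 0)
  expect_error(z_inverse(1, 100, 1, 100), "exceed")
  expect_error(z_meta(1, 0, 1, 10), ">= 1")
})

test_that("meta-inverse round trips are exact over random tuples", {
  set.seed(101)
  n_tuples <- 10000
  b_o <- rnorm(n_tuples); se_o <- runif(n_tuples, 0.01, 1)
  b_s <- rnorm(n_tuples); se_s <- runif(n_tuples, 0.01, 1)
  meta <- ivw_meta(b_o, se_o, b_s, se_s)
  inv <- ivw_inverse(meta$b, meta$se, b_o, se_o)
  expect_true(all(!inv$unstable))
  expect_lt(max(abs(inv$b - b_s) / pmax(abs(b_s), 1e-12)), 1e-10)
  expect_lt(max(abs(inv$se - se_s) / se_s), 1e-10)
  # forward of the inverse reproduces the consortium values
  fwd <- ivw_meta(inv$b, inv$se, b_o, se_o)
  expect_lt(max(abs(fwd$b - meta$b) / pmax(abs(meta$b), 1e-12)), 1e-10)

  z_all <- rnorm(n_tuples, sd = 2)
  z_o <- rnorm(n_tuples, sd = 2)
  n_all <- sample(1000:50000, n_tuples, replace = TRUE)
  n_o <- sample(10:900, n_tuples, replace = TRUE)
  zi <- z_inverse(z_all, n_all, z_o, n_o)
  expect_lt(max(abs(z_meta(z_o, n_o, zi$z, zi$n) - z_all)), 1e-12)
})

test_that("z_to_beta applies the standardized-phenotype scaling", {
  r <- z_to_beta(1.0, 200, 0.5)
  expect_equal(r$beta, 0.1)
  expect_equal(r$se, 0.1)
  r2 <- z_to_beta(2.0, 800, 0.25)
  expect_equal(r2$se, 1 / sqrt(300), tolerance = 1e-10)
  expect_equal(r2$beta, 2 / sqrt(300), tolerance = 1e-10)
  expect_equal(z_to_beta(0, 100, 0.3)$beta, 0)
  expect_error(z_to_beta(1, 100, 0.7), "maf")
  expect_error(z_to_beta(1, 100, 0), "maf")
})

test_that("pvalue_from_z is the two-sided normal tail", {
  expect_equal(pvalue_from_z(0), 1.0)
  expect_lt(abs(pvalue_from_z(1.959964) - 0.05), 1e-4)
  expect_lt(abs(pvalue_from_z(3.0) - 0.0026998), 1e-6)
  expect_equal(pvalue_from_z(-3.0), pvalue_from_z(3.0))
})

test_that("estimate_rho computes the overlap-induced correlation", {
  expect_equal(estimate_rho(300, 30000, 1000, 1), 300 / sqrt(3e7))
  expect_equal(estimate_rho(300, 30000, 1000, 0), 0)
  expect_error(estimate_rho(1000, 1000, 1000, 1), "overlapping")
  expect_error(estimate_rho(0, 1000, 1000, 1), "n_c")
})

test_that("decorrelate residualizes and nulls the correlation", {
  expect_equal(decorrelate(1.7, 0.4, 0), 1.7) # rho = 0 is the identity
  expect_equal(decorrelate(2.0, 2.0, 0.5), 1 / sqrt(0.75), tolerance = 1e-10)
  expect_error(decorrelate(1, 1, 1), "rho")
  # Monte-Carlo: bivariate-normal nulls with rho = 0.3
  set.seed(7)
  rho <- 0.3
  z_o <- rnorm(1e5)
  z_all <- rho * z_o + sqrt(1 - rho^2) * rnorm(1e5)
  zeta <- decorrelate(z_all, z_o, rho)
  expect_lt(abs(cor(zeta, z_o)), 0.01)
  expect_equal(stats::var(zeta), 1, tolerance = 0.02)
})

test_that("adjust_table(ivw) exactly recovers a held-out sub-GWAS", {
  m <- 100
  held_out <- rand_sumstats(m, seed = 21)
  overlap <- rand_sumstats(m, seed = 22)
  meta <- ivw_meta(held_out$beta, held_out$se, overlap$beta, overlap$se)
  cons <- as_sumstats(data.frame(
    variant_id = held_out$variant_id, chrom = "1", pos = held_out$pos,
    effect_allele = "A", other_allele = "G",
    beta = meta$b, se = meta$se, n = 10000, maf = held_out$maf))
  res <- adjust_table(cons, overlap, method = "ivw")
  adj <- res$adjusted
  i <- match(held_out$variant_id, adj$variant_id)
  expect_lt(max(abs(adj$beta[i] - held_out$beta) / pmax(abs(held_out$beta), 1e-12)),
            1e-8)
  expect_lt(max(abs(adj$se[i] - held_out$se) / held_out$se), 1e-8)
  expect_equal(unname(res$counts["adjusted"]), m)
  # removing information strictly increases the standard error
  j <- match(adj$variant_id[i], cons$variant_id)
  expect_true(all(adj$se[i] > cons$se[j]))
})

test_that("adjust_table(zscore) satisfies the forward-meta round trip", {
  m <- 100
  cons <- rand_sumstats(m, seed = 31, n = 9000L)
  over <- rand_sumstats(m, seed = 32, n = 600L)
  res <- adjust_table(cons, over, method = "zscore")
  adj <- res$adjusted
  i <- match(cons$variant_id, adj$variant_id)
  expect_equal(adj$n[i], rep(8400, m))
  back <- z_meta(over$zscore, over$n, adj$zscore[i], adj$n[i])
  expect_lt(max(abs(back - cons$zscore)), 1e-10)
  # beta/se recomputed at the consortium MAF under the standardized scale
  expect_equal(adj$se[i], 1 / sqrt(2 * cons$maf * (1 - cons$maf) * 8400),
               tolerance = 1e-12)
})

test_that("unstable and infeasible variants are dropped with a counted status", {
  cons <- rand_sumstats(10, seed = 41)
  over <- rand_sumstats(10, seed = 42)
  over$se <- cons$se * 2 # overlap less precise everywhere: stable
  over$se[1:3] <- cons$se[1:3] # except equal precision: remainder undefined
  res <- adjust_table(cons, over, method = "ivw")
  expect_equal(unname(res$counts["dropped_unstable"]), 3L)
  expect_false(any(res$status$variant_id[res$status$status == "dropped_unstable"]
                   %in% res$adjusted$variant_id))
  # self-adjustment: every variant unstable, hard stop
  expect_error(adjust_table(cons, cons, method = "ivw"), "unstable")
})

test_that("consortium-only variants pass through unchanged", {
  cons <- rand_sumstats(20, seed = 51)
  over <- rand_sumstats(12, seed = 52)
  res <- adjust_table(cons, over, method = "ivw")
  expect_equal(unname(res$counts["passthrough"]), 8L)
  pass_ids <- res$status$variant_id[res$status$status == "passthrough"]
  i <- match(pass_ids, res$adjusted$variant_id)
  j <- match(pass_ids, cons$variant_id)
  expect_equal(res$adjusted$beta[i], cons$beta[j])
  expect_equal(res$adjusted$se[i], cons$se[j])
})

test_that("null inputs stay null under every method", {
  mk <- function(n) as_sumstats(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0, se = 0.05, zscore = 0, n = n, maf = 0.3))
  cons <- mk(5000); cons$se <- 0.01; cons$beta <- 0
  over <- mk(500)
  for (m in c("ivw", "zscore")) {
    adj <- adjust_table(cons, over, method = m)$adjusted
    expect_equal(adj$zscore, 0, info = m)
    expect_equal(adj$beta, 0, info = m)
  }
  dec <- adjust_table(cons, over, method = "decorrelation",
                      params = list(rho = 0.3))$adjusted
  expect_equal(dec$zscore, 0)
})

test_that("zscore adjustment agrees with the directly computed non-overlap GWAS", {
  cfg <- sim_config(n_variants = 500, n_causal = 20, h2 = 0.5,
                    n_train = 3000, n_target = 800, overlap_fraction = 0.3,
                    seed = 61)
  ds <- simulate_population(cfg)
  cons <- run_gwas(ds, "consortium")
  over <- run_gwas(ds, "overlap")
  direct <- run_gwas(ds, "train_only")
  adj <- adjust_table(cons, over, method = "zscore")$adjusted
  i <- match(direct$variant_id, adj$variant_id)
  r <- cor(adj$zscore[i], direct$zscore)
  slope <- unname(coef(lm(adj$zscore[i] ~ direct$zscore))[2])
  expect_gt(r, 0.95)
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})
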