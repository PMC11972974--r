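#' Configuration for an overlap-injection simulation
#'
#' Defines one synthetic genotype/phenotype experiment: a liability-threshold
#' disease model over biallelic variants in Hardy-Weinberg equilibrium, split
#' into disjoint training and target sets, with a chosen fraction of target
#' samples additionally merged into the training set to create overlap.
#'
#' Defaults correspond to the standard contaminated-consortium scenario used
#' throughout the package's validation: 8,000 training and 2,000 target
#' samples over 2,000 variants with 50 causal, liability heritability 0.5,
#' prevalence 0.3, and 30% of the target merged into training.
#'
#' @param n_variants number of biallelic variants.
#' @param n_causal number of causal variants (`<= n_variants`).
#' @param maf_range minor-allele-frequency interval in `(0, 0.5]` from which
#'   per-variant allele frequencies are drawn uniformly.
#' @param h2 liability-scale heritability in `[0, 1)`.
#' @param prevalence disease prevalence in `(0, 1)`.
#' @param n_train training samples exclusive of injected overlap.
#' @param n_target target (evaluation) samples.
#' @param overlap_fraction fraction of target samples merged into training,
#'   in `[0, 1]`; ignored when `overlap_counts` is given.
#' @param overlap_counts optional `c(cases, controls)` drawn from the target
#'   by disease status instead of a uniform fraction.
#' @param ld_blocks `NULL` for linkage equilibrium (default), or
#'   `list(size = k, r = rho)` to group variants into blocks of `k` with
#'   pairwise latent Gaussian correlation `rho` (genotypes via a Gaussian
#'   copula thresholded to dosages).
#' @param seed integer RNG seed; every realized dataset is reproducible
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 2000L, n_causal = 50L,
                       maf_range = c(0.05, 0.5), h2 = 0.5, prevalence = 0.3,
                       n_train = 8000L, n_target = 2000L,
                       overlap_fraction = 0.3, overlap_counts = NULL,
                       ld_blocks = NULL, seed = 1L) {
  stopifnot(n_variants >= 1, n_causal >= 0, n_causal <= n_variants,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2 >= 0, h2 < 1, prevalence > 0, prevalence < 1,
            n_train >= 1, n_target >= 1,
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (!is.null(ld_blocks)) {
    stopifnot(is.list(ld_blocks), ld_blocks$size >= 1,
              ld_blocks$r >= 0, ld_blocks$r < 1)
  }
  structure(list(n_variants = as.integer(n_variants),
                 n_causal = as.integer(n_causal),
                 maf_range = maf_range, h2 = h2, prevalence = prevalence,
                 n_train = as.integer(n_train), n_target = as.integer(n_target),
                 overlap_fraction = overlap_fraction,
                 overlap_counts = overlap_counts, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# alternating non-palindromic allele pairs for simulated variants
.sim_allele_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate a genotype/phenotype population with injected sample overlap
#'
#' Genotypes are drawn per variant as `Binomial(2, p_j)` with `p_j` uniform on
#' `maf_range` (HWE; linkage equilibrium by default, or block-LD through a
#' Gaussian copula). `n_causal` variants receive liability effects
#' `Normal(0, h2/n_causal)`; the genetic score is standardized to variance
#' `h2` and completed with `Normal(0, 1 - h2)` noise; case status is liability
#' above the `1 - prevalence` normal quantile. The population of
#' `n_train + n_target` samples is split into disjoint training and target
#' sets, and `overlap_fraction` of the target (or explicit case/control
#' counts) is additionally labeled as overlap, i.e. merged into the training
#' GWAS.
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset`: list with `genotypes` (samples x variants dosage
#'   matrix, columns named by variant id), `phenotype` (0/1), `liability`,
#'   `effects` (true liability effects), `partition` (factor with levels
#'   `train_only`, `overlap`, `target_only`), `variants` (data frame of
#'   variant id, chrom, pos, alleles, population allele frequency) and
#'   `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  n <- config$n_train + config$n_target

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  ids <- sprintf("rs%06d", seq_len(m))

  if (is.null(config$ld_blocks)) {
    geno <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  } else {
    # Gaussian copula: latent block-equicorrelated normals thresholded to
    # binomial dosages. Genotype-scale correlation is attenuated relative to
    # the latent r but monotone in it.
    k <- config$ld_blocks$size
    r <- config$ld_blocks$r
    n_blocks <- ceiling(m / k)
    block_of <- rep(seq_len(n_blocks), each = k)[seq_len(m)]
    shared <- matrix(stats::rnorm(n * n_blocks), nrow = n)
    latent <- sqrt(r) * shared[, block_of, drop = FALSE] +
      sqrt(1 - r) * matrix(stats::rnorm(n * m), nrow = n)
    geno <- matrix(stats::qbinom(stats::pnorm(latent), 2L, rep(p, each = n)),
                   nrow = n, ncol = m)
  }
  colnames(geno) <- ids

  effects <- numeric(m)
  if (config$n_causal > 0 && config$h2 > 0) {
    causal <- sample.int(m, config$n_causal)
    effects[causal] <- stats::rnorm(config$n_causal,
                                    sd = sqrt(config$h2 / config$n_causal))
    g <- as.vector(geno %*% effects)
    sg <- stats::sd(g)
    if (sg > 0) g <- (g - mean(g)) / sg * sqrt(config$h2) else g <- rep(0, n)
  } else {
    g <- rep(0, n)
  }
  liability <- g + stats::rnorm(n, sd = sqrt(1 - config$h2))
  phenotype <- as.integer(liability > stats::qnorm(1 - config$prevalence))

  target_idx <- sample.int(n, config$n_target)
  partition <- rep("train_only", n)
  partition[target_idx] <- "target_only"
  if (!is.null(config$overlap_counts)) {
    oc <- config$overlap_counts
    cases <- target_idx[phenotype[target_idx] == 1L]
    ctrls <- target_idx[phenotype[target_idx] == 0L]
    if (oc[1] > length(cases) || oc[2] > length(ctrls)) {
      stop("overlap_counts exceed available target cases/controls")
    }
    ov <- c(sample(cases, oc[1]), sample(ctrls, oc[2]))
    partition[ov] <- "overlap"
  } else {
    n_ov <- round(config$overlap_fraction * config$n_target)
    if (n_ov > 0) partition[sample(target_idx, n_ov)] <- "overlap"
  }
  partition <- factor(partition, levels = c("train_only", "overlap", "target_only"))

  pair <- .sim_allele_pairs[(seq_len(m) - 1L) %% nrow(.sim_allele_pairs) + 1L, ,
                            drop = FALSE]
  variants <- data.frame(variant_id = ids, chrom = "1",
                         pos = seq_len(m) * 10000L,
                         effect_allele = pair[, 1], other_allele = pair[, 2],
                         maf = p, stringsAsFactors = FALSE)

  structure(list(genotypes = geno, phenotype = phenotype, liability = liability,
                 effects = effects, partition = partition, variants = variants,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  tab <- table(x$partition)
  cat(sprintf("simulated dataset: %d samples x %d variants (%d causal)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$effects != 0)))
  cat(sprintf("partitions: train_only=%d overlap=%d target_only=%d; cases=%d\n",
              tab["train_only"], tab["overlap"], tab["target_only"],
              sum(x$phenotype)))
  invisible(x)
}

#' Resolve a partition selector to sample indices
#'
#' @param dataset a `sim_dataset`.
#' @param subset one of `"consortium"` (training GWAS: train_only + overlap),
#'   `"train_only"`, `"overlap"`, `"target"` (overlap + target_only),
#'   `"target_only"`, or an integer/logical index vector.
#' @return Integer sample indices.
#' @export
partition_indices <- function(dataset, subset) {
  if (is.numeric(subset) || is.logical(subset)) {
    return(seq_len(nrow(dataset$genotypes))[subset])
  }
  part <- as.character(dataset$partition)
  lv <- switch(match.arg(subset, c("consortium", "train", "train_only",
                                   "overlap", "target", "target_only")),
               consortium = , train = c("train_only", "overlap"),
               train_only = "train_only",
               overlap = "overlap",
               target = c("overlap", "target_only"),
               target_only = "target_only")
  which(part %in% lv)
}

#' Per-variant GWAS on a partition of a simulated dataset
#'
#' Simple linear regression of the (optionally standardized) phenotype on
#' genotype dosage, one variant at a time, fully vectorized: returns `beta`,
#' residual-variance based `se`, `zscore = beta/se`, the two-sided normal
#' P value, `n` equal to the subset size and the subset allele frequency.
#' Monomorphic variants in the subset are emitted with `zscore = 0`, `se`
#' missing, and are counted in the `monomorphic` attribute.
#'
#' @param dataset a `sim_dataset`.
#' @param subset partition selector (see [partition_indices()]).
#' @param standardize_phenotype scale the phenotype to mean 0, SD 1 before
#'   regression (default `TRUE`; this is the scaling the Z-score adjustment
#'   algebra assumes).
#' @return A `sumstats` table.
#' @export
run_gwas <- function(dataset, subset = "consortium", standardize_phenotype = TRUE) {
  idx <- partition_indices(dataset, subset)
  if (length(idx) < 3) stop("degenerate subset: fewer than 3 samples")
  y <- dataset$phenotype[idx]
  if (length(unique(y)) < 2) stop("degenerate subset: phenotype has a single class")
  y <- if (standardize_phenotype) as.vector(scale(y)) else y - mean(y)
  X <- dataset$genotypes[idx, , drop = FALSE]
  n <- length(idx)

  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- as.vector(crossprod(X, y)) # y already centered
  mono <- sxx <= 0
  beta <- ifelse(mono, 0, sxy / ifelse(mono, 1, sxx))
  sse <- sum(y^2) - beta * sxy
  sigma2 <- pmax(sse, 0) / (n - 2)
  se <- ifelse(mono, NA_real_, sqrt(sigma2 / ifelse(mono, 1, sxx)))
  z <- ifelse(mono, 0, beta / se)
  eaf <- xm / 2
  maf <- pmin(eaf, 1 - eaf)
  maf[maf <= 0] <- NA_real_

  out <- data.frame(dataset$variants[c("variant_id", "chrom", "pos",
                                       "effect_allele", "other_allele")],
                    beta = beta, se = se, zscore = z,
                    pvalue = pvalue_from_z(z), n = n, maf = maf,
                    stringsAsFactors = FALSE)
  ss <- as_sumstats(out)
  attr(ss, "monomorphic") <- sum(mono)
  ss
}

#' Cartesian grid of overlap-injection designs
#'
#' Expands split ratios and overlap fractions into one [sim_config()] per
#' cell, holding the base configuration's total sample count fixed
#' (`n_train = ratio * total`, `n_target` the remainder) and deriving a
#' deterministic per-cell seed from the base seed.
#'
#' @param split_ratios training fractions in `(0, 1)`.
#' @param overlap_fractions overlap fractions in `[0, 1]`.
#' @param base a [sim_config()] supplying every other field.
#' @return List of `sim_config` objects with `split_ratio` and
#'   `overlap_fraction` recorded in each; the classic 5-ratio x 8-fraction
#'   design yields 40 configurations.
#' @export
make_design_grid <- function(split_ratios, overlap_fractions, base = sim_config()) {
  stopifnot(all(split_ratios > 0), all(split_ratios < 1),
            all(overlap_fractions >= 0), all(overlap_fractions <= 1))
  total <- base$n_train + base$n_target
  grid <- list()
  for (ratio in split_ratios) {
    for (frac in overlap_fractions) {
      n_train <- max(1L, round(ratio * total))
      n_target <- max(1L, total - n_train)
      seed <- (base$seed * 7919L +
                 as.integer(round(ratio * 100)) * 131L +
                 as.integer(round(frac * 1000))) %% 2147483647L
      cfg <- sim_config(n_variants = base$n_variants, n_causal = base$n_causal,
                        maf_range = base$maf_range, h2 = base$h2,
                        prevalence = base$prevalence,
                        n_train = n_train, n_target = n_target,
                        overlap_fraction = frac, ld_blocks = base$ld_blocks,
                        seed = seed)
      cfg$split_ratio <- ratio
      grid[[length(grid) + 1L]] <- cfg
    }
  }
  grid
}
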