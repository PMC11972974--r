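# Shared fixture builders and a cache for the expensive contaminated-study
# runs reused by several acceptance checks.

# Small random but valid summary table (LE variants, A/G alleles).
rand_sumstats <- function(m, seed = 1, n = 5000L) {
  set.seed(seed)
  as_sumstats(data.frame(
    variant_id = sprintf("rs%04d", seq_len(m)),
    chrom = "1", pos = seq_len(m) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta = stats::rnorm(m, sd = 0.1),
    se = stats::runif(m, 0.02, 0.2),
    n = n, maf = stats::runif(m, 0.05, 0.5),
    stringsAsFactors = FALSE))
}

# Brute-force all-pairs AUROC oracle (independent of the rank-based path).
auroc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# One full contaminated-consortium study at the standard design:
# simulate, consortium + overlap GWAS, IVW and Z-score adjustment, dense PRS
# per method, direct train-only GWAS PRS, and the diagnostic AUROCs at
# exclusion threshold 0.05. Cached per seed for reuse across test files.
.oa_cache <- new.env(parent = emptyenv())

overlap_study_run <- function(seed) {
  key <- paste0("study_", seed)
  if (!is.null(.oa_cache[[key]])) return(.oa_cache[[key]])
  res <- run_cell(sim_config(seed = seed),
                  methods = c("unadjusted", "ivw", "zscore"))
  ds <- res$dataset
  tgt <- partition_indices(ds, "target")
  G <- ds$genotypes[tgt, , drop = FALSE]
  y <- ds$phenotype[tgt]
  part <- as.character(ds$partition[tgt])

  direct <- run_gwas(ds, "train_only")
  kept <- clump(direct, G)
  s_direct <- score_prs(G, prs_weights(direct, kept))
  ev_direct <- evaluate_prs(s_direct, y, part)

  target_gwas <- run_gwas(ds, "target")
  traj <- threshold_trajectory(res$summaries, G, y, part, target_gwas,
                               thresholds = c(0, 0.05))

  av <- function(m, g) {
    ev <- res$evaluations[[m]]
    ev$auroc[ev$group == g]
  }
  traj_ov <- function(m) {
    r <- traj[traj$method == m & traj$p_threshold == 0.05 &
                traj$group == "overlap", ]
    r$auroc
  }
  out <- list(
    unadj_ov = av("unadjusted", "overlap"),
    unadj_non = av("unadjusted", "non_overlap"),
    ivw_ov = av("ivw", "overlap"),
    ivw_non = av("ivw", "non_overlap"),
    z_ov = av("zscore", "overlap"),
    z_non = av("zscore", "non_overlap"),
    direct_ov = ev_direct$auroc[ev_direct$group == "overlap"],
    traj_unadj_ov = traj_ov("unadjusted"),
    traj_z_ov = traj_ov("zscore"),
    traj_ivw_ov = traj_ov("ivw"))
  .oa_cache[[key]] <- out
  out
}

overlap_study_runs <- function(seeds = 1:5) {
  runs <- lapply(seeds, overlap_study_run)
  as.data.frame(do.call(rbind, lapply(runs, as.data.frame)))
}
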