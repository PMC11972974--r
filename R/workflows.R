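#' Run one overlap-injection cell: simulate, adjust, score, evaluate
#'
#' Convenience wrapper around the full pipeline for a single configuration:
#' simulate the population, run the consortium GWAS (training + injected
#' overlap) and the overlap-only GWAS, adjust the consortium summary by each
#' requested method, build a clumping + thresholding PRS per method, and
#' evaluate AUROC/OR on the total, overlap and non-overlap target groups.
#'
#' Scores are built from all clumped variants by default
#' (`selection = "dense"`, the genome-wide weighting dense constructors use,
#' through which overlap overfitting is visible); `selection = "best"`
#' instead picks the threshold maximizing total-target AUROC via
#' [build_prs_ct()].
#'
#' @param config a [sim_config()].
#' @param methods subset of `"unadjusted"`, `"ivw"`, `"zscore"`,
#'   `"decorrelation"`.
#' @param selection `"dense"` (default) or `"best"` (see Details).
#' @param p_grid candidate thresholds when `selection = "best"`.
#' @param window_units LD window units for clumping.
#' @return List with `dataset`, `consortium`, `overlap_gwas` (NULL when the
#'   cell has no overlap), `summaries` (named list of per-method tables),
#'   `evaluations` (named list of `oa_eval`), `best_p` (named numeric).
#' @export
run_cell <- function(config, methods = c("unadjusted", "ivw", "zscore"),
                     selection = c("dense", "best"),
                     p_grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1),
                     window_units = "bp") {
  selection <- match.arg(selection)
  methods <- match.arg(methods, c("unadjusted", "ivw", "zscore", "decorrelation"),
                       several.ok = TRUE)
  ds <- simulate_population(config)
  cons <- run_gwas(ds, "consortium")
  n_ov <- sum(ds$partition == "overlap")
  over <- if (n_ov >= 3) run_gwas(ds, "overlap") else NULL

  summaries <- list()
  for (m in methods) {
    if (m == "unadjusted" || is.null(over)) {
      summaries[[m]] <- cons
    } else if (m == "decorrelation") {
      params <- list(n_c = n_ov, n_all = cons$n[1], n_o = over$n[1], cor_y = 1)
      summaries[[m]] <- adjust_table(cons, over, method = "decorrelation",
                                     params = params)$adjusted
    } else {
      summaries[[m]] <- adjust_table(cons, over, method = m)$adjusted
    }
  }

  tgt <- partition_indices(ds, "target")
  G <- ds$genotypes[tgt, , drop = FALSE]
  y <- ds$phenotype[tgt]
  part <- as.character(ds$partition[tgt])

  evaluations <- list(); best_p <- numeric(0); scores <- list()
  for (m in names(summaries)) {
    if (selection == "best") {
      prs <- build_prs_ct(summaries[[m]], G, y, p_grid = p_grid,
                          window_units = window_units)
      s <- prs$scores
      best_p[m] <- prs$best_p
    } else {
      kept <- clump(summaries[[m]], G, window_units = window_units)
      s <- score_prs(G, prs_weights(summaries[[m]], kept,
                                    provenance = "dense (all clumped variants)"))
      best_p[m] <- 1
    }
    evaluations[[m]] <- evaluate_prs(s, y, part)
    scores[[m]] <- s
  }
  list(dataset = ds, consortium = cons, overlap_gwas = over,
       summaries = summaries, evaluations = evaluations, scores = scores,
       best_p = best_p)
}

#' Run a grid of overlap-injection experiments
#'
#' Executes [run_cell()] over every configuration of a design grid
#' (see [make_design_grid()]), optionally replicated over derived seeds, and
#' returns one tidy row per cell x method x target group. Per-cell failures
#' are recorded with their message and the run continues.
#'
#' @param grid list of `sim_config` objects (e.g. from [make_design_grid()]).
#' @param methods methods passed to [run_cell()].
#' @param replicates replicate count; replicate `r` of a cell reuses the
#'   cell's seed + `r - 1`.
#' @param selection PRS construction mode (see [run_cell()]).
#' @param p_grid thresholds when `selection = "best"`.
#' @return An `oa_experiment` data frame with columns `split_ratio`,
#'   `overlap_fraction`, `seed`, `replicate`, `method`, `group`, `n`,
#'   `n_cases`, `auroc`, `or_per_sd`, `best_p`, `status`, `message`.
#' @export
run_experiment <- function(grid, methods = c("unadjusted", "ivw", "zscore"),
                           replicates = 1L, selection = "dense",
                           p_grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)) {
  rows <- list()
  for (cfg in grid) {
    for (rep_i in seq_len(replicates)) {
      cfg_r <- cfg
      cfg_r$seed <- (cfg$seed + rep_i - 1L) %% 2147483647L
      ratio <- if (!is.null(cfg$split_ratio)) cfg$split_ratio else
        cfg$n_train / (cfg$n_train + cfg$n_target)
      res <- tryCatch(run_cell(cfg_r, methods = methods, selection = selection,
                               p_grid = p_grid),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          split_ratio = ratio, overlap_fraction = cfg$overlap_fraction,
          seed = cfg_r$seed, replicate = rep_i, method = NA_character_,
          group = NA_character_, n = NA_integer_, n_cases = NA_integer_,
          auroc = NA_real_, or_per_sd = NA_real_, best_p = NA_real_,
          status = "failed", message = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      for (m in names(res$evaluations)) {
        ev <- as.data.frame(res$evaluations[[m]])
        rows[[length(rows) + 1L]] <- data.frame(
          split_ratio = ratio, overlap_fraction = cfg$overlap_fraction,
          seed = cfg_r$seed, replicate = rep_i, method = m,
          group = ev$group, n = ev$n, n_cases = ev$n_cases,
          auroc = ev$auroc, or_per_sd = ev$or_per_sd,
          best_p = unname(res$best_p[m]), status = "ok", message = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("oa_experiment", "data.frame")
  out
}

#' File-to-file overlap adjustment with a count report
#'
#' Reads the consortium and overlap summary files, removes the overlap
#' contribution by the chosen method, writes the adjusted table to
#' `<out_prefix>.sumstats.tsv`, the per-variant status to
#' `<out_prefix>.status.tsv`, and a human-readable count report (per-status
#' counts, harmonization drops, mean standard-error inflation) to
#' `<out_prefix>.report.txt`. When the two files share no variants the
#' consortium is emitted unchanged with a warning (nothing to adjust).
#'
#' @param consortium_path,overlap_path tab-delimited summary files
#'   (see [read_sumstats()]).
#' @param method `"ivw"`, `"zscore"` or `"decorrelation"`.
#' @param out_prefix output path prefix.
#' @param dialect column-name dialect for both inputs.
#' @param ... further arguments to [adjust_table()] (`params`, `maf_source`,
#'   `eps`).
#' @return Invisibly, the `oa_adjustment` (or the unchanged consortium table
#'   when nothing was shared).
#' @export
end_to_end_adjust <- function(consortium_path, overlap_path,
                              method = c("ivw", "zscore", "decorrelation"),
                              out_prefix = "adjusted", dialect = "auto", ...) {
  method <- match.arg(method)
  cons <- read_sumstats(consortium_path, dialect = dialect)
  over <- read_sumstats(overlap_path, dialect = dialect)

  res <- tryCatch(adjust_table(cons, over, method = method, ...),
                  error = function(e) e)
  report_path <- paste0(out_prefix, ".report.txt")
  out_path <- paste0(out_prefix, ".sumstats.tsv")

  if (inherits(res, "error")) {
    if (grepl("no variants shared", conditionMessage(res))) {
      warning("no shared variants: consortium emitted unchanged (all passthrough)")
      write_sumstats(cons, out_path)
      writeLines(c(sprintf("method: %s", method),
                   sprintf("variants in consortium: %d", nrow(cons)),
                   sprintf("variants in overlap: %d", nrow(over)),
                   "shared variants: 0",
                   "all variants passed through unadjusted"),
                 report_path)
      return(invisible(cons))
    }
    stop(conditionMessage(res))
  }

  write_sumstats(res$adjusted, out_path)
  utils::write.table(res$status, paste0(out_prefix, ".status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  adj_ids <- res$status$variant_id[res$status$status == "adjusted"]
  se_cons <- cons$se[match(adj_ids, cons$variant_id)]
  se_adj <- res$adjusted$se[match(adj_ids, res$adjusted$variant_id)]
  infl <- mean(se_adj / se_cons, na.rm = TRUE)
  writeLines(c(sprintf("method: %s", method),
               sprintf("variants in consortium: %d", nrow(cons)),
               sprintf("variants in overlap: %d", nrow(over)),
               paste("harmonization drops:",
                     paste(sprintf("%s=%d", names(res$harmonization),
                                   res$harmonization), collapse = ", ")),
               paste("status counts:",
                     paste(sprintf("%s=%d", names(res$counts), res$counts),
                           collapse = ", ")),
               sprintf("mean SE inflation on adjusted variants: %.4f", infl)),
             report_path)
  invisible(res)
}
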