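#' Two-stage exclusion filter for the visual diagnosis of overlap adjustment
#'
#' Stage 1 removes every variant with `p < p_high` in either the consortium
#' or the target GWAS, together with all LD neighbors (squared correlation at
#' least `r2_threshold` with a removed variant, within the window, computed
#' from the reference genotypes). Stage 2 keeps only variants whose P value
#' is at least `p_threshold` in both tables; `p_threshold = 0` means stage 2
#' removes nothing (the "P = 0" grid point: strong-signal removal only).
#'
#' @param consortium consortium (or adjusted) `sumstats` table.
#' @param target_gwas GWAS on the full target set, as a `sumstats` table.
#' @param ref_genotypes reference dosage matrix for LD (columns named by
#'   variant id).
#' @param p_high strong-association cutoff for stage 1 (default `1e-4`).
#' @param p_threshold medium-association exclusion threshold for stage 2.
#' @param r2_threshold,window,window_units LD-neighborhood parameters (as in
#'   [clump()]).
#' @return Character vector of surviving variant ids (possibly empty).
#' @export
diagnostic_filter <- function(consortium, target_gwas, ref_genotypes,
                              p_high = 1e-4, p_threshold = 0,
                              r2_threshold = 0.1, window = 250000L,
                              window_units = c("bp", "variants")) {
  window_units <- match.arg(window_units)
  cs <- as.data.frame(consortium)
  ts <- as.data.frame(target_gwas)
  ids <- intersect(cs$variant_id, ts$variant_id)
  cs <- cs[match(ids, cs$variant_id), , drop = FALSE]
  ts <- ts[match(ids, ts$variant_id), , drop = FALSE]

  hit <- (!is.na(cs$pvalue) & cs$pvalue < p_high) |
    (!is.na(ts$pvalue) & ts$pvalue < p_high)

  # stage 1: strong hits and their LD neighborhood
  remove <- hit
  hit_ids <- ids[hit]
  cand_ids <- ids[!hit]
  in_ref_hit <- hit_ids[hit_ids %in% colnames(ref_genotypes)]
  in_ref_cand <- cand_ids[cand_ids %in% colnames(ref_genotypes)]
  if (length(in_ref_hit) > 0 && length(in_ref_cand) > 0) {
    G <- scale(ref_genotypes[, c(in_ref_hit, in_ref_cand), drop = FALSE])
    G[is.na(G)] <- 0
    nref <- nrow(ref_genotypes)
    r <- crossprod(G[, in_ref_cand, drop = FALSE],
                   G[, in_ref_hit, drop = FALSE]) / (nref - 1)
    ld <- (r^2 >= r2_threshold)
    if (window_units == "bp") {
      pos_c <- cs$pos[match(in_ref_cand, ids)]
      pos_h <- cs$pos[match(in_ref_hit, ids)]
      chr_c <- cs$chrom[match(in_ref_cand, ids)]
      chr_h <- cs$chrom[match(in_ref_hit, ids)]
      near <- outer(chr_c, chr_h, `==`) &
        abs(outer(pos_c, pos_h, `-`)) <= window
    } else {
      ix_c <- match(in_ref_cand, ids)
      ix_h <- match(in_ref_hit, ids)
      near <- abs(outer(ix_c, ix_h, `-`)) <= window
    }
    neighbor <- rowSums(ld & near) > 0
    remove[match(in_ref_cand[neighbor], ids)] <- TRUE
  }

  keep <- !remove
  # stage 2: medium-association exclusion in both tables
  if (p_threshold > 0) {
    keep <- keep & !is.na(cs$pvalue) & cs$pvalue >= p_threshold &
      !is.na(ts$pvalue) & ts$pvalue >= p_threshold
  }
  ids[keep]
}

#' AUROC trajectory under progressive exclusion of associated variants
#'
#' For each summary table and each exclusion threshold: apply
#' [diagnostic_filter()], build weights directly from the surviving variants'
#' effect sizes (no re-thresholding or re-fitting — the diagnostic probes
#' residual overfitting signal), score the target samples, and record the
#' per-group AUROC. A summary free of overlap contamination should decay to
#' 0.5 on the overlap group as associated variants are removed; an overfit
#' one retains predictive power there.
#'
#' @param summaries named list of `sumstats` tables (e.g. `unadjusted`,
#'   `ivw`, `zscore`).
#' @param genotypes target dosage matrix (columns named by variant id).
#' @param labels binary phenotype of the target samples.
#' @param partition per-target-sample group (`"overlap"`/`"target_only"`).
#' @param target_gwas GWAS on the full target set (drives the filter's
#'   target-side P values).
#' @param thresholds ascending exclusion thresholds
#'   (default `0, 0.01, 0.05, 0.1, 0.2, 0.5`).
#' @param p_high stage-1 cutoff (default `1e-4`).
#' @param r2_threshold,window,window_units LD parameters for stage 1.
#' @param reference optional `sumstats` table evaluated the same way and
#'   labeled `"reference"` (e.g. a GWAS on the non-overlap training samples).
#' @return An `oa_trajectory` data frame: one row per method x threshold x
#'   group with `n_variants_used`, `auroc`, `evaluable`.
#' @export
threshold_trajectory <- function(summaries, genotypes, labels, partition,
                                 target_gwas,
                                 thresholds = c(0, 0.01, 0.05, 0.1, 0.2, 0.5),
                                 p_high = 1e-4, r2_threshold = 0.1,
                                 window = 250000L,
                                 window_units = c("bp", "variants"),
                                 reference = NULL) {
  window_units <- match.arg(window_units)
  stopifnot(is.list(summaries), !is.null(names(summaries)))
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  if (!is.null(reference)) summaries <- c(summaries, list(reference = reference))
  partition <- as.character(partition)
  partition[partition == "non_overlap"] <- "target_only"

  rows <- list()
  for (mth in names(summaries)) {
    ss <- summaries[[mth]]
    for (t in thresholds) {
      ids <- diagnostic_filter(ss, target_gwas, genotypes, p_high = p_high,
                               p_threshold = t, r2_threshold = r2_threshold,
                               window = window, window_units = window_units)
      base <- data.frame(method = mth, p_threshold = t,
                         n_variants_used = length(ids),
                         stringsAsFactors = FALSE)
      ev <- NULL
      if (length(ids) > 0) {
        w <- prs_weights(ss, ids, provenance = sprintf("diagnostic p>=%.3g", t))
        if (nrow(w) > 0) {
          s <- score_prs(genotypes, w)
          if (stats::sd(s) > 0) ev <- evaluate_prs(s, labels, partition)
        }
      }
      if (is.null(ev)) {
        ev <- data.frame(group = c("total", "overlap", "non_overlap"),
                         n = NA_integer_, n_cases = NA_integer_,
                         auroc = NA_real_, or_per_sd = NA_real_,
                         or_flag = NA_character_, evaluable = FALSE,
                         stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- cbind(base[rep(1, nrow(ev)), ],
                                         as.data.frame(ev))
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(method = character(0), p_threshold = numeric(0),
                      n_variants_used = integer(0), group = character(0),
                      n = integer(0), n_cases = integer(0),
                      auroc = numeric(0), or_per_sd = numeric(0),
                      or_flag = character(0), evaluable = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("oa_trajectory", "data.frame")
  out
}

#' Plot a diagnostic AUROC trajectory and write its table
#'
#' Line plot of AUROC against exclusion threshold, one line per method and
#' group, with a horizontal rule at 0.5 (the no-signal level) and, when a
#' `reference` method is present, a dotted reference trajectory. The
#' underlying table is written alongside as tab-delimited text; not-evaluable
#' points appear as gaps in the lines and `NA` in the table.
#'
#' @param trajectory an `oa_trajectory` from [threshold_trajectory()].
#' @param out_prefix output path prefix; writes `<prefix>.png` and
#'   `<prefix>.tsv`.
#' @param width,height plot size in inches.
#' @return Invisibly, the paths written.
#' @export
plot_trajectory <- function(trajectory, out_prefix, width = 7, height = 4.5) {
  df <- as.data.frame(trajectory)
  if (!any(df$evaluable)) stop("no evaluable trajectory points to plot")
  tsv <- paste0(out_prefix, ".tsv")
  png_path <- paste0(out_prefix, ".png")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  dfp <- df[!is.na(df$auroc) | TRUE, , drop = FALSE]
  dfp$line <- interaction(dfp$method, dfp$group, sep = " / ")
  p <- ggplot2::ggplot(dfp, ggplot2::aes(x = p_threshold, y = auroc,
                                         colour = method, linetype = group,
                                         group = line)) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1.2) +
    ggplot2::labs(x = "exclusion P-value threshold", y = "AUROC",
                  colour = "method", linetype = "group") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(png_path, p, width = width, height = height, dpi = 120,
                  device = "png")
  invisible(c(plot = png_path, table = tsv))
}
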