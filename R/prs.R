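#' Greedy LD clumping of a summary-statistics table
#'
#' Sorts variants by ascending P value (ties broken by variant id), then
#' accepts each variant whose squared Pearson correlation with every
#' already-accepted variant inside the window is below `r2_threshold`,
#' computing LD from the supplied reference genotypes. Variants missing from
#' the reference pass through unclumped and are counted.
#'
#' @param sumstats a `sumstats` table with P values.
#' @param ref_genotypes reference dosage matrix (samples x variants, columns
#'   named by variant id).
#' @param r2_threshold squared-correlation ceiling (default 0.1).
#' @param window window size; base pairs when `window_units = "bp"`
#'   (default 250 kb, requires `chrom`/`pos`), or a variant-count window on
#'   the table order when `window_units = "variants"`.
#' @param window_units `"bp"` or `"variants"`.
#' @return Character vector of retained variant ids (in the input table's
#'   order), with attribute `n_missing_reference`.
#' @export
clump <- function(sumstats, ref_genotypes, r2_threshold = 0.1,
                  window = 250000L, window_units = c("bp", "variants")) {
  window_units <- match.arg(window_units)
  if (nrow(sumstats) == 0) stop("empty summary-statistics table")
  ss <- as.data.frame(sumstats)
  if (window_units == "bp" && (anyNA(ss$pos) || anyNA(ss$chrom))) {
    stop("bp windows require chrom and pos; use window_units = 'variants'")
  }
  in_ref <- ss$variant_id %in% colnames(ref_genotypes)
  ord <- order(ss$pvalue, ss$variant_id)

  present_ids <- ss$variant_id[in_ref]
  G <- ref_genotypes[, present_ids, drop = FALSE]
  G <- scale(G)
  G[is.na(G)] <- 0 # monomorphic in reference: correlation treated as 0
  nref <- nrow(ref_genotypes)
  col_of <- match(ss$variant_id, present_ids)

  accepted <- integer(0)
  for (i in ord) {
    if (!in_ref[i]) {
      accepted <- c(accepted, i)
      next
    }
    neigh <- accepted[in_ref[accepted]]
    if (length(neigh) > 0) {
      if (window_units == "bp") {
        neigh <- neigh[ss$chrom[neigh] == ss$chrom[i] &
                         abs(ss$pos[neigh] - ss$pos[i]) <= window]
      } else {
        neigh <- neigh[abs(neigh - i) <= window]
      }
    }
    if (length(neigh) > 0) {
      r <- as.vector(crossprod(G[, col_of[i]], G[, col_of[neigh], drop = FALSE])) /
        (nref - 1)
      if (any(r^2 >= r2_threshold)) next
    }
    accepted <- c(accepted, i)
  }
  keep <- sort(accepted)
  out <- ss$variant_id[keep]
  attr(out, "n_missing_reference") <- sum(!in_ref)
  out
}

#' Select variants by P-value threshold
#'
#' Returns the ids of variants with `pvalue <= p_max`. A threshold of 0
#' returns the empty set (P values are strictly positive), matching the
#' convention that "P = 0" means "exclude everything associated".
#'
#' @param sumstats a `sumstats` table.
#' @param p_max threshold in `[0, 1]`.
#' @return Character vector of variant ids.
#' @export
threshold_variants <- function(sumstats, p_max) {
  stopifnot(p_max >= 0, p_max <= 1)
  ss <- as.data.frame(sumstats)
  ss$variant_id[!is.na(ss$pvalue) & ss$pvalue <= p_max]
}

#' Build a PRS weight vector from a summary table
#'
#' Weights are the per-allele effect sizes (`beta`) of the selected variants.
#'
#' @param sumstats a `sumstats` table.
#' @param variants optional character vector restricting to these variant ids.
#' @param provenance optional label recording how the weights were derived.
#' @return A `prs_weights` data frame with `variant_id`, `effect_allele`,
#'   `weight`.
#' @export
prs_weights <- function(sumstats, variants = NULL, provenance = NULL) {
  ss <- as.data.frame(sumstats)
  if (!is.null(variants)) ss <- ss[ss$variant_id %in% variants, , drop = FALSE]
  ss <- ss[!is.na(ss$beta) & is.finite(ss$beta), , drop = FALSE]
  w <- data.frame(variant_id = ss$variant_id, effect_allele = ss$effect_allele,
                  weight = ss$beta, stringsAsFactors = FALSE)
  structure(w, class = c("prs_weights", "data.frame"), provenance = provenance)
}

#' Score individuals with a PRS weight vector
#'
#' `PRS_i = sum_j weight_j * dosage_ij` over the weight variants present in
#' the genotype matrix. When per-column effect alleles are supplied and a
#' weight's effect allele matches the column's other allele, the dosage is
#' flipped (`2 - x`); weights whose alleles match neither orientation, or
#' whose variants are absent, are skipped and counted.
#'
#' @param genotypes dosage matrix (samples x variants, columns named by
#'   variant id).
#' @param weights a [prs_weights()] data frame.
#' @param effect_alleles optional character vector, the allele counted by
#'   each genotype column (named by variant id); when omitted, weights are
#'   assumed to be on the genotype orientation.
#' @param other_alleles optional companion to `effect_alleles`.
#' @return Numeric score per sample, with attributes `n_used`, `n_missing`,
#'   `n_mismatched`.
#' @export
score_prs <- function(genotypes, weights, effect_alleles = NULL,
                      other_alleles = NULL) {
  ids <- weights$variant_id
  present <- ids %in% colnames(genotypes)
  n_missing <- sum(!present)
  w <- weights[present, , drop = FALSE]
  n_mismatched <- 0L
  flip <- rep(FALSE, nrow(w))
  if (!is.null(effect_alleles)) {
    ea <- toupper(effect_alleles[w$variant_id])
    aligned <- !is.na(ea) & toupper(w$effect_allele) == ea
    if (!is.null(other_alleles)) {
      oa <- toupper(other_alleles[w$variant_id])
      flip <- !aligned & !is.na(oa) & toupper(w$effect_allele) == oa
    }
    drop <- !aligned & !flip
    n_mismatched <- sum(drop)
    w <- w[!drop, , drop = FALSE]
    flip <- flip[!drop]
  }
  if (nrow(w) == 0) stop("no usable variants to score")
  wt <- ifelse(flip, -w$weight, w$weight)
  offset <- 2 * sum(w$weight[flip])
  scores <- as.vector(genotypes[, w$variant_id, drop = FALSE] %*% wt) + offset
  attr(scores, "n_used") <- nrow(w)
  attr(scores, "n_missing") <- n_missing
  attr(scores, "n_mismatched") <- n_mismatched
  scores
}

#' Area under the ROC curve by the exact rank statistic
#'
#' `P(score_case > score_control) + 0.5 P(tie)`, computed from midranks over
#' all case-control pairs (equivalent to the Mann-Whitney U statistic; no ROC
#' binning).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (1 = case).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Odds ratio per standard deviation of PRS
#'
#' Logistic regression of case status on the standardized score (plus
#' optional covariates) by iteratively reweighted least squares; returns the
#' exponentiated score coefficient. Separation or non-convergence is flagged
#' rather than raised.
#'
#' @param scores numeric scores (non-constant).
#' @param labels binary 0/1 labels.
#' @param covariates optional data frame of additional model terms.
#' @return List of class `oa_or` with `or`, `log_or`, `se`, `flag`
#'   (`"ok"`, `"separation"`, or `"nonconvergence"`) and `message`.
#' @export
or_per_sd <- function(scores, labels, covariates = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (stats::sd(scores) == 0) stop("scores are constant")
  df <- data.frame(y = labels, prs = as.vector(scale(scores)))
  form <- y ~ prs
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    form <- stats::reformulate(c("prs", names(covariates)), response = "y")
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  log_or <- co["prs", "Estimate"]
  se <- co["prs", "Std. Error"]
  flag <- "ok"; msg <- ""
  if (!fit$converged) {
    flag <- "nonconvergence"; msg <- "IRLS did not converge"
  } else if (abs(log_or) > 15 || se > 100) {
    flag <- "separation"; msg <- "quasi-complete separation: estimate diverges"
  }
  structure(list(or = exp(log_or), log_or = log_or, se = se,
                 flag = flag, message = msg),
            class = "oa_or")
}

#' @export
print.oa_or <- function(x, ...) {
  cat(sprintf("OR per SD = %.4g (log-OR %.4g, SE %.3g)%s\n", x$or, x$log_or,
              x$se, if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Evaluate a PRS on total, overlap and non-overlap target groups
#'
#' @param scores PRS per target sample.
#' @param labels binary phenotype per target sample.
#' @param partition per-sample group: `"overlap"` or `"target_only"`
#'   (synonym `"non_overlap"`); evaluation groups are `total` (everyone),
#'   `overlap` and `non_overlap`. Groups missing a class are reported as
#'   not evaluable.
#' @return An `oa_eval` data frame: one row per group with `n`, `n_cases`,
#'   `auroc`, `or_per_sd`, `or_flag`, `evaluable`.
#' @export
evaluate_prs <- function(scores, labels, partition) {
  partition <- as.character(partition)
  partition[partition == "non_overlap"] <- "target_only"
  stopifnot(length(scores) == length(labels), length(labels) == length(partition),
            all(partition %in% c("overlap", "target_only")))
  groups <- list(total = rep(TRUE, length(scores)),
                 overlap = partition == "overlap",
                 non_overlap = partition == "target_only")
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    y <- as.integer(labels[sel])
    n <- sum(sel); n_cases <- sum(y == 1L)
    if (n == 0 || n_cases == 0 || n_cases == n || stats::sd(scores[sel]) == 0) {
      return(data.frame(group = g, n = n, n_cases = n_cases,
                        auroc = NA_real_, or_per_sd = NA_real_,
                        or_flag = NA_character_, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    }
    a <- auroc(scores[sel], y)
    o <- or_per_sd(scores[sel], y)
    data.frame(group = g, n = n, n_cases = n_cases, auroc = a,
               or_per_sd = o$or, or_flag = o$flag, evaluable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("oa_eval", "data.frame")
  out
}

#' Clumping + thresholding PRS with AUROC-selected threshold
#'
#' The self-contained score constructor: clump the summary table against the
#' reference genotypes, then for each candidate P-value threshold build
#' weights from the surviving variants, score the target, and keep the
#' threshold with the highest total-target AUROC.
#'
#' @param sumstats (adjusted) `sumstats` table.
#' @param genotypes target dosage matrix used both as LD reference and for
#'   scoring.
#' @param labels binary phenotype of the scored samples.
#' @param r2_threshold,window,window_units clumping parameters (see
#'   [clump()]).
#' @param p_grid candidate thresholds (default
#'   `5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1`).
#' @return List with `scores`, `weights`, `best_p`, `n_variants`, and the
#'   per-threshold `grid` data frame.
#' @export
build_prs_ct <- function(sumstats, genotypes, labels,
                         r2_threshold = 0.1, window = 250000L,
                         window_units = "bp",
                         p_grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)) {
  kept <- clump(sumstats, genotypes, r2_threshold = r2_threshold,
                window = window, window_units = window_units)
  grid <- data.frame(p_max = p_grid, n_variants = NA_integer_, auroc = NA_real_)
  best <- NULL
  for (i in seq_along(p_grid)) {
    ids <- intersect(kept, threshold_variants(sumstats, p_grid[i]))
    grid$n_variants[i] <- length(ids)
    if (length(ids) == 0) next
    w <- prs_weights(sumstats, ids,
                     provenance = sprintf("C+T r2<%.3g p<=%.3g",
                                          r2_threshold, p_grid[i]))
    s <- score_prs(genotypes, w)
    grid$auroc[i] <- auroc(s, labels)
    if (is.null(best) || grid$auroc[i] > best$auroc) {
      best <- list(scores = s, weights = w, best_p = p_grid[i],
                   n_variants = length(ids), auroc = grid$auroc[i])
    }
  }
  if (is.null(best)) stop("no threshold retained any variants")
  best$grid <- grid
  best
}
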