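#' Fixed-effect inverse-variance weighted meta-analysis of two estimates
#'
#' Combines two per-variant effect estimates with inverse-variance weights:
#' `b = (b1/se1^2 + b2/se2^2) / (1/se1^2 + 1/se2^2)`,
#' `se = sqrt(1 / (1/se1^2 + 1/se2^2))`. Vectorized over variants.
#'
#' @param b1,se1 effect and standard error from study 1 (`se1 > 0`).
#' @param b2,se2 effect and standard error from study 2 (`se2 > 0`).
#' @return List with components `b` and `se`.
#' @export
ivw_meta <- function(b1, se1, b2, se2) {
  if (any(!is.finite(se1) | se1 <= 0) || any(!is.finite(se2) | se2 <= 0)) {
    stop("standard errors must be positive and finite")
  }
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  list(b = (b1 * w1 + b2 * w2) / (w1 + w2), se = sqrt(1 / (w1 + w2)))
}

#' Invert an IVW meta-analysis to recover the non-overlap remainder
#'
#' Given the meta-analysed (consortium) estimate and the contribution of the
#' overlapping cohort, recovers the estimate the remaining samples would have
#' produced: `se_s^2 = 1/(1/se_all^2 - 1/se_o^2)` and
#' `b_s = se_s^2 * (b_all/se_all^2 - b_o/se_o^2)`. When the overlap carries at
#' least as much precision as the consortium
#' (`1/se_all^2 - 1/se_o^2 <= eps`) the inversion is undefined and the
#' variant is flagged unstable instead. Vectorized.
#'
#' @param b_all,se_all consortium effect and standard error.
#' @param b_o,se_o overlap-cohort effect and standard error.
#' @param eps positive stability floor on the remainder precision
#'   (default `1e-12`).
#' @return List with `b`, `se` (both `NA` where unstable) and logical
#'   `unstable`.
#' @export
ivw_inverse <- function(b_all, se_all, b_o, se_o, eps = 1e-12) {
  if (any(!is.finite(se_all) | se_all <= 0) || any(!is.finite(se_o) | se_o <= 0)) {
    stop("standard errors must be positive and finite")
  }
  w_all <- 1 / se_all^2
  w_o <- 1 / se_o^2
  w_s <- w_all - w_o
  unstable <- w_s <= eps
  k <- length(w_s)
  b_all <- rep_len(b_all, k); b_o <- rep_len(b_o, k)
  w_all <- rep_len(w_all, k); w_o <- rep_len(w_o, k)
  se_s <- rep(NA_real_, k)
  b_s <- rep(NA_real_, k)
  ok <- !unstable
  se_s[ok] <- sqrt(1 / w_s[ok])
  b_s[ok] <- (b_all[ok] * w_all[ok] - b_o[ok] * w_o[ok]) / w_s[ok]
  list(b = b_s, se = se_s, unstable = unstable)
}

#' Sample-size weighted Z-score meta-analysis of two studies
#'
#' `z_all = (sqrt(n_o) z_o + sqrt(n_s) z_s) / sqrt(n_o + n_s)` — the standard
#' sample-size weighted combination of standardized scores. Vectorized.
#'
#' @param z_o,n_o Z score and sample size of one study.
#' @param z_s,n_s Z score and sample size of the other study.
#' @return Numeric vector of combined Z scores.
#' @export
z_meta <- function(z_o, n_o, z_s, n_s) {
  if (any(n_o < 1) || any(n_s < 1)) stop("sample sizes must be >= 1")
  (sqrt(n_o) * z_o + sqrt(n_s) * z_s) / sqrt(n_o + n_s)
}

#' Invert a Z-score meta-analysis to recover the non-overlap remainder
#'
#' `n_s = n_all - n_o`; `z_s = (sqrt(n_all) z_all - sqrt(n_o) z_o)/sqrt(n_s)`.
#' By construction `z_meta(z_o, n_o, z_s, n_s)` reproduces `z_all` exactly.
#' Vectorized.
#'
#' @param z_all,n_all consortium Z score and sample size.
#' @param z_o,n_o overlap-cohort Z score and sample size (`n_all > n_o`).
#' @return List with `z` and `n` of the remainder cohort.
#' @export
z_inverse <- function(z_all, n_all, z_o, n_o) {
  if (any(n_o < 1)) stop("overlap sample size must be >= 1")
  if (any(n_all <= n_o)) stop("consortium sample size must exceed the overlap size")
  n_s <- n_all - n_o
  list(z = (sqrt(n_all) * z_all - sqrt(n_o) * z_o) / sqrt(n_s), n = n_s)
}

#' Convert a Z score to an effect size and standard error
#'
#' Assumes the phenotype is scaled to mean 0, SD 1, so the standard error of a
#' per-allele effect at a variant with minor allele frequency `maf` in `n`
#' samples is `se = 1/sqrt(2 maf (1-maf) n)`, and `beta = z * se`. Vectorized.
#'
#' @param z Z score.
#' @param n sample size (`>= 1`).
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @return List with `beta` and `se`.
#' @export
z_to_beta <- function(z, n, maf) {
  if (any(!is.finite(maf) | maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (any(n < 1)) stop("sample size must be >= 1")
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  list(beta = z * se, se = se)
}

#' Two-sided normal-tail P value of a Z score
#'
#' @param z finite Z score (vectorized).
#' @return P value in `(0, 1]`.
#' @export
pvalue_from_z <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Cross-statistic correlation induced by sample overlap
#'
#' Under the null, Z statistics from two GWAS sharing `n_c` individuals are
#' correlated with `rho = (n_c / sqrt(n_all * n_o)) * cor_y`, where `cor_y` is
#' the phenotype correlation on the shared samples.
#'
#' @param n_c number of shared samples, `1 <= n_c <= min(n_all, n_o)`.
#' @param n_all,n_o total sample sizes of the two GWAS.
#' @param cor_y phenotype correlation on shared samples, in `[-1, 1]`.
#' @return The correlation `rho`; errors if `|rho| >= 1`.
#' @export
estimate_rho <- function(n_c, n_all, n_o, cor_y) {
  if (n_c < 1 || n_c > min(n_all, n_o)) {
    stop("n_c must lie in [1, min(n_all, n_o)]")
  }
  if (abs(cor_y) > 1) stop("cor_y must lie in [-1, 1]")
  rho <- (n_c / sqrt(n_all * n_o)) * cor_y
  if (abs(rho) >= 1) stop("|rho| >= 1: the two studies are fully overlapping")
  rho
}

#' De-correlate a consortium Z score from an overlap Z score
#'
#' Residualization transform `zeta = (z_all - rho * z_o)/sqrt(1 - rho^2)`:
#' under the bivariate-normal null with correlation `rho`, the result has
#' unit variance and zero correlation with `z_o`. This is the comparator to
#' the meta-inverse subtraction; it re-weights rather than removes the
#' overlap contribution. Vectorized over variants.
#'
#' @param z_all consortium Z scores.
#' @param z_o overlap Z scores.
#' @param rho cross-statistic correlation, `|rho| < 1`
#'   (see [estimate_rho()]).
#' @return De-correlated Z scores.
#' @export
decorrelate <- function(z_all, z_o, rho) {
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  (z_all - rho * z_o) / sqrt(1 - rho^2)
}

#' Remove the overlap cohort's contribution from a consortium summary table
#'
#' Harmonizes the two tables, applies the chosen per-variant adjustment to
#' every matched pair, and recomputes the full
#' `(beta, se, zscore, pvalue, n)` tuple of the adjusted record. Consortium
#' variants absent from the overlap table are emitted unchanged with status
#' `passthrough`; variants whose IVW inversion is undefined (overlap at least
#' as precise as the consortium) or whose sample sizes do not satisfy
#' `n_all > n_o` get status `dropped_unstable` and are excluded from the
#' adjusted table.
#'
#' Methods:
#' \describe{
#'   \item{ivw}{[ivw_inverse()] on `beta`/`se`; requires both tables to carry
#'     `beta` and `se`. Exactly inverts an IVW meta-analysis.}
#'   \item{zscore}{[z_inverse()] on `zscore`/`n`, then [z_to_beta()] at the
#'     chosen MAF to restore `beta`/`se`; requires `n` and `maf`. Exactly
#'     inverts a sample-size weighted Z meta-analysis.}
#'   \item{decorrelation}{[decorrelate()] with `rho` from `params`; the
#'     sample size is unchanged (the transform re-weights rather than removes
#'     samples).}
#' }
#'
#' @param consortium,overlap `sumstats` tables (see [read_sumstats()]).
#' @param method one of `"ivw"`, `"zscore"`, `"decorrelation"`.
#' @param params for `method = "decorrelation"`: list with `n_c`, `n_all`,
#'   `n_o`, `cor_y` (see [estimate_rho()]), or `rho` directly.
#' @param maf_source `"consortium"` (default) or `"overlap"`: which table's
#'   allele frequency feeds [z_to_beta()]; data-specific MAF is recommended
#'   when precise effect estimates are needed.
#' @param eps stability floor for [ivw_inverse()].
#' @return An `oa_adjustment` object: list with `adjusted` (a `sumstats`
#'   table of adjusted + passthrough records), `status` (data frame of
#'   `variant_id`, `status`), `counts` (named integer vector) and `method`.
#' @export
adjust_table <- function(consortium, overlap,
                         method = c("ivw", "zscore", "decorrelation"),
                         params = NULL, maf_source = c("consortium", "overlap"),
                         eps = 1e-12) {
  method <- match.arg(method)
  maf_source <- match.arg(maf_source)
  h <- harmonize(consortium, overlap)
  p <- h$pairs

  # effect-allele frequency may exceed 0.5 after a flip; fold before z_to_beta
  fold_maf <- function(f) ifelse(is.na(f), NA_real_, pmin(f, 1 - f))
  maf <- if (maf_source == "consortium") fold_maf(p$maf_all) else fold_maf(p$maf_o)

  status <- rep("adjusted", nrow(p))
  out <- data.frame(variant_id = p$variant_id, chrom = p$chrom, pos = p$pos,
                    effect_allele = p$effect_allele, other_allele = p$other_allele,
                    beta = NA_real_, se = NA_real_, zscore = NA_real_,
                    pvalue = NA_real_, n = NA_real_, maf = maf,
                    stringsAsFactors = FALSE)

  if (method == "ivw") {
    if (anyNA(p$beta_all) || anyNA(p$se_all) || anyNA(p$beta_o) || anyNA(p$se_o)) {
      stop("ivw adjustment requires beta and se in both tables for all shared variants")
    }
    inv <- ivw_inverse(p$beta_all, p$se_all, p$beta_o, p$se_o, eps = eps)
    status[inv$unstable] <- "dropped_unstable"
    out$beta <- inv$b
    out$se <- inv$se
    out$zscore <- inv$b / inv$se
    out$pvalue <- pvalue_from_z(out$zscore)
    out$n <- if (!anyNA(p$n_all) && !anyNA(p$n_o)) p$n_all - p$n_o else NA_real_
  } else if (method == "zscore") {
    if (anyNA(p$zscore_all) || anyNA(p$zscore_o) || anyNA(p$n_all) || anyNA(p$n_o)) {
      stop("zscore adjustment requires zscore and n in both tables for all shared variants")
    }
    if (anyNA(maf)) stop("zscore adjustment requires maf (from ", maf_source, " table)")
    feasible <- p$n_all > p$n_o
    status[!feasible] <- "dropped_unstable"
    if (any(feasible)) {
      inv <- z_inverse(p$zscore_all[feasible], p$n_all[feasible],
                       p$zscore_o[feasible], p$n_o[feasible])
      bs <- z_to_beta(inv$z, inv$n, maf[feasible])
      out$zscore[feasible] <- inv$z
      out$n[feasible] <- inv$n
      out$beta[feasible] <- bs$beta
      out$se[feasible] <- bs$se
      out$pvalue[feasible] <- pvalue_from_z(inv$z)
    }
  } else { # decorrelation
    if (is.null(params)) stop("decorrelation requires params (n_c, n_all, n_o, cor_y, or rho)")
    rho <- if (!is.null(params$rho)) params$rho else
      estimate_rho(params$n_c, params$n_all, params$n_o, params$cor_y)
    if (anyNA(p$zscore_all) || anyNA(p$zscore_o)) {
      stop("decorrelation requires zscore in both tables for all shared variants")
    }
    zeta <- decorrelate(p$zscore_all, p$zscore_o, rho)
    out$zscore <- zeta
    out$pvalue <- pvalue_from_z(zeta)
    out$n <- p$n_all
    ok_nm <- !is.na(out$n) & !is.na(maf)
    if (any(ok_nm)) {
      bs <- z_to_beta(zeta[ok_nm], out$n[ok_nm], maf[ok_nm])
      out$beta[ok_nm] <- bs$beta
      out$se[ok_nm] <- bs$se
    }
  }

  if (!any(status == "adjusted")) {
    stop("no variants could be adjusted: every shared variant is unstable ",
         "(the overlap carries as much information as the consortium)")
  }

  adjusted_rows <- out[status == "adjusted", , drop = FALSE]
  pass <- as.data.frame(h$passthrough)
  if (nrow(pass) > 0) {
    adjusted_rows <- rbind(adjusted_rows, pass[names(adjusted_rows)])
  }
  adjusted <- as_sumstats(adjusted_rows)

  status_df <- data.frame(variant_id = c(p$variant_id, pass$variant_id),
                          status = c(status, rep("passthrough", nrow(pass))),
                          stringsAsFactors = FALSE)
  counts <- c(adjusted = sum(status == "adjusted"),
              passthrough = nrow(pass),
              dropped_unstable = sum(status == "dropped_unstable"))

  structure(list(adjusted = adjusted, status = status_df, counts = counts,
                 method = method, harmonization = h$drops),
            class = "oa_adjustment")
}

#' @export
print.oa_adjustment <- function(x, ...) {
  cat(sprintf("overlap adjustment (method: %s)\n", x$method))
  cat("variant status:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
  cat(sprintf("adjusted table: %d variants\n", nrow(x$adjusted)))
  invisible(x)
}
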