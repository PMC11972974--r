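# Canonical column order of a summary-statistics table.
SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "beta", "se", "zscore", "pvalue", "n", "maf")

# Header synonyms recognised by dialect = "auto" (matched case-insensitively,
# after stripping leading '#').
.dialect_auto <- list(
  variant_id    = c("variant_id", "snp", "id", "rsid", "rs", "markername", "marker"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "alt", "ea", "allele1", "effect.allele"),
  other_allele  = c("other_allele", "a2", "ref", "oa", "nea", "allele2", "allele0"),
  beta          = c("beta", "effect", "b", "est", "log_odds"),
  se            = c("se", "stderr", "standard_error", "sebeta"),
  pvalue        = c("pvalue", "p", "p-value", "pval", "p_value", "p.value"),
  n             = c("n", "nobs", "samplesize", "n_samples", "neff"),
  zscore        = c("zscore", "z", "stat", "z_stat", "zstat"),
  maf           = c("maf", "eaf", "frq", "a1freq", "freq", "af")
)

.rel_tol <- 1e-6

#' Build a validated GWAS summary-statistics table
#'
#' Coerces a data frame with canonical column names into a `sumstats` object:
#' fills derivable fields (Z from beta/se, P from Z), folds effect-allele
#' frequencies above 0.5 to minor-allele frequencies, drops rows that violate
#' the table invariants, and records per-reason drop counts.
#'
#' Invariants enforced on retained rows: unique `variant_id`; `se > 0` where
#' present; `zscore = beta/se` where all three are present; `pvalue` equal to
#' the two-sided normal tail of `zscore` (recomputed with a warning when
#' inconsistent beyond 1e-6 relative tolerance, since the Z chain drives all
#' downstream adjustment algebra).
#'
#' @param df data frame carrying at least `variant_id`, `effect_allele`,
#'   `other_allele`, and either `beta` + `se` or `zscore`.
#' @return A `sumstats` data frame with columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, beta, se, zscore,
#'   pvalue, n, maf` and a `drop_counts` attribute (named integer vector).
#' @export
as_sumstats <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!(("beta" %in% names(df) && "se" %in% names(df)) || "zscore" %in% names(df))) {
    stop("need either beta+se or zscore columns")
  }
  for (col in SUMSTATS_COLS) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df <- df[SUMSTATS_COLS]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "beta", "se", "zscore", "pvalue", "n", "maf")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  drops <- c(missing_fields = 0L, bad_allele = 0L, nonpositive_se = 0L,
             bad_maf = 0L, bad_n = 0L, duplicate_id = 0L, unusable_row = 0L)

  keep <- !is.na(df$variant_id) & !is.na(df$effect_allele) & !is.na(df$other_allele)
  drops["missing_fields"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  ok_allele <- df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele
  drops["bad_allele"] <- sum(!ok_allele)
  df <- df[ok_allele, , drop = FALSE]

  # se must be strictly positive where given; NA se tolerated only with a Z.
  bad_se <- !is.na(df$se) & df$se <= 0
  drops["nonpositive_se"] <- sum(bad_se)
  df <- df[!bad_se, , drop = FALSE]

  # fold effect-allele frequency to MAF; reject impossible frequencies
  bad_maf <- !is.na(df$maf) & (df$maf <= 0 | df$maf >= 1)
  drops["bad_maf"] <- sum(bad_maf)
  df <- df[!bad_maf, , drop = FALSE]
  fold <- !is.na(df$maf) & df$maf > 0.5
  df$maf[fold] <- 1 - df$maf[fold]

  bad_n <- !is.na(df$n) & df$n <= 0
  drops["bad_n"] <- sum(bad_n)
  df <- df[!bad_n, , drop = FALSE]

  # each row must carry usable association evidence
  usable <- (!is.na(df$beta) & !is.na(df$se)) | !is.na(df$zscore)
  drops["unusable_row"] <- sum(!usable)
  df <- df[usable, , drop = FALSE]

  dup <- duplicated(df$variant_id)
  drops["duplicate_id"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  # fill/repair the Z chain: beta/se -> zscore -> pvalue
  has_bs <- !is.na(df$beta) & !is.na(df$se)
  z_exp <- ifelse(has_bs, df$beta / df$se, NA_real_)
  fill_z <- has_bs & is.na(df$zscore)
  df$zscore[fill_z] <- z_exp[fill_z]
  inconsistent_z <- has_bs & !is.na(df$zscore) &
    abs(df$zscore - z_exp) > .rel_tol * pmax(1, abs(df$zscore))
  if (any(inconsistent_z)) {
    warning(sum(inconsistent_z), " row(s) had zscore inconsistent with beta/se; recomputed")
    df$zscore[inconsistent_z] <- z_exp[inconsistent_z]
  }
  p_exp <- ifelse(is.na(df$zscore), NA_real_, pvalue_from_z(df$zscore))
  fill_p <- is.na(df$pvalue) & !is.na(p_exp)
  df$pvalue[fill_p] <- p_exp[fill_p]
  inconsistent_p <- !is.na(df$pvalue) & !is.na(p_exp) &
    abs(df$pvalue - p_exp) > .rel_tol * pmax(df$pvalue, p_exp)
  if (any(inconsistent_p)) {
    warning(sum(inconsistent_p), " row(s) had pvalue inconsistent with zscore; recomputed")
    df$pvalue[inconsistent_p] <- p_exp[inconsistent_p]
  }

  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"), drop_counts = drops)
}

#' Per-reason counts of rows dropped during validation
#'
#' @param x a `sumstats` object.
#' @return Named integer vector of drop reasons.
#' @export
drop_counts <- function(x) {
  dc <- attr(x, "drop_counts")
  if (is.null(dc)) integer(0) else dc
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d variants\n", nrow(x)))
  dc <- drop_counts(x)
  if (sum(dc) > 0) {
    dropped <- dc[dc > 0]
    cat("dropped during validation:",
        paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a header-bearing tab-delimited file (gzip accepted) in any of the
#' common "sumstats" dialects and returns a validated [as_sumstats()] table.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect `"auto"` to resolve common header synonyms
#'   (SNP/ID/rsid, A1/ALT/EA, A2/REF/NEA, BETA/Effect, SE/StdErr, P/pval,
#'   N, Z, MAF/EAF — EAF above 0.5 is folded to MAF), or a named character
#'   vector mapping canonical roles to file column names,
#'   e.g. `c(beta = "Effect", se = "StdErr")` (unmapped roles still resolve
#'   via the automatic synonyms).
#' @return A `sumstats` table; rows failing validation are dropped and
#'   counted (see [drop_counts()]).
#' @export
read_sumstats <- function(path, dialect = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  nm <- sub("^#", "", names(raw))
  lower <- tolower(nm)
  mapped <- list()
  explicit <- if (is.character(dialect) && length(names(dialect)) > 0) dialect else NULL
  for (role in names(.dialect_auto)) {
    src <- NA_character_
    if (!is.null(explicit) && role %in% names(explicit)) {
      hit <- match(tolower(explicit[[role]]), lower)
      if (is.na(hit)) stop("dialect maps role '", role, "' to absent column '",
                           explicit[[role]], "'")
      src <- nm[hit]
    } else {
      hit <- match(.dialect_auto[[role]], lower)
      hit <- hit[!is.na(hit)]
      if (length(hit) > 0) src <- nm[hit[1]]
    }
    if (!is.na(src)) mapped[[role]] <- raw[[match(src, nm)]]
  }
  need <- c("variant_id", "effect_allele", "other_allele")
  miss <- setdiff(need, names(mapped))
  if (length(miss) > 0) {
    stop("cannot resolve mandatory column role(s): ", paste(miss, collapse = ", "))
  }
  if (!(all(c("beta", "se") %in% names(mapped)) || "zscore" %in% names(mapped))) {
    stop("cannot resolve association columns: need beta+se or zscore")
  }
  out <- as_sumstats(as.data.frame(mapped, stringsAsFactors = FALSE))
  if (nrow(out) == 0) stop("no valid rows remain after validation: ", path)
  out
}

#' Write a summary-statistics table to tab-delimited text
#'
#' Writes the canonical 11-column header; missing fields become `NA` tokens.
#' Full numeric precision is kept so a read/write round trip reproduces the
#' numeric fields.
#'
#' @param table a `sumstats` object.
#' @param path output file path.
#' @export
write_sumstats <- function(table, path) {
  if (!inherits(table, "sumstats")) table <- as_sumstats(table)
  if (nrow(table) == 0) stop("refusing to write an empty summary-statistics table")
  df <- as.data.frame(table)[SUMSTATS_COLS]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# Flip one summary record onto the opposite allele orientation:
# swap alleles, negate beta and zscore, frequency -> 1 - frequency.
# Applying it twice restores the record exactly.
.flip_record <- function(df) {
  tmp <- df$effect_allele
  df$effect_allele <- df$other_allele
  df$other_allele <- tmp
  df$beta <- -df$beta
  df$zscore <- -df$zscore
  df$maf <- ifelse(is.na(df$maf), NA_real_, 1 - df$maf)
  df
}

#' Harmonize consortium and overlap summary tables onto shared variants
#'
#' Inner join on `variant_id` with allele reconciliation: when the overlap
#' record's effect/other alleles are swapped relative to the consortium, its
#' `beta` and `zscore` are negated and the allele frequency replaced by its
#' complement, so every stored pair is on the consortium's effect-allele
#' orientation. Strand-ambiguous palindromic variants (A/T, C/G) and pairs
#' with incompatible allele sets are dropped and counted. Consortium-only
#' variants are returned separately as pass-through: they carry no overlap
#' signal and are later emitted unadjusted.
#'
#' @param consortium,overlap `sumstats` tables.
#' @return An object of class `oa_matched`: list with `pairs` (data frame of
#'   consortium `*_all` and overlap `*_o` fields plus `flipped`),
#'   `passthrough` (consortium-only `sumstats`), `drops` (named counts) and
#'   `n_overlap_only`.
#' @export
harmonize <- function(consortium, overlap) {
  if (!inherits(consortium, "sumstats")) consortium <- as_sumstats(consortium)
  if (!inherits(overlap, "sumstats")) overlap <- as_sumstats(overlap)

  shared <- intersect(consortium$variant_id, overlap$variant_id)
  cons_only <- !(consortium$variant_id %in% shared)
  passthrough <- consortium[cons_only, , drop = FALSE]
  class(passthrough) <- c("sumstats", "data.frame")
  n_overlap_only <- sum(!(overlap$variant_id %in% shared))

  ci <- consortium[match(shared, consortium$variant_id), , drop = FALSE]
  oi <- overlap[match(shared, overlap$variant_id), , drop = FALSE]

  drops <- c(palindromic = 0L, allele_mismatch = 0L)
  pal <- .is_palindromic(ci$effect_allele, ci$other_allele) |
    .is_palindromic(oi$effect_allele, oi$other_allele)
  drops["palindromic"] <- sum(pal)
  ci <- ci[!pal, , drop = FALSE]; oi <- oi[!pal, , drop = FALSE]

  same <- ci$effect_allele == oi$effect_allele & ci$other_allele == oi$other_allele
  swapped <- ci$effect_allele == oi$other_allele & ci$other_allele == oi$effect_allele
  mism <- !(same | swapped)
  drops["allele_mismatch"] <- sum(mism)
  ci <- ci[!mism, , drop = FALSE]; oi <- oi[!mism, , drop = FALSE]
  flipped <- swapped[!mism]
  if (any(flipped)) oi[flipped, ] <- .flip_record(oi[flipped, , drop = FALSE])

  if (nrow(ci) == 0) stop("no variants shared between the two tables after harmonization")

  pairs <- data.frame(
    variant_id = ci$variant_id, chrom = ci$chrom, pos = ci$pos,
    effect_allele = ci$effect_allele, other_allele = ci$other_allele,
    beta_all = ci$beta, se_all = ci$se, zscore_all = ci$zscore,
    pvalue_all = ci$pvalue, n_all = ci$n, maf_all = ci$maf,
    beta_o = oi$beta, se_o = oi$se, zscore_o = oi$zscore,
    pvalue_o = oi$pvalue, n_o = oi$n, maf_o = oi$maf,
    flipped = flipped, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  structure(list(pairs = pairs, passthrough = passthrough, drops = drops,
                 n_overlap_only = n_overlap_only),
            class = "oa_matched")
}

#' @export
print.oa_matched <- function(x, ...) {
  cat(sprintf("harmonized pairs: %d (flipped: %d)\n",
              nrow(x$pairs), sum(x$pairs$flipped)))
  cat(sprintf("consortium-only pass-through: %d; overlap-only ignored: %d\n",
              nrow(x$passthrough), x$n_overlap_only))
  cat("dropped:", paste(sprintf("%s=%d", names(x$drops), x$drops), collapse = ", "), "\n")
  invisible(x)
}
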