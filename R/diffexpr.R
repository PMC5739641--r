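## Paired differential expression, tumour vs normal, on log2 intensities.
##
## Fold-change convention: signed_fc >= 1 means x-fold up in tumour,
## signed_fc <= -1 means x-fold down; |signed_fc| = 2^|mean log2 diff|, so
## values in (-1, 1) cannot occur.

signed_fc_from_log2 <- function(d) ifelse(d >= 0, 2^d, -(2^(-d)))

log2_from_signed_fc <- function(fc) sign(fc) * log2(abs(fc))

paired_differences <- function(study, cohort = NULL) {
  if (!is.null(cohort)) study <- subset_study(study, cohort = cohort)
  s <- study$samples
  tab <- table(s$subject_id, s$tissue)
  if (!all(c("normal", "tumour") %in% colnames(tab)) || any(tab != 1L)) {
    stop("paired analysis needs exactly one normal and one tumour sample per subject",
         call. = FALSE)
  }
  subjects <- rownames(tab)
  ni <- s$sample_id[match(paste(subjects, "normal"), paste(s$subject_id, s$tissue))]
  ti <- s$sample_id[match(paste(subjects, "tumour"), paste(s$subject_id, s$tissue))]
  d <- study$values[, ti, drop = FALSE] - study$values[, ni, drop = FALSE]
  colnames(d) <- subjects
  d
}

#' Paired t-tests per miRNA, tumour vs normal
#'
#' For each feature, the within-subject log2 differences (tumour minus
#' normal) are tested against zero with a two-sided Student t-test on
#' `n_pairs - 1` degrees of freedom. Fold-changes follow the sign-encoded
#' linear convention (a 1.5-fold decrease appears as -1.50); q-values are
#' Benjamini-Hochberg over all tested features. Features whose differences
#' have zero variance get p = 1 with a warning (the t statistic is
#' undefined there); an all-zero difference vector also gets fold-change 1.
#'
#' @param study An `expression_study` with paired samples.
#' @param cohort Optional cohort restriction before pairing.
#' @return A data.frame sorted by `p_value`, columns `mirna`, `signed_fc`,
#'   `mean_log2_diff`, `t_stat`, `p_value`, `q_value`.
#' @export
paired_ttest <- function(study, cohort = NULL) {
  d <- paired_differences(study, cohort)
  n <- ncol(d)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs", call. = FALSE)
  m <- rowMeans(d)
  v <- apply(d, 1L, stats::var)
  tstat <- m / sqrt(v / n)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  zero_var <- v == 0
  if (any(zero_var)) {
    warning(sum(zero_var),
            " feature(s) with zero-variance paired differences: p set to 1",
            call. = FALSE)
    p[zero_var] <- 1
    tstat[zero_var] <- ifelse(m[zero_var] == 0, 0, Inf * sign(m[zero_var]))
  }
  out <- data.frame(mirna = rownames(d),
                    signed_fc = signed_fc_from_log2(m),
                    mean_log2_diff = m,
                    t_stat = tstat,
                    p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select deregulated miRNAs at a significance threshold
#'
#' Gates on the raw p-value by default (mirroring selection behaviour where
#' per-feature tables report raw p); set `use_q = TRUE` to gate on the
#' Benjamini-Hochberg q-value instead.
#'
#' @param records Data.frame from [paired_ttest()] or
#'   [cross_cohort_contrast()].
#' @param alpha Significance threshold in (0,1).
#' @param use_q Gate on `q_value` instead of `p_value`.
#' @return Character vector of selected miRNA ids (sorted by p).
#' @export
select_deregulated <- function(records, alpha = 0.05, use_q = FALSE) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (is.null(records) || nrow(records) == 0L) return(character(0))
  pv <- if (use_q) records$q_value else records$p_value
  records$mirna[pv < alpha]
}

#' Cross-cohort contrast on paired log2 differences
#'
#' Compares the subject-level paired log2 differences (tumour minus normal)
#' of cohort A against cohort B per miRNA with a Welch two-sample t-test
#' (unequal variances; robust to the small, unequal cohort sizes typical of
#' paired profiling studies). `signed_fc` encodes the ratio of the two
#' cohorts' linear fold-changes: a value of 2 means the tumour/normal
#' fold-change in A is twice that in B. Swapping the cohorts inverts the
#' fold-change (x -> -1/x on the signed scale) and leaves p unchanged.
#'
#' @param study_a,study_b Paired `expression_study` objects (e.g. two cohort
#'   subsets); the feature intersection is tested.
#' @return Data.frame with the same columns as [paired_ttest()].
#' @export
cross_cohort_contrast <- function(study_a, study_b) {
  da <- paired_differences(study_a)
  db <- paired_differences(study_b)
  if (ncol(da) < 2L || ncol(db) < 2L) {
    stop("cross-cohort contrast needs at least 2 subjects per cohort", call. = FALSE)
  }
  feats <- intersect(rownames(da), rownames(db))
  if (length(feats) == 0L) stop("no shared features between cohorts", call. = FALSE)
  da <- da[feats, , drop = FALSE]
  db <- db[feats, , drop = FALSE]
  na <- ncol(da); nb <- ncol(db)
  ma <- rowMeans(da); mb <- rowMeans(db)
  va <- apply(da, 1L, stats::var); vb <- apply(db, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  zero <- se2 == 0
  if (any(zero)) {
    warning(sum(zero), " feature(s) with zero-variance contrast: p set to 1",
            call. = FALSE)
    p[zero] <- 1
    tstat[zero] <- 0
  }
  m <- ma - mb
  out <- data.frame(mirna = feats,
                    signed_fc = signed_fc_from_log2(m),
                    mean_log2_diff = m,
                    t_stat = tstat,
                    p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a differential-expression table as TSV
#'
#' Columns mirror per-feature result tables: mirna, fold_change, p_value,
#' q_value.
#'
#' @param records Data.frame from [paired_ttest()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diffexpr <- function(records, path) {
  out <- data.frame(mirna = records$mirna,
                    fold_change = records$signed_fc,
                    p_value = records$p_value,
                    q_value = records$q_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
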