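#' ANCOVA group comparison with a covariate
#'
#' Fits `value ~ group + covariate` by least squares and reports the group
#' coefficient's t statistic (with n - 3 residual degrees of freedom) and
#' its two-sided p, matching the convention of reporting a T value for the
#' adjusted group contrast; the equivalent F (= t^2) is also returned.  The
#' sign convention is `mean(first level) - mean(second level)` positive,
#' i.e. the t is positive when the reference group sits higher after
#' adjustment.
#'
#' @param values numeric outcome per subject.
#' @param group two-level factor (or character); the first level is the
#'   reference group.
#' @param covariate numeric covariate (e.g. tumor size, cm^3).
#' @return Data frame row: `statistic` (t), `f_value`, `df`, `p`,
#'   `mean_a`, `mean_b` (raw group means, first and second level).
#' @export
ancova_group_test <- function(values, group, covariate) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (any(table(group) < 3L)) stop("need at least 3 subjects per group")
  if (!all(is.finite(covariate))) stop("covariate must be finite")
  if (stats::sd(values) == 0) stop("constant outcome: ANCOVA undefined")
  X <- stats::model.matrix(~ group + covariate)
  if (qr(X)$rank < 3L) {
    stop("rank-deficient ANCOVA design: covariate is collinear with the ",
         "group indicator (or constant)")
  }
  fit <- stats::lm(values ~ group + covariate)
  sm <- summary(fit)$coefficients
  t_grp <- -sm[2L, "t value"]  # + when the first (reference) level is higher
  p <- sm[2L, "Pr(>|t|)"]
  lv <- levels(group)
  data.frame(statistic = t_grp, f_value = t_grp^2,
             df = fit$df.residual, p = p,
             mean_a = mean(values[group == lv[1L]]),
             mean_b = mean(values[group == lv[2L]]))
}

#' Independent two-sample t test
#'
#' Classical (equal-variance) Student t, as used for age and tumor size.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return Data frame row: `statistic`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
independent_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    stop("zero within-group variance: t statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Chi-square test on a contingency table
#'
#' Pearson chi-square, without continuity correction by default (the K
#' statistic convention for 2x2 mapping-count comparisons).
#'
#' @param tab contingency table (matrix of non-negative integer counts).
#' @param correct apply Yates continuity correction.
#' @return Data frame row: `statistic` (K), `df`, `p`.
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold non-negative integer counts")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' The nonparametric two-group comparison (Wilcoxon rank-sum); exact when
#' sample sizes allow and no ties are present, normal approximation with tie
#' correction otherwise.
#'
#' @param a,b numeric vectors.
#' @return Data frame row: `statistic` (U), `p`, `mean_a`, `mean_b`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  ties <- any(duplicated(c(a, b)))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = !ties,
                                            correct = TRUE))
  data.frame(statistic = unname(ht$statistic), p = ht$p.value,
             mean_a = mean(a), mean_b = mean(b))
}

#' Correlation of network properties with aphasia level
#'
#' Spearman by default since the aphasia level is ordinal; Pearson is
#' available.  Computed over the pooled cohort (both groups).
#'
#' @param values numeric network property per subject.
#' @param aphasia_levels ordinal levels (0 = none .. 5).
#' @param method `"spearman"` or `"pearson"`.
#' @return Data frame row: `statistic` (R), `p`, `n`, `method`.
#' @export
correlate_with_aphasia <- function(values, aphasia_levels,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(values) < 4L) stop("need at least 4 paired observations")
  if (stats::sd(values) == 0 || stats::sd(aphasia_levels) == 0) {
    stop("constant input: correlation undefined")
  }
  ht <- suppressWarnings(
    stats::cor.test(values, aphasia_levels, method = method, exact = FALSE)
  )
  data.frame(statistic = unname(ht$estimate), p = ht$p.value,
             n = length(values), method = method)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group-comparison table over all matrices, metrics and threshold blocks
#'
#' One ANCOVA row (tumor-size covariate) per matrix kind x metric x block
#' (the two VR thresholds plus their difference), FDR-corrected as one
#' family; the layout of the headline network-comparison table.
#'
#' @param metrics data frame from [cohort_metrics()] (columns `subject`,
#'   `kind`, `block`, `ad`, `eg`, `el` in long form; see below).
#' @param cohort cohort data frame (`subject`, `group`, `tumor_size`,
#'   `aphasia_level`).
#' @param alpha significance flag level.
#' @return Data frame: `kind`, `metric`, `block`, group means, `statistic`,
#'   `f_value`, `p`, `p_fdr`, `significant`.
#' @export
group_comparison_table <- function(metrics, cohort, alpha = 0.05) {
  long <- metrics_long(metrics)
  check_complete(long, cohort)
  key <- unique(long[, c("kind", "metric", "block")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- long$kind == key$kind[i] & long$metric == key$metric[i] &
      long$block == key$block[i]
    v <- long$value[sel][match(cohort$subject, long$subject[sel])]
    res <- tryCatch(
      ancova_group_test(v, cohort$group, cohort$tumor_size),
      error = function(e) {
        g <- as.factor(as.character(cohort$group))
        data.frame(statistic = NA_real_, f_value = NA_real_,
                   df = length(v) - 3L, p = NA_real_,
                   mean_a = mean(v[g == levels(g)[1L]]),
                   mean_b = mean(v[g == levels(g)[2L]]))
      }
    )
    cbind(key[i, , drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  # group means labelled by level order of ancova_group_test (alphabetical);
  # rename to the cohort's group labels for readability
  lv <- levels(as.factor(as.character(cohort$group)))
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lv[1L])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lv[2L])
  out$p_fdr <- fdr_adjust(out$p)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Correlation table of properties versus aphasia level
#'
#' One pooled-cohort correlation row per matrix kind x metric x block,
#' FDR-corrected as one family.
#'
#' @inheritParams group_comparison_table
#' @param method correlation method, see [correlate_with_aphasia()].
#' @return Data frame: `kind`, `metric`, `block`, `statistic` (R), `p`,
#'   `p_fdr`, `significant`.
#' @export
correlation_table <- function(metrics, cohort, method = "spearman",
                              alpha = 0.05) {
  long <- metrics_long(metrics)
  check_complete(long, cohort)
  key <- unique(long[, c("kind", "metric", "block")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- long$kind == key$kind[i] & long$metric == key$metric[i] &
      long$block == key$block[i]
    v <- long$value[sel][match(cohort$subject, long$subject[sel])]
    res <- tryCatch(
      correlate_with_aphasia(v, cohort$aphasia_level, method = method),
      error = function(e) data.frame(statistic = NA_real_, p = NA_real_,
                                     n = length(v), method = method)
    )
    cbind(key[i, , drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

metrics_long <- function(metrics) {
  stopifnot(all(c("subject", "kind", "block") %in% names(metrics)))
  vals <- c("ad", "eg", "el")
  out <- do.call(rbind, lapply(vals, function(m) {
    data.frame(subject = metrics$subject, kind = metrics$kind,
               metric = m, block = metrics$block, value = metrics[[m]],
               stringsAsFactors = FALSE)
  }))
  out
}

check_complete <- function(long, cohort) {
  missing_subj <- setdiff(cohort$subject, unique(long$subject))
  if (length(missing_subj) > 0L) {
    stop("metrics missing for subject(s): ",
         paste(missing_subj, collapse = ", "))
  }
  per <- table(long$subject)
  if (length(unique(per)) != 1L) {
    uneven <- names(per)[per != max(per)]
    stop("incomplete metric rows for subject(s): ",
         paste(uneven, collapse = ", "))
  }
  invisible(TRUE)
}
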