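# Nonparametric group comparisons and correlations: Kruskal-Wallis omnibus,
# Dunn post hoc, Mann-Whitney, Spearman, and infiltration-stratified
# correlation of features.

#' Kruskal-Wallis omnibus test across groups
#'
#' Tie-corrected rank-sum H statistic with a chi-square approximation on
#' k - 1 degrees of freedom (wraps `stats::kruskal.test`). All-identical
#' values give H = 0, p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Mean-rank differences standardized with the tie-corrected variance
#' `(N(N+1)/12 - T) * (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p values, adjusted
#' for the 6 pairwise comparisons among 4 groups (Holm by default,
#' Bonferroni available).
#'
#' @param values Numeric observations.
#' @param groups Group label per observation.
#' @param adjust Multiplicity adjustment method (see [stats::p.adjust()]).
#' @return Data frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "holm") {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least two groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[[i]] + 1 / ng[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- pmin(1, p.adjust(out$p, method = adjust))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided; exact enumeration for small tie-free samples, tie-corrected
#' normal approximation otherwise (the `stats::wilcox.test` defaults).
#'
#' @param values_a,values_b Numeric samples.
#' @return List with `U`, `p`.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both samples must be nonempty", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(values_a, values_b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks with a two-sided t-approximation
#' p value. Requires n >= 4; zero rank variance in either variable is
#' reported as missing.
#'
#' @param x,y Numeric vectors.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Stratify biopsies by tumor-cell infiltration density
#'
#' `healthy` for 0 cells / 250 um^2, `low` below 50, `high` at or above 50
#' (the boundary count 50 is assigned to the high stratum).
#'
#' @param count Integer counts of tumor cells per 250 um^2.
#' @return Factor with levels healthy, low, high.
#' @export
stratify_infiltration <- function(count) {
  if (any(count < 0, na.rm = TRUE))
    stop("infiltration counts must be >= 0", call. = FALSE)
  factor(ifelse(count == 0, "healthy", ifelse(count < 50, "low", "high")),
         levels = c("healthy", "low", "high"))
}

#' Correlate features with infiltration, per stratum
#'
#' Joins the biopsy table to the feature table by channel, stratifies by
#' infiltration density and runs a Spearman correlation of each feature
#' against the count inside each stratum. Strata with fewer than 4 biopsies
#' are reported with `NA` correlations.
#'
#' @param biopsy_table Data frame with `channel_id` and `count`.
#' @param features Feature table with `channel_id` and feature columns.
#' @param feature_cols Columns to correlate; default every numeric feature.
#' @return Data frame: `stratum`, `feature`, `rho`, `p`, `n`.
#' @export
stratify_and_correlate <- function(biopsy_table, features,
                                   feature_cols = NULL) {
  merged <- merge(biopsy_table, features, by = "channel_id")
  if (!nrow(merged))
    stop("no biopsy is linked to a recorded channel", call. = FALSE)
  if (is.null(feature_cols)) {
    num <- vapply(features, is.numeric, logical(1))
    feature_cols <- setdiff(names(features)[num],
                            c("count", "distance_mm", "total_power"))
  }
  merged$stratum <- stratify_infiltration(merged$count)
  out <- list()
  for (s in levels(merged$stratum)) {
    sub <- merged[merged$stratum == s, ]
    for (fc in feature_cols) {
      r <- if (nrow(sub) >= 4) spearman_corr(sub[[fc]], sub$count)
           else list(rho = NA_real_, p = NA_real_, n = nrow(sub))
      out[[length(out) + 1]] <- data.frame(
        stratum = s, feature = fc, rho = r$rho, p = r$p, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-feature compartment statistics (group summary + omnibus + post hoc)
#'
#' For every feature column: group mean and SD per compartment, the
#' Kruskal-Wallis omnibus H and p, and Dunn's pairwise table.
#'
#' @param features Feature table with a `label` column.
#' @param feature_cols Feature columns; default every numeric feature.
#' @param adjust Dunn adjustment method.
#' @return List with `summary` (feature x compartment means +/- SD and
#'   omnibus p) and `pairwise` (stacked Dunn tables).
#' @export
compartment_feature_stats <- function(features, feature_cols = NULL,
                                      adjust = "holm") {
  if (is.null(features$label)) stop("features must carry `label`", call. = FALSE)
  labels <- as_compartment(features$label)
  if (is.null(feature_cols)) {
    num <- vapply(features, is.numeric, logical(1))
    feature_cols <- setdiff(names(features)[num],
                            c("distance_mm", "total_power"))
  }
  summ <- list(); pw <- list()
  for (fc in feature_cols) {
    v <- features[[fc]]
    mn <- tapply(v, labels, mean, na.rm = TRUE)
    sdv <- tapply(v, labels, sd, na.rm = TRUE)
    kw <- tryCatch(kruskal_wallis(v, labels),
                   error = function(e) list(H = NA_real_, p = NA_real_))
    row <- data.frame(feature = fc, stringsAsFactors = FALSE)
    for (lv in levels(labels)) {
      row[[paste0(lv, "_mean")]] <- unname(mn[lv])
      row[[paste0(lv, "_sd")]] <- unname(sdv[lv])
    }
    row$H <- kw$H; row$p <- kw$p
    summ[[fc]] <- row
    dp <- tryCatch(dunn_posthoc(v, labels, adjust = adjust),
                   error = function(e) NULL)
    if (!is.null(dp)) { dp$feature <- fc; pw[[fc]] <- dp }
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pw, list(make.row.names = FALSE))))
}
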