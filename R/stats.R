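#' Shapiro-Wilk normality gate
#'
#' Tests each sample at alpha; the downstream test family is parametric iff
#' every group passes. Mirrors the analysis convention of gating the
#' repeated-measures tests on normality.
#'
#' @param samples numeric vector, or list of numeric vectors (all must
#'   pass).
#' @param alpha significance level (default 0.05).
#' @return `list(is_normal, p)`; `p` is the per-group vector.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  p <- vapply(samples, function(x) {
    if (length(x) < 3)
      abort_painbci("Shapiro-Wilk needs at least 3 observations",
                    "painbci_validation_error")
    shapiro.test(x)$p.value
  }, 0)
  list(is_normal = all(p > alpha), p = p)
}

#' Friedman repeated-measures test by ranks
#'
#' Chi-square statistic on within-row (within-subject) ranks with average
#' ranks for ties and the standard tie correction; rows are subjects,
#' columns conditions. Identical columns give statistic 0, p 1.
#'
#' @param m numeric matrix, rows = subjects, columns = conditions.
#' @return A `bci_test_result` list: `statistic`, `df`, `p_value`,
#'   `test_name`, and the column rank sums.
#' @export
friedman_repeated <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2)
    abort_painbci("need >= 3 rows and >= 2 conditions",
                  "painbci_validation_error")
  r <- t(apply(m, 1, rank))
  rs <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  # tie-corrected statistic (Conover form); reduces to the classic
  # 12/(nk(k+1)) sum Rj^2 - 3n(k+1) when there are no ties
  denom <- A - C
  stat <- if (denom <= 0) 0 else
    (k - 1) * (sum(rs^2) - n^2 * k * (k + 1)^2 / 4) / denom
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = stat, df = k - 1, p_value = p,
                 rank_sums = rs, n = n, k = k,
                 test_name = "Friedman rank test"),
            class = "bci_test_result")
}

#' All-pairs post hoc comparison of Friedman rank sums
#'
#' The rank-sum critical-difference procedure attributed to Siegel and
#' Castellan: for conditions u, v compare `|R_u - R_v|` with its normal
#' approximation SE `sqrt(n k (k+1) / 6)`, adjusting the per-pair level for
#' the `k(k-1)/2` comparisons (Bonferroni). By convention the table is only
#' meaningful when the omnibus test rejects; a `note` records the omnibus
#' p value.
#'
#' @param m subjects-by-conditions matrix.
#' @param alpha family-wise level.
#' @return Data frame of pairs with `z`, raw and adjusted p values and the
#'   significance flag; attribute `omnibus` carries the Friedman result.
#' @export
posthoc_pairwise <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  omni <- friedman_repeated(m)
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rs <- colSums(r)
  labs <- colnames(m) %||% paste0("C", seq_len(k))
  se <- sqrt(n * k * (k + 1) / 6)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    z <- abs(rs[pr[1]] - rs[pr[2]]) / se
    p_raw <- 2 * pnorm(-z)
    data.frame(a = labs[pr[1]], b = labs[pr[2]], z = z,
               p_raw = p_raw, p_adj = min(1, p_raw * n_pairs))
  }))
  out$significant <- omni$p_value < alpha & out$p_adj < alpha
  attr(out, "omnibus") <- omni
  out
}

#' Paired t-test with Cohen's d and post hoc power
#'
#' Paired t on the differences; Cohen's d = mean(diff) / SD(diff); post hoc
#' power for the observed d at the same alpha from the noncentral-t
#' distribution.
#'
#' @param a,b paired samples.
#' @param tail `"two"` or `"one"` (one-sided in the direction of the
#'   observed mean difference).
#' @param alpha level used for the power computation.
#' @return A `bci_test_result` list with `statistic`, `p_value`,
#'   `effect_size`, `power`, `df`.
#' @export
paired_t_effect <- function(a, b, tail = c("two", "one"), alpha = 0.05) {
  tail <- match.arg(tail)
  d <- a - b
  n <- length(d)
  if (n < 2)
    abort_painbci("need at least 2 pairs", "painbci_validation_error")
  sdd <- sd(d)
  if (sdd == 0) {
    tt <- 0; p <- 1; cd <- 0; pow <- alpha
  } else {
    tt <- mean(d) / (sdd / sqrt(n))
    p <- if (tail == "two") 2 * pt(-abs(tt), n - 1)
         else pt(abs(tt), n - 1, lower.tail = FALSE)
    cd <- mean(d) / sdd
    ncp <- abs(cd) * sqrt(n)
    pow <- if (tail == "two") {
      crit <- qt(1 - alpha / 2, n - 1)
      pt(crit, n - 1, ncp = ncp, lower.tail = FALSE) +
        pt(-crit, n - 1, ncp = ncp)
    } else {
      crit <- qt(1 - alpha, n - 1)
      pt(crit, n - 1, ncp = ncp, lower.tail = FALSE)
    }
  }
  structure(list(statistic = tt, df = n - 1, p_value = p,
                 effect_size = cd, power = pow,
                 test_name = sprintf("paired t (%s-tailed)", tail)),
            class = "bci_test_result")
}

#' @export
print.bci_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, df %s, p %.4g", x$test_name,
              x$statistic, format(x$df), x$p_value))
  if (!is.null(x$effect_size))
    cat(sprintf(", d %.3g, power %.3g", x$effect_size, x$power))
  cat("\n")
  invisible(x)
}

#' Subject-by-condition matrix of per-subject mean feature values
#'
#' Aggregates a pooled feature table (one row per window, with a `subject`
#' column) to the per-subject per-condition means the omnibus tests run on.
#'
#' @param df data frame with columns `subject`, `label` and the feature.
#' @param feature feature column name.
#' @param conditions column order of the output.
#' @export
condition_matrix <- function(df, feature,
                             conditions = intersect(CONDITION_LABELS,
                                                    unique(df$label))) {
  agg <- aggregate(df[[feature]],
                   by = list(subject = df$subject, label = df$label), mean)
  m <- matrix(NA_real_, length(unique(agg$subject)), length(conditions),
              dimnames = list(sort(unique(agg$subject)), conditions))
  for (i in seq_len(nrow(agg)))
    if (agg$label[i] %in% conditions)
      m[as.character(agg$subject[i]), agg$label[i]] <- agg$x[i]
  if (anyNA(m))
    abort_painbci("missing subject x condition cells",
                  "painbci_validation_error")
  m
}

#' Per-feature direction and significance report
#'
#' For every feature: per-condition means, the sign of the P - R and
#' P - NP differences, and the omnibus Friedman + post hoc results
#' (healthy mode, three conditions) or the paired t result (patient mode,
#' P vs R) computed on per-subject means.
#'
#' @param df pooled feature rows with columns `subject`, `label`, features.
#' @param features feature column names (default: everything else).
#' @param mode `"healthy"` or `"patient"`.
#' @param alpha significance level.
#' @return A data frame, one row per feature.
#' @export
feature_direction_report <- function(df, features = NULL,
                                     mode = c("healthy", "patient"),
                                     alpha = 0.05) {
  mode <- match.arg(mode)
  features <- features %||%
    setdiff(names(df), c("subject", "label", "window_id", "event_id"))
  if (nrow(df) == 0 || !length(features))
    return(data.frame(feature = character(0)))
  conds <- if (mode == "healthy") c("P", "NP", "R") else c("P", "R")
  conds <- intersect(conds, unique(df$label))
  rows <- lapply(features, function(f) {
    m <- condition_matrix(df, f, conds)
    means <- colMeans(m)
    row <- data.frame(feature = f)
    for (cn in conds) row[[paste0("mean_", cn)]] <- means[[cn]]
    row$sign_P_vs_R <- if (all(c("P", "R") %in% conds))
      sign(means[["P"]] - means[["R"]]) else NA
    row$sign_P_vs_NP <- if (all(c("P", "NP") %in% conds))
      sign(means[["P"]] - means[["NP"]]) else NA
    if (mode == "healthy" && length(conds) >= 2 && nrow(m) >= 3) {
      omni <- friedman_repeated(m)
      row$p_omnibus <- omni$p_value
      if (length(conds) > 2) {
        ph <- posthoc_pairwise(m, alpha)
        pr <- ph[(ph$a == "P" & ph$b == "R") | (ph$a == "R" & ph$b == "P"), ]
        pn <- ph[(ph$a == "P" & ph$b == "NP") | (ph$a == "NP" & ph$b == "P"), ]
        row$p_P_vs_R <- if (nrow(pr)) pr$p_adj[1] else NA_real_
        row$p_P_vs_NP <- if (nrow(pn)) pn$p_adj[1] else NA_real_
      }
      row$significant <- row$p_omnibus < alpha
    } else if (mode == "patient" && all(c("P", "R") %in% conds)) {
      tr <- paired_t_effect(m[, "P"], m[, "R"])
      row$p_P_vs_R <- tr$p_value
      row$effect_size <- tr$effect_size
      row$significant <- tr$p_value < alpha
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
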