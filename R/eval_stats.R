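#' Confusion table
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return A `confusion_table` list.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_table")
}

#' @rdname confusion_table
#' @param predicted,truth logical vectors (predicted positive / true
#'   positive) of equal length.
#' @export
confusion_from_labels <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusion_table(tp = sum(predicted & truth), fp = sum(predicted & !truth),
                  fn = sum(!predicted & truth), tn = sum(!predicted & !truth))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# binomial CI; Wald is the reporting default (p +/- z*sqrt(p(1-p)/n),
# clipped to [0, 1]); Wilson and Clopper-Pearson behind the flag
binom_ci <- function(x, n, conf_level = 0.95,
                     method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- switch(method,
    wald = {
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    wilson = {
      denom <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(centre - half, centre + half)
    },
    `clopper-pearson` =
      as.vector(stats::binom.test(x, n, conf.level = conf_level)$conf.int))
  pmin(pmax(ci, 0), 1)
}

#' Confusion metrics with binomial confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`
#' and NPV `tn/(tn+fn)`, each with a 95% CI. The default CI is the Wald
#' normal approximation clipped to `[0, 1]`; Wilson and Clopper-Pearson
#' are available behind `ci_method`. A metric with a zero denominator is
#' returned as `NA` and flagged with a warning, never silently zero.
#'
#' @param table a [confusion_table].
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"wald"` (default), `"wilson"` or `"clopper-pearson"`.
#' @return Data frame: `metric, estimate, lower, upper, x, n` (estimates
#'   as proportions; multiply by 100 for the percent scale).
#' @export
confusion_metrics <- function(table, conf_level = 0.95, ci_method = "wald") {
  stopifnot(inherits(table, "confusion_table"))
  defs <- list(sensitivity = c(table$tp, table$tp + table$fn),
               specificity = c(table$tn, table$tn + table$fp),
               ppv = c(table$tp, table$tp + table$fp),
               npv = c(table$tn, table$tn + table$fn))
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1L]; n <- defs[[nm]][2L]
    if (n == 0L) {
      warning(nm, " undefined: zero denominator")
      return(data.frame(metric = nm, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, x = x, n = n))
    }
    ci <- binom_ci(x, n, conf_level, ci_method)
    data.frame(metric = nm, estimate = x / n, lower = ci[1L], upper = ci[2L],
               x = x, n = n)
  })
  do.call(rbind, rows)
}

#' Exact McNemar test on discordant counts
#'
#' Two-sided exact test for paired proportions: with discordant counts
#' `b` and `c`, `p = min(1, 2 * P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)`; `p = 1` when `b = c` or `b + c = 0`.
#'
#' @param b,c discordant counts (non-negative integers).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
mcnemar_exact <- function(b, c) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Fisher's exact test for an R x 2 table by full enumeration
#'
#' Exact conditional test with both margins fixed: the p-value is the sum
#' of multivariate-hypergeometric probabilities of all R x 2 tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (float comparison tolerance 1e-9). Full enumeration is
#' exact and bit-reproducible for the small tables in scope (up to 4 x 2,
#' n of order 100).
#'
#' @param table matrix of non-negative counts with 2 columns and >= 2
#'   rows.
#' @return Two-sided p-value.
#' @export
fisher_exact_rxc <- function(table) {
  tab <- as.matrix(table)
  if (ncol(tab) != 2L || nrow(tab) < 2L) stop("table must be R x 2, R >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0L) stop("all-zero table")
  r <- rowSums(tab)
  c1 <- sum(tab[, 1L])
  n <- sum(r)
  logp_obs <- sum(lchoose(r, tab[, 1L])) - lchoose(n, c1)
  total <- 0
  recurse <- function(row, rem, logp) {
    if (row > length(r)) {
      if (rem == 0L && logp <= logp_obs + 1e-9) total <<- total + exp(logp)
      return(invisible())
    }
    rest <- if (row < length(r)) sum(r[(row + 1L):length(r)]) else 0L
    lo <- max(0L, rem - rest); hi <- min(r[row], rem)
    for (a in lo:hi)
      recurse(row + 1L, rem - a, logp + lchoose(r[row], a))
    invisible()
  }
  recurse(1L, c1, -lchoose(n, c1))
  min(1, total)
}

#' ROC curve and AUC under a strict-greater decision rule
#'
#' Sweeps all distinct score cutoffs, classifying positive when
#' `score > cutoff`, and reports (FPR, TPR) points including (0,0) and
#' (1,1); AUC by the trapezoid rule with tied scores grouped.
#'
#' @param scores numeric per-case scores (higher = more cancer-like).
#' @param labels logical or `"cancer"`/`"control"` truth per case.
#' @return List with `points` (data frame `threshold, fpr, tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "cancer"
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes are required for ROC")
  ts <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(ts, function(t)
    c(mean(scores[!labels] > t), mean(scores[labels] > t)), numeric(2L)))
  pts <- rbind(pts, c(1, 1))
  df <- data.frame(threshold = c(ts, -Inf), fpr = pts[, 1L], tpr = pts[, 2L])
  ord <- order(df$fpr, df$tpr)
  df <- df[ord, ]
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) + utils::tail(df$tpr, -1)) / 2)
  list(points = df, auc = auc)
}

#' Decision-curve analysis for binary tests
#'
#' Net benefit of each model over a grid of threshold probabilities:
#' `NB(pt) = tp/N - (fp/N) * pt/(1-pt)`, with the treat-all reference
#' `prevalence - (1-prevalence) * pt/(1-pt)` and treat-none at 0.
#'
#' @param tables named list of [confusion_table]s sharing the same cohort
#'   (equal `N` and positives).
#' @param pt_grid threshold probabilities in `(0, 1)` (default 0.01 to
#'   0.99 by 0.01).
#' @return A `net_benefit_curve` data frame: `model, pt, net_benefit`.
#' @export
decision_curve <- function(tables, pt_grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(tables) >= 1L)
  if (any(pt_grid <= 0 | pt_grid >= 1))
    stop("threshold probabilities must lie strictly inside (0, 1)")
  Ns <- vapply(tables, function(ct) ct$tp + ct$fp + ct$fn + ct$tn, numeric(1L))
  pos <- vapply(tables, function(ct) ct$tp + ct$fn, numeric(1L))
  if (length(unique(Ns)) != 1L || length(unique(pos)) != 1L)
    stop("all tables must describe the same cohort (equal N and positives)")
  N <- Ns[[1L]]; prev <- pos[[1L]] / N
  odds <- pt_grid / (1 - pt_grid)
  out <- lapply(names(tables), function(nm) {
    ct <- tables[[nm]]
    data.frame(model = nm, pt = pt_grid,
               net_benefit = ct$tp / N - (ct$fp / N) * odds)
  })
  out <- c(out, list(
    data.frame(model = "treat_all", pt = pt_grid,
               net_benefit = prev - (1 - prev) * odds),
    data.frame(model = "treat_none", pt = pt_grid, net_benefit = 0)))
  structure(do.call(rbind, out), class = c("net_benefit_curve", "data.frame"))
}

#' Compare a metric across strata with Fisher's exact test
#'
#' Builds the R x 2 success/failure table of the chosen metric across
#' strata (e.g. sensitivity across tumor locations: detected vs missed
#' cancers per location) and tests it with [fisher_exact_rxc]. The
#' significance flag uses a Bonferroni-adjusted alpha `0.05 / k`.
#'
#' @param tables named list of per-stratum [confusion_table]s.
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`,
#'   `"npv"`.
#' @param bonferroni_k number of comparisons the alpha is divided by.
#' @return List: `p_value, alpha, significant, table` (the R x 2 counts),
#'   `dropped` (strata removed for zero denominators).
#' @export
stratified_compare <- function(tables,
                               metric = c("sensitivity", "specificity",
                                          "ppv", "npv"),
                               bonferroni_k = 1L) {
  metric <- match.arg(metric)
  if (length(tables) < 2L) stop("at least 2 strata are required")
  pick <- switch(metric,
    sensitivity = function(ct) c(ct$tp, ct$fn),
    specificity = function(ct) c(ct$tn, ct$fp),
    ppv = function(ct) c(ct$tp, ct$fp),
    npv = function(ct) c(ct$tn, ct$fn))
  rows <- t(vapply(tables, pick, numeric(2L)))
  ok <- rowSums(rows) > 0
  if (any(!ok))
    warning(metric, " undefined in strata dropped: ",
            paste(names(tables)[!ok], collapse = ", "))
  rows <- rows[ok, , drop = FALSE]
  if (nrow(rows) < 2L) stop("fewer than 2 strata with a defined ", metric)
  alpha <- 0.05 / bonferroni_k
  p <- fisher_exact_rxc(rows)
  list(p_value = p, alpha = alpha, significant = p < alpha,
       table = rows, dropped = names(tables)[!ok])
}
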