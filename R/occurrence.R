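#' Per-sample class totals
#'
#' Sums the congener-resolved concentrations of each sample within each
#' analyte class.
#'
#' @param conc `cp_conc` data.frame.
#' @return data.frame with columns `sample_id`, `region`, `analyte_class`,
#'   `total_ng_g`.
#' @export
class_totals <- function(conc) {
  if (nrow(conc) == 0L) stop("no concentration records", call. = FALSE)
  agg <- stats::aggregate(
    conc_ng_g ~ sample_id + region + analyte_class,
    data = as.data.frame(conc), FUN = sum
  )
  names(agg)[names(agg) == "conc_ng_g"] <- "total_ng_g"
  agg <- agg[order(agg$region, agg$sample_id, agg$analyte_class), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Regional occurrence summary
#'
#' Per region and analyte class: sample count, detection rate (fraction of
#' class totals above the class MDL), and mean/sd/min/max of the class totals
#' (ng/g ww). The sd of a single observation is reported as 0 with
#' `sd_flag = TRUE` so summaries stay total.
#'
#' @param conc `cp_conc` data.frame.
#' @param constants output of [cp_constants()].
#' @return data.frame of class `cp_region_summary` with columns `region`,
#'   `analyte_class`, `n`, `n_detected`, `detection_rate`, `mean`, `sd`,
#'   `min`, `max`, `sd_flag`.
#' @export
summarize_regions <- function(conc, constants = cp_constants()) {
  tot <- class_totals(conc)
  key <- interaction(tot$region, tot$analyte_class, drop = TRUE)
  rows <- lapply(split(tot, key), function(d) {
    mdl <- .const_lookup(constants, d$analyte_class[1], "mdl")
    data.frame(
      region = d$region[1], analyte_class = d$analyte_class[1],
      n = nrow(d), n_detected = sum(d$total_ng_g > mdl),
      detection_rate = mean(d$total_ng_g > mdl),
      mean = mean(d$total_ng_g),
      sd = if (nrow(d) > 1L) stats::sd(d$total_ng_g) else 0,
      min = min(d$total_ng_g), max = max(d$total_ng_g),
      sd_flag = nrow(d) == 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte_class, out$region), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cp_region_summary", "data.frame")
  out
}

#' Sample-size-weighted pooled mean of regional summaries
#'
#' Pools regional mean concentrations into a single mean via
#' sum(n_i * mean_i) / sum(n_i); exactly the mean of the concatenated
#' per-sample totals when the regional means are exact.
#'
#' @param summaries data.frame with columns `analyte_class`, `n`, `mean`
#'   (e.g. [summarize_regions()] output, possibly subset to a super-region).
#' @return single numeric if one analyte class is present, otherwise a named
#'   numeric per class.
#' @export
pooled_mean <- function(summaries) {
  if (nrow(summaries) == 0L || sum(summaries$n) == 0) {
    stop("pooled_mean needs at least one summary with n > 0", call. = FALSE)
  }
  cls <- unique(summaries$analyte_class)
  v <- vapply(cls, function(cl) {
    s <- summaries[summaries$analyte_class == cl, , drop = FALSE]
    sum(s$n * s$mean) / sum(s$n)
  }, numeric(1))
  if (length(cls) == 1L) unname(v) else v
}

# tie-corrected Kruskal-Wallis H for a list of numeric vectors
.kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) 0 else h / corr
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H with a chi-square reference distribution on k - 1 degrees
#' of freedom. For small problems (total n <= `exact_n_max`) an exact
#' permutation p-value over all distinct group assignments is also computed.
#'
#' @param groups list of >= 2 numeric vectors (each non-empty).
#' @param exact_n_max exact-enumeration cutoff on the total sample size.
#' @return list of class `cp_test` with `statistic` (H), `df`, `raw_p`,
#'   `p_exact` (NA unless enumerated), `method`, `groups` (labels).
#' @export
kruskal_wallis <- function(groups, exact_n_max = 10L) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  k <- length(groups)
  if (length(unique(x)) == 1L) {
    return(structure(list(statistic = 0, df = k - 1L, raw_p = 1,
                          p_exact = NA_real_,
                          method = "Kruskal-Wallis H (tie-corrected)",
                          groups = names(groups) %||%
                            as.character(seq_len(k))),
                     class = "cp_test"))
  }
  h <- .kw_h(groups)
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  p_exact <- NA_real_
  if (n <= exact_n_max) {
    sizes <- lengths(groups)
    hs <- .kw_enumerate(x, sizes)
    p_exact <- mean(hs >= h - 1e-12)
  }
  structure(list(statistic = h, df = k - 1L, raw_p = p, p_exact = p_exact,
                 method = "Kruskal-Wallis H (tie-corrected)",
                 groups = names(groups) %||% as.character(seq_len(k))),
            class = "cp_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# enumerate H over all distinct assignments of x into groups of given sizes
.kw_enumerate <- function(x, sizes) {
  idx <- seq_along(x)
  res <- numeric(0)
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes) - 1L) {
      gs <- c(acc, list(remaining))
      res[[length(res) + 1L]] <<- .kw_h(lapply(gs, function(i) x[i]))
      return(invisible())
    }
    sz <- sizes[length(acc) + 1L]
    cmb <- utils::combn(remaining, sz, simplify = FALSE)
    for (s in cmb) recurse(setdiff(remaining, s), c(acc, list(s)))
  }
  recurse(idx, list())
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Monotone (step-up) adjusted p-values, capped at 1: order-preserving,
#' idempotent, and always >= the raw p-values.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  i <- m:1L
  adj <- pmin(1, cummin(m / i * p[o]))
  adj[order(o)]
}

#' All pairwise Wilcoxon rank-sum tests with BH-FDR adjustment
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum tests for every pair of groups
#' (exact when both sizes <= `exact_n_max` and there are no ties, otherwise
#' the tie-corrected normal approximation with continuity correction),
#' followed by Benjamini-Hochberg adjustment across the k(k-1)/2 raw
#' p-values.
#'
#' @param groups named list of >= 2 numeric vectors.
#' @param exact_n_max exact-test cutoff per group.
#' @return data.frame with columns `group1`, `group2`, `statistic` (W),
#'   `raw_p`, `adjusted_p`, `method`.
#' @export
pairwise_wilcoxon_bh <- function(groups, exact_n_max = 25L) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  labs <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    x <- groups[[ij[1]]]; y <- groups[[ij[2]]]
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- length(x) <= exact_n_max && length(y) <= exact_n_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
    )
    data.frame(group1 = labs[ij[1]], group2 = labs[ij[2]],
               statistic = unname(wt$statistic), raw_p = wt$p.value,
               method = if (use_exact) "wilcoxon-exact" else "wilcoxon-normal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$raw_p)
  out[, c("group1", "group2", "statistic", "raw_p", "adjusted_p", "method")]
}

#' Correlation with a Fisher-z confidence interval
#'
#' Pearson or Spearman correlation with a 95% CI from the Fisher z transform
#' (variance 1/(n-3) for Pearson, 1.06/(n-3) for Spearman) and a two-sided
#' p-value (t-test on r for Pearson; normal test on z for Spearman).
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param conf confidence level.
#' @return list of class `cp_cor`: `r`, `ci_low`, `ci_high`, `p`, `n`,
#'   `method`, `degenerate` (TRUE when |r| = 1 and the CI collapses).
#' @export
correlation_with_ci <- function(x, y, method = c("spearman", "pearson"),
                                conf = 0.95) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need n >= 4 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y, method = method)
  if (abs(r) >= 1 - 1e-15) {
    return(structure(list(r = r, ci_low = r, ci_high = r, p = 0, n = n,
                          method = method, degenerate = TRUE),
                     class = "cp_cor"))
  }
  se <- sqrt(if (method == "pearson") 1 else 1.06) / sqrt(n - 3)
  z <- atanh(r)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(z + c(-1, 1) * q * se)
  p <- if (method == "pearson") {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(z) / se, lower.tail = FALSE)
  }
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n,
                 method = method, degenerate = FALSE),
            class = "cp_cor")
}

#' Between-class correlations of per-sample class totals
#'
#' Correlates SCCP and MCCP class totals per region and pooled over all
#' samples, the package's analogue of the study's region-wise SCCP-MCCP
#' correlation panel.
#'
#' @param conc `cp_conc` data.frame.
#' @param method passed to [correlation_with_ci()].
#' @return data.frame with columns `region`, `n`, `r`, `ci_low`, `ci_high`,
#'   `p`, `method` (regions with n < 4 are skipped).
#' @export
class_correlations <- function(conc, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tot <- class_totals(conc)
  wide <- merge(
    tot[tot$analyte_class == "SCCP", c("sample_id", "region", "total_ng_g")],
    tot[tot$analyte_class == "MCCP", c("sample_id", "total_ng_g")],
    by = "sample_id", suffixes = c("_sccp", "_mccp")
  )
  scopes <- c("Total", sort(unique(wide$region)))
  rows <- lapply(scopes, function(rg) {
    d <- if (rg == "Total") wide else wide[wide$region == rg, , drop = FALSE]
    if (nrow(d) < 4L) return(NULL)
    ct <- correlation_with_ci(d$total_ng_g_sccp, d$total_ng_g_mccp, method)
    data.frame(region = rg, n = ct$n, r = ct$r, ci_low = ct$ci_low,
               ci_high = ct$ci_high, p = ct$p, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
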