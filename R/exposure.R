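#' Estimated daily intake (EDI)
#'
#' EDI = C x F / BW: contaminant concentration in the food (ng/g ww) times
#' daily food consumption (g/d), divided by body weight (kg), giving
#' ng/kg bw/d. Vectorized with recycling.
#'
#' @param c concentration, ng/g ww (>= 0).
#' @param f daily consumption, g/d (>= 0).
#' @param bw body weight, kg (> 0).
#' @return EDI in ng/kg bw/d.
#' @export
#' @examples
#' edi(100, 20, 50) # 40
edi <- function(c, f, bw) {
  if (any(bw <= 0)) stop("body weight must be > 0", call. = FALSE)
  if (any(c < 0) || any(f < 0)) {
    stop("concentration and consumption must be >= 0", call. = FALSE)
  }
  c * f / bw
}

#' Point-mass pseudo-fit
#'
#' A degenerate one-point "distribution" usable wherever a fitted
#' distribution is expected; [simulate_exposure()] then reduces to the
#' deterministic [edi()].
#'
#' @param value the constant.
#' @return `cp_fit` object with `family = "point"`.
#' @export
point_mass <- function(value) {
  stopifnot(is.finite(value))
  structure(list(family = "point", estimate = c(value = value),
                 logLik = NA_real_, aic = NA_real_, n = 1L,
                 candidates = list(), degenerate = TRUE),
            class = "cp_fit")
}

.fit_one <- function(x, family) {
  n <- length(x)
  if (family == "lognormal") {
    lx <- log(x)
    meanlog <- mean(lx)
    sdlog <- sqrt(mean((lx - meanlog)^2))  # MLE (divides by n)
    ll <- sum(stats::dlnorm(x, meanlog, sdlog, log = TRUE))
    list(estimate = c(meanlog = meanlog, sdlog = sdlog), logLik = ll)
  } else {
    fd <- suppressWarnings(MASS::fitdistr(x, family))
    list(estimate = fd$estimate, logLik = as.numeric(fd$loglik))
  }
}

#' Maximum-likelihood fit with AIC family selection
#'
#' Fits each candidate positive-support family by maximum likelihood
#' (lognormal in closed form; gamma and Weibull via numerical MLE) and
#' returns the minimum-AIC fit, with all candidates attached. AIC = 2k -
#' 2 logL with k = 2 parameters per family. Zeros must be removed by the
#' caller and modeled as a probability mass (see [cons_model()]); constant
#' data are refused with a degenerate-data error — represent them with
#' [point_mass()] instead.
#'
#' @param values positive numeric vector, n >= 10.
#' @param families candidate families, subset of
#'   `c("lognormal", "gamma", "weibull")`.
#' @return `cp_fit` object: `family`, `estimate`, `logLik`, `aic`, `n`,
#'   `candidates` (named list with `estimate`/`logLik`/`aic` per family).
#' @export
fit_distribution <- function(values,
                             families = c("lognormal", "gamma", "weibull")) {
  families <- match.arg(families, several.ok = TRUE)
  if (length(values) < 10L) stop("need n >= 10 values", call. = FALSE)
  if (any(values <= 0)) {
    stop("values must be positive; model zeros as a probability mass",
         call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("constant data: fitting refused (degenerate); use point_mass()",
         call. = FALSE)
  }
  cand <- list()
  for (fam in families) {
    fit <- tryCatch(.fit_one(values, fam), error = function(e) NULL)
    if (!is.null(fit)) {
      fit$aic <- 2 * 2 - 2 * fit$logLik
      cand[[fam]] <- fit
    }
  }
  if (length(cand) == 0L) stop("all candidate fits failed", call. = FALSE)
  aics <- vapply(cand, `[[`, numeric(1), "aic")
  best <- names(cand)[which.min(aics)]
  structure(list(family = best, estimate = cand[[best]]$estimate,
                 logLik = cand[[best]]$logLik, aic = cand[[best]]$aic,
                 n = length(values), candidates = cand, degenerate = FALSE),
            class = "cp_fit")
}

#' Draw from a fitted distribution
#'
#' @param fit `cp_fit` object.
#' @param n number of draws.
#' @return numeric vector of length n.
#' @export
rfit <- function(fit, n) {
  e <- fit$estimate
  switch(fit$family,
    point = rep(unname(e["value"]), n),
    lognormal = stats::rlnorm(n, e["meanlog"], e["sdlog"]),
    gamma = stats::rgamma(n, shape = e["shape"], rate = e["rate"]),
    weibull = stats::rweibull(n, shape = e["shape"], scale = e["scale"]),
    stop("unknown family: ", fit$family, call. = FALSE)
  )
}

#' Zero-inflated consumption model
#'
#' Daily consumption is 0 with probability `1 - consumer_probability` and
#' otherwise drawn from the positive-amount fit.
#'
#' @param consumer_probability per-day probability of consuming.
#' @param amount_fit `cp_fit` for the positive amounts (g/d).
#' @return list of class `cp_cons_model`.
#' @export
cons_model <- function(consumer_probability, amount_fit) {
  stopifnot(consumer_probability >= 0, consumer_probability <= 1,
            inherits(amount_fit, "cp_fit"))
  structure(list(consumer_probability = consumer_probability,
                 amount_fit = amount_fit), class = "cp_cons_model")
}

#' Monte Carlo exposure simulation
#'
#' Draws `n_iter` independent (C, F, BW) triples — concentration from
#' `conc_fit`, consumption from the zero-inflated `cons_model`, body weight
#' from `bw_fit` — and summarizes the EDI iterates by their mean, a
#' batch-means 95% CI half-width (B = 20 equal batches:
#' 1.96 x sd(batch means) / sqrt(B)), and the P95 (type-7
#' linear-interpolation empirical quantile). Fully reproducible under `seed`.
#'
#' @param conc_fit `cp_fit` for concentration (ng/g ww).
#' @param cons `cp_cons_model` for daily consumption (g/d).
#' @param bw_fit `cp_fit` for body weight (kg).
#' @param n_iter iterations, >= 1000 (the P95 is unstable below).
#' @param seed integer seed.
#' @param subgroup,analyte_class labels carried into the summary.
#' @param keep_draws keep the per-iterate input/output draws (needed for
#'   [contribution_to_variance()]).
#' @return list of class `cp_exposure_summary`: `subgroup`, `analyte_class`,
#'   `mean`, `ci_half_width`, `p95`, `median`, `n_iterations`, `seed`, and
#'   (if kept) `draws` (data.frame `c`, `f`, `bw`, `edi`).
#' @export
simulate_exposure <- function(conc_fit, cons, bw_fit, n_iter = 10000L,
                              seed = 1L, subgroup = NA_character_,
                              analyte_class = NA_character_,
                              keep_draws = FALSE) {
  stopifnot(inherits(conc_fit, "cp_fit"), inherits(cons, "cp_cons_model"),
            inherits(bw_fit, "cp_fit"))
  if (n_iter < 1000L) {
    stop("n_iter must be >= 1000 (P95 unstable below)", call. = FALSE)
  }
  set.seed(seed)
  cc <- rfit(conc_fit, n_iter)
  consume <- stats::runif(n_iter) < cons$consumer_probability
  amount <- rfit(cons$amount_fit, n_iter)
  ff <- ifelse(consume, amount, 0)
  bw <- rfit(bw_fit, n_iter)
  e <- edi(cc, ff, bw)

  b <- 20L
  nb <- (n_iter %/% b) * b
  bm <- colMeans(matrix(e[seq_len(nb)], ncol = b))
  hw <- stats::qnorm(0.975) * stats::sd(bm) / sqrt(b)

  out <- list(
    subgroup = subgroup, analyte_class = analyte_class,
    mean = mean(e), ci_half_width = hw,
    p95 = stats::quantile(e, 0.95, type = 7, names = FALSE),
    median = stats::median(e),
    n_iterations = as.integer(n_iter), seed = as.integer(seed)
  )
  if (keep_draws) out$draws <- data.frame(c = cc, f = ff, bw = bw, edi = e)
  structure(out, class = "cp_exposure_summary")
}

#' Empirical (per-individual) exposure
#'
#' The non-parametric counterpart of [simulate_exposure()]: each surveyed
#' individual keeps their own (F, BW) pair (F = mean over recall days) and is
#' paired with a concentration either resampled with replacement from the
#' empirical set of per-sample class totals (`pairing = "resample"`) or fixed
#' at their pooled mean (`pairing = "point"`). Summaries are over
#' individuals.
#'
#' @param conc `cp_conc` data.frame.
#' @param survey `cp_survey`, optionally already subgrouped.
#' @param analyte_class `"SCCP"` or `"MCCP"`.
#' @param subgroup optional group label (resolved via [subgroup_members()];
#'   requires [assign_subgroups()] columns unless `"All"`).
#' @param pairing `"resample"` (default) or `"point"`.
#' @param seed seed for the resampling draw.
#' @return `cp_exposure_summary` (with `n_iterations` = number of
#'   individuals).
#' @export
empirical_exposure <- function(conc, survey, analyte_class,
                               subgroup = "All",
                               pairing = c("resample", "point"),
                               seed = 1L) {
  pairing <- match.arg(pairing)
  tot <- class_totals(conc)
  tot <- tot$total_ng_g[tot$analyte_class == analyte_class]
  if (length(tot) == 0L) stop("no samples for ", analyte_class,
                              call. = FALSE)
  keep <- subgroup_members(survey, subgroup)
  s <- survey[keep, , drop = FALSE]
  if (nrow(s) == 0L) stop("empty subgroup: ", subgroup, call. = FALSE)
  cc <- if (pairing == "point") {
    rep(mean(tot), nrow(s))
  } else {
    set.seed(seed)
    # sample.int avoids the sample() length-1 surprise for singleton sets
    tot[sample.int(length(tot), nrow(s), replace = TRUE)]
  }
  e <- edi(cc, s$mean_consumption, s$body_weight)
  structure(list(
    subgroup = subgroup, analyte_class = analyte_class,
    mean = mean(e),
    ci_half_width = stats::qnorm(0.975) * stats::sd(e) / sqrt(length(e)),
    p95 = stats::quantile(e, 0.95, type = 7, names = FALSE),
    median = stats::median(e),
    n_iterations = nrow(s), seed = as.integer(seed)
  ), class = "cp_exposure_summary")
}

#' Rank-regression contribution to variance
#'
#' Approximates the contribution-to-variance sensitivity metric of
#' commercial Monte Carlo tools: output and input iterates are rank
#' transformed, the ranked output is regressed on the ranked inputs by
#' ordinary least squares, and each input's contribution is
#' 100 x (standardized coefficient)^2 / sum((standardized coefficients)^2)
#' x R^2, i.e. the explained-variance share apportioned among inputs.
#' Constant inputs get contribution 0 and are flagged.
#'
#' @param inputs named list or data.frame of equal-length input draw vectors
#'   (e.g. the `draws[c("c", "f", "bw")]` of one [simulate_exposure()] run).
#' @param output output draw vector (e.g. `draws$edi`).
#' @return data.frame with columns `variable`, `contribution` (percent),
#'   `constant` (flag); attribute `r_squared`.
#' @export
contribution_to_variance <- function(inputs, output) {
  inputs <- as.data.frame(inputs)
  stopifnot(nrow(inputs) == length(output))
  is_const <- vapply(inputs, function(v) stats::sd(v) == 0, logical(1))
  out <- data.frame(variable = names(inputs), contribution = 0,
                    constant = is_const, stringsAsFactors = FALSE)
  if (stats::sd(output) == 0 || all(is_const)) {
    attr(out, "r_squared") <- 0
    return(out)
  }
  ry <- rank(output)
  rx <- as.data.frame(lapply(inputs[!is_const], rank))
  fit <- stats::lm(ry ~ ., data = rx)
  # rank regressions on deterministic relations fit exactly; the summary.lm
  # "perfect fit" warning is expected there, not diagnostic
  r2 <- suppressWarnings(summary(fit))$r.squared
  beta <- stats::coef(fit)[-1] *
    vapply(rx, stats::sd, numeric(1)) / stats::sd(ry)
  w <- beta^2 / sum(beta^2)
  out$contribution[!is_const] <- 100 * w * r2
  attr(out, "r_squared") <- r2
  out
}

#' Coerce exposure summaries to a data.frame
#'
#' @param summaries list of `cp_exposure_summary` objects.
#' @return data.frame with one row per summary.
#' @export
exposure_table <- function(summaries) {
  if (inherits(summaries, "cp_exposure_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(subgroup = s$subgroup, analyte_class = s$analyte_class,
               mean = s$mean, ci_half_width = s$ci_half_width, p95 = s$p95,
               median = s$median, n_iterations = s$n_iterations,
               seed = s$seed, stringsAsFactors = FALSE)
  }))
}
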