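#' Homologue composition decomposition
#'
#' Decomposes congener-resolved concentrations into, per scope unit (sample
#' or region) and analyte class: congener-group fractions, carbon-homologue
#' fractions (summed over chlorine), chlorine-homologue fractions (summed
#' over carbon), and the class share of total CPs (SCCP + MCCP). Regional
#' scope aggregates by summing concentrations before normalizing
#' (concentration-weighted, the default) or by averaging per-sample fractions
#' (`aggregation = "mean_of_fractions"`).
#'
#' A scope unit whose class total is zero gets `NA` fractions and is listed
#' in the `zero_total` attribute.
#'
#' @param conc `cp_conc` data.frame.
#' @param scope `"per_sample"` or `"per_region"`.
#' @param aggregation regional aggregation mode (ignored for `per_sample`).
#' @return list of class `cp_profiles` with data.frames `group_fractions`
#'   (`unit`, `analyte_class`, `carbon`, `chlorine`, `group`, `fraction`),
#'   `carbon_fractions`, `chlorine_fractions`, `class_shares` (`unit`,
#'   `analyte_class`, `share`), and the `scope`/`aggregation` used.
#' @export
decompose_profiles <- function(conc,
                               scope = c("per_sample", "per_region"),
                               aggregation = c("concentration_weighted",
                                               "mean_of_fractions")) {
  scope <- match.arg(scope)
  aggregation <- match.arg(aggregation)
  if (nrow(conc) == 0L) stop("no concentration records", call. = FALSE)
  d <- as.data.frame(conc)
  d$unit <- if (scope == "per_sample") d$sample_id else d$region

  if (scope == "per_region" && aggregation == "mean_of_fractions") {
    per_sample <- decompose_profiles(conc, "per_sample")
    gf <- per_sample$group_fractions
    gf$unit <- d$region[match(gf$unit, d$sample_id)]
    grp <- stats::aggregate(
      fraction ~ unit + analyte_class + carbon + chlorine + group,
      data = gf, FUN = mean, na.rm = TRUE, na.action = stats::na.pass
    )
  } else {
    grp <- stats::aggregate(
      conc_ng_g ~ unit + analyte_class + carbon + chlorine + group,
      data = d, FUN = sum
    )
    cls_tot <- stats::aggregate(conc_ng_g ~ unit + analyte_class,
                                data = grp, FUN = sum)
    names(cls_tot)[3] <- "class_total"
    grp <- merge(grp, cls_tot, by = c("unit", "analyte_class"))
    grp$fraction <- ifelse(grp$class_total > 0,
                           grp$conc_ng_g / grp$class_total, NA_real_)
    grp$conc_ng_g <- NULL
    grp$class_total <- NULL
  }
  grp <- grp[order(grp$unit, grp$analyte_class, grp$carbon, grp$chlorine), ]
  rownames(grp) <- NULL

  margin <- function(axis) {
    m <- stats::aggregate(
      stats::as.formula(paste("fraction ~ unit + analyte_class +", axis)),
      data = grp, FUN = sum, na.action = stats::na.pass
    )
    m[order(m$unit, m$analyte_class, m[[axis]]), , drop = FALSE]
  }

  tot <- stats::aggregate(conc_ng_g ~ unit + analyte_class, data = d,
                          FUN = sum)
  all_tot <- stats::aggregate(conc_ng_g ~ unit, data = tot, FUN = sum)
  names(all_tot)[2] <- "cp_total"
  shares <- merge(tot, all_tot, by = "unit")
  shares$share <- ifelse(shares$cp_total > 0,
                         shares$conc_ng_g / shares$cp_total, NA_real_)
  shares <- shares[order(shares$unit, shares$analyte_class),
                   c("unit", "analyte_class", "share")]
  rownames(shares) <- NULL

  zero <- unique(grp$unit[is.na(grp$fraction)])
  structure(list(
    group_fractions = grp,
    carbon_fractions = margin("carbon"),
    chlorine_fractions = margin("chlorine"),
    class_shares = shares,
    scope = scope, aggregation = aggregation,
    zero_total = zero
  ), class = "cp_profiles")
}

#' Top-k congener groups of one decomposition unit
#'
#' Ranks congener groups by concentration share, ties broken by (carbon,
#' chlorine) ascending. If `k` exceeds the number of groups, all are returned
#' and the result is flagged. The `tie_flag` attribute is set when the cut
#' falls inside a run of tied shares.
#'
#' @param profiles `cp_profiles` object from [decompose_profiles()].
#' @param k number of groups to return.
#' @param unit scope unit label (defaults to the only unit present).
#' @param analyte_class `"SCCP"` or `"MCCP"`.
#' @return data.frame of the top-k rows of `group_fractions`, with attributes
#'   `tie_flag` and `truncated_k`.
#' @export
dominant_groups <- function(profiles, k, unit = NULL,
                            analyte_class = c("SCCP", "MCCP")) {
  analyte_class <- match.arg(analyte_class)
  gf <- profiles$group_fractions
  gf <- gf[gf$analyte_class == analyte_class, , drop = FALSE]
  if (is.null(unit)) {
    if (length(unique(gf$unit)) != 1L) {
      stop("multiple scope units present; pass `unit`", call. = FALSE)
    }
  } else {
    gf <- gf[gf$unit == unit, , drop = FALSE]
    if (nrow(gf) == 0L) stop("unknown unit: ", unit, call. = FALSE)
  }
  truncated <- k > nrow(gf)
  if (truncated) k <- nrow(gf)
  o <- order(-gf$fraction, gf$carbon, gf$chlorine)
  gf <- gf[o, , drop = FALSE]
  tie <- k < nrow(gf) && isTRUE(gf$fraction[k] == gf$fraction[k + 1L])
  out <- gf[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tie_flag") <- tie
  attr(out, "truncated_k") <- truncated
  out
}

#' Long-format export of a profile decomposition
#'
#' One row per (unit, class, axis, key): axis is `carbon`, `chlorine` or
#' `class_share`; suitable for stacked-bar plotting.
#'
#' @param profiles `cp_profiles` object.
#' @return tidy data.frame with columns `unit`, `analyte_class`, `axis`,
#'   `key`, `fraction`.
#' @export
profiles_long <- function(profiles) {
  cf <- profiles$carbon_fractions
  hf <- profiles$chlorine_fractions
  cs <- profiles$class_shares
  rbind(
    data.frame(unit = cf$unit, analyte_class = cf$analyte_class,
               axis = "carbon", key = paste0("C", cf$carbon),
               fraction = cf$fraction, stringsAsFactors = FALSE),
    data.frame(unit = hf$unit, analyte_class = hf$analyte_class,
               axis = "chlorine", key = paste0("Cl", hf$chlorine),
               fraction = hf$fraction, stringsAsFactors = FALSE),
    data.frame(unit = cs$unit, analyte_class = cs$analyte_class,
               axis = "class_share", key = cs$analyte_class,
               fraction = cs$share, stringsAsFactors = FALSE)
  )
}
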