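#' Margin of exposure (MOE)
#'
#' MOE = POD / exposure with the point of departure (BMDL10, mg/kg bw/d)
#' converted to ng/kg bw/d (x 10^6) so both terms share units. MOE > 1000 is
#' interpreted as no significant health concern; the classification uses the
#' unrounded ratio while `moe_reported` is rounded half away from zero to the
#' nearest integer, matching how such values are conventionally printed.
#'
#' @param pod point of departure, mg/kg bw/d (> 0).
#' @param exposure exposure estimate, ng/kg bw/d (>= 0; 0 gives an
#'   infinite-MOE flag).
#' @param basis `"mean"` (MOE^a, general population) or `"p95"` (MOE^b, high
#'   consumers).
#' @param label subgroup/region label carried through.
#' @param analyte_class analyte class label carried through.
#' @return one-row data.frame of class `cp_moe`: `label`, `analyte_class`,
#'   `basis`, `exposure`, `pod_mg_kg_d`, `moe` (unrounded), `moe_reported`
#'   (integer), `risk_flag` (TRUE = no significant concern), `infinite`.
#' @export
#' @examples
#' moe(2.3, 89.0)$moe_reported # 25843
moe <- function(pod, exposure, basis = c("mean", "p95"),
                label = NA_character_, analyte_class = NA_character_) {
  basis <- match.arg(basis)
  if (pod <= 0) stop("POD must be > 0", call. = FALSE)
  if (exposure < 0) stop("exposure must be >= 0", call. = FALSE)
  pod_ng <- pod * 1e6
  inf <- exposure == 0
  m <- if (inf) Inf else pod_ng / exposure
  out <- data.frame(
    label = label, analyte_class = analyte_class, basis = basis,
    exposure = exposure, pod_mg_kg_d = pod,
    moe = m,
    moe_reported = if (inf) Inf else .round_half_away(m),
    risk_flag = m > 1000,
    infinite = inf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cp_moe", "data.frame")
  out
}

# round half away from zero (base round() is round-half-even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' MOE table from exposure summaries
#'
#' Two MOE rows per summary: basis `"mean"` (MOE^a) and basis `"p95"`
#' (MOE^b), with the class BMDL10 as POD.
#'
#' @param summaries list of `cp_exposure_summary` objects, or a data.frame
#'   with columns `subgroup` (or `label`), `analyte_class`, `mean`, `p95`.
#' @param constants output of [cp_constants()].
#' @return `cp_moe` data.frame (possibly empty).
#' @export
moe_table <- function(summaries, constants = cp_constants()) {
  df <- if (is.data.frame(summaries)) {
    s <- summaries
    if (is.null(s$label) && !is.null(s$subgroup)) s$label <- s$subgroup
    s
  } else {
    exposure_table(summaries)
  }
  if (is.null(df) || nrow(df) == 0L) {
    out <- moe(1, 1)[0, ]
    class(out) <- c("cp_moe", "data.frame")
    return(out)
  }
  if (is.null(df$label)) df$label <- df$subgroup
  rows <- lapply(seq_len(nrow(df)), function(i) {
    pod <- .const_lookup(constants, df$analyte_class[i], "bmdl10")
    rbind(
      moe(pod, df$mean[i], "mean", df$label[i], df$analyte_class[i]),
      moe(pod, df$p95[i], "p95", df$label[i], df$analyte_class[i])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cp_moe", "data.frame")
  out
}
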