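#' Congener-group bookkeeping for chlorinated paraffins
#'
#' Chlorinated paraffins (CPs) are quantified as congener groups: the set of
#' polychlorinated n-alkanes sharing one carbon chain length and one chlorine
#' substitution count (e.g. C10Cl6). Short-chain CPs (SCCPs) span C10-C13,
#' medium-chain CPs (MCCPs) span C14-C17; with chlorination degrees Cl5-Cl10
#' each class comprises exactly 24 groups.
#'
#' @name congener
NULL

.cp_carbon <- list(SCCP = 10:13, MCCP = 14:17)
.cp_chlorine <- 5:10

#' Analyte class for a carbon chain length
#'
#' @param carbon integer vector of carbon chain lengths.
#' @return character vector, `"SCCP"` for C10-C13 and `"MCCP"` for C14-C17.
#'   Any value outside 10-17 (or non-integral) is a domain error.
#' @export
#' @examples
#' analyte_class_for_carbon(c(10, 14))
analyte_class_for_carbon <- function(carbon) {
  if (length(carbon) == 0L) return(character(0))
  if (any(!is.finite(carbon)) || any(carbon != round(carbon))) {
    stop("carbon chain length must be an integer", call. = FALSE)
  }
  bad <- carbon < 10 | carbon > 17
  if (any(bad)) {
    stop(sprintf(
      "carbon chain length outside CP classes (C10-C17): %s",
      paste(unique(carbon[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  ifelse(carbon <= 13, "SCCP", "MCCP")
}

#' Enumerate the congener groups of one or both analyte classes
#'
#' @param analyte_class `"SCCP"`, `"MCCP"`, or both (default).
#' @return data.frame with columns `analyte_class`, `carbon`, `chlorine`,
#'   `group` (label such as `"C10Cl6"`), 24 rows per class, ordered by
#'   (carbon, chlorine).
#' @export
#' @examples
#' nrow(cp_congener_groups("SCCP")) # 24
cp_congener_groups <- function(analyte_class = c("SCCP", "MCCP")) {
  analyte_class <- match.arg(analyte_class, several.ok = TRUE)
  out <- do.call(rbind, lapply(analyte_class, function(cl) {
    g <- expand.grid(chlorine = .cp_chlorine, carbon = .cp_carbon[[cl]],
                     KEEP.OUT.ATTRS = FALSE)
    data.frame(
      analyte_class = cl,
      carbon = g$carbon,
      chlorine = g$chlorine,
      group = sprintf("C%dCl%d", g$carbon, g$chlorine),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$carbon, out$chlorine), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Toxicological and analytical constants per analyte class
#'
#' BMDL10 is the lower confidence bound of the benchmark dose for a 10%
#' response, used as the point of departure (POD) in MOE calculations
#' (EFSA-recommended values). MDL is the analytical method detection limit on
#' a wet-weight basis; concentrations below it are treated as left-censored.
#'
#' @param bmdl10 named numeric, mg/kg bw/d per class.
#' @param mdl named numeric, ng/g ww per class.
#' @return data.frame with columns `analyte_class`, `bmdl10`, `mdl`.
#' @export
#' @examples
#' cp_constants()
cp_constants <- function(bmdl10 = c(SCCP = 2.3, MCCP = 36),
                         mdl = c(SCCP = 3.0, MCCP = 5.0)) {
  stopifnot(all(bmdl10 > 0), all(mdl > 0),
            all(c("SCCP", "MCCP") %in% names(bmdl10)),
            all(c("SCCP", "MCCP") %in% names(mdl)))
  data.frame(
    analyte_class = c("SCCP", "MCCP"),
    bmdl10 = unname(bmdl10[c("SCCP", "MCCP")]),
    mdl = unname(mdl[c("SCCP", "MCCP")]),
    stringsAsFactors = FALSE
  )
}

# constant named lookup used internally
.const_lookup <- function(constants, analyte_class, field) {
  i <- match(analyte_class, constants$analyte_class)
  if (anyNA(i)) stop("unknown analyte class", call. = FALSE)
  constants[[field]][i]
}
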