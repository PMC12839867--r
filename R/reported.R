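#' Published summary tables of the national chicken-meat CP survey
#'
#' Small plain-text copies of the printed aggregate statistics that anchor
#' the package's defaults and reproduction tests: the regional occurrence
#' summary (per-region sample counts, class-total means and ranges, ng/g ww)
#' and the exposure statistics (mean and P95 EDI, ng/kg bw/d) for the sex-age
#' subgroups and for the eight regions. These are printed aggregates, not raw
#' data (none were deposited with the study).
#'
#' @param which one of `"occurrence"`, `"exposure_sexage"`,
#'   `"exposure_region"`.
#' @return data.frame.
#' @export
#' @examples
#' head(reported_table("occurrence"))
reported_table <- function(which = c("occurrence", "exposure_sexage",
                                     "exposure_region")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("reported_", which, ".csv"),
                   package = "cpexposure", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Super-region membership of the eight study regions
#'
#' @return data.frame with columns `region`, `super_region` (East, North,
#'   Northeast China).
#' @export
region_groups <- function() {
  data.frame(
    region = c("Shandong", "Jiangxi", "Jiangsu",
               "Hebei", "Tianjin", "Beijing",
               "Jilin", "Heilongjiang"),
    super_region = rep(c("East China", "North China", "Northeast China"),
                       times = c(3, 3, 2)),
    stringsAsFactors = FALSE
  )
}
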