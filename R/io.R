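#' Read a long-format congener-resolved concentration table
#'
#' Expected CSV header: `sample_id,region,carbon,chlorine,conc_ng_g`.
#' Concentrations are ng/g wet weight; the token `<MDL` marks a left-censored
#' measurement and is substituted according to `mdl_policy`:
#' `lower` -> 0, `middle` -> MDL/2, `upper` -> MDL, with the class-specific
#' MDL taken from `constants`. Substituted cells are flagged in the
#' `censored` column.
#'
#' @param path CSV file path.
#' @param mdl_policy censoring substitution policy; default `"middle"`
#'   (MDL/2), the common dietary-exposure convention.
#' @param constants output of [cp_constants()].
#' @return data.frame of class `cp_conc` with columns `sample_id`, `region`,
#'   `analyte_class`, `carbon`, `chlorine`, `group`, `conc_ng_g`, `censored`;
#'   attribute `mdl_policy` records the policy used.
#' @export
read_concentrations <- function(path,
                                mdl_policy = c("middle", "lower", "upper"),
                                constants = cp_constants()) {
  mdl_policy <- match.arg(mdl_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, check.names = TRUE)
  need <- c("sample_id", "region", "carbon", "chlorine", "conc_ng_g")
  if (!all(need %in% names(raw))) {
    stop("concentration CSV must have header: ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty concentration table: ", path, call. = FALSE)
    return(.as_cp_conc(raw[, need], mdl_policy))
  }
  line <- seq_len(nrow(raw)) + 1L  # header is file line 1

  num_or_fail <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !(is.na(x) | x == "")
    if (any(bad)) {
      stop(sprintf("parse error in %s, line %d: cannot read %s '%s'",
                   path, line[which(bad)[1]], what, x[which(bad)[1]]),
           call. = FALSE)
    }
    v
  }
  carbon <- num_or_fail(raw$carbon, "carbon")
  chlorine <- num_or_fail(raw$chlorine, "chlorine")
  if (anyNA(carbon) || anyNA(chlorine)) {
    stop(sprintf("parse error in %s, line %d: missing carbon/chlorine",
                 path, line[which(is.na(carbon) | is.na(chlorine))[1]]),
         call. = FALSE)
  }
  analyte_class <- analyte_class_for_carbon(carbon)
  if (any(!chlorine %in% .cp_chlorine)) {
    stop(sprintf("chlorine substitution count outside Cl5-Cl10, line %d",
                 line[which(!chlorine %in% .cp_chlorine)[1]]), call. = FALSE)
  }
  if (any(raw$region == "" | is.na(raw$region))) {
    stop(sprintf("empty region, line %d",
                 line[which(raw$region == "" | is.na(raw$region))[1]]),
         call. = FALSE)
  }

  censored <- raw$conc_ng_g == "<MDL"
  conc <- rep(NA_real_, nrow(raw))
  conc[!censored] <- num_or_fail(raw$conc_ng_g[!censored], "concentration")
  if (anyNA(conc[!censored])) {
    stop(sprintf("parse error in %s, line %d: missing concentration",
                 path, line[!censored][which(is.na(conc[!censored]))[1]]),
         call. = FALSE)
  }
  if (any(conc[!censored] < 0)) {
    stop(sprintf("negative concentration, line %d",
                 line[!censored][which(conc[!censored] < 0)[1]]),
         call. = FALSE)
  }
  mdl <- .const_lookup(constants, analyte_class, "mdl")
  conc[censored] <- switch(mdl_policy,
    lower = 0,
    middle = mdl[censored] / 2,
    upper = mdl[censored]
  )

  out <- data.frame(
    sample_id = raw$sample_id,
    region = raw$region,
    analyte_class = analyte_class,
    carbon = as.integer(carbon),
    chlorine = as.integer(chlorine),
    group = sprintf("C%dCl%d", carbon, chlorine),
    conc_ng_g = conc,
    censored = censored,
    stringsAsFactors = FALSE
  )
  .as_cp_conc(out, mdl_policy)
}

.as_cp_conc <- function(df, mdl_policy = "middle") {
  class(df) <- c("cp_conc", "data.frame")
  attr(df, "mdl_policy") <- mdl_policy
  df
}

#' Write a concentration table in the package's exchange CSV dialect
#'
#' Numeric values are serialized at full (17 significant digit) precision so
#' that a write/read round trip is bit-identical; censored cells are written
#' back as the `<MDL` token.
#'
#' @param x `cp_conc` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(x, path) {
  conc <- .fmt_full(x$conc_ng_g)
  if (!is.null(x$censored)) conc[x$censored] <- "<MDL"
  out <- data.frame(
    sample_id = x$sample_id, region = x$region,
    carbon = x$carbon, chlorine = x$chlorine,
    conc_ng_g = conc, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt_full <- function(v) {
  vapply(v, function(x) {
    if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Read an individual-level consumption survey
#'
#' Expected CSV header: `person_id,sex,age,body_weight,day1,day2,day3`
#' (recall-day columns may be blank; at least one of up to three 24-h recall
#' days must be present). Individuals with missing body weight are excluded
#' and counted, mirroring the exclusion step of the national survey the
#' format emulates; so are individuals with no recall day at all.
#'
#' @param path CSV file path.
#' @return data.frame of class `cp_survey` with columns `person_id`, `sex`,
#'   `age`, `body_weight`, `day1..day3` (NA where absent), `n_days`,
#'   `mean_consumption` (arithmetic mean over present recall days, g/d).
#'   Attributes `n_excluded_bw` and `n_excluded_norecall` count exclusions.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("person_id", "sex", "age", "body_weight")
  if (nrow(raw) == 0L) {
    warning("empty survey table: ", path, call. = FALSE)
    empty <- data.frame(person_id = character(0), sex = character(0),
                        age = numeric(0), body_weight = numeric(0),
                        day1 = numeric(0), day2 = numeric(0),
                        day3 = numeric(0), n_days = integer(0),
                        mean_consumption = numeric(0))
    return(.as_cp_survey(empty, 0L, 0L))
  }
  if (!all(need %in% names(raw))) {
    stop("survey CSV must have header starting: ",
         paste(need, collapse = ","), call. = FALSE)
  }
  day_cols <- intersect(c("day1", "day2", "day3"), names(raw))
  if (length(day_cols) == 0L) stop("survey CSV has no recall-day columns",
                                   call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))

  sex <- tolower(raw$sex)
  if (any(!sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female', row ",
         which(!sex %in% c("male", "female"))[1], call. = FALSE)
  }
  age <- num(raw$age)
  if (any(is.na(age) | age < 0)) stop("age must be >= 0", call. = FALSE)
  bw <- num(raw$body_weight)
  excl_bw <- is.na(bw)
  if (any(bw[!excl_bw] <= 0)) stop("body weight must be > 0", call. = FALSE)

  days <- sapply(c("day1", "day2", "day3"), function(cn) {
    if (cn %in% day_cols) num(raw[[cn]]) else rep(NA_real_, nrow(raw))
  })
  days <- matrix(days, nrow = nrow(raw),
                 dimnames = list(NULL, c("day1", "day2", "day3")))
  if (any(days < 0, na.rm = TRUE)) stop("consumption must be >= 0",
                                        call. = FALSE)
  n_days <- rowSums(!is.na(days))
  excl_nd <- n_days == 0L

  keep <- !excl_bw & !excl_nd
  n_excl_bw <- sum(excl_bw)
  n_excl_nd <- sum(excl_nd & !excl_bw)
  if (n_excl_bw > 0L) {
    message(n_excl_bw, " individual(s) excluded due to missing body weight")
  }
  if (n_excl_nd > 0L) {
    message(n_excl_nd, " individual(s) excluded with no recall day")
  }
  out <- data.frame(
    person_id = raw$person_id[keep], sex = sex[keep], age = age[keep],
    body_weight = bw[keep],
    day1 = days[keep, 1], day2 = days[keep, 2], day3 = days[keep, 3],
    n_days = as.integer(n_days[keep]),
    mean_consumption = rowMeans(days[keep, , drop = FALSE], na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  .as_cp_survey(out, n_excl_bw, n_excl_nd)
}

.as_cp_survey <- function(df, n_excluded_bw = 0L, n_excluded_norecall = 0L) {
  class(df) <- c("cp_survey", "data.frame")
  attr(df, "n_excluded_bw") <- n_excluded_bw
  attr(df, "n_excluded_norecall") <- n_excluded_norecall
  df
}

#' Write a survey table in the package's exchange CSV dialect
#'
#' @param x `cp_survey` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path) {
  fmt <- function(v) {
    s <- .fmt_full(v)
    s[is.na(v)] <- ""
    s
  }
  out <- data.frame(
    person_id = x$person_id, sex = x$sex, age = fmt(x$age),
    body_weight = fmt(x$body_weight),
    day1 = fmt(x$day1), day2 = fmt(x$day2), day3 = fmt(x$day3),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' @param seed master seed for all stochastic stages.
#' @param n_iterations Monte Carlo iterations per subgroup/class.
#' @param mdl_policy below-MDL substitution policy.
#' @param consumer_rule `"every_day"` (consumed on every recall day; the
#'   study's reading of "consumed chicken daily") or `"any_day"`.
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @param profile_aggregation `"concentration_weighted"` (sum then normalize)
#'   or `"mean_of_fractions"` for regional profiles.
#' @param families candidate parametric families for distribution fitting.
#' @param simulate logical; generate synthetic inputs rather than reading.
#' @param concentrations_csv,survey_csv input paths when `simulate = FALSE`.
#' @param survey_scale multiplier applied to the synthetic survey subgroup
#'   sizes (1 = the full 55,678-respondent default world).
#' @return named list of class `cp_config`.
#' @export
default_run_config <- function(seed = 20260101L,
                               n_iterations = 10000L,
                               mdl_policy = "middle",
                               consumer_rule = "every_day",
                               correlation_method = "spearman",
                               profile_aggregation = "concentration_weighted",
                               families = c("lognormal", "gamma", "weibull"),
                               simulate = TRUE,
                               concentrations_csv = NULL,
                               survey_csv = NULL,
                               survey_scale = 1) {
  cfg <- list(
    seed = as.integer(seed), n_iterations = as.integer(n_iterations),
    mdl_policy = mdl_policy, consumer_rule = consumer_rule,
    correlation_method = correlation_method,
    profile_aggregation = profile_aggregation,
    families = families, simulate = simulate,
    concentrations_csv = concentrations_csv, survey_csv = survey_csv,
    survey_scale = survey_scale,
    constants = cp_constants()
  )
  class(cfg) <- "cp_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' Keys absent from the file fall back to [default_run_config()] values.
#'
#' @param path JSON file path.
#' @return `cp_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (k in names(j)) {
    if (k == "constants") {
      cfg$constants <- cp_constants(
        bmdl10 = unlist(j$constants$bmdl10),
        mdl = unlist(j$constants$mdl)
      )
    } else cfg[[k]] <- j[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_iterations <- as.integer(cfg$n_iterations)
  cfg
}
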