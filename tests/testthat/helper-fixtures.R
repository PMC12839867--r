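# Shared in-code fixtures; everything is generated, nothing is stored.

write_tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# a tiny two-region, two-sample concentration table covering both classes
toy_conc_lines <- function() {
  c(
    "sample_id,region,carbon,chlorine,conc_ng_g",
    "s1,Jilin,10,6,30.5",
    "s1,Jilin,11,7,70.0",
    "s1,Jilin,14,6,60.0",
    "s2,Hebei,10,6,40.0",
    "s2,Hebei,14,5,<MDL",
    "s2,Hebei,15,8,10.0"
  )
}

toy_conc <- function(mdl_policy = "middle") {
  read_concentrations(write_tmp_csv(toy_conc_lines()), mdl_policy)
}

toy_survey_lines <- function() {
  c(
    "person_id,sex,age,body_weight,day1,day2,day3",
    "p1,male,35,70,0,50,10",
    "p2,female,8,,30,30,30",
    "p3,female,60,55,20,30,40",
    "p4,male,5,18,25,25,25",
    "p5,female,16,48,,,15"
  )
}

toy_survey <- function() {
  suppressMessages(read_survey(write_tmp_csv(toy_survey_lines())))
}

# single-region spec whose generating log-sd is exactly `sdlog` (the range
# is the central-99% interval) and whose draws are untruncated, so lognormal
# parameter recovery is unconfounded
untruncated_spec <- function(n = 100, mean = 100, sdlog = 0.5,
                             dispersion = 200) {
  meanlog <- log(mean) - sdlog^2 / 2
  range <- exp(meanlog + c(-1, 1) * qnorm(0.995) * sdlog)
  region_conc_spec("Wideland", n, list(
    SCCP = list(mean = mean, range = range,
                profile = default_congener_profile("SCCP")),
    MCCP = list(mean = mean, range = range,
                profile = default_congener_profile("MCCP"))
  ), profile_dispersion = dispersion, truncate = FALSE)
}
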