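# Shared fixtures: the package's reference parameter set for a heavily
# contaminated small catchment, and small record builders.

ref_trend <- function() trend_params(9357, 2500, 0.254, 0.002)
ref_cq <- function() cq_params(0.28, 1.37, 2117)

# records at given dates with concentrations generated from the closed form
model_records <- function(dates, Q, cq = ref_cq(), trend = ref_trend()) {
  t <- days_since_accident(dates)
  sr_records(dates, Q, concentration_closed_form(Q, t, cq, trend))
}

# write a CSV fixture and return its path
write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
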