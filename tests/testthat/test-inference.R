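test_that("candidate sets encode the five a priori climate hypotheses", {
  for (scope in c("within", "multispecies")) {
    mca <- build_mca_set(scope)
    hyg <- build_hygric_set(scope)
    expect_length(mca, 5)
    expect_length(hyg, 5)
    expect_setequal(vapply(mca, `[[`, character(1), "name"),
                    c("T_min", "P_dry", "VPD", "T_min+P_dry", "Altitude"))
    for (s in c(mca, hyg)) {
      expect_true("log10_mass" %in% s$fixed)       # mass in every model
      expect_identical(s$random, c("block", "channel"))
      # environmental variables modelled separately (collinearity), except
      # the temperature + precipitation model
      expect_false(all(c("vpd_kpa", "tmin_c") %in% s$fixed))
      expect_false(all(c("altitude_m", "tmin_c") %in% s$fixed))
    }
    for (s in hyg) expect_true("log10_mr" %in% s$fixed)
    expect_true(any(vapply(hyg, function(s)
      identical(unname(s$fixed[length(s$fixed)]), "altitude_m"),
      logical(1))))  # the altitude null is present
  }
  for (s in build_mca_set("multispecies")) {
    expect_true(all(c("species", "log10_mass:species") %in% s$fixed))
  }
  for (s in build_hygric_set("multispecies")) {
    expect_true("log10_mr:species" %in% s$fixed)
  }
})

test_that("with degenerate random effects the LMM reduces to least squares", {
  st <- simulate_trait_table(quick_trait_params(sd_block = 0,
                                                sd_channel = 0, seed = 51))
  hf <- st$traits[st$traits$species == "H_fijiensis", ]
  ols <- lm(log10_mr ~ log10_mass + tmin_c + pdry_mm, data = hf)
  spec <- build_mca_set("within")[[4]]
  # single-level grouping factors degrade the model to plain least squares
  hf1 <- hf
  hf1$block <- "B01"; hf1$channel <- "C1"
  fs1 <- suppressWarnings(fit_lmm(spec, hf1))
  expect_equal(fs1$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-9)
  # data generated without block/channel variance: the mixed fit agrees
  # with least squares up to the tiny variance components it estimates
  fs <- suppressWarnings(fit_lmm(spec, hf))
  expect_true(all(fs$varcomp[c("block", "channel")] < 0.1 * fs$varcomp["resid"]))
  expect_equal(fs$coefficients$estimate, unname(coef(ols)),
               tolerance = 0.02)
  expect_true(fs$converged)
  # AIC identity holds by construction
  expect_equal(fs$aic, -2 * fs$loglik + 2 * fs$n_params)
})

test_that("fit summaries carry the structure the comparison needs", {
  st <- simulate_trait_table(quick_trait_params(seed = 52))
  fs <- suppressWarnings(fit_lmm(build_mca_set("multispecies")[[1]],
                                 st$traits))
  expect_s3_class(fs, "fit_summary")
  expect_true(all(c("tmin_c", "log10_mass") %in% fs$coefficients$term))
  expect_true(all(fs$varcomp >= 0))
  expect_true(all(c("block", "channel", "resid") %in% names(fs$varcomp)))
  expect_gt(fs$marginal_r2, 0)
  expect_lt(fs$marginal_r2, 1)
  # containment-style df: n minus group levels minus fixed coefficients
  expect_equal(unique(fs$coefficients$df),
               fs$n - length(unique(st$traits$block)) -
                 length(unique(st$traits$channel)) -
                 nrow(fs$coefficients))
  expect_error(fit_lmm(build_mca_set("within")[[1]],
                       st$traits[, setdiff(names(st$traits), "tmin_c")]),
               "tmin_c")
})

test_that("rank-deficient fixed effects are an error naming the aliased term", {
  st <- simulate_trait_table(quick_trait_params(seed = 53))
  dat <- st$traits
  dat$tmin_dup <- dat$tmin_c
  spec <- model_spec("dup", "log10_mr", c("tmin_c", "tmin_dup"), "within")
  expect_error(suppressWarnings(fit_lmm(spec, dat)), "tmin_dup")
})

test_that("marginal R2 follows the variance-partition formula", {
  fake <- list(var_fixed = 1,
               varcomp = c(block = 0.5, channel = 0.5, resid = 2))
  expect_equal(marginal_r2(fake), 0.25)
  # noiseless data: fixed effects explain everything
  st0 <- simulate_trait_table(quick_trait_params(
    sd_block = 0, sd_channel = 0, sd_resid = 0, seed = 54))
  fs0 <- suppressWarnings(fit_lmm(build_mca_set("within")[[4]],
                                  st0$traits[st0$traits$species ==
                                               "H_fijiensis", ]))
  expect_equal(fs0$marginal_r2, 1, tolerance = 1e-6)
  expect_error(marginal_r2(list(var_fixed = 0, varcomp = c(resid = 0))),
               "variance")
})

test_that("Akaike weights are the normalised relative likelihoods", {
  expect_identical(akaike_weights(3.2), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102, 110))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[1] / w[2], exp(1))
  expect_warning(w2 <- akaike_weights(c(5, NA, 7)), "excluded")
  expect_true(is.na(w2[2]) && sum(w2, na.rm = TRUE) == 1)
  # invariant to a constant shift of all AICs
  expect_equal(akaike_weights(c(100, 102, 110) - 250),
               akaike_weights(c(100, 102, 110)))
})

test_that("model comparison tables are sorted, normalised and complete", {
  st <- simulate_trait_table(quick_trait_params(seed = 55))
  cmp <- suppressWarnings(compare_models(build_mca_set("multispecies"),
                                         st$traits))
  expect_s3_class(cmp, "comparison_table")
  expect_identical(nrow(cmp), 5L)
  expect_identical(cmp$delta_aic[1], 0)
  expect_true(!is.unsorted(cmp$aic))
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-9)
  expect_true(all(cmp$weight > 0 & cmp$weight <= 1))
  expect_identical(attr(cmp, "n_used"), nrow(st$traits))
})

test_that("rows with missing values are dropped once for the whole set", {
  st <- simulate_trait_table(quick_trait_params(seed = 56))
  dat <- st$traits
  dat$vpd_kpa[1:4] <- NA   # only the VPD model references this column
  cmp <- suppressWarnings(compare_models(build_mca_set("multispecies"), dat))
  expect_identical(attr(cmp, "n_used"), nrow(dat) - 4L)
  fits <- attr(cmp, "fits")
  expect_identical(unique(vapply(fits, `[[`, numeric(1), "n")),
                   as.numeric(nrow(dat) - 4L))
})

test_that("the generating temperature+precipitation model wins the comparison", {
  wins <- 0L
  for (r in 1:15) {
    st <- simulate_trait_table(trait_sim_params(seed = 600 + r))
    cmp <- suppressWarnings(compare_models(build_mca_set("multispecies"),
                                           st$traits))
    wins <- wins + (cmp$model[1] == "T_min+P_dry")
  }
  expect_gte(wins, 12L)
})

test_that("variance inflation factors match their closed forms", {
  n <- 40
  x1 <- as.numeric(scale(sin(1:n)))
  z <- as.numeric(scale(resid(lm(cos(3 * (1:n)) ~ x1))))
  d <- data.frame(a = x1, b = z, ab = 0.5 * x1 + sqrt(0.75) * z)
  # orthogonal predictors: VIF exactly 1
  expect_equal(unname(compute_vif(d, c("a", "b"))), c(1, 1),
               tolerance = 1e-10)
  # two predictors with correlation 0.5: VIF = 1 / (1 - 0.25)
  expect_equal(unname(compute_vif(d, c("a", "ab"))),
               c(4 / 3, 4 / 3), tolerance = 1e-10)
  # duplicated predictor: infinite
  d$a2 <- d$a
  expect_true(all(is.infinite(
    suppressWarnings(compute_vif(d, c("a", "a2"))))))
  # for two predictors, VIF reduces to 1 / (1 - r^2) exactly
  st <- simulate_trait_table(trait_sim_params(seed = 57))
  vifs <- compute_vif(st$traits, c("tmin_c", "pdry_mm"))
  r2 <- cor(st$traits$tmin_c, st$traits$pdry_mm)^2
  expect_equal(unname(vifs), rep(1 / (1 - r2), 2), tolerance = 1e-10)
})
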