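#' Per-species climate summaries
#'
#' Unweighted means over individual bees (each bee contributes its
#' collection site's climate, so sites weight by how many bees were
#' collected there), plus the altitude range spanned.
#'
#' @param data Trait table with climate columns joined (`altitude_m`,
#'   `tmin_c`, `pdry_mm`, `vpd_kpa`).
#' @return Data frame: `species`, `n`, `altitude_mean`, `altitude_min`,
#'   `altitude_max`, `tmin_mean`, `pdry_mean`, `vpd_mean`.
#' @export
species_climate_means <- function(data) {
  need <- c("species", "altitude_m", "tmin_c", "pdry_mm", "vpd_kpa")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop(sprintf("climate not joined: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  agg <- aggregate(data[, c("altitude_m", "tmin_c", "pdry_mm", "vpd_kpa")],
                   by = list(species = data$species), FUN = mean)
  names(agg) <- c("species", "altitude_mean", "tmin_mean", "pdry_mean",
                  "vpd_mean")
  rng <- aggregate(data$altitude_m, by = list(species = data$species),
                   FUN = range)
  agg$altitude_min <- rng$x[, 1]
  agg$altitude_max <- rng$x[, 2]
  agg$n <- as.integer(table(data$species)[agg$species])
  agg[, c("species", "n", "altitude_mean", "altitude_min", "altitude_max",
          "tmin_mean", "pdry_mean", "vpd_mean")]
}

#' Per-species slopes of gas-exchange frequency on metabolic rate
#'
#' For each species with at least `min_n` individuals, fits
#' `fge ~ log10_mr + log10_mass + (1 | block) + (1 | channel)` and
#' extracts the log10 MR coefficient and its standard error -- how
#' steeply the frequency of gas exchange rises with metabolic rate once
#' body mass is accounted for. Species below `min_n`, or whose fit fails,
#' are excluded with a warning. Species' mean climates are appended for
#' the second-stage regressions of [slope_climate_set()].
#'
#' @param data Trait table (see [simulate_trait_table()] schema).
#' @param min_n Minimum individuals per species (default 10).
#' @return A `species_slopes` data frame: `species`, `slope`, `se`, `n`
#'   and the [species_climate_means()] columns.
#' @export
species_slopes <- function(data, min_n = 10) {
  counts <- table(data$species)
  keep <- names(counts)[counts >= min_n]
  drop <- setdiff(names(counts), keep)
  if (length(drop)) {
    warning(sprintf("species below n = %d excluded: %s", min_n,
                    paste(drop, collapse = ", ")))
  }
  if (length(keep) < 2L) {
    stop(sprintf("need >= 2 species with n >= %d", min_n), call. = FALSE)
  }
  clim <- species_climate_means(data[data$species %in% keep, ])
  rows <- lapply(keep, function(sp) {
    sub <- data[data$species == sp, ]
    mixed <- tryCatch(
      suppressWarnings(.fit_mixed(fge ~ log10_mr + log10_mass,
                                  c("block", "channel"), sub)),
      error = function(e) NULL)
    if (is.null(mixed)) return(NULL)
    fit <- mixed$fit
    beta <- if (mixed$is_lmm) lme4::fixef(fit) else coef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    if (!"log10_mr" %in% names(beta) || !is.finite(se[["log10_mr"]]) ||
        se[["log10_mr"]] <= 0) return(NULL)
    data.frame(species = sp, slope = unname(beta[["log10_mr"]]),
               se = unname(se[["log10_mr"]]), n = sum(counts[sp]),
               stringsAsFactors = FALSE)
  })
  failed <- keep[vapply(rows, is.null, logical(1))]
  if (length(failed)) {
    warning(sprintf("singular or failed fit; species excluded: %s",
                    paste(failed, collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  out <- merge(out, clim[, setdiff(names(clim), "n")], by = "species")
  class(out) <- c("species_slopes", class(out))
  out
}

#' Compare climate models of the trait-covariation slope
#'
#' Five ordinary linear regressions of the per-species FGE~MR slope on
#' the species' mean climates -- altitude, VPD, minimum temperature,
#' minimum temperature + dry-month precipitation, and precipitation --
#' compared by AIC (Gaussian closed form, via [stats::AIC()], so values
#' are comparable with mixed-model output), with Akaike weights and R2.
#' With few species these regressions have very few residual degrees of
#' freedom; they are reported regardless (and `rank_flag`ged when a
#' model has no residual df at all).
#'
#' @param slopes A [species_slopes()] data frame (>= 3 species).
#' @param weight_by_se If `TRUE`, weight species by `1/se^2`; default
#'   `FALSE` (unweighted).
#' @return A `comparison_table` data frame sorted by AIC: `model`,
#'   `n_params`, `aic`, `delta_aic`, `weight`, `r_squared`; attribute
#'   `fits` holds the `lm` objects.
#' @export
slope_climate_set <- function(slopes, weight_by_se = FALSE) {
  if (nrow(slopes) < 3L) stop("need >= 3 species slopes", call. = FALSE)
  forms <- list("Altitude" = slope ~ altitude_mean,
                "VPD" = slope ~ vpd_mean,
                "T_min" = slope ~ tmin_mean,
                "T_min+P_dry" = slope ~ tmin_mean + pdry_mean,
                "P_dry" = slope ~ pdry_mean)
  w <- if (weight_by_se) 1 / slopes$se^2 else NULL
  fits <- lapply(forms, function(f) lm(f, data = slopes, weights = w))
  tab <- data.frame(
    model = names(forms),
    n_params = vapply(fits, function(f) length(coef(f)) + 1, numeric(1)),
    aic = vapply(fits, AIC, numeric(1)),
    r_squared = vapply(fits, function(f) summary(f)$r.squared, numeric(1)),
    rank_flag = vapply(fits, function(f) f$df.residual < 1, logical(1)),
    stringsAsFactors = FALSE)
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$weight <- akaike_weights(tab$aic)
  tab <- tab[order(tab$aic),
             c("model", "n_params", "aic", "delta_aic", "weight",
               "r_squared", "rank_flag")]
  rownames(tab) <- NULL
  structure(tab, n_used = nrow(slopes), fits = fits,
            class = c("comparison_table", "data.frame"))
}
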