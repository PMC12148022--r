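#' Parameters for the climate-gradient and trait-table simulators
#'
#' Defaults emulate the study design the analysis assumes: 16 collection
#' sites along a ~1100 m tropical altitudinal gradient, 10 on the dry
#' (rain-shadow) side and 6 on the wet side, with minimum temperature
#' falling ~5 degC and dry-month precipitation rising ~100 mm per 1000 m;
#' four bee species measured over 7-channel respirometry blocks; and
#' fixed effects on the scales the mixed models are fitted on
#' (log10 ml CO2 min^-1 for metabolic rate, min^-1 for frequency of gas
#' exchange).
#'
#' @param n_sites Number of collection sites.
#' @param n_dry How many of the sites sit on the dry side.
#' @param n_per_site Bees measured per site.
#' @param altitude_range `c(min, max)` site altitude, m a.s.l.
#' @param temp_lapse Change in minimum temperature per m of altitude,
#'   degC m^-1 (negative).
#' @param sea_level_tmin Minimum temperature at 0 m on either side, degC.
#' @param precip_gain Change in dry-month precipitation per m, mm m^-1.
#' @param sea_level_pdry Wet-side dry-month precipitation at 0 m, mm.
#' @param rain_shadow_offset How much drier the dry side is at any given
#'   altitude, mm.
#' @param rh_wet,rh_dry Relative humidity (fraction of saturation) used
#'   to set each side's vapour pressure, so VPD is positive everywhere.
#' @param rh_site_sd SD of seeded per-site scatter around the side-level
#'   relative humidity. Temperature and precipitation are exact linear
#'   functions of altitude, but real vapour pressure varies site to site;
#'   without this scatter VPD would be a deterministic function of
#'   temperature and side, which no field gradient exhibits.
#' @param beta_mass Allometric coefficient of log10 dry mass on log10
#'   metabolic rate.
#' @param beta_T,beta_P Effects of `tmin_c` and `pdry_mm` on log10
#'   metabolic rate (per degC, per mm).
#' @param beta0 Intercept of the metabolic-rate model; when `NULL` it is
#'   chosen so a 2 mg bee at the gradient's mid climate has
#'   log10 MR = -2.7 (i.e. V̇CO2 ~ 0.002 ml min^-1).
#' @param beta_MR Common frequency-of-gas-exchange slope on log10 MR,
#'   used for any species missing from `species_slopes`.
#' @param beta_fge_mass Effect of log10 mass on FGE.
#' @param species_slopes Named vector of per-species FGE~log10 MR slopes.
#' @param fge_ref Mean FGE (min^-1) at the reference trait values.
#' @param sd_block,sd_channel,sd_resid Random-intercept and residual SDs
#'   of the metabolic-rate model (log10 units).
#' @param sd_fge_block,sd_fge_channel,sd_fge_resid Same for the FGE model
#'   (min^-1).
#' @param n_blocks Number of measurement blocks (nights).
#' @param n_channels Number of analyser channels.
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `trait_sim_params`.
#' @export
trait_sim_params <- function(n_sites = 16, n_dry = 10, n_per_site = 13,
                             altitude_range = c(6, 1072),
                             temp_lapse = -0.005, sea_level_tmin = 23.5,
                             precip_gain = 0.1, sea_level_pdry = 220,
                             rain_shadow_offset = 60,
                             rh_wet = 0.85, rh_dry = 0.70,
                             rh_site_sd = 0.08,
                             beta_mass = 0.76, beta_T = -0.041,
                             beta_P = -0.002, beta0 = NULL,
                             beta_MR = 0.55, beta_fge_mass = -0.43,
                             species_slopes = c(H_fijiensis = 0.67,
                                                B_puangensis = 0.95,
                                                H_groomi = 0.12,
                                                H_tuiwawae = 0.40),
                             fge_ref = 0.8,
                             sd_block = 0.06, sd_channel = 0.04,
                             sd_resid = 0.105,
                             sd_fge_block = 0.05, sd_fge_channel = 0.03,
                             sd_fge_resid = 0.05,
                             n_blocks = 10, n_channels = 7,
                             seed = NULL) {
  p <- as.list(environment())
  if (n_sites < 1) stop_field("n_sites", "must be >= 1")
  if (n_dry < 0 || n_dry > n_sites)
    stop_field("n_dry", "must lie in [0, n_sites]")
  if (n_per_site < 1) stop_field("n_per_site", "must be >= 1")
  if (length(altitude_range) != 2L || diff(altitude_range) <= 0)
    stop_field("altitude_range", "must be c(min, max) with max > min")
  for (nm in c("sd_block", "sd_channel", "sd_resid", "sd_fge_block",
               "sd_fge_channel", "sd_fge_resid")) {
    if (p[[nm]] < 0) stop_field(nm, "must be >= 0")
  }
  if (rh_wet <= 0 || rh_wet >= 1 || rh_dry <= 0 || rh_dry >= 1)
    stop_field("rh_wet/rh_dry", "must lie strictly between 0 and 1")
  if (rh_site_sd < 0) stop_field("rh_site_sd", "must be >= 0")
  structure(p, class = "trait_sim_params")
}

#' Simulate a site-climate table along an altitudinal gradient
#'
#' Sites are spread evenly over the altitude range on each side of the
#' rain shadow. Per side, minimum temperature and dry-month precipitation
#' are exact linear functions of altitude (`temp_lapse`, `precip_gain`);
#' the dry side's precipitation is offset downward by
#' `rain_shadow_offset` at every altitude. Vapour pressure is a fixed
#' fraction of saturation (per side), so VPD is positive everywhere.
#' Per-site relative humidity scatters around the side level
#' (`rh_site_sd`, drawn reproducibly from `params$seed`), so vapour
#' pressure -- and hence VPD -- varies between sites the way measured
#' climatologies do rather than being an exact function of temperature
#' and side.
#'
#' @param params A [trait_sim_params()] object.
#' @return A site-climate data frame ([annotate_sites()]-ready) with
#'   columns `site_id`, `side`, `altitude_m`, `tmin_c`, `pdry_mm`,
#'   `vp_kpa`.
#' @export
simulate_climate_gradient <- function(params = trait_sim_params()) {
  if (!inherits(params, "trait_sim_params")) {
    params <- do.call(trait_sim_params, as.list(params))
  }
  p <- params
  n_wet <- p$n_sites - p$n_dry
  spread <- function(n) if (n == 1L) mean(p$altitude_range) else
    seq(p$altitude_range[1], p$altitude_range[2], length.out = n)
  alt <- c(spread(p$n_dry), spread(n_wet))
  side <- c(rep("dry", p$n_dry), rep("wet", n_wet))
  tmin <- p$sea_level_tmin + p$temp_lapse * alt
  pdry <- p$sea_level_pdry + p$precip_gain * alt -
    ifelse(side == "dry", p$rain_shadow_offset, 0)
  rh <- ifelse(side == "dry", p$rh_dry, p$rh_wet)
  if (p$rh_site_sd > 0) {
    rh <- with_seed(p$seed,
                    pmin(0.98, pmax(0.30,
                                    rh + rnorm(length(rh), 0, p$rh_site_sd))))
  }
  vp <- rh * svp(tmin)
  data.frame(site_id = sprintf("S%02d", seq_along(alt)),
             side = side, altitude_m = alt, tmin_c = tmin,
             pdry_mm = pdry, vp_kpa = vp, stringsAsFactors = FALSE)
}

# altitude-band species pools mirroring the field design: one generalist
# along the whole gradient, one lowland species, two upland specialists
# with staggered lower range limits
.species_pool <- function(altitude, species) {
  pool <- species[1]
  if (altitude <= 400 && length(species) >= 2) pool <- c(pool, species[2])
  if (altitude >= 600 && length(species) >= 3) pool <- c(pool, species[3])
  if (altitude >= 450 && length(species) >= 4) pool <- c(pool, species[4])
  pool
}

#' Simulate a bee trait table with known effect structure
#'
#' Generates one row per bee with the generative model the downstream
#' mixed models assume:
#' \deqn{\log_{10} MR = \beta_0 + \beta_m \log_{10}(mass) + \beta_T T_{min}
#'   + \beta_P P_{dry} + u_{block} + u_{channel} + \varepsilon}
#' and frequency of gas exchange built from log10 MR and log10 mass with
#' species-specific slopes and its own crossed random intercepts. Species
#' are assigned from altitude-band pools (the first species everywhere,
#' the second below 400 m, the remaining two above 600 m), bees cycle
#' over analyser channels, and sites map onto measurement blocks.
#'
#' @param params A [trait_sim_params()] object.
#' @param sites A site-climate table from [simulate_climate_gradient()]
#'   (annotated or not; [annotate_sites()] is applied internally).
#' @return A list with `traits` (the trait table: `bee_id`, `species`,
#'   `sex`, `site_id`, `block`, `channel`, `mass_mg`, `vco2`, `fge`,
#'   `log10_mr`, `log10_mass` + joined climate columns) and `truth`
#'   (all simulated coefficients, variance components and random-effect
#'   draws).
#' @export
simulate_trait_table <- function(params = trait_sim_params(),
                                 sites = simulate_climate_gradient(params)) {
  if (!inherits(params, "trait_sim_params")) {
    params <- do.call(trait_sim_params, as.list(params))
  }
  p <- params
  if (!is.data.frame(sites) || !nrow(sites))
    stop_field("sites", "must be a non-empty site table")
  sites <- annotate_sites(sites)
  species <- names(p$species_slopes)
  if (is.null(species) || !length(species))
    stop("configuration error: species_slopes must be a named vector",
         call. = FALSE)

  with_seed(p$seed, {
    n <- nrow(sites) * p$n_per_site
    site_idx <- rep(seq_len(nrow(sites)), each = p$n_per_site)
    site <- sites[site_idx, ]
    sp <- vapply(site$altitude_m, function(a) {
      pool <- .species_pool(a, species)
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1))
    if (!all(sp %in% names(p$species_slopes))) {
      stop("configuration error: species_slopes lacks entries for species in the design",
           call. = FALSE)
    }
    block <- sprintf("B%02d", ((site_idx - 1L) %% p$n_blocks) + 1L)
    channel <- sprintf("C%d", ((seq_len(n) - 1L) %% p$n_channels) + 1L)

    # dry mass, mg: species-level lognormal (second species a bit larger)
    mass_mu <- setNames(rep(0.25, length(species)), species)
    if (length(species) >= 2) mass_mu[2] <- 0.40
    log10_mass <- rnorm(n, mass_mu[sp], 0.12)
    mass_mg <- 10^log10_mass

    ref_tmin <- p$sea_level_tmin + p$temp_lapse * mean(p$altitude_range)
    ref_pdry <- p$sea_level_pdry + p$precip_gain * mean(p$altitude_range) -
      p$rain_shadow_offset / 2
    beta0 <- p$beta0
    if (is.null(beta0)) {
      beta0 <- -2.7 - p$beta_mass * 0.3 - p$beta_T * ref_tmin -
        p$beta_P * ref_pdry
    }

    u_block <- setNames(rnorm(p$n_blocks, 0, p$sd_block),
                        sprintf("B%02d", seq_len(p$n_blocks)))
    u_channel <- setNames(rnorm(p$n_channels, 0, p$sd_channel),
                          sprintf("C%d", seq_len(p$n_channels)))
    log10_mr <- beta0 + p$beta_mass * log10_mass + p$beta_T * site$tmin_c +
      p$beta_P * site$pdry_mm + u_block[block] + u_channel[channel] +
      rnorm(n, 0, p$sd_resid)

    v_block <- setNames(rnorm(p$n_blocks, 0, p$sd_fge_block),
                        names(u_block))
    v_channel <- setNames(rnorm(p$n_channels, 0, p$sd_fge_channel),
                          names(u_channel))
    slopes <- p$species_slopes[sp]
    fge <- p$fge_ref + slopes * (log10_mr + 2.7) +
      p$beta_fge_mass * (log10_mass - 0.3) + v_block[block] +
      v_channel[channel] + rnorm(n, 0, p$sd_fge_resid)

    traits <- data.frame(
      bee_id = sprintf("bee%03d", seq_len(n)),
      species = sp,
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.7, 0.3)),
      site_id = site$site_id, block = block, channel = channel,
      mass_mg = mass_mg, vco2 = 10^log10_mr, fge = as.numeric(fge),
      log10_mr = log10_mr, log10_mass = log10_mass,
      stringsAsFactors = FALSE)
    traits <- cbind(traits,
                    site[, c("side", "altitude_m", "tmin_c", "pdry_mm",
                             "vp_kpa", "svp_kpa", "vpd_kpa")])
    rownames(traits) <- NULL
    truth <- list(beta0 = beta0, beta_mass = p$beta_mass,
                  beta_T = p$beta_T, beta_P = p$beta_P,
                  beta_MR = p$beta_MR, beta_fge_mass = p$beta_fge_mass,
                  species_slopes = p$species_slopes,
                  sd_block = p$sd_block, sd_channel = p$sd_channel,
                  sd_resid = p$sd_resid, u_block = u_block,
                  u_channel = u_channel)
    list(traits = traits, truth = truth)
  })
}
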