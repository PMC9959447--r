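## Seeded synthetic province-year panels with a known data-generating process.
##
## The generator emulates a 30-unit x 10-year balanced panel: positive,
## right-skewed activity quantities (log-normal, with a persistent unit scale
## so larger provinces are larger on both sides of the production set),
## Beta-distributed indices on (0,1) whose moments match the published
## descriptive statistics, uniform urbanisation on [35, 90], Gaussian
## controls, and an outcome that carries a linear index effect, a piecewise
## (threshold) innovation effect, an index-by-urbanisation interaction and
## i.i.d. Gaussian noise. The truth travels with the panel object.

#' Configuration of the synthetic data-generating process
#'
#' Defaults are the study conditions: 30 units, 10 years, effect sizes at the
#' published point estimates and Beta/uniform/Gaussian marginals matched to
#' the published descriptive statistics.
#'
#' @param n_units number of panel units (>= 3).
#' @param n_years number of years (>= 2).
#' @param seed integer RNG seed.
#' @param beta_ndi true linear effect of the composite index on the outcome.
#' @param theta_true true innovation-index threshold, in (0, 1).
#' @param beta_low,beta_high regime slopes of the innovation index below and
#'   above `theta_true`.
#' @param gamma_interact true index-by-urbanisation interaction.
#' @param lu_coef main effect of urbanisation (percent scale).
#' @param sigma_eps noise standard deviation (>= 0; 0 gives the noise-free
#'   identification limit).
#' @param censor_frac fraction of outcomes left-censored for Tobit
#'   experiments, in `[0, 1)`.
#' @param alpha0 intercept.
#' @param control_coefs named vector of control coefficients
#'   (AED, PS, ADR, RHC, FSA).
#' @param endog_rho strength of a shared confounder pushed into both the
#'   index and the error term (0 = exogenous); used for instrumental-variable
#'   experiments.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_units = 30L, n_years = 10L, seed = 1L,
                             beta_ndi = 1.0237, theta_true = 0.2813,
                             beta_low = 14.9609, beta_high = -4.1182,
                             gamma_interact = 0.158, lu_coef = 0,
                             sigma_eps = 0.5, censor_frac = 0,
                             alpha0 = 0.5,
                             control_coefs = c(AED = -0.0033, PS = -0.9796,
                                               ADR = -0.4523, RHC = 0.9122,
                                               FSA = 1.3899),
                             endog_rho = 0) {
  assert_that(is_number(n_units) && n_units >= 3,
              "n_units must be an integer >= 3",
              class = "agrecoeff_config_error")
  assert_that(is_number(n_years) && n_years >= 2,
              "n_years must be an integer >= 2",
              class = "agrecoeff_config_error")
  assert_that(is_number(seed), "seed must be a number",
              class = "agrecoeff_config_error")
  assert_that(is_number(theta_true) && theta_true > 0 && theta_true < 1,
              "theta_true must lie in (0, 1)", class = "agrecoeff_config_error")
  assert_that(is_number(sigma_eps) && sigma_eps >= 0,
              "sigma_eps must be >= 0", class = "agrecoeff_config_error")
  assert_that(is_number(censor_frac) && censor_frac >= 0 && censor_frac < 1,
              "censor_frac must lie in [0, 1)", class = "agrecoeff_config_error")
  nm <- c("AED", "PS", "ADR", "RHC", "FSA")
  assert_that(all(nm %in% names(control_coefs)),
              "control_coefs must name AED, PS, ADR, RHC, FSA",
              class = "agrecoeff_config_error")
  for (v in c(beta_ndi, beta_low, beta_high, gamma_interact, lu_coef, alpha0,
              endog_rho))
    assert_that(is_number(v), "effect sizes must be finite numbers",
                class = "agrecoeff_config_error")
  structure(list(
    n_units = as.integer(n_units), n_years = as.integer(n_years),
    seed = as.integer(seed), beta_ndi = beta_ndi, theta_true = theta_true,
    beta_low = beta_low, beta_high = beta_high,
    gamma_interact = gamma_interact, lu_coef = lu_coef,
    sigma_eps = sigma_eps, censor_frac = censor_frac, alpha0 = alpha0,
    control_coefs = control_coefs[nm], endog_rho = endog_rho
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_units, " units x ", x$n_years,
      " years, seed ", x$seed, "\n", sep = "")
  cat("  beta_ndi=", x$beta_ndi, " theta=", x$theta_true,
      " regimes=(", x$beta_low, ", ", x$beta_high, ") gamma=",
      x$gamma_interact, " sigma=", x$sigma_eps, "\n", sep = "")
  invisible(x)
}

## Beta(a, b) shape parameters from a target mean and sd
beta_shapes <- function(mean, sd) {
  v <- sd^2
  s <- mean * (1 - mean) / v - 1
  c(a = mean * s, b = (1 - mean) * s)
}

#' Generate the raw activity panel
#'
#' Draws, for every unit-year, crop yields for the fifteen coefficient-table
#' crops, activity levels for the six emission sources, and the raw
#' input/output quantities of the DEA system (sown and irrigated area,
#' primary employment and output-value shares for labor imputation, machinery
#' power, diesel, chemicals, output value, pollution discharges). Quantities
#' are log-normal with a persistent per-unit scale factor, so larger units are
#' proportionally larger on inputs and outputs and the efficiency frontier
#' stays non-degenerate.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `activity_panel` with data.frames `crops`
#'   (unit, year, crop, yield), `activities` (unit, year, source, activity)
#'   and `quantities` (one row per unit-year with the raw DEA quantities).
#' @export
generate_activity_panel <- function(cfg) {
  assert_that(inherits(cfg, "synthetic_config"), "cfg must be a synthetic_config",
              class = "agrecoeff_config_error")
  with_seed(cfg$seed, {
    nu <- cfg$n_units; ny <- cfg$n_years
    units <- sprintf("U%02d", seq_len(nu))
    years <- 2000L + seq_len(ny)
    scale_u <- exp(stats::rnorm(nu, 0, 0.4))          # persistent unit size
    grid <- expand.grid(unit = units, year = years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$unit, grid$year), , drop = FALSE]
    rownames(grid) <- NULL
    nr <- nrow(grid)
    su <- scale_u[match(grid$unit, units)]
    ln <- function(med, sdlog = 0.25) su * med * exp(stats::rnorm(nr, 0, sdlog))

    crops_tab <- .crop_table_defaults$crop
    crop_base <- stats::setNames(
      exp(stats::runif(length(crops_tab), log(20), log(400))), crops_tab)
    crops <- do.call(rbind, lapply(crops_tab, function(cr) {
      data.frame(unit = grid$unit, year = grid$year, crop = cr,
                 yield = su * crop_base[[cr]] * exp(stats::rnorm(nr, 0, 0.3)),
                 stringsAsFactors = FALSE)
    }))
    crops <- crops[order(crops$unit, crops$year, crops$crop), , drop = FALSE]
    rownames(crops) <- NULL

    q <- data.frame(
      unit = grid$unit, year = grid$year,
      sown_area = ln(4000),              # thousand hectares
      irrigated_area = ln(1500),
      primary_employment = ln(800),      # 10,000 people
      agri_output = ln(1200),            # billion yuan (crop share)
      total_afah_output = NA_real_,
      machinery_power = ln(3000),        # 10,000 kW
      diesel_kt = ln(120),               # 10,000 t
      pesticide_t = ln(5e4),             # t
      fertilizer_t = ln(2e5),            # pure-nutrient t
      film_t = ln(2e4),                  # t
      output_value = NA_real_,
      cod = ln(30), nh = ln(4), tn = ln(8), tp = ln(1.2),
      stringsAsFactors = FALSE
    )
    q$total_afah_output <- q$agri_output * stats::runif(nr, 1.2, 1.8)
    q$output_value <- q$agri_output * exp(stats::rnorm(nr, 0, 0.1))

    acts <- rbind(
      data.frame(unit = grid$unit, year = grid$year, source = "pesticide",
                 activity = q$pesticide_t * 1000),        # kg
      data.frame(unit = grid$unit, year = grid$year, source = "fertilizer",
                 activity = q$fertilizer_t * 1000),
      data.frame(unit = grid$unit, year = grid$year, source = "diesel",
                 activity = q$diesel_kt * 1e7),           # 10^4 t -> kg
      data.frame(unit = grid$unit, year = grid$year, source = "film",
                 activity = q$film_t * 1000),
      data.frame(unit = grid$unit, year = grid$year, source = "irrigation",
                 activity = q$irrigated_area * 1000),     # thousand ha -> ha
      data.frame(unit = grid$unit, year = grid$year, source = "tillage",
                 activity = q$sown_area * 1000)
    )
    acts <- acts[order(acts$unit, acts$year, acts$source), , drop = FALSE]
    rownames(acts) <- NULL
    structure(list(crops = crops, activities = acts, quantities = q,
                   truth = cfg),
              class = "activity_panel")
  })
}

#' Generate a regression-ready panel with known truth
#'
#' The outcome follows
#' `aee_vrs = alpha0 + beta_ndi*ndi + beta_low*inni*1(inni <= theta) +
#'  beta_high*inni*1(inni > theta) + gamma*ndi*lu + lu_coef*lu +
#'  controls'coefs + eps`, with `eps ~ N(0, sigma_eps^2)`. Sub-indices are
#' Beta draws matched to the published moments, the composite index is their
#' 0.4/0.3/0.3 combination, urbanisation is uniform on `[35, 90]` (percent)
#' and the five controls are independent Gaussians. A constant-returns
#' outcome `aee_crs` with a small linear index effect (0.1917) is generated
#' alongside. An instrument column `iv` (the index plus independent noise) is
#' included; with `endog_rho > 0` a shared confounder enters both the
#' information sub-index and the error, making the index endogenous while the
#' instrument stays valid.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame of class `synthetic_panel`, one row per unit-year, with
#'   the generating config in `attr(, "truth")` (including the censoring
#'   bound `censor_bound` when `censor_frac > 0`).
#' @export
generate_regression_panel <- function(cfg) {
  assert_that(inherits(cfg, "synthetic_config"), "cfg must be a synthetic_config",
              class = "agrecoeff_config_error")
  with_seed(cfg$seed + 1L, {
    nu <- cfg$n_units; ny <- cfg$n_years
    units <- sprintf("U%02d", seq_len(nu))
    years <- 2000L + seq_len(ny)
    grid <- expand.grid(unit = units, year = years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$unit, grid$year), , drop = FALSE]
    rownames(grid) <- NULL
    n <- nrow(grid)

    sh_infi <- beta_shapes(0.256, 0.177)
    sh_ci <- beta_shapes(0.406, 0.226)
    sh_inni <- beta_shapes(0.214, 0.150)
    infi <- stats::rbeta(n, sh_infi["a"], sh_infi["b"])
    ci <- stats::rbeta(n, sh_ci["a"], sh_ci["b"])
    inni <- stats::rbeta(n, sh_inni["a"], sh_inni["b"])
    conf <- stats::rnorm(n)
    # instrument derives from the pre-confounding index, so it stays valid
    # (relevant but independent of the error) when endog_rho > 0
    iv <- 0.4 * infi + 0.3 * ci + 0.3 * inni + stats::rnorm(n, 0, 0.05)
    if (cfg$endog_rho != 0)
      infi <- pmin(pmax(infi + cfg$endog_rho * 0.1 * conf, 1e-4), 1 - 1e-4)
    ndi <- 0.4 * infi + 0.3 * ci + 0.3 * inni
    lu <- stats::runif(n, 35, 90)
    AED <- stats::rnorm(n, 4.692, 5.389)
    PS <- stats::rnorm(n, 0.649, 0.140)
    ADR <- stats::rnorm(n, 0.151, 0.119)
    RHC <- stats::rnorm(n, 2.044, 0.0778)
    FSA <- stats::rnorm(n, 0.115, 0.0336)
    eps <- if (cfg$sigma_eps > 0) stats::rnorm(n, 0, cfg$sigma_eps) else rep(0, n)
    if (cfg$endog_rho != 0) eps <- eps + cfg$endog_rho * conf

    cc <- cfg$control_coefs
    latent <- cfg$alpha0 + cfg$beta_ndi * ndi +
      cfg$beta_low * inni * (inni <= cfg$theta_true) +
      cfg$beta_high * inni * (inni > cfg$theta_true) +
      cfg$gamma_interact * ndi * lu + cfg$lu_coef * lu +
      cc[["AED"]] * AED + cc[["PS"]] * PS + cc[["ADR"]] * ADR +
      cc[["RHC"]] * RHC + cc[["FSA"]] * FSA + eps
    bound <- -Inf
    aee_vrs <- latent
    if (cfg$censor_frac > 0) {
      bound <- unname(stats::quantile(latent, cfg$censor_frac))
      aee_vrs <- pmax(latent, bound)
    }
    aee_crs <- 0.8 + 0.1917 * ndi +
      (if (cfg$sigma_eps > 0) stats::rnorm(n, 0, 0.3 * cfg$sigma_eps) else 0)

    panel <- data.frame(grid, aee_vrs = aee_vrs, aee_crs = aee_crs,
                        ndi = ndi, infi = infi, ci = ci, inni = inni,
                        lu = lu, AED = AED, PS = PS, ADR = ADR, RHC = RHC,
                        FSA = FSA, iv = iv, stringsAsFactors = FALSE)
    truth <- unclass(cfg)
    truth$censor_bound <- bound
    attr(panel, "truth") <- truth
    class(panel) <- c("synthetic_panel", "data.frame")
    panel
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  tr <- attr(x, "truth")
  cat("<synthetic_panel> ", tr$n_units, " units x ", tr$n_years, " years (",
      nrow(x), " rows), seed ", tr$seed, "\n", sep = "")
  NextMethod()
}

#' Write a panel to the long-format CSV dialect
#'
#' Columns `unit`, `year`, then named variables; UTF-8, '.' decimal separator.
#'
#' @param panel data.frame with `unit` and `year` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  assert_that(all(c("unit", "year") %in% names(panel)),
              "panel needs 'unit' and 'year' columns")
  first <- c("unit", "year")
  panel <- panel[c(first, setdiff(names(panel), first))]
  utils::write.csv(panel, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble the DEA input/output system from an activity panel
#'
#' Runs the accounting chain on a generated (or equivalently structured)
#' activity panel: per unit-year crop sequestration and carbon emission,
#' labor imputation, the chemical composite and the pollution aggregate, and
#' returns the unit-year table ready for [dmu_set()].
#'
#' @param ap an `activity_panel` from [generate_activity_panel()], or a list
#'   with compatible `crops`, `activities`, `quantities` elements.
#' @param hi_mode passed to [carbon_sequestration()].
#' @return data.frame with one row per unit-year: id, unit, year, the six
#'   inputs, two desired outputs (`output_value`, `csa`) and two undesired
#'   outputs (`ce`, `nps`).
#' @export
assemble_dmu_table <- function(ap, hi_mode = "divide") {
  q <- ap$quantities
  key <- paste(q$unit, q$year)
  crop_key <- paste(ap$crops$unit, ap$crops$year)
  act_key <- paste(ap$activities$unit, ap$activities$year)
  coefs <- crop_coefficients()
  ecoefs <- emission_coefficients()
  csa <- vapply(key, function(k)
    carbon_sequestration(ap$crops[crop_key == k, , drop = FALSE],
                         hi_mode = hi_mode, coefficients = coefs), numeric(1))
  ce <- vapply(key, function(k)
    carbon_emission(ap$activities[act_key == k, , drop = FALSE],
                    coefficients = ecoefs), numeric(1))
  data.frame(
    id = paste(q$unit, q$year, sep = "_"),
    unit = q$unit, year = q$year,
    sown_area = q$sown_area,
    irrigated_area = q$irrigated_area,
    labor = impute_labor(q$primary_employment, q$agri_output,
                         q$total_afah_output),
    machinery_power = q$machinery_power,
    diesel = q$diesel_kt,
    chemicals = chemical_composite(q$pesticide_t, q$fertilizer_t, q$film_t),
    output_value = q$output_value,
    csa = unname(csa),
    ce = unname(ce),
    nps = nps_pollution(q$cod, q$nh, q$tn, q$tp),
    stringsAsFactors = FALSE
  )
}

## role columns of the assembled DMU table, used by the pipeline and tests
dea_roles <- function() {
  list(inputs = c("sown_area", "irrigated_area", "labor", "machinery_power",
                  "diesel", "chemicals"),
       good_outputs = c("output_value", "csa"),
       bad_outputs = c("ce", "nps"))
}
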