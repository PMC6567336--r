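#' @title Non-invasive biomass estimation pipeline
#' @description Predicts per-colony fresh weights from ROV polyp-leaf
#'   counts, aggregates them to a mean colony weight and a total population
#'   biomass over a surveyed area, and validates the prediction against a
#'   physically measured trawl sample.
#' @name biomass_pipeline
NULL

#' Predict per-colony weights from ROV observations
#'
#' Applies the cubic fresh-weight model to each observed leaf count. For
#' counts at or below the model's validity bound (`validity_min_n`,
#' default 15) the predicted weight is set to exactly 0 -- such small
#' colonies are outside the model's domain and contribute a negligible
#' share of population mass. Negative cubic output is clamped to 0 with a
#' warning.
#'
#' @param observations validated ROV data frame, or an integer vector of
#'   leaf counts.
#' @param model a [cubic_weight_model()].
#' @return Numeric vector of non-negative weights, g, one per observation.
#' @export
predict_colony_weights <- function(observations, model) {
  stopifnot(inherits(model, "cubic_weight_model"))
  counts <- if (is.data.frame(observations)) {
    observations$leaf_count
  } else {
    observations
  }
  if (length(counts) == 0) return(numeric(0))
  out <- numeric(length(counts))
  applicable <- counts > model$validity_min_n
  w <- pracma::polyval(c(model$c3, model$c2, model$c1, model$c0),
                       counts[applicable])
  if (any(w < 0)) {
    warning("negative fresh-weight prediction clamped to 0", call. = FALSE)
    w[w < 0] <- 0
  }
  out[applicable] <- w
  out
}

#' Mean predicted colony weight
#'
#' Arithmetic mean of the per-colony predicted weights, *including* the
#' zeroed small colonies: the mean is per observed colony, not per
#' model-applicable colony.
#'
#' @param weights numeric vector of predicted weights, g (non-empty).
#' @return Mean weight, g.
#' @export
mean_predicted_weight <- function(weights) {
  if (length(weights) == 0) {
    stop("cannot average an empty weight vector", call. = FALSE)
  }
  mean(weights)
}

#' Total population biomass over an area
#'
#' `total = mean_weight * density * area`: the mean predicted colony
#' weight scaled by colony surface density and the surveyed area.
#'
#' @param mean_weight mean colony weight, g (>= 0).
#' @param density colony density, colonies per m^2 (>= 0).
#' @param area surveyed area, m^2 (>= 0).
#' @return Total biomass, g.
#' @export
total_biomass <- function(mean_weight, density, area) {
  stopifnot(mean_weight >= 0, density >= 0, area >= 0)
  mean_weight * density * area
}

#' Assemble a biomass estimate
#'
#' @param m_observed number of ROV-observed colonies.
#' @param mean_predicted_weight mean predicted colony weight, g.
#' @param density colony density, colonies per m^2.
#' @param area surveyed area, m^2.
#' @param n_not_applicable number of colonies zeroed by the validity rule.
#' @return Object of class `biomass_estimate`; `total_weight_g` always
#'   equals `mean_predicted_weight * density * area`.
#' @export
biomass_estimate <- function(m_observed, mean_predicted_weight, density,
                             area, n_not_applicable) {
  stopifnot(mean_predicted_weight >= 0, density >= 0, area >= 0,
            n_not_applicable >= 0, n_not_applicable <= m_observed)
  structure(
    list(
      m_observed = m_observed,
      mean_predicted_weight_g = mean_predicted_weight,
      density_per_m2 = density,
      area_m2 = area,
      total_weight_g = total_biomass(mean_predicted_weight, density, area),
      n_not_applicable = n_not_applicable,
      fraction_not_applicable = n_not_applicable / m_observed
    ),
    class = "biomass_estimate"
  )
}

#' @export
print.biomass_estimate <- function(x, ...) {
  cat(sprintf(
    "Biomass estimate: mean colony weight %.3f g over %d colonies (%d below validity bound, set to 0)\n",
    x$mean_predicted_weight_g, x$m_observed, x$n_not_applicable
  ))
  cat(sprintf("  density %.4g colonies/m^2 x area %.4g m^2 -> total %.4g g\n",
              x$density_per_m2, x$area_m2, x$total_weight_g))
  invisible(x)
}

#' Signed relative error of a prediction
#'
#' `(predicted - measured) / measured`; negative when the prediction
#' underestimates.
#'
#' @param predicted predicted value.
#' @param measured measured reference value (non-zero).
#' @return Signed fraction.
#' @export
signed_relative_error <- function(predicted, measured) {
  if (measured == 0) {
    stop("signed_relative_error undefined: measured value is 0",
         call. = FALSE)
  }
  (predicted - measured) / measured
}

#' Validate an ROV-based weight prediction against a trawl sample
#'
#' Compares the ROV-predicted mean colony weight with the mean of the
#' fresh weights physically measured on a trawl sample of the same
#' population.
#'
#' @param predicted_mean ROV-based mean predicted colony weight, g.
#' @param trawl_colonies validated colony data frame (non-empty).
#' @return Object of class `validation_result`: `predicted_mean_g`,
#'   `measured_mean_g`, `relative_error` (signed fraction).
#' @export
validate_against_trawl <- function(predicted_mean, trawl_colonies) {
  if (!is.data.frame(trawl_colonies) || nrow(trawl_colonies) == 0) {
    stop("trawl validation needs a non-empty colony table", call. = FALSE)
  }
  measured <- mean(trawl_colonies$fresh_weight_g)
  structure(
    list(
      predicted_mean_g = predicted_mean,
      measured_mean_g = measured,
      relative_error = signed_relative_error(predicted_mean, measured)
    ),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "Validation: predicted mean %.3f g vs measured mean %.3f g (relative error %+.1f%%)\n",
    x$predicted_mean_g, x$measured_mean_g, 100 * x$relative_error
  ))
  invisible(x)
}

#' Default run configuration
#'
#' A flat list of every pipeline setting: the generator parameters of
#' [generator_config()], the two survey sizes (`n_trawl_population`
#' colonies exposed to the trawl -- default 180, so that logistic
#' selectivity at the default parameters retains about 168 -- and
#' `n_rov_population` = 207 ROV-observed colonies), the dry-weight subset
#' size (54) and its fresh-weight window (`dry_min_fresh` 0.8 g to
#' `dry_max_fresh` 4.5 g, the range over which the cubic dry law is
#' physically sensible), the colony surface density (`NULL` = derive as retained
#' colonies / area) and surveyed area (41,000 m^2 swept area), the random
#' seed, and optional input table paths (when given, those tables replace
#' the simulated ones).
#'
#' @param ... named overrides of any default.
#' @return Named list (class `run_config`).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    # generator (see generator_config for meanings)
    count_mean = 22.0, count_sd = 3.7,
    count_skewness = -1.3, count_kurtosis = 5.6,
    min_leaf_count = 4L,
    rachis_slope = 2.6, rachis_intercept = -1.1,
    total_slope = 5.8, total_intercept = 8.1,
    fresh_coef = c(-0.0013, 0.076, -1.170, 5.342),
    dry_coef = c(0.062, -0.412, 1.134, -0.416),
    noise_rachis = 0.118, noise_total = 0.106,
    noise_fresh = 0.46, noise_dry = 0.192,
    asymmetry_prob = 0.1, asymmetry_max_loss = 3L,
    trawl_l50 = 15, trawl_steepness = 0.8,
    rov_edge_miss_prob = 0.78,
    # survey / pipeline
    n_trawl_population = 180L,
    n_rov_population = 207L,
    dry_subset_size = 54L,
    dry_min_fresh = 0.8,
    dry_max_fresh = 4.5,
    density = NULL,
    area = 41000,
    validity_min_n = 15,
    dispersion_min_count = 15,
    seed = 1L,
    # optional real input tables (simulate when NULL)
    colony_table = NULL,
    rov_table = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$density)) stopifnot(cfg$density >= 0)
  stopifnot(
    cfg$area >= 0,
    cfg$n_trawl_population >= 1, cfg$n_rov_population >= 1,
    cfg$dry_subset_size >= 5
  )
  if (is.null(cfg$colony_table) || is.null(cfg$rov_table)) {
    if (is.null(cfg$seed)) {
      stop("a seed is required whenever tables are simulated", call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key: value YAML; keys are validated against the schema of
#' [default_run_config()] (unknown keys are an error), missing keys take
#' their defaults.
#'
#' @param path path to a YAML file.
#' @return Validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("run config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(default_run_config, raw)
}

rc_generator_config <- function(cfg) {
  generator_config(
    count_mean = cfg$count_mean, count_sd = cfg$count_sd,
    count_skewness = cfg$count_skewness, count_kurtosis = cfg$count_kurtosis,
    min_leaf_count = cfg$min_leaf_count,
    rachis_slope = cfg$rachis_slope, rachis_intercept = cfg$rachis_intercept,
    total_slope = cfg$total_slope, total_intercept = cfg$total_intercept,
    fresh_coef = cfg$fresh_coef, dry_coef = cfg$dry_coef,
    noise_rachis = cfg$noise_rachis, noise_total = cfg$noise_total,
    noise_fresh = cfg$noise_fresh, noise_dry = cfg$noise_dry,
    asymmetry_prob = cfg$asymmetry_prob,
    asymmetry_max_loss = cfg$asymmetry_max_loss,
    trawl_l50 = cfg$trawl_l50, trawl_steepness = cfg$trawl_steepness,
    rov_edge_miss_prob = cfg$rov_edge_miss_prob
  )
}

# Deterministic fresh-weight-spanning subset: order by fresh weight and
# take evenly spaced colonies, emulating selection of colonies "with
# different fresh weight values" for the drying protocol.
dry_subset <- function(colonies, size) {
  m <- nrow(colonies)
  size <- min(size, m)
  ord <- order(colonies$fresh_weight_g)
  idx <- ord[unique(round(seq(1, m, length.out = size)))]
  colonies[idx, , drop = FALSE]
}

#' Run the full non-invasive assessment pipeline
#'
#' End-to-end orchestration: obtain a trawl colony sample and an ROV
#' observation set (simulated from the generator configuration, or read
#' from the configured CSV paths), fit all biometric models on the trawl
#' sample, compute moment summaries and the trawl-vs-ROV distribution
#' comparison, predict per-colony weights from the ROV counts, aggregate
#' to a biomass estimate, and validate the predicted mean weight against
#' the trawl-measured mean. Deterministic for a fixed seed.
#'
#' When an ROV table path is configured but absent from disk is an error;
#' to run without ROV data (no biomass or validation blocks) set
#' `rov_table = NA`.
#'
#' @param config a [default_run_config()]-style list.
#' @return Nested report list (class `seapen_report`) with sections
#'   `meta`, `models`, `statistics`, and -- when ROV data are present --
#'   `biomass` and `validation`. Serialise with [write_report()].
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(unclass(config))
  gcfg <- rc_generator_config(config)

  simulated <- FALSE
  if (!is.null(config$seed)) set.seed(config$seed)

  if (!is.null(config$colony_table)) {
    trawl <- tryCatch(read_colony_table(config$colony_table),
                      error = function(e) {
                        stop("pipeline stage 'read trawl table': ",
                             conditionMessage(e), call. = FALSE)
                      })
  } else {
    simulated <- TRUE
    population <- generate_colonies(gcfg, config$n_trawl_population)
    trawl <- apply_trawl_selectivity(population, gcfg)
    if (nrow(trawl) < 10) {
      stop("pipeline stage 'trawl simulation': selectivity retained too few colonies",
           call. = FALSE)
    }
  }

  rov <- NULL
  if (!is.null(config$rov_table) && !is.na(config$rov_table[1])) {
    rov <- tryCatch(read_rov_table(config$rov_table),
                    error = function(e) {
                      stop("pipeline stage 'read ROV table': ",
                           conditionMessage(e), call. = FALSE)
                    })
  } else if (is.null(config$rov_table)) {
    simulated <- TRUE
    rov_population <- generate_colonies(gcfg, config$n_rov_population)
    rov <- simulate_rov_counts(rov_population, gcfg)
  }

  n_size <- leaf_count_for_size(trawl)
  n_weight <- leaf_count_for_weight(trawl)
  lr <- rachis_length(trawl)

  models <- list(
    rachis_length = fit_linear_size(n_size, lr),
    total_length = fit_linear_size(n_size, trawl$total_length_mm),
    fresh_weight_cubic = fit_cubic_weight(n_weight, trawl$fresh_weight_g,
                                          validity_min_n = config$validity_min_n),
    fresh_weight_surface = fit_weight_surface(n_weight, lr,
                                              trawl$fresh_weight_g)
  )

  # drying protocol: colonies spanning the fresh-weight range over which
  # the cubic dry law is physically sensible -- above dry_min_fresh
  # (below ~0.8 g fresh the expected dry weight falls under ~20x the
  # 0.01 g balance resolution, so relative errors there are dominated by
  # measurement quantisation) and below dry_max_fresh (beyond it the
  # cubic approaches, then exceeds, the fresh weight)
  with_dry <- trawl[!is.na(trawl$dry_weight_g) &
                      trawl$fresh_weight_g >= config$dry_min_fresh &
                      trawl$fresh_weight_g <= config$dry_max_fresh, ,
                    drop = FALSE]
  if (nrow(with_dry) >= 5) {
    sub <- dry_subset(with_dry, config$dry_subset_size)
    models$dry_weight <- fit_dry_weight(sub$fresh_weight_g, sub$dry_weight_g)
  }

  statistics <- list(
    trawl = moment_summary(n_size),
    dispersion = dispersion_by_count(trawl, config$dispersion_min_count)
  )
  if (!is.null(rov)) {
    statistics$rov <- moment_summary(rov$leaf_count)
    statistics$comparison <- compare_distributions(n_size, rov$leaf_count)
  }

  report <- list(
    meta = list(
      package = "seapenbio",
      seed = config$seed,
      simulated = simulated,
      n_trawl = nrow(trawl),
      n_rov = if (is.null(rov)) NULL else nrow(rov)
    ),
    models = models,
    statistics = statistics
  )

  if (!is.null(rov)) {
    weights <- predict_colony_weights(rov, models$fresh_weight_cubic)
    wmean <- mean_predicted_weight(weights)
    density <- if (is.null(config$density)) {
      nrow(trawl) / config$area
    } else {
      config$density
    }
    report$biomass <- biomass_estimate(
      m_observed = nrow(rov),
      mean_predicted_weight = wmean,
      density = density,
      area = config$area,
      n_not_applicable =
        sum(rov$leaf_count <= models$fresh_weight_cubic$validity_min_n)
    )
    report$validation <- validate_against_trawl(wmean, trawl)
  }

  structure(report, class = "seapen_report")
}

#' @export
print.seapen_report <- function(x, ...) {
  cat(sprintf("Sea pen assessment report (%s data, %d trawl colonies%s)\n",
              if (isTRUE(x$meta$simulated)) "synthetic" else "measured",
              x$meta$n_trawl,
              if (is.null(x$meta$n_rov)) ""
              else sprintf(", %d ROV observations", x$meta$n_rov)))
  for (m in x$models) print(m)
  print(x$statistics$trawl)
  if (!is.null(x$statistics$comparison)) print(x$statistics$comparison)
  if (!is.null(x$biomass)) print(x$biomass)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}
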