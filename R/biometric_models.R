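#' @title Biometric size and weight models
#' @description Linear models predicting rachis and total length from the
#'   max-side polyp-leaf count, cubic models predicting fresh weight from
#'   the mean-side count (plus a surface variant adding rachis length) and
#'   dry weight from fresh weight, and the RMS relative error metric used
#'   to report every model's goodness of fit.
#' @name biometric_models
NULL

#' Rachis length of measured colonies
#'
#' The rachis is the upper, polyp-bearing part of the colony -- the portion
#' visible above the sediment. It is obtained by subtracting the peduncle
#' (buried stalk) length from the total length.
#'
#' @param colonies validated colony data frame.
#' @return Numeric vector, mm; strictly positive by table invariant.
#' @export
rachis_length <- function(colonies) {
  colonies$total_length_mm - colonies$peduncle_length_mm
}

#' Leaf count used by the size models
#'
#' The maximum of the two side counts: colony length tracks the intact
#' (undamaged) leaf series.
#'
#' @param colonies validated colony data frame.
#' @return Integer vector.
#' @export
leaf_count_for_size <- function(colonies) {
  pmax(colonies$leaves_left, colonies$leaves_right)
}

#' Leaf count used by the weight models
#'
#' The mean of the two side counts (possibly half-integral): weight scales
#' with the total amount of living tissue on both sides.
#'
#' @param colonies validated colony data frame.
#' @return Numeric vector, in steps of 0.5.
#' @export
leaf_count_for_weight <- function(colonies) {
  (colonies$leaves_left + colonies$leaves_right) / 2
}

#' Root mean square relative error
#'
#' `sqrt(mean(((predicted - observed) / observed)^2))`: the package's
#' goodness-of-fit metric for all biometric models. Relative (not absolute)
#' residuals weight small and large colonies equally.
#'
#' @param predicted,observed equal-length numeric vectors; `observed` must
#'   be non-zero everywhere.
#' @return Non-negative fraction (0.118 means 11.8%).
#' @export
rms_relative_error <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 1) {
    stop("predicted and observed must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(observed == 0)) {
    stop("rms_relative_error undefined: observed values contain 0",
         call. = FALSE)
  }
  sqrt(mean(((predicted - observed) / observed)^2))
}

check_rank <- function(X, what) {
  if (qr(X)$rank < ncol(X)) {
    stop(sprintf("cannot fit %s: design is rank deficient (degenerate predictor values)",
                 what), call. = FALSE)
  }
}

#' Construct a linear size model from known coefficients
#'
#' @param slope mm per leaf.
#' @param intercept mm.
#' @param rms_relative_error,correlation,n_fit,slope_se optional fit
#'   diagnostics.
#' @return Object of class `linear_size_model`.
#' @export
linear_size_model <- function(slope, intercept, rms_relative_error = NA_real_,
                              correlation = NA_real_, n_fit = NA_integer_,
                              slope_se = NA_real_) {
  stopifnot(is.na(rms_relative_error) || rms_relative_error >= 0,
            is.na(correlation) || abs(correlation) <= 1)
  structure(
    list(slope = slope, intercept = intercept,
         rms_relative_error = rms_relative_error,
         correlation = correlation, n_fit = n_fit, slope_se = slope_se),
    class = "linear_size_model"
  )
}

#' Fit a linear size model (length ~ leaf count)
#'
#' Ordinary least squares of a length (rachis or total, mm) on the max-side
#' polyp-leaf count. The stored diagnostics are Pearson's correlation of
#' the raw pairs and the RMS relative error of the fitted line.
#'
#' @param leaf_count numeric vector of counts (>= 3 values, >= 2 distinct).
#' @param length_mm numeric vector of lengths, mm.
#' @return A [linear_size_model()] with fitted `slope`, `intercept`,
#'   `rms_relative_error`, `correlation`, `n_fit` and `slope_se` (standard
#'   error of the slope).
#' @export
fit_linear_size <- function(leaf_count, length_mm) {
  stopifnot(length(leaf_count) == length(length_mm))
  if (length(leaf_count) < 3) {
    stop("need at least 3 (count, length) pairs", call. = FALSE)
  }
  if (length(unique(leaf_count)) < 2) {
    stop("cannot fit linear size model: all leaf counts identical (rank deficient)",
         call. = FALSE)
  }
  fit <- stats::lm(length_mm ~ leaf_count)
  co <- stats::coef(fit)
  linear_size_model(
    slope = unname(co["leaf_count"]),
    intercept = unname(co["(Intercept)"]),
    rms_relative_error = rms_relative_error(stats::fitted(fit), length_mm),
    correlation = stats::cor(leaf_count, length_mm),
    n_fit = length(leaf_count),
    slope_se = unname(suppressWarnings(
      summary(fit)$coefficients["leaf_count", "Std. Error"]
    ))
  )
}

#' Predict length from leaf count
#'
#' @param model a `linear_size_model`.
#' @param n leaf count(s), >= 0.
#' @return Predicted length(s), mm. Negative predictions (extrapolation
#'   below the data) are returned with a warning.
#' @export
predict_length <- function(model, n) {
  stopifnot(inherits(model, "linear_size_model"), all(n >= 0))
  out <- model$slope * n + model$intercept
  if (any(out < 0)) {
    warning("negative length prediction: model extrapolated outside its support",
            call. = FALSE)
  }
  out
}

#' Construct a cubic fresh-weight model from known coefficients
#'
#' @param c3,c2,c1,c0 cubic coefficients, g/leaf^3 .. g.
#' @param validity_min_n exclusive lower validity bound on the leaf count
#'   (default 15): below it the model is not applicable, juvenile weights
#'   being too small and too poorly measured to constrain the fit.
#' @param rms_relative_error,n_fit optional diagnostics.
#' @return Object of class `cubic_weight_model`.
#' @export
cubic_weight_model <- function(c3, c2, c1, c0, validity_min_n = 15,
                               rms_relative_error = NA_real_,
                               n_fit = NA_integer_) {
  stopifnot(validity_min_n >= 0,
            is.na(rms_relative_error) || rms_relative_error >= 0)
  structure(
    list(c3 = c3, c2 = c2, c1 = c1, c0 = c0,
         validity_min_n = validity_min_n,
         rms_relative_error = rms_relative_error, n_fit = n_fit),
    class = "cubic_weight_model"
  )
}

#' Fit the cubic fresh-weight model (weight ~ leaf count)
#'
#' Least-squares cubic polynomial of fresh weight on the mean-side leaf
#' count. The stored RMS relative error is computed only over pairs with
#' `leaf_count > validity_min_n`, the model's validity domain.
#'
#' @param leaf_count numeric vector (>= 5 values, >= 4 distinct; half
#'   counts allowed).
#' @param weight_g fresh weights, g.
#' @param validity_min_n exclusive lower validity bound (default 15).
#' @return A [cubic_weight_model()].
#' @export
fit_cubic_weight <- function(leaf_count, weight_g, validity_min_n = 15) {
  stopifnot(length(leaf_count) == length(weight_g))
  if (length(leaf_count) < 5) {
    stop("need at least 5 (count, weight) pairs", call. = FALSE)
  }
  if (length(unique(leaf_count)) < 4) {
    stop("cannot fit cubic weight model: fewer than 4 distinct leaf counts (rank deficient)",
         call. = FALSE)
  }
  X <- cbind(leaf_count^3, leaf_count^2, leaf_count, 1)
  check_rank(X, "cubic weight model")
  fit <- stats::lm.fit(X, weight_g)
  co <- unname(fit$coefficients)
  valid <- leaf_count > validity_min_n
  err <- NA_real_
  if (any(valid)) {
    err <- rms_relative_error(fit$fitted.values[valid], weight_g[valid])
  } else {
    warning("no pairs above the validity bound; rms_relative_error is NA",
            call. = FALSE)
  }
  cubic_weight_model(co[1], co[2], co[3], co[4],
                     validity_min_n = validity_min_n,
                     rms_relative_error = err,
                     n_fit = length(leaf_count))
}

#' Predict fresh weight from leaf count
#'
#' Returns the cubic prediction for counts above the model's validity
#' bound and `NA` (not applicable) at or below it; the caller decides how
#' to treat non-applicable colonies (the biomass pipeline substitutes 0,
#' see [predict_colony_weights()]). Negative cubic output is clamped to 0
#' with a warning.
#'
#' @param model a `cubic_weight_model`.
#' @param n leaf count(s), >= 0.
#' @return Predicted fresh weight(s), g, or `NA` where not applicable.
#' @export
predict_fresh_weight <- function(model, n) {
  stopifnot(inherits(model, "cubic_weight_model"), all(n >= 0))
  out <- pracma::polyval(c(model$c3, model$c2, model$c1, model$c0), n)
  out[n <= model$validity_min_n] <- NA_real_
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning("negative fresh-weight prediction clamped to 0", call. = FALSE)
    out[neg] <- 0
  }
  out
}

#' Construct a weight surface model from known coefficients
#'
#' Fresh weight as a linear combination of `{n^3, n^2, n, rachis, 1}`: the
#' cubic leaf-count basis augmented with rachis length, which absorbs part
#' of the residual size variation at a given count.
#'
#' @param a3,a2,a1 leaf-count coefficients, g/leaf^3 .. g/leaf.
#' @param b1 rachis-length coefficient, g/mm.
#' @param a0 intercept, g.
#' @param rms_relative_error,n_fit optional diagnostics.
#' @return Object of class `surface_weight_model`.
#' @export
surface_weight_model <- function(a3, a2, a1, b1, a0,
                                 rms_relative_error = NA_real_,
                                 n_fit = NA_integer_) {
  stopifnot(is.na(rms_relative_error) || rms_relative_error >= 0)
  structure(
    list(a3 = a3, a2 = a2, a1 = a1, b1 = b1, a0 = a0,
         rms_relative_error = rms_relative_error, n_fit = n_fit),
    class = "surface_weight_model"
  )
}

#' Fit the bivariate weight surface (weight ~ leaf count + rachis length)
#'
#' @param leaf_count numeric vector (>= 6 values).
#' @param rachis_mm rachis lengths, mm.
#' @param weight_g fresh weights, g.
#' @return A [surface_weight_model()].
#' @export
fit_weight_surface <- function(leaf_count, rachis_mm, weight_g) {
  stopifnot(length(leaf_count) == length(weight_g),
            length(rachis_mm) == length(weight_g))
  if (length(leaf_count) < 6) {
    stop("need at least 6 (count, rachis, weight) triples", call. = FALSE)
  }
  X <- cbind(leaf_count^3, leaf_count^2, leaf_count, rachis_mm, 1)
  check_rank(X, "weight surface model")
  fit <- stats::lm.fit(X, weight_g)
  co <- unname(fit$coefficients)
  surface_weight_model(co[1], co[2], co[3], co[4], co[5],
                       rms_relative_error =
                         rms_relative_error(fit$fitted.values, weight_g),
                       n_fit = length(leaf_count))
}

#' Predict fresh weight from leaf count and rachis length
#'
#' @param model a `surface_weight_model`.
#' @param n leaf count(s).
#' @param rachis_mm rachis length(s), mm.
#' @return Predicted fresh weight(s), g; negatives clamped to 0 with a
#'   warning.
#' @export
predict_surface_weight <- function(model, n, rachis_mm) {
  stopifnot(inherits(model, "surface_weight_model"))
  out <- model$a3 * n^3 + model$a2 * n^2 + model$a1 * n +
    model$b1 * rachis_mm + model$a0
  if (any(out < 0)) {
    warning("negative fresh-weight prediction clamped to 0", call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' Construct a dry-weight model from known coefficients
#'
#' @param d3,d2,d1,d0 cubic coefficients of dry weight on fresh weight.
#' @param rms_relative_error,n_fit optional diagnostics.
#' @return Object of class `dry_weight_model`.
#' @export
dry_weight_model <- function(d3, d2, d1, d0, rms_relative_error = NA_real_,
                             n_fit = NA_integer_) {
  stopifnot(is.na(rms_relative_error) || rms_relative_error >= 0)
  structure(
    list(d3 = d3, d2 = d2, d1 = d1, d0 = d0,
         rms_relative_error = rms_relative_error, n_fit = n_fit),
    class = "dry_weight_model"
  )
}

#' Fit the dry-weight model (dry ~ fresh, cubic)
#'
#' Dry weight is the more stable biomass measure (living colonies hold a
#' highly variable amount of seawater); this cubic converts fresh weights
#' -- measured or predicted -- into dry biomass.
#'
#' @param fresh_g fresh weights, g (>= 5 values, >= 4 distinct).
#' @param dry_g dry weights, g.
#' @return A [dry_weight_model()].
#' @export
fit_dry_weight <- function(fresh_g, dry_g) {
  stopifnot(length(fresh_g) == length(dry_g))
  if (length(fresh_g) < 5) {
    stop("need at least 5 (fresh, dry) pairs", call. = FALSE)
  }
  if (length(unique(fresh_g)) < 4) {
    stop("cannot fit dry weight model: fewer than 4 distinct fresh weights (rank deficient)",
         call. = FALSE)
  }
  X <- cbind(fresh_g^3, fresh_g^2, fresh_g, 1)
  check_rank(X, "dry weight model")
  fit <- stats::lm.fit(X, dry_g)
  co <- unname(fit$coefficients)
  dry_weight_model(co[1], co[2], co[3], co[4],
                   rms_relative_error =
                     rms_relative_error(fit$fitted.values, dry_g),
                   n_fit = length(fresh_g))
}

#' Predict dry weight from fresh weight
#'
#' @param model a `dry_weight_model`.
#' @param fresh_g fresh weight(s), g.
#' @return Predicted dry weight(s), g; negatives clamped to 0 with a
#'   warning.
#' @export
predict_dry_weight <- function(model, fresh_g) {
  stopifnot(inherits(model, "dry_weight_model"))
  out <- pracma::polyval(c(model$d3, model$d2, model$d1, model$d0), fresh_g)
  if (any(out < 0)) {
    warning("negative dry-weight prediction clamped to 0", call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' @export
print.linear_size_model <- function(x, ...) {
  cat(sprintf("Linear size model: length = %.4g * n + %.4g mm\n",
              x$slope, x$intercept))
  cat(sprintf("  r = %.3f, RMS relative error = %.1f%%, n = %s\n",
              x$correlation, 100 * x$rms_relative_error, x$n_fit))
  invisible(x)
}

#' @export
print.cubic_weight_model <- function(x, ...) {
  cat(sprintf("Cubic fresh-weight model (valid for n > %g):\n",
              x$validity_min_n))
  cat(sprintf("  w = %.4g n^3 + %.4g n^2 + %.4g n + %.4g g\n",
              x$c3, x$c2, x$c1, x$c0))
  cat(sprintf("  RMS relative error = %.1f%%, n = %s\n",
              100 * x$rms_relative_error, x$n_fit))
  invisible(x)
}

#' @export
print.surface_weight_model <- function(x, ...) {
  cat("Fresh-weight surface model:\n")
  cat(sprintf("  w = %.4g n^3 + %.4g n^2 + %.4g n + %.4g lr + %.4g g\n",
              x$a3, x$a2, x$a1, x$b1, x$a0))
  cat(sprintf("  RMS relative error = %.1f%%, n = %s\n",
              100 * x$rms_relative_error, x$n_fit))
  invisible(x)
}

#' @export
print.dry_weight_model <- function(x, ...) {
  cat("Dry-weight model:\n")
  cat(sprintf("  wd = %.4g wf^3 + %.4g wf^2 + %.4g wf + %.4g g\n",
              x$d3, x$d2, x$d1, x$d0))
  cat(sprintf("  RMS relative error = %.1f%%, n = %s\n",
              100 * x$rms_relative_error, x$n_fit))
  invisible(x)
}
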