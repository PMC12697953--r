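#' Half-normal log-density
#'
#' Density `sqrt(2/pi)/sigma * exp(-x^2 / (2 sigma^2))` on `x >= 0`; the
#' workhorse for non-negative residuals such as displacement from a predicted
#' position or the distance between daughter cells.
#'
#' @param x non-negative value(s).
#' @param sigma scale (> 0).
#' @return log-density, vectorised over `x`.
#' @export
halfnormal_logpdf <- function(x, sigma) {
  if (any(x < 0)) uat_abort("half-normal support is x >= 0", "uat_error_domain")
  stopifnot(sigma > 0)
  0.5 * log(2 / pi) - log(sigma) - x^2 / (2 * sigma^2)
}

#' Normal log-density
#' @param x value(s).
#' @param mu mean.
#' @param sigma standard deviation (> 0).
#' @return log-density, vectorised over `x`.
#' @export
normal_logpdf <- function(x, mu, sigma) {
  stopifnot(sigma > 0)
  -log(sigma * sqrt(2 * pi)) - (x - mu)^2 / (2 * sigma^2)
}

#' Minimal axial angle difference
#'
#' Orientations of rod-shaped cells are axial (defined mod pi, no head/tail),
#' so the difference between two major-axis angles is folded into
#' `[0, pi/2]`; a 180-degree flip of a segmented rod costs nothing.
#'
#' @param a,b angles in radians.
#' @return minimal axial difference in `[0, pi/2]`, vectorised.
#' @export
axial_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' Numeric parameters of the assignment models
#'
#' @param dt minutes per processed frame (the physical imaging interval).
#' @param colony_rate colony area growth rate per minute.
#' @param sigma_move displacement scale in px per sqrt(min); the migration /
#'   division position residual is scored with scale `sigma_move * sqrt(dt)`
#'   (diffusive motion).
#' @param sigma_area relative scale of the area prediction residual
#'   (dimensionless ratio around 1).
#' @param sigma_angle scale (rad) of the cell rotation between consecutive
#'   frames in a migration.
#' @param mu_div_angle,sigma_div_angle mean and scale (rad) of the axial angle
#'   between the major axes of the two daughters of a division ("snapping"
#'   geometry; mean 0 = aligned daughters).
#' @param sigma_div_dist scale (px) of the centre-to-centre distance of
#'   daughter cells.
#' @param sigma_growth scale of the per-interval area growth factor around its
#'   colony-level mean `exp(colony_rate * dt)`.
#' @param lambda_appear,lambda_disappear constant log-penalties for appearance
#'   and disappearance assignments (typically <= 0).
#' @param r_max candidate radius in px: assignments moving a cell farther than
#'   this are never proposed. Defaults to `40 * sqrt(dt)`.
#' @param d_div_max maximal daughter-daughter distance for division candidates
#'   (defaults to `r_max`).
#' @param growth_clip clipping interval for the self-learned growth factor.
#' @return a list of class `uat_params`.
#' @export
model_params <- function(dt = 1, colony_rate = 0.01,
                         sigma_move = 5, sigma_area = 0.1,
                         sigma_angle = 0.3,
                         mu_div_angle = 0, sigma_div_angle = 0.3,
                         sigma_div_dist = 8, sigma_growth = 0.1,
                         lambda_appear = -20, lambda_disappear = -20,
                         r_max = 40 * sqrt(dt), d_div_max = r_max,
                         growth_clip = c(0.5, 4)) {
  p <- list(dt = dt, colony_rate = colony_rate, sigma_move = sigma_move,
            sigma_area = sigma_area, sigma_angle = sigma_angle,
            mu_div_angle = mu_div_angle, sigma_div_angle = sigma_div_angle,
            sigma_div_dist = sigma_div_dist, sigma_growth = sigma_growth,
            lambda_appear = lambda_appear, lambda_disappear = lambda_disappear,
            r_max = r_max, d_div_max = d_div_max, growth_clip = growth_clip)
  sigmas <- c(p$sigma_move, p$sigma_area, p$sigma_angle, p$sigma_div_angle,
              p$sigma_div_dist, p$sigma_growth)
  if (any(sigmas <= 0) || p$r_max <= 0) {
    uat_abort("all model scales and r_max must be positive",
              "uat_error_bad_params")
  }
  structure(p, class = "uat_params")
}

config_names <- function() {
  c("NN", "FO", "FO+O", "FO+G", "FO+DD", "FO+G+O+DD")
}

canonical_config_name <- function(name) {
  if (name %in% config_names()) return(name)
  if (name == "FO+O+G+DD") return("FO+G+O+DD")
  uat_abort(sprintf("unknown tracking configuration '%s'", name),
            "uat_error_unknown_config")
}

#' Assemble a named tracking configuration
#'
#' The six studied compositions of the univariate models:
#' \describe{
#'   \item{NN}{nearest neighbour baseline: zero cell motion and growth
#'     assumed.}
#'   \item{FO}{first order: each cell's next position and area are predicted
#'     from its own past displacement and growth (self-learning).}
#'   \item{FO+O}{adds the orientation model (migration rotation and daughter
#'     "snapping" angle).}
#'   \item{FO+G}{adds the colony-growth model on the per-interval area ratio.}
#'   \item{FO+DD}{adds the half-normal division-distance model on daughter
#'     separation.}
#'   \item{FO+G+O+DD}{the composite of all models.}
#' }
#' Time-dependent scales adjust to the imaging interval: the displacement scale
#' is `sigma_move * sqrt(dt)` and the expected growth factor is
#' `exp(colony_rate * dt)`.
#'
#' @param name one of `NN`, `FO`, `FO+O`, `FO+G`, `FO+DD`, `FO+G+O+DD` (the
#'   alias `FO+O+G+DD` is accepted).
#' @param dt minutes per processed frame.
#' @param colony_rate colony area growth rate per minute.
#' @param ... overrides passed to [model_params()].
#' @return list of class `uat_config` with flags `use_first_order`,
#'   `use_orientation`, `use_growth`, `use_div_distance` and a `params` entry.
#' @export
make_config <- function(name, dt = 1, colony_rate = 0.01, ...) {
  name <- canonical_config_name(name)
  flags <- switch(name,
    "NN"        = c(FALSE, FALSE, FALSE, FALSE),
    "FO"        = c(TRUE,  FALSE, FALSE, FALSE),
    "FO+O"      = c(TRUE,  TRUE,  FALSE, FALSE),
    "FO+G"      = c(TRUE,  FALSE, TRUE,  FALSE),
    "FO+DD"     = c(TRUE,  FALSE, FALSE, TRUE),
    "FO+G+O+DD" = c(TRUE,  TRUE,  TRUE,  TRUE))
  structure(list(name = name,
                 use_first_order = flags[1], use_orientation = flags[2],
                 use_growth = flags[3], use_div_distance = flags[4],
                 params = model_params(dt = dt, colony_rate = colony_rate, ...)),
            class = "uat_config")
}

#' @export
print.uat_config <- function(x, ...) {
  cat(sprintf("<uat_config> %s (dt = %g min, colony_rate = %g /min)\n",
              x$name, x$params$dt, x$params$colony_rate))
  invisible(x)
}

default_features <- function(config, ids) {
  data.frame(id = ids, vx = 0, vy = 0,
             g = exp(config$params$colony_rate * config$params$dt))
}

#' Predict next-frame position and area
#'
#' NN keeps the current state unchanged (zero motion, zero growth); FO
#' extrapolates each cell with its own last displacement and growth factor:
#' `pos + v * dt`, `area * g`. Roots carry the defaults `v = (0, 0)` and
#' `g = exp(colony_rate * dt)`.
#'
#' @param config a `uat_config`.
#' @param det detection table rows (the sources at frame t).
#' @param features data.frame with `id`, `vx`, `vy`, `g` (per-cell history
#'   features, e.g. from [estimate_velocity()] / [estimate_growth_factor()]);
#'   `NULL` uses root defaults for all cells.
#' @return data.frame with `id`, `px`, `py`, `parea`.
#' @export
predict_state <- function(config, det, features = NULL) {
  if (!config$use_first_order) {
    # NN: zero motion, zero growth
    features <- default_features(config, det$id)
    features$g <- 1
  } else if (is.null(features)) {
    features <- default_features(config, det$id)
  }
  m <- match(det$id, features$id)
  dt <- config$params$dt
  data.frame(id = det$id,
             px = det$x + features$vx[m] * dt,
             py = det$y + features$vy[m] * dt,
             parea = det$area * features$g[m])
}

#' Score migration assignments
#'
#' Joint log-likelihood (sum of univariate log-densities, the models being
#' composed as independent factors): half-normal on the distance between the
#' observed and predicted position (scale `sigma_move * sqrt(dt)`); normal on
#' the observed/predicted area ratio around 1; optionally normal on the axial
#' rotation angle (O model); optionally normal on the raw area growth factor
#' around `exp(colony_rate * dt)` (G model).
#'
#' @param config a `uat_config`.
#' @param src source detections (frame t), one row per candidate.
#' @param tgt target detections (frame t+1), row-aligned with `src`.
#' @param features per-source history features (see [predict_state()]).
#' @return numeric vector of log-scores.
#' @export
score_migration <- function(config, src, tgt, features = NULL) {
  p <- config$params
  pred <- predict_state(config, src, features)
  d <- sqrt((tgt$x - pred$px)^2 + (tgt$y - pred$py)^2)
  s <- halfnormal_logpdf(d, p$sigma_move * sqrt(p$dt)) +
    normal_logpdf(tgt$area / pred$parea, 1, p$sigma_area)
  if (config$use_orientation) {
    s <- s + normal_logpdf(axial_diff(src$orientation, tgt$orientation),
                           0, p$sigma_angle)
  }
  if (config$use_growth) {
    s <- s + normal_logpdf(tgt$area / src$area, exp(p$colony_rate * p$dt),
                           p$sigma_growth)
  }
  s
}

#' Score division assignments
#'
#' Symmetric in the two daughters: half-normal on the distance between the
#' daughter midpoint and the predicted mother position; normal on the summed
#' daughter area over the predicted area; optionally normal on the axial angle
#' between the daughters' major axes around `mu_div_angle` (the "snapping"
#' division geometry, O model); optionally half-normal on the daughter
#' centre-to-centre distance (DD model).
#'
#' @param config a `uat_config`.
#' @param src mother detections (frame t), one row per candidate.
#' @param tgt1,tgt2 daughter detections (frame t+1), row-aligned with `src`.
#' @param features per-source history features.
#' @return numeric vector of log-scores.
#' @export
score_division <- function(config, src, tgt1, tgt2, features = NULL) {
  p <- config$params
  pred <- predict_state(config, src, features)
  mx <- (tgt1$x + tgt2$x) / 2
  my <- (tgt1$y + tgt2$y) / 2
  d <- sqrt((mx - pred$px)^2 + (my - pred$py)^2)
  s <- halfnormal_logpdf(d, p$sigma_move * sqrt(p$dt)) +
    normal_logpdf((tgt1$area + tgt2$area) / pred$parea, 1, p$sigma_area)
  if (config$use_orientation) {
    s <- s + normal_logpdf(axial_diff(tgt1$orientation, tgt2$orientation),
                           p$mu_div_angle, p$sigma_div_angle)
  }
  if (config$use_div_distance) {
    sep <- sqrt((tgt1$x - tgt2$x)^2 + (tgt1$y - tgt2$y)^2)
    s <- s + halfnormal_logpdf(sep, p$sigma_div_dist)
  }
  s
}

#' Appearance / disappearance log-penalties
#'
#' Constant log-scores handling cells entering or leaving the field of view and
#' segmentation artifacts. They must be more negative than a plausible
#' migration score so that linking is preferred whenever it is credible.
#'
#' @param config a `uat_config`.
#' @param n number of assignments to score.
#' @return numeric vector of length `n`.
#' @export
score_appear <- function(config, n = 1) {
  rep(config$params$lambda_appear, n)
}

#' @rdname score_appear
#' @export
score_disappear <- function(config, n = 1) {
  rep(config$params$lambda_disappear, n)
}
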