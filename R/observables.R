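#' Infection probability of a social cluster
#'
#' The model's central identification: the probability of finding the virus
#' (walker) in a cluster is read as the probability that a member of that
#' cluster becomes infected — virion concentration in the cluster determines
#' infection risk there.  Computationally this relabels an occupancy
#' trajectory as an infection-probability trajectory.
#'
#' @param traj a `uw_trajectory` (from [solve_master()],
#'   [solve_return_closed()], [solve_oracle()] or [empirical_trajectory()]).
#' @return The same trajectory with a `quantity` column set to
#'   `"infection"`.
#' @export
infection_probability <- function(traj) {
  stopifnot(inherits(traj, "uw_trajectory"))
  traj$quantity <- "infection"
  traj
}

#' Herd-immunity trajectory
#'
#' The probability of *not* becoming infected, `1 - P_I(C, t)`: an integral
#' immunity that approaches `1 - t^(-a)` with exponent `a = ln(p)/Delta`.
#' For the origin's own cluster it grows monotonically from 0 towards
#' `1 - p^(-n) * size`.
#'
#' @param traj an infection-probability `uw_trajectory`.
#' @return A trajectory with `probability = 1 - P_I` and `quantity =
#'   "immunity"`.
#' @export
herd_immunity <- function(traj) {
  stopifnot(inherits(traj, "uw_trajectory"))
  traj$probability <- 1 - traj$probability
  traj$quantity <- "immunity"
  traj
}

#' Theoretical power-law exponent
#'
#' For linearly growing barriers the infection probability decays as
#' `t^(-a)` with `a = ln(p) / Delta`: the spreading entropy of a `p`-way
#' uniform split divided by the one-step barrier.  Doubling the barrier
#' halves the exponent; richer branching (larger `p`) speeds the approach
#' to herd immunity.
#'
#' @param p branching index (`>= 2`).
#' @param delta one-step barrier (`> 0`).
#' @return `log(p) / delta`.
#' @examples
#' theoretical_exponent(2, 2 * log(2)) # 0.5
#' @export
theoretical_exponent <- function(p, delta) {
  stopifnot(all(p >= 2), all(delta > 0))
  log(p) / delta
}

#' Spreading entropy of a cluster split
#'
#' Shannon entropy (in nats) of the distribution `q` with which infection
#' spreads from a cluster into its `p` subclusters:
#' `E = -sum_i q_i ln q_i`, maximal (`ln p`) for the uniform split.  With a
#' uniform split the decay exponent is `E / Delta`; for nonuniform `q` the
#' same formula is a stated conjecture, and downstream reports label the
#' resulting `E / Delta` as conjectured.
#'
#' @param q probability vector over subclusters (must sum to 1; `0 ln 0`
#'   counts as 0).
#' @return Entropy in nats, in `[0, log(length(q))]`.
#' @examples
#' spreading_entropy(rep(1 / 4, 4)) # log(4)
#' @export
spreading_entropy <- function(q) {
  if (any(!is.finite(q)) || any(q < 0))
    stop("`q` must be a nonnegative probability vector", call. = FALSE)
  if (abs(sum(q) - 1) > 1e-8)
    stop("`q` must sum to 1", call. = FALSE)
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Conjectured decay exponent from a spreading distribution
#'
#' `E(q) / Delta`.  Exact (`= ln(p)/Delta`) when `q` is uniform; for
#' nonuniform `q` the value is returned with `conjectured = TRUE`.
#'
#' @param q probability vector over the `p` subclusters.
#' @param delta one-step barrier.
#' @return A tibble with columns `entropy`, `exponent` and `conjectured`.
#' @export
entropy_exponent <- function(q, delta) {
  stopifnot(delta > 0)
  E <- spreading_entropy(q)
  tibble::tibble(
    entropy = E,
    exponent = E / delta,
    conjectured = max(abs(q - 1 / length(q))) > 1e-12
  )
}

#' Fit the power-law decay exponent of a trajectory
#'
#' Least-squares fit of `log(P - plateau)` against `log(t)`.  On a finite
#' tree the return probability settles on the uniform plateau `p^(-n)`
#' rather than decaying to zero, so the plateau is subtracted before the
#' log-log fit; without the correction the fitted exponent is biased
#' downward near saturation.  The fit window keeps the grid points whose
#' plateau-corrected probability lies inside `band` — early transient
#' (corrected P near 1) and saturation (corrected P comparable to the
#' plateau) are both excluded.
#'
#' @param traj a return-probability `uw_trajectory` on a log-spaced grid
#'   spanning several decades (origin-singleton subject).
#' @param band keep points with `P - plateau` inside this interval; default
#'   `c(10 * plateau, 0.1)`.
#' @param plateau long-time limit to subtract; defaults to `p^(-n)` taken
#'   from the trajectory's model.
#' @return An object of class `uw_powerfit` with the fitted exponent
#'   (`exponent_hat`, reported positive), its standard error, the time
#'   window used, and the theoretical exponent when the model's profile is
#'   linear.  Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' hm <- hop_model(social_tree(2, 8), barrier_profile(delta = 2 * log(2)))
#' traj <- solve_return_closed(hm, recommended_time_grid(hm))
#' fit_power_law(traj)
#' @export
fit_power_law <- function(traj, band = NULL, plateau = NULL) {
  stopifnot(inherits(traj, "uw_trajectory"))
  model <- attr(traj, "model")
  if (is.null(plateau)) {
    if (is.null(model)) stop("supply `plateau` for model-free trajectories",
                             call. = FALSE)
    plateau <- model$tree$p^(-as.numeric(model$tree$n))
  }
  if (is.null(band)) band <- c(10 * plateau, 0.1)
  corrected <- traj$probability - plateau
  keep <- is.finite(corrected) & corrected >= band[1] & corrected <= band[2] &
    traj$time > 0
  if (sum(keep) < 3L)
    stop(paste0("power-law fit infeasible: fewer than 3 grid points with ",
                "plateau-corrected probability in [",
                format(band[1]), ", ", format(band[2]), "]; ",
                "use a deeper tree or a longer log-spaced grid"),
         call. = FALSE)
  fit <- stats::lm(log(corrected[keep]) ~ log(traj$time[keep]))
  sm <- summary(fit)
  theory <- if (!is.null(model) && model$profile$mode == "linear")
    theoretical_exponent(model$tree$p, model$profile$delta) else NA_real_
  structure(
    list(
      exponent_hat = -unname(stats::coef(fit)[2L]),
      stderr = unname(sm$coefficients[2L, 2L]),
      intercept = unname(stats::coef(fit)[1L]),
      window = range(traj$time[keep]),
      n_points = sum(keep),
      plateau = plateau,
      band = band,
      r_squared = sm$r.squared,
      theory = theory,
      data = tibble::tibble(time = traj$time[keep], corrected = corrected[keep])
    ),
    class = "uw_powerfit"
  )
}

#' @export
print.uw_powerfit <- function(x, ...) {
  cat(sprintf("Power-law decay fit: P(t) - plateau ~ t^(-a)\n"))
  cat(sprintf("  a_hat = %.4f (se %.2g), %d points, t in [%.3g, %.3g]\n",
              x$exponent_hat, x$stderr, x$n_points, x$window[1], x$window[2]))
  if (is.finite(x$theory))
    cat(sprintf("  theoretical a = ln(p)/Delta = %.4f (rel. err %.1f%%)\n",
                x$theory, 100 * abs(x$exponent_hat - x$theory) / x$theory))
  invisible(x)
}

#' Exact mean social distance travelled by the spreader
#'
#' `<d(t)> = sum_y d(origin, y) P(y, t)`: the expected ultrametric distance
#' between the walker and its origin, computed from the analytic spectral
#' solution by summing over distance classes.  Starts at 0, grows
#' monotonically, saturates at the uniform average distance
#' `sum_m m (p-1) p^(m-1) / p^n`; in the scaling regime it grows as
#' `log(t) / Delta`.
#'
#' @param model a [hop_model()].
#' @param times nonnegative time grid.
#' @param origin starting state label (the result is origin-independent).
#' @return A tibble with columns `time` and `mean_distance`.
#' @export
mean_distance_exact <- function(model, times, origin = 0) {
  occ <- class_occupancy(model, times, origin = origin)
  occ |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      mean_distance = sum(.data$distance * .data$class_probability),
      .groups = "drop"
    )
}

#' Saturation value of the mean social distance
#'
#' The mean ultrametric distance from any fixed point under the uniform
#' distribution: the long-time limit of [mean_distance_exact()].
#'
#' @param tree a [social_tree()].
#' @return A single number in `(0, n)`.
#' @export
uniform_mean_distance <- function(tree) {
  check_tree(tree)
  sizes <- distance_class_sizes(tree)
  sum(sizes$distance * sizes$n_states) / tree$n_states
}

#' Fit the logarithmic growth law of the mean distance
#'
#' In the scaling regime the mean social distance grows as
#' `<d(t)> ~ log(t) / Delta`.  Fits a least-squares slope of `mean_distance`
#' against `log(time)` over a pre-saturation window, selected as the grid
#' points where the mean distance lies between the given fractions of its
#' saturation value (early transient and saturation excluded).
#'
#' @param dist_traj a tibble with columns `time` and `mean_distance`, as
#'   returned by [mean_distance_exact()] or [empirical_mean_distance()].
#' @param saturation the saturation value; defaults to
#'   [uniform_mean_distance()] of the model attached to `dist_traj`, and
#'   must be given for model-free input.
#' @param window_frac keep points with `mean_distance` between these
#'   fractions of `saturation`.
#' @return An object of class `uw_logfit`: `slope_hat` (estimate of
#'   `1/Delta`), `stderr`, `window`, `n_points`.  Methods: [tidy()],
#'   [glance()].
#' @export
fit_log_growth <- function(dist_traj, saturation = NULL,
                           window_frac = c(0.15, 0.7)) {
  stopifnot(all(c("time", "mean_distance") %in% names(dist_traj)))
  if (is.null(saturation)) {
    model <- attr(dist_traj, "model")
    if (is.null(model)) stop("supply `saturation` for model-free input",
                             call. = FALSE)
    saturation <- uniform_mean_distance(model$tree)
  }
  md <- dist_traj$mean_distance
  keep <- dist_traj$time > 0 & md >= window_frac[1] * saturation &
    md <= window_frac[2] * saturation
  if (sum(keep) < 3L)
    stop("log-growth fit infeasible: window saturated or empty; increase n or extend the grid",
         call. = FALSE)
  fit <- stats::lm(md[keep] ~ log(dist_traj$time[keep]))
  sm <- summary(fit)
  structure(
    list(
      slope_hat = unname(stats::coef(fit)[2L]),
      stderr = unname(sm$coefficients[2L, 2L]),
      window = range(dist_traj$time[keep]),
      n_points = sum(keep),
      saturation = saturation,
      r_squared = sm$r.squared
    ),
    class = "uw_logfit"
  )
}

#' @export
print.uw_logfit <- function(x, ...) {
  cat("Logarithmic growth fit: <d(t)> ~ slope * log(t)\n")
  cat(sprintf("  slope_hat = %.4f (se %.2g, ~ 1/Delta), %d points, t in [%.3g, %.3g]\n",
              x$slope_hat, x$stderr, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy uw_powerfit
#' @export
tidy.uw_powerfit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "intercept"),
    estimate = c(x$exponent_hat, x$intercept),
    std.error = c(x$stderr, NA_real_)
  )
}

#' @method glance uw_powerfit
#' @export
glance.uw_powerfit <- function(x, ...) {
  tibble::tibble(
    exponent_hat = x$exponent_hat,
    std.error = x$stderr,
    theory = x$theory,
    rel.error = if (is.finite(x$theory))
      abs(x$exponent_hat - x$theory) / x$theory else NA_real_,
    t_min = x$window[1], t_max = x$window[2],
    n_points = x$n_points,
    r.squared = x$r_squared
  )
}

#' @method tidy uw_logfit
#' @export
tidy.uw_logfit <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$slope_hat, std.error = x$stderr)
}

#' @method glance uw_logfit
#' @export
glance.uw_logfit <- function(x, ...) {
  tibble::tibble(
    slope_hat = x$slope_hat, std.error = x$stderr,
    t_min = x$window[1], t_max = x$window[2],
    n_points = x$n_points, r.squared = x$r_squared
  )
}

#' Export a power-law fit report as JSON
#'
#' @param fit a `uw_powerfit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "uw_powerfit"))
  jsonlite::write_json(
    list(
      exponent_hat = fit$exponent_hat,
      stderr = fit$stderr,
      theoretical_exponent = fit$theory,
      relative_error = if (is.finite(fit$theory))
        abs(fit$exponent_hat - fit$theory) / fit$theory else NULL,
      window = fit$window,
      n_points = fit$n_points,
      plateau = fit$plateau,
      band = fit$band,
      r_squared = fit$r_squared
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
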