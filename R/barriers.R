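#' Social barrier profile
#'
#' Crossing `m` levels of social hierarchy means surmounting the barrier
#' `Delta_m`.  Barriers must grow strictly with the number of levels crossed.
#' The default profile is linear, `Delta_m = m * delta`: every branch point
#' adds the same one-step barrier `delta`, so a distance-2 hop costs
#' `2 * delta`, and so on.  A custom strictly increasing sequence can be
#' given instead.
#'
#' @param delta one-step barrier `Delta > 0` (dimensionless energy) for the
#'   linear profile.
#' @param heights explicit strictly increasing positive sequence
#'   `Delta_1 < Delta_2 < ...` for a custom profile (overrides `delta`).
#'
#' @return An object of class `barrier_profile` with elements `mode`
#'   (`"linear"` or `"custom"`), `delta` (linear mode) and `heights`
#'   (custom mode).
#' @examples
#' barrier_profile(delta = 0.5)          # Delta_m = 0.5 m
#' barrier_profile(heights = c(1, 3, 9)) # custom, supports m <= 3
#' @export
barrier_profile <- function(delta = NULL, heights = NULL) {
  if (is.null(heights)) {
    if (is.null(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
      stop("`delta` must be a single positive number", call. = FALSE)
    structure(list(mode = "linear", delta = as.numeric(delta), heights = NULL),
              class = "barrier_profile")
  } else {
    heights <- as.numeric(heights)
    if (length(heights) < 1L || any(!is.finite(heights)) || any(heights <= 0))
      stop("`heights` must be positive and finite", call. = FALSE)
    if (length(heights) > 1L && any(diff(heights) <= 0))
      stop("`heights` must be strictly increasing", call. = FALSE)
    structure(list(mode = "custom", delta = NULL, heights = heights),
              class = "barrier_profile")
  }
}

#' @export
print.barrier_profile <- function(x, ...) {
  if (x$mode == "linear") {
    cat(sprintf("<barrier_profile> linear: Delta_m = m * %.6g\n", x$delta))
  } else {
    cat("<barrier_profile> custom:", paste(signif(x$heights, 6), collapse = " < "), "\n")
  }
  invisible(x)
}

#' Barrier height for an m-level hop
#'
#' @param profile a [barrier_profile()].
#' @param m number of hierarchy levels crossed (vectorised), `m >= 1`.
#' @return `Delta_m`.
#' @examples
#' barrier_height(barrier_profile(delta = 0.5), 3) # 1.5
#' @export
barrier_height <- function(profile, m) {
  stopifnot(inherits(profile, "barrier_profile"))
  m <- as.integer(m)
  if (any(is.na(m)) || any(m < 1L))
    stop("`m` must be >= 1", call. = FALSE)
  if (profile$mode == "linear") {
    m * profile$delta
  } else {
    if (any(m > length(profile$heights)))
      stop(sprintf("custom profile defines barriers only up to m = %d",
                   length(profile$heights)), call. = FALSE)
    profile$heights[m]
  }
}

#' Hop model: barrier-controlled walk rates on a social tree
#'
#' Couples a [social_tree()] with a [barrier_profile()].  The Arrhenius-type
#' weight for surmounting the `m`-level barrier is
#' `w(m) = rate_scale * exp(-Delta_m)`; it is the total jump rate from a
#' state into each of the `p - 1` sibling clusters across that barrier.
#' Within the destination cluster the rate is shared uniformly over its
#' `p^(m-1)` members, giving the per-ordered-pair transition rate
#' `w(m) / p^(m-1)` that populates the generator.  This normalisation is
#' what makes the relaxation rates scale as `R^m` with `R = exp(-Delta)`
#' and hence yields the power-law decay exponent `ln(p) / Delta`.
#'
#' @param tree a [social_tree()].
#' @param profile a [barrier_profile()]; a single number is promoted to a
#'   linear profile with that one-step barrier.
#' @param rate_scale positive overall rate multiplier (time-unit choice).
#'
#' @return An object of class `hop_model`.
#' @examples
#' hm <- hop_model(social_tree(2, 3), barrier_profile(delta = 1))
#' hop_weight(hm, 1:3)
#' @export
hop_model <- function(tree, profile, rate_scale = 1) {
  check_tree(tree)
  if (is.numeric(profile)) profile <- barrier_profile(delta = profile)
  stopifnot(inherits(profile, "barrier_profile"))
  if (profile$mode == "custom" && length(profile$heights) < tree$n)
    stop("custom profile must define barriers up to m = n", call. = FALSE)
  if (length(rate_scale) != 1L || !is.finite(rate_scale) || rate_scale <= 0)
    stop("`rate_scale` must be a single positive number", call. = FALSE)
  structure(
    list(tree = tree, profile = profile, rate_scale = as.numeric(rate_scale)),
    class = "hop_model"
  )
}

#' @export
print.hop_model <- function(x, ...) {
  print(x$tree)
  print(x$profile)
  if (x$rate_scale != 1) cat(sprintf("rate scale c = %.6g\n", x$rate_scale))
  invisible(x)
}

is_hop_model <- function(x) inherits(x, "hop_model")

check_model <- function(model) {
  if (!is_hop_model(model)) stop("expected a `hop_model`", call. = FALSE)
  model
}

#' Hop weight over an m-level barrier
#'
#' `w(m) = rate_scale * exp(-Delta_m)`: the total rate of jumping into one
#' sibling cluster across an `m`-level barrier.  For a linear profile this
#' is `rate_scale * R^m` with `R = exp(-delta)`.
#'
#' @param model a [hop_model()].
#' @param m levels crossed (vectorised), `1 <= m <= n`.
#' @return Positive hop weights, strictly decreasing in `m`.
#' @export
hop_weight <- function(model, m) {
  check_model(model)
  if (any(m > model$tree$n)) stop("`m` must be <= n", call. = FALSE)
  model$rate_scale * exp(-barrier_height(model$profile, m))
}

#' Per-pair transition rate at ultrametric distance m
#'
#' The generator's off-diagonal entry for an ordered pair of states at
#' distance `m`: the hop weight shared uniformly over the `p^(m-1)` members
#' of the destination cluster.
#'
#' @inheritParams hop_weight
#' @return `hop_weight(model, m) / p^(m-1)`.
#' @export
pair_rate <- function(model, m) {
  check_model(model)
  hop_weight(model, m) / model$tree$p^as.numeric(m - 1)
}

#' Probability of jumping to the nearest clusters
#'
#' `R = exp(-Delta)` for a linear profile: the walk's basic hop parameter.
#'
#' @param model a [hop_model()].
#' @return `exp(-Delta)` in (0, 1).
#' @export
nearest_hop_prob <- function(model) {
  check_model(model)
  if (model$profile$mode != "linear")
    stop("R = exp(-Delta) is defined for the linear profile", call. = FALSE)
  exp(-model$profile$delta)
}

#' Build the dense generator (rate matrix) of the walk
#'
#' The master equation of the walk is `dP/dt = Q P` with `Q[x, y] =
#' pair_rate(d(x, y))` off the diagonal — rates depend on the ultrametric
#' distance only — and diagonal entries set so every column (and by symmetry
#' every row) sums to zero.  The uniform distribution is stationary.
#'
#' @param model a [hop_model()].
#' @param cap refuse to materialise more than `cap` states; larger trees are
#'   handled implicitly through the analytic spectrum (see
#'   [generator_spectrum()], [solve_master()]).
#' @return Symmetric `p^n` x `p^n` rate matrix with zero row sums, labelled
#'   by state.
#' @export
build_generator <- function(model, cap = 4096) {
  check_model(model)
  tree <- model$tree
  if (tree$n_states > cap)
    stop(sprintf(paste0("tree has %s states, above the dense cap %d; ",
                        "use the analytic spectral path instead"),
                 format(tree$n_states, scientific = FALSE), cap), call. = FALSE)
  d <- distance_matrix(tree, cap = cap)
  Q <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  rates <- pair_rate(model, seq_len(tree$n))
  for (m in seq_len(tree$n)) Q[d == m] <- rates[m]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Analytic relaxation spectrum of the generator
#'
#' The hierarchical rate matrix diagonalises in closed form.  Beyond the
#' zero mode (the uniform stationary distribution), there are `n` distinct
#' relaxation rates, one per hierarchy level `m = 0 .. n-1`:
#' `eps_m = p^m r(m+1) + sum_{j > m} (p-1) p^(j-1) r(j)` with
#' `r(j) = pair_rate(model, j)`; the eigenspace of `eps_m` has dimension
#' `(p-1) p^(n-1-m)` (one copy per radius-(m+1) ball of sign patterns over
#' its `p` children).  For the linear profile this reduces to
#' `eps_m = c * ((p-R) R^(m+1) - (p-1) R^(n+1)) / (1-R)`, `R = exp(-Delta)`.
#'
#' @param model a [hop_model()].
#' @return A tibble with columns `level` (`NA` for the stationary mode, else
#'   `0..n-1`), `rate` (eigenvalue of `-Q`) and `multiplicity`; the
#'   multiplicities sum to `p^n`.
#' @export
generator_spectrum <- function(model) {
  check_model(model)
  tree <- model$tree
  p <- tree$p; n <- tree$n
  r <- pair_rate(model, seq_len(n))
  eps <- vapply(0:(n - 1L), function(m) {
    j <- (m + 1L):n
    p^as.numeric(m) * r[m + 1L] + sum((p - 1) * p^as.numeric(j - 1L) * r[j])
  }, numeric(1L))
  tibble::tibble(
    level = c(NA_integer_, 0:(n - 1L)),
    rate = c(0, eps),
    multiplicity = c(1, (p - 1) * p^as.numeric(n - 1L - (0:(n - 1L))))
  )
}

#' Closed-form relaxation rates for the linear profile
#'
#' `eps_m = c * ((p - R) R^(m+1) - (p - 1) R^(n+1)) / (1 - R)` with
#' `R = exp(-Delta)`, for `m = 0 .. n-1`.  Agrees with
#' [generator_spectrum()] and with numeric diagonalisation of
#' [build_generator()].
#'
#' @param model a [hop_model()] with a linear profile.
#' @return Numeric vector of the `n` nonzero relaxation rates.
#' @export
relaxation_rates <- function(model) {
  check_model(model)
  if (model$profile$mode != "linear")
    return(generator_spectrum(model)$rate[-1L])
  p <- model$tree$p; n <- model$tree$n
  R <- nearest_hop_prob(model)
  m <- 0:(n - 1L)
  model$rate_scale * ((p - R) * R^(m + 1) - (p - 1) * R^(n + 1)) / (1 - R)
}

#' Total exit rate from any state
#'
#' By symmetry every state has the same total exit rate
#' `sum_m (p-1) p^(m-1) pair_rate(m) = (p-1) sum_m hop_weight(m)`.
#'
#' @param model a [hop_model()].
#' @return A single positive rate.
#' @export
total_exit_rate <- function(model) {
  check_model(model)
  (model$tree$p - 1) * sum(hop_weight(model, seq_len(model$tree$n)))
}

#' Write a dense generator to CSV
#'
#' @param model a [hop_model()].
#' @param path output file.
#' @param cap dense-state cap as in [build_generator()].
#' @return `path`, invisibly.
#' @export
write_generator_csv <- function(model, path, cap = 4096) {
  Q <- build_generator(model, cap = cap)
  df <- as.data.frame(Q)
  df <- cbind(state = rownames(Q), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
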