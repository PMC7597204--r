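#' Logarithmically spaced time grid
#'
#' Asymptotics of the walk span many decades, so trajectories are sampled on
#' log-spaced grids by default.
#'
#' @param t_min,t_max positive endpoints.
#' @param points number of grid points.
#' @return Numeric vector of length `points`.
#' @export
log_time_grid <- function(t_min, t_max, points = 200) {
  stopifnot(t_min > 0, t_max > t_min, points >= 2)
  exp(seq(log(t_min), log(t_max), length.out = points))
}

#' Time grid adapted to the model's relaxation spectrum
#'
#' Spans from well before the fastest relaxation to well past the slowest
#' numerically representable one, so the full decay (and any power-law
#' window) falls inside the grid.
#'
#' @param model a [hop_model()].
#' @param points number of grid points.
#' @param pad multiplicative padding `(before fastest, after slowest)`.
#' @return Log-spaced time grid.
#' @export
recommended_time_grid <- function(model, points = 300, pad = c(1e-2, 1e2)) {
  eps <- generator_spectrum(model)$rate[-1L]
  eps <- eps[eps > 1e-290] # drop modes whose rates underflow double precision
  if (!length(eps)) stop("all relaxation rates underflow; reduce Delta or n",
                         call. = FALSE)
  log_time_grid(pad[1] / max(eps), pad[2] / min(eps), points)
}

# P_d(t) for d = 0..n: probability of finding the walker at one *specific*
# state at ultrametric distance d from its start.  Depends on the origin only
# through d.  Returns a length(times) x (n+1) matrix, column d+1 <-> distance d.
#   P_d(t) = p^-n + sum_{m=0}^{n-1} a_m(d) exp(-eps_m t),
#   a_m(d) = p^-m [m >= d] - p^-(m+1) [m >= d-1]
class_state_probs <- function(model, times) {
  tree <- model$tree
  p <- tree$p; n <- tree$n
  eps <- generator_spectrum(model)$rate[-1L] # eps_0 .. eps_{n-1}
  m <- 0:(n - 1L)
  amp <- vapply(0:n, function(d) {
    p^(-as.numeric(m)) * (m >= d) - p^(-as.numeric(m) - 1) * (m >= d - 1L)
  }, numeric(n)) # n x (n+1)
  if (n == 1L) amp <- matrix(amp, nrow = 1L)
  E <- exp(-outer(times, eps)) # times x n
  E %*% amp + p^(-as.numeric(n))
}

subject_id <- function(subject) {
  if (is_social_ball(subject)) {
    if (length(subject$prefix) == 0L) "ball:root"
    else paste0("ball:", paste(subject$prefix, collapse = ""))
  } else {
    paste0("state:", format(subject, scientific = FALSE))
  }
}

new_trajectory <- function(df, model, origin) {
  attr(df, "model") <- model
  attr(df, "origin") <- origin
  class(df) <- c("uw_trajectory", class(df))
  df
}

#' @export
print.uw_trajectory <- function(x, ...) {
  cat(sprintf("# Occupancy trajectory (origin state %s)\n",
              format(attr(x, "origin"), scientific = FALSE)))
  NextMethod()
}

resolve_subjects <- function(model, subjects, origin) {
  if (is.null(subjects)) subjects <- list(origin)
  if (!is.list(subjects) || is_social_ball(subjects)) subjects <- list(subjects)
  subjects
}

#' Solve the master equation through the analytic spectrum
#'
#' Exact occupancy probabilities of the barrier-controlled walk started as a
#' delta mass at `origin`.  Works for any strictly increasing barrier
#' profile and for arbitrarily deep trees: because transition rates depend
#' on the ultrametric distance only, the solution is a sum of `n`
#' exponentials whose rates and amplitudes are known in closed form, so no
#' matrix is ever materialised.
#'
#' For a single-state subject at distance `d` from the origin the
#' probability is `P_d(t)`; for a ball subject it is the sum over the ball's
#' members (all of which fall into at most `n` distance classes).
#'
#' @param model a [hop_model()].
#' @param times nonnegative time grid.
#' @param origin starting state label (default 0).
#' @param subjects a subject or list of subjects whose occupancy probability
#'   is tracked: state labels and/or [social_ball()]s.  Default: the
#'   origin's own singleton (the return probability).
#' @return A `uw_trajectory` tibble with columns `time`, `probability`,
#'   `subject`, `origin`.
#' @examples
#' hm <- hop_model(social_tree(2, 3), barrier_profile(delta = 1))
#' solve_master(hm, times = c(0, 1, 10, 1e4))
#' @export
solve_master <- function(model, times, origin = 0, subjects = NULL) {
  check_model(model)
  stopifnot(all(times >= 0))
  tree <- model$tree
  subjects <- resolve_subjects(model, subjects, origin)
  Pd <- class_state_probs(model, times) # times x (n+1)
  p <- tree$p
  class_sizes <- c(1, (p - 1) * p^as.numeric(0:(tree$n - 1L))) # sizes of d = 0..n
  rows <- purrr::map(subjects, function(sub) {
    if (is_social_ball(sub)) {
      if (!identical(sub$tree$p, tree$p) || !identical(sub$tree$n, tree$n))
        stop("subject ball belongs to a different tree", call. = FALSE)
      N <- sub$radius
      if (ball_contains(sub, origin)) {
        # members sit at distances 0..N from the origin, whole classes at a time
        prob <- as.vector(Pd[, 1:(N + 1L), drop = FALSE] %*% class_sizes[1:(N + 1L)])
      } else {
        D <- ball_point_dist(sub, origin)
        prob <- ball_size(sub) * Pd[, D + 1L]
      }
    } else {
      d <- label_dist(tree, origin, sub)
      prob <- Pd[, d + 1L]
    }
    tibble::tibble(time = times, probability = prob,
                   subject = subject_id(sub))
  })
  df <- dplyr::bind_rows(rows)
  df$origin <- format(origin, scientific = FALSE)
  new_trajectory(df, model, origin)
}

#' Closed-form return probability for linear barriers
#'
#' The exact solution of the master equation for the walk started at a
#' single state, evaluated at that state: with `R = exp(-Delta)`,
#' \deqn{P(t) = p^{-n} + (1 - 1/p) \sum_{m=0}^{n-1} p^{-m}
#'       \exp\{-\epsilon_m t\},}
#' where the relaxation rates are
#' `eps_m = c ((p-R) R^(m+1) - (p-1) R^(n+1)) / (1-R)`.  As `t` grows the
#' sum of exponentials traverses a power-law window `P(t) ~ t^(-ln(p)/Delta)`
#' before settling on the uniform plateau `p^-n`.
#'
#' @param model a [hop_model()] with a linear barrier profile.
#' @param times nonnegative time grid.
#' @param origin starting state label (the return probability does not
#'   depend on it; kept for provenance).
#' @return A `uw_trajectory` tibble (`time`, `probability`, `subject`,
#'   `origin`).
#' @examples
#' hm <- hop_model(social_tree(2, 1), barrier_profile(delta = log(2)))
#' # two-state chain: P(t) = 1/2 + 1/2 exp(-t)
#' solve_return_closed(hm, c(0, 1, 2))
#' @export
solve_return_closed <- function(model, times, origin = 0) {
  check_model(model)
  if (model$profile$mode != "linear")
    stop("closed form requires the linear barrier profile; use solve_master()",
         call. = FALSE)
  stopifnot(all(times >= 0))
  p <- model$tree$p; n <- model$tree$n
  eps <- relaxation_rates(model)
  m <- 0:(n - 1L)
  prob <- p^(-as.numeric(n)) +
    (1 - 1 / p) * as.vector(exp(-outer(times, eps)) %*% p^(-as.numeric(m)))
  df <- tibble::tibble(time = times, probability = prob,
                       subject = subject_id(origin),
                       origin = format(origin, scientific = FALSE))
  new_trajectory(df, model, origin)
}

#' Brute-force master-equation solution via the matrix exponential
#'
#' Ground-truth oracle for small trees: diagonalises the dense generator
#' (symmetric, so by orthogonal eigendecomposition) and propagates the delta
#' initial condition exactly.  Used to validate [solve_master()] and
#' [solve_return_closed()]; prefer those in application code.
#'
#' @inheritParams solve_master
#' @param cap refuse above `cap` states (default 1024).
#' @return A `uw_trajectory` tibble as in [solve_master()].
#' @export
solve_oracle <- function(model, times, origin = 0, subjects = NULL, cap = 1024) {
  check_model(model)
  tree <- model$tree
  if (tree$n_states > cap)
    stop(sprintf("oracle limited to %d states", cap), call. = FALSE)
  stopifnot(all(times >= 0))
  subjects <- resolve_subjects(model, subjects, origin)
  Q <- build_generator(model, cap = cap)
  eg <- eigen(Q, symmetric = TRUE)
  v0 <- eg$vectors[as.integer(origin) + 1L, ] # row of V at the origin
  # P(x, t) = sum_k V[x,k] exp(lambda_k t) V[origin,k]
  Et <- exp(outer(times, eg$values)) # times x S
  P <- Et %*% (t(eg$vectors) * v0)   # times x S: P[t, x]
  rows <- purrr::map(subjects, function(sub) {
    if (is_social_ball(sub)) {
      members <- ball_members(sub, cap = cap)$label
      prob <- rowSums(P[, members + 1L, drop = FALSE])
    } else {
      prob <- P[, as.integer(sub) + 1L]
    }
    tibble::tibble(time = times, probability = prob, subject = subject_id(sub))
  })
  df <- dplyr::bind_rows(rows)
  df$origin <- format(origin, scientific = FALSE)
  new_trajectory(df, model, origin)
}

#' Full occupancy distribution over distance classes
#'
#' Exact probability content of each ultrametric distance class around the
#' origin: `class_prob(d, t) = N_d P_d(t)` with `N_d = (p-1) p^(d-1)` states
#' at distance `d` (`N_0 = 1`).
#'
#' @inheritParams solve_master
#' @return A tibble with columns `time`, `distance`, `n_states`,
#'   `state_probability` (per state) and `class_probability`.
#' @export
class_occupancy <- function(model, times, origin = 0) {
  check_model(model)
  stopifnot(all(times >= 0))
  tree <- model$tree
  p <- tree$p; n <- tree$n
  Pd <- class_state_probs(model, times)
  sizes <- c(1, (p - 1) * p^as.numeric(0:(n - 1L)))
  tidyr::expand_grid(time = times, distance = 0:n) |>
    dplyr::mutate(
      n_states = sizes[.data$distance + 1L],
      state_probability = as.vector(t(Pd)),
      class_probability = .data$n_states * .data$state_probability
    )
}

#' Write a trajectory to CSV
#'
#' Columns `t, probability, subject_id, origin_id`.
#'
#' @param traj a `uw_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(
    t = traj$time, probability = traj$probability,
    subject_id = traj$subject, origin_id = traj$origin
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
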