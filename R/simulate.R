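# jump-chain ingredients shared by single-walker and ensemble simulators:
# from every state the total exit rate is W = (p-1) sum_m w(m) and the hop
# spans m levels with probability (p-1) w(m) / W; the destination is uniform
# over the p^(m-1) (p-1)... i.e. uniform within the chosen distance class.
jump_class_probs <- function(model) {
  w <- hop_weight(model, seq_len(model$tree$n))
  pr <- (model$tree$p - 1) * w
  pr / sum(pr)
}

# vectorised jump: from labels `cur`, hop distances `m` -> new labels.
# keeps digits above level m, re-draws digit m-1 to a different value,
# randomises the m-1 lower digits.
jump_labels <- function(cur, m, p) {
  pm1 <- p^(m - 1)
  pm <- pm1 * p
  old_digit <- (cur %/% pm1) %% p
  new_digit <- (old_digit + sample.int(p - 1L, length(cur), replace = TRUE)) %% p
  low <- floor(stats::runif(length(cur)) * pm1) # uniform 0 .. p^(m-1)-1
  (cur %/% pm) * pm + new_digit * pm1 + low
}

#' Simulate one walker's exact event path
#'
#' Event-driven (Gillespie) sampling of the continuous-time walk: holding
#' times are exponential with the state-independent total exit rate
#' `(p-1) sum_m hop_weight(m)`; each event hops `m` levels with probability
#' proportional to `(p-1) hop_weight(m)` and lands uniformly within the
#' chosen distance class.  No time discretisation is involved, so paths are
#' exact draws from the master equation's process.
#'
#' @param model a [hop_model()].
#' @param t_max simulate events up to this time.
#' @param origin starting state label.
#' @param seed optional RNG seed for a reproducible path.
#' @return A tibble with columns `time` and `state`: the state entered at
#'   each event time, starting with (`0`, `origin`).
#' @export
walk_path <- function(model, t_max, origin = 0, seed = NULL) {
  check_model(model)
  stopifnot(t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- model$tree
  W <- total_exit_rate(model)
  q <- jump_class_probs(model)
  t <- 0; cur <- as.numeric(origin)
  times <- 0; states <- cur
  repeat {
    t <- t + stats::rexp(1L, rate = W)
    if (t > t_max) break
    m <- sample.int(tree$n, 1L, prob = q)
    cur <- jump_labels(cur, m, tree$p)
    times <- c(times, t); states <- c(states, cur)
  }
  tibble::tibble(time = times, state = states)
}

#' Simulate an ensemble of independent walkers
#'
#' Draws `walkers` independent exact paths from the walk and records the
#' state of each at every observation time.  Because the exit rate is the
#' same from every state, each walker's event times form a Poisson process;
#' events are generated for all walkers at once and applied in
#' per-walker order, so runs are fast and fully reproducible from `seed`.
#'
#' @param model a [hop_model()].
#' @param times observation grid (state recorded at each time).
#' @param walkers ensemble size.
#' @param origin starting state label for every walker.
#' @param seed RNG seed (required: ensemble runs are reproducible by
#'   contract).
#' @return An object of class `uw_ensemble`: a list with the run
#'   configuration and `states`, a `walkers x length(times)` matrix of state
#'   labels.
#' @examples
#' hm <- hop_model(social_tree(2, 3), barrier_profile(delta = 1))
#' run <- walk_ensemble(hm, times = c(0, 1, 5), walkers = 500, seed = 1)
#' empirical_trajectory(run)
#' @export
walk_ensemble <- function(model, times, walkers, origin = 0, seed) {
  check_model(model)
  stopifnot(walkers >= 1, all(times >= 0))
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for reproducible ensembles", call. = FALSE)
  set.seed(seed)
  tree <- model$tree
  times <- sort(times)
  t_max <- max(times)
  W <- total_exit_rate(model)
  q <- jump_class_probs(model)

  K <- stats::rpois(walkers, W * t_max)
  total <- sum(K)
  states <- matrix(as.numeric(origin), nrow = walkers, ncol = length(times))
  if (total > 0) {
    ev_walker <- rep.int(seq_len(walkers), K)
    ev_time <- stats::runif(total) * t_max
    o <- order(ev_walker, ev_time)
    ev_walker <- ev_walker[o]; ev_time <- ev_time[o]
    ev_class <- sample.int(tree$n, total, replace = TRUE, prob = q)
    ev_state <- numeric(total)
    start <- cumsum(c(0L, K))[seq_len(walkers)] # 0-based offset of each walker's events
    cur <- rep(as.numeric(origin), walkers)
    active <- which(K > 0L)
    r <- 1L
    while (length(active)) {
      idx <- start[active] + r
      cur[active] <- jump_labels(cur[active], ev_class[idx], tree$p)
      ev_state[idx] <- cur[active]
      r <- r + 1L
      active <- active[K[active] >= r]
    }
    for (w in which(K > 0L)) {
      rng <- (start[w] + 1L):(start[w] + K[w])
      pos <- findInterval(times, ev_time[rng])
      hit <- pos > 0L
      states[w, hit] <- ev_state[rng][pos[hit]]
    }
  }
  structure(
    list(model = model, origin = origin, times = times, walkers = walkers,
         seed = seed, states = states),
    class = "uw_ensemble"
  )
}

#' @export
print.uw_ensemble <- function(x, ...) {
  cat(sprintf(
    "<uw_ensemble> %d walkers from state %s, %d observation times, seed %s\n",
    x$walkers, format(x$origin, scientific = FALSE), length(x$times),
    format(x$seed)))
  invisible(x)
}

#' Per-time empirical occupancy counts
#'
#' @param run a `uw_ensemble` from [walk_ensemble()].
#' @return A tibble with columns `time`, `state`, `count`; counts at each
#'   time sum to the walker count.
#' @export
ensemble_occupancy <- function(run) {
  stopifnot(inherits(run, "uw_ensemble"))
  purrr::map_dfr(seq_along(run$times), function(j) {
    tab <- table(run$states[, j])
    tibble::tibble(time = run$times[j],
                   state = as.numeric(names(tab)),
                   count = as.integer(tab))
  })
}

#' Empirical occupancy probability of subjects
#'
#' The fraction of walkers found in each subject (state or ball) at each
#' observation time: the Monte-Carlo estimate of the exact trajectory from
#' [solve_master()].
#'
#' @param run a `uw_ensemble`.
#' @param subjects as in [solve_master()]; default the origin's singleton.
#' @return A `uw_trajectory` tibble (`time`, `probability`, `subject`,
#'   `origin`).
#' @export
empirical_trajectory <- function(run, subjects = NULL) {
  stopifnot(inherits(run, "uw_ensemble"))
  subjects <- resolve_subjects(run$model, subjects, run$origin)
  rows <- purrr::map(subjects, function(sub) {
    inside <- if (is_social_ball(sub)) {
      k <- length(sub$prefix)
      if (k == 0L) {
        matrix(TRUE, nrow(run$states), ncol(run$states))
      } else {
        p <- run$model$tree$p; n <- run$model$tree$n
        base <- sum(sub$prefix * p^as.numeric((n - 1L):(n - k)))
        blk <- p^as.numeric(n - k)
        run$states %/% blk == base %/% blk
      }
    } else {
      run$states == as.numeric(sub)
    }
    tibble::tibble(time = run$times,
                   probability = colMeans(inside),
                   subject = subject_id(sub))
  })
  df <- dplyr::bind_rows(rows)
  df$origin <- format(run$origin, scientific = FALSE)
  new_trajectory(df, run$model, run$origin)
}

#' Empirical mean social distance from the origin
#'
#' The average ultrametric distance between each walker's current state and
#' the common origin, per observation time: the Monte-Carlo counterpart of
#' [mean_distance_exact()].
#'
#' @param run a `uw_ensemble`.
#' @return A tibble with columns `time` and `mean_distance` (in `0..n`).
#' @export
empirical_mean_distance <- function(run) {
  stopifnot(inherits(run, "uw_ensemble"))
  p <- run$model$tree$p; n <- run$model$tree$n
  o <- as.numeric(run$origin)
  d <- matrix(0, nrow(run$states), ncol(run$states))
  for (m in seq_len(n)) {
    pm <- p^as.numeric(m - 1L)
    d[run$states %/% pm != o %/% pm] <- m
  }
  tibble::tibble(time = run$times, mean_distance = colMeans(d))
}
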