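#' Social clusters as ultrametric balls
#'
#' A social cluster is the set of types sharing a fixed prefix of the most
#' important coordinates.  Clusters are exactly the balls of the ultrametric:
#' fixing the first `k` coordinates gives the ball of radius `N = n - k`
#' around any of its members.  Balls are centre-free, so the canonical
#' representation is the prefix itself; any two balls are nested or disjoint.
#'
#' @param tree a [social_tree()].
#' @param prefix integer vector of `k` fixed leading coordinates,
#'   `0 <= k <= n` (the empty prefix is the whole space).
#'
#' @return An object of class `social_ball` with elements `tree`, `prefix`
#'   and `radius = n - length(prefix)`.
#' @examples
#' tr <- social_tree(2, 3)
#' social_ball(tr, c(0))          # the 4-member cluster {0,1,2,3}
#' ball_around(tr, center = 5, radius = 1)
#' @export
social_ball <- function(tree, prefix = integer(0)) {
  check_tree(tree)
  prefix <- as.integer(prefix)
  k <- length(prefix)
  if (k > tree$n)
    stop("prefix longer than the number of hierarchy levels", call. = FALSE)
  if (k > 0 && (any(is.na(prefix)) || any(prefix < 0L) || any(prefix >= tree$p)))
    stop(sprintf("prefix coordinates must lie in 0..%d", tree$p - 1L), call. = FALSE)
  structure(
    list(tree = tree, prefix = prefix, radius = tree$n - k),
    class = "social_ball"
  )
}

#' @export
print.social_ball <- function(x, ...) {
  pf <- if (length(x$prefix)) paste(x$prefix, collapse = "") else "<root>"
  cat(sprintf("<social_ball> prefix %s, radius %d, %s members\n",
              pf, x$radius,
              format(ball_size(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

is_social_ball <- function(x) inherits(x, "social_ball")

#' @rdname social_ball
#' @param center a member label (or coordinate vector) of the ball.
#' @param radius ball radius `N` in `0..n`: the ball contains every type
#'   within hierarchic distance `N` of the centre.
#' @export
ball_around <- function(tree, center, radius) {
  check_tree(tree)
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0L || radius > tree$n)
    stop("radius must lie in 0..n", call. = FALSE)
  cm <- if (length(center) == tree$n && tree$n > 1L) {
    coords_matrix(center, tree)
  } else {
    decode_label(tree, center)
  }
  k <- tree$n - radius
  social_ball(tree, cm[1L, seq_len(k)])
}

#' Number of ground-level members of a ball
#'
#' @param ball a [social_ball()].
#' @return `p^radius`.
#' @export
ball_size <- function(ball) {
  stopifnot(is_social_ball(ball))
  ball$tree$p^as.numeric(ball$radius)
}

#' Enumerate the members of a social cluster
#'
#' @param ball a [social_ball()].
#' @param cap refuse to enumerate more than `cap` members.
#' @return A tibble with one row per member: `label` plus coordinate columns
#'   `x0 .. x(n-1)`.
#' @examples
#' tr <- social_tree(2, 3)
#' ball_members(social_ball(tr, c(0)))$label # 0 1 2 3
#' @export
ball_members <- function(ball, cap = 4096) {
  stopifnot(is_social_ball(ball))
  tree <- ball$tree
  sz <- ball_size(ball)
  if (sz > cap)
    stop(sprintf("ball has %s members, above cap %d",
                 format(sz, scientific = FALSE), cap), call. = FALSE)
  # members form a contiguous label block starting at the prefix's base label
  base <- if (length(ball$prefix)) {
    sum(ball$prefix * tree$p^as.numeric((tree$n - 1L):(tree$n - length(ball$prefix))))
  } else 0
  labels <- base + 0:(sz - 1)
  cm <- decode_label(tree, labels)
  colnames(cm) <- paste0("x", 0:(tree$n - 1L))
  dplyr::bind_cols(tibble::tibble(label = labels), tibble::as_tibble(cm))
}

#' Membership test
#'
#' @param ball a [social_ball()].
#' @param labels state labels to test.
#' @return Logical vector.
#' @export
ball_contains <- function(ball, labels) {
  stopifnot(is_social_ball(ball))
  tree <- ball$tree
  k <- length(ball$prefix)
  if (k == 0L) return(rep(TRUE, length(labels)))
  cm <- decode_label(tree, labels)
  apply(cm[, seq_len(k), drop = FALSE], 1L,
        function(r) all(r == ball$prefix))
}

#' Split a cluster into its p subclusters
#'
#' Extends the ball's prefix by one coordinate in every possible way,
#' producing `p` disjoint balls whose union is the input ball.
#'
#' @param ball a [social_ball()] of radius at least 1.
#' @return List of `p` `social_ball`s.
#' @export
ball_children <- function(ball) {
  stopifnot(is_social_ball(ball))
  if (ball$radius == 0L)
    stop("a single-point cluster has no subclusters", call. = FALSE)
  lapply(0:(ball$tree$p - 1L), function(i)
    social_ball(ball$tree, c(ball$prefix, i)))
}

#' Ultrametric distance from a point to a ball
#'
#' 0 if the point lies inside the ball; otherwise the common distance from
#' the point to every member (in an ultrametric all members of a disjoint
#' ball are equidistant from an outside point).
#'
#' @param ball a [social_ball()].
#' @param label a state label.
#' @return Integer distance in `0..n`.
#' @export
ball_point_dist <- function(ball, label) {
  stopifnot(is_social_ball(ball))
  tree <- ball$tree
  k <- length(ball$prefix)
  if (k == 0L) return(0L)
  cm <- decode_label(tree, label)[1L, ]
  j <- 0L
  while (j < k && cm[j + 1L] == ball$prefix[j + 1L]) j <- j + 1L
  if (j == k) 0L else tree$n - j
}

#' Export the social tree in Newick format
#'
#' Renders the full p-adic tree with `p^n` leaves named by their integer
#' labels.  Branch lengths are the per-level barrier heights when a
#' [barrier_profile()] is supplied (the length of the branch entering level
#' `m` from below is `barrier_height(profile, m)`), otherwise 1.
#'
#' @param tree a [social_tree()].
#' @param profile optional [barrier_profile()] for branch lengths.
#' @param cap refuse to render more than `cap` leaves.
#' @return A Newick string (semicolon-terminated).
#' @examples
#' tree_newick(social_tree(2, 1)) # "(0:1,1:1);"
#' @export
tree_newick <- function(tree, profile = NULL, cap = 4096) {
  check_tree(tree)
  if (tree$n_states > cap)
    stop(sprintf("tree has %s leaves, above cap %d",
                 format(tree$n_states, scientific = FALSE), cap), call. = FALSE)
  blen <- function(level_above) { # branch spanning one level, counted from leaves = 1
    if (is.null(profile)) 1 else barrier_height(profile, level_above)
  }
  build <- function(prefix) {
    depth <- length(prefix)
    if (depth == tree$n) {
      return(format(encode_label(tree, matrix(prefix, 1L)), scientific = FALSE))
    }
    kids <- vapply(0:(tree$p - 1L), function(i) {
      sub <- build(c(prefix, i))
      sprintf("%s:%.10g", sub, blen(tree$n - depth))
    }, character(1L))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  paste0(build(integer(0)), ";")
}
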