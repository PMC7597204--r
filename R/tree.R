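#' Construct a p-adic social tree
#'
#' A population with `n` levels of social hierarchy and branching index `p`
#' is represented as a rooted tree with `p` branches at every vertex.  The
#' `p^n` ground-level vertices are the social types: vectors of `n` base-p
#' social coordinates, coordinate 0 being the most important factor.
#'
#' @param p integer branching index, `p >= 2`: how many values each social
#'   coordinate can take.
#' @param n integer number of hierarchy levels, `n >= 1`.
#'
#' @return An object of class `social_tree` with elements `p`, `n` and
#'   `n_states = p^n`.
#' @examples
#' tr <- social_tree(2, 3)
#' tr$n_states # 8 social types
#' @export
social_tree <- function(p, n) {
  p <- as.integer(p)
  n <- as.integer(n)
  if (length(p) != 1L || is.na(p) || p < 2L)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  structure(
    list(p = p, n = n, n_states = p^as.numeric(n)),
    class = "social_tree"
  )
}

#' @export
print.social_tree <- function(x, ...) {
  cat(sprintf(
    "<social_tree> p = %d branches, n = %d levels, %s ground-level types\n",
    x$p, x$n, format(x$n_states, big.mark = ",", scientific = FALSE)
  ))
  invisible(x)
}

is_social_tree <- function(x) inherits(x, "social_tree")

check_tree <- function(tree) {
  if (!is_social_tree(tree)) stop("expected a `social_tree`", call. = FALSE)
  tree
}

coords_matrix <- function(x, tree) {
  # normalise a coordinate vector / matrix to an integer matrix, one row per point
  if (is.null(dim(x))) x <- matrix(as.integer(x), nrow = 1L)
  x <- matrix(as.integer(x), nrow = nrow(x))
  if (ncol(x) != tree$n)
    stop(sprintf("coordinate vectors must have length n = %d", tree$n), call. = FALSE)
  if (any(is.na(x)) || any(x < 0L) || any(x >= tree$p))
    stop(sprintf("coordinates must lie in 0..%d", tree$p - 1L), call. = FALSE)
  x
}

#' Hierarchic (ultrametric) social distance
#'
#' The distance between social types `x` and `y` is `n - k`, where `k` is the
#' number of leading (most important) coordinates they share.  Types that
#' differ only in the least important coordinate are at distance 1; types
#' that differ already in the most important coordinate are at the maximal
#' distance `n`.  The distance satisfies the strong triangle inequality
#' `d(x,y) <= max(d(x,z), d(y,z))`, so the social space is ultrametric.
#'
#' @param tree a [social_tree()].
#' @param x,y coordinate vectors of length `n`, or matrices with one point
#'   per row (rows are recycled to a common length).
#'
#' @return Integer vector of distances in `0..n`.
#' @examples
#' tr <- social_tree(2, 3)
#' ultra_dist(tr, decode_label(tr, 0), decode_label(tr, 1)) # 1
#' ultra_dist(tr, decode_label(tr, 0), decode_label(tr, 6)) # 3
#' @export
ultra_dist <- function(tree, x, y) {
  check_tree(tree)
  x <- coords_matrix(x, tree)
  y <- coords_matrix(y, tree)
  nr <- max(nrow(x), nrow(y))
  if (nrow(x) < nr) x <- x[rep_len(seq_len(nrow(x)), nr), , drop = FALSE]
  if (nrow(y) < nr) y <- y[rep_len(seq_len(nrow(y)), nr), , drop = FALSE]
  neq <- x != y
  d <- integer(nr)
  any_diff <- rowSums(neq) > 0L
  if (any(any_diff)) {
    first_diff <- apply(neq[any_diff, , drop = FALSE], 1L, function(r) which(r)[1L])
    d[any_diff] <- tree$n - (first_diff - 1L)
  }
  d
}

#' Encode social coordinates as an integer label
#'
#' Ground-level vertices are enumerated `0 .. p^n - 1` by reading the
#' coordinates as base-p digits with the most important coordinate as the
#' most significant digit: `label = sum_m x_m p^(n-1-m)`.
#'
#' @inheritParams ultra_dist
#' @param coords coordinate vector of length `n` or matrix of points (rows).
#' @return Numeric vector of labels in `0 .. p^n - 1`.
#' @examples
#' tr <- social_tree(2, 3)
#' encode_label(tr, c(0, 0, 1)) # 1
#' encode_label(tr, c(1, 1, 1)) # 7
#' @export
encode_label <- function(tree, coords) {
  check_tree(tree)
  coords <- coords_matrix(coords, tree)
  pow <- tree$p^as.numeric((tree$n - 1L):0L)
  as.vector(coords %*% pow)
}

#' Decode an integer label into social coordinates
#'
#' Inverse of [encode_label()].
#'
#' @inheritParams ultra_dist
#' @param labels numeric vector of labels in `0 .. p^n - 1`.
#' @return Integer matrix with one coordinate vector per row.
#' @examples
#' tr <- social_tree(2, 3)
#' decode_label(tr, 7) # (1, 1, 1)
#' @export
decode_label <- function(tree, labels) {
  check_tree(tree)
  labels <- as.numeric(labels)
  if (any(is.na(labels)) || any(labels < 0) || any(labels >= tree$n_states) ||
      any(labels != floor(labels)))
    stop(sprintf("labels must be integers in 0..%s",
                 format(tree$n_states - 1, scientific = FALSE)), call. = FALSE)
  out <- matrix(0L, nrow = length(labels), ncol = tree$n)
  rest <- labels
  for (m in tree$n:1L) {
    out[, m] <- as.integer(rest %% tree$p)
    rest <- rest %/% tree$p
  }
  out
}

#' Pairwise ultrametric distances between labelled states
#'
#' @inheritParams ultra_dist
#' @param a,b numeric label vectors (recycled).
#' @return Integer vector of distances.
#' @export
label_dist <- function(tree, a, b) {
  ultra_dist(tree, decode_label(tree, a), decode_label(tree, b))
}

#' Full distance matrix of the social space
#'
#' @inheritParams ultra_dist
#' @param cap refuse to materialise more than `cap` states.
#' @return `p^n` x `p^n` integer matrix, labelled `0 .. p^n - 1`.
#' @export
distance_matrix <- function(tree, cap = 4096) {
  check_tree(tree)
  if (tree$n_states > cap)
    stop(sprintf("tree has %s states, above the dense cap %d",
                 format(tree$n_states, scientific = FALSE), cap), call. = FALSE)
  S <- as.integer(tree$n_states)
  # states sharing a prefix of length k form contiguous label blocks of size
  # p^(n-k); distance <= lev within blocks of size p^lev
  d <- matrix(tree$n, S, S)
  for (lev in (tree$n - 1L):0L) {
    block <- tree$p^as.numeric(lev + 1L)
    for (b0 in seq(0L, S - 1L, by = block)) {
      idx <- (b0 + 1L):(b0 + block)
      d[idx, idx] <- pmin(d[idx, idx], lev + 1L)
    }
  }
  diag(d) <- 0L
  dimnames(d) <- list(0:(S - 1L), 0:(S - 1L))
  d
}

#' Number of states at each ultrametric distance from a point
#'
#' From any ground-level vertex there are `(p-1) p^(m-1)` vertices at
#' distance `m`, for `m = 1..n`.
#'
#' @inheritParams ultra_dist
#' @return A tibble with columns `distance` (1..n) and `n_states`.
#' @export
distance_class_sizes <- function(tree) {
  check_tree(tree)
  m <- seq_len(tree$n)
  tibble::tibble(
    distance = m,
    n_states = (tree$p - 1) * tree$p^as.numeric(m - 1L)
  )
}
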