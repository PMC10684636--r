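# Internal numeric and RNG helpers shared across modules.

stop_invalid <- function(msg, class = "fedasc_invalid_argument") {
  rlang::abort(msg, class = c(class, "fedasc_error"))
}

stop_degenerate <- function(msg) stop_invalid(msg, class = "fedasc_degenerate_input")
stop_shape <- function(msg) stop_invalid(msg, class = "fedasc_shape_error")
stop_size <- function(msg) stop_invalid(msg, class = "fedasc_size_exceeded")
stop_format <- function(msg) stop_invalid(msg, class = "fedasc_format_error")
stop_io <- function(msg) stop_invalid(msg, class = "fedasc_io_error")

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards.  All package randomness flows through this (or
# through explicit saved states) so cohorts and training runs are pure
# functions of their seeds.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(state) {
  if (is.null(state)) return(invisible(NULL))
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# Run expr with the RNG stream taken from `state` (a saved .Random.seed) and
# return list(value, state) with the advanced stream.  Used to thread
# deterministic shuffle/noise streams through federated rounds.
with_rng_state <- function(state, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set_rng_state(state)
  value <- force(expr)
  list(value = value, state = get_rng_state())
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009 + 7) %% 2147483647)
}

#' Separable Gaussian filtering of a matrix
#'
#' Convolves a matrix with an isotropic Gaussian kernel using two 1-D passes.
#' Borders are renormalized by the local kernel mass so that a constant image
#' is reproduced exactly (no darkening at the edge).
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0` returns
#'   `x` unchanged.
#' @param radius kernel half-width; defaults to `ceiling(3 * sigma)`.
#' @return filtered matrix, same dimensions as `x`.
#' @keywords internal
gaussian_blur <- function(x, sigma, radius = NULL) {
  if (sigma <= 0) return(x)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m, kern) {
    r <- (length(kern) - 1L) / 2L
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kern[o + r + 1L] * m[src[ok], ]
      wt[ok, ] <- wt[ok, ] + kern[o + r + 1L]
    }
    out / wt
  }
  t(blur_1d(t(blur_1d(x, k)), k))
}

# Label 4-connected components of a logical matrix.  Returns an integer
# matrix (0 = background).  Seed-fill with an integer stack; phantom masks
# are a few components so this is linear in practice.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack
      stack <- integer(0)
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      nb <- c(cur[r > 1L] - 1L, cur[r < nr] + 1L,
              cur[cc > 1L] - nr, cur[cc < nc] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      if (length(nb)) {
        lab[nb] <- nxt
        stack <- nb
      }
    }
  }
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# format a matrix size as "HxW"
dim_str <- function(x) paste(dim(x), collapse = "x")
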