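#' Stick-breaking state
#'
#' A lazily extendable prefix of the stick-breaking construction of an
#' infinite probability vector. Stick variables \eqn{\xi_\ell \in (0,1)} are
#' i.i.d. Beta(1, \eqn{\alpha}) a priori and define cluster weights
#' \eqn{\pi_1 = \xi_1}, \eqn{\pi_\ell = \xi_\ell \prod_{m<\ell}(1-\xi_m)},
#' so that \eqn{\sum_\ell \pi_\ell = 1} almost surely. Only a finite prefix
#' is ever instantiated; the un-instantiated tail carries mass
#' \eqn{\prod_{m \le L}(1-\xi_m)}.
#'
#' @param xi numeric vector of stick variables, all strictly inside (0, 1).
#'   Values touching the boundary in floating point are clamped to
#'   `1e-12` / `1 - 1e-12`.
#' @param alpha concentration parameter of the Beta(1, alpha) stick prior;
#'   larger values favour more occupied clusters absent spatial interaction.
#' @return An object of class `"sticks"`.
#' @examples
#' s <- new_sticks(c(0.5, 0.5, 0.5), alpha = 1)
#' stick_weights(s, 3)   # 0.5 0.25 0.125
#' stick_tail_mass(s, 3) # 0.125
#' @export
new_sticks <- function(xi, alpha = 1) {
  stopifnot(is.numeric(xi), length(xi) >= 1, alpha > 0)
  if (any(!is.finite(xi)) || any(xi <= 0) || any(xi >= 1)) {
    stop("stick variables xi must lie strictly inside (0, 1)")
  }
  structure(list(xi = as.numeric(xi), alpha = alpha), class = "sticks")
}

clamp_xi <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)

#' Stick-breaking weights
#'
#' Derived cluster weights for the first `L` instantiated sticks.
#'
#' @param sticks a [new_sticks()] object.
#' @param L number of leading weights to return; must not exceed the number
#'   of instantiated sticks (extend first with [extend_sticks()]).
#' @return Numeric vector \eqn{(\pi_1, \dots, \pi_L)}; all entries positive,
#'   and `sum(stick_weights(s, L)) + stick_tail_mass(s, L) == 1` to machine
#'   precision.
#' @export
stick_weights <- function(sticks, L = length(sticks$xi)) {
  stopifnot(inherits(sticks, "sticks"), L >= 1)
  if (L > length(sticks$xi)) {
    stop("only ", length(sticks$xi), " sticks instantiated; need ", L,
         " (call extend_sticks first)")
  }
  xi <- sticks$xi[seq_len(L)]
  xi * c(1, cumprod(1 - xi)[-L])
}

#' @rdname stick_weights
#' @return `stick_tail_mass()`: the mass \eqn{\prod_{m \le L}(1-\xi_m)} left
#'   beyond the first `L` sticks.
#' @export
stick_tail_mass <- function(sticks, L = length(sticks$xi)) {
  stopifnot(inherits(sticks, "sticks"), L >= 0, L <= length(sticks$xi))
  if (L == 0) return(1)
  prod(1 - sticks$xi[seq_len(L)])
}

#' Extend the instantiated stick prefix
#'
#' Appends fresh Beta(1, alpha) prior draws until the tail mass falls below
#' `u_min`, guaranteeing that no un-instantiated cluster can have weight
#' `>= u_min` — this is what keeps every slice-sampler candidate set finite.
#' Optionally also enforces a minimum instantiated length.
#'
#' @inheritParams stick_weights
#' @param u_min positive slice threshold in (0, 1).
#' @param min_len minimum number of instantiated sticks on return.
#' @return The extended `"sticks"` object (unchanged if the tail is already
#'   below `u_min` and the length already `>= min_len`). Uses the R RNG.
#' @export
extend_sticks <- function(sticks, u_min, min_len = 0) {
  stopifnot(inherits(sticks, "sticks"))
  if (!is.numeric(u_min) || length(u_min) != 1 || u_min <= 0 || u_min >= 1) {
    stop("u_min must be a single number in (0, 1)")
  }
  xi <- sticks$xi
  tail <- prod(1 - xi)
  while (tail >= u_min || length(xi) < min_len) {
    x <- clamp_xi(rbeta(1, 1, sticks$alpha))
    xi <- c(xi, x)
    tail <- tail * (1 - x)
  }
  sticks$xi <- xi
  sticks
}

# sticks whose weights match `freq` (scaled by 1 - tail_reserve) for the
# leading clusters, then prior draws out to at least min_len
sticks_from_frequencies <- function(freq, alpha, tail_reserve = 0.01,
                                    min_len = length(freq)) {
  p <- freq / sum(freq) * (1 - tail_reserve)
  xi <- numeric(length(p))
  rem <- 1
  for (l in seq_along(p)) {
    xi[l] <- clamp_xi(p[l] / rem)
    rem <- rem - p[l]
  }
  s <- new_sticks(xi, alpha)
  if (length(xi) < min_len) s <- extend_sticks(s, u_min = 0.5, min_len = min_len)
  s
}

#' @export
print.sticks <- function(x, ...) {
  cat("Stick-breaking state:", length(x$xi), "instantiated sticks,",
      "alpha =", x$alpha, "\n")
  cat("  tail mass:", format(stick_tail_mass(x)), "\n")
  invisible(x)
}
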