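# Beta-distribution belief calculus. A belief state (mu, la) stores two
# pseudo-counts: mu confirming and la disconfirming events, implying the
# density Beta(f | mu + 1, la + 1) over the unknown frequency f. Counts may
# be fractional, so that probabilistic lie/truth attribution can add partial
# evidence.

#' Create a belief state
#'
#' A belief state holds two nonnegative pseudo-counts `mu` (confirming
#' events) and `la` (disconfirming events) and represents the density
#' `Beta(f | mu + 1, la + 1)` over an unknown frequency `f` in (0, 1).
#' `belief(0, 0)` is the uninformed (uniform) belief.
#'
#' @param mu Nonnegative finite number of confirming events.
#' @param la Nonnegative finite number of disconfirming events.
#' @return An object of class `rg_belief`: a named numeric vector
#'   `c(mu, la)`.
#' @examples
#' b <- belief(17, 4)
#' belief_mean(b)      # 18/23
#' belief_variance(b)
#' @export
belief <- function(mu = 0, la = 0) {
  if (!is.numeric(mu) || !is.numeric(la) ||
      length(mu) != 1L || length(la) != 1L ||
      !is.finite(mu) || !is.finite(la) || mu < 0 || la < 0) {
    stop("invalid belief: 'mu' and 'la' must be single finite nonnegative numbers",
         call. = FALSE)
  }
  structure(c(mu = unname(mu), la = unname(la)), class = "rg_belief")
}

#' @export
print.rg_belief <- function(x, ...) {
  cat(sprintf("<belief mu=%.6g la=%.6g mean=%.4f sd=%.4f>\n",
              x[[1]], x[[2]], belief_mean(x), sqrt(belief_variance(x))))
  invisible(x)
}

as_belief <- function(x) {
  if (inherits(x, "rg_belief")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(belief(x[[1]], x[[2]]))
  if (is.list(x) && all(c("mu", "la") %in% names(x)))
    return(belief(x$mu, x$la))
  stop("cannot interpret object as a belief state", call. = FALSE)
}

#' Mean of a belief state
#'
#' The posterior mean `(mu + 1) / (mu + la + 2)` of the implied beta
#' density, the agent's current best guess of the frequency. Strictly
#' inside (0, 1) for all finite pseudo-counts.
#'
#' @param b A belief state (see [belief()]).
#' @return A probability in (0, 1).
#' @export
belief_mean <- function(b) {
  b <- as_belief(b)
  unname((b[[1]] + 1) / (b[[1]] + b[[2]] + 2))
}

#' Variance of a belief state
#'
#' The posterior variance
#' `(mu + 1)(la + 1) / ((mu + la + 3)(mu + la + 2)^2)` of the implied beta
#' density, the agent's uncertainty about the frequency.
#'
#' @inheritParams belief_mean
#' @return A nonnegative number.
#' @export
belief_variance <- function(b) {
  b <- as_belief(b)
  s <- b[[1]] + b[[2]] + 2
  unname((b[[1]] + 1) * (b[[2]] + 1) / ((s + 1) * s^2))
}

#' Log-density of a belief state
#'
#' Evaluates `log Beta(f | mu + 1, la + 1)` in nats.
#'
#' @inheritParams belief_mean
#' @param f Evaluation point, strictly inside (0, 1).
#' @return The log-density at `f`.
#' @export
belief_log_density <- function(b, f) {
  b <- as_belief(b)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("'f' must lie strictly inside (0, 1)", call. = FALSE)
  dbeta(f, b[[1]] + 1, b[[2]] + 1, log = TRUE)
}

#' Kullback-Leibler divergence between two belief states
#'
#' Closed-form KL divergence `KL(p || q)` between the beta densities implied
#' by two belief states, in nats, using log-beta and digamma functions.
#' Nonnegative, and zero exactly when the two states coincide.
#'
#' @param p,q Belief states (see [belief()]).
#' @return A nonnegative number (nats).
#' @export
kl_beta <- function(p, q) {
  p <- as_belief(p)
  q <- as_belief(q)
  cpp_kl_beta(p[[1]], p[[2]], q[[1]], q[[2]])
}

#' Conjugate fusion of two belief states
#'
#' Adds the pseudo-counts of two belief states. This is the conjugate
#' posterior when a communicated `(mu, la)` claim is taken at face value as
#' reported evidence counts (the "honest interpretation" of a message).
#'
#' @param prior,msg Belief states.
#' @return The fused belief state.
#' @export
fuse_beliefs <- function(prior, msg) {
  prior <- as_belief(prior)
  msg <- as_belief(msg)
  belief(prior[[1]] + msg[[1]], prior[[2]] + msg[[2]])
}

#' Compress a beta mixture into a single belief state
#'
#' Finds the single beta distribution minimizing `KL(mixture || beta)`.
#' The optimum matches the mixture's expectations of `ln f` and
#' `ln(1 - f)`; the resulting digamma moment equations are solved by damped
#' Newton iteration (tolerance 1e-10, at most 100 iterations). Pseudo-counts
#' of the result are kept nonnegative: if the unconstrained optimum would
#' require a negative count it is pinned at zero and the remaining equation
#' re-solved. If Newton fails to converge, mean/variance moment matching is
#' used instead and a warning is emitted.
#'
#' @param weights Nonnegative mixture weights summing to 1 (tolerance 1e-9).
#' @param components A list of belief states, same length as `weights`.
#' @return The compressed belief state.
#' @examples
#' compress_mixture(c(0.5, 0.5), list(belief(10, 0), belief(0, 10)))
#' @export
compress_mixture <- function(weights, components) {
  if (!is.numeric(weights) || length(weights) < 1L || any(weights < 0))
    stop("'weights' must be nonnegative numbers", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1 (tolerance 1e-9)", call. = FALSE)
  if (!is.list(components) || length(components) != length(weights))
    stop("'components' must be a list of beliefs matching 'weights'",
         call. = FALSE)
  components <- lapply(components, as_belief)
  mus <- vapply(components, function(b) b[[1]], numeric(1))
  las <- vapply(components, function(b) b[[2]], numeric(1))
  res <- cpp_compress(weights, mus, las)
  if (res[[3]] < 0.5)
    warning("mixture compression did not converge; ",
            "using mean/variance moment matching", call. = FALSE)
  belief(res[[1]], res[[2]])
}
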