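#' Personality profiles
#'
#' Four non-negative gains parameterise how an agent weighs arguments when
#' deciding whether to keep or flip its stance on a proposition:
#' \describe{
#'   \item{K}{fixed degree of the agent's belief set — a baseline attachment
#'     to the current stance, independent of any argument heard.}
#'   \item{K1}{persistence gain: amplifies the arguments aligned with the
#'     current stance. Higher K1, harder to move.}
#'   \item{K2}{openness gain: amplifies opposing arguments. Higher K2, more
#'     willing to change one's view.}
#'   \item{K3}{critical-thinking gain: amplifies whichever side the agent's
#'     current evaluation of the evidence favours (see
#'     [evaluation_sign()]).}
#' }
#'
#' Three presets name the qualitative archetypes: `"persistent"`
#' (K=1, K1=2, K2=0.2, K3=0.5), `"open"` (K=1, K1=0.2, K2=2, K3=0.5) and
#' `"critical"` (K=1, K1=0.5, K2=0.5, K3=2). All values are configurable.
#'
#' @param K,K1,K2,K3 finite non-negative reals.
#' @return An object of class `codel_personality`.
#' @export
#' @examples
#' personality_profile(K = 1, K1 = 2, K2 = 0.2, K3 = 0.5)
#' personality_preset("open")
personality_profile <- function(K = 1, K1 = 0, K2 = 0, K3 = 0) {
  v <- c(K = K, K1 = K1, K2 = K2, K3 = K3)
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
    stop("K, K1, K2, K3 must all be finite and >= 0", call. = FALSE)
  }
  structure(as.list(v), class = "codel_personality")
}

#' @rdname personality_profile
#' @param name one of `"persistent"`, `"open"`, `"critical"`.
#' @export
personality_preset <- function(name = c("persistent", "open", "critical")) {
  name <- match.arg(name)
  switch(name,
    persistent = personality_profile(K = 1, K1 = 2,   K2 = 0.2, K3 = 0.5),
    open       = personality_profile(K = 1, K1 = 0.2, K2 = 2,   K3 = 0.5),
    critical   = personality_profile(K = 1, K1 = 0.5, K2 = 0.5, K3 = 2))
}

#' @export
print.codel_personality <- function(x, ...) {
  cat(sprintf("<personality> K=%g K1=%g (persistence) K2=%g (openness) K3=%g (critical)\n",
              x$K, x$K1, x$K2, x$K3))
  invisible(x)
}

#' Belief state toward a proposition
#'
#' Records an agent's current stance (`support` or `oppose`) and the
#' accumulated weight of arguments heard so far, split into the mass aligned
#' with the stance (the Arg+ set) and the mass opposing it (the Arg- set).
#' Both masses are sums of positive argument weights, so they are
#' non-negative; both are zero only before any argument is heard.
#'
#' @param stance `"support"` or `"oppose"`.
#' @param aligned_mass,opposing_mass non-negative reals.
#' @return An object of class `codel_belief`.
#' @export
belief_state <- function(stance = c("support", "oppose"),
                         aligned_mass = 0, opposing_mass = 0) {
  stance <- match.arg(stance)
  stopifnot(is.numeric(aligned_mass), aligned_mass >= 0,
            is.numeric(opposing_mass), opposing_mass >= 0)
  structure(list(stance = stance,
                 aligned_mass = as.numeric(aligned_mass),
                 opposing_mass = as.numeric(opposing_mass)),
            class = "codel_belief")
}

#' @export
print.codel_belief <- function(x, ...) {
  cat(sprintf("<belief> stance=%s aligned=%g opposing=%g\n",
              x$stance, x$aligned_mass, x$opposing_mass))
  invisible(x)
}

#' Current evaluation of the evidence
#'
#' Which side the argument masses favour right now: +1 when the aligned mass
#' is at least the opposing mass (ties count for the current stance), -1
#' otherwise. Critical thinking amplifies the side this sign points to.
#'
#' @param b a [belief_state()].
#' @return +1 or -1.
#' @export
evaluation_sign <- function(b) {
  stopifnot(inherits(b, "codel_belief"))
  if (b$aligned_mass >= b$opposing_mass) 1 else -1
}

#' Keep and flip forces
#'
#' The linear belief-update rule. The force to keep the current stance is
#' the fixed belief degree plus the persistence-amplified aligned mass, with
#' critical-thinking amplification added when the evaluation favours the
#' aligned side:
#' \deqn{keep = K + (1 + K1)\,aligned + [K3\,aligned]_{sign = +1}}
#' The force to flip is the openness-amplified opposing mass, with the
#' critical amplification when the evaluation favours the opposing side:
#' \deqn{flip = (1 + K2)\,opposing + [K3\,opposing]_{sign = -1}}
#'
#' @param b a [belief_state()].
#' @param p a [personality_profile()].
#' @return A non-negative real.
#' @export
#' @examples
#' b <- belief_state("oppose", aligned_mass = 2, opposing_mass = 3)
#' p <- personality_profile(K = 1)
#' keep_force(b, p)  # 3
#' flip_force(b, p)  # 3
keep_force <- function(b, p) {
  stopifnot(inherits(b, "codel_belief"), inherits(p, "codel_personality"))
  f <- p$K + (1 + p$K1) * b$aligned_mass
  if (evaluation_sign(b) > 0) f <- f + p$K3 * b$aligned_mass
  f
}

#' @rdname keep_force
#' @export
flip_force <- function(b, p) {
  stopifnot(inherits(b, "codel_belief"), inherits(p, "codel_personality"))
  f <- (1 + p$K2) * b$opposing_mass
  if (evaluation_sign(b) < 0) f <- f + p$K3 * b$opposing_mass
  f
}

#' Keep or flip the stance
#'
#' The agent flips its stance iff the flip force strictly exceeds the keep
#' force; ties keep the prior stance (persistence is the default of belief).
#'
#' @inheritParams keep_force
#' @return `"keep_stance"` or `"flip_stance"`.
#' @export
decide <- function(b, p) {
  if (flip_force(b, p) > keep_force(b, p)) "flip_stance" else "keep_stance"
}

#' Accumulate heard arguments into a belief state
#'
#' Adds the weights of newly heard arguments to the aligned or opposing mass.
#' The stance itself never changes here; stance changes happen only through
#' [decide()].
#'
#' @param b a [belief_state()].
#' @param weights numeric vector of positive argument weights (one per
#'   argument heard; may be empty).
#' @param relative_polarity `"aligned"` if the arguments side with the
#'   agent's current stance, `"opposing"` otherwise.
#' @return The updated `codel_belief`.
#' @export
apply_arguments <- function(b, weights,
                            relative_polarity = c("aligned", "opposing")) {
  stopifnot(inherits(b, "codel_belief"))
  relative_polarity <- match.arg(relative_polarity)
  weights <- as.numeric(weights)
  if (length(weights) == 0L) return(b)
  if (anyNA(weights) || any(weights <= 0)) {
    stop("argument weights must be positive", call. = FALSE)
  }
  if (relative_polarity == "aligned") {
    b$aligned_mass <- b$aligned_mass + sum(weights)
  } else {
    b$opposing_mass <- b$opposing_mass + sum(weights)
  }
  b
}
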