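# Self-contained cart-pole balancing testbed with the canonical benchmark
# constants (gravity 9.8, cart mass 1.0, pole mass 0.1, half-length 0.5,
# force 10, explicit Euler at 0.02 s), a per-dimension uniform discretizer,
# and termination thresholds that a scheduled mutation can tighten.

#' Construct a cart-pole environment
#'
#' The episode terminates when the pole angle leaves `±angle_limit_deg`
#' degrees or the cart position leaves `±position_limit` units.  The default
#' limits are ±12 degrees and ±2.4 units; the mutated (harder) variant
#' halves both.  Discretization bins are laid uniformly over fixed reference
#' ranges (`bin_angle_deg`, `bin_position`, and symmetric velocity ranges),
#' which stay tied to the unmutated limits so that state indices keep their
#' meaning when the termination thresholds change.
#'
#' @param angle_limit_deg Termination threshold on the pole angle (degrees).
#' @param position_limit Termination threshold on the cart position.
#' @param bins Integer vector of bin counts for (cart position, cart
#'   velocity, pole angle, pole angular velocity).  Default `c(3, 3, 6, 3)`
#'   giving 162 discrete states.
#' @param step_budget Maximum steps per episode; surviving the full budget
#'   counts as the positive (balanced) outcome.
#' @param bin_position,bin_angle_deg,bin_velocity,bin_ang_velocity Reference
#'   half-ranges used by the discretizer.
#' @return Object of class `cartpole_env`.
#' @export
cartpole_env <- function(angle_limit_deg = 12, position_limit = 2.4,
                         bins = c(3L, 3L, 6L, 3L), step_budget = 200L,
                         bin_position = 2.4, bin_angle_deg = 12,
                         bin_velocity = 3, bin_ang_velocity = 3.5) {
  stopifnot(length(bins) == 4L, all(bins >= 2L))
  bins <- as.integer(bins)
  structure(
    list(type = "cartpole",
         params = list(gravity = 9.8, mass_cart = 1.0, mass_pole = 0.1,
                       half_length = 0.5, force_mag = 10.0, tau = 0.02),
         angle_limit = angle_limit_deg * pi / 180,
         position_limit = position_limit,
         bins = bins,
         bin_lo = c(-bin_position, -bin_velocity, -bin_angle_deg * pi / 180,
                    -bin_ang_velocity),
         bin_hi = c(bin_position, bin_velocity, bin_angle_deg * pi / 180,
                    bin_ang_velocity),
         n_states = as.integer(prod(bins)), n_actions = 2L,
         step_budget = as.integer(step_budget)),
    class = "cartpole_env")
}

#' @export
print.cartpole_env <- function(x, ...) {
  cat(sprintf(
    "<cartpole_env> limits: |angle| < %.1f deg, |x| < %.2f; %d discrete states (%s bins), budget %d\n",
    x$angle_limit * 180 / pi, x$position_limit, x$n_states,
    paste(x$bins, collapse = "x"), x$step_budget))
  invisible(x)
}

#' Draw an initial cart-pole state
#'
#' All four state variables (cart position, cart velocity, pole angle in
#' radians, pole angular velocity) start uniformly in `(-0.05, 0.05)`.
#'
#' @param env A `cartpole_env`.
#' @return Numeric vector `c(x, x_dot, theta, theta_dot)`.
#' @export
cartpole_reset <- function(env) {
  stats::runif(4L, -0.05, 0.05)
}

cartpole_terminated <- function(env, state) {
  abs(state[3L]) > env$angle_limit || abs(state[1L]) > env$position_limit
}

#' One explicit-Euler step of the cart-pole dynamics
#'
#' Applies the benchmark force (+10 for Right, -10 for Left) and integrates
#' the standard equations of motion with an explicit Euler step of 0.02 s.
#' Stepping an already-terminated state is an error.
#'
#' @param env A `cartpole_env`.
#' @param state Numeric vector `c(x, x_dot, theta, theta_dot)` (angle in
#'   radians).
#' @param u Action index: 1 = push Left, 2 = push Right.
#' @return List with the next `state` and the flag `terminated`.
#' @export
cartpole_step <- function(env, state, u) {
  if (cartpole_terminated(env, state))
    stop("cartpole_step: cannot step a terminated state")
  if (!u %in% c(1L, 2L)) stop("cartpole_step: action must be 1 (Left) or 2 (Right)")
  p <- env$params
  force <- if (u == 2L) p$force_mag else -p$force_mag
  total_mass <- p$mass_cart + p$mass_pole
  pml <- p$mass_pole * p$half_length
  theta <- state[3L]; theta_dot <- state[4L]
  cos_t <- cos(theta); sin_t <- sin(theta)
  temp <- (force + pml * theta_dot^2 * sin_t) / total_mass
  theta_acc <- (p$gravity * sin_t - cos_t * temp) /
    (p$half_length * (4 / 3 - p$mass_pole * cos_t^2 / total_mass))
  x_acc <- temp - pml * theta_acc * cos_t / total_mass
  nxt <- c(state[1L] + p$tau * state[2L],
           state[2L] + p$tau * x_acc,
           theta + p$tau * theta_dot,
           theta_dot + p$tau * theta_acc)
  list(state = nxt, terminated = cartpole_terminated(env, nxt))
}

#' Discretize a continuous cart-pole state into a categorical index
#'
#' Each of the four variables is binned uniformly over its reference range
#' (values outside are clipped into the edge bins), and the four bin
#' numbers are combined into a single 1-based index.  The mapping between
#' bin tuples and indices is a bijection over the bin lattice.
#'
#' @param env A `cartpole_env`.
#' @param state Numeric vector `c(x, x_dot, theta, theta_dot)`.
#' @return Integer state index in `1..prod(bins)`.
#' @export
discretize_cartpole <- function(env, state) {
  b <- integer(4L)
  for (i in 1:4) {
    frac <- (state[i] - env$bin_lo[i]) / (env$bin_hi[i] - env$bin_lo[i])
    b[i] <- as.integer(min(max(floor(frac * env$bins[i]), 0), env$bins[i] - 1L))
  }
  bin_tuple_to_index(env, b)
}

#' Convert between bin tuples and state indices
#'
#' `bin_tuple_to_index()` maps a 0-based bin tuple to the 1-based state
#' index; `index_to_bin_tuple()` is its inverse.
#'
#' @param env A `cartpole_env`.
#' @param b Integer vector of four 0-based bin numbers.
#' @export
bin_tuple_to_index <- function(env, b) {
  stopifnot(length(b) == 4L, all(b >= 0L), all(b < env$bins))
  b <- as.integer(b)
  1L + b[1L] + env$bins[1L] * (b[2L] + env$bins[2L] * (b[3L] + env$bins[3L] * b[4L]))
}

#' @rdname bin_tuple_to_index
#' @param index Integer state index in `1..prod(bins)`.
#' @export
index_to_bin_tuple <- function(env, index) {
  stopifnot(index >= 1L, index <= env$n_states)
  k <- as.integer(index) - 1L
  b <- integer(4L)
  for (i in 1:4) {
    b[i] <- k %% env$bins[i]
    k <- k %/% env$bins[i]
  }
  b
}
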