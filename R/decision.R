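#' Build a product initial state from per-agent opinions
#'
#' Each group member starts in a local superposition
#' \eqn{c_k|0\rangle + d_k|1\rangle}; the network starts in the tensor
#' product of the local states (agent 1 least significant).  Two reading
#' modes are supported for the supplied pairs: `"probabilities_sqrt"`
#' treats them as probabilities ("80% sure of option 1" becomes amplitude
#' \eqn{\sqrt{0.8}} on \eqn{|1\rangle}), the default;
#' `"amplitudes_normalized"` treats them as literal amplitudes and
#' renormalises each local state.
#'
#' @param opinions Matrix or data frame with n rows (agent k in row k) and
#'   two columns: weight on \eqn{|0\rangle} then weight on \eqn{|1\rangle}.
#' @param mode `"probabilities_sqrt"` or `"amplitudes_normalized"`.
#' @return Numeric unit vector of length `2^n`.
#' @examples
#' # three members 80% sure of option 1, two members 10% sure:
#' op <- rbind(c(0.2, 0.8), c(0.2, 0.8), c(0.2, 0.8),
#'             c(0.9, 0.1), c(0.9, 0.1))
#' psi <- product_initial_state(op)
#' sum(psi^2)  # 1
#' @export
product_initial_state <- function(opinions,
                                  mode = c("probabilities_sqrt",
                                           "amplitudes_normalized")) {
  mode <- match.arg(mode)
  opinions <- as.matrix(opinions)
  stopifnot(ncol(opinions) == 2, nrow(opinions) >= 2,
            all(is.finite(opinions)))
  locals <- lapply(seq_len(nrow(opinions)), function(k) {
    v <- opinions[k, ]
    if (mode == "probabilities_sqrt") {
      if (any(v < 0)) stop("probabilities must be nonnegative")
      s <- sum(v)
      if (s <= 0) stop("agent ", k, " has zero total probability")
      sqrt(v / s)
    } else {
      nrm <- sqrt(sum(Mod(v)^2))
      if (nrm <= 0) stop("agent ", k, " has a zero-norm local state")
      v / nrm
    }
  })
  # column vectors, agent n most significant
  psi <- kron_all(rev(lapply(locals, matrix, ncol = 1)))
  drop(psi)
}

#' Consensus stopping projectors for group decisions
#'
#' A binary group decision stops when all members agree: the two stopping
#' states are all-zeros and all-ones.  Returns the stopping projector
#' `Ms` (1s at basis indices 1 and `2^n`) and the two decision projectors
#' `M0`, `M1` picking each consensus state; `M0 + M1 = Ms`.
#'
#' @param n Number of group members, at least 2.
#' @return A list with elements `Ms`, `M0`, `M1`.
#' @export
consensus_projectors <- function(n) {
  stopifnot(n >= 2)
  list(Ms = measurement_projector(n, c(1L, 2^n), label = "consensus"),
       M0 = measurement_projector(n, 1L, label = "all_zero"),
       M1 = measurement_projector(n, 2^n, label = "all_one"))
}

# Block unitary for a decision/interference scenario: ring topology with
# homogeneous angles and identity initialization (opinions need no seeding).
decision_blocks <- function(n, topology, theta, phi) {
  if (topology != "ring") stop("group decisions are implemented on rings")
  if (n == 3) {
    ang <- ring3_homogeneous(theta, phi)
    ang$U1[] <- 0  # no seeding: all-zero block is the identity
    build_ring3(ang)
  } else {
    build_ring_n(n, theta, phi, initializing = FALSE)
  }
}

#' Run a group decision walk
#'
#' Runs the lifted walk with the two-state consensus stopping rule and,
#' at the stopping step, projects the pre-measurement state onto the
#' consensus subspace, \eqn{\rho_f = M_s \rho_T(t_f) M_s / p_s(t_f)}, and
#' reads off the decision probabilities \eqn{P_i = \mathrm{Tr}(M_i \rho_f
#' M_i)}.  The all-zero and all-one blocks of the walk operator are the
#' identity: members arrive with opinions, nothing is seeded.
#'
#' @param n Number of members.
#' @param opinions Per-agent opinion weights, see
#'   [product_initial_state()]; a length-`2^n` amplitude vector is also
#'   accepted as-is.
#' @param theta,phi Homogeneous infection / counteraction angles (or
#'   n x n matrices for `n > 3`), see [build_ring_n()].
#' @param topology Only `"ring"` is supported.
#' @param epsilon Stopping tolerance; default 0.01.
#' @param mode Opinion reading mode, see [product_initial_state()].
#' @param max_steps Step cap.
#' @return An object of class `decision_result`: `t_f`, `P0`, `P1`,
#'   `rho_f`, and the underlying `quantum_walk` in `$walk`.
#' @export
run_decision <- function(n, opinions, theta, phi, topology = "ring",
                         epsilon = 0.01,
                         mode = c("probabilities_sqrt",
                                  "amplitudes_normalized"),
                         max_steps = 20000L) {
  mode <- match.arg(mode)
  initial <- if (is.numeric(opinions) && is.null(dim(opinions)) &&
                 length(opinions) == 2^n) {
    opinions
  } else {
    product_initial_state(opinions, mode = mode)
  }
  pr <- consensus_projectors(n)
  bu <- decision_blocks(n, topology, theta, phi)
  walk <- run_walk(bu, initial = initial, stop_projector = pr$Ms,
                   epsilon = epsilon, max_steps = max_steps)
  ps_f <- walk$trajectory$ps[walk$t_f]
  if (ps_f <= 0) stop("stopping probability vanished at the final step")
  rho_f <- walk$rho_T_final
  keep <- c(1L, 2^n)
  mask <- matrix(0, 2^n, 2^n)
  mask[keep, keep] <- 1
  rho_f <- (rho_f * mask) / ps_f
  structure(list(t_f = walk$t_f, P0 = Re(rho_f[1, 1]),
                 P1 = Re(rho_f[2^n, 2^n]), rho_f = rho_f,
                 epsilon = epsilon, n_agents = n, walk = walk),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat("<decision_result> ", x$n_agents, " members, agreed at step ", x$t_f,
      "\n  P(option 0) = ", format(x$P0, digits = 6),
      ", P(option 1) = ", format(x$P1, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Joint measurement projectors for a pair of agents
#'
#' The four diagonal projectors selecting the joint states
#' \eqn{|00\rangle, |01\rangle, |10\rangle, |11\rangle} of two measured
#' agents (labels read \eqn{|b_j b_i\rangle} for agents i < j, matching
#' the global significance convention), leaving the other agents
#' untouched.  For the lowest two agents of a 5-agent network these are
#' the operators \eqn{I_8 \otimes M_i}.  The four projectors sum to the
#' identity.
#'
#' @param n Number of agents.
#' @param agents The two measured agent indices.
#' @return List of four `2^n` diagonal 0/1 matrices, in outcome order
#'   00, 01, 10, 11.
#' @export
pair_measurement_ops <- function(n, agents = c(1L, 2L)) {
  stopifnot(length(agents) == 2, all(agents %in% seq_len(n)),
            agents[1] != agents[2])
  lo <- min(agents); hi <- max(agents)
  idx <- seq_len(2^n)
  joint <- 2L * agent_bit(idx, hi) + agent_bit(idx, lo)
  lapply(0:3, function(v) {
    measurement_projector(n, idx[joint == v],
                          label = sprintf("pair(%d,%d)=%d%d", hi, lo,
                                          v %/% 2L, v %% 2L))
  })
}

# Continue a walk from a given reduced state for `steps` further steps,
# applying the usual stop/continue projection each step; returns the
# pre-projection state rho_T at the final step.
evolve_reduced <- function(sigma, bu, stop_idx, steps) {
  rho_T <- NULL
  for (t in seq_len(steps)) {
    st <- walk_step(sigma, bu$blocks, stop_idx)
    rho_T <- st$rho_T
    if (is.null(st$sigma_next)) break
    sigma <- st$sigma_next
  }
  rho_T
}

# Consensus-conditional all-ones probability at a reporting step: project
# the pre-measurement state onto the two consensus states and normalise
# (the stopped-state construction applied at that step).
consensus_share <- function(rho_T, n) {
  m0 <- Re(rho_T[1, 1])
  m1 <- Re(rho_T[2^n, 2^n])
  if (m0 + m1 <= 0) return(NA_real_)
  m1 / (m0 + m1)
}

#' Interference experiment: measure two agents mid-walk
#'
#' Runs a fixed-horizon group-decision walk twice: once undisturbed, and
#' once with a projective measurement of one agent pair at an
#' intermediate step.  At `measure_step` the pre-projection state
#' \eqn{\rho_T} is split into the four branches
#' \eqn{u_i = \mathrm{Tr}(P_i \rho_T P_i)}; each branch is collapsed,
#' renormalised, put through the usual continue projection, and evolved to
#' the horizon, where the probability that the group settles on option 1
#' is read off as \eqn{v_i}, the consensus-conditional all-ones
#' probability (the stopped-state construction of [run_decision()]
#' applied at the horizon step).  Classically the overall option-1
#' probability would be the mixture \eqn{u \cdot v}; the quantum walk
#' instead yields the unmeasured baseline, and the difference is the
#' interference effect (a violation of classical total probability).
#'
#' @inheritParams run_decision
#' @param measure_step Step at which the pair is measured (before the
#'   horizon).
#' @param agents The two measured agents; default `c(1, 2)`.
#' @param horizon Total number of steps; default 50.
#' @return An object of class `branch_ensemble`: `u` (branch
#'   probabilities), `v` (per-branch all-ones probabilities at the
#'   horizon), `composite` (`sum(u * v)`), `baseline` (unmeasured
#'   all-ones probability), plus a `branches` tibble.
#' @export
run_with_midway_measurement <- function(n, opinions, theta, phi,
                                        measure_step = 25L,
                                        agents = c(1L, 2L),
                                        horizon = 50L,
                                        topology = "ring",
                                        mode = c("probabilities_sqrt",
                                                 "amplitudes_normalized")) {
  mode <- match.arg(mode)
  stopifnot(measure_step >= 1, measure_step < horizon)
  initial <- if (is.numeric(opinions) && is.null(dim(opinions)) &&
                 length(opinions) == 2^n) {
    opinions
  } else {
    product_initial_state(opinions, mode = mode)
  }
  pr <- consensus_projectors(n)
  stop_idx <- which(diag(pr$Ms) > 0.5)
  bu <- decision_blocks(n, topology, theta, phi)

  sigma <- outer(initial, Conj(initial))
  rho_T_mid <- NULL
  for (t in seq_len(measure_step)) {
    st <- walk_step(sigma, bu$blocks, stop_idx)
    rho_T_mid <- st$rho_T
    sigma <- st$sigma_next
    if (is.null(sigma) && t < measure_step) {
      stop("walk absorbed before the measurement step")
    }
  }
  sigma_mid <- sigma  # post-projection continue state at measure_step

  ops <- pair_measurement_ops(n, agents)
  u <- vapply(ops, function(P) Re(sum(diag(P) * diag(rho_T_mid))),
              numeric(1))
  remaining <- horizon - measure_step
  v <- numeric(4)
  for (i in 1:4) {
    if (u[i] < 1e-12) { v[i] <- 0; next }
    sel <- which(diag(ops[[i]]) > 0.5)
    branch <- matrix(0, 2^n, 2^n)
    branch[sel, sel] <- rho_T_mid[sel, sel]
    branch <- branch / u[i]
    # continue projection before further evolution, as in every other step
    pc_b <- 1 - sum(Re(diag(branch))[stop_idx])
    if (pc_b < 1e-14) {
      v[i] <- consensus_share(branch, n)
      next
    }
    branch[stop_idx, ] <- 0
    branch[, stop_idx] <- 0
    branch <- branch / pc_b
    rho_T_end <- evolve_reduced(branch, bu, stop_idx, remaining)
    v[i] <- consensus_share(rho_T_end, n)
  }
  rho_T_base <- evolve_reduced(sigma_mid, bu, stop_idx, remaining)
  baseline <- consensus_share(rho_T_base, n)
  structure(list(
    u = u, v = v, composite = sum(u * v), baseline = baseline,
    interference = baseline - sum(u * v),
    measure_step = measure_step, horizon = horizon, agents = sort(agents),
    branches = tibble::tibble(
      outcome = c("00", "01", "10", "11"), u = u, v = v, uv = u * v)
  ), class = "branch_ensemble")
}

#' @export
print.branch_ensemble <- function(x, ...) {
  cat("<branch_ensemble> pair (A", x$agents[1], ", A", x$agents[2],
      ") measured at step ", x$measure_step, ", horizon ", x$horizon, "\n",
      sep = "")
  print(x$branches)
  cat("classical composite u.v = ", format(x$composite, digits = 6),
      "; unmeasured baseline = ", format(x$baseline, digits = 6),
      "\ninterference (baseline - composite) = ",
      format(x$interference, digits = 6), "\n", sep = "")
  invisible(x)
}
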