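#' Stopping projector for idea propagation
#'
#' Idea propagation stops when every agent holds the idea, i.e. at the
#' all-ones basis state; the projector carries a single 1 at the last
#' diagonal entry.
#'
#' @param n Number of agents.
#' @return A `2^n` diagonal 0/1 matrix.
#' @export
all_infected_projector <- function(n) {
  measurement_projector(n, 2^n, label = "all_infected")
}

#' Mean number of infected agents
#'
#' The expectation of the infected-agent count under the diagonal of a
#' reduced network state: \eqn{\sum_i w_i \rho_{ii}} with \eqn{w_i} the
#' number of 1-bits of basis state i (for three agents the weight vector
#' is 0,1,1,2,1,2,2,3).
#'
#' @param sigma Reduced density matrix on `2^n` basis states.
#' @return A number in `[0, n]`.
#' @export
mean_infected <- function(sigma) {
  d <- nrow(sigma)
  w <- popcount(seq_len(d))
  sum(w * Re(diag(sigma)))
}

# One lift -> evolve -> partial-trace -> measure -> project step.
#
# With sigma the reduced state and U = diag(U_1..U_d) block diagonal, the
# lifted state sigma (x) sigma has diagonal blocks sigma_ii * sigma, so
#   rho_T = Tr_C(U (sigma (x) sigma) U^dag) = sum_i sigma_ii U_i sigma U_i^dag.
# This block-structured contraction is algebraically identical to the dense
# 4^n evolution (a tested contract) and is what makes thousand-step runs
# cheap.
walk_step <- function(sigma, blocks, stop_idx) {
  d <- nrow(sigma)
  w <- Re(diag(sigma))
  rho_T <- matrix(0, d, d)
  for (i in seq_len(d)) {
    if (w[i] == 0) next
    Ui <- blocks[[i]]
    rho_T <- rho_T + w[i] * (Ui %*% sigma %*% Conj(t(Ui)))
  }
  diag_T <- Re(diag(rho_T))
  ps <- sum(diag_T[stop_idx])
  pc <- sum(diag_T[-stop_idx])
  if (pc < 1e-14) {
    sigma_next <- NULL  # absorbed: all probability mass on the stop states
  } else {
    sigma_next <- rho_T
    sigma_next[stop_idx, ] <- 0
    sigma_next[, stop_idx] <- 0
    sigma_next <- sigma_next / pc
    # guard against drift over thousands of projections
    sigma_next <- (sigma_next + Conj(t(sigma_next))) / 2
    sigma_next <- sigma_next / Re(sum(diag(sigma_next)))
  }
  list(rho_T = rho_T, ps = ps, pc = pc, sigma_next = sigma_next)
}

# Dense reference for one step: lift to 4^n, multiply by the assembled
# operator, trace out the controller.  Used in tests as the contract
# partner of walk_step()'s block contraction.
walk_step_dense <- function(sigma, bu, stop_idx) {
  d <- nrow(sigma)
  U <- assemble(bu)
  rho <- kronecker(sigma, sigma)
  rho_T <- partial_trace(U %*% rho %*% Conj(t(U)), c(d, d), traced = "A")
  diag_T <- Re(diag(rho_T))
  list(rho_T = rho_T, ps = sum(diag_T[stop_idx]),
       pc = sum(diag_T[-stop_idx]))
}

#' Run a lifted quantum walk
#'
#' Iterates the walk from a pure product start: at each step the reduced
#' network state is lifted by a tensor product with itself, evolved by the
#' block-diagonal operator, reduced back by a partial trace over the
#' controller copy, and measured against the stopping projector.  The
#' per-step stop/continue split (`ps`, `pc`) is accumulated into
#' unconditional probabilities `Ps(t) = Pc(t-1) ps(t)`,
#' `Pc(t) = Pc(t-1) pc(t)`; the run ends at the first step where the
#' cumulative stop probability reaches `1 - epsilon` (equivalently, by the
#' telescoping identity, where the product of the `pc` falls to `epsilon`).
#'
#' @param bu A [block_unitary()].
#' @param initial Initial network state: a unit amplitude vector of length
#'   `2^n` (used for both controller and target copies).  Defaults to the
#'   all-uninfected basis state.
#' @param stop_projector Diagonal 0/1 matrix marking the stopping basis
#'   states; defaults to [all_infected_projector()].
#' @param epsilon Stopping tolerance in (0, 1); default 0.01.
#' @param max_steps Step cap; reaching it without meeting the criterion
#'   flags the trajectory as truncated.
#' @param horizon If supplied, run exactly this many steps and ignore the
#'   stopping criterion (used for fixed-length interference experiments).
#' @return An object of class `quantum_walk`: a list with the trajectory
#'   tibble (`step`, `ps`, `pc`, `Ps`, `Pc`, `cum_Ps`, `mean_infected`),
#'   the stopping step `t_f`, `converged`, `epsilon`, and the final
#'   pre-projection state `rho_T_final` and post-projection state
#'   `rho_c_final`.
#' @examples
#' bu <- build_line3(line3_scenario("no_disinfection"))
#' w <- run_walk(bu, epsilon = 0.5)   # short demonstration run
#' glance(w)
#' @export
run_walk <- function(bu, initial = NULL, stop_projector = NULL,
                     epsilon = 0.01, max_steps = 20000L, horizon = NULL) {
  stopifnot(inherits(bu, "block_unitary"), epsilon > 0, epsilon < 1)
  n <- bu$n_agents
  d <- 2^n
  if (is.null(initial)) initial <- basis_state(n, strrep("0", n))
  stopifnot(length(initial) == d,
            abs(sum(Mod(initial)^2) - 1) < 1e-9)
  if (is.null(stop_projector)) stop_projector <- all_infected_projector(n)
  stop_idx <- which(Re(diag(stop_projector)) > 0.5)
  stopifnot(length(stop_idx) >= 1, length(stop_idx) < d)

  n_steps <- if (is.null(horizon)) max_steps else horizon
  sigma <- outer(initial, Conj(initial))
  Pc_prev <- 1
  cum_Ps <- 0
  rows <- vector("list", min(n_steps, 50000L))
  converged <- FALSE
  rho_T <- NULL
  t <- 0L
  while (t < n_steps) {
    t <- t + 1L
    st <- walk_step(sigma, bu$blocks, stop_idx)
    Ps_t <- Pc_prev * st$ps
    Pc_t <- Pc_prev * st$pc
    cum_Ps <- cum_Ps + Ps_t
    rho_T <- st$rho_T
    mi <- if (is.null(st$sigma_next)) mean_infected(st$rho_T)
          else mean_infected(st$sigma_next)
    rows[[t]] <- c(step = t, ps = st$ps, pc = st$pc, Ps = Ps_t, Pc = Pc_t,
                   cum_Ps = cum_Ps, mean_infected = mi)
    if (is.null(st$sigma_next)) {  # absorbed into the stop states
      converged <- TRUE
      sigma <- NULL
      break
    }
    sigma <- st$sigma_next
    Pc_prev <- Pc_t
    if (is.null(horizon) && cum_Ps >= 1 - epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!is.null(horizon)) converged <- TRUE
  traj <- tibble::as_tibble(do.call(rbind, rows[seq_len(t)]))
  structure(list(trajectory = traj, t_f = t, converged = converged,
                 truncated = !converged, epsilon = epsilon,
                 n_agents = n, stop_idx = stop_idx,
                 rho_T_final = rho_T, rho_c_final = sigma),
            class = "quantum_walk")
}

#' @export
print.quantum_walk <- function(x, ...) {
  cat("<quantum_walk> ", x$n_agents, " agents, ", x$t_f, " steps",
      if (x$truncated) " (truncated before the stopping criterion)",
      "\n  cumulative stop probability: ",
      format(x$trajectory$cum_Ps[x$t_f], digits = 6),
      " (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Write a walk trajectory to CSV
#'
#' One row per step with columns `step, ps, pc, Ps, Pc, cum_Ps,
#' mean_infected`, numbers at 10 significant digits.
#'
#' @param walk A `quantum_walk`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(walk, path) {
  stopifnot(inherits(walk, "quantum_walk"))
  tr <- walk$trajectory
  out <- data.frame(
    step = as.integer(tr$step),
    lapply(tr[c("ps", "pc", "Ps", "Pc", "cum_Ps", "mean_infected")],
           function(x) formatC(x, digits = 10, format = "g"))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a trajectory CSV
#'
#' @param path File written by [write_trajectory()].
#' @return A tibble with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
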