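#' Single-qubit measurement projectors
#'
#' `proj0()` and `proj1()` return the 2x2 projectors onto the local basis
#' states \eqn{|0\rangle} (idea rejected / agent uninfected) and
#' \eqn{|1\rangle} (idea adopted).  They are the two branches of every
#' controlled gate: together they resolve the identity, `proj0() + proj1()`.
#'
#' @return A 2x2 numeric matrix.
#' @export
proj0 <- function() matrix(c(1, 0, 0, 0), 2, 2)

#' @rdname proj0
#' @export
proj1 <- function() matrix(c(0, 0, 0, 1), 2, 2)

#' Two-dimensional rotation gate
#'
#' The elementary infection operator.  A positive angle rotates amplitude
#' from \eqn{|0\rangle} towards \eqn{|1\rangle} (the agent drifts towards
#' adopting the idea); a negative angle models counteraction/disinfection.
#'
#' @param theta Rotation angle in radians (not wrapped or normalised).
#' @return The 2x2 real orthogonal matrix
#'   \deqn{R(\theta) = \begin{pmatrix}\cos\theta & -\sin\theta\\
#'   \sin\theta & \cos\theta\end{pmatrix}.}
#' @examples
#' rotation_gate(0)            # identity
#' rotation_gate(pi / 2) %*% c(1, 0)  # |0> -> |1>
#' @export
rotation_gate <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Kronecker product over a list, first element most significant.
kron_all <- function(mats) Reduce(kronecker, mats)

# Full n-qubit operator from per-agent 2x2 factors.  Agent 1 occupies the
# least significant tensor slot, so the product runs agent n down to agent 1.
agent_kron <- function(factors) kron_all(rev(factors))

#' Computational basis state of an agent network
#'
#' Encodes the global network state \eqn{|b_n \cdots b_2 b_1\rangle}
#' (agent k's bit in position k, agent 1 least significant) as a unit
#' vector of length \eqn{2^n}.  The 1-based basis index is the binary
#' value of the bit string plus one, so for three agents "101" is basis
#' state 6.
#'
#' @param n Number of agents (qubits), a positive integer.
#' @param bits Bit string of length `n`, written most significant first
#'   (agent n's bit leftmost), e.g. `"101"` for A3 = 1, A2 = 0, A1 = 1.
#' @return Numeric unit vector of length `2^n`.
#' @examples
#' which(basis_state(3, "101") == 1)  # 6
#' @export
basis_state <- function(n, bits) {
  stopifnot(is.character(bits), length(bits) == 1L)
  if (nchar(bits) != n || grepl("[^01]", bits)) {
    stop("`bits` must be a string of exactly ", n, " characters, each 0 or 1")
  }
  v <- numeric(2^n)
  v[strtoi(bits, base = 2L) + 1L] <- 1
  v
}

# Bit of agent k (1-based, least significant) in the 1-based basis index i.
agent_bit <- function(i, k) bitwAnd(bitwShiftR(i - 1L, k - 1L), 1L)

# Number of infected agents in basis index i (popcount of i - 1).
popcount <- function(i) {
  vapply(i, function(x) sum(agent_bit(x, seq_len(32L)) == 1L), integer(1))
}

#' Generic controlled-rotation gate
#'
#' Builds the two-branch controlled unitary on `n` qubits that applies the
#' given rotations to the target agents when the control agent is in basis
#' state `control_value`, and does nothing otherwise:
#' \deqn{U = \bigotimes_k F_k + \bigotimes_k G_k,}
#' where the control slot carries the projector onto `control_value` in the
#' first branch (targets carry their rotations) and the projector onto the
#' complementary value in the second branch (all other slots identity).
#' Several targets fire together, which equals applying them one after
#' another under the same control.
#'
#' @param n Number of agents.
#' @param control_agent 1-based index of the controlling agent.
#' @param control_value 0 or 1; the control basis state that switches the
#'   rotations on.
#' @param targets Data frame (or list coercible to one) with columns
#'   `agent` and `angle`: the agents to rotate and their angles in radians.
#' @return A `2^n` x `2^n` real orthogonal matrix.
#' @examples
#' # infect A2 when A1 holds the idea (3 agents):
#' U <- build_controlled_gate(3, 1, 1, data.frame(agent = 2, angle = 0.05))
#' validate_unitary(U)
#' @export
build_controlled_gate <- function(n, control_agent, control_value, targets) {
  targets <- as.data.frame(targets)
  stopifnot(
    all(c("agent", "angle") %in% names(targets)),
    control_agent %in% seq_len(n),
    control_value %in% c(0L, 1L),
    all(targets$agent %in% seq_len(n))
  )
  idx <- c(control_agent, targets$agent)
  if (anyDuplicated(idx)) {
    stop("control agent and target agents must be distinct")
  }
  on_proj  <- if (control_value == 1) proj1() else proj0()
  off_proj <- if (control_value == 1) proj0() else proj1()
  I2 <- diag(2)
  act <- replicate(n, I2, simplify = FALSE)
  act[[control_agent]] <- on_proj
  for (r in seq_len(nrow(targets))) {
    act[[targets$agent[r]]] <- rotation_gate(targets$angle[r])
  }
  idle <- replicate(n, I2, simplify = FALSE)
  idle[[control_agent]] <- off_proj
  agent_kron(act) + agent_kron(idle)
}

#' Unconditional product of local rotations
#'
#' Rotates each listed agent by its angle with no control condition: the
#' tensor product of `rotation_gate(angle_k)` over agents (identity on
#' unlisted agents).  Used for the initialization block that seeds the idea
#' into every agent simultaneously and independently.
#'
#' @inheritParams build_controlled_gate
#' @param rotations Data frame with columns `agent`, `angle`.
#' @return A `2^n` x `2^n` real orthogonal matrix.
#' @export
build_unconditional <- function(n, rotations) {
  rotations <- as.data.frame(rotations)
  stopifnot(
    all(c("agent", "angle") %in% names(rotations)),
    all(rotations$agent %in% seq_len(n)),
    !anyDuplicated(rotations$agent)
  )
  factors <- replicate(n, diag(2), simplify = FALSE)
  for (r in seq_len(nrow(rotations))) {
    factors[[rotations$agent[r]]] <- rotation_gate(rotations$angle[r])
  }
  agent_kron(factors)
}

#' Partial trace of a bipartite density operator
#'
#' Reduces a density operator on \eqn{A \otimes B} (first tensor factor
#' most significant, as produced by `kronecker()`) to one subsystem by
#' tracing out the other.  Trace and Hermiticity are preserved.
#'
#' @param rho Square matrix of dimension `prod(dims)`.
#' @param dims Integer vector `c(dA, dB)` of the two factor dimensions.
#' @param traced Which factor to trace out, `"A"` (the leading/controller
#'   factor) or `"B"`.
#' @return The reduced density matrix of the kept factor.
#' @examples
#' bell <- c(1, 0, 0, 1) / sqrt(2)
#' partial_trace(outer(bell, bell), c(2, 2), "B")  # I/2
#' @export
partial_trace <- function(rho, dims, traced = c("A", "B")) {
  traced <- match.arg(traced)
  dA <- as.integer(dims[1]); dB <- as.integer(dims[2])
  if (nrow(rho) != dA * dB || ncol(rho) != dA * dB) {
    stop("dims (", dA, " x ", dB, ") do not factorise a ",
         nrow(rho), " x ", ncol(rho), " matrix")
  }
  if (traced == "B") {
    out <- matrix(0, dA, dA)
    for (k in seq_len(dB)) {
      idx <- seq(k, by = dB, length.out = dA)
      out <- out + rho[idx, idx]
    }
  } else {
    out <- matrix(0, dB, dB)
    for (i in seq_len(dA)) {
      idx <- (i - 1L) * dB + seq_len(dB)
      out <- out + rho[idx, idx]
    }
  }
  out
}

#' Interaction scripts and their compilation
#'
#' An interaction script is an ordered list of gate specifications, each
#' either a controlled step (`control_agent`, `control_value`, `targets`)
#' or an unconditional step (`targets` only).  `compile_script()` multiplies
#' the corresponding gates so the first listed step acts first (it is the
#' rightmost factor of the matrix product).
#'
#' @param script List of steps; each step is a list with element `targets`
#'   (data frame with `agent`, `angle`) and optionally `control_agent` and
#'   `control_value`.
#' @param n Number of agents.
#' @return A `2^n` x `2^n` matrix, unitary to 1e-10.
#' @export
compile_script <- function(script, n) {
  U <- diag(2^n)
  for (step in script) {
    g <- if (is.null(step$control_agent)) {
      build_unconditional(n, step$targets)
    } else {
      build_controlled_gate(n, step$control_agent, step$control_value,
                            step$targets)
    }
    U <- g %*% U
  }
  U
}

# Shorthand for a controlled script step.
ctrl_step <- function(control_agent, control_value, agent, angle) {
  list(control_agent = control_agent, control_value = control_value,
       targets = data.frame(agent = agent, angle = angle))
}

# Multiply every angle in a script by a scale factor (half-turn settings
# -> radians).
scale_script <- function(script, s) {
  if (s == 1) return(script)
  lapply(script, function(step) {
    step$targets$angle <- step$targets$angle * s
    step
  })
}

#' Numerical validity checks for operators
#'
#' `validate_unitary()` checks \eqn{\|U^\dagger U - I\|_{max}} against a
#' tolerance; `validate_density()` checks Hermiticity, unit trace, and
#' positive semidefiniteness of a density matrix.
#'
#' @param M,rho Square matrix to check.
#' @param tol Unitarity tolerance (default 1e-10).
#' @param herm_tol,trace_tol Hermiticity / trace tolerances (default 1e-9).
#' @param psd_floor Eigenvalue floor (default -1e-9).
#' @return `TRUE` or `FALSE`.
#' @export
validate_unitary <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) return(FALSE)
  max(abs(Conj(t(M)) %*% M - diag(nrow(M)))) < tol
}

#' @rdname validate_unitary
#' @export
validate_density <- function(rho, herm_tol = 1e-9, trace_tol = 1e-9,
                             psd_floor = -1e-9) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) return(FALSE)
  if (max(abs(rho - Conj(t(rho)))) >= herm_tol) return(FALSE)
  if (abs(Re(sum(diag(rho))) - 1) >= trace_tol) return(FALSE)
  if (abs(Im(sum(diag(rho)))) >= trace_tol) return(FALSE)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  min(Re(ev)) > psd_floor
}

#' Diagonal measurement projector
#'
#' Builds the diagonal 0/1 projector on `2^n` basis states selecting the
#' given 1-based basis indices.
#'
#' @param n Number of agents.
#' @param indices 1-based basis indices carrying a 1 on the diagonal.
#' @param label Optional text label attached as an attribute.
#' @return A `2^n` x `2^n` diagonal 0/1 matrix.
#' @export
measurement_projector <- function(n, indices, label = NULL) {
  d <- 2^n
  stopifnot(all(indices >= 1), all(indices <= d))
  m <- diag(as.numeric(seq_len(d) %in% indices))
  if (!is.null(label)) attr(m, "label") <- label
  m
}
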