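#' Angle settings for the 3-agent ring graph
#'
#' The 3-agent ring (every agent talks to both others) reuses the
#' line-graph blocks U1, U3, U6, U8 and replaces U2, U4, U5, U7 with
#' scripts in which the single infected (or single uninfected) agent
#' exchanges with both neighbours: one joint "lecture" to both listeners
#' where possible, with feedback given in order.  Angles not supplied
#' default to 0.
#'
#' @inheritParams line3_angles
#' @param U2 Named angles theta_y, theta_z (joint lecture by A1),
#'   theta_xy, theta_xz (feedback on A1 from A2 then A3).
#' @param U4 Named angles theta_z (A2's and A1's lectures of A3, both use
#'   this name), theta_y, theta_x (feedback on A2 / A1 from A3).
#' @param U5 Named angles theta_y, theta_x (lectures by A3), theta_zy,
#'   theta_zx (feedback on A3).
#' @param U7 Named angles theta_xy, theta_xz (lectures of A1 by A2 and
#'   A3), theta_y, theta_z (feedback from A1).
#' @return A named list of class `ring3_angles`.
#' @export
ring3_angles <- function(U1 = NULL, U2 = NULL, U3 = NULL, U4 = NULL,
                         U5 = NULL, U6 = NULL, U7 = NULL) {
  allowed <- list(
    U1 = c("theta_x", "theta_y", "theta_z"),
    U2 = c("theta_y", "theta_z", "theta_xy", "theta_xz"),
    U3 = c("theta_x", "theta_z", "theta_yx", "theta_yz"),
    U4 = c("theta_y", "theta_z", "theta_x"),
    U5 = c("theta_y", "theta_x", "theta_zy", "theta_zx"),
    U6 = c("theta_x", "theta_z", "theta_xy", "theta_zy"),
    U7 = c("theta_xy", "theta_xz", "theta_y", "theta_z")
  )
  supplied <- list(U1 = U1, U2 = U2, U3 = U3, U4 = U4, U5 = U5, U6 = U6,
                   U7 = U7)
  out <- lapply(names(allowed), function(b) {
    full <- stats::setNames(numeric(length(allowed[[b]])), allowed[[b]])
    s <- supplied[[b]]
    if (!is.null(s)) {
      s <- unlist(s)
      bad <- setdiff(names(s), allowed[[b]])
      if (length(bad)) stop("unknown angle(s) for ", b, ": ",
                            paste(bad, collapse = ", "))
      stopifnot(all(is.finite(s)))
      full[names(s)] <- s
    }
    full
  })
  names(out) <- names(allowed)
  structure(out, class = "ring3_angles")
}

#' Homogeneous ring-3 angles
#'
#' Convenience constructor assigning one infection angle `theta` to every
#' lecture rotation and one counteraction angle `phi` to every feedback
#' rotation across all blocks (the initialization block gets `theta` on
#' each agent).
#'
#' @param theta Infection angle in radians.
#' @param phi Counteraction angle in radians (typically negative).
#' @return A `ring3_angles` object.
#' @export
ring3_homogeneous <- function(theta, phi) {
  ring3_angles(
    U1 = c(theta_x = theta, theta_y = theta, theta_z = theta),
    U2 = c(theta_y = theta, theta_z = theta, theta_xy = phi, theta_xz = phi),
    U3 = c(theta_x = theta, theta_z = theta, theta_yx = phi, theta_yz = phi),
    U4 = c(theta_z = theta, theta_y = phi, theta_x = phi),
    U5 = c(theta_y = theta, theta_x = theta, theta_zy = phi, theta_zx = phi),
    U6 = c(theta_x = theta, theta_z = theta, theta_xy = phi, theta_zy = phi),
    U7 = c(theta_xy = theta, theta_xz = theta, theta_y = phi, theta_z = phi)
  )
}

#' Build the 3-agent ring-graph block unitary
#'
#' As [build_line3()] but with the four blocks whose controller has a
#' single infected or single uninfected agent rewritten for the ring: in
#' block 2 A1 lectures A2 and A3 jointly (then A2, then A3, feed back);
#' blocks 4 and 5 let A2 interact with A3 before A1 does; block 7 has A2
#' then A3 lecture the lone hold-out A1.  Rotation placements follow the
#' tensor positions of the defining matrix products literally.
#'
#' Angle settings are in half-turn units, as in [build_line3()].
#'
#' @param angles A [ring3_angles()] object.
#' @param angle_scale Factor converting angle settings to radians;
#'   default `pi`.
#' @return A [block_unitary()] with 8 blocks of 8x8.
#' @export
build_ring3 <- function(angles = ring3_angles(), angle_scale = pi) {
  if (!inherits(angles, "ring3_angles")) angles <- do.call(ring3_angles, angles)
  a <- angles
  line_part <- build_line3(line3_angles(U1 = a$U1, U3 = a$U3, U6 = a$U6),
                           angle_scale = angle_scale)
  scripts <- list(
    U2 = list(list(control_agent = 1, control_value = 1,
                   targets = data.frame(agent = c(3, 2),
                                        angle = c(a$U2[["theta_y"]],
                                                  a$U2[["theta_z"]]))),
              ctrl_step(2, 0, 1, a$U2[["theta_xy"]]),
              ctrl_step(3, 0, 1, a$U2[["theta_xz"]])),
    U4 = list(ctrl_step(2, 1, 3, a$U4[["theta_z"]]),
              ctrl_step(3, 0, 2, a$U4[["theta_y"]]),
              ctrl_step(3, 0, 1, a$U4[["theta_x"]]),
              ctrl_step(1, 1, 3, a$U4[["theta_z"]])),
    U5 = list(ctrl_step(3, 1, 2, a$U5[["theta_y"]]),
              ctrl_step(2, 0, 3, a$U5[["theta_zy"]]),
              ctrl_step(3, 1, 1, a$U5[["theta_x"]]),
              ctrl_step(1, 0, 3, a$U5[["theta_zx"]])),
    U7 = list(ctrl_step(2, 1, 1, a$U7[["theta_xy"]]),
              ctrl_step(1, 0, 2, a$U7[["theta_y"]]),
              ctrl_step(3, 1, 1, a$U7[["theta_xz"]]),
              ctrl_step(1, 0, 3, a$U7[["theta_z"]]))
  )
  blocks <- line_part$blocks
  for (b in c(2L, 4L, 5L, 7L)) {
    blocks[[b]] <- compile_script(scale_script(scripts[[paste0("U", b)]],
                                               angle_scale), 3)
  }
  block_unitary(blocks, 3, topology = "ring")
}

# Neighbours of agent k on an n-ring or n-line (1-based, sorted).
graph_neighbors <- function(k, n, topology = c("ring", "line")) {
  topology <- match.arg(topology)
  nb <- c(k - 1L, k + 1L)
  if (topology == "ring") {
    nb[nb == 0L] <- n
    nb[nb == n + 1L] <- 1L
  } else {
    nb <- nb[nb >= 1L & nb <= n]
  }
  sort(unique(nb))
}

# Bits of the controller basis state for index i (agent k = element k).
index_bits <- function(i, n) vapply(seq_len(n), agent_bit, integer(1), i = i)

#' Interacting agent pairs for a controller basis state
#'
#' Interaction only happens between connected agents holding different
#' ideas.  Given the controller bit string, returns all adjacent pairs
#' with differing bits as (infected agent, uninfected neighbour), ordered
#' by increasing lower pair index.
#'
#' @param bits Bit string written most significant first (as in
#'   [basis_state()]), or an integer vector of per-agent bits (element k
#'   = agent k).
#' @param topology `"ring"` or `"line"`.
#' @param include_wrap Include the (A1, An) pair for rings?  Defaults to
#'   `TRUE`, the ring's full adjacency; set `FALSE` for the alternative
#'   convention in which the wrap-around pair generates no interaction.
#' @return A [tibble::tibble] with columns `infected`, `uninfected`.
#' @export
interaction_pairs <- function(bits, topology = c("ring", "line"),
                              include_wrap = TRUE) {
  topology <- match.arg(topology)
  if (is.character(bits)) {
    n <- nchar(bits)
    b <- rev(as.integer(strsplit(bits, "")[[1]]))
  } else {
    n <- length(bits)
    b <- as.integer(bits)
  }
  stopifnot(all(b %in% 0:1))
  lo <- seq_len(n - 1L)
  hi <- lo + 1L
  if (topology == "ring" && include_wrap && n > 2L) {
    lo <- c(lo, 1L)
    hi <- c(hi, n)
  }
  keep <- b[lo] != b[hi]
  lo <- lo[keep]; hi <- hi[keep]
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  inf <- ifelse(b[lo] == 1L, lo, hi)
  tibble::tibble(infected = inf, uninfected = lo + hi - inf)
}

# Expand a scalar angle (or n x n matrix) into a lookup function a(i, j).
angle_lookup <- function(x, n, what) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(n, n)))
    function(i, j) x[i, j]
  } else {
    stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
    function(i, j) x
  }
}

# Script for one non-trivial ring-n block: each infected agent, in
# increasing index order, lectures all of its currently-uninfected
# neighbours jointly, then receives feedback from each of them in
# increasing neighbour order.  Neighbour sets are evaluated once against
# the controller bit string.
ring_block_script <- function(b, n, th, ph, include_wrap) {
  pairs <- interaction_pairs(b, "ring", include_wrap = include_wrap)
  script <- list()
  for (k in seq_len(n)) {
    if (b[k] != 1L) next
    listeners <- sort(pairs$uninfected[pairs$infected == k])
    if (!length(listeners)) next
    script <- c(script, list(list(
      control_agent = k, control_value = 1,
      targets = data.frame(agent = listeners,
                           angle = vapply(listeners, function(j) th(j, k),
                                          numeric(1))))))
    for (j in listeners) {
      script <- c(script, list(ctrl_step(j, 0, k, ph(k, j))))
    }
  }
  script
}

#' Build an n-agent ring-graph block unitary (n > 3)
#'
#' Generates the \eqn{2^n} blocks of the walk operator for a ring of
#' `n` agents from pairwise rotation angles.  Block i is derived from the
#' controller basis state i: the all-one block is the identity; the
#' all-zero block is either the unconditional seeding rotation
#' \eqn{\bigotimes_k R(\theta_k)} (`initializing = TRUE`, idea
#' propagation) or the identity (`initializing = FALSE`, group decision
#' making, where opinions need no seeding); every other block runs the
#' infect-then-counteract exchange between every connected pair of agents
#' holding different ideas, lower-indexed speakers first (see
#' [interaction_pairs()]).
#'
#' @param n Number of agents, n > 3.
#' @param theta Infection angle(s): scalar or n x n matrix with
#'   `theta[i, j]` the rotation of Ai when lectured by Aj.
#' @param phi Counteraction angle(s): scalar or n x n matrix with
#'   `phi[i, j]` the feedback rotation of Ai from Aj.
#' @param initializing Seed the idea in the all-zero block?
#' @param theta_init Per-agent seeding angles for the all-zero block
#'   (length n or scalar); defaults to the scalar `theta` when
#'   `initializing = TRUE`.
#' @param include_wrap Include the (A1, An) interaction pair; see
#'   [interaction_pairs()].
#' @param angle_scale Factor converting angle settings to radians
#'   (half-turn convention, as in [build_line3()]); default `pi`.
#' @return A [block_unitary()] with `2^n` blocks of `2^n` x `2^n`.
#' @export
build_ring_n <- function(n, theta, phi, initializing = FALSE,
                         theta_init = NULL, include_wrap = TRUE,
                         angle_scale = pi) {
  if (n <= 3L) stop("build_ring_n() requires n > 3; use build_ring3() for n = 3")
  th0 <- angle_lookup(theta, n, "theta")
  ph0 <- angle_lookup(phi, n, "phi")
  th <- function(i, j) th0(i, j) * angle_scale
  ph <- function(i, j) ph0(i, j) * angle_scale
  d <- 2^n
  blocks <- vector("list", d)
  for (i in seq_len(d)) {
    b <- index_bits(i, n)
    if (all(b == 1L)) {
      blocks[[i]] <- diag(d)
    } else if (all(b == 0L)) {
      if (initializing) {
        ti <- if (is.null(theta_init)) {
          if (is.matrix(theta)) stop("supply `theta_init` for matrix `theta`")
          rep(theta, n)
        } else {
          rep_len(theta_init, n)
        }
        blocks[[i]] <- build_unconditional(
          n, data.frame(agent = seq_len(n), angle = ti * angle_scale))
      } else {
        blocks[[i]] <- diag(d)
      }
    } else {
      blocks[[i]] <- compile_script(ring_block_script(b, n, th, ph,
                                                      include_wrap), n)
    }
  }
  block_unitary(blocks, n, topology = "ring")
}
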