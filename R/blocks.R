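#' Block-diagonal walk operator
#'
#' The walk operator on the lifted (network x mirror) space is block
#' diagonal, \eqn{U = \mathrm{diag}(U_1, \ldots, U_{2^n})}: when the
#' controller (original network) occupies basis state i, block
#' \eqn{U_i} acts on the mirror.  `block_unitary()` bundles the blocks;
#' `assemble()` expands them into the dense \eqn{4^n \times 4^n} matrix.
#'
#' @param blocks List of `2^n` square matrices, each `2^n` x `2^n`.
#' @param n_agents Number of agents n.
#' @param topology Optional label ("line" or "ring") kept for printing.
#' @return An object of class `block_unitary`.
#' @export
block_unitary <- function(blocks, n_agents, topology = NULL) {
  d <- 2^n_agents
  stopifnot(length(blocks) == d,
            all(vapply(blocks, function(b) all(dim(b) == c(d, d)), logical(1))))
  structure(list(blocks = blocks, n_agents = n_agents, topology = topology),
            class = "block_unitary")
}

#' @export
print.block_unitary <- function(x, ...) {
  cat("<block_unitary> ", length(x$blocks), " blocks of ",
      2^x$n_agents, "x", 2^x$n_agents,
      if (!is.null(x$topology)) paste0(" (", x$topology, " graph)"), "\n",
      sep = "")
  invisible(x)
}

#' @rdname block_unitary
#' @param bu A `block_unitary`.
#' @return `assemble()`: the dense block-diagonal matrix of dimension `4^n`.
#' @export
assemble <- function(bu) {
  stopifnot(inherits(bu, "block_unitary"))
  d <- 2^bu$n_agents
  U <- matrix(0, d * d, d * d)
  for (i in seq_len(d)) {
    idx <- (i - 1L) * d + seq_len(d)
    U[idx, idx] <- bu$blocks[[i]]
  }
  U
}

# Check every block of a block_unitary for unitarity.
validate_blocks <- function(bu, tol = 1e-10) {
  all(vapply(bu$blocks, validate_unitary, logical(1), tol = tol))
}

#' Angle settings for the 3-agent line graph
#'
#' Collects the per-block named rotation angles of the 3-agent line-graph
#' walk operator.  Each block has its own small set of named angles
#' (infection angles `theta_x`, `theta_y`, `theta_z` and counteraction
#' angles such as `theta_yx`, read "rotation of A2 controlled by A1");
#' any angle not supplied defaults to 0.  Negative angles model
#' disinfection.
#'
#' @param U1,U2,U3,U4,U5,U6,U7 Named numeric vectors (or lists) of angles
#'   in radians for the corresponding block.  Recognised names per block:
#'   U1: theta_x, theta_y, theta_z; U2: theta_y, theta_x;
#'   U3: theta_x, theta_z, theta_yx, theta_yz; U4: theta_z, theta_y;
#'   U5: theta_y, theta_z; U6: theta_x, theta_z, theta_xy, theta_zy;
#'   U7: theta_x, theta_y.
#' @return A named list of class `line3_angles`.
#' @export
line3_angles <- function(U1 = NULL, U2 = NULL, U3 = NULL, U4 = NULL,
                         U5 = NULL, U6 = NULL, U7 = NULL) {
  allowed <- list(
    U1 = c("theta_x", "theta_y", "theta_z"),
    U2 = c("theta_y", "theta_x"),
    U3 = c("theta_x", "theta_z", "theta_yx", "theta_yz"),
    U4 = c("theta_z", "theta_y"),
    U5 = c("theta_y", "theta_z"),
    U6 = c("theta_x", "theta_z", "theta_xy", "theta_zy"),
    U7 = c("theta_x", "theta_y")
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
  structure(out, class = "line3_angles")
}

#' Build the 3-agent line-graph block unitary
#'
#' Compiles the eight blocks of the line-graph walk operator from named
#' angle settings.  Block i is switched on when the controller network
#' occupies basis state i ("which agents currently hold the idea"):
#' block 1 (no one infected) seeds the idea into every agent
#' unconditionally; blocks 2-7 encode infect-first-then-counteract
#' exchanges between adjacent agents along A1 -- A2 -- A3; block 8
#' (everyone infected) is the identity, propagation is over.
#'
#' Angle settings are expressed in the scenario convention of units of
#' \eqn{\pi} radians (half-turns): a setting of 0.05 rotates by
#' \eqn{0.05\pi}.  This is the convention under which the worked
#' scenarios' printed settings reproduce the reported stopping times; set
#' `angle_scale = 1` to interpret settings as plain radians.
#'
#' @param angles A [line3_angles()] object (or list coercible to one).
#' @param angle_scale Factor converting angle settings to radians;
#'   default `pi`.
#' @return A [block_unitary()] with 8 blocks of 8x8.
#' @export
build_line3 <- function(angles = line3_angles(), angle_scale = pi) {
  if (!inherits(angles, "line3_angles")) angles <- do.call(line3_angles, angles)
  a <- angles
  scripts <- list(
    # U1: seed all three agents, no condition
    list(list(targets = data.frame(agent = 1:3,
                                   angle = c(a$U1["theta_x"], a$U1["theta_y"],
                                             a$U1["theta_z"])))),
    # U2: A1 infects A2, then A2 (if still clean) counteracts A1
    list(ctrl_step(1, 1, 2, a$U2[["theta_y"]]),
         ctrl_step(2, 0, 1, a$U2[["theta_x"]])),
    # U3: A2 infects both neighbours, then each clean neighbour pushes back
    list(ctrl_step(2, 1, 1, a$U3[["theta_x"]]),
         ctrl_step(2, 1, 3, a$U3[["theta_z"]]),
         ctrl_step(3, 0, 2, a$U3[["theta_yz"]]),
         ctrl_step(1, 0, 2, a$U3[["theta_yx"]])),
    # U4: A2 infects A3, A3 counteracts A2
    list(ctrl_step(2, 1, 3, a$U4[["theta_z"]]),
         ctrl_step(3, 0, 2, a$U4[["theta_y"]])),
    # U5: A3 infects A2, A2 counteracts A3
    list(ctrl_step(3, 1, 2, a$U5[["theta_y"]]),
         ctrl_step(2, 0, 3, a$U5[["theta_z"]])),
    # U6: both ends infect A2, A2 (still clean) counteracts both
    list(ctrl_step(1, 1, 2, a$U6[["theta_x"]]),
         ctrl_step(3, 1, 2, a$U6[["theta_z"]]),
         ctrl_step(2, 0, 1, a$U6[["theta_xy"]]),
         ctrl_step(2, 0, 3, a$U6[["theta_zy"]])),
    # U7: A2 infects A1, A1 counteracts A2
    list(ctrl_step(2, 1, 1, a$U7[["theta_x"]]),
         ctrl_step(1, 0, 2, a$U7[["theta_y"]]))
  )
  blocks <- c(lapply(scripts, function(s) {
    compile_script(scale_script(s, angle_scale), n = 3)
  }), list(diag(8)))
  block_unitary(blocks, 3, topology = "line")
}

#' Bundled 3-agent line-graph scenarios
#'
#' Returns the angle settings of the three worked line-graph propagation
#' scenarios: `"no_disinfection"` (all counteraction angles positive, the
#' first speaker in every exchange has the larger angle),
#' `"stubborn_middle"` (A2 is hard to persuade but influential: its
#' neighbours' angles on A2 are small, A2's counteractions are negative
#' and strong), and `"compliant_middle"` (A2 is easily persuaded and only
#' weakly pushes back).
#'
#' @param name One of `"no_disinfection"`, `"stubborn_middle"`,
#'   `"compliant_middle"`.
#' @return A [line3_angles()] object.
#' @export
line3_scenario <- function(name = c("no_disinfection", "stubborn_middle",
                                    "compliant_middle")) {
  name <- match.arg(name)
  switch(name,
    no_disinfection = line3_angles(
      U1 = c(theta_x = 0.05, theta_y = 0.01, theta_z = 0.01),
      U2 = c(theta_x = 0.01, theta_y = 0.05),
      U3 = c(theta_x = 0.05, theta_z = 0.05, theta_yx = 0.01, theta_yz = 0.01),
      U4 = c(theta_z = 0.05, theta_y = 0.01),
      U5 = c(theta_z = 0.01, theta_y = 0.05),
      U6 = c(theta_x = 0.025, theta_z = 0.025, theta_xy = 0.01,
             theta_zy = 0.01),
      U7 = c(theta_x = 0.05, theta_y = 0.01)
    ),
    stubborn_middle = line3_angles(
      U1 = c(theta_x = 0.05, theta_y = 0.01, theta_z = 0.05),
      U2 = c(theta_y = 0.01, theta_x = -0.02),
      U3 = c(theta_x = 0.02, theta_z = 0.02, theta_yx = -0.01,
             theta_yz = -0.01),
      U4 = c(theta_z = 0.02, theta_y = -0.01),
      U5 = c(theta_y = 0.01, theta_z = -0.02),
      U6 = c(theta_x = 0.01, theta_z = 0.01, theta_xy = -0.02,
             theta_zy = -0.02),
      U7 = c(theta_y = -0.01, theta_x = 0.02)
    ),
    compliant_middle = line3_angles(
      U1 = c(theta_x = 0.05, theta_y = 0.05, theta_z = 0.05),
      U2 = c(theta_y = 0.02, theta_x = -0.01),
      U3 = c(theta_x = 0.02, theta_z = 0.02, theta_yx = -0.01,
             theta_yz = -0.01),
      U4 = c(theta_z = 0.02, theta_y = -0.01),
      U5 = c(theta_y = 0.01, theta_z = -0.02),
      U6 = c(theta_x = 0.02, theta_z = 0.02, theta_xy = -0.01,
             theta_zy = -0.01),
      U7 = c(theta_y = -0.01, theta_x = 0.02)
    )
  )
}
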