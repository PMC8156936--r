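# Literal kronecker forms of the four ring-specific 3-agent blocks,
# written straight from their defining matrix products.
ring3_replaced_literal <- function(a) {
  I2 <- diag(2); I4 <- diag(4)
  M0 <- proj0(); M1 <- proj1()
  R <- rotation_gate
  UYZ <- I4 %x% M0 + R(a$U2[["theta_y"]]) %x% R(a$U2[["theta_z"]]) %x% M1
  UXy2 <- I2 %x% (M0 %x% R(a$U2[["theta_xy"]]) + M1 %x% I2)
  UXz2 <- M0 %x% I2 %x% R(a$U2[["theta_xz"]]) + M1 %x% I4
  U2 <- UXz2 %*% UXy2 %*% UYZ
  UYz <- (M0 %x% R(a$U4[["theta_y"]]) + M1 %x% I2) %x% I2
  UZy <- (I2 %x% M0 + R(a$U4[["theta_z"]]) %x% M1) %x% I2
  UXz4 <- M0 %x% I2 %x% R(a$U4[["theta_x"]]) + M1 %x% I4
  UZx4 <- I4 %x% M0 + R(a$U4[["theta_z"]]) %x% I2 %x% M1
  U4 <- UZx4 %*% UXz4 %*% UYz %*% UZy
  UY5 <- (M0 %x% I2 + M1 %x% R(a$U5[["theta_y"]])) %x% I2
  UX5 <- M0 %x% I4 + M1 %x% I2 %x% R(a$U5[["theta_x"]])
  UZy5 <- (R(a$U5[["theta_zy"]]) %x% M0 + I2 %x% M1) %x% I2
  UZx5 <- R(a$U5[["theta_zx"]]) %x% I2 %x% M0 + I4 %x% M1
  U5 <- UZx5 %*% UX5 %*% UZy5 %*% UY5
  UXy7 <- I2 %x% (M0 %x% I2 + M1 %x% R(a$U7[["theta_xy"]]))
  UXz7 <- M0 %x% I4 + M1 %x% I2 %x% R(a$U7[["theta_xz"]])
  UY7 <- I2 %x% (R(a$U7[["theta_y"]]) %x% M0 + I2 %x% M1)
  UZ7 <- R(a$U7[["theta_z"]]) %x% I2 %x% M0 + I4 %x% M1
  U7 <- UZ7 %*% UXz7 %*% UY7 %*% UXy7
  list(U2 = U2, U4 = U4, U5 = U5, U7 = U7)
}

test_that("ring-3 blocks match their literal kronecker products", {
  set.seed(12)
  ra <- function() runif(1, -0.3, 0.3)
  ang <- ring3_angles(
    U1 = c(theta_x = ra(), theta_y = ra(), theta_z = ra()),
    U2 = c(theta_y = ra(), theta_z = ra(), theta_xy = ra(), theta_xz = ra()),
    U3 = c(theta_x = ra(), theta_z = ra(), theta_yx = ra(), theta_yz = ra()),
    U4 = c(theta_y = ra(), theta_z = ra(), theta_x = ra()),
    U5 = c(theta_y = ra(), theta_x = ra(), theta_zy = ra(), theta_zx = ra()),
    U6 = c(theta_x = ra(), theta_z = ra(), theta_xy = ra(), theta_zy = ra()),
    U7 = c(theta_xy = ra(), theta_xz = ra(), theta_y = ra(), theta_z = ra())
  )
  bu <- build_ring3(ang, angle_scale = 1)
  ref <- ring3_replaced_literal(ang)
  expect_equal(bu$blocks[[2]], ref$U2, tolerance = 1e-12)
  expect_equal(bu$blocks[[4]], ref$U4, tolerance = 1e-12)
  expect_equal(bu$blocks[[5]], ref$U5, tolerance = 1e-12)
  expect_equal(bu$blocks[[7]], ref$U7, tolerance = 1e-12)
})

test_that("ring-3 shares the line-graph blocks away from the replaced four", {
  expect_equal(assemble(build_ring3(ring3_angles())), diag(64))
  ang <- ring3_homogeneous(0.05, -0.01)
  bu_ring <- build_ring3(ang)
  bu_line <- build_line3(line3_angles(U1 = ang$U1, U3 = ang$U3, U6 = ang$U6))
  for (i in c(1, 3, 6, 8)) {
    expect_identical(bu_ring$blocks[[i]], bu_line$blocks[[i]])
  }
  expect_true(liftwalk:::validate_blocks(bu_ring))
  expect_true(validate_unitary(assemble(bu_ring)))
})

test_that("interaction pairs list adjacent differing agents in order", {
  # worked 5-agent example: wrap pair excluded by convention choice
  p <- interaction_pairs("01101", "ring", include_wrap = FALSE)
  expect_equal(p$infected, c(1L, 3L, 4L))
  expect_equal(p$uninfected, c(2L, 2L, 5L))
  # the full ring adjacency additionally wraps A1-A5
  pw <- interaction_pairs("01101", "ring")
  expect_equal(nrow(pw), 4L)
  expect_true(any(pw$infected == 1L & pw$uninfected == 5L))
  expect_equal(nrow(interaction_pairs("00000", "ring")), 0L)
  expect_equal(nrow(interaction_pairs("1111", "ring")), 0L)
  # alternating bits interact on every adjacent pair
  expect_equal(nrow(interaction_pairs("0101", "ring")), 4L)
  expect_equal(nrow(interaction_pairs("0101", "line")), 3L)
})

test_that("the ring-n generator produces valid blocks", {
  expect_error(build_ring_n(3, 0.05, -0.05), "n > 3")
  expect_equal(assemble(build_ring_n(4, 0, 0)), diag(4^4))
  bu <- build_ring_n(5, 0.05, -0.05)
  expect_length(bu$blocks, 32L)
  expect_true(liftwalk:::validate_blocks(bu))
  expect_equal(bu$blocks[[32]], diag(32))  # all agree: nothing happens
  expect_equal(bu$blocks[[1]], diag(32))   # no seeding by default
})

test_that("the initializing all-zero block seeds every agent", {
  bu <- build_ring_n(5, 0.05, -0.05, initializing = TRUE)
  seed <- Reduce(`%x%`, replicate(5, rotation_gate(0.05 * pi),
                                  simplify = FALSE))
  expect_equal(bu$blocks[[1]], seed, tolerance = 1e-12)
  # heterogeneous per-agent seeding angles occupy their own slots
  bu2 <- build_ring_n(4, 0.05, -0.05, initializing = TRUE,
                      theta_init = c(0.1, 0.2, 0.3, 0.4), angle_scale = 1)
  expect_equal(bu2$blocks[[1]],
               rotation_gate(0.4) %x% rotation_gate(0.3) %x%
               rotation_gate(0.2) %x% rotation_gate(0.1),
               tolerance = 1e-12)
})

test_that("joint lectures equal sequential lectures under one control", {
  # a speaker addressing two listeners at once is the same operator as
  # addressing them one after the other
  joint <- build_controlled_gate(5, 3, 1,
                                 data.frame(agent = c(2, 4),
                                            angle = c(0.15, 0.15)))
  seq2 <- compile_script(list(liftwalk:::ctrl_step(3, 1, 2, 0.15),
                              liftwalk:::ctrl_step(3, 1, 4, 0.15)), 5)
  expect_equal(joint, seq2, tolerance = 1e-12)
})

test_that("homogeneous ring blocks have bit-reversal trace symmetry", {
  bu <- build_ring_n(5, 0.05, -0.05)
  rev_index <- function(i, n) {
    b <- vapply(seq_len(n), function(k) bitwAnd(bitwShiftR(i - 1L, k - 1L), 1L),
                integer(1))
    sum(rev(b) * 2^(seq_len(n) - 1)) + 1L
  }
  for (i in seq_len(32)) {
    j <- rev_index(i, 5)
    expect_equal(sum(diag(bu$blocks[[i]])), sum(diag(bu$blocks[[j]])),
                 tolerance = 1e-9)
  }
})
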