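test_that("basis states follow the b_n...b_1 indexing convention", {
  expect_equal(which(basis_state(3, "101") == 1), 6L)
  expect_equal(which(basis_state(3, "000") == 1), 1L)
  expect_equal(basis_state(1, "1"), c(0, 1))
  expect_error(basis_state(3, "10"), "exactly 3")
  expect_error(basis_state(3, "1x1"), "0 or 1")
  # round trip: index i holds popcount(i - 1) ones
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    bits <- paste(sample(0:1, n, replace = TRUE), collapse = "")
    i <- which(basis_state(n, bits) == 1)
    expect_equal(sum(strsplit(bits, "")[[1]] == "1"),
                 liftwalk:::popcount(i))
  }
})

test_that("rotation gates are plane rotations", {
  expect_equal(rotation_gate(0), diag(2))
  expect_equal(drop(rotation_gate(pi / 2) %*% c(1, 0)), c(0, 1))
  expect_equal(rotation_gate(0.05),
               matrix(c(cos(0.05), sin(0.05), -sin(0.05), cos(0.05)), 2, 2))
  expect_error(rotation_gate(Inf))
})

test_that("controlled gates have the two-branch projector structure", {
  th <- 0.31
  # control on the least significant qubit, rotate the other
  U <- build_controlled_gate(2, 1, 1, data.frame(agent = 2, angle = th))
  expect_equal(U, diag(2) %x% proj0() + rotation_gate(th) %x% proj1())
  # two targets fire together
  U2 <- build_controlled_gate(3, 1, 1,
                              data.frame(agent = c(2, 3), angle = c(th, 0.1)))
  expect_equal(U2, diag(4) %x% proj0() +
                   rotation_gate(0.1) %x% rotation_gate(th) %x% proj1())
  # zero angle switches the gate off entirely
  expect_equal(build_controlled_gate(3, 2, 0,
                                     data.frame(agent = 3, angle = 0)),
               diag(8))
  expect_error(build_controlled_gate(2, 1, 1,
                                     data.frame(agent = 1, angle = 0.1)),
               "distinct")
  # every controlled gate is unitary, for either control value
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    ctrl <- sample(n, 1)
    tgt <- sample(setdiff(1:n, ctrl), sample(n - 1, 1))
    U <- build_controlled_gate(n, ctrl, sample(0:1, 1),
                               data.frame(agent = tgt,
                                          angle = runif(length(tgt), -1, 1)))
    expect_true(validate_unitary(U))
  }
})

test_that("unconditional rotations are plain tensor products", {
  expect_equal(build_unconditional(3, data.frame(agent = 1:3, angle = 0)),
               diag(8))
  a <- c(0.12, -0.4, 0.7)
  U <- build_unconditional(3, data.frame(agent = 1:3, angle = a))
  expect_equal(U, rotation_gate(a[3]) %x% rotation_gate(a[2]) %x%
                  rotation_gate(a[1]))
  # equal to the product of the three single-agent rotations
  singles <- lapply(1:3, function(k) {
    build_unconditional(3, data.frame(agent = k, angle = a[k]))
  })
  expect_equal(U, singles[[3]] %*% singles[[2]] %*% singles[[1]])
  # quarter turns flip the basis state
  flip <- build_unconditional(2, data.frame(agent = 1:2, angle = pi / 2))
  expect_equal(drop(flip %*% basis_state(2, "00")), basis_state(2, "11"))
})

test_that("partial trace matches the brute-force summation oracle", {
  # product state reduces to the kept factor
  set.seed(21)
  rhoA <- random_mixed_density(4)
  rhoB <- random_mixed_density(2)
  expect_equal(partial_trace(rhoA %x% rhoB, c(4, 2), "B"), rhoA,
               tolerance = 1e-12)
  # maximally entangled Bell pair reduces to the maximally mixed state
  bell <- c(1, 0, 0, 1) / sqrt(2)
  expect_equal(partial_trace(outer(bell, bell), c(2, 2), "B"), diag(2) / 2)
  # rank-1 cross terms: Tr_B(|a1><a2| (x) |b1><b2|) = <b2|b1> |a1><a2|
  a1 <- rnorm(3); a2 <- rnorm(3); b1 <- rnorm(2); b2 <- rnorm(2)
  expect_equal(partial_trace(outer(a1, a2) %x% outer(b1, b2), c(3, 2), "B"),
               sum(b2 * b1) * outer(a1, a2), tolerance = 1e-12)
  # random 2- and 3-factor states against the oracle, both directions
  for (rep in 1:10) {
    dims <- sample(2:4, 2, replace = TRUE)
    rho <- random_mixed_density(prod(dims))
    for (tr in c("A", "B")) {
      expect_equal(partial_trace(rho, dims, tr),
                   oracle_partial_trace(rho, dims[1], dims[2], tr),
                   tolerance = 1e-12)
    }
    # three factors, traced pairwise by grouping
    rho3 <- random_mixed_density(8)
    expect_equal(partial_trace(rho3, c(4, 2), "B"),
                 oracle_partial_trace(rho3, 4, 2, "B"), tolerance = 1e-12)
    expect_equal(partial_trace(rho3, c(2, 4), "A"),
                 oracle_partial_trace(rho3, 2, 4, "A"), tolerance = 1e-12)
  }
  expect_error(partial_trace(diag(6), c(2, 2)), "factorise")
})

test_that("script compilation applies the first step first", {
  expect_equal(compile_script(list(), 3), diag(8))
  # two-step script equals the right-to-left matrix product
  s1 <- liftwalk:::ctrl_step(1, 1, 2, 0.4)
  s2 <- liftwalk:::ctrl_step(2, 0, 1, -0.2)
  g1 <- build_controlled_gate(3, 1, 1, s1$targets)
  g2 <- build_controlled_gate(3, 2, 0, s2$targets)
  expect_equal(compile_script(list(s1, s2), 3), g2 %*% g1)
  # steps sharing one control and value commute and equal the joint gate
  set.seed(0)
  for (rep in 1:5) {
    a1 <- runif(1, -1, 1); a2 <- runif(1, -1, 1)
    joint <- build_controlled_gate(3, 2, 1,
                                   data.frame(agent = c(1, 3),
                                              angle = c(a1, a2)))
    seq12 <- compile_script(list(liftwalk:::ctrl_step(2, 1, 1, a1),
                                 liftwalk:::ctrl_step(2, 1, 3, a2)), 3)
    seq21 <- compile_script(list(liftwalk:::ctrl_step(2, 1, 3, a2),
                                 liftwalk:::ctrl_step(2, 1, 1, a1)), 3)
    expect_equal(seq12, joint, tolerance = 1e-12)
    expect_equal(seq21, joint, tolerance = 1e-12)
  }
})

test_that("operator validity checks accept and reject as specified", {
  expect_true(validate_unitary(diag(5)))
  expect_true(validate_unitary(rotation_gate(0.3)))
  bad <- diag(3); bad[2, ] <- 0
  expect_false(validate_unitary(bad))
  expect_true(validate_density(diag(4) / 4))
  v <- c(1, 2, 0, -1); v <- v / sqrt(sum(v^2))
  expect_true(validate_density(outer(v, v)))
  expect_false(validate_density(diag(4)))            # trace 4
  expect_false(validate_density(diag(c(1.5, -0.5)))) # negative eigenvalue
  m <- diag(2) / 2; m[1, 2] <- 0.2                   # not Hermitian
  expect_false(validate_density(m))
})

test_that("measurement projectors are idempotent 0/1 diagonals", {
  P <- measurement_projector(3, c(1, 8))
  expect_equal(P %*% P, P)
  expect_true(all(diag(P) %in% c(0, 1)))
  expect_equal(sum(diag(P)), 2)
  expect_error(measurement_projector(3, 9))
})
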