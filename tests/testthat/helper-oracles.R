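# Independent brute-force oracles and small fixture builders.

# Partial trace by literal summation over basis outer products:
# Tr_B(|a1><a2| (x) |b1><b2|) = <b2|b1> |a1><a2|, summed entrywise.
oracle_partial_trace <- function(rho, dA, dB, traced = "B") {
  if (traced == "B") {
    out <- matrix(0, dA, dA)
    for (i in seq_len(dA)) for (j in seq_len(dA)) {
      for (k in seq_len(dB)) for (l in seq_len(dB)) {
        if (k == l) {
          out[i, j] <- out[i, j] + rho[(i - 1) * dB + k, (j - 1) * dB + l]
        }
      }
    }
  } else {
    out <- matrix(0, dB, dB)
    for (k in seq_len(dB)) for (l in seq_len(dB)) {
      for (i in seq_len(dA)) {
        out[k, l] <- out[k, l] + rho[(i - 1) * dB + k, (i - 1) * dB + l]
      }
    }
  }
  out
}

# Random pure density operator on d dimensions.
random_density <- function(d) {
  v <- stats::rnorm(d)
  v <- v / sqrt(sum(v^2))
  outer(v, v)
}

# Random mixed density operator (convex mixture of pure states).
random_mixed_density <- function(d, k = 3) {
  w <- stats::runif(k); w <- w / sum(w)
  Reduce(`+`, lapply(seq_len(k), function(i) w[i] * random_density(d)))
}

# The 3-agent line-graph blocks written directly from their defining
# matrix products (kronecker algebra only), as an independent check of
# the script compiler.  Angles in radians.
line3_blocks_literal <- function(a) {
  I2 <- diag(2); I4 <- diag(4)
  M0 <- proj0(); M1 <- proj1()
  R <- rotation_gate
  U1 <- (R(a$U1[["theta_z"]]) %x% I4) %*%
        (I2 %x% R(a$U1[["theta_y"]]) %x% I2) %*%
        (I4 %x% R(a$U1[["theta_x"]]))
  UY2 <- I2 %x% (I2 %x% M0 + R(a$U2[["theta_y"]]) %x% M1)
  UX2 <- I2 %x% (M0 %x% R(a$U2[["theta_x"]]) + M1 %x% I2)
  U2 <- UX2 %*% UY2
  UY3 <- I2 %x% (M0 %x% I2 + M1 %x% R(a$U3[["theta_x"]]))
  UZ3 <- (I2 %x% M0 + R(a$U3[["theta_z"]]) %x% M1) %x% I2
  UYx <- I2 %x% (R(a$U3[["theta_yx"]]) %x% M0 + I2 %x% M1)
  UYz <- (M0 %x% R(a$U3[["theta_yz"]]) + M1 %x% I2) %x% I2
  U3 <- UYx %*% UYz %*% UZ3 %*% UY3
  UY4 <- (M0 %x% R(a$U4[["theta_y"]]) + M1 %x% I2) %x% I2
  UZ4 <- (I2 %x% M0 + R(a$U4[["theta_z"]]) %x% M1) %x% I2
  U4 <- UY4 %*% UZ4
  UY5 <- (M0 %x% I2 + M1 %x% R(a$U5[["theta_y"]])) %x% I2
  UZ5 <- (R(a$U5[["theta_z"]]) %x% M0 + I2 %x% M1) %x% I2
  U5 <- UZ5 %*% UY5
  UX6 <- I2 %x% (I2 %x% M0 + R(a$U6[["theta_x"]]) %x% M1)
  UZ6 <- (M0 %x% I2 + M1 %x% R(a$U6[["theta_z"]])) %x% I2
  UXy <- I2 %x% (M0 %x% R(a$U6[["theta_xy"]]) + M1 %x% I2)
  UZy <- (R(a$U6[["theta_zy"]]) %x% M0 + I2 %x% M1) %x% I2
  U6 <- UZy %*% UXy %*% UZ6 %*% UX6
  UX7 <- I2 %x% (M0 %x% I2 + M1 %x% R(a$U7[["theta_x"]]))
  UY7 <- I2 %x% (R(a$U7[["theta_y"]]) %x% M0 + I2 %x% M1)
  U7 <- UY7 %*% UX7
  list(U1, U2, U3, U4, U5, U6, U7, diag(8))
}

# Random line3_angles with all angles drawn uniformly.
random_line3_angles <- function() {
  ra <- function(k) stats::runif(k, -0.2, 0.2)
  line3_angles(
    U1 = c(theta_x = ra(1), theta_y = ra(1), theta_z = ra(1)),
    U2 = c(theta_y = ra(1), theta_x = ra(1)),
    U3 = c(theta_x = ra(1), theta_z = ra(1), theta_yx = ra(1),
           theta_yz = ra(1)),
    U4 = c(theta_z = ra(1), theta_y = ra(1)),
    U5 = c(theta_y = ra(1), theta_z = ra(1)),
    U6 = c(theta_x = ra(1), theta_z = ra(1), theta_xy = ra(1),
           theta_zy = ra(1)),
    U7 = c(theta_x = ra(1), theta_y = ra(1))
  )
}
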