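# small random bodies with positive charges, separated along x1 so that
# singular laws stay finite over the sweeps used in tests
random_bodies <- function(m = 5, n = 5, seed = 42) {
  set.seed(seed)
  list(
    P = particle_set(cbind(runif(m, -1, 0), runif(m, -0.5, 0.5),
                           runif(m, -0.5, 0.5)),
                     runif(m, 0.5, 1.5), "P"),
    Q = particle_set(cbind(runif(n, 1, 2), runif(n, -0.5, 0.5),
                           runif(n, -0.5, 0.5)),
                     runif(n, 0.5, 1.5), "Q"))
}

# a surrogate that reproduces a polynomial-in-d2 shape exactly, paired with
# the matching debug law: with these, the separated model must agree with
# brute force to rounding error
exact_poly_setup <- function(coeffs = c(1, 2, 0.5), domain = c(0.5, 80)) {
  law <- interaction_law("poly_d2", coeffs = coeffs)
  sur <- fit_surrogate(function(d) rigidsep:::.horner(coeffs, d^2), domain,
                       degree = length(coeffs) - 1, n_samples = 200,
                       target = "shape_f")
  list(law = law, surrogate = sur)
}

random_unit_axis <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# independent multinomial-theorem expansion of (sum_k g_k h_k)^n used as the
# oracle for poly_power: enumerate all exponent splits alpha with
# sum(alpha) = n and coefficient n! / prod(alpha!)
multinomial_power_oracle <- function(poly, n) {
  exps <- rigidsep:::.pp_exps(poly)
  coefs <- unname(poly$terms)
  r <- length(coefs)
  splits <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (a in 0:total) {
      rest <- splits(total - a, parts - 1)
      out <- rbind(out, cbind(a, rest))
    }
    out
  }
  alphas <- splits(n, r)
  terms_e <- NULL
  terms_c <- numeric(0)
  for (i in seq_len(nrow(alphas))) {
    al <- alphas[i, ]
    cmult <- factorial(n) / prod(factorial(al))
    e <- colSums(exps * al)
    terms_e <- rbind(terms_e, e)
    terms_c <- c(terms_c, cmult * prod(coefs^al))
  }
  pose_poly(poly$basis, terms_e, terms_c)
}

expect_poly_equal <- function(a, b, tol = 1e-9) {
  keys <- union(names(a$terms), names(b$terms))
  va <- stats::setNames(numeric(length(keys)), keys)
  vb <- va
  va[names(a$terms)] <- a$terms
  vb[names(b$terms)] <- b$terms
  scale <- max(abs(c(va, vb)), 1e-300)
  expect_lt(max(abs(va - vb)) / scale, tol)
}
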