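tr <- pose_family("translation_x1")
rot <- pose_family("rotation_x3")
se3 <- pose_family("general_se3")

test_that("d2 polynomial matches its closed forms for single pairs", {
  p <- d2_polynomial(c(0, 0, 0), c(1, 0, 0), tr)
  expect_equal(unname(p$terms[c("0", "1", "2")]), c(1, 2, 1)) # (1 + x1)^2
  # chord of the unit circle: 2 - 2 cos(theta)
  pr <- d2_polynomial(c(1, 0, 0), c(1, 0, 0), rot)
  expect_equal(unname(pr$terms[c("0:0", "0:1")]), c(2, -2))
  expect_false("1:0" %in% names(pr$terms))
})

test_that("d2 polynomial evaluates to the true squared distance for every family", {
  set.seed(11)
  for (rep in 1:10) {
    p0 <- rnorm(3); q0 <- rnorm(3)
    for (fam in list(tr, rot, se3)) {
      poly <- d2_polynomial(p0, q0, fam)
      for (k in 1:5) {
        vals <- switch(fam$kind,
          translation_x1 = runif(1, -3, 3),
          rotation_x3 = runif(1, -pi, pi),
          general_se3 = c(rnorm(3) * 0.8, rnorm(3)))
        true <- sum((apply_pose(make_pose(fam, vals), q0) - p0)^2)
        expect_equal(eval_pose_poly(poly, vals), true, tolerance = 1e-10)
      }
    }
  }
})

test_that("posed coordinate polynomials are degree <= 1 and track apply_pose", {
  q0 <- c(1, 2, 3)
  p1 <- posed_coordinate_polynomial(q0, 1, tr)
  expect_equal(unname(p1$terms[c("0", "1")]), c(1, 1))
  p2 <- posed_coordinate_polynomial(c(1, 0, 0), 2, rot)
  expect_equal(unname(p2$terms), 1)
  expect_equal(names(p2$terms), "1:0") # sin theta
  set.seed(12)
  for (rep in 1:10) {
    q0 <- rnorm(3)
    vals <- c(rnorm(3) * 0.5, rnorm(3))
    posed <- apply_pose(make_pose(se3, vals), q0)
    for (l in 1:3) {
      poly <- posed_coordinate_polynomial(q0, l, se3)
      expect_true(all(rowSums(rigidsep:::.pp_exps(poly)) <= 1))
      expect_equal(eval_pose_poly(poly, vals), posed[l], tolerance = 1e-12)
    }
  }
})

test_that("polynomial product applies reduction and matches hand expansion", {
  x1p1 <- pose_poly(pose_primitive_set("translation_x1"), rbind(0L, 1L),
                    c(1, 1))
  sq <- poly_multiply(x1p1, x1p1)
  expect_equal(unname(sq$terms[c("0", "1", "2")]), c(1, 2, 1))
  sin1 <- pose_poly(pose_primitive_set("rotation_x3"), c(1L, 0L), 1)
  cos2 <- pose_poly(pose_primitive_set("rotation_x3"), c(0L, 2L), 1)
  prod <- poly_multiply(sin1, cos2)
  expect_equal(unname(prod$terms[c("1:0", "3:0")]), c(1, -1)) # sin - sin^3
  expect_error(poly_multiply(x1p1, sin1), "different bases")
})

test_that("multiplication is commutative and associative on random polynomials", {
  set.seed(13)
  basis <- pose_primitive_set("rotation_x3")
  rand_poly <- function() {
    k <- sample(2:4, 1)
    pose_poly(basis, cbind(sample(0:3, k, TRUE), sample(0:2, k, TRUE)),
              rnorm(k))
  }
  for (rep in 1:10) {
    a <- rand_poly(); b <- rand_poly(); c <- rand_poly()
    expect_poly_equal(poly_multiply(a, b), poly_multiply(b, a), tol = 1e-12)
    expect_poly_equal(poly_multiply(poly_multiply(a, b), c),
                      poly_multiply(a, poly_multiply(b, c)), tol = 1e-10)
  }
})

test_that("poly_power matches the multinomial-theorem oracle", {
  basis <- pose_primitive_set("translation_x1")
  one <- pose_poly(basis, matrix(1L), 1)
  expect_equal(unname(poly_power(one, 0)$terms), 1)
  expect_equal(names(poly_power(one, 0)$terms), "0")
  expect_equal(names(poly_power(one, 5)$terms), "5")
  set.seed(14)
  # trinomial over the se3 basis: no reduction rules interfere, so repeated
  # multiplication must equal the explicit multinomial expansion
  b3 <- pose_primitive_set("general_se3")
  tri <- pose_poly(b3, rbind(rep(0L, 12),
                             c(1L, rep(0L, 11)),
                             c(0L, 0L, 0L, 0L, 1L, rep(0L, 7))),
                   c(1.5, -2, 0.75))
  expect_poly_equal(poly_power(tri, 4), multinomial_power_oracle(tri, 4),
                    tol = 1e-12)
  expect_error(poly_power(tri, -1), "non-negative")
})

test_that("pair expansion has the documented basis structure", {
  setup <- exact_poly_setup()
  # degree-9 surrogate of 1/d for structural checks
  s9 <- fit_surrogate(function(d) 1 / d, c(1, 82), degree = 9,
                      target = "shape_f")
  pe <- pair_expansion(c(-0.3, 0.1, 0), c(1.2, -0.4, 0.2), 1.1, 0.9,
                       s9, interaction_law("coulomb_energy"), tr,
                       "scalar_energy")
  exps <- rigidsep:::.pp_exps(pe$energy)
  expect_lte(nrow(exps), 19) # x1^0 .. x1^18
  expect_lte(max(exps), 18)
  per <- pair_expansion(c(-0.3, 0.1, 0), c(1.2, -0.4, 0.2), 1.1, 0.9,
                        s9, interaction_law("coulomb_energy"), rot,
                        "scalar_energy")
  er <- rigidsep:::.pp_exps(per$energy)
  expect_true(all(er[, 2] <= 1)) # only sin^k and sin^k cos survive
  expect_lte(nrow(er), 20)
  # single pair, f = d^2 shape: energy poly is s * (d2 poly)
  sd2 <- fit_surrogate(function(d) d^2, c(0.5, 40), degree = 1,
                       n_samples = 100, target = "shape_f")
  pe2 <- pair_expansion(c(0, 0, 0), c(1, 0, 0), 2, 3, sd2,
                        interaction_law("poly_d2"), tr, "scalar_energy")
  expect_equal(unname(pe2$energy$terms[c("0", "1", "2")]), 6 * c(1, 2, 1),
               tolerance = 1e-9)
})

test_that("surrogate target and output kind must agree", {
  s <- fit_surrogate(function(d) 1 / d, c(1, 10), degree = 3,
                     target = "shape_f")
  expect_error(pair_expansion(c(0, 0, 0), c(1, 0, 0), 1, 1, s,
                              interaction_law("coulomb_force"), tr,
                              "force_vector"),
               "target")
})
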