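tr <- pose_family("translation_x1")

test_that("pose basis values enumerate the stored monomials", {
  b <- random_bodies(3, 3, seed = 31)
  setup <- exact_poly_setup(c(0, 0, 1), domain = c(0.5, 80)) # f = d^4
  m <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law, tr,
                                  "scalar_energy")
  h0 <- pose_basis_values(m, 0)
  expect_equal(h0, as.numeric(m$monomials[, 1] == 0))
  h2 <- pose_basis_values(m, 2)
  expect_equal(h2, 2^m$monomials[, 1])
  mr <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law,
                                   pose_family("rotation_x3"),
                                   "scalar_energy")
  hr <- pose_basis_values(mr, 0) # sin = 0, cos = 1
  expect_equal(hr, as.numeric(mr$monomials[, 1] == 0))
})

test_that("net_value is a dot product, linear in the coefficients", {
  b <- random_bodies(4, 4, seed = 32)
  setup <- exact_poly_setup()
  m <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law, tr,
                                  "scalar_energy")
  m5 <- m
  m5$components$energy <- 5 * m$components$energy
  x <- 1.7
  expect_equal(net_value(m5, x), 5 * net_value(m, x), tolerance = 1e-12)
  mc <- m
  mc$components$energy <- rep(0, length(m$components$energy))
  mc$components$energy[m$monomials[, 1] == 0] <- 5
  expect_equal(net_value(mc, 0.3), 5)
  expect_equal(net_value(mc, 2.9), 5)
})

test_that("brute force oracle sums pairwise laws (both engines agree)", {
  lawE <- interaction_law("coulomb_energy")
  a <- particle_set(matrix(0, 1, 3), 1, "a")
  bq <- particle_set(matrix(c(2, 0, 0), 1, 3), 1, "b")
  expect_equal(brute_force_net(a, bq, lawE, pose(), "scalar_energy"), 0.5)
  doubled <- particle_set(rbind(bq$coords, bq$coords), c(1, 1), "bb")
  expect_equal(brute_force_net(a, doubled, lawE, pose(), "scalar_energy"), 1)
  b <- random_bodies(6, 5, seed = 33)
  p <- make_pose(tr, 1.3)
  expect_equal(
    brute_force_net(b$P, b$Q, lawE, p, "scalar_energy", engine = "cpp"),
    brute_force_net(b$P, b$Q, lawE, p, "scalar_energy", engine = "r"),
    tolerance = 1e-12)
  lawF <- interaction_law("coulomb_force")
  for (kind in c("force_vector", "moment_vector")) {
    expect_equal(
      brute_force_net(b$P, b$Q, lawF, p, kind, engine = "cpp"),
      brute_force_net(b$P, b$Q, lawF, p, kind, engine = "r"),
      tolerance = 1e-12)
  }
  coinc <- particle_set(b$P$coords[1, , drop = FALSE], 1, "c")
  expect_error(brute_force_net(b$P, coinc, lawE, pose(), "scalar_energy",
                               engine = "r"),
               "[Cc]oincident")
})

test_that("brute-force net force is minus the translation gradient of the energy", {
  b <- random_bodies(5, 5, seed = 34)
  lawE <- interaction_law("coulomb_energy")
  lawF <- interaction_law("coulomb_force")
  x0 <- 0.9
  h <- 1e-5
  f <- brute_force_net(b$P, b$Q, lawF, make_pose(tr, x0), "force_vector")
  # net force on Q along x1 is -dE/dx1; central differences on the energy
  eplus <- brute_force_net(b$P, b$Q, lawE, make_pose(tr, x0 + h),
                           "scalar_energy")
  eminus <- brute_force_net(b$P, b$Q, lawE, make_pose(tr, x0 - h),
                            "scalar_energy")
  grad <- (eplus - eminus) / (2 * h)
  expect_equal(unname(f["f1"]), -grad, tolerance = 1e-5 * abs(grad))
})

test_that("the approximation pass performs zero pairwise-law evaluations", {
  b <- random_bodies(8, 8, seed = 35)
  setup <- exact_poly_setup()
  m <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law, tr,
                                  "scalar_energy")
  sr <- pose_sweep(m, b$P, b$Q, setup$law, tr, seq(0, 3, length.out = 50),
                   with_brute = TRUE, engine = "r")
  expect_identical(sr$pairwise_eval_count, 0)
  # while the brute pass did evaluate all pairs at every pose
  reset_pairwise_eval_count()
  invisible(brute_force_net(b$P, b$Q, setup$law, pose(), "scalar_energy",
                            engine = "r"))
  expect_identical(pairwise_eval_count(), 64)
})

test_that("sweeps match single-pose calls and stay exact for polynomial laws", {
  b <- random_bodies(6, 6, seed = 36)
  setup <- exact_poly_setup()
  m <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law, tr,
                                  "scalar_energy")
  empty <- pose_sweep(m, b$P, b$Q, setup$law, tr, numeric(0))
  expect_equal(nrow(empty$approx), 0)
  one <- pose_sweep(m, b$P, b$Q, setup$law, tr, 1.1, engine = "r")
  expect_equal(unname(one$approx[1, 1]), net_value(m, 1.1))
  expect_equal(unname(one$brute[1, 1]),
               brute_force_net(b$P, b$Q, setup$law, make_pose(tr, 1.1),
                               "scalar_energy", engine = "r"))
  sr <- pose_sweep(m, b$P, b$Q, setup$law, tr, seq(0, 4, length.out = 100),
                   engine = "r")
  expect_lt(max(abs(sr$approx - sr$brute) / abs(sr$brute)), 1e-9)
  expect_equal(as.numeric(average_percent_error(sr)), 0, tolerance = 1e-7)
})

test_that("average percent error arithmetic and exclusions", {
  fake <- structure(list(
    values = matrix(1:3, 3), output_kind = "scalar_energy",
    approx = matrix(c(1.1, 2, 4), 3, 1, dimnames = list(NULL, "energy")),
    brute = matrix(c(1, 2, 4), 3, 1, dimnames = list(NULL, "energy")),
    pairwise_eval_count = 0), class = "sweep_result")
  expect_equal(as.numeric(average_percent_error(fake)), 10 / 3,
               tolerance = 1e-12)
  fake$approx <- 1.01 * fake$brute
  expect_equal(as.numeric(average_percent_error(fake)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(average_percent_error(fake, metric = "rms")), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(average_percent_error(fake, metric = "signed_mean")),
               1, tolerance = 1e-12)
  fake$brute[2, 1] <- 0 # dead reference value must be excluded, with a note
  expect_message(ape <- average_percent_error(fake), "excluded")
  expect_equal(attr(ape, "n_excluded"), 1)
  expect_equal(attr(ape, "n_used"), 2)
  # vector outputs use Euclidean-norm relative error
  vec <- structure(list(
    values = matrix(1:2, 2), output_kind = "force_vector",
    approx = matrix(c(1, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE,
                    dimnames = list(NULL, c("f1", "f2", "f3"))),
    brute = matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE,
                   dimnames = list(NULL, c("f1", "f2", "f3"))),
    pairwise_eval_count = 0), class = "sweep_result")
  expect_equal(percent_errors(vec), c(0, 100))
})
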