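tr <- pose_family("translation_x1")
rot <- pose_family("rotation_x3")
se3 <- pose_family("general_se3")

test_that("fast and generic accumulation build identical models", {
  b <- random_bodies(4, 3, seed = 21)
  setup <- exact_poly_setup(c(0.5, 1, 0.25), domain = c(0.5, 60))
  for (fam in list(tr, rot)) {
    mg <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law,
                                     fam, "scalar_energy", engine = "generic")
    mf <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law,
                                     fam, "scalar_energy", engine = "fast")
    expect_equal(mf$monomials, mg$monomials)
    expect_equal(mf$components, mg$components, tolerance = 1e-12)
  }
  lawf <- interaction_law("coulomb_force")
  sf <- fit_surrogate(function(d) 1 / d^3, c(0.5, 60), degree = 5,
                      target = "shape_f_over_d")
  for (kind in c("force_vector", "moment_vector")) {
    mg <- accumulate_characteristics(b$P, b$Q, sf, lawf, tr, kind,
                                     engine = "generic")
    mf <- accumulate_characteristics(b$P, b$Q, sf, lawf, tr, kind,
                                     engine = "fast")
    expect_equal(mf$monomials, mg$monomials)
    expect_equal(mf$components, mg$components, tolerance = 1e-10)
  }
})

test_that("characteristics are linear and additive over particle sets", {
  setup <- exact_poly_setup()
  b <- random_bodies(4, 4, seed = 22)
  single <- particle_set(b$Q$coords[1, , drop = FALSE], b$Q$props[1], "q1")
  doubled <- particle_set(rbind(single$coords, single$coords),
                          rep(single$props, 2), "q1x2")
  m1 <- accumulate_characteristics(b$P, single, setup$surrogate, setup$law,
                                   tr, "scalar_energy")
  m2 <- accumulate_characteristics(b$P, doubled, setup$surrogate, setup$law,
                                   tr, "scalar_energy")
  expect_equal(m2$components$energy, 2 * m1$components$energy,
               tolerance = 1e-12)
  # M = N = 1 reduces to the single pair expansion
  p1 <- particle_set(b$P$coords[1, , drop = FALSE], b$P$props[1], "p1")
  mp <- accumulate_characteristics(p1, single, setup$surrogate, setup$law,
                                   tr, "scalar_energy")
  pe <- pair_expansion(p1$coords[1, ], single$coords[1, ], p1$props,
                       single$props, setup$surrogate, setup$law, tr,
                       "scalar_energy")
  expect_equal(unname(mp$components$energy),
               unname(pe$energy$terms[as.character(mp$monomials[, 1])]),
               tolerance = 1e-12)
  # union additivity: characteristics of P1 u P2 = sum of the parts
  idx <- 1:2
  Pa <- particle_set(b$P$coords[idx, ], b$P$props[idx], "Pa")
  Pb <- particle_set(b$P$coords[-idx, ], b$P$props[-idx], "Pb")
  ma <- accumulate_characteristics(Pa, b$Q, setup$surrogate, setup$law, tr,
                                   "scalar_energy")
  mb <- accumulate_characteristics(Pb, b$Q, setup$surrogate, setup$law, tr,
                                   "scalar_energy")
  mall <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law,
                                     tr, "scalar_energy")
  expect_equal(ma$components$energy + mb$components$energy,
               mall$components$energy, tolerance = 1e-11)
})

test_that("the separated model is exact for polynomial-in-d2 laws (all families)", {
  b <- random_bodies(10, 10, seed = 23)
  setup <- exact_poly_setup(c(1, 0.5, 0.2), domain = c(0.25, 120))
  set.seed(24)
  for (fam in list(tr, rot, se3)) {
    model <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law,
                                        fam, "scalar_energy")
    for (k in 1:20) {
      vals <- switch(fam$kind,
        translation_x1 = runif(1, 0, 4),
        rotation_x3 = runif(1, -pi, pi),
        general_se3 = c(rnorm(3) * 0.6, rnorm(3) * 0.8))
      appr <- net_value(model, vals)
      ref <- brute_force_net(b$P, b$Q, setup$law, make_pose(fam, vals),
                             "scalar_energy", engine = "r")
      expect_lt(abs(appr - ref) / abs(ref), 1e-9)
    }
  }
})

test_that("model size does not depend on particle count", {
  setup <- exact_poly_setup()
  b1 <- random_bodies(3, 3, seed = 25)
  b2 <- random_bodies(30, 30, seed = 26)
  m1 <- accumulate_characteristics(b1$P, b1$Q, setup$surrogate, setup$law,
                                   tr, "scalar_energy")
  m2 <- accumulate_characteristics(b2$P, b2$Q, setup$surrogate, setup$law,
                                   tr, "scalar_energy")
  expect_equal(dim(m1$monomials), dim(m2$monomials))
})

test_that("compute_d2_range brackets pairwise distances over the sweep", {
  a <- particle_set(matrix(0, 1, 3), 1, "a")
  bq <- particle_set(matrix(c(1, 0, 0), 1, 3), 1, "b")
  expect_equal(compute_d2_range(a, bq, tr, c(0, 0)), c(1, 1))
  expect_equal(compute_d2_range(a, bq, tr, c(0, 5)), c(1, 36))
  b <- random_bodies(8, 6, seed = 27)
  rng <- compute_d2_range(b$P, b$Q, tr, c(0, 3), grid = 21)
  d2s <- unlist(lapply(seq(0, 3, length.out = 21), function(x) {
    qp <- apply_pose(make_pose(tr, x), b$Q$coords)
    as.vector(outer(rowSums(b$P$coords^2), rowSums(qp^2), "+") -
                2 * b$P$coords %*% t(qp))
  }))
  expect_equal(rng, range(d2s), tolerance = 1e-12)
})

test_that("accumulation warns when the surrogate cannot cover the sweep", {
  b <- random_bodies(3, 3, seed = 28)
  s <- fit_surrogate(function(d) 1 / d, c(1, 4), degree = 3,
                     target = "shape_f")
  expect_warning(
    accumulate_characteristics(b$P, b$Q, s, interaction_law("coulomb_energy"),
                               tr, "scalar_energy", check_sweep = c(0, 5)),
    "not fully covered")
})

test_that("model JSON round trip preserves evaluation", {
  b <- random_bodies(4, 4, seed = 29)
  setup <- exact_poly_setup()
  m <- accumulate_characteristics(b$P, b$Q, setup$surrogate, setup$law, rot,
                                  "scalar_energy")
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(net_value(m2, -0.4), net_value(m, -0.4), tolerance = 1e-12)
})
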