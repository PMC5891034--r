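#' Pairwise distance-dependent interaction laws
#'
#' An interaction law factors as `prefactor(lambda_i, lambda_j) * shape(d)`:
#' the scalar prefactor carries the two per-particle properties and the shape
#' carries the full distance dependence. This separability is what lets the
#' shape alone be surrogated as a polynomial in squared distance, with the
#' prefactor absorbed into the per-pair geometry coefficients.
#'
#' Built-in laws (`interaction_law(name, ...)`):
#' \describe{
#'   \item{`coulomb_energy`}{`lambda_i lambda_j / (4 pi eps d)`; scalar energy.
#'     Default `eps = 1/(4*pi)` so that the energy is simply `lambda^2 / d`.}
#'   \item{`coulomb_force`}{central force of magnitude
#'     `lambda_i lambda_j / (4 pi eps d^2)` along the pair axis.}
#'   \item{`spring`}{linear spring, magnitude `k * d` (param `k`).}
#'   \item{`power_law`}{`A / d^n` (params `A`, `n`).}
#'   \item{`lj_energy`}{`A / d^12 - B / d^6` with prefactor identically 1
#'     (params `A`, `B`).}
#'   \item{`poly_d2`}{debug law whose shape is exactly a polynomial in squared
#'     distance (param `coeffs`, ascending in `d^2`); with it the separated
#'     model is exact, which the test-suite oracles exploit.}
#' }
#'
#' @param name law name (see above)
#' @param ... law parameters (`eps`, `k`, `A`, `B`, `n`, `coeffs`)
#' @return object of class `"interaction_law"` with fields `name`, `shape`
#'   (function of distance, unit prefactor), `prefactor` (function of the two
#'   properties), `output_kind`, `params`
#' @examples
#' law <- interaction_law("coulomb_energy")
#' law_magnitude(law, d = 2, lambda_i = 1, lambda_j = 1) # 0.5
#' @export
interaction_law <- function(name, ...) {
  params <- list(...)
  pick <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  law <- switch(name,
    coulomb_energy = {
      eps <- pick("eps", 1 / (4 * pi))
      if (eps <= 0) stop("eps must be positive")
      k <- 1 / (4 * pi * eps)
      list(shape = function(d) k / d, prefactor = function(li, lj) li * lj,
           output_kind = "scalar_energy", singular = TRUE,
           params = list(eps = eps))
    },
    coulomb_force = {
      eps <- pick("eps", 1 / (4 * pi))
      if (eps <= 0) stop("eps must be positive")
      k <- 1 / (4 * pi * eps)
      list(shape = function(d) k / d^2, prefactor = function(li, lj) li * lj,
           output_kind = "central_force_vector", singular = TRUE,
           params = list(eps = eps))
    },
    spring = {
      k <- pick("k", 1)
      list(shape = function(d) k * d, prefactor = function(li, lj) li * lj,
           output_kind = "central_force_vector", singular = FALSE,
           params = list(k = k))
    },
    power_law = {
      A <- pick("A", 1); n <- pick("n", 6)
      list(shape = function(d) A / d^n, prefactor = function(li, lj) li * lj,
           output_kind = "scalar_energy", singular = TRUE,
           params = list(A = A, n = n))
    },
    lj_energy = {
      A <- pick("A", 1); B <- pick("B", 1)
      list(shape = function(d) A / d^12 - B / d^6,
           prefactor = function(li, lj) rep(1, length(li)),
           output_kind = "scalar_energy", singular = TRUE,
           params = list(A = A, B = B))
    },
    poly_d2 = {
      coeffs <- pick("coeffs", c(0, 1))
      list(shape = function(d) .horner(coeffs, d^2),
           prefactor = function(li, lj) li * lj,
           output_kind = "scalar_energy", singular = FALSE,
           params = list(coeffs = coeffs))
    },
    custom = {
      # user-supplied magnitude(d, li, lj); must factor as prefactor x shape
      magnitude <- params$magnitude
      prefactor <- pick("prefactor", function(li, lj) li * lj)
      if (!is.function(magnitude)) stop("custom law needs a magnitude function")
      p11 <- prefactor(1, 1)
      if (!is.finite(p11) || p11 == 0) stop("prefactor(1, 1) must be nonzero")
      list(shape = function(d) magnitude(d, 1, 1) / p11,
           prefactor = prefactor, magnitude = magnitude,
           output_kind = pick("output_kind", "scalar_energy"),
           singular = pick("singular", TRUE), params = params)
    },
    stop("unknown interaction law: ", name))
  law$name <- name
  class(law) <- "interaction_law"
  .assert_separable(law)
  law
}

#' @export
print.interaction_law <- function(x, ...) {
  cat("<interaction_law>", x$name, "(", x$output_kind, ")\n")
  invisible(x)
}

# Registration-time check of the separable-prefactor assumption: the full
# magnitude must equal prefactor(li, lj) * magnitude(d, 1, 1) / prefactor(1, 1)
# on a grid of distances and property pairs. Built-in laws satisfy this by
# construction; custom laws that do not factor are rejected here.
.assert_separable <- function(law, tol = 1e-10) {
  g <- expand.grid(d = c(0.7, 1.3, 2.9, 7.7),
                   li = c(0.5, 1, 2), lj = c(0.25, 1, 3))
  full <- if (is.function(law$magnitude)) {
    law$magnitude(g$d, g$li, g$lj)
  } else {
    law$prefactor(g$li, g$lj) * law$shape(g$d)
  }
  fact <- law$prefactor(g$li, g$lj) * law$shape(g$d)
  if (max(abs(full - fact)) > tol * max(1, max(abs(full)))) {
    stop("law '", law$name,
         "' does not factor as prefactor(lambda_i, lambda_j) x shape(d); ",
         "the separated representation requires a separable prefactor")
  }
  invisible(TRUE)
}

.horner <- function(coeffs, x) {
  out <- rep(coeffs[length(coeffs)], length(x))
  if (length(coeffs) > 1) {
    for (k in (length(coeffs) - 1):1) out <- out * x + coeffs[k]
  }
  out
}

#' Evaluate a pairwise law
#'
#' The magnitude of the law for properties `lambda_i`, `lambda_j` at distance
#' `d` (all vectorised). This is the only sanctioned evaluation path and it
#' increments the instrumentation counter by the number of evaluations (see
#' [pairwise_eval_count()]).
#'
#' @param law an [interaction_law()]
#' @param d distance(s), positive for singular laws
#' @param lambda_i,lambda_j particle properties
#' @return numeric vector of magnitudes
#' @export
law_magnitude <- function(law, d, lambda_i, lambda_j) {
  stopifnot(inherits(law, "interaction_law"))
  if (law$singular && any(d <= 0)) {
    stop("law '", law$name, "' is singular at d <= 0")
  }
  .count_pairwise_evals(length(d))
  law$prefactor(lambda_i, lambda_j) * law$shape(d)
}

#' Coulomb energy of two point charges
#'
#' `lambda_i lambda_j / (4 pi eps d)`. With the package default
#' `eps = 1/(4*pi)` this reduces to `lambda_i lambda_j / d` (the worked
#' examples report dimensionless energies and never state a dielectric).
#'
#' @param lambda_i,lambda_j charges
#' @param d distance, `> 0`
#' @param eps dielectric constant, `> 0`
#' @export
coulomb_energy <- function(lambda_i, lambda_j, d, eps = 1 / (4 * pi)) {
  if (any(d <= 0)) stop("coulomb energy is singular at d <= 0")
  if (eps <= 0) stop("eps must be positive")
  lambda_i * lambda_j / (4 * pi * eps * d)
}

#' Components of a central pairwise force
#'
#' The force on particle j of Q from particle i of P acts along the pair
#' axis: component l is `(|f|/d) * (q_l - p_l)`, so the returned vector is
#' parallel to `q_posed - p` with norm `|f(d)|`.
#'
#' @param law an [interaction_law()] with `output_kind`
#'   `"central_force_vector"`
#' @param p particle position in P (3-vector, reference pose)
#' @param q_posed particle position in Q after posing (3-vector)
#' @param lambda_i,lambda_j particle properties
#' @return force 3-vector
#' @export
central_force_components <- function(law, p, q_posed, lambda_i, lambda_j) {
  p <- as.numeric(p); q_posed <- as.numeric(q_posed)
  stopifnot(length(p) == 3, length(q_posed) == 3)
  delta <- q_posed - p
  d <- sqrt(sum(delta^2))
  if (d == 0) stop("coincident points: central force undefined at d = 0")
  (law_magnitude(law, d, lambda_i, lambda_j) / d) * delta
}

#' Pairwise moment about the frame origin
#'
#' `m = q_posed x f`: the moment of the pairwise force about the origin of
#' the fixed frame attached to body P.
#'
#' @param q_posed posed position of the Q particle (3-vector)
#' @param force force 3-vector
#' @return moment 3-vector
#' @export
pairwise_moment <- function(q_posed, force) {
  q <- as.numeric(q_posed); f <- as.numeric(force)
  stopifnot(length(q) == 3, length(f) == 3)
  c(q[2] * f[3] - q[3] * f[2],
    q[3] * f[1] - q[1] * f[3],
    q[1] * f[2] - q[2] * f[1])
}

# shape to be surrogated for a given target:
# shape_f        -> shape(d)        (energies)
# shape_f_over_d -> shape(d) / d    (force/moment component weights)
law_shape_for_target <- function(law, target = c("shape_f", "shape_f_over_d")) {
  target <- match.arg(target)
  shape <- law$shape
  if (target == "shape_f") shape else function(d) shape(d) / d
}
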