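#' Pose primitive sets
#'
#' The elementary scalar pose functions from which pose-basis monomials are
#' built, per family:
#' \describe{
#'   \item{translation_x1}{`x1`}
#'   \item{rotation_x3}{`sin` and `cos` of the rotation angle, with the
#'     rewrite rule `cos^2 -> 1 - sin^2` applied to every monomial, so stored
#'     monomials carry a cos exponent of at most 1}
#'   \item{general_se3}{the nine rotation-matrix entries `R11..R33` plus
#'     `x1, x2, x3`, treated as independent primitives (their algebraic
#'     dependencies are ignored; only evaluation correctness matters)}
#' }
#'
#' @param kind family kind, as in [pose_family()]
#' @return object of class `"pose_basis"`
#' @export
pose_primitive_set <- function(kind = c("translation_x1", "rotation_x3",
                                        "general_se3")) {
  kind <- match.arg(kind)
  prims <- switch(kind,
    translation_x1 = "x1",
    rotation_x3 = c("sin", "cos"),
    general_se3 = c("R11", "R12", "R13", "R21", "R22", "R23",
                    "R31", "R32", "R33", "x1", "x2", "x3"))
  structure(list(kind = kind, primitives = prims), class = "pose_basis")
}

#' @export
print.pose_basis <- function(x, ...) {
  cat("<pose_basis>", x$kind, ":", paste(x$primitives, collapse = ", "), "\n")
  invisible(x)
}

# Values of the primitives at a concrete pose-parameter vector.
primitive_values <- function(basis, values) {
  values <- as.numeric(values)
  switch(basis$kind,
    translation_x1 = c(x1 = values[1]),
    rotation_x3 = c(sin = sin(values[1]), cos = cos(values[1])),
    general_se3 = {
      p <- make_pose(pose_family("general_se3"), values)
      R <- if (p$angle == 0) diag(3) else axis_angle_matrix(p$axis, p$angle)
      stats::setNames(c(t(R), p$translation),
                      pose_primitive_set("general_se3")$primitives)
    })
}

## ---- sparse pose polynomials -------------------------------------------
## terms: named numeric vector; names are exponent tuples joined by ":".

.pp_key <- function(exps) {
  if (is.null(dim(exps))) exps <- matrix(exps, nrow = 1)
  apply(exps, 1, paste, collapse = ":")
}

.pp_exps <- function(poly) {
  keys <- names(poly$terms)
  if (length(keys) == 0) {
    return(matrix(integer(0), 0, length(poly$basis$primitives)))
  }
  out <- do.call(rbind, lapply(strsplit(keys, ":", fixed = TRUE), as.integer))
  colnames(out) <- poly$basis$primitives
  out
}

#' Construct a pose polynomial
#'
#' A sparse multivariate polynomial over a family's pose primitives: a map
#' from exponent tuples to numeric coefficients. Construction applies the
#' basis rewrite rules (`cos^2 -> 1 - sin^2` for `rotation_x3`), merges
#' duplicate monomials, and prunes coefficients below `1e-14` relative to
#' the largest one (cancellation dust would otherwise inflate the term
#' count, i.e. the separation rank).
#'
#' @param basis a [pose_primitive_set()]
#' @param exponents integer matrix, one row per term, one column per
#'   primitive (or a vector for a single term)
#' @param coefficients numeric vector, one per term
#' @return object of class `"pose_poly"`
#' @export
pose_poly <- function(basis, exponents, coefficients) {
  stopifnot(inherits(basis, "pose_basis"))
  if (is.null(dim(exponents))) {
    exponents <- matrix(as.integer(exponents), ncol = length(basis$primitives))
  }
  storage.mode(exponents) <- "integer"
  if (ncol(exponents) != length(basis$primitives)) {
    stop("exponent tuples must have one entry per primitive")
  }
  if (nrow(exponents) != length(coefficients)) {
    stop("need one coefficient per exponent tuple")
  }
  if (any(exponents < 0)) stop("exponents must be non-negative")
  red <- .pp_reduce(basis, exponents, as.numeric(coefficients))
  .pp_finish(basis, red$exps, red$coefs)
}

# rewrite rules; currently only rotation_x3's cos^2 -> 1 - sin^2
.pp_reduce <- function(basis, exps, coefs) {
  if (basis$kind == "rotation_x3" && nrow(exps) > 0) {
    repeat {
      hi <- which(exps[, 2] >= 2L)
      if (length(hi) == 0) break
      keep_e <- exps[-hi, , drop = FALSE]
      keep_c <- coefs[-hi]
      # cos^e = cos^(e-2) * (1 - sin^2)
      e1 <- exps[hi, , drop = FALSE]; e1[, 2] <- e1[, 2] - 2L
      e2 <- e1; e2[, 1] <- e2[, 1] + 2L
      exps <- rbind(keep_e, e1, e2)
      coefs <- c(keep_c, coefs[hi], -coefs[hi])
    }
  }
  list(exps = exps, coefs = coefs)
}

# merge duplicates, prune, canonical order
.pp_finish <- function(basis, exps, coefs) {
  if (nrow(exps) > 0) {
    keys <- .pp_key(exps)
    agg <- rowsum(coefs, keys)
    terms <- stats::setNames(agg[, 1], rownames(agg))
    mx <- max(abs(terms))
    if (mx > 0) terms <- terms[abs(terms) > 1e-14 * mx]
    terms <- terms[order(names(terms))]
  } else {
    terms <- stats::setNames(numeric(0), character(0))
  }
  structure(list(basis = basis, terms = terms), class = "pose_poly")
}

pp_const <- function(basis, value = 1) {
  if (value == 0) {
    return(.pp_finish(basis, matrix(integer(0), 0, length(basis$primitives)),
                      numeric(0)))
  }
  pose_poly(basis, rep(0L, length(basis$primitives)), value)
}

#' @export
print.pose_poly <- function(x, ...) {
  cat("<pose_poly> (", x$basis$kind, ") ", length(x$terms), " term(s)\n",
      sep = "")
  if (length(x$terms) > 0) {
    exps <- .pp_exps(x)
    lab <- apply(exps, 1, function(e) {
      nz <- which(e > 0)
      if (length(nz) == 0) return("1")
      paste(ifelse(e[nz] == 1, x$basis$primitives[nz],
                   paste0(x$basis$primitives[nz], "^", e[nz])), collapse = "*")
    })
    for (i in seq_len(min(length(lab), 12))) {
      cat("  ", format(x$terms[i]), "*", lab[i], "\n")
    }
    if (length(lab) > 12) cat("  ...\n")
  }
  invisible(x)
}

#' Pose-polynomial arithmetic
#'
#' `poly_add` sums, `poly_scale` multiplies by a scalar, `poly_multiply`
#' forms the distributive product (exponent tuples add, then the basis
#' rewrite rules and zero-pruning are applied), and `poly_power` raises to a
#' non-negative integer power by repeated multiplication -- the mechanism by
#' which powers of the squared-distance polynomial stay in separated form.
#'
#' @param a,b pose polynomials over the same basis
#' @param s scalar
#' @param k non-negative integer power
#' @return a pose polynomial
#' @export
poly_multiply <- function(a, b) {
  .pp_check_basis(a, b)
  if (length(a$terms) == 0 || length(b$terms) == 0) return(pp_const(a$basis, 0))
  ea <- .pp_exps(a); eb <- .pp_exps(b)
  na <- nrow(ea); nb <- nrow(eb)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  exps <- ea[ia, , drop = FALSE] + eb[ib, , drop = FALSE]
  coefs <- a$terms[ia] * b$terms[ib]
  red <- .pp_reduce(a$basis, exps, coefs)
  .pp_finish(a$basis, red$exps, red$coefs)
}

#' @rdname poly_multiply
#' @export
poly_power <- function(a, k) {
  stopifnot(inherits(a, "pose_poly"))
  if (length(k) != 1 || k < 0 || k != round(k)) {
    stop("power must be a single non-negative integer")
  }
  out <- pp_const(a$basis, 1)
  if (k == 0) return(out)
  for (i in seq_len(k)) out <- poly_multiply(out, a)
  out
}

#' @rdname poly_multiply
#' @export
poly_add <- function(a, b) {
  .pp_check_basis(a, b)
  keys <- union(names(a$terms), names(b$terms))
  va <- stats::setNames(numeric(length(keys)), keys)
  va[names(a$terms)] <- a$terms
  va[names(b$terms)] <- va[names(b$terms)] + b$terms
  exps <- do.call(rbind, lapply(strsplit(keys, ":", fixed = TRUE), as.integer))
  if (is.null(exps)) exps <- matrix(integer(0), 0, length(a$basis$primitives))
  .pp_finish(a$basis, exps, unname(va))
}

#' @rdname poly_multiply
#' @export
poly_scale <- function(a, s) {
  stopifnot(inherits(a, "pose_poly"), length(s) == 1)
  if (s == 0 || length(a$terms) == 0) return(pp_const(a$basis, 0))
  structure(list(basis = a$basis, terms = a$terms * s), class = "pose_poly")
}

.pp_check_basis <- function(a, b) {
  stopifnot(inherits(a, "pose_poly"), inherits(b, "pose_poly"))
  if (!identical(a$basis$kind, b$basis$kind)) {
    stop("pose polynomials live over different bases: ",
         a$basis$kind, " vs ", b$basis$kind)
  }
}

#' Evaluate a pose polynomial at pose-parameter values
#'
#' @param poly a [pose_poly()]
#' @param values pose-parameter vector for the basis's family
#' @return numeric scalar
#' @export
eval_pose_poly <- function(poly, values) {
  stopifnot(inherits(poly, "pose_poly"))
  if (length(poly$terms) == 0) return(0)
  pv <- primitive_values(poly$basis, values)
  exps <- .pp_exps(poly)
  h <- apply(exps, 1, function(e) prod(pv^e))
  sum(poly$terms * h)
}

## ---- pose-dependent coordinates and squared distance --------------------

#' Posed coordinate of a Q particle as a pose polynomial
#'
#' The l-th coordinate of `R q0 + x` written over the family's primitives;
#' always degree <= 1.
#'
#' @param q0 reference coordinates of the Q particle (3-vector)
#' @param l component index 1, 2 or 3
#' @param family a [pose_family()]
#' @return a [pose_poly()]
#' @export
posed_coordinate_polynomial <- function(q0, l, family) {
  stopifnot(inherits(family, "pose_family"), l %in% 1:3)
  q0 <- as.numeric(q0)
  basis <- pose_primitive_set(family$kind)
  np <- length(basis$primitives)
  z <- rep(0L, np)
  one <- function(i) { e <- z; e[i] <- 1L; e }
  switch(family$kind,
    translation_x1 = {
      if (l == 1) {
        pose_poly(basis, rbind(z, one(1)), c(q0[1], 1))
      } else {
        pp_const(basis, q0[l])
      }
    },
    rotation_x3 = {
      # (q1 cos - q2 sin, q1 sin + q2 cos, q3)
      if (l == 1) {
        pose_poly(basis, rbind(one(2), one(1)), c(q0[1], -q0[2]))
      } else if (l == 2) {
        pose_poly(basis, rbind(one(1), one(2)), c(q0[1], q0[2]))
      } else {
        pp_const(basis, q0[3])
      }
    },
    general_se3 = {
      # sum_m R_lm q0_m + x_l ; primitives are rowwise R11..R33 then x1..x3
      idx <- (l - 1) * 3 + 1:3
      exps <- rbind(one(idx[1]), one(idx[2]), one(idx[3]), one(9 + l))
      pose_poly(basis, exps, c(q0, 1))
    })
}

#' Squared pair distance as a pose polynomial
#'
#' `d^2 = || R q0 + x - p0 ||^2` expanded over the family's primitives. For
#' the one-parameter families the closed forms are used directly:
#' translation gives `x1^2 + 2 (q1 - p1) x1 + ||q0 - p0||^2`; rotation about
#' the third axis gives `A + B sin + C cos` with
#' `A = p1^2 + p2^2 + q1^2 + q2^2 + (q3 - p3)^2`,
#' `B = 2 (p1 q2 - p2 q1)`, `C = -2 (p1 q1 + p2 q2)`. The general family is
#' assembled from [posed_coordinate_polynomial()] by the generic algebra.
#'
#' @param p0,q0 reference coordinates (3-vectors) of the P and Q particles
#' @param family a [pose_family()]
#' @return a [pose_poly()] whose value at any pose equals the squared
#'   distance between `p0` and the posed `q0`
#' @export
d2_polynomial <- function(p0, q0, family) {
  stopifnot(inherits(family, "pose_family"))
  p0 <- as.numeric(p0); q0 <- as.numeric(q0)
  basis <- pose_primitive_set(family$kind)
  switch(family$kind,
    translation_x1 = {
      delta <- q0 - p0
      pose_poly(basis, rbind(0L, 1L, 2L),
                c(sum(delta^2), 2 * delta[1], 1))
    },
    rotation_x3 = {
      A <- p0[1]^2 + p0[2]^2 + q0[1]^2 + q0[2]^2 + (q0[3] - p0[3])^2
      B <- 2 * (p0[1] * q0[2] - p0[2] * q0[1])
      Cc <- -2 * (p0[1] * q0[1] + p0[2] * q0[2])
      pose_poly(basis, rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L)), c(A, B, Cc))
    },
    general_se3 = {
      acc <- pp_const(basis, 0)
      for (l in 1:3) {
        cl <- poly_add(posed_coordinate_polynomial(q0, l, family),
                       pp_const(basis, -p0[l]))
        acc <- poly_add(acc, poly_multiply(cl, cl))
      }
      acc
    })
}

#' Separated expansion of one particle pair
#'
#' Composes the fitted surrogate with the pair's squared-distance polynomial
#' and, for vector outputs, with the posed-coordinate polynomials:
#' \describe{
#'   \item{scalar_energy}{one polynomial
#'     `s(lambda_i, lambda_j) * sum_k a_k (d^2 poly)^k`; requires a
#'     surrogate with target `"shape_f"`.}
#'   \item{force_vector}{three polynomials, the energy-style sum (from a
#'     `"shape_f_over_d"` surrogate of `|f|/d`) times
#'     `(posed q coordinate l) - p0_l`.}
#'   \item{moment_vector}{the cross product of the posed coordinates with
#'     the force polynomials, expanded in the algebra.}
#' }
#'
#' @param p0,q0 reference coordinates (3-vectors)
#' @param lambda_i,lambda_j particle properties
#' @param surrogate a [fit_surrogate()] result
#' @param law an [interaction_law()]
#' @param family a [pose_family()]
#' @param output_kind `"scalar_energy"`, `"force_vector"` or
#'   `"moment_vector"`
#' @return named list of [pose_poly()], one per output component
#' @export
pair_expansion <- function(p0, q0, lambda_i, lambda_j, surrogate, law, family,
                           output_kind = c("scalar_energy", "force_vector",
                                           "moment_vector")) {
  output_kind <- match.arg(output_kind)
  .check_surrogate_target(surrogate, output_kind)
  basis <- pose_primitive_set(family$kind)
  s <- law$prefactor(lambda_i, lambda_j)

  D <- d2_polynomial(p0, q0, family)
  a <- surrogate$coeffs
  E <- pp_const(basis, a[1])
  pw <- pp_const(basis, 1)
  for (k in seq_len(surrogate$degree)) {
    pw <- poly_multiply(pw, D)
    if (a[k + 1] != 0) E <- poly_add(E, poly_scale(pw, a[k + 1]))
  }

  if (output_kind == "scalar_energy") {
    return(list(energy = poly_scale(E, s)))
  }

  Cl <- lapply(1:3, function(l) posed_coordinate_polynomial(q0, l, family))
  Fl <- lapply(1:3, function(l) {
    poly_scale(poly_multiply(E, poly_add(Cl[[l]], pp_const(basis, -p0[l]))), s)
  })
  names(Fl) <- c("f1", "f2", "f3")
  if (output_kind == "force_vector") return(Fl)

  Ml <- list(
    m1 = poly_add(poly_multiply(Cl[[2]], Fl[[3]]),
                  poly_scale(poly_multiply(Cl[[3]], Fl[[2]]), -1)),
    m2 = poly_add(poly_multiply(Cl[[3]], Fl[[1]]),
                  poly_scale(poly_multiply(Cl[[1]], Fl[[3]]), -1)),
    m3 = poly_add(poly_multiply(Cl[[1]], Fl[[2]]),
                  poly_scale(poly_multiply(Cl[[2]], Fl[[1]]), -1)))
  Ml
}

.check_surrogate_target <- function(surrogate, output_kind) {
  stopifnot(inherits(surrogate, "poly_surrogate"))
  want <- if (output_kind == "scalar_energy") "shape_f" else "shape_f_over_d"
  if (!identical(surrogate$target, want)) {
    stop("surrogate target '", surrogate$target, "' does not match output ",
         "kind '", output_kind, "' (need '", want, "')")
  }
  invisible(TRUE)
}
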