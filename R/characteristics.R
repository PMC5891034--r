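#' Characteristic model: pose basis plus characteristic constants
#'
#' The end product of preprocessing: a shared list of pose-basis monomials
#' and, per output component, the vector of characteristic constants `C_k`
#' obtained by summing each pair's geometry coefficient over all M*N pairs.
#' Its size depends on the surrogate degree and pose family only -- never on
#' the particle counts -- and evaluating it performs no pairwise-law
#' evaluations.
#'
#' @name characteristic_model
NULL

new_characteristic_model <- function(kind, monomials, components, output_kind,
                                     provenance = list()) {
  basis <- pose_primitive_set(kind)
  storage.mode(monomials) <- "integer"
  colnames(monomials) <- basis$primitives
  # canonical monomial order (total degree, then exponents left to right) so
  # every accumulation path yields byte-identical models
  if (nrow(monomials) > 1) {
    ord <- do.call(order, c(list(rowSums(monomials)),
                            lapply(seq_len(ncol(monomials)),
                                   function(j) monomials[, j])))
    monomials <- monomials[ord, , drop = FALSE]
    components <- lapply(components, function(v) v[ord])
  }
  stopifnot(all(vapply(components, length, 1L) == nrow(monomials)))
  if (!all(vapply(components, function(x) all(is.finite(x)), TRUE))) {
    stop("non-finite characteristic constants (overflow during accumulation?)")
  }
  structure(list(kind = kind, basis = basis, monomials = monomials,
                 components = components, output_kind = output_kind,
                 provenance = provenance),
            class = "characteristic_model")
}

#' @export
print.characteristic_model <- function(x, ...) {
  cat("<characteristic_model>", x$output_kind, "over", x$kind,
      "\n  separation rank r =", nrow(x$monomials),
      " components:", paste(names(x$components), collapse = ", "), "\n")
  if (!is.null(x$provenance$M)) {
    cat("  accumulated over", x$provenance$M, "x", x$provenance$N, "pairs\n")
  }
  invisible(x)
}

# drop monomials negligible across every component
.prune_model_rows <- function(monomials, components) {
  mat <- do.call(cbind, components)
  mx <- max(abs(mat))
  keep <- if (mx > 0) apply(abs(mat), 1, max) > 1e-14 * mx else rep(TRUE, nrow(mat))
  list(monomials = monomials[keep, , drop = FALSE],
       components = lapply(components, function(v) v[keep]))
}

#' Accumulate characteristic constants over all particle pairs
#'
#' Expands every pair of particles with [pair_expansion()] and sums the
#' per-pair coefficients termwise -- a one-time `O(M N)` computation whose
#' result has size independent of M and N. For the one-parameter families
#' (`translation_x1`, all output kinds; `rotation_x3`, scalar energy) a
#' vectorised fast path processes pairs in chunks; the generic path loops
#' over pairs with the sparse algebra and works for every family. Both
#' paths produce identical models (this is verified in the test suite).
#'
#' @param P,Q [particle_set()]s for the fixed and the moving body
#' @param surrogate a [fit_surrogate()] result (target `"shape_f"` for
#'   energy, `"shape_f_over_d"` for force/moment)
#' @param law an [interaction_law()]
#' @param family a [pose_family()]
#' @param output_kind `"scalar_energy"`, `"force_vector"` or
#'   `"moment_vector"`
#' @param engine `"auto"` (fast path when available), `"fast"`, or
#'   `"generic"`
#' @param chunk_size pairs per chunk in the fast path (memory control)
#' @param check_sweep optional sweep specification (see
#'   [compute_d2_range()]); when given, the pair distances over the sweep
#'   are checked against the surrogate domain and a warning is issued if
#'   they fall outside it
#' @return a [characteristic_model]
#' @export
accumulate_characteristics <- function(P, Q, surrogate, law, family,
                                       output_kind = c("scalar_energy",
                                                       "force_vector",
                                                       "moment_vector"),
                                       engine = c("auto", "fast", "generic"),
                                       chunk_size = 200000L,
                                       check_sweep = NULL) {
  output_kind <- match.arg(output_kind)
  engine <- match.arg(engine)
  stopifnot(inherits(P, "particle_set"), inherits(Q, "particle_set"))
  if (nrow(P$coords) == 0 || nrow(Q$coords) == 0) {
    stop("particle sets must be non-empty")
  }
  .check_surrogate_target(surrogate, output_kind)

  if (!is.null(check_sweep)) {
    rng <- compute_d2_range(P, Q, family, check_sweep)
    if (rng[1] < surrogate$domain[1] || rng[2] > surrogate$domain[2]) {
      warning("pair squared distances over the sweep ([", format(rng[1]), ", ",
              format(rng[2]), "]) are not fully covered by the surrogate ",
              "domain [", format(surrogate$domain[1]), ", ",
              format(surrogate$domain[2]), "]")
    }
  }

  fast_ok <- family$kind == "translation_x1" ||
    (family$kind == "rotation_x3" && output_kind == "scalar_energy")
  use_fast <- switch(engine,
    auto = fast_ok,
    fast = { if (!fast_ok) stop("no fast path for ", family$kind, " / ",
                                output_kind); TRUE },
    generic = FALSE)

  prov <- list(
    surrogate = surrogate[c("degree", "domain", "target", "sigma_r",
                            "max_rel_error")],
    law = law$name, family = family$kind, output_kind = output_kind,
    M = nrow(P$coords), N = nrow(Q$coords),
    labels = c(P = P$label, Q = Q$label))

  if (use_fast) {
    .accumulate_fast(P, Q, surrogate, law, family, output_kind, chunk_size,
                     prov)
  } else {
    .accumulate_generic(P, Q, surrogate, law, family, output_kind, prov)
  }
}

.accumulate_generic <- function(P, Q, surrogate, law, family, output_kind,
                                prov) {
  acc <- NULL # named list of key -> coefficient maps
  for (i in seq_len(nrow(P$coords))) {
    for (j in seq_len(nrow(Q$coords))) {
      polys <- pair_expansion(P$coords[i, ], Q$coords[j, ],
                              P$props[i], Q$props[j],
                              surrogate, law, family, output_kind)
      if (is.null(acc)) {
        acc <- lapply(polys, function(p) p$terms)
      } else {
        for (comp in names(polys)) {
          tm <- polys[[comp]]$terms
          keys <- union(names(acc[[comp]]), names(tm))
          v <- stats::setNames(numeric(length(keys)), keys)
          v[names(acc[[comp]])] <- acc[[comp]]
          v[names(tm)] <- v[names(tm)] + tm
          acc[[comp]] <- v
        }
      }
    }
  }
  keys <- sort(unique(unlist(lapply(acc, names))))
  np <- length(pose_primitive_set(family$kind)$primitives)
  monomials <- if (length(keys) > 0) {
    do.call(rbind, lapply(strsplit(keys, ":", fixed = TRUE), as.integer))
  } else matrix(integer(0), 0, np)
  components <- lapply(acc, function(v) {
    out <- stats::setNames(numeric(length(keys)), keys)
    out[names(v)] <- v
    unname(out)
  })
  pr <- .prune_model_rows(monomials, components)
  new_characteristic_model(family$kind, pr$monomials, pr$components,
                           output_kind, prov)
}

## ---- vectorised fast paths ---------------------------------------------

.accumulate_fast <- function(P, Q, surrogate, law, family, output_kind,
                             chunk_size, prov) {
  M <- nrow(P$coords); N <- nrow(Q$coords)
  a <- surrogate$coeffs
  n <- surrogate$degree
  # chunk over Q indices so each chunk is a full M x nq block
  nq_per <- max(1L, as.integer(chunk_size / M))
  starts <- seq(1L, N, by = nq_per)

  if (family$kind == "translation_x1") {
    ncol_e <- 2 * n + 1
    ncol_out <- if (output_kind == "scalar_energy") ncol_e else 2 * n + 2
    comp_names <- switch(output_kind, scalar_energy = "energy",
                         force_vector = c("f1", "f2", "f3"),
                         moment_vector = c("m1", "m2", "m3"))
    tot <- lapply(comp_names, function(x) numeric(ncol_out))
    names(tot) <- comp_names
    for (s0 in starts) {
      jj <- s0:min(s0 + nq_per - 1L, N)
      block <- .trans_block(P, Q, jj, a, n, output_kind, law, ncol_e, ncol_out)
      for (comp in comp_names) tot[[comp]] <- tot[[comp]] + block[[comp]]
    }
    monomials <- matrix(0:(ncol_out - 1), ncol = 1)
    pr <- .prune_model_rows(monomials, tot)
    return(new_characteristic_model("translation_x1", pr$monomials,
                                    pr$components, output_kind, prov))
  }

  # rotation_x3, scalar energy: basis {sin^m, sin^m cos}
  K <- n + 2L # column head-room for the cos^2 rewrite during powering
  totS <- numeric(K); totT <- numeric(K)
  for (s0 in starts) {
    jj <- s0:min(s0 + nq_per - 1L, N)
    block <- .rot_energy_block(P, Q, jj, a, n, law, K)
    totS <- totS + block$S
    totT <- totT + block$T
  }
  monomials <- rbind(cbind(0:(K - 1), 0L), cbind(0:(K - 1), 1L))
  pr <- .prune_model_rows(monomials, list(energy = c(totS, totT)))
  new_characteristic_model("rotation_x3", pr$monomials, pr$components,
                           "scalar_energy", prov)
}

# one M x length(jj) block of pairs for the translation family
.trans_block <- function(P, Q, jj, a, n, output_kind, law, ncol_e, ncol_out) {
  pc <- P$coords; qc <- Q$coords[jj, , drop = FALSE]
  M <- nrow(pc)
  dxv <- rep(qc[, 1], each = M) - pc[, 1]
  dyv <- rep(qc[, 2], each = M) - pc[, 2]
  dzv <- rep(qc[, 3], each = M) - pc[, 3]
  w <- law$prefactor(rep(P$props, times = nrow(qc)), rep(Q$props[jj], each = M))
  np <- length(dxv)
  # per-pair d^2 = x^2 + bb x + cc
  bb <- 2 * dxv
  cc <- dxv^2 + dyv^2 + dzv^2
  # E = sum_k a_k (d^2)^k as per-pair coefficient rows over x^0..x^(2n)
  E <- matrix(0, np, ncol_e)
  pow <- matrix(0, np, ncol_e)
  pow[, 1] <- 1
  E[, 1] <- a[1]
  for (k in seq_len(n)) {
    new <- matrix(0, np, ncol_e)
    new[, 1] <- cc * pow[, 1]
    new[, 2] <- cc * pow[, 2] + bb * pow[, 1]
    for (m in 3:(2 * k + 1)) {
      new[, m] <- cc * pow[, m] + bb * pow[, m - 1] + pow[, m - 2]
    }
    pow <- new
    if (a[k + 1] != 0) E <- E + a[k + 1] * pow
  }
  if (output_kind == "scalar_energy") {
    return(list(energy = colSums(w * E)))
  }
  shift <- function(mat) cbind(0, mat) # multiply by x
  F1 <- cbind(dxv * E, 0) + shift(E) # (dx + x) * E
  F2 <- cbind(dyv * E, 0)
  F3 <- cbind(dzv * E, 0)
  if (output_kind == "force_vector") {
    return(list(f1 = colSums(w * F1), f2 = colSums(w * F2),
                f3 = colSums(w * F3)))
  }
  # moment about the frame origin; posed q = (q1 + x, q2, q3)
  q1 <- rep(qc[, 1], each = M); q2 <- rep(qc[, 2], each = M)
  q3 <- rep(qc[, 3], each = M)
  mul_q1x <- function(Fm) cbind(q1 * Fm, 0)[, seq_len(ncol_out), drop = FALSE] +
    shift(Fm)[, seq_len(ncol_out), drop = FALSE]
  M1 <- q2 * F3 - q3 * F2
  M2 <- q3 * F1 - mul_q1x(F3)
  M3 <- mul_q1x(F2) - q2 * F1
  list(m1 = colSums(w * M1), m2 = colSums(w * M2), m3 = colSums(w * M3))
}

# rotation energy block: polynomials kept as (S, T) coefficient matrices,
# poly = sum_m S[, m+1] sin^m + sum_m T[, m+1] sin^m cos, cos^2 rewritten
.rot_energy_block <- function(P, Q, jj, a, n, law, K) {
  pc <- P$coords; qc <- Q$coords[jj, , drop = FALSE]
  M <- nrow(pc)
  p1 <- pc[, 1]; p2 <- pc[, 2]; p3 <- pc[, 3]
  q1 <- rep(qc[, 1], each = M); q2 <- rep(qc[, 2], each = M)
  q3 <- rep(qc[, 3], each = M)
  Av <- (p1^2 + p2^2) + (q1^2 + q2^2) + (q3 - p3)^2
  Bv <- 2 * (p1 * q2 - p2 * q1)
  Cv <- -2 * (p1 * q1 + p2 * q2)
  w <- law$prefactor(rep(P$props, times = nrow(qc)), rep(Q$props[jj], each = M))
  np <- length(Av)
  S <- matrix(0, np, K); T <- matrix(0, np, K)
  accS <- matrix(0, np, K); accT <- matrix(0, np, K)
  S[, 1] <- 1
  accS[, 1] <- a[1]
  for (k in seq_len(n)) {
    nS <- matrix(0, np, K); nT <- matrix(0, np, K)
    for (m in seq_len(K)) {
      v <- Av * S[, m] + Cv * T[, m]
      if (m > 1) v <- v + Bv * S[, m - 1]
      if (m > 2) v <- v - Cv * T[, m - 2] # cos^2 -> 1 - sin^2
      nS[, m] <- v
      wv <- Av * T[, m] + Cv * S[, m]
      if (m > 1) wv <- wv + Bv * T[, m - 1]
      nT[, m] <- wv
    }
    S <- nS; T <- nT
    if (a[k + 1] != 0) {
      accS <- accS + a[k + 1] * S
      accT <- accT + a[k + 1] * T
    }
  }
  list(S = colSums(w * accS), T = colSums(w * accT))
}

#' Squared-distance range of all pairs over a pose sweep
#'
#' Minimum and maximum pairwise squared distance over all M*N pairs at a
#' grid of sweep values -- the range over which the surrogate regression must
#' be valid. Exact at the evaluated poses.
#'
#' @param P,Q [particle_set()]s
#' @param family a [pose_family()]
#' @param sweep either an interval `c(lo, hi)` of the single free parameter
#'   (one-parameter families) or a matrix of pose-parameter rows
#' @param grid number of evenly spaced values when `sweep` is an interval
#'   (`>= 2`)
#' @return `c(d2_min, d2_max)`
#' @export
compute_d2_range <- function(P, Q, family, sweep, grid = 101L) {
  stopifnot(inherits(P, "particle_set"), inherits(Q, "particle_set"))
  if (nrow(P$coords) == 0 || nrow(Q$coords) == 0) {
    stop("particle sets must be non-empty")
  }
  vals <- .sweep_values(family, sweep, grid)
  pc <- P$coords
  pn <- rowSums(pc^2)
  lo <- Inf; hi <- -Inf
  for (i in seq_len(nrow(vals))) {
    ps <- make_pose(family, vals[i, ])
    qp <- apply_pose(ps, Q$coords)
    d2 <- outer(pn, rowSums(qp^2), "+") - 2 * pc %*% t(qp)
    lo <- min(lo, d2); hi <- max(hi, d2)
  }
  c(max(lo, 0), hi)
}

.sweep_values <- function(family, sweep, grid = 101L) {
  if (is.matrix(sweep)) {
    if (ncol(sweep) != n_free(family)) {
      stop("sweep matrix must have one column per free pose parameter")
    }
    return(sweep)
  }
  sweep <- as.numeric(sweep)
  if (n_free(family) != 1) {
    stop("interval sweeps need a one-parameter family; give a matrix of ",
         "pose values for ", family$kind)
  }
  if (length(sweep) != 2) stop("sweep must be c(lo, hi) or a matrix")
  if (grid < 2) stop("grid must be >= 2")
  matrix(seq(sweep[1], sweep[2], length.out = grid), ncol = 1)
}
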