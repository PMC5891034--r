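#' Evaluate the pose-basis monomials of a model at one pose
#'
#' `h_k` is the k-th stored monomial evaluated at the primitive values of
#' the given pose parameters.
#'
#' @param model a [characteristic_model]
#' @param values pose-parameter vector for the model's family
#' @return numeric vector of length equal to the separation rank
#' @export
pose_basis_values <- function(model, values) {
  stopifnot(inherits(model, "characteristic_model"))
  values <- as.numeric(values)
  if (length(values) != n_free(pose_family(model$kind))) {
    stop("pose value arity does not match family '", model$kind, "'")
  }
  pv <- primitive_values(model$basis, values)
  mon <- model$monomials
  h <- numeric(nrow(mon))
  for (k in seq_len(nrow(mon))) h[k] <- prod(pv^mon[k, ])
  h
}

#' Net interaction from a characteristic model
#'
#' The dot product of each component's characteristic constants with the
#' pose-basis values: `sum_k C_k h_k`. Performs zero pairwise-law
#' evaluations whatever the particle counts behind the model (see
#' [pairwise_eval_count()]).
#'
#' @inheritParams pose_basis_values
#' @return scalar (energy models) or named 3-vector (force/moment models)
#' @export
net_value <- function(model, values) {
  h <- pose_basis_values(model, values)
  out <- vapply(model$components, function(C) sum(C * h), numeric(1))
  if (length(out) == 1) unname(out) else out
}

#' Brute-force net interaction: the pairwise oracle
#'
#' Direct summation over all M*N particle pairs at one pose: the net energy
#' `sum_ij s(lambda_i, lambda_j) shape(d_ij)`, the net force as the vector
#' sum of central pairwise forces, or the net moment `sum_ij q_j x f_ij`
#' about the frame origin. Used as ground truth for the separated model.
#'
#' Engines: `"r"` is a vectorised pure-R double loop over pairs that works
#' for any registered law; `"cpp"` is a compiled kernel for the Coulomb
#' laws; `"auto"` picks the compiled kernel when the law allows. Both count
#' M*N pairwise-law evaluations on the instrumentation counter.
#'
#' @param P,Q [particle_set()]s
#' @param law an [interaction_law()]
#' @param pose a [pose()] (applied to Q)
#' @param output_kind `"scalar_energy"`, `"force_vector"` or
#'   `"moment_vector"`
#' @param engine `"auto"`, `"r"` or `"cpp"`
#' @return scalar or 3-vector
#' @export
brute_force_net <- function(P, Q, law, pose,
                            output_kind = c("scalar_energy", "force_vector",
                                            "moment_vector"),
                            engine = c("auto", "r", "cpp")) {
  output_kind <- match.arg(output_kind)
  engine <- match.arg(engine)
  stopifnot(inherits(P, "particle_set"), inherits(Q, "particle_set"),
            inherits(law, "interaction_law"))
  qp <- apply_pose(pose, Q$coords)
  M <- nrow(P$coords); N <- nrow(qp)

  coulomb_ok <- (law$name == "coulomb_energy" && output_kind == "scalar_energy") ||
    (law$name == "coulomb_force" && output_kind != "scalar_energy")
  use_cpp <- switch(engine,
    auto = coulomb_ok,
    cpp = { if (!coulomb_ok) stop("compiled kernel only covers the Coulomb ",
                                  "laws"); TRUE },
    r = FALSE)

  if (use_cpp) {
    inv4pieps <- 1 / (4 * pi * law$params$eps)
    out <- bf_coulomb_all(P$coords, P$props, qp, Q$props, inv4pieps)
    if (!all(is.finite(out))) .bf_report_coincident(P$coords, qp)
    .count_pairwise_evals(M * N)
    return(switch(output_kind,
      scalar_energy = out[1],
      force_vector = stats::setNames(out[2:4], c("f1", "f2", "f3")),
      moment_vector = stats::setNames(out[5:7], c("m1", "m2", "m3"))))
  }

  pc <- P$coords
  d2 <- outer(rowSums(pc^2), rowSums(qp^2), "+") - 2 * pc %*% t(qp)
  d2[d2 < 0] <- 0
  if (any(d2 == 0)) .bf_report_coincident(pc, qp)
  d <- sqrt(d2)
  L <- outer(P$props, Q$props, law$prefactor)
  shp <- law$shape(d)
  .count_pairwise_evals(M * N)
  if (output_kind == "scalar_energy") return(sum(L * shp))
  W <- L * shp / d
  if (output_kind == "force_vector") {
    f <- vapply(1:3, function(l) {
      sum(W * (matrix(qp[, l], M, N, byrow = TRUE) - pc[, l]))
    }, numeric(1))
    return(stats::setNames(f, c("f1", "f2", "f3")))
  }
  # net moment: sum_j q_j x (sum_i f_ij)
  fj <- vapply(1:3, function(l) {
    colSums(W * (matrix(qp[, l], M, N, byrow = TRUE) - pc[, l]))
  }, numeric(N))
  fj <- matrix(fj, N, 3)
  m <- c(sum(qp[, 2] * fj[, 3] - qp[, 3] * fj[, 2]),
         sum(qp[, 3] * fj[, 1] - qp[, 1] * fj[, 3]),
         sum(qp[, 1] * fj[, 2] - qp[, 2] * fj[, 1]))
  stats::setNames(m, c("m1", "m2", "m3"))
}

.bf_report_coincident <- function(pc, qp) {
  d2 <- outer(rowSums(pc^2), rowSums(qp^2), "+") - 2 * pc %*% t(qp)
  ij <- which(d2 <= 0, arr.ind = TRUE)
  i <- ij[1, 1]; j <- ij[1, 2]
  stop("coincident points at this pose: P particle ", i, " and Q particle ",
       j, " overlap; pairwise law is singular")
}

#' Sweep a characteristic model (and optionally the oracle) over poses
#'
#' Evaluates the separated model at each pose value with [net_value()]
#' (recording that this pass performs zero pairwise-law evaluations) and,
#' when requested, the brute-force reference with [brute_force_net()]. An
#' optional per-snapshot perturbation turns the reference into an
#' almost-rigid evaluation: at snapshot i, every particle coordinate of both
#' bodies is displaced by independent uniform draws within a cube of the
#' given edge before the brute-force sum, while the separated model keeps
#' the rigid reference geometry.
#'
#' @inheritParams brute_force_net
#' @param model a [characteristic_model]
#' @param family a [pose_family()] matching the model
#' @param values numeric vector of sweep values (one-parameter families) or
#'   a matrix of pose-parameter rows
#' @param with_brute evaluate the brute-force reference as well
#' @param perturb_edge edge of the almost-rigid perturbation cube (0 = rigid)
#' @param perturb_seed base seed for the per-snapshot perturbations
#' @return object of class `"sweep_result"`: `values`, `approx` (poses x
#'   components), `brute` (or `NULL`), `pairwise_eval_count` for the approx
#'   pass, `output_kind`
#' @export
pose_sweep <- function(model, P, Q, law, family, values, with_brute = TRUE,
                       engine = c("auto", "r", "cpp"), perturb_edge = 0,
                       perturb_seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "characteristic_model"))
  if (!identical(model$kind, family$kind)) {
    stop("model was built for family '", model$kind, "'")
  }
  vals <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
  if (ncol(vals) != n_free(family)) {
    stop("pose values must have one column per free parameter")
  }
  nv <- nrow(vals)
  comp <- names(model$components)

  before <- pairwise_eval_count()
  approx <- matrix(0, nv, length(comp), dimnames = list(NULL, comp))
  for (i in seq_len(nv)) approx[i, ] <- net_value(model, vals[i, ])
  approx_evals <- pairwise_eval_count() - before

  brute <- NULL
  if (with_brute) {
    brute <- matrix(0, nv, length(comp), dimnames = list(NULL, comp))
    for (i in seq_len(nv)) {
      Pb <- P; Qb <- Q
      if (perturb_edge > 0) {
        Pb <- perturb_particles(P, perturb_edge, perturb_seed, i)
        Qb <- perturb_particles(Q, perturb_edge, perturb_seed + 500000L, i)
      }
      brute[i, ] <- brute_force_net(Pb, Qb, law, make_pose(family, vals[i, ]),
                                    model$output_kind, engine)
    }
  }
  structure(list(values = vals, approx = approx, brute = brute,
                 pairwise_eval_count = approx_evals,
                 output_kind = model$output_kind),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", nrow(x$values), "pose(s),", x$output_kind,
      if (is.null(x$brute)) "(approx only)" else "(with brute force)", "\n")
  cat("  pairwise-law evaluations in approx pass:", x$pairwise_eval_count,
      "\n")
  invisible(x)
}

#' Per-pose percent errors of a sweep
#'
#' For scalar outputs, `|approx - brute| / |brute| * 100` per pose; for
#' vector outputs, the Euclidean-norm version
#' `||approx - brute|| / ||brute|| * 100`. Poses where the reference
#' magnitude falls below `1e-12` times the sweep maximum are returned as
#' `NA` (near-zero denominators, possible with mixed-sign charges).
#'
#' @param result a [pose_sweep()] result with the brute-force pass present
#' @return numeric vector (NA at excluded poses)
#' @export
percent_errors <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  if (is.null(result$brute)) stop("sweep was run without the brute-force pass")
  a <- result$approx; b <- result$brute
  if (ncol(a) == 1) {
    denom <- abs(b[, 1])
    num <- abs(a[, 1] - b[, 1])
  } else {
    denom <- sqrt(rowSums(b^2))
    num <- sqrt(rowSums((a - b)^2))
  }
  bad <- denom < 1e-12 * max(denom, 0)
  out <- num / denom * 100
  out[bad] <- NA_real_
  out
}

#' Average percent error of a sweep against the brute-force reference
#'
#' The default metric is the mean over poses of the absolute relative error
#' (percent); `"rms"` and `"signed_mean"` variants are available for
#' sensitivity checks since reported "average error" conventions differ.
#' Excluded near-zero-denominator poses are dropped from the mean and their
#' count reported via the `"n_excluded"` attribute (with a message).
#'
#' @param result a [pose_sweep()] result with the brute-force pass
#' @param metric `"mean_abs"` (default), `"rms"` or `"signed_mean"`
#' @return percentage (numeric scalar) with attributes `n_used` and
#'   `n_excluded`
#' @export
average_percent_error <- function(result,
                                  metric = c("mean_abs", "rms", "signed_mean")) {
  metric <- match.arg(metric)
  pe <- percent_errors(result)
  excluded <- sum(is.na(pe))
  if (excluded > 0) {
    message(excluded, " pose(s) excluded from the error mean ",
            "(near-zero reference value)")
  }
  pe_ok <- pe[!is.na(pe)]
  if (length(pe_ok) == 0) stop("no poses with usable reference values")
  val <- switch(metric,
    mean_abs = mean(pe_ok),
    rms = sqrt(mean(pe_ok^2)),
    signed_mean = {
      a <- result$approx; b <- result$brute
      keep <- !is.na(pe)
      if (ncol(a) == 1) {
        mean((a[keep, 1] - b[keep, 1]) / b[keep, 1]) * 100
      } else {
        na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
        mean((na[keep] - nb[keep]) / nb[keep]) * 100
      }
    })
  structure(val, n_used = length(pe_ok), n_excluded = excluded)
}
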