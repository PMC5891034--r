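#' Fit a polynomial-in-squared-distance surrogate of a pairwise shape
#'
#' Least-squares fit of `sum_k a_k (d^2)^k` to `shape(d)` over a stated
#' squared-distance range. Choosing squared distance as the regression
#' variable is what keeps the later pose expansion finite: under any rigid
#' pose family, `d^2` is a polynomial in a handful of pose primitives, so its
#' powers are too.
#'
#' Sampling is a uniform grid in `d` (endpoints included), which weights the
#' short range -- where singular laws vary fastest -- more heavily than a
#' uniform grid in `d^2` would. The regression is solved by QR factorisation
#' of a Vandermonde matrix in the rescaled variable
#' `t = (d^2 - mid) / halfwidth` (so `t` spans `[-1, 1]`), then converted
#' exactly (binomial expansion) to monomial coefficients in `d^2`. A warning
#' is issued when the design matrix is ill-conditioned enough that the
#' converted coefficients lose several digits.
#'
#' @param shape function of distance `d` (vectorised)
#' @param domain squared-distance interval `c(d2_min, d2_max)`; the lower
#'   bound must be positive when the shape is singular at the origin
#' @param degree polynomial degree `n >= 0` in `d^2` (default 9)
#' @param n_samples number of fit samples (`> degree`, default 2000)
#' @param target what the shape stands for: `"shape_f"` (an energy-like
#'   magnitude) or `"shape_f_over_d"` (magnitude over distance, the form used
#'   for force and moment components)
#' @return object of class `"poly_surrogate"`: `coeffs` (`a_0..a_n`),
#'   `degree`, `domain`, `target`, `sigma_r` (residual standard deviation),
#'   `max_rel_error` (max relative fit error over the sample). The fit sample
#'   is attached as attribute `"sample"` (columns `d2`, `y`, `resid`).
#' @examples
#' s <- fit_surrogate(function(d) 1 / d, domain = c(1, 82), degree = 9)
#' eval_surrogate(s, 25) # close to 1/5
#' @export
fit_surrogate <- function(shape, domain, degree = 9, n_samples = 2000,
                          target = c("shape_f", "shape_f_over_d")) {
  target <- match.arg(target)
  stopifnot(is.function(shape), length(domain) == 2)
  domain <- as.numeric(domain)
  if (!all(is.finite(domain)) || domain[2] <= domain[1]) {
    stop("domain must be a non-degenerate interval [d2_min, d2_max]")
  }
  if (domain[1] < 0) stop("squared distances cannot be negative")
  if (degree < 0 || degree != round(degree)) stop("degree must be a non-negative integer")
  if (n_samples <= degree) stop("n_samples must exceed the degree")

  d <- seq(sqrt(domain[1]), sqrt(domain[2]), length.out = n_samples)
  y <- shape(d)
  if (!all(is.finite(y))) {
    stop("shape is not finite over the domain; for singular laws the ",
         "domain lower bound must be positive")
  }

  mid <- mean(domain)
  half <- diff(domain) / 2
  t <- (d^2 - mid) / half
  V <- outer(t, 0:degree, "^")
  qrV <- qr(V)
  if (qrV$rank < degree + 1) {
    stop("design matrix is rank deficient; lower the degree")
  }
  b <- qr.coef(qrV, y)
  resid <- y - drop(V %*% b)

  # exact conversion t^k -> monomials in d2 via the binomial theorem
  a <- numeric(degree + 1)
  for (k in 0:degree) {
    jj <- 0:k
    a[jj + 1] <- a[jj + 1] + b[k + 1] * choose(k, jj) * (-mid)^(k - jj) / half^k
  }
  # estimate digits lost in the monomial representation: the converted
  # coefficients can be large and of mixed sign even when the fit is tame
  scale_ratio <- max(abs(b * c(1, cumprod(rep(1 / half, degree))))) /
    max(abs(a), .Machine$double.xmin)
  if (is.finite(scale_ratio) && scale_ratio > 1e8) {
    warning("monomial conversion loses ~", round(log10(scale_ratio)),
            " digits (degree too high for this domain); estimated absolute ",
            "coefficient error ~", format(scale_ratio * .Machine$double.eps))
  }

  dof <- n_samples - (degree + 1)
  sigma_r <- if (dof > 0) sqrt(sum(resid^2) / dof) else 0
  nz <- abs(y) > 0
  max_rel_error <- if (any(nz)) max(abs(resid[nz] / y[nz])) else 0

  structure(
    list(coeffs = unname(a), degree = degree, domain = domain, target = target,
         sigma_r = sigma_r, max_rel_error = max_rel_error),
    sample = data.frame(d2 = d^2, y = y, resid = resid),
    class = "poly_surrogate")
}

#' @export
print.poly_surrogate <- function(x, ...) {
  cat("<poly_surrogate> degree", x$degree, "in d^2 on [",
      format(x$domain[1]), ",", format(x$domain[2]), "] target", x$target,
      "\n  sigma_r =", format(x$sigma_r),
      " max_rel_error =", format(x$max_rel_error), "\n")
  invisible(x)
}

#' Evaluate a polynomial surrogate at squared distances
#'
#' Horner evaluation of `sum_k a_k (d2)^k`. Values outside the fitted domain
#' are extrapolated with a warning rather than refused: almost-rigid
#' perturbation experiments legitimately push a few distances slightly past
#' the rigid-body range.
#'
#' @param s a [fit_surrogate()] result
#' @param d2 squared distance(s)
#' @return surrogate value(s)
#' @export
eval_surrogate <- function(s, d2) {
  stopifnot(inherits(s, "poly_surrogate"))
  out_of <- d2 < s$domain[1] | d2 > s$domain[2]
  if (any(out_of)) {
    warning(sum(out_of), " evaluation(s) outside the fitted d^2 domain [",
            format(s$domain[1]), ", ", format(s$domain[2]),
            "]; extrapolating")
  }
  .horner(s$coeffs, d2)
}
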