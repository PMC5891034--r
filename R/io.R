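#' Read and write particle files
#'
#' The native format is CSV with header `x,y,z,prop` (one row per particle).
#' Extended XYZ is also accepted on input: a count line, a comment line,
#' then one line per particle with an optional leading element symbol
#' followed by `x y z prop`.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"csv"` or `"xyz"`
#' @param label body label for the returned set
#' @return `read_particles()` returns a [particle_set()];
#'   `write_particles()` writes CSV and returns the path invisibly
#' @export
read_particles <- function(path, format = c("auto", "csv", "xyz"),
                           label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "csv"
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    df <- read.csv(path)
    need <- c("x", "y", "z", "prop")
    if (!all(need %in% names(df))) {
      stop("particle CSV needs columns x, y, z, prop")
    }
    return(particle_set(as.matrix(df[, c("x", "y", "z")]), df$prop, label))
  }
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("extended XYZ must start with the particle count")
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  rows <- lapply(parts, function(p) {
    if (length(p) == 5) p <- p[-1] # leading element symbol
    if (length(p) != 4) stop("XYZ rows need x y z plus one property column")
    as.numeric(p)
  })
  m <- do.call(rbind, rows)
  particle_set(m[, 1:3, drop = FALSE], m[, 4], label)
}

#' @rdname read_particles
#' @param ps a [particle_set()]
#' @export
write_particles <- function(ps, path) {
  stopifnot(inherits(ps, "particle_set"))
  df <- data.frame(x = ps$coords[, 1], y = ps$coords[, 2],
                   z = ps$coords[, 3], prop = ps$props)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize surrogates and characteristic models to JSON
#'
#' @param s a [fit_surrogate()] result
#' @param path file path
#' @return the reading functions return the reconstructed object; the
#'   writers return the path invisibly
#' @export
write_surrogate_json <- function(s, path) {
  stopifnot(inherits(s, "poly_surrogate"))
  jsonlite::write_json(
    list(degree = s$degree, coeffs = s$coeffs, domain = s$domain,
         target = s$target, sigma_r = s$sigma_r,
         max_rel_error = s$max_rel_error),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate_json
#' @export
read_surrogate_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coeffs = as.numeric(x$coeffs), degree = as.integer(x$degree),
                 domain = as.numeric(x$domain), target = x$target,
                 sigma_r = as.numeric(x$sigma_r),
                 max_rel_error = as.numeric(x$max_rel_error)),
            class = "poly_surrogate")
}

#' @rdname write_surrogate_json
#' @param model a [characteristic_model]
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "characteristic_model"))
  jsonlite::write_json(
    list(kind = model$kind,
         primitives = model$basis$primitives,
         monomials = model$monomials,
         components = model$components,
         output_kind = model$output_kind,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mon <- x$monomials
  if (!is.matrix(mon)) {
    mon <- matrix(as.integer(unlist(mon)), ncol = length(x$primitives),
                  byrow = TRUE)
  }
  new_characteristic_model(x$kind, mon,
                           lapply(x$components, as.numeric),
                           x$output_kind, x$provenance)
}

#' Write a sweep result as CSV with a JSON error summary sidecar
#'
#' The CSV holds the pose-parameter columns and one column per output
#' component for the approximation and (when present) the brute-force
#' reference. The sidecar `<path>.summary.json` holds the average percent
#' error, exclusion count and the pairwise-evaluation count of the approx
#' pass.
#'
#' @param result a [pose_sweep()] result
#' @param path CSV path
#' @export
write_sweep_csv <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  vals <- result$values
  colnames(vals) <- paste0("pose", seq_len(ncol(vals)))
  df <- data.frame(vals, check.names = FALSE)
  ap <- result$approx
  colnames(ap) <- paste0("approx_", colnames(result$approx))
  df <- cbind(df, ap)
  summary <- list(pairwise_eval_count = result$pairwise_eval_count,
                  output_kind = result$output_kind)
  if (!is.null(result$brute)) {
    br <- result$brute
    colnames(br) <- paste0("brute_", colnames(result$brute))
    df <- cbind(df, br)
    ape <- average_percent_error(result)
    summary$average_percent_error <- as.numeric(ape)
    summary$n_excluded <- attr(ape, "n_excluded")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# full artefact dump for run_experiment(out_dir = ...)
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, report$preset)
  suppressMessages(write_sweep_csv(report$sweep, paste0(base, "_sweep.csv")))
  write_model_json(report$model, paste0(base, "_model.json"))
  write_surrogate_json(report$surrogate, paste0(base, "_surrogate.json"))
  jsonlite::write_json(
    list(preset = report$preset, seed = report$seed,
         n_particles = report$n_particles, n_snapshots = report$n_snapshots,
         degree = report$degree, perturb_edge = report$perturb_edge,
         d2_range = report$d2_range,
         sigma_r = report$surrogate$sigma_r,
         max_rel_fit_error = report$surrogate$max_rel_error,
         separation_rank = report$separation_rank,
         average_percent_error = report$average_percent_error,
         n_excluded = report$n_excluded),
    paste0(base, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
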