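# Algorithm 1: stability classification of two-species networks on the
# trace-determinant plane.

#' Symbolic trace, determinant and discriminant of a 2x2 Jacobian
#'
#' @param J a 2x2 list-matrix of `spoly` entries.
#' @return list with `trace`, `determinant`, `discriminant` (`spoly`),
#'   expanded; `discriminant = trace^2 - 4 determinant` identically.
#' @export
symbolic_plane <- function(J) {
  if (nrow(J) != 2L || ncol(J) != 2L)
    stop("trace-determinant analysis needs a 2x2 matrix; got ",
         nrow(J), "x", ncol(J), " (only two species can be involved)")
  tr <- sp_add(J[[1, 1]], J[[2, 2]])
  de <- sp_sub(sp_mul(J[[1, 1]], J[[2, 2]]), sp_mul(J[[1, 2]], J[[2, 1]]))
  dis <- sp_sub(sp_pow(tr, 2L), sp_scale(de, 4))
  list(trace = tr, determinant = de, discriminant = dis)
}

#' Classify a point of the trace-determinant plane
#'
#' det < 0: saddle (unstable); det > 0 and trace > 0: unstable;
#' det > 0 and trace < 0: stable; a zero among determinant, trace or
#' discriminant marks a bifurcation point.
#'
#' @param trace,determinant,discriminant numeric values.
#' @param tol relative tolerance below which a float value counts as zero.
#' @return one of `"saddle-unstable"`, `"unstable"`, `"stable"`,
#'   `"bifurcation"`.
#' @export
classify_point <- function(trace, determinant, discriminant, tol = 1e-12) {
  near0 <- function(v) abs(v) <= tol * max(1, abs(trace), abs(determinant),
                                           abs(discriminant))
  if (near0(determinant) || near0(trace) || near0(discriminant))
    return("bifurcation")
  if (determinant < 0) return("saddle-unstable")
  if (trace > 0) return("unstable")
  "stable"
}

# Log-uniform draw on [lo, hi]; spans the magnitudes of liquid-phase rate
# constants.
runif_log <- function(n, lo = 1e-3, hi = 1e3) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Random scan of the trace-determinant plane
#'
#' Draws rate constants log-uniformly on `[1e-3, 1e3]` (dual pairs forced
#' equal), fixes every concentration at 0.01 (arbitrary units), and
#' classifies each resulting point.
#'
#' @param network a two-species `reaction_network`.
#' @param n_samples number of random points.
#' @param seed optional integer seed.
#' @return data.frame with one row per sample: rate constants, trace,
#'   determinant, discriminant, verdict.
#' @export
random_point_scan <- function(network, n_samples = 10L, seed = NULL) {
  if (length(network$species) != 2L)
    stop("random_point_scan needs a two-species network")
  if (!is.null(seed)) set.seed(seed)
  odes <- network_odes(network)
  plane <- symbolic_plane(jacobian_matrix(odes))
  reps <- rate_representatives(network)
  nrx <- length(network$reactions)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    kdraw <- runif_log(nrx)
    k <- kdraw[reps + 1L]              # dual pairs exactly equal
    vals <- c(stats::setNames(k, paste0("k", seq_len(nrx) - 1L)),
              x0 = 0.01, x1 = 0.01)
    tr <- sp_eval(plane$trace, vals)
    de <- sp_eval(plane$determinant, vals)
    dis <- sp_eval(plane$discriminant, vals)
    out[[s]] <- c(as.list(vals[seq_len(nrx)]),
                  list(trace = tr, determinant = de, discriminant = dis,
                       verdict = classify_point(tr, de, dis)))
  }
  do.call(rbind, lapply(out, function(row)
    as.data.frame(row, stringsAsFactors = FALSE)))
}
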