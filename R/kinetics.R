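#' Fraction of labeled strand in complex under irreversible second-order
#' annealing
#'
#' For A + B -> AB with rate constant k and initial concentrations A0
#' (labeled strand) and B0 (target), the complexed amount x(t) solves
#' dx/dt = k (A0 - x)(B0 - x). The closed form is
#' `x(t) = A0 B0 (e^{(B0-A0)kt} - 1) / (B0 e^{(B0-A0)kt} - A0)` for
#' A0 != B0 and `x(t) = A0^2 k t / (1 + A0 k t)` for A0 = B0; the
#' returned value is `x(t)/A0`, in \[0, 1\]. Evaluated in an
#' exponentially stable form for large kt.
#'
#' @param k Rate constant, 1/(M s), >= 0.
#' @param A0 Initial labeled-strand concentration, M, > 0.
#' @param B0 Initial target concentration, M, > 0.
#' @param t Time(s), s, >= 0 (vectorized).
#' @return Fraction(s) of labeled strand complexed.
#' @export
fraction_complexed <- function(k, A0, B0, t) {
  if (any(c(k, A0, B0) < 0) || any(t < 0))
    stop("k, A0, B0 and t must be non-negative", call. = FALSE)
  if (A0 == 0 || B0 == 0 || k == 0) return(rep(0, length(t)))
  d <- (B0 - A0) * k * t
  out <- numeric(length(t))
  same <- abs(B0 - A0) < .Machine$double.eps * max(A0, B0)
  if (same) {
    out <- A0 * k * t / (1 + A0 * k * t)
  } else {
    # work with e^{-|d|} so the exponential never overflows
    pos <- d >= 0
    ed <- exp(-abs(d))
    out[pos] <- B0 * (1 - ed[pos]) / (B0 - A0 * ed[pos])
    out[!pos] <- B0 * (ed[!pos] - 1) / (B0 * ed[!pos] - A0)
  }
  pmin(pmax(out, 0), 1)
}

#' Simulate a noisy annealing time course
#'
#' Closed-form [fraction_complexed()] values perturbed by multiplicative
#' lognormal noise with coefficient of variation `noise_cv`, clipped to
#' \[0, 1\]. Reproducible under a fixed seed.
#'
#' @param k,A0,B0 As in [fraction_complexed()].
#' @param times Sampling times in seconds (default 10, 30, 60, 120, 300,
#'   600, 1200 s).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer RNG seed.
#' @return An object of class `annealing_timecourse`: list with `times`,
#'   `fraction`, `A0`, `B0`.
#' @export
simulate_timecourse <- function(k, A0, B0,
                                times = c(10, 30, 60, 120, 300, 600, 1200),
                                noise_cv = 0, seed = 1L) {
  stopifnot(noise_cv >= 0, all(diff(times) > 0))
  f <- fraction_complexed(k, A0, B0, times)
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    f <- f * rlnorm(length(f), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    f <- pmin(pmax(f, 0), 1)
  }
  annealing_timecourse(times, f, A0, B0)
}

#' Construct an annealing time course
#' @param times Strictly increasing times in seconds, >= 0.
#' @param fraction Fractions complexed, each in \[0, 1\].
#' @param A0,B0 Initial concentrations, M, > 0.
#' @return Object of class `annealing_timecourse`.
#' @export
annealing_timecourse <- function(times, fraction, A0, B0) {
  stopifnot(length(times) == length(fraction), length(times) >= 3L,
            all(diff(times) > 0), all(times >= 0),
            all(fraction >= 0 & fraction <= 1), A0 > 0, B0 > 0)
  structure(list(times = as.numeric(times), fraction = as.numeric(fraction),
                 A0 = A0, B0 = B0),
            class = "annealing_timecourse")
}

#' Read / write annealing time courses as TSV
#'
#' Columns `t_seconds`, `fraction`; concentrations are supplied
#' separately (they are experiment metadata, not per-point data).
#'
#' @param path TSV path.
#' @param A0,B0 Initial concentrations, M.
#' @return [annealing_timecourse()] for the reader; invisible path for
#'   the writer.
#' @export
read_timecourse <- function(path, A0, B0) {
  df <- read_table_schema(path, c(t_seconds = "numeric", fraction = "numeric"))
  annealing_timecourse(df$t_seconds, df$fraction, A0, B0)
}

#' @rdname read_timecourse
#' @param tc An `annealing_timecourse`.
#' @export
write_timecourse <- function(tc, path) {
  write.table(data.frame(t_seconds = tc$times, fraction = tc$fraction),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate the observed second-order annealing rate constant
#'
#' Single-parameter least squares of [fraction_complexed()] against the
#' measured fractions, on the fraction scale (not linearized). The search
#' runs over log10(k) bounded to k in \[1e2, 1e10\] 1/(M s) and starts
#' from the initial-slope estimate `k0 = (df/dt)(0) / B0`.
#'
#' @param tc An [annealing_timecourse()].
#' @return List of class `rate_estimate`: `k_obs` (1/(M s)), `sse`,
#'   `converged`, `k_init`.
#' @export
estimate_kobs <- function(tc) {
  stopifnot(inherits(tc, "annealing_timecourse"))
  f <- tc$fraction
  if (all(f == 0) || any(!is.finite(f)))
    stop("time course unfittable: all-zero or non-finite fractions", call. = FALSE)
  slope0 <- f[1] / tc$times[1]
  k_init <- max(min(slope0 / tc$B0, 1e10), 1e2)
  sse <- function(log10k) {
    pred <- fraction_complexed(10^log10k, tc$A0, tc$B0, tc$times)
    sum((pred - f)^2)
  }
  fit <- optim(log10(k_init), sse, method = "Brent", lower = 2, upper = 10)
  structure(list(k_obs = 10^fit$par, sse = fit$value,
                 converged = fit$convergence == 0L, k_init = k_init),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate: k_obs = %.3g /M/s, sse = %.3g, converged = %s>\n",
              x$k_obs, x$sse, x$converged))
  invisible(x)
}
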