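#' Gauss error function
#'
#' `erf(x) = 2*pnorm(x*sqrt(2)) - 1`, vectorized.
#'
#' @param x numeric.
#' @return erf(x).
#' @export
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Reduced threading energy
#'
#' Total threading energy divided by the number of transmembrane
#' segments, `e = E / NTM`; the per-segment normalization that makes
#' chains of different sizes comparable on one reliability curve.
#'
#' @param E threading energy (or vector).
#' @param ntm number of membrane segments, >= 1.
#' @return `E / ntm`.
#' @export
reduced_energy <- function(E, ntm) {
  if (any(ntm < 1L)) abort("NTM must be at least 1")
  E / ntm
}

#' Cumulative reduced-energy curve
#'
#' The parametric form fitted to the empirical cumulative distribution of
#' reduced energies: `H = erf(e*a - b)/2 + 0.5`, strictly increasing in
#' `e` for `a > 0` and confined to (0, 1).
#'
#' @param e reduced energy (vectorized).
#' @param a,b curve parameters.
#' @return H in (0, 1).
#' @export
cumulative_curve <- function(e, a, b) erf(e * a - b) / 2 + 0.5

#' Reliability model container
#'
#' Fitted (a, b) parameter pairs of the native and decoy cumulative
#' reduced-energy curves. The shipped defaults are the package's
#' reference fit values for the two curves.
#'
#' @param a_native,b_native,a_decoy,b_decoy curve parameters.
#' @return A `tmf_reliability`.
#' @export
reliability_model <- function(a_native = 1.380, b_native = -2.473,
                              a_decoy = 2.050, b_decoy = -3.145) {
  if (!all(is.finite(c(a_native, b_native, a_decoy, b_decoy)))) {
    abort("reliability parameters must be finite")
  }
  structure(
    list(a_native = a_native, b_native = b_native,
         a_decoy = a_decoy, b_decoy = b_decoy),
    class = "tmf_reliability"
  )
}

#' @rdname reliability_model
#' @export
default_reliability_model <- function() reliability_model()

#' @export
print.tmf_reliability <- function(x, ...) {
  cat(sprintf(
    "<tmf_reliability> native: a = %.4g, b = %.4g; decoy: a = %.4g, b = %.4g\n",
    x$a_native, x$b_native, x$a_decoy, x$b_decoy
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tmf_reliability <- function(x, ...) {
  tibble(
    population = c("native", "decoy"),
    a = c(x$a_native, x$a_decoy),
    b = c(x$b_native, x$b_decoy)
  )
}

#' @exportS3Method generics::glance
glance.tmf_reliability <- function(x, ...) {
  tibble(
    a_native = x$a_native, b_native = x$b_native,
    a_decoy = x$a_decoy, b_decoy = x$b_decoy,
    crossing_e = (x$b_native - x$b_decoy) / (x$a_native - x$a_decoy)
  )
}

# least-squares erf-curve fit to the Hazen empirical CDF of one sample
fit_erf_cdf <- function(e, label = "sample") {
  e <- sort(e)
  n <- length(e)
  if (n < 10L) abort(sprintf("need at least 10 %s reduced energies", label))
  if (diff(range(e)) < .Machine$double.eps^0.5) {
    abort(sprintf("degenerate (constant) %s reduced energies", label))
  }
  H <- (seq_len(n) - 0.5) / n
  df <- data.frame(e = e, H = H)
  fit <- minpack.lm::nlsLM(
    H ~ erf(e * a - b) / 2 + 0.5,
    data = df,
    start = list(a = 1, b = mean(e)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  coef(fit)
}

#' Fit native and decoy cumulative curves
#'
#' Fits `H = erf(e*a - b)/2 + 0.5` by nonlinear least squares to the
#' empirical cumulative distributions (Hazen plotting positions,
#' `(rank - 0.5)/n`) of the native and decoy reduced-energy samples. The
#' decoy sample should hold, per query, the reduced energy of the best
#' scoring non-native template.
#'
#' @param native_e,decoy_e numeric vectors (>= 10 values each).
#' @return A `tmf_reliability` with an attribute `n` recording the two
#'   sample sizes.
#' @export
fit_curves <- function(native_e, decoy_e) {
  cn <- fit_erf_cdf(native_e, "native")
  cd <- fit_erf_cdf(decoy_e, "decoy")
  out <- reliability_model(cn[["a"]], cn[["b"]], cd[["a"]], cd[["b"]])
  attr(out, "n") <- c(native = length(native_e), decoy = length(decoy_e))
  out
}

#' Reliability of nativeness
#'
#' `H_native / (H_native + H_decoy)` evaluated at the reduced energy of
#' the top-ranked template, clamped below at 0.5 so the score lies in
#' `[0.5, 1]`: with the default parameters the raw ratio dips marginally
#' below 0.5 above the curve-crossing energy, a regime where the
#' prediction is uninformative anyway. Low (very negative) reduced
#' energies give scores near 1.
#'
#' @param e reduced energy (vectorized).
#' @param model a [reliability_model()].
#' @return Score in `[0.5, 1]`.
#' @export
reliability_score <- function(e, model = default_reliability_model()) {
  # H = erf(x)/2 + 0.5 = pnorm(x * sqrt(2)); the ratio is computed from
  # log-CDFs so deep in the native tail (where both H underflow) the
  # score remains the correct limit instead of 0/0
  log_hn <- pnorm(sqrt(2) * (e * model$a_native - model$b_native), log.p = TRUE)
  log_hd <- pnorm(sqrt(2) * (e * model$a_decoy - model$b_decoy), log.p = TRUE)
  pmax(1 / (1 + exp(log_hd - log_hn)), 0.5)
}

#' Write / read a reliability model as JSON
#'
#' @param model a `tmf_reliability`.
#' @param path file path.
#' @param metadata named provenance list.
#' @return `write_reliability_model`: the path, invisibly.
#' @export
write_reliability_model <- function(model, path, metadata = list()) {
  jsonlite::write_json(
    list(
      a_native = model$a_native, b_native = model$b_native,
      a_decoy = model$a_decoy, b_decoy = model$b_decoy,
      metadata = metadata
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_reliability_model
#' @export
read_reliability_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  reliability_model(obj$a_native, obj$b_native, obj$a_decoy, obj$b_decoy)
}

#' Plot the native/decoy cumulative curves and the reliability score
#'
#' @param object a `tmf_reliability`.
#' @param e_range range of reduced energies to draw (default -6..1).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tmf_reliability <- function(object, e_range = c(-6, 1), ...) {
  e <- seq(e_range[1], e_range[2], length.out = 400)
  df <- bind_rows(
    tibble(e = e, value = cumulative_curve(e, object$a_native, object$b_native),
           curve = "H native"),
    tibble(e = e, value = cumulative_curve(e, object$a_decoy, object$b_decoy),
           curve = "H decoy"),
    tibble(e = e, value = reliability_score(e, object), curve = "reliability")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reduced energy e = E / NTM", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
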