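# Population sparseness and perceptron storage-capacity analytics.

#' Sparseness index of a rate vector
#'
#' For mean firing rates `v_i` over `n >= 2` stimuli, the activity ratio is
#' `A = (sum(v)/n)^2 / sum(v^2/n)` and the sparseness index is
#' `SI = (1 - A) / (1 - 1/n)`. SI is 0 when every stimulus evokes the same
#' rate and 1 when a single stimulus drives the neuron; it is invariant to
#' rescaling the rates.
#'
#' @param rates non-negative numeric vector of mean firing rates (Hz), one
#'   entry per stimulus, length >= 2.
#' @return SI in `[0, 1]`.
#' @export
#' @examples
#' sparseness_index(c(5, 5, 5, 5))  # 0
#' sparseness_index(c(8, 0, 0, 0))  # 1
sparseness_index <- function(rates) {
  n <- length(rates)
  if (n < 2) stop("need rates for at least 2 stimuli")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  if (all(rates == 0))
    stop("sparseness index undefined for an all-zero rate vector")
  A <- (sum(rates) / n)^2 / (sum(rates^2) / n)
  (1 - A) / (1 - 1 / n)
}

#' Sparseness index per neuron from a rate matrix
#'
#' @param rate_matrix neurons x stimuli matrix of mean firing rates.
#' @return numeric vector of SI values; `NA` for all-zero rows.
#' @export
sparseness_profile <- function(rate_matrix) {
  apply(as.matrix(rate_matrix), 1, function(v) {
    if (all(v == 0)) NA_real_ else sparseness_index(v)
  })
}

#' Stability constant of a neuron
#'
#' Default interpretation: `kappa = T / sqrt(tau_s * tau_m)` for input
#' pattern duration `T` and synaptic/membrane time constants; the published
#' formula is typographically ambiguous, so the parse is pluggable
#' via `interpretation` and every capacity report carries the identifier of
#' the parse that produced it.
#'
#' @param T input pattern duration (ms).
#' @param tau_s synaptic time constant (ms), conventionally `tau_m / 4`.
#' @param tau_m membrane time constant (ms).
#' @param interpretation `"T_over_sqrt"` (default) for
#'   `T / sqrt(tau_s * tau_m)` or `"T_times_sqrt"` for
#'   `T * sqrt(tau_s * tau_m)`.
#' @return the stability constant `kappa`.
#' @export
#' @examples
#' stability_constant(320, 16, 64)  # 10
stability_constant <- function(T, tau_s, tau_m,
                               interpretation = c("T_over_sqrt", "T_times_sqrt")) {
  interpretation <- match.arg(interpretation)
  if (any(c(T, tau_s, tau_m) <= 0)) stop("T, tau_s and tau_m must be positive")
  switch(interpretation,
         T_over_sqrt = T / sqrt(tau_s * tau_m),
         T_times_sqrt = T * sqrt(tau_s * tau_m))
}

#' Perceptron storage capacity from the stability constant
#'
#' Default interpretation: `alpha_c = ln(ln(kappa^2)) / (2 ln 2)`, defined
#' for `ln(kappa^2) > 1`; monotonically increasing in `kappa` on its domain.
#' The parse of the published formula is pluggable (see
#' [stability_constant()]).
#'
#' @param kappa stability constant.
#' @param interpretation identifier of the formula parse; only
#'   `"lnln_over_2ln2"` is currently implemented.
#' @return storage capacity `alpha_c` (associations per synapse).
#' @export
storage_capacity <- function(kappa, interpretation = "lnln_over_2ln2") {
  interpretation <- match.arg(interpretation)
  if (any(log(kappa^2) <= 1))
    stop("storage capacity undefined: ln(kappa^2) must exceed 1")
  log(log(kappa^2)) / (2 * log(2))
}

.default_tau_m <- c(GrC = 1.4, PC = 64)  # ms

#' Storage capacity as a function of the mean output rate
#'
#' Evaluates the capacity-versus-rate transform: the capacity per active
#' input per pattern duration, `alpha_c(kappa) / (r_out * tau)`, which is
#' non-increasing in the rate-time product `r_out * tau`. The two cell types
#' live in disjoint regimes: granule cells require `r_out * tau <= 0.1`,
#' Purkinje cells `r_out * tau >= 1`.
#'
#' @param r_out mean output firing rate (Hz); may be a vector.
#' @param tau membrane time constant in seconds; defaults to the cell type's
#'   value (1.4 ms for GrC, 64 ms for PC).
#' @param cell_type `"GrC"` or `"PC"` (sets the regime check and default tau).
#' @param T input pattern duration (ms) used for the stability constant
#'   (default 300, the simulation window).
#' @param interpretation formula parse identifiers, recorded in the output.
#' @return a data frame with columns `r_out`, `rate_time_product`,
#'   `capacity`, `cell_type`, and attribute `interpretation`.
#' @export
capacity_vs_rate <- function(r_out, tau = NULL, cell_type = c("GrC", "PC"),
                             T = 300,
                             interpretation = c(kappa = "T_over_sqrt",
                                                alpha = "lnln_over_2ln2")) {
  cell_type <- match.arg(cell_type)
  tau_m_ms <- .default_tau_m[[cell_type]]
  if (is.null(tau)) tau <- tau_m_ms / 1000
  rt <- r_out * tau
  if (cell_type == "GrC" && any(rt > 0.1))
    stop("granule-cell regime requires r_out * tau <= 0.1")
  if (cell_type == "PC" && any(rt < 1))
    stop("Purkinje-cell regime requires r_out * tau >= 1")
  kappa <- stability_constant(T, tau_s = tau_m_ms / 4, tau_m = tau_m_ms,
                              interpretation = interpretation[["kappa"]])
  alpha <- storage_capacity(kappa, interpretation = interpretation[["alpha"]])
  out <- data.frame(r_out = r_out, rate_time_product = rt,
                    capacity = alpha / rt, cell_type = cell_type)
  attr(out, "interpretation") <- interpretation
  attr(out, "kappa") <- kappa
  attr(out, "alpha_c") <- alpha
  out
}

#' Write a sparseness report to CSV
#'
#' @param si numeric vector of per-neuron sparseness indices.
#' @param path output CSV path (columns `neuron_id`, `SI`).
#' @return the path, invisibly.
#' @export
write_sparseness_csv <- function(si, path) {
  utils::write.csv(data.frame(neuron_id = seq_along(si), SI = si),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a capacity curve to JSON
#'
#' The JSON document carries the formula-interpretation identifiers along
#' with the curve so every reported number is traceable to the parse that
#' produced it.
#'
#' @param curve a [capacity_vs_rate()] result.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_capacity_json <- function(curve, path) {
  jsonlite::write_json(list(interpretation = as.list(attr(curve, "interpretation")),
                            kappa = attr(curve, "kappa"),
                            alpha_c = attr(curve, "alpha_c"),
                            curve = curve),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
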