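#' Spiking-model parameter set
#'
#' Construct and validate the parameter set of the modified
#' integrate-and-fire oxytocin neuron. The membrane potential follows
#' `V = V_rest + V_syn - HAP - AHP + DAP`, where `V_syn` is the summed
#' synaptic perturbation and each afterpotential is a single variable
#' incremented at spike time by its `k` and decaying exponentially with
#' half-life `lambda` (ms). Defaults are the consensus ("typical oxytocin
#' cell") values; see [consensus_neuron_params()].
#'
#' @param I_re excitatory PSP arrival rate (Hz).
#' @param I_ratio inhibitory-to-excitatory arrival-rate ratio.
#' @param e_h EPSP amplitude (mV), positive.
#' @param i_h IPSP amplitude (mV), negative.
#' @param lambda_syn PSP half-life (ms).
#' @param k_HAP,lambda_HAP hyperpolarising afterpotential increment (mV) and
#'   half-life (ms).
#' @param k_DAP,lambda_DAP fast depolarising afterpotential increment (mV)
#'   and half-life (ms).
#' @param k_AHP,lambda_AHP medium afterhyperpolarisation increment (mV) and
#'   half-life (ms).
#' @param V_rest resting potential (mV).
#' @param V_thresh spike threshold (mV); must exceed `V_rest`.
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params()        # consensus cell
#' p$I_re
#' @export
neuron_params <- function(I_re = 370, I_ratio = 0.5, e_h = 2, i_h = -2,
                          lambda_syn = 7.5,
                          k_HAP = 50, lambda_HAP = 8,
                          k_DAP = 3, lambda_DAP = 50,
                          k_AHP = 0.5, lambda_AHP = 600,
                          V_rest = -62, V_thresh = -50) {
  p <- list(I_re = I_re, I_ratio = I_ratio, e_h = e_h, i_h = i_h,
            lambda_syn = lambda_syn,
            k_HAP = k_HAP, lambda_HAP = lambda_HAP,
            k_DAP = k_DAP, lambda_DAP = lambda_DAP,
            k_AHP = k_AHP, lambda_AHP = lambda_AHP,
            V_rest = V_rest, V_thresh = V_thresh)
  class(p) <- "neuron_params"
  validate_neuron_params(p)
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Validate a neuron parameter set
#'
#' Checks the structural invariants of [neuron_params()]: positive
#' half-lives, non-negative afterpotential increments, EPSP amplitude
#' positive and IPSP amplitude negative, resting potential below threshold,
#' and non-negative input rates.
#'
#' @param p a `neuron_params` object or named list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_neuron_params <- function(p) {
  need <- names(formals(neuron_params))
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    stop("missing neuron parameter(s): ", paste(missing, collapse = ", "))
  }
  num <- vapply(p[need], function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("non-numeric neuron parameter(s): ", paste(need[!num], collapse = ", "))
  }
  if (p$I_re < 0) stop("I_re must be >= 0")
  if (p$I_ratio < 0) stop("I_ratio must be >= 0")
  for (nm in c("lambda_syn", "lambda_HAP", "lambda_DAP", "lambda_AHP")) {
    if (p[[nm]] <= 0) stop(nm, " (half-life) must be > 0")
  }
  for (nm in c("k_HAP", "k_DAP", "k_AHP")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (p$e_h <= 0) stop("e_h must be > 0")
  if (p$i_h >= 0) stop("i_h must be < 0")
  if (p$V_rest >= p$V_thresh) stop("V_rest must be below V_thresh")
  invisible(p)
}

#' Consensus ("typical oxytocin cell") parameters
#'
#' The fit-derived standard parameter set summarising the published per-cell
#' model fits: excitatory input at 370 Hz with half as many inhibitory
#' events, 2 mV PSPs with 7.5-ms half-life, a 50 mV / 8 ms HAP, a
#' 3 mV / 50 ms fast DAP, a 0.5 mV / 600 ms medium AHP, resting potential
#' -62 mV and threshold -50 mV.
#'
#' @return A `neuron_params` object.
#' @export
consensus_neuron_params <- function() neuron_params()

#' Spiking-model variants
#'
#' The four afterpotential configurations used when fitting cells:
#' HAP only, HAP + AHP, HAP + DAP, and HAP + AHP + DAP. Absent components
#' are forced to zero increment by [apply_variant()].
#'
#' @return Character vector of the four variant names.
#' @export
model_variants <- function() {
  c("HAP_only", "HAP_AHP", "HAP_DAP", "HAP_AHP_DAP")
}

#' Constrain a parameter set to a model variant
#'
#' Zeroes the afterpotential increments that the variant excludes
#' (`HAP_only` forces `k_DAP = k_AHP = 0`; `HAP_AHP` forces `k_DAP = 0`;
#' `HAP_DAP` forces `k_AHP = 0`).
#'
#' @param params a `neuron_params` object.
#' @param variant one of [model_variants()].
#' @return The constrained `neuron_params`.
#' @export
apply_variant <- function(params, variant) {
  variant <- match.arg(variant, model_variants())
  if (variant %in% c("HAP_only", "HAP_AHP")) params$k_DAP <- 0
  if (variant %in% c("HAP_only", "HAP_DAP")) params$k_AHP <- 0
  validate_neuron_params(params)
  params
}

#' Free parameters searched when fitting a variant
#'
#' The fitting procedure varies the synaptic input rate and the `k`/`lambda`
#' pair of each afterpotential present in the variant (at most seven
#' parameters for the full model).
#'
#' @param variant one of [model_variants()].
#' @return Character vector of parameter names.
#' @export
free_parameters <- function(variant) {
  variant <- match.arg(variant, model_variants())
  out <- c("I_re", "k_HAP", "lambda_HAP")
  if (variant %in% c("HAP_DAP", "HAP_AHP_DAP")) out <- c(out, "k_DAP", "lambda_DAP")
  if (variant %in% c("HAP_AHP", "HAP_AHP_DAP")) out <- c(out, "k_AHP", "lambda_AHP")
  out
}

#' Published per-cell best-fit parameters
#'
#' The 13 per-cell best fits of the spiking model to supraoptic oxytocin
#' neurons recorded during gavage experiments, as transcribed from the
#' published table (shipped as a CSV under `extdata`). `NA` marks an
#' afterpotential absent from a cell's best-fitting variant.
#'
#' @return A data.frame with columns `cell`, `I_re`, `k_HAP`, `lambda_HAP`,
#'   `k_DAP`, `lambda_DAP`, `k_AHP`, `lambda_AHP`.
#' @export
oxytocin_fits <- function() {
  path <- system.file("extdata", "oxytocin_fits.csv", package = "oxysim",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write flat `key = value` parameter configuration files
#'
#' Parameter sets are serialised as plain-text files with one `name = value`
#' pair per line and `#` comments, using the field names of
#' [neuron_params()].
#'
#' @param path file path.
#' @return `read_params_config()` returns a `neuron_params` object.
#' @export
read_params_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  names(vals) <- trimws(vapply(kv, `[`, character(1), 1))
  do.call(neuron_params, as.list(vals))
}

#' @param params a `neuron_params` object.
#' @rdname read_params_config
#' @export
write_params_config <- function(params, path) {
  validate_neuron_params(params)
  lines <- sprintf("%s = %.15g", names(unclass(params)),
                   unlist(unclass(params)))
  writeLines(lines, path)
  invisible(path)
}
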