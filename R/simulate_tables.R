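#' The 10-point confirmation dose ladder
#'
#' Zero-dose (DMSO) control followed by nine log-spaced concentrations from
#' 1 pM to 100 uM (decade steps), in molar.
#'
#' @return Numeric vector of length 10.
#' @export
dose_ladder <- function() c(0, 10^seq(-12, -4))

#' Simulate a viability dose-response table
#'
#' Evaluates one population's four-parameter-logistic kill curve on a dose
#' ladder and adds Gaussian noise, producing the CSV-ready table consumed by
#' [fit_dose_response()].
#'
#' @param drug_model A [drug_effect_model()].
#' @param population Population name within the model's effects.
#' @param doses Strictly increasing dose vector whose first entry is the
#'   zero-dose control; needs >= 4 distinct nonzero doses.
#' @param replicates Number of replicates per dose.
#' @param noise_sd Gaussian noise SD in viability percentage points
#'   (0 gives exact curve values).
#' @param seed Integer seed.
#' @return Data.frame `compound, dose_M, replicate, viability_pct`.
#' @export
simulate_dose_response_table <- function(drug_model, population,
                                         doses = dose_ladder(),
                                         replicates = 3, noise_sd = 0,
                                         seed = 1L) {
  if (doses[1] != 0)
    stop("first dose must be the zero-dose control", call. = FALSE)
  if (any(diff(doses) <= 0))
    stop("doses must be strictly increasing", call. = FALSE)
  if (length(unique(doses[doses > 0])) < 4)
    stop("need >= 4 distinct nonzero doses (fit impossible downstream)",
         call. = FALSE)
  e <- drug_model$effects[[population]]
  if (is.null(e))
    stop(sprintf("no effect model for population '%s'", population),
         call. = FALSE)
  set.seed(seed)
  tab <- expand.grid(dose_M = doses, replicate = seq_len(replicates))
  v <- viability_4pl(tab$dose_M, e$top, e$bottom, e$ic50, e$hill)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  data.frame(compound = drug_model$compound_id, dose_M = tab$dose_M,
             replicate = tab$replicate, viability_pct = v,
             stringsAsFactors = FALSE)
}

#' Simulate a resazurin (570/600 nm) plate-reader signal
#'
#' Linear readout model: `signal = background + gain * viable_count` plus
#' optional Gaussian noise; strictly increasing in the viable count when
#' noise-free.
#'
#' @param viable_count Number of metabolically active cells (>= 0).
#' @param gain Signal per cell (> 0).
#' @param background Background signal.
#' @param noise_sd Gaussian noise SD (0 = deterministic).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Numeric signal(s).
#' @export
simulate_resazurin <- function(viable_count, gain, background,
                               noise_sd = 0, seed = 1L) {
  stopifnot_scalar_positive(gain, "gain")
  signal <- background + gain * viable_count
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + rnorm(length(signal), 0, noise_sd)
  }
  signal
}
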