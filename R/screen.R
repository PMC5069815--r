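#' Percent inhibition relative to negative controls
#'
#' `100 * (1 - count / mean(negative control counts))`, computed separately
#' per population. Not clipped below zero: growth stimulation reports as
#' negative inhibition.
#'
#' @param count Cell count(s) in the treated well(s).
#' @param negative_control_counts Counts from >= 3 QC-passing
#'   negative-control wells.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(count, negative_control_counts) {
  if (length(negative_control_counts) < 3)
    stop("need >= 3 negative-control wells", call. = FALSE)
  m <- mean(negative_control_counts)
  if (!is.finite(m) || m <= 0)
    stop("negative-control mean is zero or undefined", call. = FALSE)
  100 * (1 - count / m)
}

#' Z'-factor screening window
#'
#' \eqn{Z' = 1 - 3(\sigma_p + \sigma_n) / |\mu_p - \mu_n|} from positive- and
#' negative-control readouts; at most 1 by construction, and the screen's
#' readout here is the per-well HCC cell count.
#'
#' @param positive_values,negative_values Control readouts (>= 2 each).
#' @return Z' (dimensionless).
#' @export
compute_zprime <- function(positive_values, negative_values) {
  if (length(positive_values) < 2 || length(negative_values) < 2)
    stop("need >= 2 values per control arm", call. = FALSE)
  mu_p <- mean(positive_values); mu_n <- mean(negative_values)
  if (mu_p == mu_n) stop("no assay window", call. = FALSE)
  1 - 3 * (sd(positive_values) + sd(negative_values)) / abs(mu_p - mu_n)
}

#' Call selective hits with the dual-threshold rule
#'
#' Replicate wells are combined by arithmetic mean inhibition per compound;
#' a compound is a hit iff mean HCC inhibition strictly exceeds
#' `huh7_min_inhib` AND mean hepatocyte inhibition is strictly below
#' `fa2n4_max_inhib`. Replicates disagreeing by more than
#' `disagreement_limit` percentage points are flagged.
#'
#' @param screen_table Per-well data.frame with columns `compound`,
#'   `hcc_inhib_pct`, `hep_inhib_pct`, `qc_pass` (only QC-passing wells are
#'   used).
#' @param huh7_min_inhib,fa2n4_max_inhib Hit thresholds in percent (defaults
#'   50 and 20).
#' @param disagreement_limit Replicate-range flag threshold (percentage
#'   points).
#' @return Data.frame per compound: mean inhibitions, well count, replicate
#'   disagreement flag, `hit`. Compounds with zero QC-passing wells are
#'   excluded and listed in the `excluded` attribute.
#' @export
call_hits <- function(screen_table, huh7_min_inhib = 50,
                      fa2n4_max_inhib = 20, disagreement_limit = 30) {
  tab <- screen_table[screen_table$qc_pass, , drop = FALSE]
  all_compounds <- unique(screen_table$compound)
  excluded <- setdiff(all_compounds, unique(tab$compound))
  if (nrow(tab) == 0) {
    out <- data.frame(compound = character(0), hcc_inhib_pct = numeric(0),
                      hep_inhib_pct = numeric(0), n_wells = integer(0),
                      replicate_disagreement = logical(0), hit = logical(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  agg <- do.call(rbind, lapply(split(tab, tab$compound), function(d)
    data.frame(compound = d$compound[1],
               hcc_inhib_pct = mean(d$hcc_inhib_pct),
               hep_inhib_pct = mean(d$hep_inhib_pct),
               n_wells = nrow(d),
               replicate_disagreement =
                 diff(range(d$hcc_inhib_pct)) > disagreement_limit,
               stringsAsFactors = FALSE)))
  agg$hit <- agg$hcc_inhib_pct > huh7_min_inhib &
             agg$hep_inhib_pct < fa2n4_max_inhib
  agg <- agg[order(agg$compound), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "excluded") <- excluded
  agg
}

#' Run the image-based pilot screen end to end
#'
#' For every non-empty well: segment nuclei field by field, measure marker
#' intensities, then (after deriving classification thresholds from the
#' pooled negative-control wells) classify cells, apply the cell-count QC,
#' compute the plate Z'-factor on HCC counts of positive vs negative
#' controls, gate the plate, compute per-population percent inhibition
#' against the negative-control means, and call hits with the dual
#' threshold rule.
#'
#' @param layout Plate-layout data.frame (see [plate_layout_384()]).
#' @param image_provider Function taking one layout row and returning a list
#'   with `fields` (per-field named channel-image lists); e.g.
#'   [simulated_image_provider()] or [tiff_image_provider()].
#' @param min_cells QC minimum cells per well (strict; default 100).
#' @param zprime_gate Minimum acceptable plate Z' (default 0.5). Below the
#'   gate the screen is aborted: no hits are called, but the result and
#'   report are still produced.
#' @param huh7_min_inhib,fa2n4_max_inhib Hit thresholds (percent).
#' @param thresholds Optional `class_thresholds`; when `NULL` they are
#'   derived from the negative-control wells.
#' @param seg_params See [default_seg_params()].
#' @param fallback_cutoffs Fixed cutoffs used if control distributions are
#'   unimodal.
#' @param out_dir Optional directory; when given, `screen_wells.csv`,
#'   `screen_compounds.csv` and `plate_report.txt` are written there.
#' @param verbose Print progress per well.
#' @return Object of class `screen_result`: `wells` (per-well table),
#'   `compounds` (per-compound table with hit flags), `zprime`, `aborted`,
#'   `thresholds`, `qc_excluded`, `report` (character lines).
#' @export
run_pilot_screen <- function(layout, image_provider, min_cells = 100,
                             zprime_gate = 0.5, huh7_min_inhib = 50,
                             fa2n4_max_inhib = 20, thresholds = NULL,
                             seg_params = default_seg_params(),
                             fallback_cutoffs = NULL, out_dir = NULL,
                             verbose = FALSE) {
  if (!any(layout$role == "positive_control"))
    stop("no assay window: plate has no positive-control wells",
         call. = FALSE)
  validate_layout(layout)
  wells <- layout[layout$role != "empty", , drop = FALSE]
  feats <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    entry <- wells[i, ]
    sim <- image_provider(entry)
    wf <- NULL
    for (f in seq_along(sim$fields)) {
      chans <- sim$fields[[f]]
      lab <- detect_nuclei(chans$hoechst, seg_params)
      m <- measure_markers(lab, chans[setdiff(names(chans), "hoechst")])
      if (nrow(m) > 0) {
        m$field <- f
        wf <- rbind(wf, m)
      }
    }
    feats[[i]] <- wf
    if (verbose)
      message(sprintf("well %s (%s): %d cells", entry$well, entry$role,
                      if (is.null(wf)) 0L else nrow(wf)))
  }
  neg_idx <- which(wells$role == "negative_control")
  if (is.null(thresholds)) {
    pooled <- do.call(rbind, feats[neg_idx])
    thresholds <- derive_thresholds_from_controls(
      pooled, fixed = fallback_cutoffs)
  }
  well_rows <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    wf <- feats[[i]]
    if (is.null(wf))
      wf <- measure_markers(matrix(0L, 2, 2),
                            list(chalv1 = matrix(0, 2, 2),
                                 afp = matrix(0, 2, 2)))
    cl <- classify_cells(wf, thresholds)
    qc <- qc_well(cl$features, min_cells)
    well_rows[[i]] <- data.frame(
      plate = wells$plate[i], well = wells$well[i], role = wells$role[i],
      compound = wells$compound[i], dose_M = wells$dose_M[i],
      replicate = wells$replicate[i], n_cells = qc$n_cells,
      hcc_count = unname(cl$counts["HCC"]),
      hep_count = unname(cl$counts["HEPATOCYTE"]),
      ambiguous_count = unname(cl$counts["AMBIGUOUS"]),
      qc_pass = qc$pass, qc_reason = qc$reason,
      stringsAsFactors = FALSE)
  }
  wtab <- do.call(rbind, well_rows)
  qc_excluded <- wtab$well[!wtab$qc_pass]

  neg <- wtab[wtab$role == "negative_control" & wtab$qc_pass, ]
  pos <- wtab[wtab$role == "positive_control" & wtab$qc_pass, ]
  zp <- compute_zprime(pos$hcc_count, neg$hcc_count)
  aborted <- zp < zprime_gate

  wtab$hcc_inhib_pct <- percent_inhibition(wtab$hcc_count, neg$hcc_count)
  wtab$hep_inhib_pct <- percent_inhibition(wtab$hep_count, neg$hep_count)

  compounds <- NULL
  if (!aborted) {
    test <- wtab[wtab$role == "test", , drop = FALSE]
    compounds <- call_hits(test, huh7_min_inhib, fa2n4_max_inhib)
  }
  report <- c(
    sprintf("Plate %s pilot screen", wtab$plate[1]),
    sprintf("Wells analysed: %d (QC-excluded: %d)", nrow(wtab),
            length(qc_excluded)),
    if (length(qc_excluded))
      sprintf("QC-excluded wells: %s", paste(qc_excluded, collapse = ", ")),
    sprintf("Classification cutoffs: %s",
            paste(sprintf("%s=%.1f (%s)", names(thresholds$cutoffs),
                          thresholds$cutoffs, thresholds$method),
                  collapse = ", ")),
    sprintf("Z' (HCC count, %d pos / %d neg controls): %.3f",
            nrow(pos), nrow(neg), zp),
    if (aborted)
      sprintf("SCREEN ABORTED: Z' %.3f below gate %.2f", zp, zprime_gate)
    else
      sprintf("Hits (>%g%% HCC and <%g%% hepatocyte inhibition): %s",
              huh7_min_inhib, fa2n4_max_inhib,
              if (sum(compounds$hit)) paste(compounds$compound[compounds$hit],
                                            collapse = ", ") else "none"))
  res <- structure(list(wells = wtab, compounds = compounds, zprime = zp,
                        aborted = aborted, thresholds = thresholds,
                        qc_excluded = qc_excluded, report = report),
                   class = "screen_result")
  if (!is.null(out_dir)) write_screen_result(res, out_dir)
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
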