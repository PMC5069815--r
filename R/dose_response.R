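#' Fit a four-parameter logistic dose-response curve
#'
#' Constrained least-squares fit of
#' \eqn{V(c) = bottom + (top - bottom)/(1 + (c/\mathrm{IC50})^h)} on the
#' log10-dose axis. The zero-dose control anchors the top plateau and is
#' represented three decades below the lowest nonzero dose (the log axis has
#' no zero). Initialisation takes top/bottom from the response extremes and
#' the IC50 start from the dose bracketing 50 % of the response range;
#' five multistarts jitter the log10 IC50 start by up to one decade each
#' way, the best residual sum of squares wins and ties go to the lower Hill
#' slope. Bounds: `0 <= bottom <= top <= 120` (slight stimulation allowed),
#' `hill` in (0, 10].
#'
#' @param doses Dose vector in molar (>= 5 distinct values including a
#'   zero-dose control; negative doses are an error).
#' @param responses Viability percentages, same length.
#' @param fix_hill Optional fixed Hill slope (e.g. 1); `NULL` fits it.
#' @param anchor_decades How many decades below the lowest nonzero dose the
#'   zero-dose control sits on the log axis (default 3; fitted IC50s are
#'   insensitive to this choice well below 0.5 %).
#' @return Object of class `dose_response_fit` with `top`, `bottom`, `ic50`
#'   (molar), `hill`, per-parameter standard errors, `rss`, `converged`,
#'   `extrapolated`, `n_points`.
#' @export
fit_dose_response <- function(doses, responses, fix_hill = NULL,
                              anchor_decades = 3) {
  if (any(doses < 0)) stop("negative doses are not allowed", call. = FALSE)
  if (length(doses) != length(responses))
    stop("doses and responses must match", call. = FALSE)
  if (length(unique(doses)) < 5 || !any(doses == 0))
    stop("need >= 5 distinct doses including a zero-dose control",
         call. = FALSE)
  nz <- doses[doses > 0]
  x0 <- log10(min(nz)) - anchor_decades  # zero-dose anchor on the log axis
  x <- ifelse(doses == 0, x0, log10(doses))
  y <- responses
  fit0 <- list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
               hill = NA_real_, se = c(top = NA, bottom = NA,
                                       log10_ic50 = NA, hill = NA),
               rss = NA_real_, converged = FALSE, extrapolated = NA,
               n_points = length(doses))
  if (diff(range(y)) < 10) {
    # monotone-flat data: no measurable signal, refuse an IC50
    return(structure(fit0, class = "dose_response_fit"))
  }
  top0 <- min(max(y), 120); bot0 <- max(min(y), 0)
  half <- (top0 + bot0) / 2
  ord <- order(x)
  below <- which(y[ord] <= half)
  lx0 <- if (length(below)) x[ord][below[1]] else median(x)
  starts <- lx0 + c(0, -1, -0.5, 0.5, 1)
  best <- NULL
  for (s in starts) {
    f <- tryCatch({
      if (is.null(fix_hill)) {
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^(hill * (x - lic))),
          start = list(top = top0, bottom = bot0, lic = s, hill = 1),
          lower = c(top = 0, bottom = 0, lic = x0 - 3, hill = 1e-3),
          upper = c(top = 120, bottom = 120, lic = log10(max(nz)) + 3,
                    hill = 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        hill_fixed <- fix_hill
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) /
            (1 + 10^(hill_fixed * (x - lic))),
          start = list(top = top0, bottom = bot0, lic = s),
          lower = c(top = 0, bottom = 0, lic = x0 - 3),
          upper = c(top = 120, bottom = 120, lic = log10(max(nz)) + 3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(residuals(f)^2)
    h <- if (is.null(fix_hill)) coef(f)[["hill"]] else fix_hill
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && h < best$hill)) {
      best <- list(fit = f, rss = rss, hill = h)
    }
  }
  if (is.null(best)) return(structure(fit0, class = "dose_response_fit"))
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  top <- cf[["top"]]; bottom <- cf[["bottom"]]
  if (bottom > top) { tmp <- top; top <- bottom; bottom <- tmp }
  ic50 <- 10^cf[["lic"]]
  extrap <- ic50 < min(nz) / 100 || ic50 > max(nz) * 100
  structure(list(
    top = top, bottom = bottom, ic50 = ic50, hill = best$hill,
    se = c(top = unname(se["top"]), bottom = unname(se["bottom"]),
           log10_ic50 = unname(se["lic"]),
           hill = if (is.null(fix_hill)) unname(se["hill"]) else 0),
    rss = best$rss, converged = TRUE, extrapolated = extrap,
    n_points = length(doses)), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: not converged (no measurable response range)\n")
  } else {
    cat(sprintf(
      "4PL fit: top %.2f, bottom %.2f, IC50 %.4g M, hill %.3f (RSS %.3g)%s\n",
      x$top, x$bottom, x$ic50, x$hill, x$rss,
      if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  }
  invisible(x)
}

#' IC50 enhancement ratio (selectivity)
#'
#' `ic50er = IC50(reference, hepatocyte) / IC50(target, HCC)`; values above 1
#' mean HCC-selective toxicity. Unitless, so invariant to a common rescaling
#' of concentrations.
#'
#' @param fit_ref Converged fit for the reference (hepatocyte) population.
#' @param fit_target Converged fit for the target (HCC) population.
#' @param compound_id Optional compound label.
#' @return List of class `selectivity_result` with `ic50_ref`, `ic50_target`
#'   (molar) and `ic50er`.
#' @export
compute_ic50er <- function(fit_ref, fit_target, compound_id = NA_character_) {
  if (!isTRUE(fit_ref$converged) || !isTRUE(fit_target$converged))
    stop("both fits must be converged to form an IC50 ratio", call. = FALSE)
  structure(list(compound_id = compound_id, ic50_ref = fit_ref$ic50,
                 ic50_target = fit_target$ic50,
                 ic50er = fit_ref$ic50 / fit_target$ic50),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("IC50ER %s: %.4g / %.4g M = %.6f\n",
              if (is.na(x$compound_id)) "" else x$compound_id,
              x$ic50_ref, x$ic50_target, x$ic50er))
  invisible(x)
}

#' Compare dose-response fits between two conditions
#'
#' Fits each replicate's viability table separately per condition, reports
#' the IC50 fold-shift (condition B over A, from mean log10 IC50s) and a
#' two-sample Student's t-test on the per-replicate log10 IC50s
#' (significance at p < 0.05). With fewer than 3 replicates in either arm
#' the t-test is skipped and only the fold-shift is reported.
#'
#' @param table_a,table_b Viability tables (`dose_M`, `replicate`,
#'   `viability_pct`) for the two conditions.
#' @param fix_hill Optional fixed Hill slope passed to the fits.
#' @return List of class `fit_comparison`: per-replicate IC50s, fold shift,
#'   `p_value` (NA when skipped), `significant`.
#' @export
compare_fits <- function(table_a, table_b, fix_hill = NULL) {
  rep_ic50 <- function(tab, label) {
    sapply(split(tab, tab$replicate), function(d) {
      f <- fit_dose_response(d$dose_M, d$viability_pct, fix_hill = fix_hill)
      if (!f$converged)
        stop(sprintf("replicate fit failed to converge (%s)", label),
             call. = FALSE)
      f$ic50
    })
  }
  ic_a <- rep_ic50(table_a, "condition A")
  ic_b <- rep_ic50(table_b, "condition B")
  fold <- 10^(mean(log10(ic_b)) - mean(log10(ic_a)))
  p <- NA_real_
  if (length(ic_a) >= 3 && length(ic_b) >= 3) {
    ta <- log10(ic_a); tb <- log10(ic_b)
    p <- if (sd(ta) == 0 && sd(tb) == 0 && mean(ta) == mean(tb)) 1
         else t.test(ta, tb)$p.value
  }
  structure(list(ic50_a = ic_a, ic50_b = ic_b, fold_shift = fold,
                 p_value = p,
                 significant = is.finite(p) && p < 0.05),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("IC50 fold-shift (B/A): %.3f; t-test p = %s%s\n",
              x$fold_shift,
              if (is.na(x$p_value)) "skipped (<3 replicates)"
              else format(x$p_value, digits = 3),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
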