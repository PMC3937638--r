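# One-site isothermal titration calorimetry: forward simulation of
# per-injection heats with volume-displacement bookkeeping, nonlinear
# least-squares fitting of (N, Kb, dH), and the derived thermodynamic
# quantities dG = -RT ln Kb, TdS = dH - dG and percent-of-reference
# affinity.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.9872e-3

#' ITC protocol description
#'
#' @param cell_volume_ml calorimeter cell volume in ml (VP-ITC nominal
#'   1.4 ml).
#' @param injection_volumes_ul per-injection volumes in microliters
#'   (default 26 x 5 ul).
#' @param cell_conc_mM macromolecule (protein) concentration in the cell,
#'   mM.
#' @param syringe_conc_mM ligand concentration in the syringe, mM.
#' @param temperature_K temperature in Kelvin.
#' @return an object of class \code{itc_protocol}.
#' @export
itc_protocol <- function(cell_volume_ml = 1.4,
                         injection_volumes_ul = rep(5, 26),
                         cell_conc_mM = 0.015,
                         syringe_conc_mM = 0.24,
                         temperature_K = 298.15) {
  stopifnot(cell_volume_ml > 0, all(injection_volumes_ul > 0),
            cell_conc_mM > 0, syringe_conc_mM > 0, temperature_K > 0)
  structure(list(cell_volume_ml = cell_volume_ml,
                 injection_volumes_ul = injection_volumes_ul,
                 cell_conc_mM = cell_conc_mM,
                 syringe_conc_mM = syringe_conc_mM,
                 temperature_K = temperature_K),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat("<itc_protocol> ", length(x$injection_volumes_ul), " x ",
      x$injection_volumes_ul[1], " ul into ", x$cell_volume_ml, " ml; ",
      "cell ", x$cell_conc_mM, " mM, syringe ", x$syringe_conc_mM,
      " mM, ", x$temperature_K, " K\n", sep = "")
  invisible(x)
}

#' One-site binding parameters
#'
#' @param N stoichiometry (sites per macromolecule).
#' @param Kb association constant in 1/M (must be positive).
#' @param dH binding enthalpy in kcal/mol.
#' @param se optional named vector of standard errors.
#' @return an object of class \code{binding_params}.
#' @export
binding_params <- function(N, Kb, dH, se = NULL) {
  stopifnot(Kb > 0)
  structure(list(N = N, Kb = Kb, dH = dH, se = se),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> N = %.3f, Kb = %.4g 1/M, dH = %.3f kcal/mol\n",
              x$N, x$Kb, x$dH))
  if (!is.null(x$se))
    cat("  se:", paste(names(x$se), signif(x$se, 3), sep = "=",
                       collapse = "  "), "\n")
  invisible(x)
}

# total concentrations in the cell after cumulative injected volume dv
# (liters), under the standard perfusion-displacement bookkeeping
.cell_concentrations <- function(protocol) {
  v0 <- protocol$cell_volume_ml * 1e-3            # L
  dv <- cumsum(protocol$injection_volumes_ul) * 1e-6
  m0 <- protocol$cell_conc_mM * 1e-3              # mol/L
  x0 <- protocol$syringe_conc_mM * 1e-3
  list(v0 = v0, dv = dv,
       Mt = m0 * (1 - dv / (2 * v0)) / (1 + dv / (2 * v0)),
       Xt = x0 * (dv / v0) / (1 + dv / (2 * v0)))
}

# bound-ligand concentration from the one-site mass-action quadratic,
# written in the numerically stable root form
.bound_conc <- function(N, Kb, Mt, Xt) {
  b <- 1 + Xt / (N * Mt) + 1 / (N * Kb * Mt)
  c4 <- Xt / (N * Mt)
  theta <- 2 * c4 / (b + sqrt(pmax(b^2 - 4 * c4, 0)))
  N * Mt * theta
}

#' Simulate a one-site titration
#'
#' Per-injection heats (ucal) from the one-site binding isotherm, including
#' the displaced-volume correction: each injection pushes cell contents
#' into the overflow, diluting both species.
#'
#' @param params a \code{\link{binding_params}}.
#' @param protocol an \code{\link{itc_protocol}}.
#' @param noise_sd Gaussian noise standard deviation in ucal (0 = exact).
#' @param seed RNG seed used when \code{noise_sd > 0}.
#' @return an object of class \code{itc_series}: numeric vector of heats in
#'   ucal with the protocol attached as an attribute.
#' @export
simulate_titration <- function(params, protocol, noise_sd = 0, seed = 1) {
  cc <- .cell_concentrations(protocol)
  bound <- .bound_conc(params$N, params$Kb, cc$Mt, cc$Xt)
  q <- bound * params$dH * 1000 * cc$v0 * 1e6      # ucal in cell
  qprev <- c(0, q[-length(q)])
  dvr <- protocol$injection_volumes_ul * 1e-6 / cc$v0
  heats <- q - qprev + dvr * (q + qprev) / 2
  if (noise_sd > 0) {
    set.seed(seed)
    heats <- heats + stats::rnorm(length(heats), 0, noise_sd)
  }
  itc_series(heats, protocol)
}

#' Construct an ITC series
#' @param heats per-injection heats in ucal.
#' @param protocol the matching \code{\link{itc_protocol}}.
#' @return an \code{itc_series}.
#' @export
itc_series <- function(heats, protocol) {
  if (length(heats) != length(protocol$injection_volumes_ul))
    stop("series length (", length(heats),
         ") does not match protocol injection count (",
         length(protocol$injection_volumes_ul), ")")
  structure(as.numeric(heats), protocol = protocol, class = "itc_series")
}

#' @export
print.itc_series <- function(x, ...) {
  cat("<itc_series> ", length(x), " injections; total heat ",
      sprintf("%.1f", sum(x)), " ucal\n", sep = "")
  invisible(x)
}

.model_heats <- function(N, Kb, dH, protocol) {
  as.numeric(simulate_titration(binding_params(N, Kb, dH), protocol))
}

#' Fit a one-site binding model to an ITC series
#'
#' Nonlinear least squares over (N, log Kb, dH) via Levenberg-Marquardt.
#' Starting heuristics: dH from the mean of the first three injection heats
#' per mole of injected ligand, N = 1, and Kb from a coarse grid of c-values
#' (c = N Kb Mt) refined by the optimizer.  When a blank (ligand-into-
#' buffer) series is supplied it is subtracted first.
#'
#' @param series an \code{\link{itc_series}}.
#' @param protocol protocol; defaults to the one attached to the series.
#' @param blank optional blank series to subtract.
#' @param drop_first discard the first injection (a common instrument
#'   practice for diffusion across the syringe tip); off by default.
#' @return a \code{\link{binding_params}} with standard errors and a
#'   \code{converged} field; on failure the result carries
#'   \code{converged = FALSE} and a \code{message} rather than erroring.
#' @export
fit_one_site <- function(series, protocol = attr(series, "protocol"),
                         blank = NULL, drop_first = FALSE) {
  heats <- as.numeric(series)
  if (!is.null(blank)) heats <- heats - as.numeric(blank)
  if (length(heats) < 5) stop("need at least 5 injections to fit")
  weights <- rep(1, length(heats))
  if (drop_first) weights[1] <- 0
  cc <- .cell_concentrations(protocol)
  inj_mol <- protocol$injection_volumes_ul * 1e-6 *
    protocol$syringe_conc_mM * 1e-3
  dh0 <- mean(heats[1:3] / (inj_mol[1:3] * 1e6)) / 1000   # kcal/mol
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  df <- data.frame(y = heats)
  best <- NULL
  for (c0 in c(1, 10, 100, 1000)) {
    k0 <- c0 / (protocol$cell_conc_mM * 1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .model_heats(N, exp(lKb), dH, protocol), data = df,
        start = list(N = 1, lKb = log(k0), dH = dh0), weights = weights,
        lower = c(0.05, log(1e1), -100), upper = c(5, log(1e12), 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out <- binding_params(NA_real_, 1, NA_real_)
    out$converged <- FALSE
    out$message <- "nonlinear least squares failed for all starting values"
    return(out)
  }
  est <- stats::coef(best$fit)
  sm <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kb <- exp(est[["lKb"]])
  se <- c(N = unname(sm[1]), Kb = unname(sm[2]) * kb, dH = unname(sm[3]))
  out <- binding_params(est[["N"]], kb, est[["dH"]], se = se)
  out$converged <- best$fit$convInfo$isConv %||% TRUE
  out$rss <- best$rss
  # degenerate data: essentially no heat evolved
  if (abs(out$dH) < 1e-3 || max(abs(heats)) < 10 * stats::sd(heats) / sqrt(length(heats))) {
    out$flag <- "near-zero enthalpy; parameters unreliable"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derived thermodynamics of a one-site fit
#'
#' \code{dG = -R T ln Kb}, \code{TdS = dH - dG} (an arithmetic identity),
#' \code{Kd = 1/Kb}, and the affinity as a percentage of a reference
#' association constant.
#'
#' @param params a \code{\link{binding_params}}.
#' @param temperature_K temperature (default 298.15 K).
#' @param reference_Kb reference association constant in 1/M (defaults to
#'   \code{params$Kb}, giving 100 percent).
#' @return list of class \code{thermo_row}: \code{dG}, \code{dH},
#'   \code{TdS} (kcal/mol), \code{Kd} (M), \code{percent}.
#' @export
derive_thermo <- function(params, temperature_K = 298.15,
                          reference_Kb = params$Kb) {
  stopifnot(params$Kb > 0, reference_Kb > 0)
  dG <- -R_KCAL * temperature_K * log(params$Kb)
  structure(list(dG = dG, dH = params$dH, TdS = params$dH - dG,
                 Kd = 1 / params$Kb,
                 percent = 100 * params$Kb / reference_Kb),
            class = "thermo_row")
}

#' @export
print.thermo_row <- function(x, ...) {
  cat(sprintf("<thermo_row> dG %.2f  dH %.2f  TdS %.2f kcal/mol;  Kd %.3g M;  %s%% of reference\n",
              x$dG, x$dH, x$TdS, x$Kd, format_percent(x$percent)))
  invisible(x)
}

#' Format a percent-of-reference value at the printed table precision
#'
#' One decimal place below 100, integer at or above 100 (three significant
#' figures throughout).
#' @param x percent values.
#' @return character vector.
#' @export
format_percent <- function(x) {
  ifelse(x >= 100, sprintf("%.0f", signif(x, 3)), sprintf("%.1f", x))
}

#' Affinity/thermodynamics table relative to a reference oligomer
#'
#' @param panel named list of \code{\link{binding_params}} (names are
#'   oligomer labels).
#' @param reference_name name of the reference member (its Kb defines
#'   100 percent).
#' @param temperature_K temperature for the dG computation.
#' @return data frame with columns \code{oligomer}, \code{N}, \code{Kb_1e5}
#'   (Kb in units of 1e5 1/M), \code{dG}, \code{dH}, \code{TdS},
#'   \code{percent} (formatted at table precision) and
#'   \code{percent_value} (unrounded).
#' @export
build_affinity_table <- function(panel, reference_name,
                                 temperature_K = 298.15) {
  if (!reference_name %in% names(panel))
    stop("reference '", reference_name, "' not present in the panel")
  ref_kb <- panel[[reference_name]]$Kb
  rows <- lapply(names(panel), function(nm) {
    p <- panel[[nm]]
    th <- derive_thermo(p, temperature_K, ref_kb)
    data.frame(oligomer = nm, N = p$N, Kb_1e5 = p$Kb / 1e5,
               dG = th$dG, dH = th$dH, TdS = th$TdS,
               percent = format_percent(th$percent),
               percent_value = th$percent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published one-site parameters for the Link module oligosaccharide panel
#'
#' The reference panel of stoichiometries, association constants and
#' enthalpies for defined HA, chondroitin and hybrid oligosaccharides
#' binding the TSG-6 Link module, as shipped in
#' \code{inst/extdata/link_tsg6_itc_panel.tsv} (printed values; Kb in units
#' of 1e5 1/M).
#'
#' @return data frame with columns \code{oligomer}, \code{N},
#'   \code{Kb_1e5}, \code{dG}, \code{dH}, \code{TdS}, \code{percent}.
#' @export
itc_reference_panel <- function() {
  path <- system.file("extdata", "link_tsg6_itc_panel.tsv",
                      package = "hagroove", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
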