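#' @include AllClasses.R utils.R
NULL

#' Normalised percentage inhibition (NPI) plate normalisation
#'
#' Normalises each plate so that the mean of its positive-control wells is 0
#' and the mean of its negative-control wells is 1:
#' \deqn{v' = (v - \bar v_{pos}) / (\bar v_{neg} - \bar v_{pos}).}
#' Applied per plate; affine rescalings of a plate's raw values therefore
#' leave the normalised values unchanged.
#'
#' @param plate a \code{\linkS4class{PlateGrid}} of raw values.
#' @return the \code{PlateGrid} with normalised values and
#'   \code{isNormalized(x) == TRUE}.
#' @examples
#' sim <- simulatePlates(plateSimConfig(n_compounds = 10, seed = 1))
#' npi <- npiNormalize(sim$plates)
#' @export
npiNormalize <- function(plate) {
  stopifnot(is(plate, "PlateGrid"))
  w <- as.data.frame(plate@wells)
  bad <- w$role != "empty" & !is.finite(w$value)
  if (any(bad)) {
    warning(sum(bad), " non-finite well value(s) dropped before NPI")
    w <- w[!bad, , drop = FALSE]
  }
  for (p in unique(w$plate)) {
    sel <- w$plate == p
    mp <- mean(w$value[sel & w$role == "pos_ctrl"])
    mn <- mean(w$value[sel & w$role == "neg_ctrl"])
    if (!is.finite(mp) || !is.finite(mn))
      stop(sprintf("plate '%s' lacks a control role", p))
    if (mn == mp)
      stop(sprintf("degenerate plate '%s': control means coincide", p))
    w$value[sel] <- (w$value[sel] - mp) / (mn - mp)
  }
  PlateGrid(w, normalized = TRUE)
}

#' Differential viability between two treatment arms
#'
#' The vehicle-arm mean is subtracted from the treated-arm mean, producing
#' the differential survival value; the replicate values of both arms enter
#' a two-sided t-test. The default pools the arm variances (Student), the
#' form whose type-I error stays at the nominal level with screen-scale
#' replicate counts (three wells per arm); \code{var_equal = FALSE}
#' selects the unequal-variance Welch form, which is conservative at
#' those sizes. When both arms have zero variance the p-value is 1 if the
#' means agree and 0 otherwise (documented convention for degenerate
#' replicates).
#'
#' @param treated,vehicle numeric replicate vectors (>= 2 each).
#' @param var_equal pool the arm variances (default TRUE).
#' @return list with \code{differential} and \code{p.value}.
#' @examples
#' differentialViability(c(0.5, 0.6, 0.7), c(0.9, 1.0, 1.1))
#' @export
differentialViability <- function(treated, vehicle, var_equal = TRUE) {
  treated <- treated[is.finite(treated)]
  vehicle <- vehicle[is.finite(vehicle)]
  if (length(treated) < 2L || length(vehicle) < 2L)
    stop("need >=2 replicates per arm")
  list(differential = mean(treated) - mean(vehicle),
       p.value = .t_p(treated, vehicle, var_equal = var_equal))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, preserving input
#' order.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
adjustBH <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Score a plate screen: per-compound differential viability
#'
#' Aggregates an NPI-normalised \code{\linkS4class{PlateGrid}} into one row
#' per compound x concentration: mean normalised viability per arm, the
#' differential survival value (treated mean minus vehicle mean over the
#' replicate wells), a two-sided t-test over the replicate values
#' (pooled variance by default, see
#' \code{\link{differentialViability}}), and BH-adjusted p-values
#' (adjusted within each concentration).
#'
#' @param plates a \code{PlateGrid}; raw plates are NPI-normalised first.
#' @param treated_arm,vehicle_arm arm labels to compare.
#' @param var_equal pool the arm variances in the t-test (default TRUE;
#'   see \code{\link{differentialViability}}).
#' @return data.frame: \code{compound}, \code{concentration_uM},
#'   \code{mean_vehicle}, \code{mean_treated}, \code{differential},
#'   \code{p}, \code{padj}.
#' @examples
#' cfg <- plateSimConfig(n_compounds = 24, well_noise_sd = 20, seed = 5)
#' res <- scoreScreen(simulatePlates(cfg)$plates)
#' head(res)
#' @export
scoreScreen <- function(plates, treated_arm = "pretreat",
                        vehicle_arm = "vehicle", var_equal = TRUE) {
  stopifnot(is(plates, "PlateGrid"))
  if (!isNormalized(plates)) plates <- npiNormalize(plates)
  w <- as.data.frame(plateWells(plates))
  w <- w[w$role == "compound" & w$arm %in% c(treated_arm, vehicle_arm), ]
  if (!nrow(w)) stop("no compound wells for the requested arms")
  out <- list()
  for (conc in sort(unique(w$concentration_uM))) {
    wc <- w[w$concentration_uM == conc, ]
    for (cm in unique(wc$compound)) {
      tv <- wc$value[wc$compound == cm & wc$arm == treated_arm]
      vv <- wc$value[wc$compound == cm & wc$arm == vehicle_arm]
      if (length(tv) < 2L || length(vv) < 2L) next
      dv <- differentialViability(tv, vv, var_equal = var_equal)
      out[[length(out) + 1L]] <- data.frame(
        compound = cm, concentration_uM = conc,
        mean_vehicle = mean(vv), mean_treated = mean(tv),
        differential = dv$differential, p = dv$p.value)
    }
  }
  res <- do.call(rbind, out)
  res$padj <- ave(res$p, res$concentration_uM, FUN = adjustBH)
  rownames(res) <- NULL
  res
}

#' Classify screen hits into tolerant / sensitized / unchanged
#'
#' A compound is \emph{sensitized} when \code{padj < alpha} and its
#' differential survival is below \code{sensitize_cut} (default -0.3, the
#' published rule), \emph{tolerant} when \code{padj < alpha} and the
#' differential exceeds \code{tolerance_cut} (symmetric default +0.3),
#' and \emph{unchanged} otherwise.
#'
#' @param results data.frame from \code{\link{scoreScreen}}.
#' @param alpha adjusted-p significance cut (default 0.05).
#' @param sensitize_cut differential cut for sensitization (default -0.3).
#' @param tolerance_cut differential cut for tolerance (default +0.3).
#' @return \code{results} with an added \code{hit_class} column.
#' @export
classifyHits <- function(results, alpha = 0.05, sensitize_cut = -0.3,
                         tolerance_cut = 0.3) {
  stopifnot(all(c("padj", "differential") %in% colnames(results)))
  cls <- rep("unchanged", nrow(results))
  sig <- results$padj < alpha
  cls[sig & results$differential < sensitize_cut] <- "sensitized"
  cls[sig & results$differential > tolerance_cut] <- "tolerant"
  results$hit_class <- cls
  results
}

#' Select compounds for a follow-up screen
#'
#' Compounds whose mean normalised vehicle-arm viability at the stated
#' concentration is strictly below \code{cut} (default: viability < 0.7
#' at 5 micromolar, the rule used to pick the second-screen library).
#'
#' @param results data.frame from \code{\link{scoreScreen}} (needs
#'   \code{mean_vehicle}).
#' @param cut strict upper viability bound (default 0.7).
#' @param concentration concentration in micromolar (default 5).
#' @return character vector of compound ids.
#' @export
selectFollowup <- function(results, cut = 0.7, concentration = 5) {
  stopifnot(all(c("compound", "concentration_uM", "mean_vehicle") %in%
                  colnames(results)))
  sel <- results$concentration_uM == concentration &
    results$mean_vehicle < cut
  unique(results$compound[sel])
}
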