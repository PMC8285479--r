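#' @include AllClasses.R utils.R
NULL

#' Configuration for the 384-well plate simulator
#'
#' Describes a differential-viability screen: compounds arrayed over 16 x 24
#' plates with positive (kill) and negative (vehicle) controls alternating
#' down two dedicated control columns, screened in several treatment arms at
#' several concentrations with replicate plates.
#'
#' The raw readout model is
#' \deqn{\mathrm{raw} = \mathrm{baseline} \times v + \epsilon,}
#' where \eqn{v} is the compound's true fractional viability (plus an
#' additive arm-specific interaction shift in treated arms) and
#' \eqn{\epsilon \sim N(0, \mathrm{well\_noise\_sd}^2)}. Positive-control
#' wells are drawn around \code{kill_floor}, negative-control wells around
#' \code{baseline_viability}.
#'
#' @param n_compounds number of library compounds.
#' @param concentrations concentrations in micromolar (default 1 and 5).
#' @param arms treatment arms; the first is the vehicle arm, all others are
#'   treated arms receiving the interaction shift.
#' @param replicate_count replicate plates per arm x concentration.
#' @param control_columns the two columns that carry controls (default 2
#'   and 23); controls alternate positive/negative by row parity.
#' @param baseline_viability mean raw signal of negative-control wells.
#' @param kill_floor mean raw signal of positive-control wells; must be
#'   below \code{baseline_viability}.
#' @param well_noise_sd standard deviation of raw well noise.
#' @param compound_effect_dist function \code{n -> n} true fractional
#'   viabilities, one per compound.
#' @param interaction_set named numeric vector mapping compound id to an
#'   additive treated-arm viability shift (negative = sensitisation,
#'   positive = tolerance).
#' @param n_plates layout plates available per concentration; defaults to
#'   the minimum needed to host all compounds.
#' @param seed integer seed.
#' @return a \code{plateSimConfig} list.
#' @seealso \code{\link{simulatePlates}}
#' @export
plateSimConfig <- function(n_compounds = 352L,
                           concentrations = c(1, 5),
                           arms = c("vehicle", "pretreat"),
                           replicate_count = 3L,
                           control_columns = c(2L, 23L),
                           baseline_viability = 1000,
                           kill_floor = 50,
                           well_noise_sd = 10,
                           compound_effect_dist = function(n)
                             runif(n, 0.4, 1.1),
                           interaction_set = numeric(0),
                           n_plates = NULL,
                           seed = 1L) {
  n_compounds <- .check_count(n_compounds, "n_compounds", 1L)
  replicate_count <- .check_count(replicate_count, "replicate_count", 2L)
  if (length(control_columns) != 2L ||
      any(control_columns < 1L | control_columns > 24L))
    stop("control_columns must be two column indices in 1..24")
  if (kill_floor >= baseline_viability)
    stop("kill_floor must be below baseline_viability")
  if (length(arms) < 2L) stop("need a vehicle arm and >=1 treated arm")
  wells_per_plate <- 16L * (24L - 2L)
  need <- ceiling(n_compounds / wells_per_plate)
  if (is.null(n_plates)) n_plates <- need
  n_plates <- .check_count(n_plates, "n_plates", 1L)
  if (n_compounds > n_plates * wells_per_plate)
    stop(sprintf(paste0("capacity error: %d compounds do not fit on %d ",
                        "plate(s) of %d compound wells"),
                 n_compounds, n_plates, wells_per_plate))
  structure(list(n_compounds = n_compounds,
                 concentrations = concentrations, arms = arms,
                 replicate_count = replicate_count,
                 control_columns = as.integer(control_columns),
                 baseline_viability = baseline_viability,
                 kill_floor = kill_floor, well_noise_sd = well_noise_sd,
                 compound_effect_dist = compound_effect_dist,
                 interaction_set = interaction_set,
                 n_plates = n_plates, seed = as.integer(seed)),
            class = "plateSimConfig")
}

#' Simulate a differential-viability plate screen with known ground truth
#'
#' Generates raw 384-well plates for every arm, concentration and replicate
#' of a \code{\link{plateSimConfig}}, together with a sidecar ground-truth
#' table of each compound's true viability and interaction shift. The truth
#' table is never consumed by the analysis functions; it exists to validate
#' them.
#'
#' @param cfg a \code{\link{plateSimConfig}}.
#' @return a list with elements \code{plates} (a
#'   \code{\linkS4class{PlateGrid}} of raw values) and \code{truth}
#'   (data.frame: \code{compound}, \code{viability},
#'   \code{interaction_shift}).
#' @examples
#' sim <- simulatePlates(plateSimConfig(n_compounds = 20, seed = 7))
#' sim$plates
#' head(sim$truth)
#' @export
simulatePlates <- function(cfg) {
  stopifnot(inherits(cfg, "plateSimConfig"))
  .with_seed(cfg$seed, {
    compounds <- sprintf("cmpd_%04d", seq_len(cfg$n_compounds))
    viability <- cfg$compound_effect_dist(cfg$n_compounds)
    shift <- setNames(numeric(cfg$n_compounds), compounds)
    known <- intersect(names(cfg$interaction_set), compounds)
    shift[known] <- cfg$interaction_set[known]
    truth <- data.frame(compound = compounds, viability = viability,
                        interaction_shift = unname(shift))

    cmpd_cols <- setdiff(seq_len(24L), cfg$control_columns)
    layout_rows <- rep(seq_len(16L), times = length(cmpd_cols))
    layout_cols <- rep(cmpd_cols, each = 16L)
    wells_per_plate <- length(layout_rows)

    recs <- list()
    for (conc in cfg$concentrations) {
      for (p in seq_len(cfg$n_plates)) {
        idx <- ((p - 1L) * wells_per_plate + 1L):(p * wells_per_plate)
        idx <- idx[idx <= cfg$n_compounds]
        if (!length(idx)) next
        slot_ <- seq_along(idx)
        for (arm in cfg$arms) {
          treated <- arm != cfg$arms[1L]
          for (r in seq_len(cfg$replicate_count)) {
            plate_id <- sprintf("P%02d_%guM_%s_r%d", p, conc, arm, r)
            ctrl_rows <- rep(seq_len(16L), times = 2L)
            ctrl_cols <- rep(cfg$control_columns, each = 16L)
            ctrl_role <- ifelse(ctrl_rows %% 2L == 1L, "pos_ctrl",
                                "neg_ctrl")
            ctrl_mu <- ifelse(ctrl_role == "pos_ctrl", cfg$kill_floor,
                              cfg$baseline_viability)
            v_eff <- viability[idx] + if (treated) shift[idx] else 0
            v_eff <- pmax(v_eff, 0)
            cmpd_mu <- cfg$baseline_viability * v_eff
            n_all <- length(ctrl_mu) + length(cmpd_mu)
            noise <- rnorm(n_all, 0, cfg$well_noise_sd)
            recs[[length(recs) + 1L]] <- data.frame(
              plate = plate_id,
              row = c(ctrl_rows, layout_rows[slot_]),
              column = c(ctrl_cols, layout_cols[slot_]),
              role = c(ctrl_role, rep("compound", length(idx))),
              compound = c(rep(NA_character_, length(ctrl_mu)),
                           compounds[idx]),
              concentration_uM = conc,
              arm = arm, replicate = r,
              value = c(ctrl_mu, cmpd_mu) + noise)
          }
        }
      }
    }
    wells <- do.call(rbind, recs)
    list(plates = PlateGrid(wells, normalized = FALSE), truth = truth)
  })
}
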