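#' @include AllClasses.R utils.R
NULL

#' Valid-value filtering of an LFQ matrix
#'
#' Removes proteins with too few observed intensities. Mode
#' \code{"overall-fraction"} keeps rows with at least
#' \code{min_fraction} observed values over all samples (e.g. the 66\%
#' rule used for IP experiments); mode \code{"per-group-count"} keeps rows
#' with at least \code{min_count} observed values in every group
#' (\code{scope = "all"}, e.g. "two valid values out of three in both
#' conditions") or in at least one group (\code{scope = "any"}).
#' The filter never increases the row count and is idempotent.
#'
#' @param lfq an \code{\linkS4class{LFQMatrix}}.
#' @param mode \code{"overall-fraction"} or \code{"per-group-count"}.
#' @param min_fraction minimum observed fraction (default 0.66).
#' @param min_count minimum observed count per group (default 2).
#' @param scope for per-group mode: require the count in \code{"all"}
#'   groups (default) or \code{"any"} group.
#' @return the filtered \code{LFQMatrix} (a warning, not an error, if no
#'   row survives).
#' @export
filterValid <- function(lfq, mode = c("overall-fraction",
                                      "per-group-count"),
                        min_fraction = 0.66, min_count = 2L,
                        scope = c("all", "any")) {
  mode <- match.arg(mode); scope <- match.arg(scope)
  stopifnot(is(lfq, "LFQMatrix"))
  x <- lfq@intensities
  obs <- !is.na(x)
  keep <- if (mode == "overall-fraction") {
    rowMeans(obs) >= min_fraction
  } else {
    per_group <- vapply(levels(lfq@groups), function(g)
      rowSums(obs[, lfq@groups == g, drop = FALSE]), numeric(nrow(x)))
    per_group <- matrix(per_group, nrow = nrow(x))
    if (scope == "all") apply(per_group >= min_count, 1L, all)
    else apply(per_group >= min_count, 1L, any)
  }
  if (!any(keep)) warning("valid-value filter removed every protein")
  new("LFQMatrix", intensities = x[keep, , drop = FALSE],
      groups = lfq@groups,
      missing = lfq@missing[keep, , drop = FALSE])
}

#' Downshifted-normal imputation of missing LFQ intensities
#'
#' Replaces missing values per sample column by independent draws from a
#' normal distribution shifted below the column's observed intensity
#' distribution: with observed mean \eqn{\mu} and sd \eqn{\sigma},
#' imputed values follow
#' \deqn{N(\mu - \mathrm{downshift}\cdot\sigma,\;
#'       (\mathrm{width}\cdot\sigma)^2),}
#' with the standard width 0.3 and downshift 1.8. This mimics the
#' low-abundance origin of missing-not-at-random dropout. Deterministic
#' given \code{seed}; the pre-imputation missingness mask is preserved in
#' the returned object.
#'
#' @param lfq an \code{\linkS4class{LFQMatrix}}.
#' @param width imputation width in units of the column sd (default 0.3).
#' @param downshift downshift in units of the column sd (default 1.8).
#' @param seed integer seed (NULL uses the current RNG state).
#' @return the completed \code{LFQMatrix}.
#' @examples
#' sim <- simulateLFQ(n_proteins = 50, missing_rate = 0.4, seed = 9)
#' imp <- imputeDownshift(sim$lfq, seed = 1)
#' anyNA(intensityMatrix(imp))
#' @export
imputeDownshift <- function(lfq, width = 0.3, downshift = 1.8,
                            seed = NULL) {
  stopifnot(is(lfq, "LFQMatrix"))
  x <- lfq@intensities
  .with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (!any(miss)) next
      obs <- x[!miss, j]
      if (length(obs) < 3L)
        stop(sprintf("column %d has <3 observed values", j))
      sdo <- sd(obs)
      if (sdo == 0)
        stop(sprintf("imputation error: column %d has zero sd", j))
      x[miss, j] <- rnorm(sum(miss), mean(obs) - downshift * sdo,
                          width * sdo)
    }
    x
  }) -> x
  new("LFQMatrix", intensities = x, groups = lfq@groups,
      missing = lfq@missing)
}

#' Differential test over a two-group LFQ matrix
#'
#' Per-protein two-sided Welch t-test between the two groups with calls
#' \code{"up"}/\code{"down"} when \code{p <= p_cut} and the log2
#' difference passes \code{diff_cut} with matching sign (published
#' thresholds: P <= 0.05 and difference >= 1.5 | <= -1.5 on the log2
#' scale; the ratio-scale reading \code{scale = "ratio"} uses
#' \code{log2(diff_cut)} instead). Proteins fully observed in one group
#' and fully missing in the other (before imputation) bypass testing and
#' are flagged \code{"on"}/\code{"off"}; rows with fewer than two usable
#' values per group are skipped with a message.
#'
#' @param lfq an \code{\linkS4class{LFQMatrix}} (typically after
#'   \code{\link{filterValid}} and \code{\link{imputeDownshift}}).
#' @param p_cut p-value threshold (default 0.05).
#' @param diff_cut difference threshold (default 1.5).
#' @param scale \code{"log2diff"} (default: threshold on the log2
#'   difference itself) or \code{"ratio"} (threshold on the fold change,
#'   i.e. log2 difference >= log2(diff_cut)).
#' @return data.frame: \code{protein}, group means, \code{log2_diff}
#'   (group2 - group1), \code{p}, \code{neg_log10_p}, \code{call} in
#'   up/down/ns, \code{on_off} in on/off/"" .
#' @export
differentialTest <- function(lfq, p_cut = 0.05, diff_cut = 1.5,
                             scale = c("log2diff", "ratio")) {
  scale <- match.arg(scale)
  stopifnot(is(lfq, "LFQMatrix"))
  if (nlevels(lfq@groups) != 2L) stop("exactly two groups required")
  cut_val <- if (scale == "log2diff") diff_cut else log2(diff_cut)
  g <- lfq@groups; lev <- levels(g)
  x <- lfq@intensities; m <- lfq@missing
  skipped <- 0L
  rows <- lapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]; mi <- m[i, ]
    a <- xi[g == lev[1L]]; b <- xi[g == lev[2L]]
    obs_a <- !mi[g == lev[1L]]; obs_b <- !mi[g == lev[2L]]
    onoff <- ""
    if (all(obs_b) && !any(obs_a)) onoff <- "on"    # present only in grp2
    if (all(obs_a) && !any(obs_b)) onoff <- "off"   # lost in grp2
    if (onoff != "")
      return(data.frame(protein = rownames(x)[i],
                        mean_1 = mean(a, na.rm = TRUE),
                        mean_2 = mean(b, na.rm = TRUE),
                        log2_diff = mean(b, na.rm = TRUE) -
                          mean(a, na.rm = TRUE),
                        p = NA_real_, neg_log10_p = NA_real_,
                        call = "ns", on_off = onoff))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    d <- mean(b) - mean(a)
    p <- .welch_p(b, a)
    call <- "ns"
    if (p <= p_cut && d >= cut_val) call <- "up"
    if (p <= p_cut && d <= -cut_val) call <- "down"
    data.frame(protein = rownames(x)[i], mean_1 = mean(a),
               mean_2 = mean(b), log2_diff = d, p = p,
               neg_log10_p = -log10(p), call = call, on_off = "")
  })
  if (skipped)
    message(skipped, " protein(s) skipped: <2 usable values in a group")
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lev[1L])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lev[2L])
  rownames(out) <- NULL
  out
}

#' Call IP interactors by enrichment over a control pull-down
#'
#' Per protein, the log2 LFQ difference of IP over control (e.g. IgG) and
#' a two-sided Welch t-test; a protein is an interactor when the
#' difference is at least \code{enrich_cut} and \eqn{-\log_{10} p}
#' exceeds \code{logp_cut}. Presets reproduce the published rules:
#' \code{"GR"} = 2.5 LFQ enrichment with \eqn{-\log p > 2};
#' \code{"p57"} = 1.5 LFQ enrichment with \eqn{-\log p > 1.3}.
#'
#' @param ip,control protein x replicate matrices over the same proteins
#'   (log2 intensities), or a single \code{\linkS4class{LFQMatrix}} in
#'   \code{ip} whose two groups are (control, IP) in level order.
#' @param enrich_cut,logp_cut thresholds; both required unless a preset is
#'   given.
#' @param preset \code{"GR"}, \code{"p57"} or \code{NULL}.
#' @param igg_correct optional protein x replicate matrix of an IgG
#'   baseline subtracted protein-wise (per-protein IgG mean) from both
#'   matrices before testing; NULL disables.
#' @return data.frame: \code{protein}, \code{log2_enrichment}, \code{p},
#'   \code{neg_log10_p}, \code{interactor} (logical).
#' @examples
#' ip <- matrix(rnorm(30, 25), 10, 3,
#'              dimnames = list(sprintf("p%02d", 1:10), NULL))
#' ig <- matrix(rnorm(30, 22), 10, 3, dimnames = dimnames(ip))
#' head(enrichmentCall(ip, ig, preset = "GR"))
#' @export
enrichmentCall <- function(ip, control = NULL, enrich_cut = NULL,
                           logp_cut = NULL, preset = NULL,
                           igg_correct = NULL) {
  presets <- list(GR = c(2.5, 2), p57 = c(1.5, 1.3))
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    if (is.null(enrich_cut)) enrich_cut <- presets[[preset]][1L]
    if (is.null(logp_cut)) logp_cut <- presets[[preset]][2L]
  }
  if (is.null(enrich_cut) || is.null(logp_cut))
    stop("both enrich_cut and logp_cut are required (or use a preset)")
  if (is(ip, "LFQMatrix")) {
    g <- ip@groups
    if (nlevels(g) != 2L) stop("LFQMatrix input needs two groups")
    x <- ip@intensities
    control <- x[, g == levels(g)[1L], drop = FALSE]
    ip <- x[, g == levels(g)[2L], drop = FALSE]
  }
  if (is.null(control)) stop("missing control group")
  stopifnot(is.matrix(ip), is.matrix(control),
            nrow(ip) == nrow(control))
  if (is.null(rownames(ip)))
    rownames(ip) <- sprintf("protein_%d", seq_len(nrow(ip)))
  if (!is.null(igg_correct)) {
    stopifnot(nrow(igg_correct) == nrow(ip))
    base <- rowMeans(igg_correct, na.rm = TRUE)
    ip <- ip - base; control <- control - base
  }
  out <- lapply(seq_len(nrow(ip)), function(i) {
    a <- ip[i, ]; b <- control[i, ]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    d <- mean(a) - mean(b)
    p <- .welch_p(a, b)
    data.frame(protein = rownames(ip)[i], log2_enrichment = d, p = p,
               neg_log10_p = -log10(p),
               interactor = d >= enrich_cut && -log10(p) > logp_cut)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
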