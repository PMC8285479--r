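#' @include AllClasses.R utils.R
NULL

#' Configuration for the 4C contact-profile simulator
#'
#' Generates one viewpoint's normalised 4C contact profile over a grid of
#' monotone, non-overlapping restriction fragments in two conditions.
#' Fragments whose midpoint falls inside an effect region have their
#' condition-2 signal multiplied by the declared effect; elsewhere the two
#' conditions are exchangeable. Per-fragment noise is multiplicative
#' log-normal with log-sd \code{dispersion}.
#'
#' @param n_fragments number of fragments.
#' @param chrom chromosome name.
#' @param span_start 1-based start of the simulated span.
#' @param fragment_width_range min/max fragment width in bp.
#' @param gap_range min/max gap between fragments in bp.
#' @param effect_regions data.frame with columns \code{start}, \code{end}
#'   (1-based inclusive) and \code{effect} (multiplicative condition-2
#'   effect); must lie within the simulated span.
#' @param dispersion log-normal noise sd (0 = noise-free).
#' @param replicate_count replicates per condition.
#' @param conditions length-2 character vector of condition names.
#' @param seed integer seed.
#' @return a \code{fourcSimConfig} list.
#' @seealso \code{\link{simulateFourC}}
#' @export
fourcSimConfig <- function(n_fragments = 60L,
                           chrom = "chr11",
                           span_start = 2750000L,
                           fragment_width_range = c(800L, 3000L),
                           gap_range = c(50L, 400L),
                           effect_regions = NULL,
                           dispersion = 0.1,
                           replicate_count = 2L,
                           conditions = c("vehicle", "GC"),
                           seed = 1L) {
  n_fragments <- .check_count(n_fragments, "n_fragments", 5L)
  if (length(conditions) != 2L) stop("exactly two conditions required")
  structure(list(n_fragments = n_fragments, chrom = chrom,
                 span_start = as.integer(span_start),
                 fragment_width_range = fragment_width_range,
                 gap_range = gap_range, effect_regions = effect_regions,
                 dispersion = dispersion,
                 replicate_count = .check_count(replicate_count,
                                                "replicate_count", 1L),
                 conditions = conditions, seed = as.integer(seed)),
            class = "fourcSimConfig")
}

#' Simulate a two-condition 4C contact profile with known effect regions
#'
#' @param cfg a \code{\link{fourcSimConfig}}.
#' @return a list with elements \code{profile} (a
#'   \code{\linkS4class{FourCProfile}}) and \code{truth} (data.frame:
#'   fragment coordinates, baseline signal, true multiplicative effect).
#' @examples
#' eff <- data.frame(start = 2760000, end = 2790000, effect = 2)
#' sim <- simulateFourC(fourcSimConfig(effect_regions = eff, seed = 2))
#' sim$profile
#' @export
simulateFourC <- function(cfg) {
  stopifnot(inherits(cfg, "fourcSimConfig"))
  .with_seed(cfg$seed, {
    n <- cfg$n_fragments
    widths <- round(runif(n, cfg$fragment_width_range[1L],
                          cfg$fragment_width_range[2L]))
    gaps <- round(runif(n, cfg$gap_range[1L], cfg$gap_range[2L]))
    starts <- cfg$span_start + cumsum(c(0, widths[-n] + gaps[-n]))
    ends <- starts + widths - 1L
    if (any(starts[-1L] <= ends[-n]))
      stop("validation error: simulated fragments overlap")
    frags <- GRanges(cfg$chrom, IRanges(start = starts, end = ends))
    names(frags) <- sprintf("frag_%03d", seq_len(n))

    mids <- floor((starts + ends) / 2)
    effect <- rep(1, n)
    if (!is.null(cfg$effect_regions)) {
      er <- cfg$effect_regions
      span_end <- ends[n]
      if (any(er$start < cfg$span_start | er$end > span_end))
        stop("effect regions must lie within the simulated span")
      for (i in seq_len(nrow(er)))
        effect[mids >= er$start[i] & mids <= er$end[i]] <-
          effect[mids >= er$start[i] & mids <= er$end[i]] * er$effect[i]
    }

    baseline <- exp(rnorm(n, log(50), 0.6))
    k <- cfg$replicate_count
    noise <- function() if (cfg$dispersion > 0)
      exp(matrix(rnorm(n * k, 0, cfg$dispersion), n, k)) else
        matrix(1, n, k)
    sig1 <- baseline * noise()
    sig2 <- (baseline * effect) * noise()
    signal <- cbind(sig1, sig2)
    colnames(signal) <- c(sprintf("%s_r%d", cfg$conditions[1L], seq_len(k)),
                          sprintf("%s_r%d", cfg$conditions[2L], seq_len(k)))
    rownames(signal) <- names(frags)

    profile <- FourCProfile(viewpoint = "viewpoint",
                            fragments = frags, signal = signal,
                            condition = rep(cfg$conditions, each = k),
                            replicate = rep(seq_len(k), times = 2L))
    truth <- data.frame(fragment = names(frags), chrom = cfg$chrom,
                        start = starts, end = ends, baseline = baseline,
                        effect = effect)
    list(profile = profile, truth = truth)
  })
}
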