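#' @include AllClasses.R utils.R
NULL

#' Parse a printed genomic region string
#'
#' Parses \code{"chr11: 2773921-2812270"}-style strings (1-based inclusive
#' coordinates, as printed in methods sections) into a \code{GRanges}. The
#' inclusive span length is \code{end - start + 1}.
#'
#' @param x character vector of region strings, optionally named.
#' @return a \code{GRanges} with one range per string.
#' @examples
#' r <- parseRegion(c(a = "chr11: 2773921-2812270"))
#' GenomicRanges::width(r)  # 38350
#' @export
parseRegion <- function(x) {
  m <- regmatches(x, regexec("^\\s*([^: ]+)\\s*:\\s*([0-9,]+)\\s*-\\s*([0-9,]+)\\s*$",
                             x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed region string: ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  s <- as.numeric(gsub(",", "", vapply(m, `[`, "", 3L)))
  e <- as.numeric(gsub(",", "", vapply(m, `[`, "", 4L)))
  if (any(s > e))
    stop("malformed region (start > end): ",
         paste(x[s > e], collapse = ", "))
  gr <- GRanges(chrom, IRanges(start = s, end = e))
  names(gr) <- names(x)
  gr
}

#' Fragments of a 4C profile falling in a region
#'
#' Selects the fragments whose midpoint lies within the region
#' (inclusive): a fragment whose midpoint equals the region end is
#' included. Midpoint assignment keeps fragments straddling a region
#' boundary unambiguous.
#'
#' @param profile a \code{\linkS4class{FourCProfile}}.
#' @param region a length-1 \code{GRanges} (or a region string accepted by
#'   \code{\link{parseRegion}}).
#' @return integer indices of the selected fragments.
#' @export
fragmentsInRegion <- function(profile, region) {
  stopifnot(is(profile, "FourCProfile"))
  if (is.character(region)) region <- parseRegion(region)
  stopifnot(length(region) == 1L)
  fr <- fragmentRanges(profile)
  chr_ok <- as.character(GenomicRanges::seqnames(fr)) ==
    as.character(GenomicRanges::seqnames(region))
  if (!any(chr_ok))
    stop("region chromosome absent from profile")
  mids <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  idx <- which(chr_ok & mids >= GenomicRanges::start(region) &
                 mids <= GenomicRanges::end(region))
  if (!length(idx))
    stop("empty region: no fragment midpoint falls inside")
  idx
}

#' Compare 4C contact signal between conditions over a region
#'
#' For each fragment in the region, replicate signals are averaged per
#' condition and the per-fragment paired difference (condition 2 minus
#' condition 1) is formed. The differences enter a two-sided Wilcoxon
#' signed-rank test: exact enumeration with at most 20 non-zero untied
#' differences, otherwise the normal approximation with continuity
#' correction; zero differences are dropped. When every difference is
#' zero the result is p = 1 with zero effect. The test depends only on
#' signs and ranks of the differences, so a common multiplicative
#' rescaling of both conditions leaves the p-value unchanged.
#' \code{paired = FALSE} instead applies the unpaired rank-sum test to the
#' two sets of per-fragment condition means.
#'
#' @param profile a \code{\linkS4class{FourCProfile}}.
#' @param region a length-1 \code{GRanges} or region string; needs >= 5
#'   fragments inside.
#' @param paired logical; paired signed-rank (default) or unpaired
#'   rank-sum.
#' @return list with \code{region}, \code{n_fragments}, \code{median_diff}
#'   (median per-fragment difference) and \code{p.value}.
#' @examples
#' eff <- data.frame(start = 2760000, end = 2800000, effect = 2)
#' sim <- simulateFourC(fourcSimConfig(effect_regions = eff, seed = 1))
#' regionCompare(sim$profile, "chr11: 2760000-2800000")
#' @export
regionCompare <- function(profile, region, paired = TRUE) {
  stopifnot(is(profile, "FourCProfile"))
  if (is.character(region)) region <- parseRegion(region)
  idx <- fragmentsInRegion(profile, region)
  if (length(idx) < 5L)
    stop("need >=5 fragments in the region")
  cd <- signalInfo(profile)
  conds <- unique(cd$condition)
  sig <- contactSignal(profile)[idx, , drop = FALSE]
  m1 <- rowMeans(sig[, cd$condition == conds[1L], drop = FALSE])
  m2 <- rowMeans(sig[, cd$condition == conds[2L], drop = FALSE])
  d <- m2 - m1
  if (paired) {
    if (all(d == 0))
      return(list(region = as.character(region), n_fragments = length(idx),
                  median_diff = 0, p.value = 1))
    sr <- .signedrank(d)
    p <- sr$p.value
  } else {
    p <- .ranksum(m1, m2)$p.value
  }
  list(region = as.character(region), n_fragments = length(idx),
       median_diff = median(d), p.value = p)
}
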