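#' @include AllClasses.R utils.R
NULL

#' Simulate a label-free proteomics intensity matrix with MNAR missingness
#'
#' Generates a protein x sample matrix of log2 LFQ intensities in two
#' groups, with optional injected differential proteins and
#' missing-not-at-random dropout: the probability that an entry is missing
#' decreases with its intensity,
#' \deqn{P(\mathrm{miss} \mid x) = \min(1,\; 2r\,(1 - \Phi((x - m)/s))),}
#' with \eqn{m, s} the matrix mean and sd, so the expected overall
#' missingness equals the rate parameter \eqn{r} while concentrating
#' dropout at low abundance -- the censoring assumption behind
#' downshifted-normal imputation. \code{missing_rate = 0} yields a
#' complete matrix.
#'
#' @param n_proteins number of proteins.
#' @param groups per-sample group labels (character/factor); the second
#'   level is the "treated" group receiving the differential shifts.
#' @param n_diff number of differential proteins (the first \code{n_diff}
#'   rows; alternating up/down).
#' @param diff_log2fc absolute log2 shift of differential proteins.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param base_mean,base_sd distribution of per-protein baseline log2
#'   intensity.
#' @param missing_rate expected overall dropout rate \eqn{r}
#'   (0 = complete).
#' @param seed integer seed.
#' @return list with \code{lfq} (an \code{\linkS4class{LFQMatrix}}) and
#'   \code{truth} (data.frame: \code{protein}, \code{base},
#'   \code{log2_shift}).
#' @examples
#' sim <- simulateLFQ(n_proteins = 100, n_diff = 5, seed = 11)
#' sim$lfq
#' @export
simulateLFQ <- function(n_proteins = 1000L,
                        groups = rep(c("vehicle", "GC"), each = 3L),
                        n_diff = 0L,
                        diff_log2fc = 2,
                        noise_sd = 0.3,
                        base_mean = 26, base_sd = 2.5,
                        missing_rate = 0.3,
                        seed = 1L) {
  n_proteins <- .check_count(n_proteins, "n_proteins", 1L)
  n_diff <- .check_count(n_diff, "n_diff", 0L)
  if (n_diff > n_proteins) stop("n_diff cannot exceed n_proteins")
  if (!is.factor(groups))
    groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  .with_seed(seed, {
    prot <- sprintf("prot_%04d", seq_len(n_proteins))
    base <- rnorm(n_proteins, base_mean, base_sd)
    shift <- numeric(n_proteins)
    if (n_diff)
      shift[seq_len(n_diff)] <- diff_log2fc *
        ifelse(seq_len(n_diff) %% 2L == 1L, 1, -1)
    treated <- groups == levels(groups)[2L]
    mu <- outer(base, rep(1, length(groups))) +
      outer(shift, as.numeric(treated))
    x <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow = n_proteins)
    dimnames(x) <- list(prot, sprintf("%s_r%d", groups,
                                      ave(seq_along(groups), groups,
                                          FUN = seq_along)))
    if (missing_rate > 0) {
      pmiss <- pmin(1, 2 * missing_rate *
                      (1 - pnorm(x, mean(x), sd(x))))
      x[matrix(runif(length(x)), nrow = n_proteins) < pmiss] <- NA
    }
    list(lfq = LFQMatrix(x, groups),
         truth = data.frame(protein = prot, base = base,
                            log2_shift = shift))
  })
}
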