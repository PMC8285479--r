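#' @include AllClasses.R utils.R
NULL

#' Per-sample gene-signature activity score
#'
#' For each signature gene the expression values are z-scored across
#' samples (sample sd, n-1 denominator); the per-sample activity score is
#' the mean (optionally sum) of those per-gene z-scores over the signature.
#' This is the standard single-sample signature score used to summarise,
#' e.g., a 253-gene GR-activation signature on a tumor cohort. Signature
#' genes absent from the matrix are skipped with a message; genes with zero
#' variance across samples are excluded with a warning.
#'
#' Because each gene is z-scored first, the score is invariant to per-gene
#' affine rescaling of the expression matrix.
#'
#' @param exprs gene x sample numeric matrix, or a
#'   \code{\linkS4class{CohortData}}.
#' @param signature character vector of signature gene ids.
#' @param aggregate \code{"mean"} (default) or \code{"sum"} of per-gene
#'   z-scores.
#' @return data.frame with columns \code{sample} and \code{score}.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_samples = 30, seed = 2))
#' sc <- signatureScore(sim$cohort, sim$truth$signature_genes)
#' cor(sc$score, sim$truth$latent, method = "spearman")
#' @export
signatureScore <- function(exprs, signature, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is(exprs, "CohortData")) exprs <- exprMatrix(exprs)
  if (ncol(exprs) < 2L) stop("need >=2 samples")
  present <- intersect(signature, rownames(exprs))
  n_absent <- length(setdiff(signature, present))
  if (n_absent)
    message(n_absent, " signature gene(s) absent from the matrix; skipped")
  if (!length(present)) stop("no signature gene present in the matrix")
  x <- exprs[present, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " zero-variance signature gene(s) excluded from the score")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!nrow(x)) stop("all signature genes have zero variance")
  z <- (x - rowMeans(x)) / sds
  score <- if (aggregate == "mean") colMeans(z) else colSums(z)
  data.frame(sample = colnames(exprs), score = unname(score))
}

#' Stratify samples by activity score
#'
#' Scheme \code{"quartile-extremes"} labels the top 25\% of samples
#' \code{"high"}, the bottom 25\% \code{"low"} and the middle
#' \code{"excluded"} (the "25\% split" comparison of extreme quartiles);
#' scheme \code{"tertiles"} splits into three equal-count groups
#' \code{"low"}/\code{"mid"}/\code{"high"}. Ties are broken by stable
#' sample order; an all-tied score vector is refused.
#'
#' @param scores data.frame from \code{\link{signatureScore}} or a numeric
#'   vector.
#' @param scheme \code{"quartile-extremes"} or \code{"tertiles"}.
#' @return character vector of stratum labels, parallel to the input.
#' @export
stratifySamples <- function(scores, scheme = c("quartile-extremes",
                                               "tertiles")) {
  scheme <- match.arg(scheme)
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  n <- length(s)
  if (scheme == "quartile-extremes" && n < 4L)
    stop("quartile scheme needs >=4 samples")
  if (scheme == "tertiles" && n < 3L)
    stop("tertile scheme needs >=3 samples")
  if (diff(range(s)) == 0)
    stop("tie-degeneracy: all scores equal, stratification refused")
  ord <- order(s, seq_len(n))   # stable tie-break by sample order
  lab <- rep(NA_character_, n)
  if (scheme == "quartile-extremes") {
    k <- floor(n / 4)
    lab[ord[seq_len(k)]] <- "low"
    lab[ord[(n - k + 1L):n]] <- "high"
    lab[is.na(lab)] <- "excluded"
  } else {
    sizes <- rep(n %/% 3L, 3L)
    sizes[seq_len(n %% 3L)] <- sizes[seq_len(n %% 3L)] + 1L
    lab[ord] <- rep(c("low", "mid", "high"), times = sizes)
  }
  lab
}

#' Compare activity scores between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when both groups
#' have at most 8 observations and no ties, otherwise the normal
#' approximation with continuity correction and mid-rank ties (the form
#' reported for cohort comparisons of GR-activity scores).
#'
#' @param scores numeric vector (or data.frame from
#'   \code{\link{signatureScore}}).
#' @param groups vector of group labels with exactly two used levels.
#' @return list with \code{statistic} (rank-sum U), \code{p.value} and
#'   \code{exact}.
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
compareGroups <- function(scores, groups) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups required")
  x <- s[groups == levels(groups)[1L]]
  y <- s[groups == levels(groups)[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >=2 samples per group")
  .ranksum(x, y)
}
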