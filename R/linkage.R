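#' @include AllClasses.R utils.R
NULL

#' Rank correlation between enhancer accessibility and gene expression
#'
#' Spearman rank correlation with mid-rank ties (Pearson selectable), the
#' estimator used to link a candidate enhancer's chromatin accessibility to
#' its target gene's expression across tumor samples. Being rank-based it
#' is invariant under strictly monotone transforms of either input.
#'
#' @param acc,expr paired per-sample numeric vectors (>= 4 samples).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return the correlation coefficient.
#' @examples
#' linkageCorrelation(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
linkageCorrelation <- function(acc, expr, method = c("spearman",
                                                     "pearson")) {
  method <- match.arg(method)
  if (method == "spearman") return(.spearman(acc, expr))
  ok <- is.finite(acc) & is.finite(expr)
  acc <- acc[ok]; expr <- expr[ok]
  if (length(acc) < 4L) stop("need >=4 paired finite observations")
  if (sd(acc) == 0 || sd(expr) == 0)
    stop("undefined correlation: constant input vector")
  cor(acc, expr, method = "pearson")
}

#' Rank a candidate enhancer against a local background null
#'
#' Computes the accessibility-expression correlation for every background
#' enhancer and places the candidate's correlation within that empirical
#' null as a tie-aware mid-quantile:
#' \deqn{q = (\#\{\rho_{bg} < \rho_{cand}\} + 0.5\,\#\{\rho_{bg} =
#'   \rho_{cand}\}) / N.}
#' Background enhancers with constant accessibility are dropped with a
#' message. This mirrors the histogram-with-red-line comparison of a
#' candidate enhancer against the surrounding enhancers of a locus.
#'
#' @param candidate_rho the candidate's correlation (from
#'   \code{\link{linkageCorrelation}}).
#' @param background enhancer x sample accessibility matrix of background
#'   enhancers (>= 20 rows for a meaningful quantile).
#' @param expr per-sample expression vector of the target gene.
#' @param method correlation estimator, as in
#'   \code{\link{linkageCorrelation}}.
#' @return list with \code{background_rhos} and \code{empirical_quantile}.
#' @export
backgroundNull <- function(candidate_rho, background, expr,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.matrix(background), ncol(background) == length(expr))
  if (nrow(background) < 20L)
    warning("fewer than 20 background enhancers: quantile is coarse")
  keep <- apply(background, 1L, sd) > 0
  if (any(!keep))
    message(sum(!keep), " constant background enhancer(s) dropped")
  background <- background[keep, , drop = FALSE]
  if (!nrow(background)) stop("no usable background enhancers")
  rhos <- apply(background, 1L, linkageCorrelation, expr = expr,
                method = method)
  q <- (sum(rhos < candidate_rho) + 0.5 * sum(rhos == candidate_rho)) /
    length(rhos)
  list(background_rhos = rhos, empirical_quantile = q)
}

#' Neighbor-gene specificity of an enhancer linkage
#'
#' Correlates the candidate enhancer's accessibility with each neighboring
#' gene's expression using the same estimator as
#' \code{\link{linkageCorrelation}}. A specific enhancer-target link shows
#' strong correlation with the target but not with the neighbors.
#' Constant neighbor vectors are flagged undefined and excluded.
#'
#' @param acc candidate accessibility per sample.
#' @param neighbors gene x sample matrix of neighbor-gene expression.
#' @param method correlation estimator.
#' @return named numeric vector of per-neighbor correlations (undefined
#'   neighbors omitted).
#' @export
neighborSpecificity <- function(acc, neighbors, method = c("spearman",
                                                           "pearson")) {
  method <- match.arg(method)
  stopifnot(is.matrix(neighbors), ncol(neighbors) == length(acc))
  usable <- apply(neighbors, 1L, sd) > 0
  if (any(!usable))
    message(sum(!usable), " constant neighbor(s) flagged undefined and ",
            "excluded")
  vapply(rownames(neighbors)[usable], function(g)
    linkageCorrelation(acc, neighbors[g, ], method = method),
    numeric(1))
}

#' Correlation conditioned on stepwise removal of low-expressing samples
#'
#' Recomputes the accessibility-expression correlation after removing, for
#' each fraction \code{f} on the grid, the \code{f} lowest-expressing
#' samples of a conditioning gene (e.g. the receptor gene), keeping ties in
#' stable sample order. A linkage that is active only in
#' receptor-expressing samples yields a curve that rises with \code{f}; an
#' unconditioned linkage yields a flat curve. The curve starts at
#' \code{f = 0} with the unconditioned correlation.
#'
#' @param acc,expr candidate accessibility and target expression per
#'   sample.
#' @param conditioning per-sample expression of the conditioning gene.
#' @param fractions removal-fraction grid (default 0, 0.1, ..., 0.8).
#' @param method correlation estimator.
#' @return data.frame with columns \code{fraction}, \code{n} (samples
#'   retained) and \code{rho}; truncated with a warning where fewer than 4
#'   samples would remain.
#' @export
conditionedCorrelationCurve <- function(acc, expr, conditioning,
                                        fractions = seq(0, 0.8, by = 0.1),
                                        method = c("spearman",
                                                   "pearson")) {
  method <- match.arg(method)
  n <- length(acc)
  stopifnot(length(expr) == n, length(conditioning) == n)
  if (floor(max(fractions) * n) > n - 10L)
    warning("largest removal fraction leaves fewer than 10 samples")
  ord <- order(conditioning, seq_len(n))  # ascending, stable ties
  out <- list()
  for (f in sort(fractions)) {
    drop_n <- floor(f * n)
    keep <- ord[(drop_n + 1L):n]
    if (length(keep) < 4L) {
      warning("curve truncated: fewer than 4 samples retained at f = ", f)
      break
    }
    out[[length(out) + 1L]] <- data.frame(
      fraction = f, n = length(keep),
      rho = linkageCorrelation(acc[keep], expr[keep], method = method))
  }
  do.call(rbind, out)
}

#' Full enhancer-linkage analysis on a cohort
#'
#' Convenience wrapper running \code{\link{linkageCorrelation}},
#' \code{\link{backgroundNull}}, \code{\link{neighborSpecificity}} and
#' \code{\link{conditionedCorrelationCurve}} on a
#' \code{\linkS4class{CohortData}}.
#'
#' @param cohort a \code{CohortData}.
#' @param candidate candidate enhancer id (row of the accessibility
#'   matrix).
#' @param target target gene id (row of the expression matrix).
#' @param neighbors character vector of neighbor gene ids (default: rows
#'   starting with \code{"NEIGHBOR"}).
#' @param condition_on conditioning gene id (e.g. the receptor gene); NULL
#'   skips the conditioned curve.
#' @param method correlation estimator.
#' @param fractions removal grid for the conditioned curve.
#' @return list of class \code{"linkageResult"}: \code{candidate},
#'   \code{target}, \code{rho_candidate}, \code{background_rhos},
#'   \code{empirical_quantile}, \code{neighbor_rhos},
#'   \code{conditioned_curve}.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_samples = 60, seed = 8))
#' res <- linkageAnalysis(sim$cohort, "candidate", "TARGET",
#'                        condition_on = "GR")
#' res$empirical_quantile
#' @export
linkageAnalysis <- function(cohort, candidate, target,
                            neighbors = grep("^NEIGHBOR",
                                             rownames(exprMatrix(cohort)),
                                             value = TRUE),
                            condition_on = NULL,
                            method = c("spearman", "pearson"),
                            fractions = seq(0, 0.8, by = 0.1)) {
  method <- match.arg(method)
  stopifnot(is(cohort, "CohortData"))
  acc <- accMatrix(cohort); ex <- exprMatrix(cohort)
  if (!candidate %in% rownames(acc)) stop("unknown candidate enhancer")
  if (!target %in% rownames(ex)) stop("unknown target gene")
  av <- acc[candidate, ]; tv <- ex[target, ]
  rho <- linkageCorrelation(av, tv, method = method)
  bg <- acc[setdiff(rownames(acc), candidate), , drop = FALSE]
  null <- backgroundNull(rho, bg, tv, method = method)
  nbr <- if (length(neighbors))
    neighborSpecificity(av, ex[neighbors, , drop = FALSE],
                        method = method) else numeric(0)
  curve <- if (!is.null(condition_on)) {
    if (!condition_on %in% rownames(ex)) stop("unknown conditioning gene")
    conditionedCorrelationCurve(av, tv, ex[condition_on, ],
                                fractions = fractions, method = method)
  } else NULL
  structure(list(candidate = candidate, target = target,
                 rho_candidate = rho,
                 background_rhos = null$background_rhos,
                 empirical_quantile = null$empirical_quantile,
                 neighbor_rhos = nbr, conditioned_curve = curve),
            class = "linkageResult")
}

#' Plot a linkage background null
#'
#' Histogram of the background-enhancer correlations with the candidate's
#' correlation marked as a vertical line.
#'
#' @param x a \code{"linkageResult"} from \code{\link{linkageAnalysis}}.
#' @param ... passed to \code{hist}.
#' @return invisibly, \code{x}.
#' @export
plotBackgroundNull <- function(x, ...) {
  stopifnot(inherits(x, "linkageResult"))
  graphics::hist(x$background_rhos,
                 main = sprintf("%s vs %s (quantile %.3f)", x$candidate,
                                x$target, x$empirical_quantile),
                 xlab = "background correlation", ...)
  graphics::abline(v = x$rho_candidate, col = "red", lwd = 2)
  invisible(x)
}
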