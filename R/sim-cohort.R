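#' @include AllClasses.R utils.R
NULL

#' Configuration for the tumor-cohort simulator
#'
#' Emulates a tumor cohort in which a latent GR-activity variable drives a
#' gene-expression signature, and a candidate enhancer's chromatin
#' accessibility is coupled to a target gene's expression through a shared
#' component, optionally gated by the expression of the receptor gene
#' itself (samples with low receptor expression carry no linkage).
#' Background enhancers and neighbor genes are generated independently of
#' the target, so that under \code{linkage_effect = 0} the candidate
#' enhancer is exchangeable with the background.
#'
#' With \code{gate = "none"} and \code{noise_sd = 1} the population
#' (Pearson) correlation between candidate accessibility and target
#' expression is \eqn{\lambda^2 / (\lambda^2 + 1)} for
#' \eqn{\lambda = } \code{linkage_effect}; the default
#' \eqn{\lambda = \sqrt{1.5}} therefore gives a true correlation of 0.6.
#'
#' @param n_samples number of tumor samples (>= 4).
#' @param n_signature_genes signature size (default 253).
#' @param n_background_enhancers local background enhancers (default 306).
#' @param n_neighbor_genes neighboring genes around the target (default 4).
#' @param signature_loading effect of the latent activity on each signature
#'   gene.
#' @param linkage_effect coupling strength between candidate accessibility
#'   and target expression; 0 disables the linkage.
#' @param gate \code{"none"} (linkage in every sample) or \code{"top-half"}
#'   (linkage only in samples with receptor expression above the cohort
#'   median).
#' @param noise_sd standard deviation of the independent noise added to
#'   every matrix entry.
#' @param seed integer seed.
#' @return a \code{cohortSimConfig} list.
#' @seealso \code{\link{simulateCohort}}
#' @export
cohortSimConfig <- function(n_samples = 200L,
                            n_signature_genes = 253L,
                            n_background_enhancers = 306L,
                            n_neighbor_genes = 4L,
                            signature_loading = 1,
                            linkage_effect = sqrt(1.5),
                            gate = c("none", "top-half"),
                            noise_sd = 1,
                            seed = 1L) {
  n_samples <- .check_count(n_samples, "n_samples", 4L)
  gate <- match.arg(gate)
  structure(list(n_samples = n_samples,
                 n_signature_genes = .check_count(n_signature_genes,
                                                  "n_signature_genes", 1L),
                 n_background_enhancers =
                   .check_count(n_background_enhancers,
                                "n_background_enhancers", 1L),
                 n_neighbor_genes = .check_count(n_neighbor_genes,
                                                 "n_neighbor_genes", 0L),
                 signature_loading = signature_loading,
                 linkage_effect = linkage_effect, gate = gate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohortSimConfig")
}

#' Simulate a tumor cohort with a known enhancer-gene linkage
#'
#' @param cfg a \code{\link{cohortSimConfig}}.
#' @return a list with elements \code{cohort} (a
#'   \code{\linkS4class{CohortData}}) and \code{truth} (list:
#'   \code{latent} per-sample activity, \code{receptor} per-sample receptor
#'   expression, \code{gate_weight} 0/1 per sample, \code{linked} logical,
#'   \code{signature_genes}, \code{candidate}, \code{target}).
#'
#' Gene rows are the signature genes (\code{SIG_...}), the neighbor genes
#' (\code{NEIGHBOR_...}), the target gene \code{TARGET} and the receptor
#' gene \code{GR}. Enhancer rows are \code{candidate} plus
#' \code{bg_...}, with coordinates tiled around the target locus on chr11.
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_samples = 50, seed = 3))
#' sim$cohort
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohortSimConfig"))
  .with_seed(cfg$seed, {
    n <- cfg$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    latent <- rnorm(n)
    receptor <- rnorm(n)
    w <- if (cfg$gate == "top-half")
      as.numeric(receptor >= median(receptor)) else rep(1, n)
    common <- rnorm(n)

    sig_genes <- sprintf("SIG_%03d", seq_len(cfg$n_signature_genes))
    nbr_genes <- if (cfg$n_neighbor_genes)
      sprintf("NEIGHBOR_%d", seq_len(cfg$n_neighbor_genes)) else character(0)

    sig <- matrix(cfg$signature_loading * rep(latent, each = length(sig_genes)),
                  nrow = length(sig_genes),
                  dimnames = list(sig_genes, samples)) +
      matrix(rnorm(length(sig_genes) * n, 0, cfg$noise_sd),
             nrow = length(sig_genes))
    nbr <- matrix(rnorm(length(nbr_genes) * n, 0, cfg$noise_sd),
                  nrow = length(nbr_genes),
                  dimnames = list(nbr_genes, samples))
    target <- cfg$linkage_effect * w * common + rnorm(n, 0, cfg$noise_sd)
    exprs <- rbind(sig, nbr,
                   TARGET = target,
                   GR = receptor)
    colnames(exprs) <- samples

    nbg <- cfg$n_background_enhancers
    bg_ids <- sprintf("bg_%03d", seq_len(nbg))
    acc <- rbind(
      candidate = cfg$linkage_effect * w * common +
        rnorm(n, 0, cfg$noise_sd),
      matrix(rnorm(nbg * n, 0, cfg$noise_sd), nrow = nbg,
             dimnames = list(bg_ids, samples)))
    colnames(acc) <- samples

    # candidate at the locus, background alternating up/downstream on chr11
    offs <- ceiling(seq_len(nbg) / 2) * 4000 *
      ifelse(seq_len(nbg) %% 2L == 1L, 1, -1)
    starts <- c(2770000, 2770000 + offs)
    enh <- GRanges("chr11", IRanges(start = starts, width = 1500))
    names(enh) <- c("candidate", bg_ids)

    cohort <- CohortData(exprs = exprs, accessibility = acc, enhancers = enh,
                         sampleData = DataFrame(latent = latent,
                                                receptor = receptor,
                                                row.names = samples))
    truth <- list(latent = setNames(latent, samples),
                  receptor = setNames(receptor, samples),
                  gate_weight = setNames(w, samples),
                  linked = cfg$linkage_effect != 0,
                  signature_genes = sig_genes,
                  candidate = "candidate", target = "TARGET")
    list(cohort = cohort, truth = truth)
  })
}
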