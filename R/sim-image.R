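#' @include AllClasses.R utils.R
NULL

#' Configuration for the fluorescence micrograph simulator
#'
#' Generates a two-channel micrograph: a nuclear channel (DAPI-like) of
#' disk-shaped nuclei with cosine-tapered edges over a low-frequency
#' additive background gradient plus Gaussian noise, and a marker channel
#' where each nucleus carries a constant mean per its positivity class
#' plus noise. A fraction of nuclei is placed in touching pairs that
#' overlap by 10-20\% of the mean radius: enough to merge under naive
#' thresholding yet separable by a distance-transform watershed. The
#' ground-truth label map and positivity table are emitted alongside the
#' image and never consumed by the analysis pipeline.
#'
#' @param size image size in pixels, \code{c(ny, nx)}.
#' @param pixel_size micrometres per pixel.
#' @param n_nuclei number of nuclei.
#' @param radius_range_um min/max nucleus radius in micrometres.
#' @param touching_fraction fraction of nuclei placed in touching pairs.
#' @param taper_um width of the cosine edge taper in micrometres.
#' @param nuclear_amplitude peak nuclear-channel intensity (counts).
#' @param background_amplitude amplitude of the additive background
#'   gradient (counts).
#' @param noise_sd Gaussian pixel noise sd (counts); the nuclear-channel
#'   SNR is \code{nuclear_amplitude / noise_sd}.
#' @param marker_positive_fraction fraction of marker-positive nuclei;
#'   assignment is deterministic (the first
#'   \code{round(fraction * n_nuclei)} nuclei are positive).
#' @param marker_neg_mean,marker_pos_mean marker-channel per-nucleus mean
#'   for negative/positive nuclei (counts).
#' @param marker_nucleus_sd between-nucleus sd of the marker mean.
#' @param marker_noise_sd marker-channel pixel noise sd.
#' @param seed integer seed.
#' @return an \code{imageSimConfig} list.
#' @seealso \code{\link{simulateImage}}
#' @export
imageSimConfig <- function(size = c(256L, 256L),
                           pixel_size = 0.6,
                           n_nuclei = 40L,
                           radius_range_um = c(4, 6),
                           touching_fraction = 0,
                           taper_um = 1,
                           nuclear_amplitude = 10000,
                           background_amplitude = 1500,
                           noise_sd = 1000,
                           marker_positive_fraction = 0,
                           marker_neg_mean = 1000,
                           marker_pos_mean = 3000,
                           marker_nucleus_sd = 300,
                           marker_noise_sd = 200,
                           seed = 1L) {
  n_nuclei <- .check_count(n_nuclei, "n_nuclei", 0L)
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (touching_fraction < 0 || touching_fraction > 1)
    stop("touching_fraction must be in [0, 1]")
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_nuclei = n_nuclei, radius_range_um = radius_range_um,
                 touching_fraction = touching_fraction, taper_um = taper_um,
                 nuclear_amplitude = nuclear_amplitude,
                 background_amplitude = background_amplitude,
                 noise_sd = noise_sd,
                 marker_positive_fraction = marker_positive_fraction,
                 marker_neg_mean = marker_neg_mean,
                 marker_pos_mean = marker_pos_mean,
                 marker_nucleus_sd = marker_nucleus_sd,
                 marker_noise_sd = marker_noise_sd,
                 seed = as.integer(seed)),
            class = "imageSimConfig")
}

#' Simulate a two-channel micrograph with ground-truth segmentation
#'
#' @param cfg an \code{\link{imageSimConfig}}.
#' @return a list with elements \code{nuclear} and \code{marker} (numeric
#'   matrices in counts), \code{labels} (ground-truth integer label map,
#'   pixels of touching nuclei assigned to the nearer centre),
#'   \code{truth} (data.frame: nucleus centre in px, radius in um,
#'   positivity, true marker mean) and \code{pixel_size}.
#' @examples
#' sim <- simulateImage(imageSimConfig(n_nuclei = 10, seed = 4))
#' range(sim$labels)
#' @export
simulateImage <- function(cfg) {
  stopifnot(inherits(cfg, "imageSimConfig"))
  .with_seed(cfg$seed, {
    ny <- cfg$size[1L]; nx <- cfg$size[2L]
    px <- cfg$pixel_size
    n <- cfg$n_nuclei
    radii <- if (n) runif(n, cfg$radius_range_um[1L],
                          cfg$radius_range_um[2L]) / px else numeric(0)

    # --- centre placement: singles keep clearance, pairs overlap 10-20% --
    n_pairs <- floor(round(cfg$touching_fraction * n) / 2)
    cx <- numeric(n); cy <- numeric(n); placed <- 0L
    place_one <- function(r, near = NULL, overlap_with = NA) {
      for (try in seq_len(2000L)) {
        if (is.null(near)) {
          x <- runif(1, r + 1, nx - r - 1)
          y <- runif(1, r + 1, ny - r - 1)
        } else {
          ov <- runif(1, 0.1, 0.2) * mean(c(r, overlap_with))
          d <- r + overlap_with - ov
          th <- runif(1, 0, 2 * pi)
          x <- near[1L] + d * cos(th); y <- near[2L] + d * sin(th)
          if (x < r + 1 || x > nx - r - 1 || y < r + 1 || y > ny - r - 1)
            next
        }
        ok <- TRUE
        if (placed > 0L) {
          dd <- sqrt((cx[seq_len(placed)] - x)^2 +
                     (cy[seq_len(placed)] - y)^2)
          lim <- radii[seq_len(placed)] + r + 2
          if (!is.null(near)) {
            # allow contact with the intended partner only
            partner <- which(cx[seq_len(placed)] == near[1L] &
                             cy[seq_len(placed)] == near[2L])[1L]
            lim[partner] <- 0
          }
          ok <- all(dd >= lim)
        }
        if (ok) return(c(x, y))
      }
      stop("could not place nuclei; reduce n_nuclei or radii")
    }
    i <- 1L
    while (i <= n) {
      if (n_pairs > 0L && i %% 2L == 1L && (i + 1L) / 2L <= n_pairs &&
          i + 1L <= n) {
        p1 <- place_one(radii[i])
        cx[i] <- p1[1L]; cy[i] <- p1[2L]; placed <- i
        p2 <- place_one(radii[i + 1L], near = p1,
                        overlap_with = radii[i])
        cx[i + 1L] <- p2[1L]; cy[i + 1L] <- p2[2L]; placed <- i + 1L
        i <- i + 2L
      } else {
        p <- place_one(radii[i])
        cx[i] <- p[1L]; cy[i] <- p[2L]; placed <- i
        i <- i + 1L
      }
    }

    # --- paint label map and nuclear channel ----------------------------
    labels <- matrix(0L, ny, nx)
    bestd <- matrix(Inf, ny, nx)
    nuclear <- matrix(0, ny, nx)
    taper <- max(cfg$taper_um / px, 1e-6)
    for (k in seq_len(n)) {
      r <- radii[k]
      xs <- max(1L, floor(cx[k] - r - 1)):min(nx, ceiling(cx[k] + r + 1))
      ys <- max(1L, floor(cy[k] - r - 1)):min(ny, ceiling(cy[k] + r + 1))
      d <- sqrt(outer((ys - cy[k])^2, (xs - cx[k])^2, "+"))
      inside <- d <= r
      prof <- matrix(0, nrow(d), ncol(d))
      core <- d <= r - taper
      edge <- inside & !core
      prof[core] <- 1
      prof[edge] <- 0.5 * (1 + cos(pi * (d[edge] - (r - taper)) / taper))
      nuclear[ys, xs] <- pmax(nuclear[ys, xs],
                              cfg$nuclear_amplitude * prof)
      dn <- d / r   # normalised distance decides contested pixels
      claim <- inside & dn < bestd[ys, xs]
      lab_sub <- labels[ys, xs]; bd_sub <- bestd[ys, xs]
      lab_sub[claim] <- k; bd_sub[claim] <- dn[claim]
      labels[ys, xs] <- lab_sub; bestd[ys, xs] <- bd_sub
    }

    # --- background gradient + noise ------------------------------------
    if (cfg$background_amplitude > 0) {
      u <- runif(1); v <- 1 - u
      grad <- cfg$background_amplitude *
        (u * outer(rep(1, ny), seq_len(nx) / nx) +
         v * outer(seq_len(ny) / ny, rep(1, nx)))
      nuclear <- nuclear + grad
    }
    if (cfg$noise_sd > 0)
      nuclear <- nuclear + matrix(rnorm(ny * nx, 0, cfg$noise_sd), ny, nx)
    nuclear <- pmax(nuclear, 0)

    # --- marker channel -------------------------------------------------
    n_pos <- round(cfg$marker_positive_fraction * n)
    positive <- seq_len(n) <= n_pos
    mk_mean <- ifelse(positive, cfg$marker_pos_mean, cfg$marker_neg_mean) +
      if (n) rnorm(n, 0, cfg$marker_nucleus_sd) else numeric(0)
    marker <- matrix(100, ny, nx)
    if (n) marker[labels > 0L] <- mk_mean[labels[labels > 0L]]
    if (cfg$marker_noise_sd > 0)
      marker <- marker + matrix(rnorm(ny * nx, 0, cfg$marker_noise_sd),
                                ny, nx)
    marker <- pmax(marker, 0)

    truth <- data.frame(nucleus = seq_len(n), x = cx, y = cy,
                        radius_um = radii * px, positive = positive,
                        marker_mean = mk_mean)
    list(nuclear = nuclear, marker = marker, labels = labels,
         truth = truth, pixel_size = px)
  })
}
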