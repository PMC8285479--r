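#' @include AllClasses.R utils.R
NULL

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(sprintf("validation error in %s: missing column(s) %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' Read / write long-format plate tables
#'
#' Plates travel as tab-separated long format with columns \code{plate},
#' \code{row}, \code{column}, \code{role}, \code{compound},
#' \code{concentration_uM}, \code{arm}, \code{replicate}, \code{value}.
#'
#' @param path file path.
#' @param x a \code{\linkS4class{PlateGrid}}.
#' @param normalized whether the stored values are NPI-normalised.
#' @return \code{readPlates}: a \code{PlateGrid}; \code{writePlates}:
#'   invisibly, \code{path}.
#' @export
readPlates <- function(path, normalized = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, .plate_cols, basename(path))
  PlateGrid(df, normalized = normalized)
}

#' @rdname readPlates
#' @export
writePlates <- function(x, path) {
  stopifnot(is(x, "PlateGrid"))
  write.table(as.data.frame(plateWells(x)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write feature x sample matrices as TSV
#'
#' First column = feature id, remaining columns = samples. Blank cells
#' are read as missing (\code{NA}).
#'
#' @param path file path.
#' @param x numeric matrix with rownames.
#' @param id_col header of the id column (default \code{"id"}).
#' @return \code{readMatrixTSV}: a numeric matrix; \code{writeMatrixTSV}:
#'   invisibly, \code{path}.
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("validation error in %s: need id + sample columns",
                 basename(path)))
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname readMatrixTSV
#' @export
writeMatrixTSV <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED uses 0-based half-open coordinates on disk; in memory intervals
#' are \code{GRanges} (1-based inclusive), so starts are shifted by one
#' on read and back on write. A BED line \code{chr11 2799338 2801363}
#' therefore becomes a range of width 2025. Malformed lines
#' (\code{start > end}) are rejected with their line number.
#'
#' @param path file path.
#' @param x a named \code{GRanges}.
#' @return \code{readBed}: a \code{GRanges} (names from column 4 when
#'   present); \code{writeBed}: invisibly, \code{path}.
#' @export
readBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop(sprintf("validation error in %s: BED needs >=3 columns",
                 basename(path)))
  bad <- which(df[[2L]] > df[[3L]])
  if (length(bad))
    stop(sprintf("validation error in %s line %d: start > end",
                 basename(path), bad[1L]))
  gr <- GRanges(df[[1L]], IRanges(start = df[[2L]] + 1L, end = df[[3L]]))
  if (ncol(df) >= 4L) names(gr) <- df[[4L]]
  gr
}

#' @rdname readBed
#' @export
writeBed <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x),
                   name = if (is.null(names(x)))
                     sprintf("region_%d", seq_along(x)) else names(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write region tables with printed (1-based inclusive) coordinates
#'
#' Region files carry the coordinates exactly as printed in methods
#' sections: tab-separated \code{name}, \code{chrom}, \code{start},
#' \code{end}, 1-based inclusive, so the span length is
#' \code{end - start + 1}.
#'
#' @param path file path.
#' @param x a named \code{GRanges}.
#' @return \code{readRegions}: a named \code{GRanges};
#'   \code{writeRegions}: invisibly, \code{path}.
#' @export
readRegions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, c("name", "chrom", "start", "end"), basename(path))
  bad <- which(df$start > df$end)
  if (length(bad))
    stop(sprintf("validation error in %s line %d: start > end",
                 basename(path), bad[1L] + 1L))
  gr <- GRanges(df$chrom, IRanges(start = df$start, end = df$end))
  names(gr) <- df$name
  gr
}

#' @rdname readRegions
#' @export
writeRegions <- function(x, path) {
  stopifnot(is(x, "GRanges"))
  df <- data.frame(name = names(x),
                   chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x),
                   end = GenomicRanges::end(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 4C profiles as long TSV
#'
#' Columns \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#' \code{condition}, \code{replicate}, \code{signal}.
#'
#' @param path file path.
#' @param x a \code{\linkS4class{FourCProfile}}.
#' @param viewpoint viewpoint id for the reconstructed profile.
#' @return \code{readFourC}: a \code{FourCProfile}; \code{writeFourC}:
#'   invisibly, \code{path}.
#' @export
readFourC <- function(path, viewpoint = "viewpoint") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, c("chrom", "start", "end", "condition", "replicate",
                      "signal"), basename(path))
  key <- paste(df$chrom, df$start, df$end, sep = ":")
  frag_keys <- unique(key)
  ord <- order(vapply(strsplit(frag_keys, ":"), function(p)
    as.numeric(p[2L]), numeric(1)))
  frag_keys <- frag_keys[ord]
  parts <- strsplit(frag_keys, ":")
  frags <- GRanges(vapply(parts, `[`, "", 1L),
                   IRanges(start = as.numeric(vapply(parts, `[`, "", 2L)),
                           end = as.numeric(vapply(parts, `[`, "", 3L))))
  names(frags) <- sprintf("frag_%03d", seq_along(frags))
  col_key <- paste(df$condition, df$replicate, sep = "_r")
  cols <- unique(col_key)
  sig <- matrix(NA_real_, length(frags), length(cols),
                dimnames = list(names(frags), cols))
  sig[cbind(match(key, frag_keys), match(col_key, cols))] <- df$signal
  if (anyNA(sig))
    stop(sprintf("validation error in %s: conditions do not cover the %s",
                 basename(path), "same fragment set"))
  cond <- vapply(strsplit(cols, "_r"), `[`, "", 1L)
  repl <- as.integer(vapply(strsplit(cols, "_r"), `[`, "", 2L))
  FourCProfile(viewpoint = viewpoint, fragments = frags, signal = sig,
               condition = cond, replicate = repl)
}

#' @rdname readFourC
#' @export
writeFourC <- function(x, path) {
  stopifnot(is(x, "FourCProfile"))
  fr <- fragmentRanges(x); cd <- signalInfo(x); sig <- contactSignal(x)
  rows <- do.call(rbind, lapply(seq_len(ncol(sig)), function(j)
    data.frame(chrom = as.character(GenomicRanges::seqnames(fr)),
               start = GenomicRanges::start(fr),
               end = GenomicRanges::end(fr),
               condition = cd$condition[j], replicate = cd$replicate[j],
               signal = sig[, j])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write LFQ matrices and group maps
#'
#' The intensity matrix travels as a feature x sample TSV with blank
#' cells for missing values; group labels travel as a two-column TSV
#' (\code{sample}, \code{group}).
#'
#' @param matrix_path,groups_path file paths.
#' @param x an \code{\linkS4class{LFQMatrix}}.
#' @return \code{readLFQ}: an \code{LFQMatrix}; \code{writeLFQ}:
#'   invisibly, \code{matrix_path}.
#' @export
readLFQ <- function(matrix_path, groups_path) {
  m <- readMatrixTSV(matrix_path)
  gm <- read.delim(groups_path, stringsAsFactors = FALSE)
  .require_cols(gm, c("sample", "group"), basename(groups_path))
  miss <- setdiff(colnames(m), gm$sample)
  if (length(miss))
    stop("validation error: samples without group label: ",
         paste(miss, collapse = ", "))
  LFQMatrix(m, gm$group[match(colnames(m), gm$sample)])
}

#' @rdname readLFQ
#' @export
writeLFQ <- function(x, matrix_path, groups_path) {
  stopifnot(is(x, "LFQMatrix"))
  writeMatrixTSV(intensityMatrix(x), matrix_path, id_col = "protein")
  write.table(data.frame(sample = colnames(intensityMatrix(x)),
                         group = as.character(sampleGroups(x))),
              groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write two-channel 16-bit TIFF micrographs with a JSON sidecar
#'
#' The nuclear and marker channels are stored as two 16-bit pages of one
#' TIFF; the physical pixel size travels in a JSON sidecar
#' (\code{<image>.json} with field \code{pixel_size_um}). Intensities are
#' stored as integer counts in 0..65535.
#'
#' @param path TIFF path (sidecar is \code{paste0(path, ".json")}).
#' @param nuclear,marker numeric matrices in counts.
#' @param pixel_size micrometres per pixel.
#' @return \code{readImagePair}: list with \code{nuclear}, \code{marker},
#'   \code{pixel_size}; \code{writeImagePair}: invisibly, \code{path}.
#' @export
readImagePair <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop("validation error: expected a 2-channel (2-page) TIFF")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("validation error: missing JSON sidecar ", basename(sidecar))
  meta <- jsonlite::read_json(sidecar)
  if (is.null(meta$pixel_size_um))
    stop("validation error: sidecar lacks pixel_size_um")
  list(nuclear = round(pages[[1L]] * 65535),
       marker = round(pages[[2L]] * 65535),
       pixel_size = as.numeric(meta$pixel_size_um))
}

#' @rdname readImagePair
#' @export
writeImagePair <- function(nuclear, marker, pixel_size, path) {
  clip <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(clip(nuclear), clip(marker)), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a label map as a 16-bit TIFF
#'
#' @param labels integer matrix.
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
writeLabelTiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
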