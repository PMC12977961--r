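#' Streamline bundle in world millimetres
#'
#' A `tract_bundle` is an ordered list of streamlines; each streamline is an
#' n x 3 matrix of points in scanner-space mm (the TCK convention). Every
#' streamline must have at least two finite points.
#'
#' @param streamlines list of numeric n x 3 matrices.
#' @return an object of class `tract_bundle` with fields `streamlines` and
#'   `count`.
#' @export
tract_bundle <- function(streamlines = list()) {
  if (!is.list(streamlines)) stop("streamlines must be a list", call. = FALSE)
  streamlines <- lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    if (!is.matrix(s) || ncol(s) != 3L)
      stop("streamline ", i, " is not an n x 3 matrix", call. = FALSE)
    if (nrow(s) < 2L)
      stop("streamline ", i, " has fewer than 2 points", call. = FALSE)
    if (!all(is.finite(s)))
      stop("streamline ", i, " contains non-finite coordinates", call. = FALSE)
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, count = length(streamlines)),
            class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<tract_bundle> %d streamlines, %s points each\n", x$count,
              if (x$count) paste0(min(npts), "-", max(npts)) else "0"))
  invisible(x)
}

#' Read an MRtrix TCK tractogram
#'
#' Parses the text header, then the Float32 little-endian point stream:
#' streamlines are separated by NaN triplets and the file ends with an Inf
#' triplet. Coordinates are scanner-space mm.
#'
#' @param path path to a `.tck` file.
#' @return a [tract_bundle()].
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path))
    stop("tractogram file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = 8192L)
  if (length(head_raw) < 14L ||
      rawToChar(head_raw[1:13]) != "mrtrix tracks")
    stop("'", basename(path), "' is not a TCK file (bad magic)", call. = FALSE)
  end_pos <- grepRaw("\nEND\n", head_raw, fixed = TRUE)
  if (!length(end_pos))
    stop("TCK header of '", basename(path), "' is truncated", call. = FALSE)
  head_txt <- rawToChar(head_raw[seq_len(end_pos - 1L)])
  hdr <- strsplit(head_txt, "\n", fixed = TRUE)[[1L]]
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", hit[1L]))
  }
  dt <- field("datatype")
  if (!is.na(dt) && dt != "Float32LE")
    stop("unsupported TCK datatype '", dt, "' (only Float32LE)", call. = FALSE)
  offset <- as.integer(sub("^\\.\\s*", "", field("file")))
  if (is.na(offset))
    stop("TCK header lacks a valid 'file' offset", call. = FALSE)
  seek(con, where = offset, origin = "start")
  nbytes <- file.size(path) - offset
  vals <- readBin(con, "numeric", n = nbytes %/% 4L, size = 4L,
                  endian = "little")
  if (length(vals) %% 3L != 0L)
    stop("TCK point stream of '", basename(path),
         "' is truncated (not a whole number of triplets)", call. = FALSE)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  n <- nrow(pts)
  if (n == 0L || !all(is.infinite(pts[n, ])))
    stop("TCK file '", basename(path),
         "' is truncated (missing Inf terminator)", call. = FALSE)
  pts <- pts[-n, , drop = FALSE]
  if (nrow(pts) == 0L) return(tract_bundle(list()))
  sep <- rowSums(is.na(pts)) > 0L
  if (any(sep & rowSums(is.na(pts)) != 3L))
    stop("corrupt TCK separator (partial NaN triplet)", call. = FALSE)
  grp <- cumsum(c(TRUE, sep[-length(sep)])) # streamline id per row
  keep <- !sep
  if (!all(is.finite(pts[keep, ])))
    stop("TCK file contains non-finite coordinates inside a streamline",
         call. = FALSE)
  if (!any(keep)) return(tract_bundle(list()))
  sl <- split.data.frame(pts[keep, , drop = FALSE], grp[keep])
  tract_bundle(unname(lapply(sl, as.matrix)))
}

#' Write an MRtrix TCK tractogram
#'
#' @param bundle a [tract_bundle()]; an empty bundle writes a valid file.
#' @param path output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(bundle, path) {
  stopifnot(inherits(bundle, "tract_bundle"))
  body_fixed <- paste0("mrtrix tracks\n",
                       "datatype: Float32LE\n",
                       "count: ", bundle$count, "\n")
  # the 'file' line quotes the byte offset of the binary section, which
  # depends on its own width; iterate to a fixed point
  offset <- nchar(body_fixed) + nchar("file: . \nEND\n") + 1L
  repeat {
    hdr <- paste0(body_fixed, "file: . ", offset, "\nEND\n")
    if (nchar(hdr) == offset) break
    offset <- nchar(hdr)
  }
  stream <- unlist(lapply(bundle$streamlines, function(s) {
    c(t(s), NaN, NaN, NaN)
  }), use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  if (length(stream))
    writeBin(stream, con, size = 4L, endian = "little")
  writeBin(c(Inf, Inf, Inf), con, size = 4L, endian = "little")
  invisible(path)
}

#' Resample a polyline to a maximum arc-length spacing
#'
#' Each segment of length L contributes sample points at arc positions
#' `j * step` for `j = 0, 1, ..., floor(L / step)` plus its endpoint, so
#' original vertices are always among the samples and consecutive samples
#' along a segment are never more than `step` mm apart. The rows are the
#' full sample set but not in arc-length order (the set, not the sequence,
#' is what the voxel-visitation operations consume).
#'
#' @param points n x 3 matrix, world mm.
#' @param step maximum spacing, mm, > 0.
#' @return m x 3 matrix of sample points (m >= n).
#' @export
resample_polyline <- function(points, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("resampling step must be a single positive number (mm)",
         call. = FALSE)
  n <- nrow(points)
  if (n < 2L) return(points)
  a <- points[-n, , drop = FALSE]
  d <- points[-1L, , drop = FALSE] - a
  len <- sqrt(rowSums(d^2))
  m <- pmax(floor(len / step + 1e-9), 0)
  m[len == 0] <- 0
  if (sum(m) == 0) return(points)
  segidx <- rep.int(seq_len(n - 1L), m)
  frac <- (sequence(m) * step) / len[segidx]
  rbind(points,
        a[segidx, , drop = FALSE] + d[segidx, , drop = FALSE] * frac)
}
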