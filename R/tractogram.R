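#' Construct a tractogram
#'
#' A tractogram is a list of streamlines — ordered polylines of world-space
#' points in millimetres — with an optional bundle label per streamline
#' (e.g. AF, FAT, SLF3, ILF, IFOF, UF, or "other").
#'
#' @param streamlines list of numeric matrices (n_i x 3), each with >= 2
#'   points and no repeated consecutive point.
#' @param bundles character vector of bundle labels (recycled if length 1);
#'   defaults to `"other"`.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, bundles = "other") {
  stopifnot(is.list(streamlines))
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L) stop("streamline points must be n x 3")
    if (nrow(s) < 2L) stop("a streamline needs at least 2 points")
    steps <- diff(s)
    if (any(rowSums(steps^2) == 0))
      stop("consecutive streamline points must be distinct")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  bundles <- rep_len(as.character(bundles), length(streamlines))
  structure(list(streamlines = streamlines, bundles = bundles),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> %d streamlines, bundles: %s\n",
              length(x$streamlines),
              paste(sort(unique(x$bundles)), collapse = ", ")))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Read a tractogram
#'
#' Supported dialects: `"jsonl"` (one JSON object per line with fields
#' `bundle` and `points`), `"trk"` (TrackVis) and `"tck"` (MRtrix). Whatever
#' the on-disk convention, returned points are world-space millimetres.
#'
#' @param path input file.
#' @param dialect one of `"jsonl"`, `"trk"`, `"tck"`; default guessed from the
#'   file extension.
#' @return a [tractogram()].
#' @export
read_tractogram <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      trk = "trk", tck = "tck", jsonl = "jsonl",
                      stop("cannot guess tractogram dialect from extension: ",
                           path))
  }
  switch(dialect,
         jsonl = read_tractogram_jsonl(path),
         trk   = read_tractogram_trk(path),
         tck   = read_tractogram_tck(path),
         stop("unknown tractogram dialect: ", dialect))
}

#' Write a tractogram
#'
#' @param trac a [tractogram()].
#' @param path output file.
#' @param dialect `"jsonl"`, `"trk"` or `"tck"`; default from extension.
#' @param grid for `"trk"`, a [volume_grid()] supplying the header geometry
#'   (required: the TrackVis format stores points relative to a voxel grid).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(trac, path, dialect = NULL, grid = NULL) {
  stopifnot(inherits(trac, "tractogram"))
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      trk = "trk", tck = "tck", jsonl = "jsonl",
                      stop("cannot guess tractogram dialect from extension: ",
                           path))
  }
  switch(dialect,
         jsonl = write_tractogram_jsonl(trac, path),
         trk   = write_tractogram_trk(trac, path, grid),
         tck   = write_tractogram_tck(trac, path),
         stop("unknown tractogram dialect: ", dialect))
  invisible(path)
}

read_tractogram_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sl <- vector("list", length(lines))
  bl <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    if (is.null(rec$points)) stop("jsonl record ", i, " lacks a points field")
    pts <- matrix(as.numeric(unlist(rec$points)), ncol = 3, byrow = is.list(rec$points))
    if (is.matrix(rec$points)) pts <- rec$points
    if (nrow(pts) < 2L)
      stop("jsonl record ", i, " has fewer than 2 points")
    sl[[i]] <- pts
    bl[i] <- if (is.null(rec$bundle)) "other" else as.character(rec$bundle)
  }
  tractogram(sl, bl)
}

write_tractogram_jsonl <- function(trac, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(trac$streamlines)) {
    rec <- list(bundle = trac$bundles[i],
                points = unname(trac$streamlines[[i]]))
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# --- TrackVis (.trk), version 2 -------------------------------------------
# Points on disk are in "voxel-mm": continuous voxel coordinate (corner
# origin) times voxel size. World mm = vox_to_ras %*% (p / voxel_size - 0.5).

read_tractogram_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic[1:5], charToRaw("TRACK")))
    stop("not a TrackVis .trk file: ", path)
  dim3 <- readBin(con, "integer", 3, size = 2)
  voxel_size <- readBin(con, "double", 3, size = 4)
  origin <- readBin(con, "double", 3, size = 4)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  vox_to_ras <- matrix(readBin(con, "double", 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000L) stop("unsupported .trk header (size ", hdr_size, ")")
  if (all(vox_to_ras == 0)) stop(".trk file lacks a vox_to_ras transform")
  sl <- list()
  repeat {
    n <- readBin(con, "integer", 1, size = 4)
    if (length(n) == 0L) break
    pts <- matrix(readBin(con, "double", 3 * n, size = 4), ncol = 3,
                  byrow = TRUE)
    if (n_scalars > 0)  # interleaved with points: re-read properly
      stop(".trk files with per-point scalars are not supported")
    if (n_props > 0) invisible(readBin(con, "double", n_props, size = 4))
    vox <- sweep(pts, 2, voxel_size, "/") - 0.5
    world <- cbind(vox, 1) %*% t(vox_to_ras)
    sl[[length(sl) + 1L]] <- world[, 1:3, drop = FALSE]
    if (length(sl) == n_count) break
  }
  tractogram(sl)
}

write_tractogram_trk <- function(trac, path, grid) {
  if (is.null(grid))
    stop("writing .trk requires a reference volume_grid for the header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(as.raw(0), con)
  writeBin(as.integer(dim(grid$values)), con, size = 2)
  writeBin(as.numeric(grid$voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)            # origin (unused)
  writeBin(0L, con, size = 2)                    # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                    # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(grid$affine)), con, size = 4)
  writeBin(raw(444), con)
  writeBin(c(charToRaw("RAS"), raw(1)), con)     # voxel_order
  writeBin(raw(4), con)                          # pad2
  writeBin(numeric(6), con, size = 4)            # image_orientation_patient
  writeBin(raw(2), con)                          # pad1
  writeBin(raw(6), con)                          # invert/swap flags
  writeBin(length(trac$streamlines), con, size = 4)
  writeBin(2L, con, size = 4)                    # version
  writeBin(1000L, con, size = 4)                 # hdr_size
  inv <- solve(grid$affine)
  for (s in trac$streamlines) {
    vox <- cbind(s, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, grid$voxel_size, "*")
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

# --- MRtrix (.tck): points stored directly in scanner/world mm ------------

read_tractogram_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header is ASCII up to the END line; locate "\nEND\n" on the raw bytes
  pat <- charToRaw("\nEND\n")
  hits <- which(raw == pat[1])
  end_at <- NA_integer_
  for (h in hits) {
    if (h + 4L <= length(raw) && identical(raw[h:(h + 4L)], pat)) {
      end_at <- h + 4L
      break
    }
  }
  if (is.na(end_at)) stop("unterminated .tck header")
  head_txt <- rawToChar(raw[seq_len(end_at)])
  if (!grepl("^mrtrix tracks", head_txt))
    stop("not an MRtrix .tck file: ", path)
  lines <- strsplit(head_txt, "\n", fixed = TRUE)[[1]]
  end_i <- which(lines == "END")[1]
  if (is.na(end_i)) stop("unterminated .tck header")
  offset <- NA_integer_
  datatype <- "Float32LE"
  for (line in lines[seq_len(end_i)]) {
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.integer(sub("^\\.\\s+", "", val))
    if (key == "datatype") datatype <- val
  }
  if (datatype != "Float32LE")
    stop("unsupported .tck datatype: ", datatype)
  if (is.na(offset)) stop(".tck header lacks a file offset")
  vals <- readBin(raw[(offset + 1L):length(raw)], "double",
                  length(raw), size = 4)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(is.nan(pts[, 1]) | is.infinite(pts[, 1]))
  sl <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) sl[[length(sl) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    if (is.infinite(pts[b, 1])) break
    start <- b + 1L
  }
  tractogram(sl)
}

write_tractogram_tck <- function(trac, path) {
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(trac$streamlines)))
  # reserve room for the offset line, then END
  offset_line <- function(off) sprintf("file: . %d", off)
  body_guess <- paste(c(header, offset_line(100000), "END"), collapse = "\n")
  offset <- nchar(body_guess, type = "bytes") + 1L  # trailing newline
  hdr <- paste(c(header, offset_line(offset), "END"), collapse = "\n")
  # fix point: recompute until stable (offset width can change)
  while (nchar(hdr, type = "bytes") + 1L != offset) {
    offset <- nchar(hdr, type = "bytes") + 1L
    hdr <- paste(c(header, offset_line(offset), "END"), collapse = "\n")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, "\n")), con)
  for (s in trac$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4)
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4)
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4)
  invisible(path)
}
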