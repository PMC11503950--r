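#' Read a 3-D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3-D array) and `grid` (a [grid_spec()] built
#'   from the image dimensions and the first pixel dimension).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D image, got %d dimensions in %s", length(d), path))
  vs <- RNifti::pixdim(img)[1]
  g <- grid_spec(d, voxel_size = vs)
  list(data = array(as.numeric(img), dim = d), grid = g)
}

#' Write a 3-D volume as NIfTI-1 (float32)
#'
#' @param data 3-D numeric array.
#' @param grid the [grid_spec()] the volume lives on.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  check_volume(data, grid)
  img <- RNifti::asNifti(array(data, dim = grid$shape), internal = FALSE)
  RNifti::pixdim(img) <- rep(grid$voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a tractogram (TCK or plain-text fallback)
#'
#' TCK files (MRtrix track format) store points in world millimetres; they
#' are converted to continuous voxel coordinates by dividing by `voxel_size`
#' (the phantom affine is a pure scaling). The text fallback holds one
#' streamline per block of whitespace-separated `x y z` voxel-coordinate
#' lines, blocks separated by blank lines; an optional `# bundle: <id>` line
#' before a block labels it, and `# subject: <id>` anywhere names the subject.
#'
#' @param path path to a `.tck` or text (`.txt`) streamline file.
#' @param grid [grid_spec()] used to convert world -> voxel coordinates for
#'   TCK input (ignored for text input, which is already in voxel units).
#' @return A `tractogram` object: `subject_id`, `streamlines` (list of n x 3
#'   matrices), `bundle_of` (character labels, possibly `NA`).
#' @export
read_tractogram <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tck$", path, ignore.case = TRUE)) {
    read_tck(path, grid)
  } else {
    read_tractogram_text(path)
  }
}

#' Write a tractogram
#'
#' @param tract a `tractogram` object.
#' @param path output path; `.tck` selects binary TCK (points written in
#'   world mm), anything else the text fallback (voxel coordinates). For TCK
#'   a JSON sidecar `<path>.labels.json` stores subject id and bundle labels.
#' @param grid [grid_spec()] for voxel -> world conversion (TCK only).
#' @return The path, invisibly.
#' @export
write_tractogram <- function(tract, path, grid = NULL) {
  if (grepl("\\.tck$", path, ignore.case = TRUE)) {
    write_tck(tract, path, grid)
  } else {
    write_tractogram_text(tract, path)
  }
  invisible(path)
}

new_tractogram <- function(subject_id, streamlines, bundle_of = NULL) {
  if (is.null(bundle_of)) bundle_of <- rep(NA_character_, length(streamlines))
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2)
      stop("every streamline must be a matrix with >= 2 rows and 3 columns")
    if (!all(is.finite(s))) stop("streamline contains non-finite points")
  }
  structure(list(subject_id = subject_id, streamlines = streamlines,
                 bundle_of = as.character(bundle_of)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> subject %s: %d streamlines, %d bundles\n",
              x$subject_id, length(x$streamlines),
              length(unique(stats::na.omit(x$bundle_of)))))
  invisible(x)
}

read_tractogram_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    warning("empty tractogram file: ", path)
    return(structure(list(subject_id = NA_character_, streamlines = list(),
                          bundle_of = character(0)), class = "tractogram"))
  }
  subject <- NA_character_
  streamlines <- list()
  bundles <- character(0)
  cur <- list(); cur_bundle <- NA_character_
  flush <- function() {
    if (length(cur) >= 1) {
      m <- do.call(rbind, cur)
      if (nrow(m) < 2)
        stop(sprintf("streamline block ending before line %d has < 2 points", i))
      streamlines[[length(streamlines) + 1L]] <<- m
      bundles[length(bundles) + 1L] <<- cur_bundle
    }
    cur <<- list(); cur_bundle <<- NA_character_
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) { flush(); next }
    if (startsWith(ln, "#")) {
      if (grepl("^#\\s*subject:", ln))
        subject <- trimws(sub("^#\\s*subject:", "", ln))
      if (grepl("^#\\s*bundle:", ln))
        cur_bundle <- trimws(sub("^#\\s*bundle:", "", ln))
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(v) != 3 || any(!is.finite(v)))
      stop(sprintf("malformed point on line %d of %s: '%s'", i, path, ln))
    cur[[length(cur) + 1L]] <- v
  }
  flush()
  new_tractogram(subject, streamlines, bundles)
}

write_tractogram_text <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(tract$subject_id))
    writeLines(paste0("# subject: ", tract$subject_id), con)
  for (i in seq_along(tract$streamlines)) {
    if (!is.na(tract$bundle_of[i]))
      writeLines(paste0("# bundle: ", tract$bundle_of[i]), con)
    m <- tract$streamlines[[i]]
    writeLines(apply(m, 1, function(p) sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
    writeLines("", con)
  }
}

# MRtrix .tck: textual header terminated by END, then little-endian float32
# triplets; streamlines separated by a NaN triplet, file ends with Inf triplet.
read_tck <- function(path, grid) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file: ", path)
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("unterminated TCK header in ", path)
    if (identical(trimws(ln), "END")) break
    if (grepl("^file:", ln))
      offset <- as.integer(trimws(sub("^file:\\s*\\.\\s*", "", ln)))
    if (grepl("^datatype:", ln) && !grepl("Float32LE", ln))
      stop("unsupported TCK datatype in ", path)
  }
  if (is.na(offset)) stop("TCK header lacks file offset in ", path)
  close(con); on.exit(NULL)
  con <- file(path, "rb"); on.exit(close(con))
  seek(con, offset)
  raw_n <- file.info(path)$size - offset
  vals <- readBin(con, "numeric", n = raw_n / 4, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur) && nrow(cur) >= 2)
        streamlines[[length(streamlines) + 1L]] <- cur
      cur <- NULL
    } else {
      cur <- rbind(cur, p)
    }
  }
  if (!is.null(cur) && nrow(cur) >= 2)
    streamlines[[length(streamlines) + 1L]] <- cur
  vs <- if (is.null(grid)) 1 else grid$voxel_size
  streamlines <- lapply(streamlines, function(m) m / vs)
  sidecar <- paste0(path, ".labels.json")
  subject <- NA_character_; bundles <- NULL
  if (file.exists(sidecar)) {
    lab <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    subject <- lab$subject_id
    bundles <- lab$bundle_of
  }
  new_tractogram(subject, streamlines, bundles)
}

write_tck <- function(tract, path, grid) {
  vs <- if (is.null(grid)) 1 else grid$voxel_size
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(tract$streamlines)))
  # reserve room for the offset line, then patch the real offset in
  probe <- paste0(c(header, "file: . 000000", "END", ""), collapse = "\n")
  offset <- nchar(probe, type = "bytes")
  header <- c(header, sprintf("file: . %06d", offset), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writChar <- paste0(paste0(header, collapse = "\n"), "\n")
  writeBin(charToRaw(writChar), con)
  nan3 <- rep(NaN, 3); inf3 <- rep(Inf, 3)
  for (m in tract$streamlines) {
    writeBin(as.numeric(t(m * vs)), con, size = 4, endian = "little")
    writeBin(nan3, con, size = 4, endian = "little")
  }
  writeBin(inf3, con, size = 4, endian = "little")
  close(con); on.exit(NULL)
  jsonlite::write_json(list(subject_id = tract$subject_id,
                            bundle_of = tract$bundle_of),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}
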