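#' @include constructors.R
NULL

# File surfaces use millimetres and degrees; everything internal is SI.

#' Read / write sensor arrays
#'
#' JSON layout: `{"frame": ..., "sensors": [{"label", "position_mm",
#' "orientation", "gain"}]}`. TSV layout: columns label, x_mm, y_mm, z_mm,
#' ox, oy, oz, gain. Positions are stored in millimetres, orientations as
#' unit vectors.
#'
#' @param path file path; format chosen by extension (.json / .tsv).
#' @param array a [SensorArray-class].
#' @return `readSensorArray` returns a [SensorArray-class].
#' @export
readSensorArray <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    s <- j$sensors
    asMat <- function(x) {
      if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
      unname(as.matrix(x))
    }
    sensorArray(asMat(s$position_mm) / 1000, asMat(s$orientation),
                as.numeric(s$gain), as.character(s$label), j$frame %||% "head")
  } else {
    d <- utils::read.delim(path, sep = "\t")
    sensorArray(as.matrix(d[, c("x_mm", "y_mm", "z_mm")]) / 1000,
                as.matrix(d[, c("ox", "oy", "oz")]), d$gain, d$label)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readSensorArray
#' @export
writeSensorArray <- function(array, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pos <- sensorPositions(array) * 1000
    sensors <- lapply(seq_len(nChannels(array)), function(i) list(
      label = channelLabels(array)[i],
      position_mm = pos[i, ],
      orientation = sensorOrientations(array)[i, ],
      gain = sensorGains(array)[i]))
    jsonlite::write_json(list(frame = array@frame, sensors = sensors), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    pos <- sensorPositions(array) * 1000
    o <- sensorOrientations(array)
    d <- data.frame(label = channelLabels(array), x_mm = pos[, 1],
                    y_mm = pos[, 2], z_mm = pos[, 3], ox = o[, 1], oy = o[, 2],
                    oz = o[, 3], gain = sensorGains(array))
    utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write rigid poses as JSON
#'
#' Axis-angle rotation in radians, translation in millimetres.
#' @param path file path.
#' @param pose a [RigidTransform-class].
#' @export
readPose <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(j$rotation_rad, j$translation_mm / 1000)
}

#' @rdname readPose
#' @export
writePose <- function(pose, path) {
  jsonlite::write_json(list(rotation_rad = pose@rotation,
                            translation_mm = pose@translation * 1000),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write triangulated surface meshes
#'
#' Minimal OBJ (`v`/`f` records) and ASCII-STL support; vertex coordinates in
#' millimetres on disk, metres in memory.
#' @param path mesh path (.obj or .stl).
#' @param mesh list with `vertices` (metres) and `faces`.
#' @export
readSurface <- function(path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    vl <- ln[startsWith(ln, "v ")]
    fl <- ln[startsWith(ln, "f ")]
    v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[1:3]))))
    list(vertices = v / 1000, faces = f)
  } else if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    ln <- trimws(readLines(path))
    vx <- ln[startsWith(ln, "vertex")]
    v <- do.call(rbind, lapply(strsplit(vx, "\\s+"),
                               function(x) as.numeric(x[2:4]))) / 1000
    nf <- nrow(v) / 3
    # STL repeats vertices per facet; merge identical coordinates
    key <- apply(round(v * 1e9), 1, paste, collapse = ",")
    uk <- !duplicated(key)
    idx <- match(key, key[uk])
    list(vertices = v[uk, , drop = FALSE],
         faces = matrix(idx, ncol = 3, byrow = TRUE))
  } else stop("unsupported mesh format: ", path)
}

#' @rdname readSurface
#' @export
writeSurface <- function(mesh, path) {
  v <- rbind(mesh$vertices) * 1000
  f <- rbind(mesh$faces)
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid surface", con)
    for (k in seq_len(nrow(f))) {
      tri <- v[f[k, ], , drop = FALSE]
      n <- crossProd3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- vnorm(n); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid surface", con)
  } else stop("unsupported mesh format: ", path)
  invisible(path)
}

#' Read / write data matrices as TSV
#'
#' Channels x samples, one row per channel, first column the channel label;
#' values in tesla. A JSON sidecar (`<path>.json`) carries the sample rate
#' and window.
#' @param path TSV path.
#' @param data a [DataMatrix-class].
#' @export
readDataMatrix <- function(path) {
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dataMatrix(as.matrix(d[, -1]), meta$sample_rate_hz, d[[1]],
             meta$window_s)
}

#' @rdname readDataMatrix
#' @export
writeDataMatrix <- function(data, path) {
  d <- data.frame(label = channelLabels(data), dataValues(data))
  names(d) <- c("label", sprintf("s%06d", seq_len(nSamples(data))))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sample_rate_hz = data@sampleRate,
                            window_s = data@window,
                            units = "tesla"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write numeric matrices as a binary container with JSON sidecar
#'
#' Row-major little-endian doubles in `<path>`, dimensions/units/provenance in
#' `<path>.json`.
#' @param m numeric matrix.
#' @param path output path.
#' @param units unit string recorded in the sidecar.
#' @param provenance named list of provenance fields (e.g. input hashes).
#' @export
writeMatrixBin <- function(m, path, units = "", provenance = list()) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  jsonlite::write_json(c(list(nrow = nrow(m), ncol = ncol(m), units = units,
                              storage = "float64-row-major-le"), provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMatrixBin
#' @export
readMatrixBin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$nrow * meta$ncol, size = 8,
               endian = "little")
  matrix(x, meta$nrow, meta$ncol, byrow = TRUE)
}

#' Write a perturbation curve as TSV + JSON metadata
#'
#' TSV columns: offset, mean_F, rel_F, repeat_1..n. The JSON sidecar records
#' the kind, seed and the threshold widths at -3 nats.
#' @param curve a [PerturbationCurve-class].
#' @param path TSV output path.
#' @param deltaF threshold used for the recorded widths.
#' @export
writeCurve <- function(curve, path, deltaF = -3) {
  m <- colMeans(curve@Fvalues)
  d <- data.frame(offset = curve@offsets, mean_F = m, rel_F = m - max(m))
  reps <- t(curve@Fvalues)
  colnames(reps) <- sprintf("repeat_%d", seq_len(nrow(curve@Fvalues)))
  utils::write.table(cbind(d, reps), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  w <- tryCatch(widthAtThreshold(curve, deltaF), error = function(e) NULL)
  jsonlite::write_json(list(kind = curve@kind, unit = curve@unit,
                            seed = curve@seed, threshold = deltaF,
                            width = w),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Quick look at a perturbation curve
#'
#' Base-graphics plot of the normalised (relative) curve with per-repeat
#' points and the evidence threshold line.
#' @param x a [PerturbationCurve-class].
#' @param deltaF threshold drawn as a horizontal line.
#' @param ... passed to [plot()].
#' @export
plotCurve <- function(x, deltaF = -3, ...) {
  rel <- relativeF(x)
  off <- x@offsets
  graphics::plot(off, rel, type = "b", pch = 16,
                 xlab = sprintf("perturbation (%s)", x@unit),
                 ylab = "relative free energy (nats)", ...)
  shift <- max(colMeans(x@Fvalues))
  for (r in seq_len(nrow(x@Fvalues)))
    graphics::points(off, x@Fvalues[r, ] - shift, col = "grey70", cex = 0.4)
  graphics::abline(h = deltaF, lty = 2)
  invisible(x)
}
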