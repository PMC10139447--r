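# On-disk formats: 16-bit grayscale depth PNGs, delimited gaze logs, and
# YAML session manifests. Reading 16-bit PNG goes through png::readPNG;
# writing uses a minimal in-package PNG chunk writer (filter type 0,
# grayscale, bit depth 16) since no installed writer emits 16-bit PNG.

# ---- CRC32 (for PNG chunks) -------------------------------------------------

.crc_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  for (n in 0:255) {
    cval <- as.integer(n)
    for (k in 1:8) {
      cval <- if (bitwAnd(cval, 1L) != 0L)
        bitwXor(poly, bitwShiftR(cval, 1L))
      else bitwShiftR(cval, 1L)
    }
    tab[n + 1] <- cval
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(.crc_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

int_be <- function(x, size = 4L) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(crc32(body)))
}

#' Write a depth frame as 16-bit grayscale PNG
#'
#' Depths are passed through [encode_depth()] (nonlinear 16-bit mapping
#' using the frame camera's near/far) and written as a single-channel,
#' 16-bit grayscale PNG readable by any standard PNG reader.
#'
#' @param frame A [depth_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(frame, path) {
  codes <- encode_depth(frame$values, frame$camera)
  h <- nrow(codes); w <- ncol(codes)
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16, 0, 0, 0, 0)))
  # scanlines: filter byte 0 + big-endian u16 pixels, row-major
  pix <- writeBin(as.integer(t(codes)), raw(), size = 2L, endian = "big")
  pix <- matrix(pix, nrow = 2L * w)
  scan <- as.raw(rbind(raw(ncol(pix)), pix))
  idat <- memCompress(scan, type = "gzip")  # zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a 16-bit depth PNG
#'
#' Inverse of [write_depth_png()]: reads the 16-bit grayscale image and
#' decodes the nonlinear depth mapping with the supplied camera's near/far.
#' Truncated or non-grayscale files are rejected.
#'
#' @param path PNG path.
#' @param camera The [camera_model()] recorded in the session manifest.
#' @param timestamp Frame timestamp in seconds.
#' @return A [depth_frame()].
#' @export
read_depth_png <- function(path, camera, timestamp = 0) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 2L)
    stop("expected single-channel grayscale depth PNG: ", path)
  codes <- round(img * 65535)
  depth_frame(decode_depth(codes, camera), camera, timestamp)
}

# ---- gaze logs --------------------------------------------------------------

.gaze_log_cols <- c("t", "lx", "ly", "lz", "rx", "ry", "rz",
                    "laz", "lel", "raz", "rel", "valid")

#' Write a gaze trace as a delimited text log
#'
#' One row per sample: time (s), per-eye origin xyz (cm), per-eye Helmholtz
#' azimuth/elevation (deg, 6 decimal places — below tracker noise), validity
#' flag. Sampling rate and inter-ocular distance are recorded in comment
#' lines so the file round-trips losslessly.
#'
#' @param trace A [gaze_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_log <- function(trace, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vrdisparity gaze log v1",
               sprintf("# sample_rate_hz: %.9g", attr(trace, "sample_rate")),
               sprintf("# iod_cm: %.9g", attr(trace, "iod"))), con)
  df <- as.data.frame(trace)
  num <- setdiff(.gaze_log_cols, "valid")
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  df$valid <- as.integer(df$valid)
  writeLines(paste(.gaze_log_cols, collapse = ","), con)
  writeLines(do.call(paste, c(df[.gaze_log_cols], sep = ",")), con)
  invisible(path)
}

#' Read a gaze log
#'
#' Rejects files that are empty, missing columns, contain malformed rows
#' (reported with their line numbers) or have non-monotone timestamps
#' (reported with the offending row).
#'
#' @param path CSV path written by [write_gaze_log()] (or the same layout).
#' @return A [gaze_trace()].
#' @export
read_gaze_log <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop("empty gaze log: ", path)
  header <- strsplit(body[1], ",")[[1]]
  miss <- setdiff(.gaze_log_cols, header)
  if (length(miss)) stop("gaze log missing columns: ",
                         paste(miss, collapse = ", "))
  if (length(body) < 2L) stop("gaze log has a header but no samples: ", path)
  df <- utils::read.csv(text = body, check.names = FALSE)
  num <- setdiff(.gaze_log_cols, "valid")
  bad <- which(Reduce(`|`, lapply(df[num], function(x) !is.finite(as.numeric(x)))))
  if (length(bad))
    stop("malformed gaze log rows (line ",
         paste(bad + length(meta) + 1L, collapse = ", "), ")")
  nonmono <- which(diff(df$t) <= 0)
  if (length(nonmono))
    stop("non-monotone timestamps in gaze log at row ", nonmono[1] + 1L,
         " (line ", nonmono[1] + 1L + length(meta) + 1L, ")")
  df$valid <- as.logical(df$valid)
  get_meta <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(m)) as.numeric(sub(".*: *", "", m[1])) else default
  }
  gaze_trace(df[.gaze_log_cols],
             sample_rate = get_meta("sample_rate_hz", 90),
             iod = get_meta("iod_cm", 6.33))
}

# ---- session manifests and directories --------------------------------------

#' Write a session manifest
#'
#' YAML key-value manifest describing one recorded (or simulated) session:
#' game and participant labels, camera parameters (which make the depth
#' codec self-describing), screen optical distance, inter-ocular distance,
#' and the file inventory.
#'
#' @param path Manifest path (YAML).
#' @param game,participant Labels.
#' @param camera A [camera_model()].
#' @param screen_distance_D Screen optical distance in diopters (> 0).
#' @param iod Inter-ocular distance, cm.
#' @param depth_files,gaze_file File names relative to the manifest.
#' @return `path`, invisibly.
#' @export
write_session_manifest <- function(path, game, participant, camera,
                                   screen_distance_D = 1.54, iod = 6.33,
                                   depth_files = character(0),
                                   gaze_file = NULL) {
  stopifnot(screen_distance_D > 0)
  m <- list(game = game, participant = participant,
            camera = list(width = unname(camera$resolution[["width"]]),
                          height = unname(camera$resolution[["height"]]),
                          hfov = camera$hfov, vfov = camera$vfov,
                          near = camera$near, far = camera$far),
            screen_distance_D = screen_distance_D, iod_cm = iod,
            files = list(depth = as.list(depth_files),
                         gaze = gaze_file))
  yaml::write_yaml(m, path)
  invisible(path)
}

#' Read and validate a session manifest
#'
#' @param path Manifest path.
#' @param check_files Verify that every listed file exists next to the
#'   manifest (default TRUE).
#' @return A list with `game`, `participant`, `camera` ([camera_model()]),
#'   `screen_distance_D`, `iod_cm`, `files`.
#' @export
read_session_manifest <- function(path, check_files = TRUE) {
  m <- yaml::read_yaml(path)
  need <- c("game", "participant", "camera", "screen_distance_D",
            "iod_cm", "files")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing fields: ",
                         paste(miss, collapse = ", "))
  if (m$screen_distance_D <= 0) stop("screen optical distance must be > 0")
  cm <- m$camera
  m$camera <- camera_model(cm$width, cm$height, cm$hfov, cm$vfov,
                           cm$near, cm$far)
  if (check_files) {
    listed <- c(unlist(m$files$depth), m$files$gaze)
    missing <- listed[!file.exists(file.path(dirname(path), listed))]
    if (length(missing)) stop("manifest lists missing files: ",
                              paste(missing, collapse = ", "))
  }
  m
}

#' Write a simulated session to a directory
#'
#' Depth frames as 16-bit PNGs named by frame index, the gaze trace as a
#' CSV log, and a manifest tying them together.
#'
#' @param session A list with `frames` and `trace` (see
#'   [simulate_session()]).
#' @param dir Output directory (created if needed).
#' @param game,participant Labels for the manifest.
#' @param ... Passed to [write_session_manifest()].
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, game = "synthetic",
                          participant = "sim", ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  depth_files <- sprintf("frame_%05d.png", seq_along(session$frames))
  for (i in seq_along(session$frames))
    write_depth_png(session$frames[[i]], file.path(dir, depth_files[i]))
  write_gaze_log(session$trace, file.path(dir, "gaze.csv"))
  cam <- if (length(session$frames)) session$frames[[1]]$camera
         else camera_model()
  timestamps <- vapply(session$frames, `[[`, numeric(1), "timestamp")
  writeLines(sprintf("%s,%.6f", depth_files, timestamps),
             file.path(dir, "frames.csv"))
  write_session_manifest(file.path(dir, "manifest.yaml"), game, participant,
                         cam, depth_files = depth_files,
                         gaze_file = "gaze.csv", ...)
  invisible(dir)
}

#' Read a session directory
#'
#' @param dir Directory written by [write_session()].
#' @return List with `manifest`, `frames` (list of [depth_frame()]) and
#'   `trace` ([gaze_trace()]).
#' @export
read_session <- function(dir) {
  manifest <- read_session_manifest(file.path(dir, "manifest.yaml"))
  ft_path <- file.path(dir, "frames.csv")
  ts <- if (file.exists(ft_path)) {
    ftab <- utils::read.csv(ft_path, header = FALSE)
    stats::setNames(ftab[[2]], ftab[[1]])
  } else NULL
  frames <- lapply(unlist(manifest$files$depth), function(f)
    read_depth_png(file.path(dir, f), manifest$camera,
                   timestamp = if (!is.null(ts)) unname(ts[f]) else 0))
  trace <- read_gaze_log(file.path(dir, manifest$files$gaze))
  list(manifest = manifest, frames = frames, trace = trace)
}
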