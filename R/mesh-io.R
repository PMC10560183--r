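#' Read a corresponded mesh sequence from PLY/OBJ files
#'
#' Reads one mesh file per frame, in the order the paths are given, and
#' validates that every frame has the same vertex count (correspondence by
#' index). Units are taken as millimetres as stored; no unit detection is
#' attempted.
#'
#' @param paths character vector of PLY (ascii or binary little-endian) or
#'   OBJ file paths, one per frame, in temporal order.
#' @param fps frame rate of the recording in Hz.
#' @inheritParams mesh_sequence
#' @return A [mesh_sequence].
#' @export
read_mesh_sequence <- function(paths, fps, subject_id = NA_character_,
                               timepoint = NA_character_,
                               expression = NA_character_,
                               fh_normal = NULL) {
  if (length(paths) < 2L)
    stop("need at least two frame files", call. = FALSE)
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    frames[[i]] <- read_mesh_frame(paths[i])
    if (i > 1L && n_vertices(frames[[i]]) != n_vertices(frames[[1L]]))
      stop(sprintf(
        "correspondence error at frame %d ('%s'): %d vertices, expected %d",
        i - 1L, paths[i], n_vertices(frames[[i]]), n_vertices(frames[[1L]])
      ), call. = FALSE)
  }
  mesh_sequence(frames, fps, subject_id = subject_id, timepoint = timepoint,
                expression = expression, fh_normal = fh_normal)
}

#' Read a single mesh frame from a PLY or OBJ file
#'
#' @param path file path; format chosen by extension (`.ply` / `.obj`).
#' @return A [mesh_frame].
#' @export
read_mesh_frame <- function(path) {
  if (!file.exists(path))
    stop(sprintf("mesh file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stop(sprintf("unsupported mesh format '.%s' for '%s'", ext, path),
         call. = FALSE)
  )
}

#' Write a mesh sequence as one file per frame
#'
#' @param sequence a [mesh_sequence].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; frames become `<prefix>_0000.<ext>` etc.
#' @param format `"ply"` or `"obj"`.
#' @param binary write binary little-endian PLY instead of ascii
#'   (PLY only; stores coordinates as float32, the format's customary
#'   vertex type).
#' @return Character vector of written paths, invisibly.
#' @export
write_mesh_sequence <- function(sequence, dir, prefix = "frame",
                                format = c("ply", "obj"), binary = FALSE) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%04d.%s", prefix,
                                  seq_along(sequence$frames) - 1L, format))
  for (i in seq_along(sequence$frames)) {
    if (format == "ply") write_ply(sequence$frames[[i]], paths[i], binary)
    else write_obj(sequence$frames[[i]], paths[i])
  }
  invisible(paths)
}

# ---- PLY ------------------------------------------------------------------
# Minimal PLY support: 'vertex' element with scalar properties including
# x,y,z, and an optional 'face' element with one list property. ascii and
# binary_little_endian, as produced by common mesh tools.

ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L, float = 4L, float32 = 4L,
  double = 8L, float64 = 8L
)

ply_read_scalar <- function(con, type) {
  switch(type,
    char = , int8 = readBin(con, "integer", 1L, size = 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, "integer", 1L, size = 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, "integer", 1L, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, "integer", 1L, size = 4L, endian = "little"),
    float = , float32 = readBin(con, "numeric", 1L, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(con, "numeric", 1L, size = 8L,
                                 endian = "little"),
    stop(sprintf("unsupported PLY property type '%s'", type), call. = FALSE)
  )
}

parse_ply_header <- function(lines, path) {
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop(sprintf("'%s' is not a PLY file (missing 'ply' magic)", path),
         call. = FALSE)
  fmt <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  if (fmt[1L] != "format" ||
      !fmt[2L] %in% c("ascii", "binary_little_endian"))
    stop(sprintf("'%s': unsupported PLY format line '%s'", path, lines[2L]),
         call. = FALSE)
  elements <- list()
  cur <- NULL
  for (ln in lines[-(1:2)]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!length(tok) || tok[1L] == "comment") next
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur))
        stop(sprintf("'%s': property before element in header", path),
             call. = FALSE)
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], type = tok[4L], count_type = tok[3L],
               list = TRUE)
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], type = tok[2L], list = FALSE)
      }
    } else if (tok[1L] == "end_header") {
      break
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex))
    stop(sprintf("'%s': PLY file has no vertex element", path), call. = FALSE)
  list(format = fmt[2L], elements = elements)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines terminated by "end_header"
  header_lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln))
      stop(sprintf("'%s': unexpected end of file in PLY header", path),
           call. = FALSE)
    header_lines <- c(header_lines, ln)
    if (trimws(ln) == "end_header") break
    if (length(header_lines) > 1000L)
      stop(sprintf("'%s': runaway PLY header", path), call. = FALSE)
  }
  hdr <- parse_ply_header(header_lines, path)

  if (hdr$format == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    out <- list()
    for (el in hdr$elements) {
      if (el$count > length(body) - pos)
        stop(sprintf("'%s': truncated PLY body", path), call. = FALSE)
      rows <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      out[[el$name]] <- list(element = el, rows = rows)
    }
    vx <- out$vertex
    pnames <- vapply(vx$element$props, `[[`, "", "name")
    vals <- do.call(rbind, lapply(strsplit(trimws(vx$rows), "\\s+"),
                                  as.numeric))
    need <- match(c("x", "y", "z"), pnames)
    if (anyNA(need))
      stop(sprintf("'%s': PLY vertex element lacks x/y/z", path),
           call. = FALSE)
    vertices <- vals[, need, drop = FALSE]
    faces <- NULL
    if (!is.null(out$face) && out$face$element$count > 0L) {
      faces <- t(vapply(strsplit(trimws(out$face$rows), "\\s+"),
                        function(tok) {
        n <- as.integer(tok[1L])
        if (n != 3L)
          stop(sprintf("'%s': only triangular faces supported", path),
               call. = FALSE)
        as.integer(tok[2:4])
      }, integer(3)))
      faces <- faces + 1L  # PLY face indices are 0-based
    }
  } else {
    els <- hdr$elements
    vertices <- NULL
    faces <- NULL
    for (el in els) {
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        ptypes <- vapply(el$props, `[[`, "", "type")
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          stop(sprintf("'%s': list property on vertex element unsupported",
                       path), call. = FALSE)
        sizes <- ply_type_size[ptypes]
        if (anyNA(sizes))
          stop(sprintf("'%s': unknown PLY property type", path),
               call. = FALSE)
        raw <- readBin(con, "raw", el$count * sum(sizes))
        if (length(raw) < el$count * sum(sizes))
          stop(sprintf("'%s': truncated PLY vertex data", path),
               call. = FALSE)
        rcon <- rawConnection(raw)
        vals <- matrix(NA_real_, el$count, length(pnames))
        for (r in seq_len(el$count))
          for (p in seq_along(pnames))
            vals[r, p] <- as.numeric(ply_read_scalar(rcon, ptypes[p]))
        close(rcon)
        need <- match(c("x", "y", "z"), pnames)
        if (anyNA(need))
          stop(sprintf("'%s': PLY vertex element lacks x/y/z", path),
               call. = FALSE)
        vertices <- vals[, need, drop = FALSE]
      } else if (el$name == "face") {
        lp <- el$props[[1L]]
        if (!lp$list)
          stop(sprintf("'%s': face element without list property", path),
               call. = FALSE)
        faces <- matrix(NA_integer_, el$count, 3L)
        for (r in seq_len(el$count)) {
          n <- ply_read_scalar(con, lp$count_type)
          if (n != 3L)
            stop(sprintf("'%s': only triangular faces supported", path),
                 call. = FALSE)
          for (k in 1:3) faces[r, k] <- ply_read_scalar(con, lp$type)
        }
        faces <- faces + 1L
      } else {
        stop(sprintf("'%s': unsupported PLY element '%s'", path, el$name),
             call. = FALSE)
      }
    }
  }
  mesh_frame(vertices, faces)
}

write_ply <- function(frame, path, binary = FALSE) {
  nv <- nrow(frame$vertices)
  nf <- if (is.null(frame$faces)) 0L else nrow(frame$faces)
  hdr <- c(
    "ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    "comment written by facemotion",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    if (nf > 0L) c(sprintf("element face %d", nf),
                   "property list uchar int vertex_indices"),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.numeric(t(frame$vertices)), con, size = 4L,
             endian = "little")
    if (nf > 0L)
      for (r in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(frame$faces[r, ] - 1L), con, size = 4L,
                 endian = "little")
      }
  } else {
    writeLines(apply(frame$vertices, 1L,
                     function(v) paste(format(v, digits = 9), collapse = " ")),
               con, sep = "\n")
    if (nf > 0L)
      writeLines(apply(frame$faces - 1L, 1L,
                       function(f) paste(c(3L, f), collapse = " ")),
                 con, sep = "\n")
  }
  invisible(path)
}

# ---- OBJ ------------------------------------------------------------------
# Only v and f records are consumed; all other records are skipped (a debug
# message lists the skipped record types). OBJ indices are 1-based on disk.

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keys <- sub("\\s.*$", "", lines)
  vlines <- lines[keys == "v"]
  flines <- lines[keys == "f"]
  skipped <- setdiff(unique(keys), c("v", "f"))
  if (length(skipped))
    message("read_obj: skipping OBJ record types: ",
            paste(skipped, collapse = ", "))
  if (!length(vlines))
    stop(sprintf("'%s': OBJ file has no vertex records", path), call. = FALSE)
  vertices <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v))
      stop(sprintf("'%s': malformed OBJ vertex record '%s'", path,
                   paste(tok, collapse = " ")), call. = FALSE)
    v
  }))
  faces <- NULL
  if (length(flines)) {
    faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(tok) {
      idx <- as.integer(sub("/.*$", "", tok[-1L]))
      if (length(idx) != 3L || anyNA(idx))
        stop(sprintf("'%s': only triangular OBJ faces supported", path),
             call. = FALSE)
      idx
    }))
  }
  mesh_frame(vertices, faces)
}

write_obj <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by facemotion", con)
  writeLines(apply(frame$vertices, 1L, function(v)
    paste(c("v", format(v, digits = 9)), collapse = " ")), con)
  if (!is.null(frame$faces) && nrow(frame$faces) > 0L)
    writeLines(apply(frame$faces, 1L, function(f)
      paste(c("f", f), collapse = " ")), con)
  invisible(path)
}

# ---- landmark map and manifest -------------------------------------------

#' Read a landmark map file
#'
#' The file is flat text, one `name index` pair per line (whitespace
#' separated), `#` starting a comment. Indices in the file are 0-based (the
#' interchange convention shared with ROI exports); they are converted to
#' R's 1-based indexing on read.
#'
#' @param path landmark file path.
#' @param n_vertices optional vertex count to validate indices against.
#' @return A [landmark_map].
#' @export
read_landmark_map <- function(path, n_vertices = NULL) {
  if (!file.exists(path))
    stop(sprintf("landmark file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "\\s+")
  bad <- vapply(tok, length, integer(1)) != 2L
  if (any(bad))
    stop(sprintf("'%s': malformed landmark line '%s'", path,
                 lines[which(bad)[1L]]), call. = FALSE)
  idx0 <- suppressWarnings(as.integer(vapply(tok, `[`, "", 2L)))
  if (anyNA(idx0) || any(idx0 < 0L))
    stop(sprintf("'%s': landmark indices must be non-negative integers",
                 path), call. = FALSE)
  names(idx0) <- vapply(tok, `[`, "", 1L)
  landmark_map(idx0 + 1L, n_vertices = n_vertices)
}

#' Write a landmark map file
#'
#' @param landmarks a [landmark_map].
#' @param path output path; indices are written 0-based.
#' @return `path`, invisibly.
#' @export
write_landmark_map <- function(landmarks, path) {
  writeLines(sprintf("%s %d", names(landmarks), unclass(landmarks) - 1L),
             path)
  invisible(path)
}

#' Read or write a sequence manifest
#'
#' A manifest is a CSV describing a set of recordings: columns
#' `subject_id`, `timepoint`, `expression`, `fps`, `frame`, `path`, one row
#' per frame file. Frame paths are interpreted relative to the manifest's
#' directory unless absolute. Within a recording, frames are ordered by the
#' `frame` column (deterministic ingestion independent of file-name order).
#'
#' @param path manifest CSV path.
#' @return A data.frame of manifest rows.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timepoint", "expression", "fps", "frame", "path")
  missing_cols <- setdiff(need, names(mf))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  mf
}

#' Load all sequences described by a manifest
#'
#' @param manifest a manifest data.frame from [read_manifest()].
#' @param base_dir directory against which relative frame paths resolve.
#' @param fh_normal optional Frankfort Horizontal normal applied to every
#'   sequence (capture-level head-pose calibration).
#' @return Named list of [mesh_sequence] objects, keyed
#'   `subject/timepoint/expression`.
#' @export
load_manifest_sequences <- function(manifest, base_dir = ".",
                                    fh_normal = NULL) {
  key <- interaction(manifest$subject_id, manifest$timepoint,
                     manifest$expression, drop = TRUE, sep = "/")
  out <- list()
  for (k in levels(key)) {
    rows <- manifest[key == k, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", rows$path), rows$path,
                    file.path(base_dir, rows$path))
    out[[k]] <- read_mesh_sequence(
      paths, fps = rows$fps[1L],
      subject_id = as.character(rows$subject_id[1L]),
      timepoint = rows$timepoint[1L], expression = rows$expression[1L],
      fh_normal = fh_normal
    )
  }
  out
}
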