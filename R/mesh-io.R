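# STL (ASCII + binary) and PLY (ASCII + binary little-endian) readers/writers.
# STL stores soup triangles; vertices are merged on read. PLY may carry an
# integer per-face property (e.g. region_id) used as an alternate label dialect.

#' Read a triangle mesh from STL or PLY
#'
#' Format is detected from the file extension and contents. Duplicate vertices
#' within `merge_eps` mm are merged and face indices remapped.
#'
#' @param path mesh file (`.stl` or `.ply`).
#' @param merge_eps vertex merge tolerance in mm.
#' @return a [leg_mesh()]; PLY integer face properties are attached as
#'   attribute `face_props` (data.frame, one row per face).
#' @export
read_mesh <- function(path, merge_eps = 1e-6) {
  if (!file.exists(path)) {
    stop_legalign(sprintf("mesh file not found: %s", path), "legalign_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop_legalign(sprintf("unsupported mesh format '%s' (want .stl or .ply)", ext),
                  "legalign_format_error")
  )
  props <- attr(mesh, "face_props")
  merged <- merge_vertices(mesh, eps = merge_eps)
  if (!is.null(props)) {
    attr(merged, "face_props") <- props[attr(merged, "face_map"), , drop = FALSE]
  }
  validate_mesh(merged)
  merged
}

is_binary_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80) return(FALSE)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(ntri) == 0) return(FALSE)
  expected <- 80 + 4 + 50 * as.numeric(ntri)
  file.size(path) == expected
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", 50 * ntri)
    m <- matrix(raw, nrow = 50)
    floats <- readBin(as.raw(m[1:48, ]), "numeric", 12 * ntri, size = 4,
                      endian = "little")
    tri <- matrix(floats, nrow = 12)  # normal (3) + 3 vertices (9) per column
    verts <- matrix(as.numeric(tri[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop_legalign(sprintf("cannot parse ASCII STL: %s", path), "legalign_format_error")
    }
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  }
  n <- nrow(verts)
  if (n < 12) stop_legalign("STL contains fewer than 4 triangles", "legalign_format_error")
  leg_mesh(verts, matrix(seq_len(n), ncol = 3, byrow = TRUE), validate = FALSE)
}

#' Write a mesh to STL
#'
#' @param mesh a [leg_mesh()].
#' @param path output file.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # 12 floats per triangle (normal + 3 vertices) + 2 attribute bytes
    dat <- t(cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))
    fraw <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
    block <- matrix(as.raw(0L), 50, nrow(f))
    block[1:48, ] <- matrix(fraw, nrow = 48)
    writeBin(as.raw(block), con)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid legalign", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.12g %.12g %.12g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.12g %.12g %.12g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid legalign", con)
  }
  invisible(path)
}

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "numeric", 1, size = sz, endian = "little")
  } else {
    readBin(con, "integer", 1, size = sz, endian = "little",
            signed = !(sz < 4 && grepl("^u", type)))
  }
}

read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  # header is always ASCII lines
  hdr <- character(0)
  repeat {
    line <- readBin(con, "raw", 1)
    buf <- raw(0)
    while (length(line) == 1 && line != as.raw(10L)) {
      buf <- c(buf, line); line <- readBin(con, "raw", 1)
    }
    txt <- trimws(rawToChar(buf))
    hdr <- c(hdr, txt)
    if (txt == "end_header") break
    if (length(hdr) > 200) stop_legalign("PLY header not terminated", "legalign_format_error")
  }
  if (hdr[1] != "ply") stop_legalign("not a PLY file", "legalign_format_error")
  fmt <- strsplit(grep("^format", hdr, value = TRUE)[1], "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop_legalign(sprintf("unsupported PLY format '%s'", fmt), "legalign_format_error")
  }
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (h in hdr) {
    p <- strsplit(h, "\\s+")[[1]]
    if (p[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = p[2], count = as.integer(p[3]), props = list())
    } else if (p[1] == "property" && !is.null(cur)) {
      if (p[2] == "list") {
        cur$props[[p[5]]] <- list(list = TRUE, count_type = p[3], type = p[4])
      } else {
        cur$props[[p[3]]] <- list(list = FALSE, type = p[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop_legalign("PLY lacks vertex or face element", "legalign_format_error")
  }

  if (fmt == "ascii") {
    rest <- strsplit(paste(readLines(con, warn = FALSE), collapse = " "), "\\s+")[[1]]
    rest <- as.numeric(rest[nzchar(rest)])
    pos <- 1
    take <- function(n) { out <- rest[pos:(pos + n - 1)]; pos <<- pos + n; out }
  } else {
    take <- NULL  # binary handled per-property below
  }

  read_element <- function(el) {
    vals <- vector("list", el$count)
    pnames <- names(el$props)
    for (i in seq_len(el$count)) {
      row <- list()
      for (pn in pnames) {
        pr <- el$props[[pn]]
        if (pr$list) {
          cnt <- if (fmt == "ascii") take(1) else ply_read_scalar(con, pr$count_type)
          items <- if (fmt == "ascii") take(cnt) else
            vapply(seq_len(cnt), function(k) ply_read_scalar(con, pr$type), numeric(1))
          row[[pn]] <- items
        } else {
          row[[pn]] <- if (fmt == "ascii") take(1) else ply_read_scalar(con, pr$type)
        }
      }
      vals[[i]] <- row
    }
    vals
  }

  for (nm in names(elements)) elements[[nm]]$data <- read_element(elements[[nm]])

  vdat <- elements$vertex$data
  verts <- cbind(vapply(vdat, `[[`, numeric(1), "x"),
                 vapply(vdat, `[[`, numeric(1), "y"),
                 vapply(vdat, `[[`, numeric(1), "z"))
  fdat <- elements$face$data
  idx_name <- intersect(c("vertex_indices", "vertex_index"), names(elements$face$props))[1]
  if (is.na(idx_name)) {
    stop_legalign("PLY face element lacks vertex_indices", "legalign_format_error")
  }
  fl <- lapply(fdat, `[[`, idx_name)
  if (any(lengths(fl) != 3)) {
    stop_legalign("PLY contains non-triangular faces", "legalign_format_error")
  }
  faces <- matrix(as.integer(unlist(fl)), ncol = 3, byrow = TRUE) + 1L  # 0- to 1-based
  mesh <- leg_mesh(verts, faces, validate = FALSE)
  extra <- setdiff(names(elements$face$props), idx_name)
  if (length(extra)) {
    fp <- as.data.frame(lapply(extra, function(pn) {
      vapply(fdat, function(r) as.numeric(r[[pn]]), numeric(1))
    }))
    names(fp) <- extra
    attr(mesh, "face_props") <- fp
  }
  mesh
}

#' Write a mesh to PLY (ASCII)
#'
#' @param mesh a [leg_mesh()].
#' @param path output file.
#' @param face_props optional data.frame of integer per-face properties
#'   (e.g. `region_id`) written alongside `vertex_indices`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, face_props = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices")
  if (!is.null(face_props)) {
    stopifnot(nrow(face_props) == nrow(f))
    hdr <- c(hdr, sprintf("property int %s", names(face_props)))
  }
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  if (!is.null(face_props)) {
    for (pn in names(face_props)) fl <- paste(fl, as.integer(face_props[[pn]]))
  }
  writeLines(fl, con)
  invisible(path)
}
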