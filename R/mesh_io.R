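#' Read a triangular surface mesh from PLY, STL or OBJ
#'
#' Supported flavours: PLY ascii and binary_little_endian (scalar vertex
#' properties, one face list property), STL ascii and binary, OBJ `v`/`f`
#' records (polygonal faces are fan-triangulated; `v/vt/vn` slashes accepted).
#' Coordinates are kept as stored and assumed to be millimetres. STL files
#' store no shared vertices, so duplicates are always welded on load; for the
#' other formats duplicate vertices within 1e-6 mm are welded. Meshes that
#' remain disconnected after cleanup keep only their largest component, with
#' a warning.
#'
#' @param path file path.
#' @param format "ply", "stl" or "obj"; default inferred from the extension.
#' @param name mesh label; defaults to the file name without extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "stl", "obj"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  raw <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path)
  )
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L) {
    stop("empty mesh in ", path)
  }
  mesh <- triangle_mesh(raw$vertices, raw$faces, name = name, validate = FALSE)
  clean_mesh(mesh, weld_tol = 1e-6, keep_largest = TRUE)
}

#' Write a triangular surface mesh to PLY, STL or OBJ
#'
#' @param mesh a valid [triangle_mesh()].
#' @param path output file path.
#' @param format "ply", "stl" or "obj"; default inferred from the extension.
#' @param binary write binary PLY/STL instead of ascii (ignored for OBJ).
#' @param digits significant digits for ascii output.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE, digits = 9) {
  validate_mesh(mesh)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "stl", "obj"))
  switch(format,
    ply = write_ply(mesh, path, binary = binary, digits = digits),
    stl = write_stl(mesh, path, binary = binary, digits = digits),
    obj = write_obj(mesh, path, digits = digits)
  )
  invisible(path)
}

# ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = n, size = sz, endian = "little")
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", n = n, size = sz, signed = signed || sz >= 4,
            endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = list(name,type,list_count_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], count_type = tok[3], list = TRUE)
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY header missing format line")
  if (!"vertex" %in% names(elements) || !"face" %in% names(elements)) {
    stop("PLY file lacks vertex or face element")
  }
  if (fmt == "ascii") {
    read_ply_ascii(con, elements)
  } else if (fmt == "binary_little_endian") {
    read_ply_binary(con, elements)
  } else {
    stop("unsupported PLY format: ", fmt)
  }
}

read_ply_ascii <- function(con, elements) {
  body <- readLines(con)
  body <- body[nzchar(trimws(body))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    if (el$count == 0L) next
    lines <- body[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
      pn <- vapply(el$props, `[[`, "", "name")
      out$vertices <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
    } else if (el$name == "face") {
      fl <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
      out$faces <- do.call(rbind, lapply(fl, function(r) {
        k <- r[1]
        idx <- r[2:(1 + k)] + 1L
        if (k == 3L) idx else t(vapply(2:(k - 1),
          function(j) c(idx[1], idx[j], idx[j + 1]), integer(3)))
      }))
      if (is.null(dim(out$faces))) out$faces <- matrix(out$faces, ncol = 3)
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    if (el$name == "vertex" && !any(vapply(el$props, `[[`, TRUE, "list"))) {
      types <- vapply(el$props, `[[`, "", "type")
      homog <- length(unique(types)) == 1L
      if (homog) {
        vals <- ply_read_scalar(con, types[1], n = el$count * length(types))
        m <- matrix(vals, ncol = length(types), byrow = TRUE)
      } else {
        m <- matrix(0, el$count, length(types))
        for (i in seq_len(el$count)) {
          for (j in seq_along(types)) m[i, j] <- ply_read_scalar(con, types[j])
        }
      }
      pn <- vapply(el$props, `[[`, "", "name")
      out$vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
    } else if (el$name == "face") {
      p <- el$props[[1]]
      faces <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        k <- ply_read_scalar(con, p$count_type)
        idx <- ply_read_scalar(con, p$type, n = k) + 1L
        faces[[i]] <- if (k == 3L) idx else t(vapply(2:(k - 1),
          function(j) c(idx[1], idx[j], idx[j + 1]), integer(3)))
      }
      out$faces <- do.call(rbind, faces)
      if (is.null(dim(out$faces))) out$faces <- matrix(out$faces, ncol = 3)
    } else {
      # skip unknown scalar element
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (isTRUE(p$list)) {
            k <- ply_read_scalar(con, p$count_type)
            ply_read_scalar(con, p$type, n = k)
          } else ply_read_scalar(con, p$type)
        }
      }
    }
  }
  out
}

write_ply <- function(mesh, path, binary = FALSE, digits = 9) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    vfmt <- paste0("%.", digits, "g")
    vlines <- sprintf(paste(vfmt, vfmt, vfmt),
                      mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
    flines <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                      mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
    writeLines(c(hdr, vlines, flines), path)
  }
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(512, sz))
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !stl_binary_size_matches(path, sz)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  stl_weld(tri)
}

stl_binary_size_matches <- function(path, sz) {
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  sz == 84 + 50 * as.numeric(n)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  vals <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                function(t) as.numeric(t[2:4])))
  if (is.null(vals) || nrow(vals) %% 3 != 0) stop("malformed ascii STL")
  vals
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  tri <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
    tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", n = 2)
  }
  tri
}

stl_weld <- function(tri) {
  # triangle soup -> indexed mesh: exact-match weld then numeric weld in clean_mesh
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  first <- match(key, key)
  keep <- which(first == seq_along(first))
  remap <- match(first, keep)
  list(vertices = tri[keep, , drop = FALSE],
       faces = matrix(remap, ncol = 3, byrow = TRUE))
}

write_stl <- function(mesh, path, binary = FALSE, digits = 9) {
  fn <- face_normals(mesh)$normals
  v <- mesh$vertices
  f <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(fn[i, ], t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    g <- paste0("%.", digits, "g")
    out <- c(sprintf("solid %s", mesh$name))
    for (i in seq_len(nrow(f))) {
      out <- c(out,
        sprintf(paste("facet normal", g, g, g), fn[i, 1], fn[i, 2], fn[i, 3]),
        "  outer loop",
        sprintf(paste("    vertex", g, g, g),
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "  endloop", "endfacet")
    }
    writeLines(c(out, sprintf("endsolid %s", mesh$name)), path)
  }
  invisible(path)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  vertices <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(t) as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    idx <- as.integer(vapply(strsplit(t[-1], "/", fixed = TRUE), `[[`, "", 1L))
    idx <- ifelse(idx < 0L, nrow(vertices) + 1L + idx, idx)  # negative = relative
    if (length(idx) == 3L) idx else t(vapply(2:(length(idx) - 1),
      function(j) c(idx[1], idx[j], idx[j + 1]), integer(3)))
  }))
  if (is.null(dim(faces)) && !is.null(faces)) faces <- matrix(faces, ncol = 3)
  list(vertices = vertices, faces = faces)
}

write_obj <- function(mesh, path, digits = 9) {
  g <- paste0("%.", digits, "g")
  vlines <- sprintf(paste("v", g, g, g), mesh$vertices[, 1],
                    mesh$vertices[, 2], mesh$vertices[, 3])
  flines <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                    mesh$faces[, 3])
  writeLines(c(sprintf("# %s", mesh$name), vlines, flines), path)
  invisible(path)
}
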