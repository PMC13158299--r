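#' Triangle mesh
#'
#' @param vertices v x 3 numeric matrix (mm).
#' @param faces f x 3 integer matrix of 1-based vertex indices.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be v x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  # reject degenerate zero-area faces
  for (i in seq_len(nrow(faces))) {
    a <- vertices[faces[i, 1L], ]; b <- vertices[faces[i, 2L], ]
    c_ <- vertices[faces[i, 3L], ]
    cr <- c((b - a)[2L] * (c_ - a)[3L] - (b - a)[3L] * (c_ - a)[2L],
            (b - a)[3L] * (c_ - a)[1L] - (b - a)[1L] * (c_ - a)[3L],
            (b - a)[1L] * (c_ - a)[2L] - (b - a)[2L] * (c_ - a)[1L])
    if (sum(cr^2) < 1e-24) stop("degenerate zero-area face at row ", i)
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read landmark configurations
#'
#' Supported formats: `csv` (columns name,x,y,z; `NA` cells mark missing
#' landmarks), the `tps` dialect (`LM3=` blocks, one specimen per block,
#' missing landmarks coded as -9999 triplets) and `nts` (Sample x Variables
#' header; -999 missing code).
#'
#' @param path file path.
#' @param format `"csv"`, `"tps"` or `"nts"`; guessed from the extension
#'   when missing.
#' @return for `csv`, a single [landmark_config]; for `tps`/`nts`, a list
#'   of them (one per specimen).
#' @export
read_landmarks <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "tps", "nts"))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("CSV must have columns name,x,y,z (got: ",
           paste(names(df), collapse = ","), ")")
    coords <- as.matrix(df[, c("x", "y", "z")])
    landmark_config(coords,
                    specimen_id = sub("\\.[^.]*$", "", basename(path)),
                    landmark_names = df$name)
  } else if (format == "tps") {
    lines <- readLines(path)
    out <- list()
    i <- 1L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (grepl("^LM3?\\s*=", ln, ignore.case = TRUE)) {
        k <- as.integer(sub("^LM3?\\s*=\\s*", "", ln, ignore.case = TRUE))
        if (is.na(k)) stop("unparseable LM header at line ", i)
        block <- lines[(i + 1L):(i + k)]
        vals <- lapply(seq_along(block), function(j) {
          v <- suppressWarnings(as.numeric(strsplit(trimws(block[j]),
                                                    "\\s+")[[1L]]))
          if (length(v) != 3L || anyNA(v))
            stop("unparseable coordinate row at line ", i + j)
          v
        })
        coords <- do.call(rbind, vals)
        coords[coords <= -9998] <- NA
        i <- i + k + 1L
        id <- paste0("specimen", length(out) + 1L)
        while (i <= length(lines) &&
               grepl("^(ID|IMAGE|SCALE)\\s*=", trimws(lines[i]),
                     ignore.case = TRUE)) {
          if (grepl("^ID\\s*=", trimws(lines[i]), ignore.case = TRUE))
            id <- sub("^ID\\s*=\\s*", "", trimws(lines[i]),
                      ignore.case = TRUE)
          i <- i + 1L
        }
        out <- c(out, list(landmark_config(coords, specimen_id = id)))
      } else i <- i + 1L
    }
    ks <- vapply(out, function(x) nrow(x$coords), 1L)
    if (length(unique(ks)) > 1L)
      stop("inconsistent landmark counts across specimens: ",
           paste(unique(ks), collapse = ","))
    out
  } else {
    lines <- lines_strip <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "\"")]
    toks <- strsplit(lines[1L], "\\s+")[[1L]]
    hdr <- suppressWarnings(as.numeric(sub("[A-Za-z]$", "", toks)))
    n <- hdr[2L]; p <- hdr[4L]
    if (anyNA(c(n, p))) stop("unparseable NTS header")
    k <- p / 3L
    vals <- suppressWarnings(as.numeric(unlist(strsplit(lines[-1L],
                                                        "\\s+"))))
    vals <- vals[!is.na(vals) | TRUE]
    if (length(vals) < n * p) stop("too few values in NTS body")
    vals[vals <= -998] <- NA
    lapply(seq_len(n), function(i) {
      m <- matrix(vals[((i - 1L) * p + 1L):(i * p)], k, 3L, byrow = TRUE)
      landmark_config(m, specimen_id = paste0("specimen", i))
    })
  }
}

#' Write a landmark configuration
#'
#' @param config a [landmark_config] (or list of them, for `tps`).
#' @param path output path.
#' @param format `"csv"` (canonical interchange; `NA` cells for missing
#'   landmarks) or `"tps"`.
#' @export
write_landmarks <- function(config, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "tps"))
  if (format == "csv") {
    stopifnot(inherits(config, "landmark_config"))
    coords <- config$coords
    coords[config$missing, ] <- NA
    df <- data.frame(name = config$landmark_names, x = coords[, 1L],
                     y = coords[, 2L], z = coords[, 3L])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (inherits(config, "landmark_config")) config <- list(config)
    con <- file(path, "w")
    on.exit(close(con))
    for (cfg in config) {
      coords <- cfg$coords
      coords[cfg$missing, ] <- -9999
      writeLines(sprintf("LM3=%d", nrow(coords)), con)
      writeLines(apply(coords, 1L, function(r)
        paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
              collapse = " ")), con)
      writeLines(sprintf("ID=%s", cfg$specimen_id), con)
    }
  }
  invisible(path)
}

#' Read a triangle mesh (PLY, OBJ or ASCII STL)
#'
#' ASCII and binary-little-endian PLY, Wavefront OBJ (v/f records,
#' triangles) and ASCII STL are supported.
#'
#' @param path file path; format guessed from the extension unless given.
#' @param format `"ply"`, `"obj"` or `"stl"`.
#' @return a [triangle_mesh].
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "obj", "stl"))
  if (format == "ply") read_ply(path)
  else if (format == "obj") read_obj(path)
  else read_stl_ascii(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    trimws(rawToChar(chars))
  }
  if (read_hline() != "ply") stop("malformed PLY header: missing magic")
  fmt <- NULL; nv <- NULL; nf <- NULL
  vprops <- character(0)
  current <- ""
  repeat {
    ln <- read_hline()
    if (ln == "end_header") break
    w <- strsplit(ln, "\\s+")[[1L]]
    if (w[1L] == "format") fmt <- w[2L]
    else if (w[1L] == "element") {
      current <- w[2L]
      if (w[2L] == "vertex") nv <- as.integer(w[3L])
      if (w[2L] == "face") nf <- as.integer(w[3L])
    } else if (w[1L] == "property" && current == "vertex" &&
               w[2L] != "list") vprops <- c(vprops, w[3L])
  }
  if (is.null(fmt) || is.null(nv) || is.null(nf))
    stop("malformed PLY header")
  ix <- match(c("x", "y", "z"), vprops)
  if (anyNA(ix)) stop("PLY vertex element lacks x/y/z")
  np <- length(vprops)
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vv <- t(vapply(body[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])[seq_len(np)],
      numeric(np)))
    verts <- vv[, ix, drop = FALSE]
    ff <- t(vapply(body[nv + seq_len(nf)], function(l) {
      v <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
      if (v[1L] != 3L) stop("only triangular faces are supported")
      v[2:4]
    }, integer(3L)))
  } else if (fmt == "binary_little_endian") {
    vv <- matrix(readBin(con, "numeric", nv * np, size = 4L,
                         endian = "little"), nv, np, byrow = TRUE)
    verts <- vv[, ix, drop = FALSE]
    ff <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1L))
      if (cnt != 3L) stop("only triangular faces are supported")
      ff[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    }
  } else stop("unsupported PLY format: ", fmt)
  dimnames(verts) <- NULL
  triangle_mesh(verts, ff + 1L)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- t(vapply(vl, function(l)
    as.numeric(strsplit(trimws(sub("^v", "", l)), "\\s+")[[1L]])[1:3],
    numeric(3L)))
  faces <- t(vapply(fl, function(l) {
    toks <- strsplit(trimws(sub("^f", "", l)), "\\s+")[[1L]]
    if (length(toks) != 3L) stop("only triangular faces are supported")
    as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
  }, integer(3L)))
  dimnames(verts) <- NULL
  dimnames(faces) <- NULL
  triangle_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path))
  vl <- lines[startsWith(lines, "vertex")]
  pts <- t(vapply(vl, function(l) {
    toks <- strsplit(l, "\\s+")[[1L]]
    as.numeric(toks[-1L])[1:3]
  }, numeric(3L)))
  if (nrow(pts) %% 3L != 0L) stop("malformed STL: vertex count not /3")
  # merge coincident vertices
  key <- apply(round(pts, 9L), 1L, paste, collapse = "_")
  uk <- !duplicated(key)
  verts <- pts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format `"ply"` (default) or `"obj"`.
#' @param binary logical; write binary-little-endian PLY instead of ASCII.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "obj"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
    return(invisible(path))
  }
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4L,
             endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                       mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Parses a Newick file or string into an `ape::phylo` tree (rooted trees
#' with branch lengths; polytomies allowed).
#'
#' @param path_or_text file path, or Newick text containing `(`.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(path_or_text) {
  txt <- if (grepl("\\(", path_or_text)) path_or_text
  else paste(readLines(path_or_text), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick input (", n_open, " '(' vs ",
         n_close, " ')')")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("failed to parse Newick input")
  tr
}
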