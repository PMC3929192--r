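#' Read and write triangle meshes (PLY, OFF, VTK legacy)
#'
#' ASCII mesh exchange in the three formats the pipeline emits.  The format
#' is inferred from the file extension (`.ply`, `.off`, `.vtk`).
#' Connectivity round-trips exactly; coordinates round-trip at the printed
#' precision (17 significant digits, i.e. bit-faithful for doubles).  PLY
#' can carry per-vertex scalar properties and 8-bit RGB colors; OFF and VTK
#' write geometry only.  Non-triangular faces in an input file are an
#' error — no implicit triangulation is performed.
#'
#' @param path file path; extension selects the format.
#' @param mesh a `triangle_mesh`.
#' @param per_vertex_scalars optional named list/data frame of numeric
#'   vectors (one value per vertex) written as extra PLY vertex properties.
#' @param per_vertex_colors optional character vector of hex colors (one
#'   per vertex), written as `uchar red/green/blue` PLY properties.
#' @return `read_mesh()`: a `triangle_mesh` (with a `scalars` attribute if
#'   the PLY carried extra properties); `write_mesh()`: `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, per_vertex_scalars = NULL,
                       per_vertex_colors = NULL) {
  fmt <- tolower(tools::file_ext(path))
  switch(fmt,
         ply = write_ply(mesh, path, per_vertex_scalars, per_vertex_colors),
         off = write_off(mesh, path),
         vtk = write_vtk(mesh, path),
         stop("unsupported mesh format: .", fmt))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- tolower(tools::file_ext(path))
  switch(fmt,
         ply = read_ply(path),
         off = read_off(path),
         vtk = read_vtk(path),
         stop("unsupported mesh format: .", fmt))
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

write_ply <- function(mesh, path, scalars = NULL, colors = NULL) {
  nv <- n_vertices(mesh)
  props <- c("property float64 x", "property float64 y", "property float64 z")
  cols <- lapply(1:3, function(k) fmt_num(mesh$vertices[, k]))
  if (!is.null(scalars)) {
    for (nm in names(scalars)) {
      v <- scalars[[nm]]
      if (length(v) != nv) stop("scalar '", nm, "' has wrong length")
      props <- c(props, paste("property float64", nm))
      cols <- c(cols, list(fmt_num(as.numeric(v))))
    }
  }
  if (!is.null(colors)) {
    if (length(colors) != nv) stop("colors must have one entry per vertex")
    rgb <- t(grDevices::col2rgb(colors))
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
    cols <- c(cols, list(rgb[, 1], rgb[, 2], rgb[, 3]))
  }
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nv), props,
              paste("element face", n_faces(mesh)),
              "property list uchar int vertex_indices", "end_header")
  vlines <- do.call(paste, cols)
  flines <- paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not an ascii PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header has no end_header")
  hdr <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", hdr)))
    stop("only ascii PLY is supported")
  # parse elements and their properties in order
  elems <- list(); cur <- NULL
  for (l in hdr) {
    tok <- strsplit(l, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = character(0),
                           list_prop = FALSE)
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        elems[[cur]]$list_prop <- TRUE
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
      }
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY must declare vertex and face elements")
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$n; nf <- elems$face$n
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vmat <- matrix(as.numeric(unlist(vtok)), nrow = nv, byrow = TRUE)
  colnames(vmat) <- elems$vertex$props
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  cnt <- vapply(ftok, function(x) as.integer(x[1]), integer(1))
  if (any(cnt != 3L))
    stop("non-triangular face(s) in PLY (counts: ",
         paste(unique(cnt), collapse = ", "), "); triangulate first")
  fmat <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))),
                 ncol = 3, byrow = TRUE) + 1L
  m <- triangle_mesh(vmat[, c("x", "y", "z"), drop = FALSE], fmat)
  extra <- setdiff(colnames(vmat), c("x", "y", "z", "red", "green", "blue"))
  if (length(extra))
    attr(m, "scalars") <- as.data.frame(vmat[, extra, drop = FALSE])
  if (all(c("red", "green", "blue") %in% colnames(vmat)))
    attr(m, "colors") <- grDevices::rgb(vmat[, "red"], vmat[, "green"],
                                        vmat[, "blue"], maxColorValue = 255)
  m
}

write_off <- function(mesh, path) {
  writeLines(c("OFF",
               paste(n_vertices(mesh), n_faces(mesh), 0),
               do.call(paste, lapply(1:3, function(k) fmt_num(mesh$vertices[, k]))),
               paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L)),
             path)
}

read_off <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtok <- strsplit(lines[2 + seq_len(nv)], "\\s+")
  vmat <- matrix(as.numeric(unlist(vtok)), nrow = nv, byrow = TRUE)[, 1:3,
                                                                    drop = FALSE]
  ftok <- strsplit(lines[2 + nv + seq_len(nf)], "\\s+")
  cnt <- vapply(ftok, function(x) as.integer(x[1]), integer(1))
  if (any(cnt != 3L)) stop("non-triangular face(s) in OFF; triangulate first")
  fmat <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))),
                 ncol = 3, byrow = TRUE) + 1L
  triangle_mesh(vmat, fmat)
}

write_vtk <- function(mesh, path) {
  nf <- n_faces(mesh)
  writeLines(c("# vtk DataFile Version 3.0",
               "triangle mesh", "ASCII", "DATASET POLYDATA",
               paste("POINTS", n_vertices(mesh), "double"),
               do.call(paste, lapply(1:3, function(k) fmt_num(mesh$vertices[, k]))),
               paste("POLYGONS", nf, 4L * nf),
               paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L)),
             path)
}

read_vtk <- function(path) {
  lines <- trimws(readLines(path))
  if (!grepl("^# vtk DataFile", lines[1])) stop("not a VTK legacy file: ", path)
  if (!any(toupper(lines) == "DATASET POLYDATA"))
    stop("only DATASET POLYDATA is supported")
  pts_at <- grep("^POINTS", toupper(lines))
  if (length(pts_at) != 1L) stop("VTK file must have one POINTS section")
  nv <- as.integer(strsplit(lines[pts_at], "\\s+")[[1]][2])
  # point coordinates may wrap across lines: collect numbers until 3*nv read
  nums <- numeric(0); i <- pts_at
  while (length(nums) < 3L * nv) {
    i <- i + 1L
    nums <- c(nums, as.numeric(strsplit(lines[i], "\\s+")[[1]]))
  }
  vmat <- matrix(nums[seq_len(3L * nv)], ncol = 3, byrow = TRUE)
  poly_at <- grep("^POLYGONS", toupper(lines))
  if (length(poly_at) != 1L) stop("VTK POLYDATA must have a POLYGONS section")
  nf <- as.integer(strsplit(lines[poly_at], "\\s+")[[1]][2])
  ftok <- strsplit(lines[poly_at + seq_len(nf)], "\\s+")
  cnt <- vapply(ftok, function(x) as.integer(x[1]), integer(1))
  if (any(cnt != 3L)) stop("non-triangular polygon(s) in VTK; triangulate first")
  fmat <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))),
                 ncol = 3, byrow = TRUE) + 1L
  triangle_mesh(vmat, fmat)
}
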