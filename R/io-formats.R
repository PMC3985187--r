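# Readers/writers for the package's exchange formats: legacy-ASCII VTK and
# OBJ for meshes (with per-element stress/fiber arrays), JSON for cell
# polygons, CSV for curves/tables, ImageJ .roi / RoiSet.zip for polygonal
# regions, and a run-manifest helper.

#' Write a surface mesh (plus element fields) as legacy ASCII VTK
#'
#' @param mesh a `surface_mesh`.
#' @param path output `.vtk` file.
#' @param element_data named list of per-element vectors (scalars) or
#'   3-column matrices (vectors), e.g. sigma1 / dir1 from a stress field.
#' @param X optional deformed coordinates to write instead of the reference.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, element_data = list(), X = NULL) {
  if (is.null(X)) X <- mesh$vertices
  con <- file(path, "w")
  on.exit(close(con))
  nT <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               "pavemech surface mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(X), "double")), con)
  writeLines(paste(X[, 1L], X[, 2L], X[, 3L]), con)
  writeLines(paste("CELLS", nT, 4L * nT), con)
  writeLines(paste(3L, mesh$triangles[, 1L] - 1L, mesh$triangles[, 2L] - 1L,
                   mesh$triangles[, 3L] - 1L), con)
  writeLines(paste("CELL_TYPES", nT), con)
  writeLines(as.character(rep(5L, nT)), con)
  element_data <- c(list(cell_label = mesh$cell,
                         thickness = mesh$thickness), element_data)
  writeLines(paste("CELL_DATA", nT), con)
  for (nm in names(element_data)) {
    v <- element_data[[nm]]
    if (is.matrix(v) && ncol(v) == 3L) {
      writeLines(paste("VECTORS", nm, "double"), con)
      writeLines(paste(v[, 1L], v[, 2L], v[, 3L]), con)
    } else {
      writeLines(c(paste("SCALARS", nm, "double", 1L),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(as.numeric(v)), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_vtk()]
#'
#' @param path `.vtk` file.
#' @return list: `mesh` (a `surface_mesh` with cell labels and thickness
#'   restored), `element_data` (named list of the remaining arrays).
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1L]
  if (is.na(ip)) stop("not a VTK file produced by write_vtk (no POINTS)")
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1L]][2L])
  pts <- matrix(as.numeric(unlist(strsplit(ln[(ip + 1L):(ip + np)], "\\s+"))),
                ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1L]
  nc <- as.integer(strsplit(ln[ic], "\\s+")[[1L]][2L])
  cel <- matrix(as.integer(unlist(strsplit(ln[(ic + 1L):(ic + nc)], "\\s+"))),
                ncol = 4L, byrow = TRUE)
  tri <- cel[, 2:4, drop = FALSE] + 1L
  ed <- list()
  i <- grep("^CELL_DATA", ln)[1L]
  if (!is.na(i)) {
    i <- i + 1L
    while (i <= length(ln)) {
      hd <- strsplit(ln[i], "\\s+")[[1L]]
      if (hd[1L] == "SCALARS") {
        vals <- as.numeric(ln[(i + 2L):(i + 1L + nc)])
        ed[[hd[2L]]] <- vals
        i <- i + 2L + nc
      } else if (hd[1L] == "VECTORS") {
        vals <- matrix(as.numeric(unlist(strsplit(ln[(i + 1L):(i + nc)],
                                                  "\\s+"))),
                       ncol = 3L, byrow = TRUE)
        ed[[hd[2L]]] <- vals
        i <- i + 1L + nc
      } else i <- i + 1L
    }
  }
  cellv <- if (!is.null(ed$cell_label)) as.integer(ed$cell_label) else 1L
  thick <- if (!is.null(ed$thickness)) ed$thickness else 1
  ed$cell_label <- NULL; ed$thickness <- NULL
  list(mesh = surface_mesh(pts, tri, cell = cellv, thickness = thick),
       element_data = ed)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a `surface_mesh`.
#' @param path output `.obj` file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1L], mesh$vertices[, 2L],
                   mesh$vertices[, 3L]), con)
  writeLines(paste("f", mesh$triangles[, 1L], mesh$triangles[, 2L],
                   mesh$triangles[, 3L]), con)
  invisible(path)
}

#' Write / read cell polygons as JSON
#'
#' The JSON dialect is a list of cells, each an array of [x, y] vertex pairs
#' (micrometers).
#'
#' @param polygons list of n x 2 matrices, or a `cell_complex`.
#' @param path JSON file.
#' @return `path` invisibly (write); list of matrices (read).
#' @export
write_polygons_json <- function(polygons, path) {
  if (inherits(polygons, "cell_complex"))
    polygons <- lapply(seq_along(polygons$cells),
                       function(i) cell_ring(polygons, i))
  jsonlite::write_json(lapply(polygons, function(m) unname(as.matrix(m))),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_json
#' @export
read_polygons_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(cell) {
    m <- do.call(rbind, lapply(cell, function(v) as.numeric(unlist(v))))
    if (is.null(m) || ncol(m) != 2L)
      stop("polygon JSON entries must be lists of [x, y] pairs")
    m
  })
}

#' Write an ImageJ polygon ROI file
#'
#' Emits the classic binary `.roi` record (type polygon, integer
#' coordinates) understood by ImageJ's ROI manager. Used mainly to build
#' test fixtures in code.
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates.
#' @param path output `.roi` file.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(vertices, path) {
  v <- round(as.matrix(vertices))
  left <- min(v[, 1L]); top <- min(v[, 2L])
  con <- file(path, "wb")
  on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "big")
  writeChar("Iout", con, nchars = 4L, eos = NULL)
  wb2(228L)                                    # version
  writeBin(as.integer(c(0L, 0L)), con, size = 1L) # type polygon, pad
  wb2(c(top, left, max(v[, 2L]), max(v[, 1L]))) # top left bottom right
  wb2(nrow(v))                                 # n coordinates
  writeBin(raw(64L - 18L), con)                # rest of the 64-byte header
  wb2(v[, 1L] - left)
  wb2(v[, 2L] - top)
  invisible(path)
}

#' Read an ImageJ ROI file (polygon type) or a RoiSet zip
#'
#' Only polygon-type ROIs (type code 0) are decoded.
#'
#' @param path a `.roi` file or a `.zip` of them.
#' @return for `.roi`, an n x 2 vertex matrix; for `.zip`, a named list of
#'   matrices.
#' @export
read_imagej_roi <- function(path) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    tmp <- tempfile("rois")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    files <- utils::unzip(path, exdir = tmp)
    out <- lapply(files, read_imagej_roi)
    names(out) <- sub("\\.roi$", "", basename(files), ignore.case = TRUE)
    return(out)
  }
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:4]) != "Iout") stop("not an ImageJ ROI file (magic)")
  rb2 <- function(off) 256L * as.integer(raw[off + 1L]) +
    as.integer(raw[off + 2L]) # big-endian u16, 0-based offset
  type <- as.integer(raw[7L])
  if (type != 0L) stop("only polygon ROIs are supported (type ", type, ")")
  top <- rb2(8L); left <- rb2(10L)
  n <- rb2(16L)
  x <- vapply(seq_len(n) - 1L, function(i) rb2(64L + 2L * i), 0L) + left
  y <- vapply(seq_len(n) - 1L, function(i) rb2(64L + 2L * n + 2L * i), 0L) + top
  cbind(x = x, y = y)
}

#' Write force curves as a CSV bundle
#'
#' One CSV with columns `row`, `col`, `separation_nm`, `force_nN`,
#' `segment`.
#'
#' @param grid a `force_curve_grid`.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_force_curves_csv <- function(grid, path) {
  stopifnot(inherits(grid, "force_curve_grid"))
  rows <- lapply(seq_along(grid$curves), function(k) {
    cv <- grid$curves[[k]]
    i <- (k - 1L) %/% grid$shape[2L] + 1L
    j <- (k - 1L) %% grid$shape[2L] + 1L
    data.frame(row = i, col = j, separation_nm = cv$separation,
               force_nN = cv$force, segment = cv$segment)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_curves_csv
#' @export
read_force_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  shape <- c(max(df$row), max(df$col))
  curves <- vector("list", prod(shape))
  for (k in seq_len(prod(shape))) {
    i <- (k - 1L) %/% shape[2L] + 1L
    j <- (k - 1L) %% shape[2L] + 1L
    sub <- df[df$row == i & df$col == j, , drop = FALSE]
    curves[[k]] <- force_curve(sub$separation_nm, sub$force_nN, sub$segment)
  }
  structure(list(curves = curves, shape = shape, spec = NULL),
            class = "force_curve_grid")
}

#' Write a run manifest
#'
#' Every analysis run can echo its full effective configuration (parameters,
#' seeds, package version) next to its outputs, so the run is reproducible
#' from the manifest alone.
#'
#' @param config named list (e.g. a [load_config()] result).
#' @param path output JSON file.
#' @param seed the seed in effect.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, seed = NULL) {
  payload <- list(
    package = "pavemech",
    version = as.character(utils::packageVersion("pavemech")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
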