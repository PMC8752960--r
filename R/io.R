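# Mesh and table I/O: ASCII VTU (unstructured grid) with the boundary
# triangles carried as labelled surface cells, CARP-style .pts/.elem/.lon
# text triples, and tidy CSV/JSON exports.

surface_label_codes <- c(LV_ENDO = 1L, RV_ENDO = 2L, EPI = 3L, BASE = 4L)
region_codes <- c(LV_WALL = 1L, RV_WALL = 2L)

#' Assemble and validate a ventricular mesh from raw arrays
#'
#' Entry point for externally supplied meshes. Tetrahedra with negative
#' signed volume are reoriented; all invariants are then checked.
#'
#' @param nodes n x 3 numeric matrix of coordinates, mm.
#' @param tets m x 4 integer matrix of 1-based node indices.
#' @param fibre m x 3 matrix of unit fibre vectors.
#' @param region Character vector (`"LV_WALL"`/`"RV_WALL"`) per element.
#' @param boundary_tris b x 3 matrix of boundary-triangle node indices.
#' @param boundary_labels Character vector of surface labels per triangle.
#' @return A validated `ventricular_mesh`.
#' @export
mesh_from_arrays <- function(nodes, tets, fibre, region,
                             boundary_tris = NULL, boundary_labels = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  tets <- orient_tets(nodes, tets)
  bf <- boundary_faces(tets, nrow(nodes))
  if (is.null(boundary_tris)) {
    abort("boundary triangles with surface labels are required",
          class = "quadlead_label_error")
  }
  bt <- as.matrix(boundary_tris); storage.mode(bt) <- "integer"
  key <- function(tr) {
    a <- pmin(tr[, 1], tr[, 2], tr[, 3]); cm <- pmax(tr[, 1], tr[, 2], tr[, 3])
    b <- tr[, 1] + tr[, 2] + tr[, 3] - a - cm
    paste(a, b, cm)
  }
  idx <- match(key(bf$tris), key(bt))
  if (anyNA(idx)) {
    abort("supplied boundary triangles do not cover the mesh boundary",
          class = "quadlead_label_error")
  }
  boundary <- list(tris = bf$tris, owner = bf$owner,
                   label = as.character(boundary_labels)[idx])
  mesh <- new_ventricular_mesh(nodes, as.matrix(fibre), region = region,
                               tets = tets, boundary = boundary)
  validate_ventricular_mesh(mesh)
  mesh
}

#' Write a mesh to an ASCII VTU file
#'
#' Writes the tetrahedra plus the labelled boundary triangles as a mixed
#' unstructured grid. Element arrays `fibre` (3 components), `region` and
#' `surface_label` (0 on volume cells) are always written; additional
#' per-node arrays can be supplied.
#'
#' @param mesh A `ventricular_mesh`.
#' @param path Output file.
#' @param point_data Named list of per-node vectors (or 3-column matrices).
#' @param cell_data Named list of per-element vectors (padded with `NA` on
#'   the boundary-triangle cells).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets); b <- nrow(mesh$boundary$tris)
  num <- function(x) {
    x <- as.numeric(x); x[is.na(x)] <- -1
    paste(format(x, trim = TRUE, digits = 17, scientific = FALSE), collapse = " ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m + b)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w('%s', num(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  conn <- c(as.vector(t(mesh$tets - 1L)), as.vector(t(mesh$boundary$tris - 1L)))
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w('%s', paste(conn, collapse = " "))
  w('        </DataArray>')
  offs <- c(seq_len(m) * 4L, m * 4L + seq_len(b) * 3L)
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w('%s', paste(offs, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w('%s', paste(c(rep(10L, m), rep(5L, b)), collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData>')
  w('        <DataArray type="Int32" Name="region" format="ascii">')
  w('%s', paste(c(region_codes[mesh$region], rep(0L, b)), collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="surface_label" format="ascii">')
  w('%s', paste(c(rep(0L, m), surface_label_codes[mesh$boundary$label]),
                collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Float64" Name="fibre" NumberOfComponents="3" format="ascii">')
  w('%s', num(cbind(t(mesh$fibre), matrix(0, 3, b))))
  w('        </DataArray>')
  for (nmx in names(cell_data)) {
    w('        <DataArray type="Float64" Name="%s" format="ascii">', nmx)
    w('%s', num(c(cell_data[[nmx]], rep(NA, b))))
    w('        </DataArray>')
  }
  w('      </CellData>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nmx in names(point_data)) {
      v <- point_data[[nmx]]
      if (is.matrix(v)) {
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
          nmx, ncol(v))
        w('%s', num(t(v)))
      } else {
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nmx)
        w('%s', num(v))
      }
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a mesh from an ASCII VTU file written by [write_vtu()]
#'
#' @param path VTU file.
#' @return A list with the validated `ventricular_mesh` and any extra
#'   `point_data` / `cell_data` arrays.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_arr <- function(xpath, name = NULL) {
    node <- if (is.null(name)) xml2::xml_find_first(piece, xpath) else
      xml2::xml_find_first(piece, sprintf("%s[@Name='%s']", xpath, name))
    if (inherits(node, "xml_missing")) return(NULL)
    vals <- scan(text = xml2::xml_text(node), quiet = TRUE)
    nc <- xml2::xml_attr(node, "NumberOfComponents")
    attr(vals, "ncomp") <- if (is.na(nc)) 1L else as.integer(nc)
    vals
  }
  pts <- get_arr("./Points/DataArray")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- as.integer(get_arr("./Cells/DataArray", "connectivity"))
  offs <- as.integer(get_arr("./Cells/DataArray", "offsets"))
  types <- as.integer(get_arr("./Cells/DataArray", "types"))
  starts <- c(1L, head(offs, -1) + 1L)
  is_tet <- types == 10L
  tets <- do.call(rbind, lapply(which(is_tet), function(i)
    conn[starts[i]:offs[i]])) + 1L
  tris <- do.call(rbind, lapply(which(types == 5L), function(i)
    conn[starts[i]:offs[i]])) + 1L
  region_raw <- get_arr("./CellData/DataArray", "region")
  lab_raw <- get_arr("./CellData/DataArray", "surface_label")
  fib_raw <- get_arr("./CellData/DataArray", "fibre")
  fib <- matrix(fib_raw, ncol = 3, byrow = TRUE)[is_tet, , drop = FALSE]
  region <- names(region_codes)[region_raw[is_tet]]
  labels <- names(surface_label_codes)[lab_raw[!is_tet]]
  mesh <- mesh_from_arrays(nodes, tets, fib, region, tris, labels)
  known <- c("connectivity", "offsets", "types", "region", "surface_label", "fibre")
  cd_nodes <- xml2::xml_find_all(piece, "./CellData/DataArray")
  cell_data <- list()
  for (nd in cd_nodes) {
    nmx <- xml2::xml_attr(nd, "Name")
    if (nmx %in% known) next
    v <- scan(text = xml2::xml_text(nd), quiet = TRUE)[is_tet]
    v[v == -1] <- NA
    cell_data[[nmx]] <- v
  }
  pd_nodes <- xml2::xml_find_all(piece, "./PointData/DataArray")
  point_data <- list()
  for (nd in pd_nodes) {
    nmx <- xml2::xml_attr(nd, "Name")
    nc <- xml2::xml_attr(nd, "NumberOfComponents")
    ncomp <- if (is.na(nc)) 1L else as.integer(nc)
    v <- scan(text = xml2::xml_text(nd), quiet = TRUE)
    point_data[[nmx]] <- if (ncomp > 1) matrix(v, ncol = ncomp, byrow = TRUE) else v
  }
  list(mesh = mesh, point_data = point_data, cell_data = cell_data)
}

#' Write / read a mesh as a CARP-style text triple
#'
#' `<base>.pts` (node count + coordinates), `<base>.elem` (element count +
#' `Tt` rows with 0-based node indices and region code), `<base>.lon`
#' (per-element fibre vectors), plus `<base>.surf` carrying the labelled
#' boundary triangles (0-based indices), which the plain CARP triple does
#' not store.
#'
#' @param mesh A `ventricular_mesh`.
#' @param base Path prefix (no extension).
#' @return `base`, invisibly (`write_carp`); the validated mesh
#'   (`read_carp`).
#' @export
write_carp <- function(mesh, base) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  pts <- file.path(paste0(base, ".pts"))
  writeLines(c(format(nrow(mesh$nodes)),
               apply(format(mesh$nodes, digits = 17, trim = TRUE,
                            scientific = FALSE), 1, paste, collapse = " ")), pts)
  elem <- paste("Tt", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L,
                region_codes[mesh$region])
  writeLines(c(format(nrow(mesh$tets)), elem), paste0(base, ".elem"))
  writeLines(c("1", apply(format(mesh$fibre, digits = 17, trim = TRUE,
                                 scientific = FALSE), 1, paste, collapse = " ")),
             paste0(base, ".lon"))
  surf <- paste("Tr", mesh$boundary$tris[, 1] - 1L, mesh$boundary$tris[, 2] - 1L,
                mesh$boundary$tris[, 3] - 1L,
                surface_label_codes[mesh$boundary$label])
  writeLines(c(format(nrow(mesh$boundary$tris)), surf), paste0(base, ".surf"))
  invisible(base)
}

#' @rdname write_carp
#' @export
read_carp <- function(base) {
  pts_lines <- readLines(paste0(base, ".pts"))
  n <- as.integer(pts_lines[1])
  nodes <- matrix(scan(text = pts_lines[2:(n + 1)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  el_lines <- readLines(paste0(base, ".elem"))
  m <- as.integer(el_lines[1])
  el_tok <- do.call(rbind, strsplit(el_lines[2:(m + 1)], "\\s+"))
  tets <- matrix(as.integer(el_tok[, 2:5]), ncol = 4) + 1L
  region <- names(region_codes)[as.integer(el_tok[, 6])]
  lon_lines <- readLines(paste0(base, ".lon"))
  fib <- matrix(scan(text = lon_lines[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
  sf_lines <- readLines(paste0(base, ".surf"))
  bs <- as.integer(sf_lines[1])
  sf_tok <- do.call(rbind, strsplit(sf_lines[2:(bs + 1)], "\\s+"))
  tris <- matrix(as.integer(sf_tok[, 2:4]), ncol = 3) + 1L
  labels <- names(surface_label_codes)[as.integer(sf_tok[, 5])]
  mesh_from_arrays(nodes, tets, fib, region, tris, labels)
}

#' Export coordinates and AHA map as CSV
#'
#' @param coords A [compute_uvc()] result.
#' @param aha Optional [map_aha17()] result.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_coordinates_csv <- function(coords, aha = NULL, path) {
  df <- tibble(node_id = seq_along(coords$z), z = coords$z, rho = coords$rho,
               phi = coords$phi, nu = coords$nu)
  if (!is.null(aha)) df$segment <- as.integer(aha)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an activation map as CSV
#'
#' @param map An `activation_map`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_activation_csv <- function(map, path) {
  utils::write.csv(tibble(node_id = seq_along(map), t_ms = as.numeric(map)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort manifest as JSON
#'
#' @param cohort A [sample_cohort()] result.
#' @param path Output JSON.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  man <- attr(cohort, "manifest")
  spec <- attr(cohort, "spec")
  jsonlite::write_json(
    list(cohort_type = spec$cohort_type, n_subjects = spec$n_subjects,
         random_seed = spec$random_seed, subjects = man),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
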