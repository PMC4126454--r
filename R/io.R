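#' Read and write meshes in an Abaqus-INP subset
#'
#' Supports the keyword subset `*NODE`, `*ELEMENT, TYPE=CPS4`, `*ELSET`
#' and `*NSET` (plain id lists, one-based). Region labels travel as the
#' element sets `CORTICAL`, `TRABECULAR` and `ROI`; boundary node sets as
#' `DISTAL`, `HEAD` and `TROCHANTER`. Mesh thickness and the arc-center
#' marks are stored in `**` comment lines so the round trip is lossless.
#'
#' @param path file path.
#' @return `read_inp()` returns a [mesh2d()].
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  marks <- list(); thickness <- 10
  for (ln in grep("^\\*\\* *(MARK|THICKNESS)", lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^\\*\\*", "", ln)), "[ ,]+")[[1]]
    if (tok[1] == "THICKNESS") thickness <- as.numeric(tok[2])
    if (tok[1] == "MARK") marks[[tok[2]]] <- as.numeric(tok[3:4])
  }
  lines <- lines[!grepl("^\\*\\*", lines)]
  kw <- grep("^\\*", lines)
  if (!length(kw)) stop("not an INP file: no keyword lines", call. = FALSE)
  blocks <- Map(function(a, b) lines[seq(a, b)],
                kw, c(kw[-1] - 1, length(lines)))
  nodes <- NULL; elements <- NULL
  elsets <- list(); nsets <- list()
  for (blk in blocks) {
    head <- toupper(blk[1])
    body <- blk[-1]
    body <- body[nzchar(trimws(body))]
    nums <- function(x) as.numeric(unlist(strsplit(trimws(x), "[ ,]+")))
    if (startsWith(head, "*NODE")) {
      m <- do.call(rbind, lapply(body, nums))
      nodes <- m[order(m[, 1]), 2:3, drop = FALSE]
      if (!all(m[order(m[, 1]), 1] == seq_len(nrow(m))))
        stop("non-contiguous node numbering not supported", call. = FALSE)
    } else if (startsWith(head, "*ELEMENT")) {
      if (!grepl("TYPE *= *CPS4", head))
        stop("only element type CPS4 is supported", call. = FALSE)
      m <- do.call(rbind, lapply(body, nums))
      elements <- m[order(m[, 1]), 2:5, drop = FALSE]
    } else if (startsWith(head, "*ELSET")) {
      nm <- sub(".*ELSET *= *([A-Za-z0-9_]+).*", "\\1", head)
      elsets[[nm]] <- as.integer(unlist(lapply(body, nums)))
    } else if (startsWith(head, "*NSET")) {
      nm <- sub(".*NSET *= *([A-Za-z0-9_]+).*", "\\1", head)
      nsets[[nm]] <- as.integer(unlist(lapply(body, nums)))
    }
  }
  if (is.null(nodes) || is.null(elements))
    stop("INP file lacks *NODE or *ELEMENT blocks", call. = FALSE)
  ne <- nrow(elements)
  region <- rep("trabecular", ne)
  if (!is.null(elsets$CORTICAL)) region[elsets$CORTICAL] <- "cortical"
  roi <- rep(FALSE, ne)
  if (!is.null(elsets$ROI)) roi[elsets$ROI] <- TRUE
  mesh2d(nodes, elements, region, roi,
         sets = list(distal = nsets$DISTAL, head = nsets$HEAD,
                     trochanter = nsets$TROCHANTER),
         thickness = thickness, marks = marks)
}

#' @rdname read_inp
#' @param mesh a [mesh2d()] object.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  ids <- function(v) {
    v <- as.integer(v)
    vapply(split(v, ceiling(seq_along(v) / 16)),
           paste, "", collapse = ", ")
  }
  wr("** 2D proximal femur mesh (plane stress, CPS4)")
  wr("** THICKNESS %g", mesh$thickness)
  for (nm in names(mesh$marks))
    wr("** MARK %s %.10g %.10g", nm, mesh$marks[[nm]][1], mesh$marks[[nm]][2])
  wr("*NODE")
  writeLines(sprintf("%d, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wr("*ELEMENT, TYPE=CPS4")
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$elements)),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4]), con)
  for (nm in c("cortical", "trabecular")) {
    wr("*ELSET, ELSET=%s", toupper(nm))
    writeLines(ids(which(mesh$region == nm)), con)
  }
  if (any(mesh$roi)) {
    wr("*ELSET, ELSET=ROI")
    writeLines(ids(which(mesh$roi)), con)
  }
  for (nm in names(mesh$sets)) {
    wr("*NSET, NSET=%s", toupper(nm))
    writeLines(ids(mesh$sets[[nm]]), con)
  }
  invisible(path)
}

#' Write element fields as a legacy VTK unstructured grid
#'
#' Writes the mesh and any number of per-element scalar fields as an
#' ASCII legacy-VTK unstructured grid (cell data), viewable in ParaView.
#'
#' @param mesh a [mesh2d()] object.
#' @param fields named list of numeric vectors (one value per element).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, fields = list(), path) {
  ne <- nrow(mesh$elements)
  stopifnot(all(lengths(fields) == ne))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "bone remodeling fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.8g %.8g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d",
                     mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
                     mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  if (length(fields)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.8g", fields[[nm]]), con)
    }
  }
  invisible(path)
}
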