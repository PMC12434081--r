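# Criterion BSA from triangulated body-scan meshes.
#
# A mesh is a list with `vertices` (n x 3 numeric matrix, meters) and
# `faces` (m x 3 integer matrix of 1-based vertex indices). Surface area is
# the unconditional sum of absolute triangle areas: winding/orientation is
# ignored and self-intersections are not detected, matching how body-scan
# software quantifies BSA from an avatar mesh.

#' Construct a triangulated mesh object
#'
#' @param vertices Numeric matrix (n x 3) of vertex coordinates in meters.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || !all(is.finite(vertices)))
    stop("`vertices` must be a finite n x 3 matrix", call. = FALSE)
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), ncol = 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) stop("`faces` must be an m x 3 index matrix", call. = FALSE)
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices reference missing vertices", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces;",
      "surface area", format(mesh_surface_area(x), digits = 6), "m^2\n")
  invisible(x)
}

#' Area of a 3D triangle
#'
#' Computes 0.5 * |(p1 - p0) x (p2 - p0)|. Degenerate (collinear) triangles
#' have area 0.
#'
#' @param p0,p1,p2 Numeric length-3 coordinate vectors (meters).
#' @return Area in m^2 (non-negative scalar).
#' @export
#' @examples
#' triangle_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # 0.5
triangle_area <- function(p0, p1, p2) {
  p <- c(p0, p1, p2)
  if (length(p) != 9L || !all(is.finite(p)))
    stop("triangle vertices must be three finite 3D points", call. = FALSE)
  u <- p1 - p0
  v <- p2 - p0
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

#' Total surface area of a triangulated mesh
#'
#' Sum of the areas of all faces. Invariant under rigid motions and under
#' relabelling of vertices or faces; scaling all vertices by k scales the
#' area by k^2.
#'
#' @param mesh A [tri_mesh()] (or any list with `vertices` and `faces`).
#' @return Total area in m^2. An empty face list yields 0 with a warning.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (is.null(v) || is.null(f)) stop("mesh must have $vertices and $faces", call. = FALSE)
  if (nrow(f) == 0L) {
    warning("mesh has no faces; surface area is 0", call. = FALSE)
    return(0)
  }
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  cr1 <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cr2 <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cr3 <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(0.5 * sqrt(cr1^2 + cr2^2 + cr3^2))
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records; polygonal faces with more than three vertices
#' are fan-triangulated. Texture/normal indices (`f v/vt/vn`) are ignored.
#'
#' @param path Path to an OBJ file.
#' @param scale Multiplier applied to vertex coordinates (e.g. `1e-3` for a
#'   mesh stored in millimeters). Default 1 (meters).
#' @return A [tri_mesh()].
#' @export
read_obj <- function(path, scale = 1) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines)) stop("no vertex records in ", path, call. = FALSE)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- list()
  for (fl in flines) {
    toks <- strsplit(trimws(sub("^f", "", fl)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1L))
    if (length(idx) < 3L) stop("face with fewer than 3 vertices", call. = FALSE)
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  tri_mesh(verts * scale, do.call(rbind, faces))
}

#' Read a PLY mesh (ASCII or binary little-endian)
#'
#' Supports the common x/y/z vertex layout with a uchar-counted vertex_indices
#' (or vertex_index) face list. Non-triangular faces are fan-triangulated.
#'
#' @inheritParams read_obj
#' @return A [tri_mesh()].
#' @export
read_ply <- function(path, scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("unexpected end of PLY header", call. = FALSE)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)

  # element blocks in declared order, with their property declarations
  el_idx <- grep("^element", header)
  elements <- lapply(seq_along(el_idx), function(i) {
    dec <- strsplit(trimws(header[el_idx[i]]), "\\s+")[[1]]
    upto <- if (i < length(el_idx)) el_idx[i + 1] - 1L else length(header) - 1L
    props <- header[(el_idx[i] + 1L):upto]
    props <- grep("^property", trimws(props), value = TRUE)
    list(name = dec[2], count = as.integer(dec[3]), props = props)
  })

  .ply_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  .read_scalar <- function(type) {
    sz <- .ply_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", 1L, size = sz, endian = "little")
    else
      readBin(con, "integer", 1L, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  verts <- NULL; faces <- list()
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    for (el in elements) {
      rows <- body[seq.int(pos, length.out = el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        pnames <- vapply(strsplit(trimws(el$props), "\\s+"), `[`, "", 3L)
        xyz <- match(c("x", "y", "z"), pnames)
        verts <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                       function(tk) as.numeric(tk[xyz])))
      } else if (el$name == "face") {
        for (r in rows) {
          tk <- as.integer(strsplit(trimws(r), "\\s+")[[1]])
          n <- tk[1]; idx <- tk[2:(1 + n)] + 1L
          for (k in seq_len(n - 2L))
            faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
        }
      }
    }
  } else {
    for (el in elements) {
      ptoks <- strsplit(trimws(el$props), "\\s+")
      if (el$name == "vertex") {
        types <- vapply(ptoks, `[`, "", 2L)
        pnames <- vapply(ptoks, `[`, "", 3L)
        verts <- matrix(NA_real_, el$count, 3L)
        for (i in seq_len(el$count)) {
          row <- vapply(types, .read_scalar, 0)
          verts[i, ] <- row[match(c("x", "y", "z"), pnames)]
        }
      } else if (el$name == "face") {
        lst <- ptoks[[1]]  # property list <count_t> <index_t> vertex_indices
        if (lst[2] != "list") stop("unsupported face property layout", call. = FALSE)
        count_t <- lst[3]; index_t <- lst[4]
        for (i in seq_len(el$count)) {
          n <- .read_scalar(count_t)
          idx <- vapply(seq_len(n), function(j) .read_scalar(index_t), 0L) + 1L
          for (k in seq_len(n - 2L))
            faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
        }
      } else {
        # skip unknown fixed-width element
        for (i in seq_len(el$count))
          for (tk in ptoks) .read_scalar(tk[2])
      }
    }
  }
  if (is.null(verts)) stop("PLY file has no vertex element", call. = FALSE)
  tri_mesh(verts * scale, do.call(rbind, faces))
}

#' Read a mesh file, dispatching on extension
#'
#' @inheritParams read_obj
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path, scale),
         ply = read_ply(path, scale),
         stop("unsupported mesh format: .", ext, call. = FALSE))
}

#' Average replicate scan-derived BSA values
#'
#' Duplicate scan acquisitions are averaged to give the per-subject criterion
#' BSA; a single available scan passes through with a warning.
#'
#' @param scan_areas Numeric vector of per-scan BSA values (m^2), length >= 1.
#' @return Arithmetic mean (m^2).
#' @export
average_replicates <- function(scan_areas) {
  scan_areas <- scan_areas[!is.na(scan_areas)]
  if (!length(scan_areas)) stop("no scan areas supplied", call. = FALSE)
  if (any(scan_areas <= 0)) stop("scan areas must be > 0", call. = FALSE)
  if (length(scan_areas) == 1L)
    warning("single scan only; criterion BSA taken from one replicate", call. = FALSE)
  mean(scan_areas)
}

#' Iterative two-sided Grubbs outlier test
#'
#' Flags the observation with maximum absolute deviation if
#' G = max|x_i - mean| / sd exceeds the t-based critical value at level
#' `alpha`, removes it, and repeats until no observation is flagged. Used as
#' preprocessing QC on the cohort distribution of criterion BSA.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return A list with `outliers` (integer indices into `values`, possibly
#'   empty), and `steps`, a data frame of per-iteration G statistics and
#'   critical values.
#' @export
#' @examples
#' grubbs_outliers(c(1.7, 1.75, 1.8, 1.78, 2.9))$outliers
grubbs_outliers <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 3L)
    stop("Grubbs test needs at least 3 values", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("zero-variance sample; Grubbs test not applicable", call. = FALSE)
    return(list(outliers = integer(0),
                steps = data.frame(n = integer(0), G = numeric(0),
                                   G_crit = numeric(0), flagged = integer(0))))
  }
  active <- seq_along(values)
  flagged <- integer(0)
  steps <- list()
  repeat {
    x <- values[active]
    n <- length(x)
    if (n < 3L || stats::sd(x) == 0) break
    dev <- abs(x - mean(x))
    i_max <- which.max(dev)
    G <- dev[i_max] / stats::sd(x)
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    G_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    hit <- G > G_crit
    steps[[length(steps) + 1L]] <-
      data.frame(n = n, G = G, G_crit = G_crit,
                 flagged = if (hit) active[i_max] else NA_integer_)
    if (!hit) break
    flagged <- c(flagged, active[i_max])
    active <- active[-i_max]
  }
  list(outliers = sort(flagged), steps = do.call(rbind, steps))
}

#' Mesh-derived criterion BSA for a cohort scan table
#'
#' Accepts either precomputed per-scan BSA columns (`scan1_bsa_m2`,
#' `scan2_bsa_m2`) or mesh file paths (`mesh_path_1`, `mesh_path_2`),
#' averages replicates, and runs Grubbs QC over the cohort.
#'
#' @param scans Data frame with `id` plus either scan-BSA or mesh-path columns.
#' @param alpha Grubbs significance level.
#' @param scale Coordinate scale passed to [read_mesh()].
#' @return A list with `criterion` (tibble `id`, `criterion_bsa_m2`) and
#'   `qc` (the [grubbs_outliers()] result, with flagged ids).
#' @export
criterion_from_scans <- function(scans, alpha = 0.05, scale = 1) {
  stopifnot(is.data.frame(scans), "id" %in% names(scans))
  if (anyDuplicated(scans$id)) stop("duplicate subject ids", call. = FALSE)
  has_bsa <- all(c("scan1_bsa_m2") %in% names(scans))
  has_mesh <- all(c("mesh_path_1") %in% names(scans))
  if (!has_bsa && !has_mesh)
    stop("scan table needs scan1_bsa_m2/scan2_bsa_m2 or mesh_path_1/mesh_path_2 columns",
         call. = FALSE)
  crit <- vapply(seq_len(nrow(scans)), function(i) {
    if (has_bsa) {
      areas <- c(scans$scan1_bsa_m2[i],
                 if ("scan2_bsa_m2" %in% names(scans)) scans$scan2_bsa_m2[i])
    } else {
      paths <- c(scans$mesh_path_1[i],
                 if ("mesh_path_2" %in% names(scans)) scans$mesh_path_2[i])
      paths <- paths[!is.na(paths) & nzchar(paths)]
      areas <- vapply(paths, function(p) mesh_surface_area(read_mesh(p, scale)), 0)
    }
    average_replicates(areas)
  }, 0)
  qc <- grubbs_outliers(crit, alpha = alpha)
  qc$flagged_ids <- scans$id[qc$outliers]
  list(criterion = tibble::tibble(id = scans$id, criterion_bsa_m2 = crit), qc = qc)
}
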