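# Watertight triangulated primitives with closed-form surface areas, used as
# oracles for the mesh surface-area kernel: single triangle, cube, icosphere
# (subdivided icosahedron projected to the sphere), and capsule (cylinder
# with hemispherical caps). Inscribed meshes underestimate curved surfaces
# and converge to the analytic area with refinement.

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# split each face into 4, de-duplicating midpoint vertices, projecting new
# vertices onto the sphere of given radius
.subdivide_sphere <- function(v, f, radius) {
  env <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- env[[key]]
    if (!is.null(idx)) return(idx)
    m <- (verts[[i]] + verts[[j]]) / 2
    m <- m * radius / sqrt(sum(m^2))
    verts[[length(verts) + 1L]] <<- m
    env[[key]] <- length(verts)
    length(verts)
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), faces = newf)
}

#' Generate a triangulated test mesh with known surface area
#'
#' Shapes: `"triangle"` (one face through `points`, default the unit right
#' triangle, area 1/2 base x height), `"cube"` (12 faces, area 6 side^2),
#' `"icosphere"` (20 x 4^subdivisions faces inscribed in a sphere, area
#' converging to 4 pi r^2 from below), `"capsule"` (cylinder of given
#' `length` with hemispherical caps, area converging to
#' 2 pi r length + 4 pi r^2).
#'
#' @param shape One of `"triangle"`, `"cube"`, `"icosphere"`, `"capsule"`.
#' @param side Cube edge length (m).
#' @param radius Sphere/capsule radius (m), > 0.
#' @param subdivisions Icosphere subdivision level (>= 0).
#' @param length Capsule cylindrical section length (m), >= 0.
#' @param segments Capsule angular/ring resolution (>= 3).
#' @param points 3 x 3 matrix of vertices for `"triangle"`.
#' @param scale Global coordinate multiplier.
#' @return A [tri_mesh()]; attribute `"analytic_area"` holds the closed-form
#'   area of the continuous shape at `scale`.
#' @export
#' @examples
#' mesh_surface_area(make_test_mesh("cube", side = 1))        # 6
#' m <- make_test_mesh("icosphere", radius = 1, subdivisions = 3)
make_test_mesh <- function(shape = c("triangle", "cube", "icosphere", "capsule"),
                           side = 1, radius = 1, subdivisions = 2, length = 1,
                           segments = 24, points = NULL, scale = 1) {
  shape <- match.arg(shape)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (side <= 0) stop("side must be > 0", call. = FALSE)
  if (length < 0) stop("length must be >= 0", call. = FALSE)
  mesh <- switch(shape,
    triangle = {
      v <- if (is.null(points)) rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) else as.matrix(points)
      list(vertices = v, faces = matrix(1:3, 1))
    },
    cube = {
      s <- side
      v <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
      # two triangles per face of the axis-aligned cube
      quads <- rbind(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                     c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6))
      f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i)
        rbind(quads[i, c(1, 2, 3)], quads[i, c(1, 3, 4)])))
      list(vertices = v, faces = f)
    },
    icosphere = {
      if (subdivisions < 0) stop("subdivisions must be >= 0", call. = FALSE)
      m <- .icosahedron()
      m$vertices <- m$vertices * radius
      for (k in seq_len(subdivisions))
        m <- .subdivide_sphere(m$vertices, m$faces, radius)
      m
    },
    capsule = {
      if (segments < 3) stop("segments must be >= 3", call. = FALSE)
      nth <- as.integer(segments)          # around the axis
      nph <- max(2L, as.integer(segments / 2))  # rings per hemisphere
      theta <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
      # profile: (r(z), z) from bottom pole to top pole along the capsule axis
      phis <- seq(-pi / 2, 0, length.out = nph + 1L)
      prof_r <- c(radius * cos(phis), radius * cos(rev(phis[-(nph + 1L)])))
      prof_z <- c(radius * sin(phis) - length / 2,
                  -radius * sin(rev(phis[-(nph + 1L)])) + length / 2)
      nr <- base::length(prof_r)
      verts <- list(c(0, 0, -radius - length / 2))  # bottom pole
      ring_start <- integer(nr)
      for (i in seq_len(nr)) {
        ring_start[i] <- base::length(verts) + 1L
        for (th in theta)
          verts[[base::length(verts) + 1L]] <-
            c(prof_r[i] * cos(th), prof_r[i] * sin(th), prof_z[i])
      }
      top <- base::length(verts) + 1L
      verts[[top]] <- c(0, 0, radius + length / 2)
      f <- list()
      # bottom fan (first profile ring has r ~ 0 only at the pole itself, so
      # connect the pole to ring 1)
      r1 <- ring_start[1]
      for (j in seq_len(nth)) {
        jn <- j %% nth + 1L
        f[[base::length(f) + 1L]] <- c(1L, r1 + j - 1L, r1 + jn - 1L)
      }
      for (i in seq_len(nr - 1L)) {
        a <- ring_start[i]; b <- ring_start[i + 1L]
        for (j in seq_len(nth)) {
          jn <- j %% nth + 1L
          f[[base::length(f) + 1L]] <- c(a + j - 1L, b + j - 1L, b + jn - 1L)
          f[[base::length(f) + 1L]] <- c(a + j - 1L, b + jn - 1L, a + jn - 1L)
        }
      }
      rl <- ring_start[nr]
      for (j in seq_len(nth)) {
        jn <- j %% nth + 1L
        f[[base::length(f) + 1L]] <- c(top, rl + jn - 1L, rl + j - 1L)
      }
      list(vertices = do.call(rbind, verts), faces = do.call(rbind, f))
    })
  analytic <- switch(shape,
    triangle = triangle_area(mesh$vertices[1, ], mesh$vertices[2, ],
                             mesh$vertices[3, ]) * scale^2,
    cube = 6 * side^2 * scale^2,
    icosphere = 4 * pi * radius^2 * scale^2,
    capsule = (2 * pi * radius * length + 4 * pi * radius^2) * scale^2)
  out <- tri_mesh(mesh$vertices * scale, mesh$faces)
  attr(out, "analytic_area") <- analytic
  out
}

#' Write a mesh to a Wavefront OBJ file
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
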