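# Axisymmetric cosine-throat stenosis geometry and STL surface export.
# All in-file coordinates are millimetres (the CFD-meshing convention);
# a scale factor converts to metres for SI workflows.

#' Describe an axisymmetric cosine-throat stenosis geometry
#'
#' A straight tube of length `total_length_L` and radius `base_radius_R0`
#' with a focal cosine contraction of length `throat_length_Ls` centred at
#' `throat_center_zc`. The radial depth of the contraction is
#' \eqn{\Delta R = R_0 \sigma}. Axial resolution defaults to a locally
#' refined grid: spacing at most Ls/20 inside the throat window and at most
#' 1 mm outside.
#'
#' @param sigma Fractional diameter reduction in `[0, 1)`.
#' @param total_length_L Tube length (mm), default 30.
#' @param base_radius_R0 Baseline radius (mm), default 1.5.
#' @param throat_length_Ls Throat length (mm), default 5.
#' @param throat_center_zc Throat centre (mm), default 15; the window
#'   `zc +/- Ls/2` must lie inside `[0, L]`.
#' @param n_axial Number of axial stations (>= 2); default `NULL` builds the
#'   locally refined grid.
#' @param n_circumferential Vertices per ring (>= 3), default 64.
#' @param capped_ends If `TRUE`, [generate_surface()] closes the tube with
#'   triangle-fan end caps.
#' @return Object of class `stenosis_geometry`.
#' @export
stenosis_geometry <- function(sigma, total_length_L = 30, base_radius_R0 = 1.5,
                              throat_length_Ls = 5, throat_center_zc = 15,
                              n_axial = NULL, n_circumferential = 64,
                              capped_ends = FALSE) {
  check_sigma(sigma)
  stopifnot(total_length_L > 0, base_radius_R0 > 0, throat_length_Ls > 0,
            n_circumferential >= 3)
  if (throat_center_zc - throat_length_Ls / 2 < 0 ||
      throat_center_zc + throat_length_Ls / 2 > total_length_L) {
    stop("throat window zc +/- Ls/2 must lie within [0, L]")
  }
  if (!is.null(n_axial) && n_axial < 2) stop("n_axial must be >= 2")
  structure(list(sigma = sigma, total_length_L = total_length_L,
                 base_radius_R0 = base_radius_R0,
                 throat_length_Ls = throat_length_Ls,
                 throat_center_zc = throat_center_zc,
                 n_axial = n_axial, n_circumferential = n_circumferential,
                 capped_ends = capped_ends),
            class = "stenosis_geometry")
}

#' Radius profile of the cosine throat
#'
#' Inside the throat window `zc +/- Ls/2`:
#' \deqn{R(z) = R_0 - \frac{\Delta R}{2}\left(1 +
#'   \cos\frac{2\pi (z - z_c)}{L_s}\right), \qquad \Delta R = R_0 \sigma,}
#' and `R0` outside. The profile meets the parent vessel with continuous
#' slope at the window edges (the cosine derivative vanishes there) and
#' attains its minimum `R0 (1 - sigma)` at `zc`.
#'
#' @param z Axial coordinate(s) (mm) in `[0, L]`. Vectorised.
#' @param geom A [stenosis_geometry()].
#' @return Radius (mm).
#' @export
radius_profile <- function(z, geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (any(z < 0 | z > geom$total_length_L)) {
    stop("z outside [0, L]")
  }
  R0 <- geom$base_radius_R0
  dR <- R0 * geom$sigma
  zc <- geom$throat_center_zc
  Ls <- geom$throat_length_Ls
  inside <- abs(z - zc) <= Ls / 2
  r <- rep(R0, length(z))
  r[inside] <- R0 - (dR / 2) * (1 + cos(2 * pi * (z[inside] - zc) / Ls))
  r
}

axial_stations <- function(geom) {
  if (!is.null(geom$n_axial)) {
    return(seq(0, geom$total_length_L, length.out = geom$n_axial))
  }
  zc <- geom$throat_center_zc
  Ls <- geom$throat_length_Ls
  lo <- zc - Ls / 2
  hi <- zc + Ls / 2
  seg <- function(a, b, dz_max) {
    if (b <= a) return(numeric(0))
    seq(a, b, length.out = max(2, ceiling((b - a) / dz_max) + 1))
  }
  z <- sort(unique(c(seg(0, lo, 1), seg(lo, hi, Ls / 20),
                     seg(hi, geom$total_length_L, 1))))
  z
}

#' Triangulated surface of revolution of the stenosis geometry
#'
#' Revolves the radius profile around the tube axis and triangulates the
#' quad strips between adjacent rings (two triangles per quad), giving
#' `2 * n_circumferential * (n_axial - 1)` wall triangles with outward
#' normals. With `capped_ends` the two rims are closed by triangle fans
#' around centre vertices, adding `2 * n_circumferential` triangles;
#' otherwise the tube is an open watertight manifold whose only boundary
#' edges are the two rims.
#'
#' @param geom A [stenosis_geometry()].
#' @return Object of class `tri_mesh`: list with `vertices` (n x 3 matrix,
#'   mm, columns x/y/z with z the axis) and `faces` (m x 3 integer matrix of
#'   vertex indices, counter-clockwise seen from outside).
#' @export
generate_surface <- function(geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  z <- axial_stations(geom)
  nz <- length(z)
  nth <- geom$n_circumferential
  if (nz < 2 || nth < 3) stop("degenerate resolution: need >= 2 rings of >= 3 vertices")
  theta <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  r <- radius_profile(z, geom)
  verts <- matrix(0, nz * nth, 3)
  for (i in seq_len(nz)) {
    rows <- (i - 1) * nth + seq_len(nth)
    verts[rows, 1] <- r[i] * cos(theta)
    verts[rows, 2] <- r[i] * sin(theta)
    verts[rows, 3] <- z[i]
  }
  vid <- function(i, j) (i - 1L) * nth + ((j - 1L) %% nth) + 1L
  faces <- matrix(0L, 2L * nth * (nz - 1L), 3L)
  f <- 0L
  for (i in seq_len(nz - 1L)) {
    for (j in seq_len(nth)) {
      a <- vid(i, j); b <- vid(i, j + 1L)
      c_ <- vid(i + 1L, j); d <- vid(i + 1L, j + 1L)
      # outward orientation: CCW when viewed from outside the tube
      faces[f + 1L, ] <- c(a, c_, b)
      faces[f + 2L, ] <- c(b, c_, d)
      f <- f + 2L
    }
  }
  if (geom$capped_ends) {
    c0 <- nrow(verts) + 1L
    c1 <- nrow(verts) + 2L
    verts <- rbind(verts, c(0, 0, z[1]), c(0, 0, z[nz]))
    caps <- matrix(0L, 2L * nth, 3L)
    for (j in seq_len(nth)) {
      # start cap faces -z: wind so the normal points out of the tube
      caps[j, ] <- c(c0, vid(1L, j + 1L), vid(1L, j))
      caps[nth + j, ] <- c(c1, vid(nz, j), vid(nz, j + 1L))
    }
    faces <- rbind(faces, caps)
  }
  structure(list(vertices = verts, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Edge manifold check of a triangle mesh
#'
#' @param mesh A `tri_mesh`.
#' @return List with `n_internal` (edges shared by exactly 2 triangles),
#'   `n_boundary` (edges on exactly 1 triangle) and `n_bad` (any other
#'   multiplicity). A watertight closed surface has `n_boundary == 0`; an
#'   open tube's boundary edges all lie on the two rims.
#' @export
mesh_edge_summary <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  mult <- table(key)
  list(n_internal = sum(mult == 2), n_boundary = sum(mult == 1),
       n_bad = sum(mult > 2))
}

facet_normal <- function(v1, v2, v3) {
  n <- c((v2[2] - v1[2]) * (v3[3] - v1[3]) - (v2[3] - v1[3]) * (v3[2] - v1[2]),
         (v2[3] - v1[3]) * (v3[1] - v1[1]) - (v2[1] - v1[1]) * (v3[3] - v1[3]),
         (v2[1] - v1[1]) * (v3[2] - v1[2]) - (v2[2] - v1[2]) * (v3[1] - v1[1]))
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 0)
}

#' Write a triangle mesh to STL
#'
#' Standard STL, binary (80-byte header, little-endian uint32 facet count,
#' 50-byte facets) or ASCII (`solid` blocks). Coordinates are written as
#' stored, in millimetres by default; use `scale = 0.001` to emit metres.
#'
#' @param mesh A `tri_mesh`.
#' @param path Output file path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @param scale Coordinate multiplier applied on write (default 1).
#' @param name Solid name for the ASCII header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii"), scale = 1,
                      name = "padflow") {
  mode <- match.arg(mode)
  if (nrow(mesh$faces) == 0) stop("refusing to write an empty mesh")
  v <- mesh$vertices * scale
  f <- mesh$faces
  res <- tryCatch({
    if (mode == "ascii") {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("solid %s", name), con)
      for (k in seq_len(nrow(f))) {
        p <- v[f[k, ], , drop = FALSE]
        n <- facet_normal(p[1, ], p[2, ], p[3, ])
        writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                     "    outer loop",
                     sprintf("      vertex %.9g %.9g %.9g",
                             p[, 1], p[, 2], p[, 3]),
                     "    endloop", "  endfacet"), con)
      }
      writeLines(sprintf("endsolid %s", name), con)
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      header <- charToRaw(formatC(paste0("binary STL ", name), width = -80))
      writeBin(header[seq_len(80)], con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      for (k in seq_len(nrow(f))) {
        p <- v[f[k, ], , drop = FALSE]
        n <- facet_normal(p[1, ], p[2, ], p[3, ])
        writeBin(as.numeric(c(n, t(p))), con, size = 4, endian = "little")
        writeBin(as.raw(c(0, 0)), con)
      }
    }
    path
  }, error = function(e) {
    stop("STL write failed for '", path, "': ", conditionMessage(e))
  })
  invisible(res)
}

#' Read an STL file back into a triangle mesh
#'
#' Supports both binary and ASCII STL (auto-detected). Vertices are
#' deduplicated exactly, so a write/read round trip preserves the triangle
#' count and vertex coordinates to float32 precision.
#'
#' @param path STL file path.
#' @return A `tri_mesh`.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 80)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") && {
    # a binary file may also start with "solid"; verify the size heuristic
    sz <- file.info(path)$size
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    sz != 84 + 50 * nf
  }
  tri <- if (is_ascii) {
    lines <- readLines(path)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    coords
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    coords <- matrix(0, 3 * nf, 3)
    for (k in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", n = 2))
      coords[3 * (k - 1) + 1:3, ] <- matrix(vals[4:12], 3, byrow = TRUE)
    }
    coords
  }
  if (nrow(tri) %% 3 != 0) stop("corrupt STL: vertex count not divisible by 3")
  key <- apply(tri, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  structure(list(vertices = verts, faces = faces), class = "tri_mesh")
}
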