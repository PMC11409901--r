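# 3D convex hull volume via incremental construction.
#
# Points are centred and rescaled to the unit box before any predicate is
# evaluated, so the visibility tolerance is dimensionless; the volume is
# rescaled at the end. Returns NA when the point set is degenerate (fewer
# than 4 distinct points, or all points coplanar), which callers treat as
# "no 3D hull exists".

hull_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# face normal (not unit) and offset for triangle (a, b, c), oriented so that
# the interior point is on the negative side
hull_face <- function(pts, tri, interior) {
  a <- pts[tri[1], ]; b <- pts[tri[2], ]; c_ <- pts[tri[3], ]
  nrm <- hull_cross(b - a, c_ - a)
  d <- sum(nrm * a)
  if (sum(nrm * interior) - d > 0) {
    tri <- tri[c(1, 3, 2)]
    nrm <- -nrm
    d <- -d
  }
  list(tri = tri, normal = nrm, d = d)
}

#' Volume of the 3D convex hull of a point set
#'
#' Computes the convex hull of the localization coordinates by incremental
#' construction and returns its volume. Used as the default region-of-
#' interest volume proxy: the tightest deterministic convex region covering
#' the imaged structure.
#'
#' @param pts Numeric matrix with 3 columns (x, y, z), in nm.
#' @return Hull volume in nm^3, or `NA_real_` when no 3D hull exists (fewer
#'   than 4 distinct points or a degenerate, coplanar/collinear cloud).
#' @export
convex_hull_volume <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (!is.numeric(pts) || ncol(pts) != 3) abort("pts must be an n x 3 numeric matrix")
  n <- nrow(pts)
  if (n < 4) return(NA_real_)

  ctr <- colMeans(pts)
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) return(NA_real_)
  p <- sweep(pts, 2, ctr, "-") / scale
  eps <- 1e-10

  # initial simplex: spread apart as far as possible
  i1 <- which.min(p[, 1])
  d1 <- rowSums(sweep(p, 2, p[i1, ], "-")^2)
  i2 <- which.max(d1)
  if (d1[i2] <= eps) return(NA_real_)
  e1 <- p[i2, ] - p[i1, ]
  cr <- t(apply(sweep(p, 2, p[i1, ], "-"), 1, function(v) hull_cross(e1, v)))
  a2 <- rowSums(cr^2)
  i3 <- which.max(a2)
  if (a2[i3] <= eps^2) return(NA_real_)
  nrm0 <- hull_cross(e1, p[i3, ] - p[i1, ])
  h <- abs(as.vector(sweep(p, 2, p[i1, ], "-") %*% nrm0)) / sqrt(sum(nrm0^2))
  i4 <- which.max(h)
  if (h[i4] <= eps) return(NA_real_)  # coplanar

  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(p[simplex, ])
  faces <- list(
    hull_face(p, simplex[c(1, 2, 3)], interior),
    hull_face(p, simplex[c(1, 2, 4)], interior),
    hull_face(p, simplex[c(1, 3, 4)], interior),
    hull_face(p, simplex[c(2, 3, 4)], interior)
  )

  for (i in setdiff(seq_len(n), simplex)) {
    nm <- do.call(rbind, lapply(faces, `[[`, "normal"))
    dd <- vapply(faces, `[[`, numeric(1), "d")
    vis <- which(as.vector(nm %*% p[i, ]) - dd > eps)
    if (length(vis) == 0) next
    # horizon: edges bounding the visible region (appear in exactly one
    # visible face)
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      rbind(f$tri[c(1, 2)], f$tri[c(2, 3)], f$tri[c(3, 1)])
    }))
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1)), , drop = FALSE]
    faces <- faces[-vis]
    for (r in seq_len(nrow(horizon))) {
      faces[[length(faces) + 1]] <-
        hull_face(p, c(horizon[r, 1], horizon[r, 2], i), interior)
    }
  }

  vol <- 0
  for (f in faces) {
    a <- p[f$tri[1], ] - interior
    b <- p[f$tri[2], ] - interior
    c_ <- p[f$tri[3], ] - interior
    vol <- vol + abs(sum(a * hull_cross(b, c_))) / 6
  }
  vol * scale^3
}
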