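#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t
#' @importFrom stats rnorm runif sd cor quantile median
NULL

## ---- small vector helpers ---------------------------------------------------

row_norms <- function(x) sqrt(rowSums(x * x))

unit_rows <- function(x) {
  n <- row_norms(x)
  n[n == 0] <- 1
  x / n
}

row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

row_dots <- function(a, b) rowSums(a * b)

#' Geodesic (great-circle) distance between unit vectors, in radians
#'
#' @param p,q matrices (or single vectors) of unit 3-vectors, row-wise.
#' @return numeric vector of angles in radians.
#' @export
geodesic_distance <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  if (nrow(p) == 1 && nrow(q) > 1) p <- p[rep(1, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1 && nrow(p) > 1) q <- q[rep(1, nrow(p)), , drop = FALSE]
  # chord-based formula, numerically stable near 0 and pi
  2 * asin(pmin(1, 0.5 * row_norms(p - q)))
}

## ---- icosphere construction -------------------------------------------------

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = unit_rows(v), faces = f)
}

subdivide_once <- function(vertices, faces) {
  nv <- nrow(vertices)
  a <- faces[, 1]; b <- faces[, 2]; c <- faces[, 3]
  # unique undirected edges, midpoint index lookup
  e_all <- rbind(cbind(a, b), cbind(b, c), cbind(c, a))
  e_key <- cbind(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  key_str <- paste(e_key[, 1], e_key[, 2])
  uniq <- !duplicated(key_str)
  e_uni <- e_key[uniq, , drop = FALSE]
  mid_idx <- nv + match(key_str, key_str[uniq])
  mids <- unit_rows((vertices[e_uni[, 1], , drop = FALSE] +
                     vertices[e_uni[, 2], , drop = FALSE]) / 2)
  nf <- nrow(faces)
  m_ab <- mid_idx[seq_len(nf)]
  m_bc <- mid_idx[nf + seq_len(nf)]
  m_ca <- mid_idx[2 * nf + seq_len(nf)]
  new_faces <- rbind(
    cbind(a, m_ab, m_ca),
    cbind(b, m_bc, m_ab),
    cbind(c, m_ca, m_bc),
    cbind(m_ab, m_bc, m_ca)
  )
  list(
    vertices = rbind(vertices, mids),
    faces = new_faces,
    parents = e_uni      # parent vertex pair of each appended midpoint
  )
}

neighbor_lists <- function(n_vertices, faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices)))
}

edge_list <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Build a standard-topology icosphere
#'
#' Constructs the shared spherical mesh all subjects of a cohort use. Vertices
#' of coarser subdivision levels are a prefix of finer levels, which the
#' multiresolution alignment exploits.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = icosahedron,
#'   6 gives the 40,962-vertex standard mesh). Must be in 0..7.
#' @return an object of class `sphere_mesh` with fields `vertices` (n x 3 unit
#'   rows), `faces`, `neighbors`, `edges`, `n_vertices`, `subdivisions`,
#'   `parents` (per-level midpoint parent pairs), `incident_faces`,
#'   `smooth_op` (sparse 1-ring averaging operator), `mean_edge`.
#' @export
build_icosphere <- function(subdivisions) {
  if (length(subdivisions) != 1 || is.na(subdivisions) ||
      subdivisions != round(subdivisions) || subdivisions < 0 || subdivisions > 7) {
    stop("`subdivisions` must be a single integer in 0..7", call. = FALSE)
  }
  ico <- icosahedron()
  vertices <- ico$vertices
  faces <- ico$faces
  parents <- vector("list", subdivisions)
  if (subdivisions > 0) {
    for (k in seq_len(subdivisions)) {
      s <- subdivide_once(vertices, faces)
      vertices <- s$vertices
      faces <- s$faces
      parents[[k]] <- s$parents
    }
  }
  n <- nrow(vertices)
  storage.mode(faces) <- "integer"
  nbrs <- neighbor_lists(n, faces)
  edges <- edge_list(faces)
  deg <- lengths(nbrs)
  # 1-ring uniform averaging operator (self + neighbors)
  i <- c(seq_len(n), rep(seq_len(n), deg))
  j <- c(seq_len(n), unlist(nbrs, use.names = FALSE))
  w <- 1 / (deg + 1)
  x <- c(w, rep(w, deg))
  smooth_op <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  # incident faces per vertex, NA-padded matrix
  fi <- rep(seq_len(nrow(faces)), 3)
  vi <- as.vector(faces)
  by_v <- split(fi, factor(vi, levels = seq_len(n)))
  kmax <- max(lengths(by_v))
  incident <- matrix(NA_integer_, n, kmax)
  for (k in seq_len(kmax)) {
    has <- lengths(by_v) >= k
    incident[has, k] <- vapply(by_v[has], `[`, integer(1), k)
  }
  mean_edge <- mean(geodesic_distance(vertices[edges[, 1], , drop = FALSE],
                                      vertices[edges[, 2], , drop = FALSE]))
  # neighbor index matrix (self-padded) for vectorised graph hill-climbing
  kmax_nb <- max(deg)
  nbmat <- matrix(rep(seq_len(n), kmax_nb), n, kmax_nb)
  for (k in seq_len(kmax_nb)) {
    has <- deg >= k
    nbmat[has, k] <- vapply(nbrs[has], `[`, integer(1), k)
  }
  # per-face Cramer vectors for barycentric solves: b_k = p . C_k[face, ]
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  det <- row_dots(v1, row_cross(v2, v3))
  cramer <- list(row_cross(v2, v3) / det, row_cross(v3, v1) / det, row_cross(v1, v2) / det)
  structure(
    list(
      vertices = vertices, faces = faces, neighbors = nbrs, edges = edges,
      n_vertices = n, subdivisions = subdivisions, parents = parents,
      incident_faces = incident, smooth_op = smooth_op, mean_edge = mean_edge,
      cramer = cramer, neighbor_matrix = nbmat
    ),
    class = "sphere_mesh"
  )
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat(sprintf("<sphere_mesh> %d vertices, %d faces (subdivisions = %d, mean edge %.3f rad)\n",
              x$n_vertices, nrow(x$faces), x$subdivisions, x$mean_edge))
  invisible(x)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a `sphere_mesh`
#' @return integer (2 for a closed orientable genus-0 surface)
#' @export
euler_characteristic <- function(mesh) {
  mesh$n_vertices - nrow(mesh$edges) + nrow(mesh$faces)
}

#' Number of vertices of the prefix mesh at a coarser subdivision level
#' @noRd
level_n_vertices <- function(subdivisions) 10L * 4L^subdivisions + 2L

## ---- folded meshes ----------------------------------------------------------

#' Construct a folded-cortex mesh sharing an icosphere's topology
#'
#' @param mesh the `sphere_mesh` carrying the topology.
#' @param vertices n x 3 matrix of folded coordinates in mm.
#' @return an object of class `folded_mesh` with outward vertex normals.
#' @export
folded_mesh <- function(mesh, vertices) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != mesh$n_vertices || ncol(vertices) != 3) {
    stop("folded vertex matrix must be n_vertices x 3", call. = FALSE)
  }
  fn <- face_normals(vertices, mesh$faces, check = TRUE)
  structure(
    list(vertices = vertices, mesh = mesh, normals = vertex_normals(mesh, vertices, fn)),
    class = "folded_mesh"
  )
}

#' @export
print.folded_mesh <- function(x, ...) {
  cat(sprintf("<folded_mesh> %d vertices in mm space\n", nrow(x$vertices)))
  invisible(x)
}

face_normals <- function(vertices, faces, check = FALSE) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- row_cross(b - a, c - a)   # magnitude = 2 * face area
  if (check) {
    areas <- row_norms(cr)
    bad <- which(areas <= .Machine$double.eps * max(areas))
    if (length(bad)) {
      stop(sprintf("degenerate (zero-area) face(s): %s",
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  cr
}

vertex_normals <- function(mesh, vertices, fn = NULL) {
  if (is.null(fn)) fn <- face_normals(vertices, mesh$faces)
  n <- mesh$n_vertices
  # rowsum-based accumulation (area-weighted since |fn| = 2 * area)
  acc <- matrix(0, n, 3)
  for (k in 1:3) {
    r <- rowsum(fn, mesh$faces[, k])
    acc[as.integer(rownames(r)), ] <- acc[as.integer(rownames(r)), ] + r
  }
  unit_rows(acc)
}

## ---- scalar maps ------------------------------------------------------------

#' Per-vertex scalar map bound to a mesh
#'
#' A lightweight container: numeric vector with a label. All package
#' operations also accept plain numeric vectors of the right length.
#'
#' @param values numeric vector, one finite value per vertex.
#' @param mesh the owning `sphere_mesh` (used for the length check).
#' @param label free-text description.
#' @return numeric vector of class `scalar_map`.
#' @export
scalar_map <- function(values, mesh, label = "") {
  values <- as.numeric(values)
  if (length(values) != mesh$n_vertices) {
    stop("scalar map length must equal mesh vertex count", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("scalar map values must all be finite", call. = FALSE)
  structure(values, label = label, class = c("scalar_map", "numeric"))
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map> '%s': %d vertices, range [%.4g, %.4g]\n",
              attr(x, "label"), length(x), min(x), max(x)))
  invisible(x)
}

## ---- curvature --------------------------------------------------------------

#' Discrete signed curvature of a folded mesh, squashed to [-1, 1]
#'
#' Fits an algebraic sphere (|x|^2 + b.x + c = 0, linear least squares) to
#' each vertex and its 1-ring; the signed inverse radius of the fitted sphere
#' is the local curvature, with the sign taken from the side of the surface
#' the fitted center lies on (convex / gyral regions positive). The result is
#' normalised by the global mean edge length (making it invariant under
#' uniform rescaling of the geometry and exactly constant on a perfect
#' sphere) and squashed with tanh into [-1, 1].
#'
#' @param folded a `folded_mesh`.
#' @param gain slope of the tanh squashing (default 3).
#' @return a `scalar_map` on the owning sphere mesh with values in (-1, 1).
#' @export
mean_curvature <- function(folded, gain = 3) {
  stopifnot(inherits(folded, "folded_mesh"))
  mesh <- folded$mesh
  V <- folded$vertices
  nb <- mesh$neighbors
  n <- mesh$n_vertices
  deg <- lengths(nb)
  # point sets per vertex: the vertex itself plus its 1-ring
  grp <- c(seq_len(n), rep(seq_len(n), deg))
  pts <- c(seq_len(n), unlist(nb, use.names = FALSE))
  X <- V[pts, , drop = FALSE]
  y <- -rowSums(X^2)
  # accumulate per-vertex normal equations for theta = (b1, b2, b3, c)
  Sxx <- rowsum(cbind(X[, 1]^2, X[, 1] * X[, 2], X[, 1] * X[, 3],
                      X[, 2]^2, X[, 2] * X[, 3], X[, 3]^2), grp)
  Sx  <- rowsum(X, grp)
  Sy  <- rowsum(cbind(X * y, y), grp)
  m   <- deg + 1
  theta <- matrix(0, n, 4)
  A <- matrix(0, 4, 4)
  for (v in seq_len(n)) {
    A[1, 1] <- Sxx[v, 1]; A[1, 2] <- A[2, 1] <- Sxx[v, 2]; A[1, 3] <- A[3, 1] <- Sxx[v, 3]
    A[2, 2] <- Sxx[v, 4]; A[2, 3] <- A[3, 2] <- Sxx[v, 5]; A[3, 3] <- Sxx[v, 6]
    A[1, 4] <- A[4, 1] <- Sx[v, 1]; A[2, 4] <- A[4, 2] <- Sx[v, 2]
    A[3, 4] <- A[4, 3] <- Sx[v, 3]; A[4, 4] <- m[v]
    th <- tryCatch(solve(A, Sy[v, ]), error = function(e) NULL)
    if (is.null(th)) {
      stop(sprintf("curvature fit failed at vertex %d (degenerate 1-ring)", v),
           call. = FALSE)
    }
    theta[v, ] <- th
  }
  center <- -theta[, 1:3] / 2
  # refined normal: gradient of the fitted implicit sphere, oriented by the
  # (crude, area-weighted) outward mesh normal; exactly radial on a sphere
  n_fit <- unit_rows(V - center)
  flip <- sign(row_dots(n_fit, folded$normals))
  flip[flip == 0] <- 1
  n_fit <- n_fit * flip
  # umbrella vector projected on the refined normal, normalised per vertex by
  # the mean squared half edge length: a signed mean-curvature estimate that
  # is exactly constant on a perfect sphere
  j <- unlist(nb, use.names = FALSE)
  i <- rep(seq_len(n), deg)
  diffs <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
  L <- rowsum(diffs, i) / deg
  num <- -row_dots(L, n_fit)
  den <- rowsum(rowSums(diffs^2), i)[, 1] / (2 * deg)
  raw <- num / den
  edge_mm <- mean(row_norms(V[mesh$edges[, 1], , drop = FALSE] -
                            V[mesh$edges[, 2], , drop = FALSE]))
  scalar_map(tanh(gain * raw * edge_mm), mesh, label = "mean curvature")
}

## ---- smoothing --------------------------------------------------------------

#' Nearest-neighbor iterative smoothing of a per-vertex map
#'
#' One iteration replaces each value by the unweighted mean of itself and its
#' 1-ring neighbors; at 1.5 mm vertex spacing one iteration approximates a 2D
#' Gaussian kernel of about 3 mm FWHM.
#'
#' @param values per-vertex numeric vector (or `scalar_map`).
#' @param mesh the `sphere_mesh`.
#' @param iterations non-negative iteration count.
#' @return smoothed numeric vector (a `scalar_map` if the input was one).
#' @export
smooth_map <- function(values, mesh, iterations = 1) {
  if (length(iterations) != 1 || is.na(iterations) || iterations < 0 ||
      iterations != round(iterations)) {
    stop("`iterations` must be a single non-negative integer", call. = FALSE)
  }
  v <- as.numeric(values)
  if (length(v) != mesh$n_vertices) stop("map length does not match mesh", call. = FALSE)
  if (iterations > 0) {
    S <- mesh$smooth_op
    for (k in seq_len(iterations)) v <- as.numeric(S %*% v)
  }
  if (inherits(values, "scalar_map")) {
    scalar_map(v, mesh, label = attr(values, "label"))
  } else v
}

#' Smooth a multi-column matrix of per-vertex time series (one iteration each)
#' @noRd
smooth_matrix <- function(Y, mesh, iterations = 1) {
  if (iterations == 0) return(Y)
  S <- mesh$smooth_op
  for (k in seq_len(iterations)) Y <- as.matrix(S %*% Y)
  Y
}

#' Four-level coarse-to-fine curvature pyramid
#'
#' @param values per-vertex curvature.
#' @param mesh the `sphere_mesh`.
#' @param iterations strictly decreasing smoothing iteration counts,
#'   heaviest first (default scaled from (200, 80, 20, 2) at subdivisions = 4).
#' @return list with `levels` (list of 4 maps) and `smoothing_iterations`.
#' @export
multiscale_curvature <- function(values, mesh,
                                 iterations = default_level_iterations(mesh$subdivisions)) {
  if (length(iterations) != 4 || any(diff(iterations) >= 0)) {
    stop("`iterations` must be 4 strictly decreasing counts", call. = FALSE)
  }
  levels <- lapply(iterations, function(it) smooth_map(values, mesh, it))
  structure(list(levels = levels, smoothing_iterations = iterations),
            class = "multiscale_curvature")
}

#' Default smoothing schedule, scaled so the physical smoothing extent is
#' constant across mesh resolutions (iterations scale with vertex count).
#' @noRd
default_level_iterations <- function(subdivisions) {
  base <- c(200, 80, 20, 2)           # defined at subdivisions = 4
  pmax(1L, as.integer(round(base * 4^(subdivisions - 4))))
}

## ---- resampling -------------------------------------------------------------

#' Index of the nearest mesh vertex for each query direction
#'
#' Greedy ascent of the inner product over the mesh graph. Because the
#' vertices are extreme points of their convex hull and the mesh graph is the
#' hull's edge graph, a local maximum of a linear functional is the global
#' maximum, so the climb returns the exact nearest vertex. Seeded from the
#' coarse icosahedral prefix, or from `init` (e.g. the previous iteration's
#' answer in an optimisation loop).
#'
#' @param mesh a `sphere_mesh`
#' @param query q x 3 matrix of unit vectors
#' @param init optional integer vector of starting vertex indices
#' @return integer vector of vertex indices
#' @export
nearest_vertex <- function(mesh, query, init = NULL) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  q <- nrow(query)
  V <- mesh$vertices
  if (is.null(init)) {
    n_seed <- min(mesh$n_vertices, 162L)
    cur <- max.col(query %*% t(V[seq_len(n_seed), , drop = FALSE]),
                   ties.method = "first")
  } else {
    cur <- as.integer(init)
  }
  nb <- mesh$neighbor_matrix
  best <- rowSums(query * V[cur, , drop = FALSE])
  repeat {
    improved <- FALSE
    for (k in seq_len(ncol(nb))) {
      cand <- nb[cur, k]
      d <- rowSums(query * V[cand, , drop = FALSE])
      better <- d > best + 1e-15
      if (any(better)) {
        cur[better] <- cand[better]
        best[better] <- d[better]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  cur
}

#' Barycentric interpolation weights on the sphere
#'
#' For each unit query direction, finds the mesh triangle containing its
#' gnomonic (central) projection among faces incident to the nearest vertex
#' and returns normalised barycentric weights. Falls back to the nearest
#' vertex when no incident face contains the query (numerically rare).
#'
#' @return list(idx = q x 3 vertex indices, w = q x 3 weights summing to 1)
#' @noRd
barycentric_weights <- function(mesh, query, init = NULL) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  q <- nrow(query)
  nn <- nearest_vertex(mesh, query, init = init)
  idx <- cbind(nn, nn, nn)
  w <- cbind(rep(1, q), 0, 0)
  pending <- rep(TRUE, q)
  V <- mesh$vertices
  Fc <- mesh$faces
  inc <- mesh$incident_faces
  C1 <- mesh$cramer[[1]]; C2 <- mesh$cramer[[2]]; C3 <- mesh$cramer[[3]]
  for (k in seq_len(ncol(inc))) {
    rows <- which(pending)
    if (!length(rows)) break
    f <- inc[nn[rows], k]
    ok <- !is.na(f)
    rows <- rows[ok]; f <- f[ok]
    if (!length(rows)) next
    p <- query[rows, , drop = FALSE]
    b1 <- row_dots(p, C1[f, , drop = FALSE])
    b2 <- row_dots(p, C2[f, , drop = FALSE])
    b3 <- row_dots(p, C3[f, , drop = FALSE])
    inside <- is.finite(b1) & is.finite(b2) & is.finite(b3) &
      b1 >= -1e-9 & b2 >= -1e-9 & b3 >= -1e-9
    hit <- rows[inside]
    if (length(hit)) {
      s <- b1[inside] + b2[inside] + b3[inside]
      w[hit, ] <- cbind(b1[inside], b2[inside], b3[inside]) / s
      idx[hit, ] <- cbind(Fc[f[inside], 1], Fc[f[inside], 2], Fc[f[inside], 3])
      pending[hit] <- FALSE
    }
  }
  list(idx = idx, w = w, nn = nn)
}

#' Resample a per-vertex map at arbitrary points on the sphere
#'
#' @param mesh the source `sphere_mesh`.
#' @param values per-vertex values on `mesh`.
#' @param query q x 3 matrix of unit directions.
#' @param method `"nearest"` (closest vertex value) or `"barycentric"`
#'   (triangle-interpolated at the spherical projection).
#' @return numeric vector of length q.
#' @export
resample_map <- function(mesh, values, query, method = c("barycentric", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  nrm <- row_norms(query)
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("query points must be unit-norm", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) != mesh$n_vertices) stop("map length does not match mesh", call. = FALSE)
  if (method == "nearest") {
    values[nearest_vertex(mesh, query)]
  } else {
    bw <- barycentric_weights(mesh, query)
    rowSums(bw$w * matrix(values[bw$idx], nrow(query), 3))
  }
}

#' Resample several per-vertex fields at once with shared weights
#' @noRd
resample_fields <- function(mesh, fields, query, method = "barycentric") {
  fields <- as.matrix(fields)
  if (method == "nearest") {
    return(fields[nearest_vertex(mesh, query), , drop = FALSE])
  }
  bw <- barycentric_weights(mesh, query)
  out <- matrix(0, nrow(query), ncol(fields))
  for (k in 1:3) out <- out + bw$w[, k] * fields[bw$idx[, k], , drop = FALSE]
  out
}

## ---- misc mesh utilities ----------------------------------------------------

#' Vertices within a geodesic disc
#' @param mesh a `sphere_mesh`
#' @param center unit 3-vector
#' @param radius geodesic radius in radians
#' @return integer vertex indices
#' @export
geodesic_disc <- function(mesh, center, radius) {
  which(geodesic_distance(mesh$vertices, matrix(center, 1)) <= radius)
}

#' Edge-connected components of a vertex subset
#' @param mesh a `sphere_mesh`
#' @param vertex_set integer vertex indices
#' @return list of integer vectors (components, largest first)
#' @export
connected_components <- function(mesh, vertex_set) {
  vertex_set <- sort(unique(as.integer(vertex_set)))
  if (!length(vertex_set)) return(list())
  in_set <- logical(mesh$n_vertices)
  in_set[vertex_set] <- TRUE
  seen <- logical(mesh$n_vertices)
  comps <- list()
  for (s in vertex_set) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- mesh$neighbors[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(-lengths(comps))]
}

#' Spherical (signed) orientation of every face under a vertex position field
#' @noRd
face_orientations <- function(positions, faces) {
  a <- positions[faces[, 1], , drop = FALSE]
  b <- positions[faces[, 2], , drop = FALSE]
  c <- positions[faces[, 3], , drop = FALSE]
  row_dots(a, row_cross(b, c))
}

#' TRUE when no spherical face is inverted (all orientations positive)
#' @noRd
no_face_inversions <- function(positions, faces) {
  all(face_orientations(positions, faces) > 0)
}
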