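#' Ordered head-to-tail centerline path
#'
#' Constructor for the centerline container: an ordered 3-D polyline in mm
#' with per-station unit tangents and cumulative arclength. Index 1 is the
#' head end once the path has been oriented (see [orient_path]).
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param step_mm nominal resampling interval.
#' @return A `centerline_path` object.
#' @export
centerline_path <- function(points, step_mm = NA_real_) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points")
  arc <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  if (any(diff(arc) <= 0)) stop("arclength must be strictly increasing ",
                                "(coincident consecutive points)")
  structure(list(points = points, tangents = path_tangents(points),
                 arclength_mm = arc, step_mm = step_mm),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> %d stations, %.1f mm\n",
              nrow(x$points), max(x$arclength_mm)))
  invisible(x)
}

# unit tangents by central differences (one-sided at the ends)
path_tangents <- function(points) {
  n <- nrow(points)
  idx_fwd <- pmin(seq_len(n) + 1L, n)
  idx_bwd <- pmax(seq_len(n) - 1L, 1L)
  tang <- points[idx_fwd, , drop = FALSE] - points[idx_bwd, , drop = FALSE]
  tang / sqrt(rowSums(tang^2))
}

resample_points <- function(points, step_mm) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  keep <- c(TRUE, diff(arc) > 1e-9)
  points <- points[keep, , drop = FALSE]
  arc <- arc[keep]
  total <- arc[length(arc)]
  grid <- seq(0, total, by = step_mm)
  if (total - grid[length(grid)] > 1e-9) grid <- c(grid, total)
  sapply(seq_len(3L), function(a) stats::approx(arc, points[, a], xout = grid)$y)
}

# prolong both path ends along the mean direction of the last few
# stations while the walked point stays inside the mask; the walk is
# capped at the endpoint's clearance (distance to the nearest background
# voxel, i.e. the local inscribed radius), so rounded organ tips -- where
# the skeleton already reaches the extremity -- gain almost nothing while
# flat-cut ends recover their eroded extent
extend_to_boundary <- function(points, mask, vol, span = 5L,
                               max_extension_mm = 25) {
  d <- dim(mask)
  inside <- function(p) {
    ijk <- world_to_voxel(vol, p)
    all(ijk >= 1L) && all(ijk <= d) && mask[ijk[1L], ijk[2L], ijk[3L]]
  }
  clearance <- function(p) {
    ctr <- world_to_voxel(vol, p)
    rad <- ceiling(max_extension_mm / vol$spacing)
    idx <- lapply(seq_len(3L), function(a)
      seq.int(max(1L, ctr[a] - rad[a]), min(d[a], ctr[a] + rad[a])))
    sub <- mask[idx[[1L]], idx[[2L]], idx[[3L]]]
    bg <- which(!sub)
    if (length(bg) == 0L) return(max_extension_mm)
    ijk <- arrayInd(bg, dim(sub))
    ijk <- sweep(ijk, 2L, vapply(idx, `[`, integer(1L), 1L) - 1L, "+")
    min(sqrt(rowSums(sweep(voxel_to_world(vol, ijk), 2L,
                           as.numeric(p), "-")^2)))
  }
  step <- min(vol$spacing) / 2
  one_end <- function(pts) {                # extends the start of pts
    k <- min(span, nrow(pts) - 1L)
    dir <- pts[1L, ] - pts[1L + k, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) return(pts)
    dir <- dir / nrm
    limit <- min(max_extension_mm, clearance(pts[1L, ]))
    added <- NULL
    for (i in seq_len(floor(limit / step))) {
      p <- pts[1L, ] + i * step * dir
      if (!inside(p)) break
      added <- rbind(p, added)
    }
    rbind(added, pts)
  }
  points <- one_end(points)
  points <- one_end(points[nrow(points):1L, , drop = FALSE])
  points[nrow(points):1L, , drop = FALSE]
}

moving_average <- function(points, window) {
  if (window <= 1L) return(points)
  n <- nrow(points)
  half <- floor(window / 2)
  out <- points
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(points[lo:hi, , drop = FALSE])
  }
  out
}

#' Estimate the pancreas centerline from segmentation masks
#'
#' Implements the centerline step of the D/P algorithm on the union of the
#' parenchyma and MPD masks: largest 26-connected component, 3-D
#' topological thinning to a curve skeleton, skeleton graph
#' (26-connectivity, edges weighted by physical inter-voxel distance),
#' geodesic diameter (the longest shortest path over all voxel pairs,
#' ties broken toward the lexicographically smallest endpoint voxel
#' index), moving-average smoothing, arclength resampling and
#' central-difference tangents. Orientation (which end is the head) is
#' decided separately by [orient_path].
#'
#' @param pancreas_mask binary [image_volume].
#' @param mpd_mask optional binary [image_volume] on the same grid.
#' @param step_mm resampling interval (default 1 mm).
#' @param smoothing_window moving-average window in skeleton stations.
#' @return An unoriented `centerline_path`.
#' @export
estimate_centerline <- function(pancreas_mask, mpd_mask = NULL, step_mm = 1,
                                smoothing_window = 5L) {
  stopifnot(is_image_volume(pancreas_mask))
  arr <- pancreas_mask$data > 0
  if (!is.null(mpd_mask)) {
    stopifnot(is_image_volume(mpd_mask),
              all(dim(mpd_mask$data) == dim(arr)))
    arr <- arr | (mpd_mask$data > 0)
  }
  if (!any(arr)) stop("mask is empty: no foreground voxels")
  comp <- largest_component(arr)
  skel <- array(.thin_3d(comp, dim(comp)), dim = dim(comp))
  vox <- which(skel)
  if (length(vox) < 2L)
    stop("skeleton degenerated to ", length(vox),
         " voxel(s); the mask may be a compact blob rather than a tube")
  ijk <- arrayInd(vox, dim(skel))
  xyz <- voxel_to_world(pancreas_mask, ijk)

  # skeleton graph: 26-neighbour edges weighted by physical distance
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  d <- dim(skel)
  edges <- NULL
  wts <- NULL
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2L, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    tgt <- match(lin, vox)
    src <- which(ok)[!is.na(tgt)]
    tgt <- tgt[!is.na(tgt)]
    keep <- src < tgt                       # each undirected edge once
    if (!any(keep)) next
    edges <- rbind(edges, cbind(src[keep], tgt[keep]))
    wts <- c(wts, sqrt(rowSums((xyz[src[keep], , drop = FALSE] -
                                xyz[tgt[keep], , drop = FALSE])^2)))
  }
  if (is.null(edges)) stop("skeleton voxels are mutually disconnected")
  g <- igraph::make_graph(t(edges), n = length(vox), directed = FALSE)
  igraph::E(g)$weight <- wts
  memb <- igraph::components(g)$membership
  main <- which.max(tabulate(memb))
  sub <- which(memb == main)

  dm <- igraph::distances(g, v = sub, to = sub)
  dm[!is.finite(dm)] <- -Inf
  best <- max(dm)
  cand <- which(dm >= best - 1e-9, arr.ind = TRUE)
  # deterministic tie-break: smallest (then second-smallest) voxel index
  endpt <- t(apply(cand, 1L, function(rc) {
    pair <- sort(c(vox[sub[rc[1L]]], vox[sub[rc[2L]]]))
    pair
  }))
  pick <- order(endpt[, 1L], endpt[, 2L])[1L]
  from <- sub[cand[pick, 1L]]; to <- sub[cand[pick, 2L]]
  if (vox[from] > vox[to]) { tmp <- from; from <- to; to <- tmp }
  vp <- igraph::shortest_paths(g, from = from, to = to, output = "vpath")$vpath[[1L]]
  pts <- xyz[as.integer(vp), , drop = FALSE]

  # thinning erodes flat organ ends before a curve endpoint can form, so
  # the geodesic stops short of the organ extremities; walk each end
  # outward along its local direction until leaving the mask
  pts <- extend_to_boundary(pts, comp, pancreas_mask)
  pts <- moving_average(pts, smoothing_window)
  pts <- resample_points(pts, step_mm)
  centerline_path(pts, step_mm = step_mm)
}

#' Orient a centerline head-to-tail
#'
#' Decides which end of an estimated centerline is the pancreatic head.
#' The rule is either an explicit head-end coordinate (`head_point`) or an
#' anatomical direction vector (`head_vector`): the head is the endpoint
#' with the larger projection onto the vector. Idempotent; applying the
#' reversed rule reverses the point order exactly.
#'
#' @param path a `centerline_path`.
#' @param head_rule a [head_point] or [head_vector] rule.
#' @return The oriented `centerline_path` (index 1 = head).
#' @export
orient_path <- function(path, head_rule) {
  stopifnot(inherits(path, "centerline_path"))
  ends <- path$points[c(1L, nrow(path$points)), , drop = FALSE]
  score <- switch(head_rule$type,
    point = -sqrt(rowSums(sweep(ends, 2L, head_rule$value, "-")^2)),
    vector = as.vector(ends %*% head_rule$value),
    stop("unknown head rule type: ", head_rule$type))
  if (abs(score[1L] - score[2L]) < 1e-9)
    stop("head rule is ambiguous: both endpoints score equally; ",
         "supply an explicit head coordinate")
  if (score[1L] >= score[2L]) return(path)
  centerline_path(path$points[nrow(path$points):1L, , drop = FALSE],
                  step_mm = path$step_mm)
}

#' @rdname orient_path
#' @param value for `head_point` a length-3 mm coordinate near the head;
#'   for `head_vector` a direction vector pointing toward the head.
#' @export
head_point <- function(value) list(type = "point", value = as.numeric(value))

#' @rdname orient_path
#' @export
head_vector <- function(value) list(type = "vector", value = as.numeric(value))

#' Export / import a centerline as CSV
#'
#' @param path a `centerline_path`.
#' @param file CSV path with columns
#'   `station_index,x_mm,y_mm,z_mm,arclength_mm`.
#' @return `file` (write) or a `centerline_path` (read).
#' @export
write_path_csv <- function(path, file) {
  df <- data.frame(station_index = seq_len(nrow(path$points)) - 1L,
                   x_mm = path$points[, 1L], y_mm = path$points[, 2L],
                   z_mm = path$points[, 3L],
                   arclength_mm = path$arclength_mm)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(file) {
  df <- utils::read.csv(file)
  centerline_path(unname(as.matrix(df[, c("x_mm", "y_mm", "z_mm")])))
}
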