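#' @importFrom stats pgamma rnorm runif coef
NULL

COVER_CLASSES <- c("shoreline", "crops", "woody_wetland",
                   "herbaceous_wetland", "urban", "other")

#' Build a rectangular grid of stopover nodes
#'
#' Tiles a rectangular extent with square nodes of side `resolution`.
#' Synthetic grids use planar coordinates in km (`x` east, `y` north);
#' real-world grids use lon/lat degrees. The coordinate mode is stored
#' explicitly in the grid metadata and never inferred from the values.
#'
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` in km
#'   (planar) or `c(lonmin, lonmax, latmin, latmax)` in degrees (lonlat).
#' @param resolution node side length, km (planar). At the reference
#'   resolution of 32.19 km each node covers 1036 km^2.
#' @param coords `"planar"` or `"lonlat"`.
#' @return A `flyway_grid`: a list with a `nodes` data.frame
#'   (`node_id`, `x`, `y`, `area`, cover columns initialised to zero,
#'   `breeding`), plus `resolution`, `coords`, `n_x`, `n_y`.
#' @export
build_grid <- function(extent, resolution, coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  stopifnot(length(extent) == 4, is.numeric(extent))
  if (!(resolution > 0)) stop("resolution must be positive")
  dx <- extent[2] - extent[1]
  dy <- extent[4] - extent[3]
  if (dx <= 0 || dy <= 0) stop("degenerate extent: box has nonpositive side")
  # integer tiling; tolerate float fuzz so 96.57/32.19 counts as exactly 3
  n_x <- max(1L, as.integer(floor(dx / resolution + 1e-9)))
  n_y <- max(1L, as.integer(floor(dy / resolution + 1e-9)))
  cx <- extent[1] + (seq_len(n_x) - 0.5) * resolution
  cy <- extent[3] + (seq_len(n_y) - 0.5) * resolution
  nodes <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  nodes <- data.frame(node_id = seq_len(nrow(nodes)) - 1L, nodes)
  nodes$area <- resolution^2
  for (cc in COVER_CLASSES) nodes[[cc]] <- 0
  nodes$breeding <- FALSE
  structure(list(nodes = nodes, resolution = resolution, coords = coords,
                 n_x = n_x, n_y = n_y),
            class = "flyway_grid")
}

#' @export
print.flyway_grid <- function(x, ...) {
  cat(sprintf("<flyway_grid> %d nodes (%d x %d), resolution %.4g km, %s coords\n",
              nrow(x$nodes), x$n_x, x$n_y, x$resolution, x$coords))
  cat(sprintf("  node area %.4g km^2, %d breeding nodes\n",
              x$nodes$area[1], sum(x$nodes$breeding)))
  invisible(x)
}

check_cover <- function(cover) {
  cover <- as.data.frame(cover)
  present <- intersect(COVER_CLASSES, names(cover))
  if (length(present) == 0) stop("no recognised cover columns present")
  m <- as.matrix(cover[, present, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("cover proportions must lie in [0, 1]")
  if (any(rowSums(m) > 1 + 1e-9))
    stop("cover proportions sum to more than 1 in some node")
  cover[, present, drop = FALSE]
}

#' Roosting quality of each node
#'
#' The default rule equates roosting quality with the shoreline
#' proportion of a node (shoreline cover is used as a mapped proxy for
#' roost availability). The alternative rule adds the two wetland
#' classes, treating shoreline, woody wetland and herbaceous wetland as
#' roosting habitat.
#'
#' @param cover data.frame of per-node cover proportions.
#' @param rule `"shoreline"` (default) or `"shoreline_wetland"`.
#' @return numeric vector of roosting quality in \[0, 1\].
#' @export
roosting_quality <- function(cover, rule = c("shoreline", "shoreline_wetland")) {
  rule <- match.arg(rule)
  cover <- check_cover(cover)
  r <- if (rule == "shoreline") {
    cover$shoreline %||% rep(0, nrow(cover))
  } else {
    (cover$shoreline %||% 0) + (cover$woody_wetland %||% 0) +
      (cover$herbaceous_wetland %||% 0)
  }
  pmin(pmax(r, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial forage endowment per node and cover class
#'
#' Forage (kJ) is area x cover proportion x energy density, discounted
#' for accessibility by distance to the nearest roosting habitat:
#' nodes whose forage sits far from roosts yield less net energy.
#' The discount is exponential with a configurable e-folding distance
#' whose default (16 km) is the local-movement scale below which bird
#' displacement counts as within-node dispersal.
#'
#' @param cover data.frame of per-node cover proportions.
#' @param area node areas, km^2 (scalar or vector).
#' @param energy_density named vector, kJ per km^2 of each cover class.
#' @param roost_distance per-node distance to nearest roosting habitat, km.
#' @param efold e-folding distance of the accessibility discount, km.
#' @return matrix (node x cover class) of initial forage, kJ.
#' @export
initial_forage <- function(cover, area, energy_density,
                           roost_distance = 0, efold = 16) {
  cover <- check_cover(cover)
  if (any(energy_density < 0)) stop("negative forage energy densities")
  if (any(roost_distance < 0)) stop("negative roost distances")
  classes <- names(cover)
  dens <- energy_density[classes]
  dens[is.na(dens)] <- 0
  access <- exp(-roost_distance / efold)   # 1 at distance 0
  f0 <- as.matrix(cover) * rep(dens, each = nrow(cover))
  f0 <- f0 * area * access
  dimnames(f0) <- list(NULL, classes)
  f0
}

#' Pairwise node distance matrix (km)
#'
#' Euclidean for planar grids; great-circle (haversine, radius 6371 km)
#' for lon/lat grids.
#'
#' @param grid a `flyway_grid`.
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
distance_matrix <- function(grid) {
  nodes <- grid$nodes
  if (grid$coords == "planar") {
    d <- as.matrix(stats::dist(nodes[, c("x", "y")]))
  } else {
    p <- as.matrix(nodes[, c("x", "y")])  # lon, lat
    n <- nrow(p)
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    d <- matrix(geosphere::distHaversine(p[idx$i, , drop = FALSE],
                                         p[idx$j, , drop = FALSE],
                                         r = 6371000) / 1000, n, n)
  }
  dimnames(d) <- NULL
  d
}

#' Distance from each node to the nearest breeding node
#'
#' @param grid a `flyway_grid` with at least one breeding node flagged.
#' @param dist optional precomputed [distance_matrix()].
#' @return numeric vector, km; exactly 0 on breeding nodes.
#' @export
breeding_distance <- function(grid, dist = NULL) {
  br <- which(grid$nodes$breeding)
  if (length(br) == 0) stop("grid has no breeding nodes")
  if (is.null(dist)) dist <- distance_matrix(grid)
  db <- apply(dist[, br, drop = FALSE], 1, min)
  db[br] <- 0
  db
}

#' Initialise the population on the breeding grounds
#'
#' All abundance is placed on breeding nodes in proportion to habitat
#' quality times an optional survey weight (the synthetic default uses
#' quality alone), and by default entirely in the top body-condition
#' class. Accounting is continuous-mass: abundance is real-valued and
#' the total equals `n0` exactly.
#'
#' @param grid a `flyway_grid` with breeding flags and roosting quality.
#' @param n0 initial population size (> 0).
#' @param n_classes number of body-condition classes.
#' @param quality per-node habitat quality used for allocation; defaults
#'   to the grid's roosting quality column `R` if present, else uniform.
#' @param survey_weights optional per-node survey weights (multiplied
#'   with quality; the combination rule is a documented model choice).
#' @param class_alloc vector of length `n_classes` of proportions, or
#'   `"top"` to start everyone in the best class.
#' @return list with `ab` (node x class abundance matrix), `deaths` (0),
#'   and `day` (1).
#' @export
init_population <- function(grid, n0, n_classes = 21, quality = NULL,
                            survey_weights = NULL, class_alloc = "top") {
  if (!(n0 > 0)) stop("n0 must be positive")
  br <- which(grid$nodes$breeding)
  if (length(br) == 0) stop("grid has no breeding nodes")
  n <- nrow(grid$nodes)
  if (is.null(quality)) quality <- grid$nodes$R %||% rep(1, n)
  w <- quality[br]
  if (!is.null(survey_weights)) w <- w * survey_weights[br]
  if (any(w < 0)) stop("negative allocation weights")
  if (sum(w) <= 0) stop("total allocation weight is zero")
  alloc <- w / sum(w)
  if (identical(class_alloc, "top")) {
    class_alloc <- c(rep(0, n_classes - 1), 1)
  }
  stopifnot(length(class_alloc) == n_classes,
            all(class_alloc >= 0), sum(class_alloc) > 0)
  class_alloc <- class_alloc / sum(class_alloc)
  ab <- matrix(0, n, n_classes)
  ab[br, ] <- n0 * outer(alloc, class_alloc)
  # pin the float residual on the largest cell so the total is exactly n0
  imax <- which.max(ab)
  ab[imax] <- ab[imax] + (n0 - sum(ab))
  list(ab = ab, deaths = 0, day = 1L)
}
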