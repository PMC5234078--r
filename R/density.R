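# Phosphate head-group density (3-D Gaussian KDE on a regular grid, exported
# as OpenDX), density thresholding with connected components, and membrane
# thickness maps.

#' 3-D Gaussian kernel density of phosphate positions of contacting lipids
#'
#' Collects, over all frames, the head-group phosphorus coordinates of lipids
#' in contact with the protein in that frame, and evaluates a product-Gaussian
#' KDE on a regular grid.  Count-density normalization: each point contributes
#' a kernel of unit mass, so the grid integral equals the number of points.
#' Values are reported in nm^-3 (1 nm^-3 = 1e-3 A^-3).
#'
#' @param traj an aligned `md_trajectory`.
#' @param contacts a `contact_table` for the same trajectory.
#' @param bandwidth kernel s.d. per axis (A); default Scott's rule
#'   `sigma_i * n^(-1/7)`.
#' @param spacing grid spacing (A), default 1.
#' @return a `density_grid`: `origin` (A), `spacing` (A), `values` 3-D array
#'   (nm^-3), `bandwidth` (A), `n_points`.
#' @export
phosphate_density <- function(traj, contacts, bandwidth = NULL, spacing = 1.0) {
  top <- traj$topology
  ids <- contacts$lipid_ids
  pts <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(f) {
    inc <- ids[contacts$in_contact[f, ]]
    if (!length(inc)) return(NULL)
    pidx <- which(top$molecule == "lipid" & top$element == "P" &
                    top$lipid_id %in% inc)
    traj$frames[[f]][pidx, , drop = FALSE]
  }))
  if (is.null(pts) || !nrow(pts)) stop("no contact events: nothing to estimate")
  kde3d_grid(pts, bandwidth = bandwidth, spacing = spacing)
}

#' Evaluate a count-normalized 3-D Gaussian KDE on a regular grid
#'
#' @param points n x 3 matrix of coordinates (A).
#' @param bandwidth per-axis kernel s.d. (A), scalar or length 3; default
#'   Scott's rule.
#' @param spacing grid spacing (A).
#' @param pad grid padding beyond the data range, in bandwidths.
#' @return a `density_grid` (values in nm^-3).
#' @export
kde3d_grid <- function(points, bandwidth = NULL, spacing = 1.0, pad = 4) {
  stopifnot(is.matrix(points), ncol(points) == 3L, nrow(points) >= 1L)
  if (spacing <= 0) stop("spacing must be positive")
  n <- nrow(points)
  if (is.null(bandwidth)) {
    sig <- apply(points, 2, sd)
    sig[!is.finite(sig) | sig <= 0] <- 1.0
    bandwidth <- sig * n^(-1 / 7)  # Scott's rule, d = 3
  }
  bandwidth <- rep_len(bandwidth, 3L)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  axes <- lapply(1:3, function(d) {
    lo <- min(points[, d]) - pad * bandwidth[d]
    hi <- max(points[, d]) + pad * bandwidth[d]
    seq(lo, hi, by = spacing)
  })
  dims <- vapply(axes, length, integer(1))
  vals <- array(0, dims)
  # separable kernel: accumulate the outer product per point, truncated at
  # `pad` bandwidths (mass loss < 1e-4 per axis at pad = 4)
  for (k in seq_len(n)) {
    w <- lapply(1:3, function(d) {
      i <- which(abs(axes[[d]] - points[k, d]) <= pad * bandwidth[d])
      list(i = i, v = dnorm(axes[[d]][i], points[k, d], bandwidth[d]))
    })
    if (any(vapply(w, function(u) length(u$i) == 0L, logical(1)))) next
    vals[w[[1]]$i, w[[2]]$i, w[[3]]$i] <-
      vals[w[[1]]$i, w[[2]]$i, w[[3]]$i] +
      outer(outer(w[[1]]$v, w[[2]]$v), w[[3]]$v)
  }
  structure(list(origin = vapply(axes, min, numeric(1)), spacing = spacing,
                 values = vals * 1000,  # A^-3 -> nm^-3
                 bandwidth = bandwidth, n_points = n),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %s voxels, spacing %.2f A, max %.3g nm^-3, integral ~%.1f points\n",
              paste(dim(x$values), collapse = "x"), x$spacing, max(x$values),
              grid_integral(x)))
  invisible(x)
}

#' Integral of a density grid in point-count units
#'
#' @param grid a `density_grid`.
#' @export
grid_integral <- function(grid) {
  sum(grid$values) / 1000 * grid$spacing^3
}

#' Threshold a density grid and label connected regions
#'
#' @param grid a `density_grid`.
#' @param cutoff density cutoff (nm^-3); default 2e-5.
#' @return list with `mask` (logical array of voxels >= cutoff), `labels`
#'   (integer array, 0 = background), `n_components`, and `volumes` (A^3,
#'   ranked descending).
#' @export
threshold_density <- function(grid, cutoff = 2e-5) {
  mask <- grid$values >= cutoff
  lab <- label_components_26(mask)
  sizes <- if (max(lab) > 0) sort(tabulate(lab[lab > 0]), decreasing = TRUE)
    else integer(0)
  list(mask = mask, labels = lab, n_components = max(lab),
       volumes = sizes * grid$spacing^3, cutoff = cutoff)
}

# 26-connected component labelling by flood fill.
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  comp <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      pos <- arrayInd(queue, d)
      queue <- integer(0)
      for (r in seq_len(nrow(pos))) {
        cand <- sweep(nb, 2, pos[r, ], "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
          cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
        ci <- cand[ok, , drop = FALSE]
        lin <- ci[, 1] + d[1] * (ci[, 2] - 1L) + d[1] * d[2] * (ci[, 3] - 1L)
        new <- lin[mask[lin] & lab[lin] == 0L]
        lab[new] <- comp
        queue <- c(queue, new)
      }
    }
  }
  lab
}

#' Write a density grid in OpenDX format
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing),
    sprintf("delta 0 %.6g 0", grid$spacing),
    sprintf("delta 0 0 %.6g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX convention: last grid index (z) varies fastest
  flat <- as.vector(aperm(grid$values, c(3, 2, 1)))
  lines <- vapply(split(flat, ceiling(seq_along(flat) / 3)),
                  function(ch) paste(sprintf("%.8g", ch), collapse = " "),
                  character(1))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX density grid
#'
#' @param path DX file path.
#' @return a `density_grid`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  cnt <- as.integer(strsplit(sub(".*counts ", "", lines[grep("gridpositions", lines)[1]]), " ")[[1]])
  origin <- as.numeric(strsplit(sub("origin ", "", lines[grep("^origin", lines)[1]]), " ")[[1]])
  deltas <- lines[grep("^delta", lines)]
  spacing <- as.numeric(strsplit(sub("delta ", "", deltas[1]), " ")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1L
  end <- grep("attribute", lines)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  arr <- aperm(array(vals, rev(cnt)), c(3, 2, 1))  # stored z-fastest
  structure(list(origin = origin, spacing = spacing, values = arr,
                 bandwidth = NA_real_, n_points = NA_integer_),
            class = "density_grid")
}

#' Membrane thickness map from leaflet phosphate surfaces
#'
#' Per xy-cell, the mean upper-leaflet phosphorus z minus the mean
#' lower-leaflet phosphorus z, accumulated over all frames.  Cells lacking
#' either leaflet are masked (`NA`), never zero-filled.  Coordinates are
#' wrapped into the box in xy when a box is present.
#'
#' @param traj an aligned `md_trajectory` (leaflets are assigned per frame).
#' @param grid_spacing xy cell size (A), default 4.
#' @return a `thickness_map`: `x`, `y` cell centers, `thickness` matrix (A,
#'   `NA` where uncovered), `coverage` counts, and `minimum`
#'   (list with `x`, `y`, `thickness`).
#' @export
thickness_map <- function(traj, grid_spacing = 4) {
  stopifnot(grid_spacing > 0)
  top <- traj$topology
  pidx <- which(top$molecule == "lipid" & top$element == "P")
  if (length(pidx) < 2L) stop("need phosphorus atoms to build a thickness map")
  boxed <- !is.null(traj$box)
  if (boxed) {
    bx <- traj$box[1, 1]; by <- traj$box[1, 2]
    xr <- c(0, bx); yr <- c(0, by)
  } else {
    allxy <- do.call(rbind, lapply(traj$frames, function(f) f[pidx, 1:2]))
    xr <- range(allxy[, 1]); yr <- range(allxy[, 2])
  }
  xb <- seq(xr[1], xr[2] + grid_spacing, by = grid_spacing)
  yb <- seq(yr[1], yr[2] + grid_spacing, by = grid_spacing)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  sum_up <- matrix(0, nx, ny); n_up <- matrix(0L, nx, ny)
  sum_lo <- matrix(0, nx, ny); n_lo <- matrix(0L, nx, ny)
  for (f in seq_len(n_frames(traj))) {
    co <- traj$frames[[f]][pidx, , drop = FALSE]
    xy <- co[, 1:2, drop = FALSE]
    if (boxed) xy <- cbind(xy[, 1] %% bx, xy[, 2] %% by)
    z <- co[, 3]
    upper <- z > median(z)
    ix <- pmin(pmax(findInterval(xy[, 1], xb), 1L), nx)
    iy <- pmin(pmax(findInterval(xy[, 2], yb), 1L), ny)
    for (k in seq_along(z)) {
      if (upper[k]) {
        sum_up[ix[k], iy[k]] <- sum_up[ix[k], iy[k]] + z[k]
        n_up[ix[k], iy[k]] <- n_up[ix[k], iy[k]] + 1L
      } else {
        sum_lo[ix[k], iy[k]] <- sum_lo[ix[k], iy[k]] + z[k]
        n_lo[ix[k], iy[k]] <- n_lo[ix[k], iy[k]] + 1L
      }
    }
  }
  covered <- n_up > 0 & n_lo > 0
  thick <- matrix(NA_real_, nx, ny)
  thick[covered] <- sum_up[covered] / n_up[covered] -
    sum_lo[covered] / n_lo[covered]
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  yc <- (yb[-1] + yb[-length(yb)]) / 2
  minimum <- if (any(covered)) {
    i <- which(thick == min(thick, na.rm = TRUE), arr.ind = TRUE)[1, ]
    list(x = xc[i[1]], y = yc[i[2]], thickness = min(thick, na.rm = TRUE))
  } else NULL
  structure(list(x = xc, y = yc, thickness = thick,
                 coverage = n_up + n_lo, minimum = minimum,
                 grid_spacing = grid_spacing),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("thickness_map: %dx%d cells (%.1f A); thickness %.1f-%.1f A",
              length(x$x), length(x$y), x$grid_spacing,
              min(x$thickness, na.rm = TRUE), max(x$thickness, na.rm = TRUE)))
  if (!is.null(x$minimum))
    cat(sprintf("; minimum %.1f A at (%.1f, %.1f)\n", x$minimum$thickness,
                x$minimum$x, x$minimum$y))
  else cat("\n")
  invisible(x)
}

#' Write a thickness map as delimited text
#'
#' @param map a `thickness_map`.
#' @param path output path.
#' @export
write_thickness_map <- function(map, path) {
  d <- expand.grid(x = map$x, y = map$y)
  d$thickness <- as.vector(map$thickness)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# grid_spacing=%g", map$grid_spacing), con)
  write.table(d, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
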