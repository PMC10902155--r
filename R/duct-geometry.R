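#' Parameterized 2D duct geometry
#'
#' A plane channel of length `L` and height `H = 2h` with a smooth
#' constriction (a cosine-squared bump) on the top wall. The bump emulates a
#' narrowed nasal passage: a deep bump plays the pre-operative anatomy, a
#' shallower one the post-operative, surgically widened passage. The bottom
#' wall is never modified, mimicking the unoperated side.
#'
#' @param L channel length (m).
#' @param H channel height (m), `H = 2h` with `h` the nominal half-height.
#' @param nx,ny number of cells in the streamwise and wall-normal directions.
#' @param centre bump centre (m); default `L/2`.
#' @param width bump support width (m); default `L/2`.
#' @param depth bump depth as a fraction of `H`, in `[0, 1)`; 0 is a straight
#'   channel.
#' @return an object of class `duct_geometry`.
#' @export
duct_geometry <- function(L, H, nx, ny, centre = L / 2, width = L / 2,
                          depth = 0) {
  stopifnot(L > 0, H > 0, nx >= 4, ny >= 4, width > 0)
  if (depth < 0 || depth >= 1) {
    stop("constriction depth must lie in [0, 1): the channel never fully closes",
         call. = FALSE)
  }
  structure(list(L = L, H = H, nx = as.integer(nx), ny = as.integer(ny),
                 centre = centre, width = width, depth = depth),
            class = "duct_geometry")
}

#' @export
print.duct_geometry <- function(x, ...) {
  cat(sprintf("<duct_geometry> L = %g, H = %g, %d x %d cells, bump depth %.3g\n",
              x$L, x$H, x$nx, x$ny, x$depth))
  invisible(x)
}

# C1 wall bump profile in [0, 1]
bump_profile <- function(x, centre, width) {
  s <- abs(x - centre) / (width / 2)
  ifelse(s < 1, cos(pi * s / 2)^2, 0)
}

#' Build the staggered grid for a duct geometry
#'
#' Discretizes the duct on a marker-and-cell (MAC) staggered Cartesian grid:
#' pressure at cell centres, `u` on vertical faces, `v` on horizontal faces.
#' The constriction is represented by a blocked-cell (stairstep) mask, as
#' recorded in the returned metadata: a cell is solid when its centre lies
#' above the wall profile, so the open gap converges to the nominal
#' `(1 - depth) * H` at first order in the cell height.
#'
#' @param geom a [duct_geometry()].
#' @return a list with grid spacings, coordinates, the solid-cell mask and
#'   face-fluidity masks; errors if fewer than 8 cells span the constricted
#'   gap.
#' @export
build_grid <- function(geom) {
  stopifnot(inherits(geom, "duct_geometry"))
  nx <- geom$nx; ny <- geom$ny
  dx <- geom$L / nx; dy <- geom$H / ny
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  yw <- geom$H * (1 - geom$depth * bump_profile(xc, geom$centre, geom$width))
  solid <- outer(seq_len(nx), seq_len(ny), function(i, j) yc[j] > yw[i])
  fluidP <- !solid
  open_cells <- rowSums(fluidP)
  if (min(open_cells) < 8L) {
    stop("fewer than 8 cells span the constricted gap (",
         min(open_cells), "); refine ny or reduce depth", call. = FALSE)
  }
  fluidU <- rbind(fluidP[1L, ], fluidP[-nx, ] & fluidP[-1L, ], fluidP[nx, ])
  fluidV <- cbind(rep(FALSE, nx),
                  fluidP[, -ny] & fluidP[, -1L],
                  rep(FALSE, nx))
  list(geom = geom, nx = nx, ny = ny, dx = dx, dy = dy, xc = xc, yc = yc,
       wall_profile = yw, solid = solid, fluidP = fluidP,
       fluidU = fluidU, fluidV = fluidV,
       open_height = open_cells * dy,
       throat_height = min(open_cells) * dy,
       metadata = list(constriction_representation = "blocked-cell stairstep mask"))
}

#' Open height of the duct at its narrowest section
#'
#' @param grid a grid from [build_grid()].
#' @return the discrete throat opening (m).
#' @export
grid_throat_height <- function(grid) grid$throat_height
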