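#' Geometric density maps for the subtomogram simulator
#'
#' Renders a centred, nonnegative density volume for one shape specification
#' on a cubic grid. The shapes are simple geometric stand-ins for
#' macromolecular density maps; class distinguishability is controlled by
#' their size parameters, mimicking the small/medium/large difficulty
#' gradient of macromolecules sorted by molecular weight.
#'
#' Supported types and their parameters (all in voxels):
#' \describe{
#'   \item{`sphere`}{`radius`}
#'   \item{`ellipsoid`}{semi-axes `a`, `b`, `c`}
#'   \item{`dumbbell`}{two spheres of `radius` with centres at `+/- offset`
#'     along x}
#'   \item{`rod`}{cylinder of `radius` and `half_length` along z}
#'   \item{`hollow_shell`}{spherical shell between `inner` and `outer` radii}
#'   \item{`l_tetromino`}{L-shaped union of cubes with edge `cube`}
#' }
#'
#' @param shape_spec a list with element `type` (one of the names above) and
#'   the type's size parameters.
#' @param grid_size voxels per edge of the cubic grid (>= 8).
#' @return a `grid_size^3` array; the shape interior is 1, background exactly 0.
#' @examples
#' v <- generate_shape_density(list(type = "sphere", radius = 5), 32)
#' sum(v > 0)
#' @export
generate_shape_density <- function(shape_spec, grid_size) {
  if (!is.list(shape_spec) || is.null(shape_spec$type))
    .fscc_stop("shape_spec must be a list with a 'type' element")
  if (grid_size < 8) .fscc_stop("grid_size must be >= 8")
  g <- as.integer(grid_size)
  half <- (g - 1) / 2  # largest extent that stays inside the grid
  ax <- seq_len(g) - (g + 1) / 2
  X <- array(rep(ax, times = g * g), dim = c(g, g, g))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  type <- shape_spec$type
  p <- shape_spec
  chk <- function(extent, what) {
    if (extent > half)
      .fscc_stop(sprintf("%s (extent %.1f voxels) does not fit inside grid %d",
                         what, extent, g))
  }
  vol <- switch(type,
    sphere = {
      r <- p$radius
      if (is.null(r) || r < 0) .fscc_stop("sphere needs radius >= 0")
      chk(r, "sphere")
      (X^2 + Y^2 + Z^2 <= r^2) * 1
    },
    ellipsoid = {
      if (any(vapply(p[c("a", "b", "c")], is.null, TRUE)))
        .fscc_stop("ellipsoid needs semi-axes a, b, c")
      chk(max(p$a, p$b, p$c), "ellipsoid")
      ((X / p$a)^2 + (Y / p$b)^2 + (Z / p$c)^2 <= 1) * 1
    },
    dumbbell = {
      r <- p$radius; d <- p$offset
      if (is.null(r) || is.null(d)) .fscc_stop("dumbbell needs radius and offset")
      chk(r + d, "dumbbell")
      (((X - d)^2 + Y^2 + Z^2 <= r^2) | ((X + d)^2 + Y^2 + Z^2 <= r^2)) * 1
    },
    rod = {
      r <- p$radius; h <- p$half_length
      if (is.null(r) || is.null(h)) .fscc_stop("rod needs radius and half_length")
      chk(max(r, h), "rod")
      ((X^2 + Y^2 <= r^2) & (abs(Z) <= h)) * 1
    },
    hollow_shell = {
      ro <- p$outer; ri <- p$inner
      if (is.null(ro) || is.null(ri) || ri >= ro)
        .fscc_stop("hollow_shell needs inner < outer radii")
      chk(ro, "hollow_shell")
      r2 <- X^2 + Y^2 + Z^2
      ((r2 <= ro^2) & (r2 >= ri^2)) * 1
    },
    l_tetromino = {
      s <- p$cube
      if (is.null(s)) .fscc_stop("l_tetromino needs cube edge")
      chk(1.5 * s, "l_tetromino")
      inbox <- function(cx, cy, cz) {
        (abs(X - cx) <= s / 2) & (abs(Y - cy) <= s / 2) & (abs(Z - cz) <= s / 2)
      }
      # three cubes stacked along z, one attached along x at the bottom
      (inbox(0, 0, -s) | inbox(0, 0, 0) | inbox(0, 0, s) | inbox(s, 0, -s)) * 1
    },
    .fscc_stop("unknown shape type: ", type)
  )
  vol
}

#' Default shape catalogue for a given grid size
#'
#' A fixed set of up to eight shape specifications whose sizes scale with
#' the grid. The catalogue is organized as shape *families* at large,
#' medium and small size tiers — mirroring how macromolecules group by
#' molecular weight, with structurally similar classes occurring at
#' different sizes. A random base/novel split therefore tends to leave a
#' similar base relative for each novel class, which is the regime in
#' which transferring base-class feature statistics is justified.
#'
#' @param n_classes number of shape classes requested (1..8).
#' @param grid_size voxels per edge; shapes are scaled to fit.
#' @return a list of `n_classes` shape specifications.
#' @export
default_shape_set <- function(n_classes, grid_size = 32) {
  u <- grid_size / 32  # scale factor relative to the reference grid
  all <- list(
    list(type = "sphere",       radius = 10 * u),                  # large
    list(type = "hollow_shell", outer = 11 * u, inner = 7 * u),    # large
    list(type = "ellipsoid",    a = 9 * u, b = 6 * u, c = 4 * u),  # medium
    list(type = "dumbbell",     radius = 4.5 * u, offset = 7 * u), # medium
    list(type = "rod",          radius = 3.5 * u, half_length = 10 * u),
    list(type = "sphere",       radius = 5 * u),                   # small
    list(type = "rod",          radius = 2 * u, half_length = 6 * u),
    list(type = "l_tetromino",  cube = 5 * u)                      # small
  )
  if (n_classes < 1 || n_classes > length(all))
    .fscc_stop("n_classes must be between 1 and ", length(all))
  all[seq_len(n_classes)]
}
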