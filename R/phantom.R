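#' Tissue configuration for digital pelvis phantoms
#'
#' Nominal HU means and texture standard deviations per tissue, rectal
#' air-pocket statistics, and the admissible pelvis width range. Nominal
#' values follow standard radiology ranges; air is exactly -1000 HU by
#' definition of the Hounsfield scale.
#'
#' @param hu named numeric vector of nominal HU means for `air`, `fat`,
#'   `muscle`, `spongy_bone`, `cortical_bone`, `bladder`, `ctv`.
#' @param texture_sd named numeric vector of Gaussian texture SDs (HU) for
#'   the same tissues; air carries no texture.
#' @param air_pocket_prob per-slice probability of a rectal air pocket.
#' @param pocket_radius_mm length-2 range of pocket radii in mm.
#' @param width_range_mm admissible lateral pelvis widths in mm.
#' @return a list of class `tissue_config`.
#' @export
tissue_config <- function(hu = c(air = -1000, fat = -100, muscle = 45,
                                 spongy_bone = 300, cortical_bone = 700,
                                 bladder = 15, ctv = 50),
                          texture_sd = c(air = 0, fat = 15, muscle = 15,
                                         spongy_bone = 20, cortical_bone = 20,
                                         bladder = 10, ctv = 12),
                          air_pocket_prob = 0.3,
                          pocket_radius_mm = c(5, 15),
                          width_range_mm = c(250, 400)) {
  tissues <- c("air", "fat", "muscle", "spongy_bone", "cortical_bone",
               "bladder", "ctv")
  if (!all(tissues %in% names(hu))) stop("'hu' must name all seven tissues")
  if (any(hu < -1000 | hu > 3100)) stop("nominal HU must lie in [-1000, 3100]")
  if (hu[["air"]] != -1000) stop("air nominal HU must be exactly -1000")
  structure(list(hu = hu[tissues], texture_sd = texture_sd[tissues],
                 air_pocket_prob = air_pocket_prob,
                 pocket_radius_mm = pocket_radius_mm,
                 width_range_mm = width_range_mm),
            class = "tissue_config")
}

#' Tissue label codes used by the phantom generator
#' @return named integer vector mapping tissue name to label code.
#' @export
phantom_label_table <- function() {
  c(air = 0L, fat = 1L, muscle = 2L, spongy_bone = 3L, cortical_bone = 4L,
    bladder = 5L, ctv = 6L)
}

#' Generate a seeded digital pelvis phantom
#'
#' Builds an HU volume plus tissue label map emulating an axial pelvic CT:
#' an elliptical body of lateral extent `width_mm` with subcutaneous fat and
#' muscle layers, two femoral heads of spongy bone with a cortical shell, a
#' bladder ellipsoid, a clinical-target-volume ellipsoid, and a rectum tube
#' that may contain seeded air pockets. Voxels outside the body are air
#' (-1000 HU exactly); every other voxel is its tissue nominal plus seeded
#' Gaussian texture, clipped to `[-1000, 3100]`.
#'
#' @param width_mm lateral body width in mm; must lie within
#'   `config$width_range_mm` and inside the grid.
#' @param n_slices number of axial slices (>= 1).
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param config a [tissue_config()].
#' @param grid_size in-plane grid edge in voxels (default 512, so a wide
#'   pelvis still exceeds a 208-mm reconstruction field of view).
#' @param spacing isotropic voxel size in mm.
#' @param force_pockets optional logical: `TRUE`/`FALSE` forces air pockets
#'   on every/no slice (used to build mismatching CT/CBCT scenarios);
#'   `NULL` draws per-slice with `config$air_pocket_prob`.
#' @return a [cbct_volume] with `labels` and the [phantom_label_table()].
#' @export
generate_phantom <- function(width_mm, n_slices = 8L, seed = 1L,
                             config = tissue_config(), grid_size = 512L,
                             spacing = 1, force_pockets = NULL) {
  stopifnot_scalar_num(width_mm, "width_mm", positive = TRUE)
  if (n_slices < 1L) stop("'n_slices' must be >= 1")
  if (width_mm < config$width_range_mm[1] || width_mm > config$width_range_mm[2])
    stop(sprintf("width_mm = %g outside configured range [%g, %g]", width_mm,
                 config$width_range_mm[1], config$width_range_mm[2]))
  if (width_mm > (grid_size - 4) * spacing)
    stop(sprintf("width_mm = %g mm does not fit the %d x %d grid at %g mm",
                 width_mm, grid_size, grid_size, spacing))
  lt <- phantom_label_table()
  nx <- ny <- as.integer(grid_size)
  cx <- (nx + 1) / 2
  xs <- ((1:nx) - cx) * spacing   # lateral, mm
  ys <- ((1:ny) - cx) * spacing   # anterior(-) / posterior(+), mm
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  a <- width_mm / 2
  b <- 0.70 * a
  ell <- function(cxm, cym, am, bm) ((X - cxm) / am)^2 + ((Y - cym) / bm)^2 <= 1

  with_seed(seed, {
    zmid <- (n_slices + 1) / 2
    # organ semi-axes (mm); spheres/ellipsoids shrink away from the mid slice
    r_fem <- 0.16 * a
    labels <- array(lt[["air"]], dim = c(nx, ny, n_slices))
    for (z in seq_len(n_slices)) {
      dz <- (z - zmid) * spacing
      lab <- matrix(lt[["air"]], nx, ny)
      body <- ell(0, 0, a, b)
      lab[body] <- lt[["fat"]]                       # subcutaneous fat
      lab[ell(0, 0, 0.93 * a, 0.93 * b)] <- lt[["muscle"]]
      lab[ell(0, 0, 0.82 * a, 0.82 * b)] <- lt[["fat"]]  # deep fat background
      shrink <- function(r) { s <- r^2 - dz^2; if (s > 0) sqrt(s) else 0 }
      rf <- shrink(r_fem)
      if (rf > 0) {
        for (sgn in c(-1, 1)) {
          lab[ell(sgn * 0.55 * a, 0.05 * b, rf + 3 * spacing, rf + 3 * spacing)] <-
            lt[["cortical_bone"]]
          lab[ell(sgn * 0.55 * a, 0.05 * b, rf, rf)] <- lt[["spongy_bone"]]
        }
      }
      rb <- shrink(0.20 * b * 2)  # bladder z-extent
      if (rb > 0) {
        fz <- rb / (0.40 * b)
        lab[ell(0, -0.35 * b, 0.22 * a * fz, 0.20 * b * fz)] <- lt[["bladder"]]
      }
      rc <- shrink(0.12 * b * 2)
      if (rc > 0) {
        fz <- rc / (0.24 * b)
        lab[ell(0, 0.10 * b, 0.15 * a * fz, 0.12 * b * fz)] <- lt[["ctv"]]
      }
      # rectum: muscle-walled tube, constant along z
      r_rec <- max(0.08 * a, 8)
      lab[ell(0, 0.55 * b, r_rec, r_rec)] <- lt[["muscle"]]
      pocket <- if (is.null(force_pockets)) runif(1) < config$air_pocket_prob
                else isTRUE(force_pockets)
      rp <- runif(1, config$pocket_radius_mm[1], config$pocket_radius_mm[2])
      jx <- runif(1, -2, 2); jy <- runif(1, -2, 2)
      if (pocket) {
        pk <- ell(jx, 0.55 * b + jy, min(rp, r_rec - spacing),
                  min(rp, r_rec - spacing))
        lab[pk] <- lt[["air"]]
      }
      labels[, , z] <- lab
    }
    hu <- array(-1000, dim = dim(labels))
    for (tn in names(lt)) {
      if (tn == "air") next
      m <- labels == lt[[tn]]
      n <- sum(m)
      if (n > 0)
        hu[m] <- config$hu[[tn]] + rnorm(n, 0, config$texture_sd[[tn]])
    }
    hu <- pmin(pmax(hu, -1000), 3100)
    v <- cbct_volume(hu, spacing = spacing, labels = labels, label_table = lt)
    attr(v, "width_mm") <- width_mm
    attr(v, "seed") <- seed
    v
  })
}

#' Sample a cohort of phantoms with variable pelvis width
#'
#' Draws `n` widths uniformly over `width_range` and generates one phantom
#' per width with a per-phantom seed derived deterministically from the
#' master seed.
#'
#' @param n number of phantoms (>= 1).
#' @param width_range length-2 mm range, within the config limits.
#' @param seed master seed.
#' @param config a [tissue_config()].
#' @param ... further arguments passed to [generate_phantom()].
#' @return list of [cbct_volume]s, each carrying `width_mm` and `seed`
#'   attributes.
#' @export
sample_cohort <- function(n, width_range = c(280, 380), seed = 1L,
                          config = tissue_config(), ...) {
  if (n < 1L) stop("'n' must be >= 1")
  if (length(width_range) != 2L || diff(width_range) < 0)
    stop("'width_range' must be an increasing length-2 range")
  if (width_range[1] < config$width_range_mm[1] ||
      width_range[2] > config$width_range_mm[2])
    stop("'width_range' outside the configured width limits")
  widths <- with_seed(seed, runif(n, width_range[1], width_range[2]))
  seeds <- derive_seeds(seed + 1L, n)
  lapply(seq_len(n), function(i)
    generate_phantom(widths[i], seed = seeds[i], config = config, ...))
}

#' Write a cohort manifest as JSON
#'
#' @param cohort list of phantoms from [sample_cohort()].
#' @param paths character vector of volume file paths (parallel to `cohort`).
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, paths, file) {
  man <- lapply(seq_along(cohort), function(i) list(
    path = paths[i],
    width_mm = attr(cohort[[i]], "width_mm"),
    seed = attr(cohort[[i]], "seed")))
  jsonlite::write_json(man, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
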