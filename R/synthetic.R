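# Parametric synthetic torso: a layered elliptical-cylinder hexahedral
# mesh with an embedded heart block, a PQRST-like epicardial activation
# model, electrode sampling and noisy recordings.  Stands in for clinical
# vest recordings so that every pipeline stage is testable offline.
#
# Geometry: each horizontal level carries a "butterfly" (O-grid) layout —
# a central (m+1) x (m+1) square grid whose 4m perimeter nodes fan out
# through `n_rings` rings to the outer ellipse, with n_sectors = 4m
# angular sectors.  Levels are extruded vertically.  All hexahedra are
# genuine (8 distinct nodes, positive Jacobians); the axis is covered by
# the square core, avoiding collapsed wedge elements.
#
# Closed-form counts for this construction (checked in the tests):
#   nodes          = L * ((m+1)^2 + S R)
#   elements       = (L-1) * (m^2 + S R)
#   outer faces    = 2 (m^2 + S R) + S (L-1)

#' Synthetic torso configuration
#'
#' Defaults describe a desk-scale torso: 22 node levels spaced 1.27 cm,
#' 32 sectors, 2 radial rings, elliptical cross-section 14 x 10 cm, an
#' interior 4 x 4 x 4-element heart block, and the vest-style electrode
#' pattern (an electrode every third level, every other sector, giving
#' 8 x 16 = 128 electrodes).
#'
#' @param n_levels number of node levels (>= 3).
#' @param n_sectors angular sectors, a multiple of 4 (>= 8).
#' @param n_rings radial rings between the core square and the outer
#'   ellipse (>= 2).
#' @param level_spacing vertical node spacing, cm.
#' @param outer_a,outer_b ellipse semi-axes per level, cm (recycled).
#' @param core_frac core square half-width as a fraction of `min(a, b)`.
#' @param tissue_layout list with elements `heart`, `core`, and `rings`
#'   (list of named fraction vectors, innermost first, recycled outward).
#' @param tissues a [tissue_table()] covering all labels used.
#' @param heart_cells,heart_layers integer ranges of core cells / element
#'   layers forming the heart block (must keep the block strictly
#'   interior).
#' @param electrode_level_stride,electrode_sector_stride electrode lattice
#'   strides on the lateral surface grid (defaults 3 and 2).
#' @param noise_sd additive measurement noise SD, mV.
#' @param seed RNG seed for the noise.
#' @return List of class `ecgi_synth_config`.
#' @export
synth_config <- function(n_levels = 22, n_sectors = 32, n_rings = 2,
                         level_spacing = 1.27,
                         outer_a = 14, outer_b = 10,
                         core_frac = 0.45,
                         tissue_layout = list(
                           heart = c(myocardium = 1),
                           core = c(muscle = 1),
                           rings = list(c(lung = 0.8, muscle = 0.2),
                                        c(muscle = 0.8, fat = 0.2))),
                         tissues = tissue_table(
                           c("myocardium", "muscle", "lung", "fat"),
                           c(0.1, 0.2, 0.05, 0.04)),
                         heart_cells = NULL, heart_layers = NULL,
                         electrode_level_stride = 3,
                         electrode_sector_stride = 2,
                         noise_sd = 0, seed = 1L) {
  if (n_levels < 3) stop("'n_levels' must be >= 3")
  if (n_sectors %% 4 != 0 || n_sectors < 8)
    stop("'n_sectors' must be a multiple of 4, >= 8")
  if (n_rings < 2) stop("'n_rings' must be >= 2")
  if (electrode_level_stride < 1 || electrode_sector_stride < 1)
    stop("electrode strides must be >= 1")
  m <- n_sectors / 4
  if (is.null(heart_cells)) {
    c0 <- floor(m / 2) - 1
    heart_cells <- max(1, c0):min(m, c0 + 3)
  }
  if (is.null(heart_layers)) {
    l0 <- floor((n_levels - 1) / 2) - 1
    heart_layers <- max(2, l0):min(n_levels - 2, l0 + 3)
  }
  if (min(heart_layers) < 2 || max(heart_layers) > n_levels - 2)
    stop("heart block must not touch the outer surface (layers)")
  structure(list(
    n_levels = n_levels, n_sectors = n_sectors, n_rings = n_rings,
    level_spacing = level_spacing,
    outer_a = rep_len(outer_a, n_levels), outer_b = rep_len(outer_b, n_levels),
    core_frac = core_frac, tissue_layout = tissue_layout, tissues = tissues,
    heart_cells = heart_cells, heart_layers = heart_layers,
    electrode_level_stride = electrode_level_stride,
    electrode_sector_stride = electrode_sector_stride,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ecgi_synth_config")
}

# perimeter walk of the core square: sector s (1..4m) -> core grid (i, j)
# indices in 0..m, counter-clockwise from the bottom-left corner
.square_perimeter_ij <- function(s, m) {
  k <- (s - 1) %% (4 * m)
  if (k < m) c(k, 0)
  else if (k < 2 * m) c(m, k - m)
  else if (k < 3 * m) c(3 * m - k, m)
  else c(0, 4 * m - k)
}

#' Build the synthetic layered torso mesh
#'
#' Deterministic for a fixed configuration.  The heart block is flagged
#' and guaranteed strictly interior; the lateral surface nodes carry a
#' structured `(level, sector)` grid used by the electrode layout and the
#' pyramid interpolation.
#'
#' @param config a [synth_config()].
#' @return An [ecgi_mesh()] with `surface_grid` attached.
#' @export
build_synthetic_torso <- function(config) {
  L <- config$n_levels; S <- config$n_sectors; R <- config$n_rings
  m <- S / 4
  n_core <- (m + 1)^2
  n_per_level <- n_core + S * R
  core_id <- function(lev, i, j) (lev - 1) * n_per_level + j * (m + 1) + i + 1
  ring_id <- function(lev, r, s)
    (lev - 1) * n_per_level + n_core + (r - 1) * S + ((s - 1) %% S) + 1

  nodes <- matrix(0, L * n_per_level, 3)
  for (lev in seq_len(L)) {
    a <- config$outer_a[lev]; b <- config$outer_b[lev]
    h <- config$core_frac * min(a, b)
    z <- (lev - 1) * config$level_spacing
    for (j in 0:m) for (i in 0:m)
      nodes[core_id(lev, i, j), ] <- c(-h + 2 * h * i / m, -h + 2 * h * j / m, z)
    for (s in 1:S) {
      ij <- .square_perimeter_ij(s, m)
      q <- c(-h + 2 * h * ij[1] / m, -h + 2 * h * ij[2] / m)
      tpar <- atan2(q[2], q[1])
      e <- c(a * cos(tpar), b * sin(tpar))
      for (r in 1:R) {
        p <- q + (e - q) * r / R
        nodes[ring_id(lev, r, s), ] <- c(p, z)
      }
    }
  }

  # elements, layer by layer: m^2 core cells then S cells per ring
  n_cell <- m^2 + S * R
  elements <- matrix(0L, (L - 1) * n_cell, 8)
  heart <- rep(FALSE, (L - 1) * n_cell)
  ring0 <- function(lev, r, s) {          # ring r = 0 means square perimeter
    if (r == 0) {
      ij <- .square_perimeter_ij(s, m)
      core_id(lev, ij[1], ij[2])
    } else ring_id(lev, r, s)
  }
  e <- 0L
  for (lay in seq_len(L - 1)) {
    for (cj in seq_len(m)) for (ci in seq_len(m)) {
      e <- e + 1L
      bot <- c(core_id(lay, ci - 1, cj - 1), core_id(lay, ci, cj - 1),
               core_id(lay, ci, cj), core_id(lay, ci - 1, cj))
      elements[e, ] <- c(bot, bot + n_per_level)
      heart[e] <- (ci %in% config$heart_cells) && (cj %in% config$heart_cells) &&
        (lay %in% config$heart_layers)
    }
    for (r in seq_len(R)) for (s in seq_len(S)) {
      e <- e + 1L
      bot <- c(ring0(lay, r - 1, s), ring0(lay, r, s),
               ring0(lay, r, s + 1), ring0(lay, r - 1, s + 1))
      elements[e, ] <- c(bot, bot + n_per_level)
    }
  }

  # tissue fractions per element
  tl <- config$tissue_layout
  tnames <- config$tissues$name
  frac_row <- function(fr) {
    out <- stats::setNames(numeric(length(tnames)), tnames)
    out[names(fr)] <- fr
    out
  }
  fractions <- matrix(0, nrow(elements), length(tnames),
                      dimnames = list(NULL, tnames))
  e <- 0L
  for (lay in seq_len(L - 1)) {
    for (cell in seq_len(m^2)) {
      e <- e + 1L
      fractions[e, ] <- frac_row(if (heart[e]) tl$heart else tl$core)
    }
    for (r in seq_len(R)) {
      fr <- tl$rings[[min(r, length(tl$rings))]]
      for (s in seq_len(S)) {
        e <- e + 1L
        fractions[e, ] <- frac_row(fr)
      }
    }
  }

  grid <- data.frame(
    node = as.integer(vapply(seq_len(L), function(lev)
      vapply(1:S, function(s) ring_id(lev, R, s), numeric(1)), numeric(S))),
    level = rep(seq_len(L), each = S),
    sector = rep(1:S, times = L))
  attr(grid, "n_sectors") <- S
  attr(grid, "wrap") <- TRUE

  mesh <- ecgi_mesh(nodes, elements, config$tissues, fractions, heart,
                    surface_grid = grid)
  if (any(mesh$on_outer_surface[unique(as.vector(
    mesh$elements[mesh$heart, , drop = FALSE]))]))
    stop("heart block touches the outer surface")
  mesh$config <- config
  mesh
}

#' Vest-style electrode layout on the synthetic torso
#'
#' Places electrodes on the lateral surface grid at every
#' `level_stride`-th level and every `sector_stride`-th sector (the
#' every-third-level, alternating-sector vest pattern by default).
#'
#' @param mesh a [build_synthetic_torso()] mesh.
#' @param level_stride,sector_stride lattice strides (defaults from the
#'   mesh configuration, else 3 and 2).
#' @return An [electrode_layout()].
#' @export
synthetic_electrode_layout <- function(mesh, level_stride = NULL,
                                       sector_stride = NULL) {
  grid <- mesh$surface_grid
  if (is.null(grid)) stop("mesh has no lateral surface grid")
  cfg <- mesh$config
  if (is.null(level_stride))
    level_stride <- if (!is.null(cfg)) cfg$electrode_level_stride else 3
  if (is.null(sector_stride))
    sector_stride <- if (!is.null(cfg)) cfg$electrode_sector_stride else 2
  levs <- seq(1, max(grid$level), by = level_stride)
  secs <- seq(1, attr(grid, "n_sectors"), by = sector_stride)
  sel <- grid$level %in% levs & grid$sector %in% secs
  picked <- grid[sel, ]
  picked <- picked[order(picked$level, picked$sector), ]
  electrode_layout(picked$node, mesh)
}

#' PQRST-like activation parameters
#'
#' One cardiac beat as a sum of region-localized raised-cosine pulses:
#' atrial depolarization (P), septal/early ventricular (Q), ventricular
#' depolarization (R, S) and repolarization (T).  Each pulse is
#' `amp * sin^2(pi (t - onset) / (2 width))` on
#' `[onset, onset + 2 width]` and exactly zero elsewhere, so the
#' activation is smooth and identically zero before the first onset.
#' Defaults give a 740 ms beat sampled at 1 kHz.
#'
#' @param phases `data.frame` with columns `name`, `onset` (ms), `width`
#'   (ms, half-duration; the peak sits at `onset + width`), `amp` (mV)
#'   and `region` (one of `"atria"`, `"septum"`, `"rv"`, `"lv"`,
#'   `"ventricles"`, `"all"`).
#' @param beat_length beat length in ms (samples at 1 kHz).
#' @param sample_rate fixed at 1000 Hz.
#' @return List of class `ecgi_activation_params`.
#' @export
activation_params <- function(
    phases = data.frame(
      name   = c("P", "Q", "R", "S", "T"),
      onset  = c(5, 110, 148, 185, 330),
      width  = c(30, 20, 22, 18, 90),
      amp    = c(0.25, -0.35, 1.4, -0.45, 0.45),
      region = c("atria", "septum", "rv", "lv", "ventricles"),
      stringsAsFactors = FALSE),
    beat_length = 740, sample_rate = 1000) {
  if (sample_rate != 1000) stop("the sampling frequency is fixed at 1 kHz")
  if (any(phases$onset < 0 | phases$onset >= beat_length))
    stop("phase onsets must lie within the beat")
  if (any(!is.finite(phases$amp))) stop("amplitudes must be finite")
  structure(list(phases = phases, beat_length = as.integer(beat_length),
                 sample_rate = sample_rate),
            class = "ecgi_activation_params")
}

# smooth spatial region weights on the epicardial nodes
.region_weights <- function(mesh, region) {
  en <- epicardial_nodes(mesh)
  p <- mesh$nodes[en, , drop = FALSE]
  zr <- range(p[, 3]); ctr <- colMeans(p)
  zt <- (p[, 3] - zr[1]) / max(zr[2] - zr[1], 1e-12)   # 0 bottom, 1 top
  th <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])        # 0 = +x ("front-right")
  sig <- function(x) 1 / (1 + exp(-x / 0.08))
  ang <- function(t0) (0.5 * (1 + cos(th - t0)))^2
  switch(region,
         atria      = sig(zt - 0.68),
         septum     = exp(-((zt - 0.52) / 0.16)^2),
         rv         = (1 - sig(zt - 0.55)) * ang(-0.9),
         lv         = (1 - sig(zt - 0.55)) * ang(2.0),
         ventricles = 1 - sig(zt - 0.65),
         all        = rep(1, length(zt)),
         stop("unknown region: ", region))
}

#' Simulate a ground-truth epicardial activation
#'
#' Evaluates the [activation_params()] pulse model on every epicardial
#' node: smooth per-node potential waveforms, identically zero before the
#' first onset, with exactly `beat_length` samples at 1 kHz (sample k is
#' time k ms).
#'
#' @param mesh a mesh with a non-empty epicardial surface.
#' @param params an [activation_params()].
#' @return An `ecgi_epi` ground truth (`nodes`, `values`).
#' @export
simulate_epicardial_activation <- function(mesh, params = activation_params()) {
  en <- epicardial_nodes(mesh)
  tt <- seq_len(params$beat_length)         # ms
  V <- matrix(0, length(en), length(tt))
  for (k in seq_len(nrow(params$phases))) {
    ph <- params$phases[k, ]
    pulse <- numeric(length(tt))
    inside <- tt >= ph$onset & tt <= ph$onset + 2 * ph$width
    pulse[inside] <- ph$amp * sin(pi * (tt[inside] - ph$onset) / (2 * ph$width))^2
    V <- V + outer(.region_weights(mesh, ph$region), pulse)
  }
  structure(list(nodes = en, values = V), class = "ecgi_epi")
}

#' Synthesize electrode recordings from a ground truth
#'
#' Forward-solves the ground-truth epicardial potentials through the
#' volume conductor, samples the result at the electrode nodes, and adds
#' seeded iid Gaussian measurement noise:
#' `recordings = forward(ground_truth)[electrodes, ] + N(0, noise_sd^2)`.
#'
#' @param mesh the torso mesh.
#' @param ground_truth an `ecgi_epi`.
#' @param layout an [electrode_layout()].
#' @param noise_sd noise standard deviation, mV.
#' @param seed RNG seed (required when `noise_sd > 0` for
#'   reproducibility).
#' @param K optional precomputed conductivity matrix.
#' @param forward_op optional precomputed [forward_operator()] for the
#'   ground-truth node set.
#' @return `M x T` recording matrix (mV), rownames = electrode ids.
#' @export
synthesize_recordings <- function(mesh, ground_truth, layout, noise_sd = 0,
                                  seed = NULL, K = NULL, forward_op = NULL) {
  if (!all(mesh$on_outer_surface[layout$node]))
    stop("electrode node not on the outer surface")
  if (is.null(forward_op))
    forward_op <- forward_operator(mesh, K, ground_truth$nodes)
  u <- forward_op(ground_truth$values)
  rec <- u[layout$node, , drop = FALSE]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    rec <- rec + matrix(stats::rnorm(length(rec), sd = noise_sd),
                        nrow(rec), ncol(rec))
  }
  rownames(rec) <- layout$electrode
  rec
}

#' Regular box mesh (test bed and oracle fixture)
#'
#' An `nx x ny x nz`-element axis-aligned grid of identical hexahedra.
#' Degenerate single-element meshes are fully supported — they are the
#' oracle test bed of the FEM kernels.
#'
#' @param nx,ny,nz element counts per axis.
#' @param spacing element edge length, cm (scalar or length 3).
#' @param origin corner of the box.
#' @param tissues a [tissue_table()] (default a single unit-conductivity
#'   medium).
#' @param element_tissue character vector (length `E`, recycled) naming
#'   the tissue of each element.
#' @param heart logical vector flagging heart elements (default none).
#' @return An [ecgi_mesh()].
#' @export
build_box_mesh <- function(nx, ny, nz, spacing = 1, origin = c(0, 0, 0),
                           tissues = tissue_table("medium", 1),
                           element_tissue = tissues$name[1],
                           heart = FALSE) {
  spacing <- rep_len(spacing, 3)
  nid <- function(i, j, k)
    (k * (ny + 1) + j) * (nx + 1) + i + 1       # i,j,k 0-based
  coords <- as.matrix(expand.grid(i = 0:nx, j = 0:ny, k = 0:nz))
  nodes <- cbind(origin[1] + coords[, 1] * spacing[1],
                 origin[2] + coords[, 2] * spacing[2],
                 origin[3] + coords[, 3] * spacing[3])
  nodes <- nodes[order(nid(coords[, 1], coords[, 2], coords[, 3])), , drop = FALSE]
  E <- nx * ny * nz
  elements <- matrix(0L, E, 8)
  e <- 0L
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    e <- e + 1L
    bot <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k))
    top <- c(nid(i, j, k + 1), nid(i + 1, j, k + 1), nid(i + 1, j + 1, k + 1),
             nid(i, j + 1, k + 1))
    elements[e, ] <- c(bot, top)
  }
  element_tissue <- rep_len(element_tissue, E)
  fractions <- matrix(0, E, nrow(tissues), dimnames = list(NULL, tissues$name))
  fractions[cbind(seq_len(E), match(element_tissue, tissues$name))] <- 1
  ecgi_mesh(nodes, elements, tissues, fractions, rep_len(heart, E))
}
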