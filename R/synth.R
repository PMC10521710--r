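#' HER2 score levels
#'
#' HER2 IHC expression is scored on the four-level Dako HercepTest scale:
#' 0 (negative), 1+ (negative), 2+ (weakly positive/equivocal) and
#' 3+ (positive). Internally scores are coded as ordinals 0..3.
#'
#' @param x score given as ordinal (0..3) or label ("0", "1+", "2+", "3+").
#' @return Integer ordinal in 0..3 with the label as names.
#' @export
her2_score <- function(x) {
  labels <- her2_levels()
  if (is.character(x) || is.factor(x)) {
    i <- match(as.character(x), labels)
    if (anyNA(i)) stop("unknown HER2 score label: ", paste(x[is.na(i)], collapse = ", "))
    return(setNames(i - 1L, labels[i]))
  }
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 0L | x > 3L)) stop("HER2 score must be in 0..3")
  setNames(x, labels[x + 1L])
}

#' @rdname her2_score
#' @export
her2_levels <- function() c("0", "1+", "2+", "3+")

#' Geometry parameters for the synthetic tissue simulator
#'
#' Controls cell placement and the per-grade membrane staining model.  The
#' per-grade rows encode the diagnostic phenotypes: grade 0 has no membrane
#' stain; 1+ has faint, partial rings (completeness < 0.5); 2+ has weak to
#' moderate complete rings in well over 10% of cells; 3+ has strong complete
#' rings in the majority of cells. `frac_complete` is enforced exactly (a
#' fixed rounded count of cells receives complete rings) so the >10%
#' complete-ring criterion for 2+/3+ holds by construction.
#'
#' @param height,width tile size in pixels.
#' @param cells_per_kpx expected cells per 1000 pixels of tissue.
#' @param min_separation minimum distance between cell centres (pixels).
#' @param nucleus_radius range (min, max) of nucleus radii in pixels.
#' @param membrane_gap distance from the nucleus edge to the membrane ring
#'   centreline, in pixels.
#' @param grade_table per-grade staining parameters (see Details).
#' @return A list of class `her2_geometry`.
#' @export
her2_geometry <- function(height = 256, width = 256,
                          cells_per_kpx = 0.9,
                          min_separation = 20,
                          nucleus_radius = c(4, 7),
                          membrane_gap = 2.5,
                          grade_table = NULL) {
  if (height <= 0 || width <= 0) stop("tile dimensions must be positive")
  if (is.null(grade_table)) {
    grade_table <- data.frame(
      grade           = 0:3,
      frac_stained    = c(0, 0.40, 0.50, 0.80),
      frac_complete   = c(0, 0.02, 0.30, 0.60),
      completeness_lo = c(0, 0.15, 0.50, 0.60),
      completeness_hi = c(0, 0.45, 0.85, 0.90),
      dab_od          = c(0, 0.15, 0.40, 0.90),
      cyto_dab_od     = c(0, 0.00, 0.02, 0.04),
      ring_thickness  = c(0, 1.2, 1.6, 2.2)
    )
  }
  structure(list(height = height, width = width,
                 cells_per_kpx = cells_per_kpx,
                 min_separation = min_separation,
                 nucleus_radius = nucleus_radius,
                 membrane_gap = membrane_gap,
                 grade_table = grade_table),
            class = "her2_geometry")
}

#' Optics parameters for rendering synthetic image pairs
#'
#' The brightfield IHC image is rendered from per-stain optical densities by
#' the Beer-Lambert law, `rgb = 10^(-OD)`, using unit hematoxylin and DAB
#' stain vectors (the standard colour-deconvolution conventions).  The four
#' autofluorescence channels are saturating nonlinear mixtures
#' `1 - exp(-k * mix)` of the latent structure maps (nucleus, membrane,
#' cytoplasm, stroma) plus additive Gaussian noise; DAPI is nucleus-weighted
#' and Cy5 carries the membrane-correlated signal.
#'
#' @param stain_matrix 3x3 matrix of unit stain OD row vectors
#'   (hematoxylin, DAB, residual); defaults to [default_stain_matrix()].
#' @param hema_od peak hematoxylin optical density of nuclei.
#' @param af_mix 4x5 matrix of autofluorescence mixing weights; rows are
#'   channels (DAPI, FITC, TxRed, Cy5), columns are
#'   (offset, nucleus, membrane, cytoplasm, stroma).
#' @param af_gain saturation constant k of the nonlinearity.
#' @param af_noise_sd per-channel additive Gaussian noise sd on \[0, 1\].
#' @param ihc_noise_sd additive noise of the brightfield render (default 0;
#'   slide scanners are effectively shot-noise free after flat-fielding).
#' @param poisson_noise optional Poisson (shot) noise on the AF channels,
#'   off by default.
#' @param poisson_scale photon scale used when `poisson_noise = TRUE`.
#' @return A list of class `her2_optics`.
#' @export
her2_optics <- function(stain_matrix = default_stain_matrix(),
                        hema_od = 0.7,
                        af_mix = NULL,
                        af_gain = 2.2,
                        af_noise_sd = 0.02,
                        ihc_noise_sd = 0,
                        poisson_noise = FALSE,
                        poisson_scale = 5000) {
  if (hema_od < 0) stop("optical densities must be non-negative")
  if (is.null(af_mix)) {
    af_mix <- rbind(
      dapi  = c(0.05, 1.15, 0.00, 0.06, 0.12),
      fitc  = c(0.04, 0.10, 0.00, 0.35, 0.70),
      txred = c(0.03, 0.00, 0.35, 0.55, 0.25),
      cy5   = c(0.02, 0.12, 0.80, 0.00, 0.25))
    colnames(af_mix) <- c("offset", "nucleus", "membrane", "cytoplasm", "stroma")
  }
  structure(list(stain_matrix = stain_matrix, hema_od = hema_od,
                 af_mix = af_mix, af_gain = af_gain,
                 af_noise_sd = af_noise_sd, ihc_noise_sd = ihc_noise_sd,
                 poisson_noise = poisson_noise, poisson_scale = poisson_scale),
            class = "her2_optics")
}

#' Generate a latent tissue map with grade-dependent membrane staining
#'
#' Places cells by seeded dart throwing with a minimum separation, rasterises
#' soft-edged circular nuclei and membrane rings (annuli at a fixed offset
#' from the nucleus edge), assigns ring completeness per the grade table,
#' and adds a smooth stromal autofluorescence field.
#'
#' @param grade HER2 score (ordinal 0..3 or label).
#' @param geometry a [her2_geometry()] parameter set.
#' @param seed integer seed; identical inputs give bit-identical maps.
#' @return A list of class `latent_tissue` with binary `nucleus_mask` and
#'   `membrane_mask`, integer `nucleus_labels`, per-cell
#'   `complete_ring_flags`, `stroma_field` in \[0, 1\], the soft density maps
#'   used for rendering, and bookkeeping fields.
#' @export
generate_latent <- function(grade, geometry = her2_geometry(), seed = 1) {
  g <- her2_score(grade)
  H <- geometry$height; W <- geometry$width
  if (H <= 0 || W <= 0) stop("tile dimensions must be positive")
  gp <- geometry$grade_table[geometry$grade_table$grade == unname(g), ]
  if (nrow(gp) != 1L) stop("grade missing from grade_table")

  with_seed(seed, {
    n_target <- max(1L, round(geometry$cells_per_kpx * H * W / 1000))
    centers <- place_cells(n_target, H, W, geometry$min_separation)
    n <- nrow(centers)
    radii <- runif(n, geometry$nucleus_radius[1], geometry$nucleus_radius[2])

    # staining assignment: an exact count of cells gets complete rings, a
    # further share partial rings, the rest none
    n_complete <- round(gp$frac_complete * n)
    n_stained <- max(n_complete, round(gp$frac_stained * n))
    ord <- sample.int(n)
    stained <- logical(n); complete <- logical(n)
    if (n_stained > 0) stained[ord[seq_len(n_stained)]] <- TRUE
    if (n_complete > 0) complete[ord[seq_len(n_complete)]] <- TRUE
    completeness <- numeric(n)
    completeness[complete] <- 1
    partial <- stained & !complete
    completeness[partial] <- runif(sum(partial), gp$completeness_lo,
                                   min(gp$completeness_hi, 0.94))
    arc_start <- runif(n, 0, 2 * pi)

    nuc_den <- matrix(0, H, W); mem_den <- matrix(0, H, W)
    cyto_den <- matrix(0, H, W); labels <- matrix(0L, H, W)
    thick <- gp$ring_thickness
    for (i in seq_len(n)) {
      r0 <- centers[i, 1]; c0 <- centers[i, 2]; rn <- radii[i]
      ring_r <- rn + geometry$membrane_gap + thick / 2
      ext <- ceiling(ring_r + thick / 2 + 1.5)
      rr <- max(1, floor(r0 - ext)):min(H, ceiling(r0 + ext))
      cc <- max(1, floor(c0 - ext)):min(W, ceiling(c0 + ext))
      dr <- rr - r0; dc <- cc - c0
      d <- sqrt(outer(dr^2, dc^2, `+`))
      na <- clamp01(rn + 0.5 - d)
      nuc_den[rr, cc] <- pmax(nuc_den[rr, cc], na)
      labels[rr, cc][na > 0.5] <- i
      ca <- clamp01(ring_r - d) # filled cell disk up to the ring
      cyto_den[rr, cc] <- pmax(cyto_den[rr, cc], ca)
      if (stained[i] && completeness[i] > 0 && thick > 0) {
        ra <- clamp01(thick / 2 + 0.5 - abs(d - ring_r))
        ang <- outer(dr, dc, function(a, b) atan2(b, a)) # angle from centre
        rel <- (ang - arc_start[i]) %% (2 * pi)
        arc <- rel <= completeness[i] * 2 * pi
        mem_den[rr, cc] <- pmax(mem_den[rr, cc], ra * arc * gp$dab_od)
      }
    }
    stroma <- cpp_gauss_blur(matrix(runif(H * W), H, W), 10)
    rng <- range(stroma)
    stroma <- (stroma - rng[1]) / max(rng[2] - rng[1], 1e-12)

    structure(list(
      nucleus_mask = nuc_den > 0.5,
      nucleus_labels = labels,
      membrane_mask = mem_den > 0.5 * gp$dab_od & gp$dab_od > 0,
      complete_ring_flags = complete,
      stroma_field = stroma,
      height = H, width = W,
      nucleus_density = nuc_den,
      membrane_density = mem_den,     # already scaled by the grade's DAB OD
      cytoplasm_density = cyto_den,
      cyto_dab_od = gp$cyto_dab_od,
      cells = data.frame(row = centers[, 1], col = centers[, 2],
                         radius = radii, stained = stained,
                         completeness = completeness),
      grade = unname(g), seed = seed), class = "latent_tissue")
  })
}

# seeded dart throwing with minimum separation
place_cells <- function(n_target, H, W, min_sep, max_tries = 40L) {
  pts <- matrix(numeric(0), 0, 2)
  margin <- 2
  for (i in seq_len(n_target)) {
    for (t in seq_len(max_tries)) {
      p <- c(runif(1, 1 + margin, H - margin), runif(1, 1 + margin, W - margin))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep^2) {
        pts <- rbind(pts, p)
        break
      }
    }
  }
  pts
}

#' Render a paired autofluorescence / IHC tile from a latent tissue map
#'
#' The brightfield image follows the Beer-Lambert law with hematoxylin
#' optical density on nuclei and DAB density on the membrane rings (plus a
#' faint cytoplasmic DAB term at high grades); pixels without stain render
#' white. The four autofluorescence channels are saturating mixtures of the
#' latent maps plus seeded Gaussian noise.
#'
#' @param latent a `latent_tissue` object from [generate_latent()].
#' @param optics a [her2_optics()] parameter set.
#' @param seed seed for the rendering noise (defaults to the latent's seed).
#' @return A list of class `synthetic_pair` with elements `af`
#'   (`[H, W, 4]`), `ihc` (`[H, W, 3]`), `latent`, `grade` and `seed`.
#' @export
render_pair <- function(latent, optics = her2_optics(), seed = latent$seed) {
  if (!inherits(latent, "latent_tissue")) stop("latent must be a latent_tissue")
  H <- latent$height; W <- latent$width
  if (optics$hema_od < 0) stop("optical densities must be non-negative")
  M <- optics$stain_matrix
  h_od <- optics$hema_od * latent$nucleus_density
  d_od <- latent$membrane_density + latent$cyto_dab_od * latent$cytoplasm_density

  ihc <- array(0, c(H, W, 3))
  for (ch in 1:3)
    ihc[, , ch] <- 10^-(h_od * M[1, ch] + d_od * M[2, ch])

  # membrane AF signal stays proportional to the DAB optical density so the
  # AF -> IHC mapping is single-valued across grades (the premise that HER2
  # expression leaves an autofluorescence signature)
  comp <- list(offset = 1, nucleus = latent$nucleus_density,
               membrane = latent$membrane_density,
               cytoplasm = latent$cytoplasm_density,
               stroma = latent$stroma_field)
  af <- array(0, c(H, W, 4))
  with_seed(seed + 104729L, {
    for (ch in 1:4) {
      mix <- optics$af_mix[ch, 1] +
        optics$af_mix[ch, 2] * comp$nucleus +
        optics$af_mix[ch, 3] * comp$membrane +
        optics$af_mix[ch, 4] * comp$cytoplasm +
        optics$af_mix[ch, 5] * comp$stroma
      sig <- 1 - exp(-optics$af_gain * mix)
      if (optics$poisson_noise)
        sig <- rpois(length(sig), sig * optics$poisson_scale) / optics$poisson_scale
      if (optics$af_noise_sd > 0)
        sig <- sig + rnorm(length(sig), 0, optics$af_noise_sd)
      af[, , ch] <- clamp01(sig)
    }
    if (optics$ihc_noise_sd > 0)
      ihc <- clamp01(ihc + rnorm(length(ihc), 0, optics$ihc_noise_sd))
  })
  dimnames(af) <- list(NULL, NULL, c("DAPI", "FITC", "TxRed", "Cy5"))
  structure(list(af = af, ihc = ihc, latent = latent,
                 grade = latent$grade, seed = latent$seed),
            class = "synthetic_pair")
}

#' Simulate one paired autofluorescence / IHC tile
#'
#' Convenience wrapper: [generate_latent()] followed by [render_pair()].
#' Identical `(grade, geometry, optics, seed)` give bit-identical pairs.
#' @inheritParams generate_latent
#' @inheritParams render_pair
#' @export
simulate_pair <- function(grade, geometry = her2_geometry(),
                          optics = her2_optics(), seed = 1) {
  render_pair(generate_latent(grade, geometry, seed), optics, seed)
}

#' Simulate a multi-patient paired-tile dataset
#'
#' Generates `n_per_grade` tiles at each requested grade, grouping
#' consecutive tiles of a grade into pseudo-patients of `tiles_per_patient`
#' tiles, mimicking the patient structure of a slide cohort.
#'
#' @param n_per_grade tiles per HER2 grade.
#' @param grades grades to simulate (default all four).
#' @param tiles_per_patient tiles assigned to each pseudo-patient.
#' @param geometry,optics simulator parameter sets.
#' @param seed base seed; tile i of grade g uses `seed + 1000*g + i`.
#' @return List of `synthetic_pair`s with a `manifest` attribute
#'   (data.frame: tile_id, patient_id, grade, seed).
#' @export
synth_dataset <- function(n_per_grade = 5, grades = 0:3,
                          tiles_per_patient = 5,
                          geometry = her2_geometry(),
                          optics = her2_optics(), seed = 1) {
  pairs <- list(); man <- NULL
  for (g in her2_score(grades)) {
    for (i in seq_len(n_per_grade)) {
      s <- seed + 1000L * g + i
      p <- simulate_pair(g, geometry, optics, s)
      tile_id <- sprintf("g%d_t%03d", g, i)
      patient_id <- sprintf("P_g%d_%02d", g, (i - 1) %/% tiles_per_patient + 1)
      attr(p, "tile_id") <- tile_id
      attr(p, "patient_id") <- patient_id
      pairs[[tile_id]] <- p
      man <- rbind(man, data.frame(tile_id = tile_id, patient_id = patient_id,
                                   grade = g, seed = s))
    }
  }
  attr(pairs, "manifest") <- man
  pairs
}

# --- deformation fields ------------------------------------------------------

#' Deformation field constructor
#'
#' A dense per-pixel displacement map in the pull-back convention:
#' `warped(r, c) = image(r + dr(r, c), c + dc(r, c))`, 0-based pixel-centred
#' (row, col) coordinates.
#' @param dr,dc displacement matrices (pixels) along rows and columns.
#' @export
deformation_field <- function(dr, dc) {
  stopifnot_same_shape(dr, dc, "field components")
  if (!all(is.finite(dr)) || !all(is.finite(dc)))
    stop("deformation field must be finite")
  structure(list(dr = dr, dc = dc), class = "deformation_field")
}

#' Warp specification for the synthetic registration harness
#'
#' Describes a known ground-truth warp: an affine pull-back component plus a
#' smooth sinusoidal elastic component whose displacement magnitude is
#' bounded by `elastic_amplitude`.
#'
#' @param shape (height, width) of the field in pixels.
#' @param affine 2x3 pull-back matrix mapping output (row, col, 1) to source
#'   coordinates; defaults to the identity.
#' @param elastic_amplitude peak elastic displacement magnitude (pixels).
#' @param elastic_period spatial period of the sinusoid (pixels).
#' @param seed seed for the sinusoid phases.
#' @export
warp_spec <- function(shape = c(256, 256),
                      affine = rbind(c(1, 0, 0), c(0, 1, 0)),
                      elastic_amplitude = 0, elastic_period = 128, seed = 0) {
  if (elastic_amplitude < 0) stop("elastic_amplitude must be >= 0")
  if (elastic_amplitude > 0 && elastic_period <= 0)
    stop("elastic_period must be positive")
  structure(list(shape = shape, affine = affine,
                 elastic_amplitude = elastic_amplitude,
                 elastic_period = elastic_period, seed = seed),
            class = "warp_spec")
}

#' Materialise a warp specification as a dense deformation field
#'
#' The elastic part is `a * sin(alpha) * (cos(beta), sin(beta))` with
#' `alpha = 2*pi*(r + c)/p`, `beta = 2*pi*(r - c)/p` (plus seeded phases), so
#' its vector magnitude is `a * |sin(alpha)| <= a` everywhere.
#' @param spec a [warp_spec()].
#' @return A [deformation_field()].
#' @export
make_warp <- function(spec) {
  if (!inherits(spec, "warp_spec")) stop("spec must be a warp_spec")
  H <- spec$shape[1]; W <- spec$shape[2]
  if (H <= 0 || W <= 0) stop("field dimensions must be positive")
  r <- matrix(0:(H - 1), H, W)
  c_ <- matrix(0:(W - 1), H, W, byrow = TRUE)
  A <- spec$affine
  dr <- A[1, 1] * r + A[1, 2] * c_ + A[1, 3] - r
  dc <- A[2, 1] * r + A[2, 2] * c_ + A[2, 3] - c_
  if (spec$elastic_amplitude > 0) {
    ph <- with_seed(spec$seed, runif(2, 0, 2 * pi))
    p <- spec$elastic_period
    alpha <- 2 * pi * (r + c_) / p + ph[1]
    beta <- 2 * pi * (r - c_) / p + ph[2]
    dr <- dr + spec$elastic_amplitude * sin(alpha) * cos(beta)
    dc <- dc + spec$elastic_amplitude * sin(alpha) * sin(beta)
  }
  deformation_field(dr, dc)
}

#' Warp an image along a deformation field
#'
#' Pull-back resampling: `out(r, c) = image(r + dr, c + dc)` with bilinear
#' (default) or nearest-neighbour interpolation.  Out-of-bounds samples
#' replicate the edge by default, or take a constant fill value.
#'
#' @param image matrix or `[H, W, C]` array.
#' @param field a [deformation_field()] matching the image dimensions.
#' @param interpolation "bilinear" or "nearest".
#' @param fill "replicate" or "constant".
#' @param fill_value constant used when `fill = "constant"`.
#' @export
warp_image <- function(image, field, interpolation = c("bilinear", "nearest"),
                       fill = c("replicate", "constant"), fill_value = 1) {
  interpolation <- match.arg(interpolation)
  fill <- match.arg(fill)
  d <- img_dim(image)
  if (!identical(d[1:2], dim(field$dr)[1:2]) &&
      !identical(as.integer(d[1:2]), as.integer(dim(field$dr))))
    stop("field dimensions do not match image")
  x <- if (length(d) == 2L) array(image, c(d, 1L)) else image
  out <- if (interpolation == "bilinear")
    cpp_warp_bilinear(x, field$dr, field$dc,
                      if (fill == "constant") 1L else 0L, fill_value)
  else cpp_warp_nearest(x, field$dr, field$dc, fill_value)
  if (length(d) == 2L) matrix(out, d[1], d[2]) else {
    dim(out) <- d
    dimnames(out) <- dimnames(image)
    out
  }
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration `g <- -f(x + g(x))`; accurate away from borders for
#' smooth, moderate fields.
#' @param field a [deformation_field()].
#' @param iters number of fixed-point iterations.
#' @export
field_inverse <- function(field, iters = 25) {
  gr <- -field$dr; gc <- -field$dc
  H <- nrow(gr); W <- ncol(gr)
  for (i in seq_len(iters)) {
    g <- deformation_field(gr, gc)
    fr <- warp_image(field$dr, g)
    fc <- warp_image(field$dc, g)
    gr <- -fr; gc <- -fc
  }
  deformation_field(gr, gc)
}

#' Compose two deformation fields
#'
#' Returns the field equivalent to warping first by `f1` and then by `f2`:
#' `F(x) = f2(x) + f1(x + f2(x))`.
#' @param f1,f2 [deformation_field()]s (f1 applied first).
#' @export
compose_fields <- function(f1, f2) {
  deformation_field(f2$dr + warp_image(f1$dr, f2),
                    f2$dc + warp_image(f1$dc, f2))
}
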