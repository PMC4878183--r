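#' Specification of a synthetic crown-like-structure scene
#'
#' Parameters of the seeded generator that emulates the tissue experiment:
#' macrophages either ringing adipocytes (crown geometry, the configuration
#' around dead adipocytes in obese adipose tissue) or dispersed away from them
#' (resident macrophages), with membrane-localized LAMP-1 signal, punctate
#' lysosomal signal, a calnexin-positive permeable subpopulation, and additive
#' Gaussian noise clipped at zero. All painted quantities are recorded as
#' ground truth before noise. Intensities are 16-bit-range floats.
#'
#' Defaults represent the study conditions: the permeable fraction defaults to
#' 0.22, the observed calnexin-positive share of crown macrophages in
#' high-fat-diet tissue; per-cell signal heterogeneity is lognormal
#' (`sdlog = 0.35`), reflecting the heterogeneous, non-normal per-cell
#' response that motivates rank-based testing.
#'
#' @param image_shape `(H, W)` in pixels, each >= 64.
#' @param pixel_size micrometres per pixel.
#' @param n_adipocytes,n_macrophages object counts (>= 0).
#' @param geometry `"crown"` or `"dispersed"`.
#' @param membrane_signal_mean mean membrane LAMP-1 per ring pixel (AFU).
#' @param lysosomal_signal_mean mean total AFU per lysosomal punctum.
#' @param permeable_fraction probability a macrophage is calnexin-positive.
#' @param background_level additive background (AFU) in every channel.
#' @param noise_sd Gaussian noise SD (AFU); clipped at 0.
#' @param seed integer seed; the scene has its own RNG stream.
#' @param macrophage_radius_px,adipocyte_radius_px,nucleus_radius_px geometry
#'   of the disc primitives.
#' @param n_puncta_mean Poisson mean of lysosomal puncta per macrophage.
#' @param heterogeneity_sdlog lognormal sdlog of the per-cell signal factor
#'   (mean 1).
#' @param fitc_level,cy5_level,dapi_level paint levels of the gating channels.
#' @param quantize round intensities to integers.
#' @return A validated `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(256, 256), pixel_size = 0.31,
                       n_adipocytes = 3, n_macrophages = 12,
                       geometry = c("crown", "dispersed"),
                       membrane_signal_mean = 120, lysosomal_signal_mean = 4000,
                       permeable_fraction = 0.22, background_level = 60,
                       noise_sd = 0, seed = 1,
                       macrophage_radius_px = 7, adipocyte_radius_px = 28,
                       nucleus_radius_px = 3, n_puncta_mean = 4,
                       heterogeneity_sdlog = 0.35,
                       fitc_level = 150, cy5_level = 180, dapi_level = 200,
                       quantize = FALSE) {
  geometry <- match.arg(geometry)
  if (length(image_shape) != 2 || any(image_shape < 64))
    abort("`image_shape` must be (H, W) with both >= 64.")
  if (permeable_fraction < 0 || permeable_fraction > 1)
    abort("`permeable_fraction` must lie in [0, 1].")
  if (n_adipocytes < 0 || n_macrophages < 0) abort("counts must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (background_level < 0) abort("`background_level` must be >= 0.")
  as.list(environment())
}

with_scene_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

disc_pixels <- function(shape, center, radius, inner_radius = -1) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(shape[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(shape[2], ceiling(center[2] + radius))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  sel <- d2 <= radius^2 & d2 > inner_radius^2
  if (!any(sel)) return(integer(0))
  rr <- rep(rows, times = length(cols))[as.vector(sel)]
  cc <- rep(cols, each = length(rows))[as.vector(sel)]
  (cc - 1L) * shape[1] + rr
}

add_noise <- function(m, noise_sd, quantize = FALSE) {
  d <- dim(m)
  if (noise_sd > 0) m <- pmax(m + rnorm(length(m), 0, noise_sd), 0)
  if (quantize) m <- round(m)
  m <- pmin(m, 65535)
  dim(m) <- d
  m
}

place_nonoverlapping <- function(n, shape, margin, min_dist, max_tries,
                                 reject = NULL, seed_note = "") {
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      abort(paste0("could not place ", n, " objects without overlap after ",
                   max_tries, " tries", seed_note, "."))
    p <- c(runif(1, margin, shape[1] - margin), runif(1, margin, shape[2] - margin))
    if (!is.null(reject) && reject(p)) next
    if (nrow(centers) > 0 &&
        min(sqrt(rowSums((centers - matrix(p, nrow(centers), 2, byrow = TRUE))^2))) < min_dist)
      next
    centers <- rbind(centers, p)
  }
  centers
}

#' Generate a crown-like-structure fluorescence scene
#'
#' Draws the four-channel tissue scene described by a [scene_spec()]: FITC
#' (F4/80) fills each macrophage disc, Cy3 (LAMP-1) is painted on a membrane
#' ring and/or interior lysosomal puncta, DAPI marks one nucleus per
#' macrophage, and Cy5 (calnexin) fills exactly the permeable subset. In
#' crown geometry macrophages sit on jittered angular slots of an adipocyte
#' perimeter annulus; dispersed macrophages are placed away from every
#' adipocyte. Ground truth records each painted quantity before noise.
#'
#' @param spec a [scene_spec()].
#' @return List with `stack` (a [channel_stack()]) and `truth`, a
#'   `scene_ground_truth` holding a per-cell tibble (`cell_id`, `row`, `col`,
#'   `permeable`, `contact`, `true_surface_signal`, `true_lysosomal_signal`),
#'   the macrophage label map, nucleus and adipocyte masks, and the spec.
#' @export
generate_cls_scene <- function(spec) {
  sh <- spec$image_shape
  r_m <- spec$macrophage_radius_px; r_a <- spec$adipocyte_radius_px
  seed_note <- paste0(" (seed ", spec$seed, ")")

  with_scene_seed(spec$seed, {
    # --- adipocytes ---
    a_margin <- r_a + 2 * r_m + 4
    if (spec$n_adipocytes > 0 && any(sh < 2 * a_margin))
      abort(paste0("image too small for adipocytes of radius ", r_a, seed_note))
    adip <- if (spec$n_adipocytes > 0) {
      place_nonoverlapping(spec$n_adipocytes, sh, a_margin,
                           min_dist = 2 * (r_a + 2 * r_m + 2),
                           max_tries = 5000, seed_note = seed_note)
    } else matrix(numeric(0), ncol = 2)

    # --- macrophage centres ---
    if (spec$geometry == "crown") {
      if (spec$n_adipocytes == 0 && spec$n_macrophages > 0)
        abort(paste0("crown geometry needs at least one adipocyte", seed_note))
      ring_r <- r_a + r_m + 1
      # slot pitch leaves >= ~6 px between neighbouring cell edges after
      # jitter, so smoothing cannot bridge adjacent macrophages
      slots_per <- floor(2 * pi * ring_r / (2 * r_m + 8))
      if (spec$n_macrophages > slots_per * spec$n_adipocytes)
        abort(paste0("crown capacity exceeded: ", spec$n_macrophages,
                     " macrophages for ", spec$n_adipocytes, " adipocytes",
                     seed_note))
      host <- rep(seq_len(max(spec$n_adipocytes, 1)),
                  length.out = spec$n_macrophages)
      centers <- matrix(0, spec$n_macrophages, 2)
      for (ai in unique(host)) {
        mine <- which(host == ai)
        angles <- (sample(slots_per, length(mine)) - 1 +
                     runif(length(mine), -0.05, 0.05)) / slots_per * 2 * pi
        centers[mine, 1] <- adip[ai, 1] + ring_r * sin(angles)
        centers[mine, 2] <- adip[ai, 2] + ring_r * cos(angles)
      }
      contact <- rep(TRUE, spec$n_macrophages)
    } else {
      far <- r_a + 3 * r_m
      reject <- function(p) {
        nrow(adip) > 0 &&
          min(sqrt(rowSums((adip - matrix(p, nrow(adip), 2, byrow = TRUE))^2))) < far
      }
      centers <- place_nonoverlapping(spec$n_macrophages, sh, r_m + 2,
                                      min_dist = 2 * r_m + 2, max_tries = 20000,
                                      reject = reject, seed_note = seed_note)
      contact <- rep(FALSE, spec$n_macrophages)
    }
    n <- spec$n_macrophages

    # --- per-cell draws ---
    permeable <- if (n > 0) runif(n) < spec$permeable_fraction else logical(0)
    het <- if (n > 0)
      exp(rnorm(n, -spec$heterogeneity_sdlog^2 / 2, spec$heterogeneity_sdlog))
    else numeric(0)
    n_puncta <- if (n > 0) rpois(n, spec$n_puncta_mean) else integer(0)

    # --- paint channels ---
    blank <- function() matrix(spec$background_level, sh[1], sh[2])
    fitc <- blank(); cy3 <- blank(); dapi <- blank(); cy5 <- blank()
    labels <- matrix(0L, sh[1], sh[2])
    nucleus_mask <- matrix(FALSE, sh[1], sh[2])
    adipocyte_mask <- matrix(FALSE, sh[1], sh[2])
    for (ai in seq_len(nrow(adip)))
      adipocyte_mask[disc_pixels(sh, adip[ai, ], r_a)] <- TRUE

    true_surface <- true_lyso <- numeric(n)
    for (i in seq_len(n)) {
      body <- disc_pixels(sh, centers[i, ], r_m)
      fitc[body] <- spec$fitc_level
      labels[body] <- i
      # membrane band inset from the disc edge so that smoothing keeps the
      # painted signal inside the F4/80 mask (painting stays conservative)
      ring <- disc_pixels(sh, centers[i, ], r_m - 1.5, inner_radius = r_m - 3.5)
      if (spec$membrane_signal_mean > 0) {
        cy3[ring] <- cy3[ring] + spec$membrane_signal_mean * het[i]
        true_surface[i] <- spec$membrane_signal_mean * het[i] * length(ring)
      }
      if (n_puncta[i] > 0 && spec$lysosomal_signal_mean > 0) {
        for (p in seq_len(n_puncta[i])) {
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, max(r_m - 3.5, 0))
          pc <- centers[i, ] + rad * c(sin(ang), cos(ang))
          px <- disc_pixels(sh, pc, 1.3)
          px <- intersect(px, body)
          if (length(px) == 0) next
          amount <- spec$lysosomal_signal_mean * het[i]
          cy3[px] <- cy3[px] + amount / length(px)
          true_lyso[i] <- true_lyso[i] + amount
        }
      }
      nuc <- disc_pixels(sh, centers[i, ], spec$nucleus_radius_px)
      dapi[nuc] <- spec$dapi_level
      nucleus_mask[nuc] <- TRUE
      if (permeable[i]) cy5[body] <- spec$cy5_level
    }

    stack <- channel_stack(list(
      FITC = add_noise(fitc, spec$noise_sd, spec$quantize),
      Cy3  = add_noise(cy3,  spec$noise_sd, spec$quantize),
      DAPI = add_noise(dapi, spec$noise_sd, spec$quantize),
      Cy5  = add_noise(cy5,  spec$noise_sd, spec$quantize)),
      pixel_size = spec$pixel_size)

    truth <- structure(list(
      cells = tibble::tibble(
        cell_id = seq_len(n),
        row = centers[, 1], col = centers[, 2],
        permeable = permeable, contact = contact,
        true_surface_signal = true_surface,
        true_lysosomal_signal = true_lyso,
        n_puncta = n_puncta),
      labels = labels,
      nucleus_mask = nucleus_mask,
      adipocyte_mask = adipocyte_mask,
      adipocyte_centers = adip,
      spec = spec), class = "scene_ground_truth")

    list(stack = stack, truth = truth)
  })
}

#' Specification of a synthetic ratiometric pH scene
#'
#' @param ph_field numeric matrix of true pH per pixel, values in `[3, 9]`.
#' @param calibration_truth 4-parameter logistic parameters of the generating
#'   ratio response, `list(a, d, c, b)`: ratio = `d + (a-d)/(1+(ph/c)^b)`,
#'   strictly decreasing in pH (CypHer 5E brightens with acidity).
#' @param alexa_level AFU of the pH-insensitive Alexa488 channel inside the
#'   labelled region.
#' @param noise_sd Gaussian noise SD (AFU) on both channels.
#' @param nuclear_regions optional logical matrix; within it the CypHer dye
#'   over-accumulates (x1.6), so these pixels must be excluded downstream.
#' @param label_mask optional logical matrix of dye-labelled pixels; default
#'   is a centred disc covering most of the frame, outside of which both
#'   channels are dark.
#' @param seed integer seed.
#' @return A validated `ph_scene_spec` list.
#' @export
ph_scene_spec <- function(ph_field,
                          calibration_truth = list(a = 3, d = 0.2, c = 6, b = 6),
                          alexa_level = 800, noise_sd = 0,
                          nuclear_regions = NULL, label_mask = NULL, seed = 1) {
  if (!is.matrix(ph_field)) abort("`ph_field` must be a matrix of pH values.")
  if (any(ph_field < 3 | ph_field > 9)) abort("pH values must lie in [3, 9].")
  grid <- seq(3, 9, by = 0.05)
  resp <- response_4pl(grid, calibration_truth)
  if (any(diff(resp) >= 0))
    abort("`calibration_truth` must give a strictly decreasing ratio response in pH.")
  if (is.null(label_mask)) {
    sh <- dim(ph_field)
    label_mask <- matrix(FALSE, sh[1], sh[2])
    label_mask[disc_pixels(sh, (sh + 1) / 2, min(sh) / 2 - 4)] <- TRUE
  }
  if (!identical(dim(label_mask), dim(ph_field)))
    abort("`label_mask` shape must match `ph_field`.")
  if (!is.null(nuclear_regions) && !identical(dim(nuclear_regions), dim(ph_field)))
    abort("`nuclear_regions` shape must match `ph_field`.")
  list(ph_field = ph_field, calibration_truth = calibration_truth,
       alexa_level = alexa_level, noise_sd = noise_sd,
       nuclear_regions = nuclear_regions, label_mask = label_mask,
       seed = seed)
}

#' Four-parameter logistic ratio response
#'
#' @param ph pH values.
#' @param params `list(a, d, c, b)`.
#' @return Ratio values, strictly decreasing in pH for `a > d`, `b > 0`.
#' @export
response_4pl <- function(ph, params) {
  params$d + (params$a - params$d) / (1 + (ph / params$c)^params$b)
}

#' Generate a dual-fluorophore pH scene
#'
#' Paints the pH-insensitive Alexa488 channel at a constant level inside the
#' labelled region and the CypHer 5E channel as
#' `alexa_level * response(ph_field)`, so the noise-free per-pixel ratio
#' equals the generating response exactly. Nuclear regions over-accumulate
#' CypHer, emulating the differential dye uptake that forces their exclusion.
#'
#' @param spec a [ph_scene_spec()].
#' @return List with `stack` (channels `CypHer5E`, `Alexa488`) and `truth`
#'   (`ph_field`, `calibration_truth`, `label_mask`, `nuclear_regions`).
#' @export
generate_ph_scene <- function(spec) {
  sh <- dim(spec$ph_field)
  with_scene_seed(spec$seed, {
    alexa <- matrix(0, sh[1], sh[2])
    alexa[spec$label_mask] <- spec$alexa_level
    cypher <- alexa * response_4pl(spec$ph_field, spec$calibration_truth)
    if (!is.null(spec$nuclear_regions))
      cypher[spec$nuclear_regions] <- cypher[spec$nuclear_regions] * 1.6
    stack <- channel_stack(list(
      CypHer5E = add_noise(cypher, spec$noise_sd),
      Alexa488 = add_noise(alexa, spec$noise_sd)))
    truth <- list(ph_field = spec$ph_field,
                  calibration_truth = spec$calibration_truth,
                  label_mask = spec$label_mask,
                  nuclear_regions = spec$nuclear_regions)
    list(stack = stack, truth = truth)
  })
}

#' Specification of a synthetic EM volume
#'
#' Describes a phase-tiled FIB-SEM-like volume: a macrophage block and an
#' adipocyte block meeting at an interface plane, with lumenal cavities at
#' the interface. Sealed cavities are fully enclosed by cell material;
#' unsealed ones are connected to a volume face by a one-voxel lumen channel.
#'
#' @param volume_shape `(Z, Y, X)` voxel counts.
#' @param voxel_size_nm `(dz, dy, dx)` in nm; anisotropy allowed (the imaging
#'   reference is 10 nm in-plane, 20 nm slices).
#' @param cavities list of cavity descriptions:
#'   `list(shape = "box"|"ellipsoid", center = (z,y,x), size = half-widths
#'   (z,y,x), sealed = TRUE/FALSE)`.
#' @param density_levels named intensities, ascending
#'   `(background, lumen, macrophage, adipocyte)`.
#' @param noise_sd Gaussian intensity noise SD.
#' @param shell_px background border thickness (voxels).
#' @param seed integer seed.
#' @return A validated `volume_spec` list.
#' @export
volume_spec <- function(volume_shape = c(48, 64, 64),
                        voxel_size_nm = c(20, 10, 10),
                        cavities = list(),
                        density_levels = c(background = 20, lumen = 70,
                                           macrophage = 140, adipocyte = 210),
                        noise_sd = 0, shell_px = 2, seed = 1) {
  if (length(volume_shape) != 3 || any(volume_shape < 16))
    abort("`volume_shape` must be (Z, Y, X), each >= 16.")
  if (any(voxel_size_nm <= 0)) abort("voxel sizes must be positive.")
  need <- c("background", "lumen", "macrophage", "adipocyte")
  if (!all(need %in% names(density_levels)))
    abort("`density_levels` must name background, lumen, macrophage, adipocyte.")
  list(volume_shape = volume_shape, voxel_size_nm = voxel_size_nm,
       cavities = cavities, density_levels = density_levels,
       noise_sd = noise_sd, shell_px = shell_px, seed = seed)
}

cavity_voxels <- function(shape, cav) {
  ax <- lapply(1:3, function(k) {
    lo <- max(1L, floor(cav$center[k] - cav$size[k]))
    hi <- min(shape[k], ceiling(cav$center[k] + cav$size[k]))
    lo:hi
  })
  grid <- expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]])
  if (identical(cav$shape, "ellipsoid")) {
    keep <- ((grid$z - cav$center[1]) / cav$size[1])^2 +
      ((grid$y - cav$center[2]) / cav$size[2])^2 +
      ((grid$x - cav$center[3]) / cav$size[3])^2 <= 1
    grid <- grid[keep, , drop = FALSE]
  } else {
    keep <- abs(grid$z - cav$center[1]) <= cav$size[1] &
      abs(grid$y - cav$center[2]) <= cav$size[2] &
      abs(grid$x - cav$center[3]) <= cav$size[3]
    grid <- grid[keep, , drop = FALSE]
  }
  (grid$x - 1L) * shape[1] * shape[2] + (grid$y - 1L) * shape[1] + grid$z
}

#' Generate a synthetic EM volume with known compartments
#'
#' Builds the phase and intensity volumes from a [volume_spec()]: a
#' background shell, macrophage and adipocyte half-volumes meeting at a
#' mid-X interface, and the requested lumenal cavities. Unsealed cavities get
#' a one-voxel lumen channel to the nearest X face. Before returning, the
#' sealed/unsealed flags are verified by flood fill from the volume faces
#' through lumen and background (self-consistency check).
#'
#' @param spec a [volume_spec()].
#' @return List with `volume` (an [em_volume()], intensities only) and
#'   `truth`: tibble of cavities (`cavity_id`, `voxel_count`, `volume_nm3`,
#'   `sealed`), the true phase array and the spec.
#' @export
generate_em_volume <- function(spec) {
  sh <- spec$volume_shape
  for (cav in spec$cavities) {
    if (any(cav$center - cav$size < 1) || any(cav$center + cav$size > sh))
      abort("cavity extends beyond the volume bounds.")
  }
  with_scene_seed(spec$seed, {
    phases <- array("background", sh)
    s <- spec$shell_px
    interior_z <- (1 + s):(sh[1] - s)
    interior_y <- (1 + s):(sh[2] - s)
    x_mid <- floor(sh[3] / 2)
    phases[interior_z, interior_y, (1 + s):x_mid] <- "macrophage"
    phases[interior_z, interior_y, (x_mid + 1):(sh[3] - s)] <- "adipocyte"

    cav_ids <- vector("list", length(spec$cavities))
    for (i in seq_along(spec$cavities)) {
      cav <- spec$cavities[[i]]
      vox <- cavity_voxels(sh, cav)
      if (any(phases[vox] == "background"))
        abort("cavity is not enclosed by cell material; move it inside the shell.")
      phases[vox] <- "lumen"
      cav_ids[[i]] <- vox
      if (!isTRUE(cav$sealed)) {
        # one-voxel lumen channel along +X to the face
        cz <- round(cav$center[1]); cy <- round(cav$center[2])
        phases[cz, cy, round(cav$center[3]):sh[3]] <- "lumen"
      }
    }

    # self-consistency: flood fill from faces through lumen + background
    open_space <- phases == "lumen" | phases == "background"
    lab <- label_components(open_space, connectivity = 26)
    face_ids <- unique(c(lab[c(1, sh[1]), , ], lab[, c(1, sh[2]), ],
                         lab[, , c(1, sh[3])]))
    face_ids <- setdiff(face_ids, 0L)
    for (i in seq_along(spec$cavities)) {
      reachable <- any(lab[cav_ids[[i]]] %in% face_ids)
      if (reachable == isTRUE(spec$cavities[[i]]$sealed))
        abort(paste0("internal inconsistency: cavity ", i,
                     " sealed flag disagrees with flood fill."))
    }

    # open cavities: the escape channel is lumen phase but is not part of the
    # cavity body, so their truth counts cover the body only
    counts <- vapply(cav_ids, length, integer(1))

    intensity <- array(spec$density_levels[phases], sh)
    if (spec$noise_sd > 0)
      intensity <- array(pmax(0, intensity + rnorm(length(intensity), 0, spec$noise_sd)), sh)

    truth <- list(
      cavities = tibble::tibble(
        cavity_id = seq_along(spec$cavities),
        voxel_count = counts,
        volume_nm3 = counts * prod(spec$voxel_size_nm),
        sealed = vapply(spec$cavities, function(c) isTRUE(c$sealed), logical(1))),
      phases = phases,
      spec = spec)
    list(volume = em_volume(intensity, spec$voxel_size_nm), truth = truth)
  })
}

#' Generate a per-cell uptake / foam-cell scene
#'
#' Draws the culture-model scene for integrated-power readouts: every
#' macrophage is outlined by a CtB ring, the signal channel (Alexa546-labelled
#' adipocyte material, or LipidTOX) carries interior puncta whose noise-free
#' total equals the requested per-cell truth, and an adipocyte disc provides
#' the contact-gating mask. Cells flagged in `contact_pattern` are placed
#' tangent to the adipocyte; the rest are placed well away from it.
#'
#' @param per_cell_truth numeric vector of true total AFU per cell (>= 0).
#' @param contact_pattern logical vector, same length.
#' @param seed integer seed.
#' @param image_shape `(H, W)`; chosen automatically when `NULL`.
#' @param cell_radius_px,ring_width_px,adipocyte_radius_px geometry; the
#'   adipocyte radius grows if needed to seat all contacting cells.
#' @param ctb_level,adipo_level paint levels (AFU).
#' @param background_level additive background in every channel.
#' @param noise_sd Gaussian noise SD, clipped at 0.
#' @param signal_channel_name name for the signal channel (`"Alexa546"` or
#'   `"LipidTOX"`).
#' @return List with `stack` (channels `CtB`, signal, `Adipocyte`) and
#'   `truth`: per-cell tibble (`cell_id`, `row`, `col`, `true_signal`,
#'   `contact`), label map and adipocyte mask.
#' @export
generate_uptake_scene <- function(per_cell_truth, contact_pattern, seed = 1,
                                  image_shape = NULL, cell_radius_px = 8,
                                  ring_width_px = 2, adipocyte_radius_px = 24,
                                  ctb_level = 150, adipo_level = 160,
                                  background_level = 0, noise_sd = 0,
                                  signal_channel_name = "Alexa546") {
  n <- length(per_cell_truth)
  if (length(contact_pattern) != n)
    abort("`per_cell_truth` and `contact_pattern` lengths differ.")
  if (any(per_cell_truth < 0)) abort("per-cell truth values must be >= 0.")
  r <- cell_radius_px
  n_contact <- sum(contact_pattern)
  # adipocyte large enough to seat the contacting cells on its perimeter
  r_a <- adipocyte_radius_px
  if (n_contact > 0)
    r_a <- max(r_a, ceiling(n_contact * (2 * r + 3) / (2 * pi)) - r)
  if (is.null(image_shape)) {
    side <- max(128, 2 * (r_a + 4 * r + 24))
    image_shape <- c(side, side)
  }
  sh <- image_shape
  seed_note <- paste0(" (seed ", seed, ")")

  with_scene_seed(seed, {
    center_a <- sh / 2
    ring_r <- r_a + r
    contact_idx <- which(contact_pattern)
    centers <- matrix(0, n, 2)
    if (n_contact > 0) {
      slots <- max(n_contact, floor(2 * pi * ring_r / (2 * r + 3)))
      angles <- (sample(slots, n_contact) - 1) / slots * 2 * pi
      centers[contact_idx, 1] <- center_a[1] + ring_r * sin(angles)
      centers[contact_idx, 2] <- center_a[2] + ring_r * cos(angles)
    }
    if (n_contact < n) {
      far <- r_a + 3 * r + 6
      reject <- function(p) sqrt(sum((p - center_a)^2)) < far
      free <- place_nonoverlapping(n - n_contact, sh, r + 2,
                                   min_dist = 2 * r + 2, max_tries = 20000,
                                   reject = reject, seed_note = seed_note)
      centers[!contact_pattern, ] <- free
    }

    blank <- function() matrix(background_level, sh[1], sh[2])
    ctb <- blank(); sig <- blank(); adipo <- blank()
    labels <- matrix(0L, sh[1], sh[2])
    adip_px <- disc_pixels(sh, center_a, r_a)
    adipo[adip_px] <- adipo[adip_px] + adipo_level
    adipocyte_mask <- matrix(FALSE, sh[1], sh[2])
    adipocyte_mask[adip_px] <- TRUE

    true_signal <- numeric(n)
    for (i in seq_len(n)) {
      ring <- disc_pixels(sh, centers[i, ], r, inner_radius = r - ring_width_px)
      body <- disc_pixels(sh, centers[i, ], r)
      ctb[ring] <- ctb[ring] + ctb_level
      labels[body] <- i
      if (per_cell_truth[i] > 0) {
        interior <- disc_pixels(sh, centers[i, ], r - ring_width_px - 1)
        k <- min(3L, max(1L, length(interior) %/% 8))
        px <- unlist(lapply(seq_len(k), function(j) {
          ang <- 2 * pi * j / k; rad <- (r - ring_width_px - 2) / 2
          disc_pixels(sh, centers[i, ] + rad * c(sin(ang), cos(ang)), 1.3)
        }))
        px <- intersect(unique(px), interior)
        if (length(px) == 0) px <- interior[1]
        sig[px] <- sig[px] + per_cell_truth[i] / length(px)
        true_signal[i] <- sum(per_cell_truth[i] / length(px) * length(px))
      }
    }

    channels <- list(CtB = add_noise(ctb, noise_sd),
                     signal = add_noise(sig, noise_sd),
                     Adipocyte = add_noise(adipo, noise_sd))
    names(channels)[2] <- signal_channel_name
    truth <- structure(list(
      cells = tibble::tibble(cell_id = seq_len(n),
                             row = centers[, 1], col = centers[, 2],
                             true_signal = true_signal,
                             contact = contact_pattern),
      labels = labels,
      adipocyte_mask = adipocyte_mask), class = "scene_ground_truth")
    list(stack = channel_stack(channels), truth = truth)
  })
}
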