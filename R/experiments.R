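#' Simulated surface-LAMP-1 comparison (crown vs. resident macrophages)
#'
#' End-to-end parameter-recovery experiment: a treated arm of crown
#' macrophages is generated with a known fold increase of membrane LAMP-1
#' over a control arm of dispersed macrophages, both arms are quantified with
#' the tissue mask-algebra pipeline, and the arms are compared per cell with
#' the Wilcoxon rank-sum test. The signal-to-noise ratio is defined as the
#' control membrane signal per ring pixel over the per-pixel noise SD.
#'
#' @param n_cells macrophages per arm.
#' @param fold_change true treated/control membrane-signal ratio.
#' @param snr control membrane signal / noise SD; `Inf` for noise-free.
#' @param seed integer seed (two scene seeds are derived from it).
#' @param membrane_signal_mean control membrane LAMP-1 per ring pixel (AFU).
#' @param permeable_fraction calnexin-positive share in both arms.
#' @return List: `per_cell` (tibble of per-macrophage signals by condition),
#'   `fold_field` (ratio of field-level signal-per-cell values),
#'   `fold_per_cell` (ratio of per-cell medians), `p_value` (rank-sum),
#'   and the two `per_cell_result` field summaries.
#' @export
simulate_lamp1_experiment <- function(n_cells = 40, fold_change = 2.2,
                                      snr = 10, seed = 1,
                                      membrane_signal_mean = 120,
                                      permeable_fraction = 0.22) {
  noise_sd <- if (is.finite(snr)) membrane_signal_mean / snr else 0
  n_adip <- max(1, ceiling(n_cells / 8))
  side <- max(256, ceiling(sqrt(n_adip) * 2.6 * (28 + 2 * 7 + 4)) + 64)
  base <- list(image_shape = c(side, side), n_adipocytes = n_adip,
               n_macrophages = n_cells, lysosomal_signal_mean = 0,
               n_puncta_mean = 0, permeable_fraction = permeable_fraction,
               noise_sd = noise_sd)

  ctrl_spec <- do.call(scene_spec, c(base, list(
    geometry = "dispersed", membrane_signal_mean = membrane_signal_mean,
    seed = scene_seed(seed, 1))))
  trt_spec <- do.call(scene_spec, c(base, list(
    geometry = "crown", membrane_signal_mean = membrane_signal_mean * fold_change,
    seed = scene_seed(seed, 2))))

  ctrl <- generate_cls_scene(ctrl_spec)
  trt <- generate_cls_scene(trt_spec)

  field_ctrl <- surface_lamp1_per_cell(ctrl$stack)
  field_trt <- surface_lamp1_per_cell(trt$stack)

  pc <- dplyr::bind_rows(
    dplyr::mutate(surface_lamp1_per_macrophage(ctrl$stack), condition = "control"),
    dplyr::mutate(surface_lamp1_per_macrophage(trt$stack), condition = "crown"))
  a <- pc$surface_lamp1[pc$condition == "crown" & !pc$permeable]
  b <- pc$surface_lamp1[pc$condition == "control" & !pc$permeable]
  test <- rank_sum_test(a, b, mode = "normal")

  list(per_cell = pc,
       fold_field = field_trt$signal_per_cell / field_ctrl$signal_per_cell,
       fold_per_cell = median(a) / median(b),
       p_value = test$p_value,
       field_control = field_ctrl, field_treated = field_trt)
}

scene_seed <- function(seed, k) {
  # sub-seeds are drawn through the RNG rather than by linear arithmetic:
  # seeds at a fixed arithmetic offset initialize correlated
  # Mersenne-Twister streams, which couples the experiment arms
  withr::with_seed(as.integer(as.numeric(seed) %% 2147483647),
                   sample.int(2147483646L, k)[k])
}

#' One null replicate of the uptake pipeline
#'
#' Generates two uptake scenes whose per-cell truths are drawn from the same
#' lognormal distribution, runs the full quantification (CtB labelling,
#' adipocyte-contact gating, integrated power) on both, and returns the
#' rank-sum p-value. Under this null the p-value is uniform up to
#' discreteness, so the rejection rate at any level alpha estimates alpha —
#' the type-I calibration of the whole pipeline.
#'
#' @param n_cells cells per arm.
#' @param seed integer seed.
#' @param meanlog,sdlog lognormal parameters of the shared truth distribution.
#' @param noise_sd per-pixel Gaussian noise (AFU).
#' @return The two-sided rank-sum p-value.
#' @export
simulate_null_uptake_replicate <- function(n_cells = 20, seed = 1,
                                           meanlog = log(3000), sdlog = 0.6,
                                           noise_sd = 4) {
  powers <- lapply(1:2, function(arm) {
    sd_arm <- scene_seed(seed, arm)
    truths <- withr::with_seed(sd_arm, stats::rlnorm(n_cells, meanlog, sdlog))
    scene <- generate_uptake_scene(truths, rep(TRUE, n_cells),
                                   seed = scene_seed(seed, arm + 10),
                                   noise_sd = noise_sd)
    quantify_uptake(scene$stack)$power
  })
  rank_sum_test(powers[[1]], powers[[2]], mode = "normal")$p_value
}

#' Quantify an uptake scene
#'
#' The culture-model uptake pipeline: label cells from the CtB channel, build
#' the adipocyte mask from the labelled-adipocyte channel, gate on contact,
#' and integrate the signal channel per contacting cell.
#'
#' @param stack a [channel_stack()] with `CtB`, a signal channel and
#'   `Adipocyte`.
#' @param signal_channel signal channel name; defaults to the first channel
#'   that is neither `CtB` nor `Adipocyte`.
#' @param radius_px contact radius (pixels).
#' @param ... passed to [label_cells_from_ctb()].
#' @return Tibble of contacting cells: `cell_id`, `power`, `in_contact`.
#' @export
quantify_uptake <- function(stack, signal_channel = NULL, radius_px = 1, ...) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.null(signal_channel))
    signal_channel <- setdiff(channel_names(stack), c("CtB", "Adipocyte"))[1]
  cells <- label_cells_from_ctb(get_channel(stack, "CtB"), ...)
  adip <- adipocyte_mask_from_channel(get_channel(stack, "Adipocyte"),
                                      largest_only = TRUE)
  contact <- contact_filter(cells, adip, radius_px = radius_px)
  cell_power(cells, get_channel(stack, signal_channel)) |>
    dplyr::left_join(contact, by = "cell_id") |>
    dplyr::filter(.data$in_contact)
}

#' Simulated pH-field recovery
#'
#' Generates a scene with a smooth pH field (an acidified pocket, pH ~4.8,
#' inside a neutral pH 7.4 region), builds the calibration curve from
#' noise-free uniform buffer scenes rendered through the same ratio response,
#' recovers the pixel-wise pH map, and reports the RMSE against the true
#' field over defined pixels away from the mask edge (where smoothing mixes
#' labelled and unlabelled pixels).
#'
#' @param seed integer seed.
#' @param snr Alexa channel level / noise SD; `Inf` for noise-free.
#' @param shape image shape.
#' @param buffer_phs calibration buffer pH values.
#' @param edge_px border of the labelled region excluded from the RMSE.
#' @return List: `rmse`, `ph_map`, `truth`, `curve`, `n_eval`.
#' @export
simulate_ph_recovery <- function(seed = 1, snr = Inf, shape = c(192, 192),
                                 buffer_phs = seq(4, 8, by = 0.5),
                                 edge_px = 8) {
  resp <- list(a = 3, d = 0.2, c = 6, b = 6)
  field <- ph_pocket_field(shape, ph_ambient = 7.4, ph_pocket = 4.8,
                           radius = min(shape) / 5)
  alexa_level <- 800
  noise_sd <- if (is.finite(snr)) alexa_level / snr else 0
  scene <- generate_ph_scene(ph_scene_spec(
    field, calibration_truth = resp, alexa_level = alexa_level,
    noise_sd = noise_sd, seed = seed))

  curve <- fit_calibration(calibration_standards(buffer_phs, resp, alexa_level))
  ri <- ratio_image(scene$stack)
  pm <- ph_map(ri, curve)

  inner <- erode_mask(scene$truth$label_mask, edge_px)
  eval_px <- inner & !is.na(pm$ph)
  err <- pm$ph[eval_px] - field[eval_px]
  list(rmse = sqrt(mean(err^2)), ph_map = pm, truth = scene$truth,
       curve = curve, n_eval = sum(eval_px))
}

#' Smooth acidified-pocket pH field
#'
#' @param shape `(H, W)`.
#' @param ph_ambient,ph_pocket ambient and pocket pH.
#' @param radius pocket radius (pixels); the transition is a smooth sigmoid
#'   in distance.
#' @param center pocket centre; defaults to the image centre.
#' @return Matrix of pH values.
#' @export
ph_pocket_field <- function(shape, ph_ambient = 7.4, ph_pocket = 4.8,
                            radius = 30, center = (shape + 1) / 2) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  w <- 1 / (1 + exp((d - radius) / (radius / 4)))
  ph_ambient + (ph_pocket - ph_ambient) * w
}

#' Calibration standards from uniform buffer scenes
#'
#' Renders one uniform-pH scene per buffer through the generator (noise-free)
#' and reduces each to its mean defined ratio, mimicking the acquisition of
#' calibration buffer images.
#'
#' @param buffer_phs buffer pH values (>= 3 required downstream).
#' @param calibration_truth generating ratio response (see [ph_scene_spec()]).
#' @param alexa_level Alexa channel level (AFU).
#' @param shape buffer image shape.
#' @return Tibble with `ph` and `ratio`, ready for [fit_calibration()].
#' @export
calibration_standards <- function(buffer_phs,
                                  calibration_truth = list(a = 3, d = 0.2, c = 6, b = 6),
                                  alexa_level = 800, shape = c(64, 64)) {
  purrr::map_dfr(buffer_phs, function(ph) {
    sc <- generate_ph_scene(ph_scene_spec(
      matrix(ph, shape[1], shape[2]), calibration_truth = calibration_truth,
      alexa_level = alexa_level, noise_sd = 0, seed = 1))
    ri <- ratio_image(sc$stack, method = "fixed", value = alexa_level / 2)
    tibble::tibble(ph = ph, ratio = mean(ri$ratio, na.rm = TRUE))
  })
}

erode_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  dist <- EBImage::imageData(EBImage::distmap(mask * 1))
  dist > px
}

#' Simulated sealed-compartment detection
#'
#' Generates an EM-like volume containing two sealed interface cavities and
#' one cavity opened to a face, classifies phases by intensity banding, and
#' extracts compartments.
#'
#' @param seed integer seed.
#' @param noise_sd intensity noise SD (phase levels are 20/70/140/210).
#' @return List: `compartments` (detected), `truth` (generated), `volume`.
#' @export
simulate_em_case <- function(seed = 1, noise_sd = 0) {
  spec <- volume_spec(
    volume_shape = c(48, 64, 96),
    voxel_size_nm = c(20, 10, 10),
    cavities = list(
      list(shape = "box", center = c(16, 20, 48), size = c(4, 4, 4), sealed = TRUE),
      list(shape = "box", center = c(32, 44, 48), size = c(3, 3, 3), sealed = TRUE),
      list(shape = "box", center = c(24, 32, 70), size = c(3, 3, 3), sealed = FALSE)),
    noise_sd = noise_sd, seed = seed)
  gen <- generate_em_volume(spec)
  # no pre-smoothing: it would erode one-voxel escape channels; at the phase
  # contrasts used (minimum gap 50 AFU) banding alone is reliable
  vol <- classify_phases(gen$volume, thresholds = c(45, 105, 175),
                         phase_order = c("background", "lumen", "macrophage", "adipocyte"))
  list(compartments = extract_compartments(vol), truth = gen$truth,
       volume = vol)
}

#' Simulated foam-cell experiment
#'
#' Generates a treated scene whose per-cell LipidTOX truths are a two-
#' population mixture (a `positive_fraction` share of lipid-laden cells) and
#' a control scene of background-level cells, then calls foam cells with the
#' adaptive median + k*MAD rule against the control powers.
#'
#' @param n_cells cells per scene.
#' @param positive_fraction true share of foam cells in the treated scene.
#' @param seed integer seed.
#' @param noise_sd per-pixel noise (AFU).
#' @return List: `fraction` (recovered positive fraction), `call`
#'   (a `positivity_call`), `truth_fraction` (realized share).
#' @export
simulate_foam_experiment <- function(n_cells = 200, positive_fraction = 0.6,
                                     seed = 1, noise_sd = 2) {
  n_scene <- 25 # cells per generated image
  stopifnot(n_cells %% n_scene == 0)
  gen_arm <- function(truth_fun, base_seed) {
    purrr::map_dfr(seq_len(n_cells / n_scene), function(i) {
      truths <- withr::with_seed(scene_seed(base_seed, i), truth_fun(n_scene))
      scene <- generate_uptake_scene(truths, rep(TRUE, n_scene),
                                     seed = scene_seed(base_seed, i + 100),
                                     noise_sd = noise_sd,
                                     signal_channel_name = "LipidTOX")
      quantify_uptake(scene$stack)
    })
  }
  pos_draw <- function(n) {
    pos <- stats::runif(n) < positive_fraction
    ifelse(pos, stats::rlnorm(n, log(8000), 0.4), stats::rlnorm(n, log(150), 0.5))
  }
  ctrl_draw <- function(n) stats::rlnorm(n, log(150), 0.5)

  treated <- gen_arm(pos_draw, seed)
  control <- gen_arm(ctrl_draw, seed + 5000)
  call <- positivity(treated, rule = "mad", control = control$power)
  list(fraction = call$fraction, call = call,
       n_treated = nrow(treated), n_control = nrow(control))
}
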