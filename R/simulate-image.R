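# Synthetic multiplex-image generator. Renders two ground-truth myeloid
# populations (microglia, TAMs) as disks with per-population, per-marker
# intensity models onto a background, with optional Gaussian blur and
# additive noise. Ground truth stays analytic so every downstream stage of
# the pipeline can be validated exactly.

#' Specification for a simulated multiplex image
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size, um per pixel.
#' @param n_microglia,n_tam number of cells per population.
#' @param cell_radius_px_range integer (min, max) disk radius in pixels.
#' @param marker_panel ordered marker names; must include `"Iba1"` and
#'   exactly one of `"P2RY12"`/`"TMEM119"`, optionally one of
#'   `"CD14"`/`"CD163"`.
#' @param intensity_model nested list `population -> marker -> params`:
#'   either `list(mean=, sd=)` (normal, truncated at 0) or
#'   `list(meanlog=, sdlog=, dist="lognormal")`. Defaults emulate a
#'   bimodal microglial-marker split between the populations and an
#'   overlapping log-normal continuum for CD14/CD163. See
#'   [default_intensity_model()].
#' @param background_level,noise_sd background intensity and additive
#'   Gaussian noise sd (arbitrary intensity units).
#' @param blur_sigma_px Gaussian PSF sigma in pixels (0 = no blur).
#' @param vessel_fraction fraction of TAM-like cells placed along a
#'   simulated vessel path (perivascular macrophages in control tissue).
#' @param max_overlap_fraction fraction of cells allowed to violate the
#'   non-touching placement constraint; the default 0 keeps connected
#'   components identifiable as single cells.
#' @param seed integer RNG seed; simulation is deterministic given the spec.
#' @return An `image_sim_spec` list, validated.
#' @export
image_sim_spec <- function(width_px = 512L, height_px = 512L,
                           pixel_size_um = 0.5,
                           n_microglia = 50L, n_tam = 50L,
                           cell_radius_px_range = c(4L, 7L),
                           marker_panel = c("Iba1", "P2RY12", "CD163"),
                           intensity_model = NULL,
                           background_level = 0, noise_sd = 0,
                           blur_sigma_px = 0, vessel_fraction = 0,
                           max_overlap_fraction = 0, seed = 1L) {
  assert_scalar_number(width_px, "width_px", lower = 8)
  assert_scalar_number(height_px, "height_px", lower = 8)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(n_microglia, "n_microglia", lower = 0)
  assert_scalar_number(n_tam, "n_tam", lower = 0)
  if (n_microglia + n_tam < 1)
    stop_myelogate("n_microglia + n_tam must be >= 1 (empty scene disallowed)",
                   "validation_error")
  if (length(cell_radius_px_range) != 2L ||
      cell_radius_px_range[1] > cell_radius_px_range[2] ||
      cell_radius_px_range[1] < 1)
    stop_myelogate("cell_radius_px_range must be (min, max) with min >= 1",
                   "validation_error")
  if (!"Iba1" %in% marker_panel)
    stop_myelogate("marker_panel must include Iba1", "validation_error")
  mg_marker <- microglial_marker(marker_panel)
  highlow_marker(marker_panel)
  assert_scalar_number(background_level, "background_level", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(blur_sigma_px, "blur_sigma_px", lower = 0)
  assert_scalar_number(vessel_fraction, "vessel_fraction", 0, 1)
  assert_scalar_number(max_overlap_fraction, "max_overlap_fraction", 0, 1)
  if (is.null(intensity_model))
    intensity_model <- default_intensity_model(marker_panel)
  for (pop in c("microglia", "tam")) {
    if (is.null(intensity_model[[pop]]))
      stop_myelogate(sprintf("intensity_model lacks population '%s'", pop),
                     "validation_error")
    for (m in marker_panel) {
      entry <- intensity_model[[pop]][[m]]
      if (is.null(entry))
        stop_myelogate(sprintf("intensity_model[%s] lacks marker '%s'",
                               pop, m), "validation_error")
      if (model_mean(entry) < 0)
        stop_myelogate("intensity means must be >= 0", "validation_error")
    }
  }
  if (model_mean(intensity_model$microglia[[mg_marker]]) <=
      model_mean(intensity_model$tam[[mg_marker]]))
    stop_myelogate(paste0(
      "microglial-marker mean must be strictly higher in microglia than in ",
      "TAMs (the bimodality the gating relies on)"), "validation_error")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    n_microglia = as.integer(n_microglia), n_tam = as.integer(n_tam),
    cell_radius_px_range = as.integer(cell_radius_px_range),
    marker_panel = marker_panel, intensity_model = intensity_model,
    background_level = background_level, noise_sd = noise_sd,
    blur_sigma_px = blur_sigma_px, vessel_fraction = vessel_fraction,
    max_overlap_fraction = max_overlap_fraction, seed = as.integer(seed)),
    class = "image_sim_spec")
}

#' Default per-population intensity model
#'
#' Iba1 is bright in both populations (it is the pan-myeloid mask/master
#' channel). The microglial marker is bimodal: bright in microglia, dim in
#' TAMs — the two clear populations the gating exploits. CD14/CD163 is an
#' overlapping log-normal continuum, shifted upward in TAMs but not
#' TAM-exclusive.
#'
#' @param marker_panel marker names as in [image_sim_spec()].
#' @return nested list `population -> marker -> params`.
#' @export
default_intensity_model <- function(marker_panel) {
  mg <- microglial_marker(marker_panel)
  hl <- highlow_marker(marker_panel)
  model <- list(
    microglia = list(Iba1 = list(mean = 140, sd = 15)),
    tam       = list(Iba1 = list(mean = 160, sd = 15)))
  model$microglia[[mg]] <- list(mean = 150, sd = 10)
  model$tam[[mg]]       <- list(mean = 30,  sd = 10)
  if (!is.null(hl)) {
    model$microglia[[hl]] <- list(meanlog = 3.0, sdlog = 0.6,
                                  dist = "lognormal")
    model$tam[[hl]]       <- list(meanlog = 3.9, sdlog = 0.6,
                                  dist = "lognormal")
  }
  model
}

model_mean <- function(entry) {
  if (identical(entry$dist, "lognormal"))
    exp(entry$meanlog + entry$sdlog^2 / 2)
  else entry$mean
}

draw_intensity <- function(entry, n) {
  if (identical(entry$dist, "lognormal"))
    stats::rlnorm(n, entry$meanlog, entry$sdlog)
  else pmax(0, stats::rnorm(n, entry$mean, entry$sd))
}

# Rejection-sample non-overlapping disk centers; cells tagged as vessel
# cells are constrained to a band around a random straight path.
place_cells <- function(spec, radii, vessel_cell) {
  n <- length(radii)
  W <- spec$width_px; H <- spec$height_px
  max_bad <- floor(spec$max_overlap_fraction * n)
  xs <- numeric(n); ys <- numeric(n)
  # vessel path: random point + direction through the frame
  theta <- stats::runif(1, 0, pi)
  vx <- cos(theta); vy <- sin(theta)
  cx0 <- stats::runif(1, 0.3 * W, 0.7 * W)
  cy0 <- stats::runif(1, 0.3 * H, 0.7 * H)
  n_bad <- 0L
  for (i in seq_len(n)) {
    r <- radii[i]
    placed <- FALSE
    for (attempt in seq_len(400L)) {
      if (vessel_cell[i]) {
        t <- stats::runif(1, -max(W, H), max(W, H))
        x <- cx0 + t * vx + stats::rnorm(1, 0, 2)
        y <- cy0 + t * vy + stats::rnorm(1, 0, 2)
        if (x < r + 1 || x > W - r - 1 || y < r + 1 || y > H - r - 1) next
      } else {
        x <- stats::runif(1, r + 1, W - r - 1)
        y <- stats::runif(1, r + 1, H - r - 1)
      }
      if (i > 1L) {
        j <- seq_len(i - 1L)
        # gap >= 2 px between disk rims keeps 8-connected components apart
        ok <- all((xs[j] - x)^2 + (ys[j] - y)^2 >=
                    (radii[j] + r + 2)^2)
      } else ok <- TRUE
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) {
      if (n_bad < max_bad) {
        n_bad <- n_bad + 1L   # allowed overlap: keep last attempt
        placed <- TRUE
      } else {
        stop_myelogate(sprintf(
          paste0("could not place %d cells without exceeding the overlap ",
                 "budget (max_overlap_fraction = %g); reduce counts or ",
                 "raise the budget"), n, spec$max_overlap_fraction),
          "placement_error")
      }
    }
    xs[i] <- x; ys[i] <- y
  }
  cbind(x = xs, y = ys)
}

#' Simulate a multiplex immunofluorescence image with ground truth
#'
#' Places `n_microglia + n_tam` disk-shaped cells (non-touching by
#' default), draws each cell's per-marker foreground intensity from its
#' population's intensity model, renders one raster per marker
#' (`background + foreground`, Gaussian blur, additive noise), and returns
#' the image together with the per-cell ground truth.
#'
#' @param spec an [image_sim_spec()].
#' @param case_id,tissue_type metadata attached to the output image.
#' @return list with elements `image` (a [multiplex_image()]) and `truth`
#'   (data frame: `cell_id`, `true_label`, `x_px`, `y_px` (0-based
#'   centres), `radius_px`, `vessel`, and `true_<marker>` foreground
#'   means). Deterministic for a fixed spec (including its seed).
#' @export
simulate_image <- function(spec, case_id = "sim", tissue_type = "grade_iv") {
  stopifnot(inherits(spec, "image_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_microglia + spec$n_tam
    label <- rep(c("microglia", "tam"), c(spec$n_microglia, spec$n_tam))
    radii <- sample(seq(spec$cell_radius_px_range[1],
                        spec$cell_radius_px_range[2]), n, replace = TRUE)
    vessel_cell <- rep(FALSE, n)
    if (spec$vessel_fraction > 0 && spec$n_tam > 0) {
      n_ves <- round(spec$vessel_fraction * spec$n_tam)
      ves_idx <- which(label == "tam")[seq_len(n_ves)]
      vessel_cell[ves_idx] <- TRUE
    }
    centers <- place_cells(spec, radii, vessel_cell)
    truth <- data.frame(cell_id = seq_len(n), true_label = label,
                        x_px = centers[, "x"] - 1,  # 0-based convention
                        y_px = centers[, "y"] - 1,
                        radius_px = radii, vessel = vessel_cell,
                        stringsAsFactors = FALSE)
    H <- spec$height_px; W <- spec$width_px
    channels <- list()
    for (m in spec$marker_panel) {
      fg <- numeric(n)
      for (pop in c("microglia", "tam")) {
        idx <- which(label == pop)
        if (length(idx))
          fg[idx] <- draw_intensity(spec$intensity_model[[pop]][[m]],
                                    length(idx))
      }
      truth[[paste0("true_", m)]] <- fg
      raster <- matrix(spec$background_level, H, W)
      for (i in seq_len(n)) {
        r <- radii[i]
        cx <- centers[i, "x"]; cy <- centers[i, "y"]
        xr <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
        yr <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
        disk <- outer((yr - cy)^2, (xr - cx)^2, `+`) <= r^2
        raster[yr, xr][disk] <- raster[yr, xr][disk] -
          spec$background_level + fg[i]
      }
      if (spec$blur_sigma_px > 0)
        raster <- as.matrix(EBImage::gblur(raster,
                                           sigma = spec$blur_sigma_px))
      if (spec$noise_sd > 0)
        raster <- raster + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
      channels[[m]] <- raster
    }
    list(image = multiplex_image(channels, spec$pixel_size_um,
                                 case_id = case_id,
                                 tissue_type = tissue_type),
         truth = truth)
  })
}

#' Simulate a single-cell intensity table directly
#'
#' Draws per-cell marker means straight from the intensity model — i.e.
#' what [measure_cells()] would report for a zero-noise, zero-background
#' render — bypassing rasterization. Useful for exercising the gating and
#' population-metric stages at cell counts where rendering full images
#' would be wasteful.
#'
#' @inheritParams simulate_image
#' @return A `cell_table` with an extra `true_label` column.
#' @export
simulate_cell_table <- function(spec, case_id = "sim",
                                tissue_type = "grade_iv") {
  stopifnot(inherits(spec, "image_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_microglia + spec$n_tam
    label <- rep(c("microglia", "tam"), c(spec$n_microglia, spec$n_tam))
    r_mid <- mean(spec$cell_radius_px_range)
    area <- max(1L, round(pi * r_mid^2))
    tab <- data.frame(
      case_id = case_id, tissue_type = tissue_type, cell_id = seq_len(n),
      x_px = NA_real_, y_px = NA_real_,
      area_px = area, area_um2 = area * spec$pixel_size_um^2,
      tissue_area_mm2 = spec$width_px * spec$height_px *
        spec$pixel_size_um^2 / 1e6,
      stringsAsFactors = FALSE)
    for (m in spec$marker_panel) {
      v <- numeric(n)
      for (pop in c("microglia", "tam")) {
        idx <- which(label == pop)
        if (length(idx))
          v[idx] <- draw_intensity(spec$intensity_model[[pop]][[m]],
                                   length(idx))
      }
      tab[[paste0("mean_", m)]] <- v
    }
    tab$true_label <- label
    as_cell_table(tab)
  })
}

#' Tissue-type presets for the image simulator
#'
#' Encodes the qualitative composition of each tissue group: epilepsy
#' tissue is almost solely microglia with near-background CD14/CD163
#' (any TAM-like cells are perivascular, along a vessel path); meningiomas
#' and low-grade tumors are TAM-dominated; grade IV tumors hold a mixture.
#'
#' @param tissue_type one of the four tissue groups.
#' @param n_cells total cell count for the preset scene.
#' @param ... overrides forwarded to [image_sim_spec()].
#' @return An [image_sim_spec()].
#' @export
image_sim_preset <- function(tissue_type = c("epilepsy", "meningioma",
                                             "low_grade", "grade_iv"),
                             n_cells = 150L, ...) {
  tissue_type <- match.arg(tissue_type)
  dots <- list(...)
  panel <- dots$marker_panel %||% c("Iba1", "P2RY12", "CD163")
  model <- default_intensity_model(panel)
  hl <- highlow_marker(panel)
  frac_mg <- switch(tissue_type,
                    epilepsy = 0.97, meningioma = 0.05,
                    low_grade = 0.10, grade_iv = 0.35)
  args <- list(n_microglia = round(frac_mg * n_cells),
               n_tam = n_cells - round(frac_mg * n_cells),
               marker_panel = panel)
  if (tissue_type == "epilepsy" && !is.null(hl)) {
    # near-background CD14/CD163 in control tissue, both populations;
    # residual TAM-like cells sit on vessels
    model$microglia[[hl]] <- list(meanlog = 1.5, sdlog = 0.4,
                                  dist = "lognormal")
    model$tam[[hl]] <- list(meanlog = 2.5, sdlog = 0.4, dist = "lognormal")
    args$vessel_fraction <- 1
  }
  args$intensity_model <- dots$intensity_model %||% model
  dots$intensity_model <- NULL
  do.call(image_sim_spec, utils::modifyList(args, dots))
}
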