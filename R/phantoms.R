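# Synthetic co-registered multi-modal lesion phantoms.
#
# The generator emulates the kind of data the pipeline was designed for --
# one physical lesion imaged by several co-registered MRI modalities on
# deliberately different grids (coarse-slice T2 vs fine DCE) -- with
# class-dependent morphology (smooth vs spiculated) and class-dependent
# intensity/enhancement profiles. It makes no claim of radiological
# realism: its job is to give every pipeline stage learnable, controllable
# structure. All randomness is a deterministic function of the seed.

.default_grids <- list(
  T2WI       = list(dim = c(32L, 32L, 16L), spacing = c(2, 2, 4)),
  nonfs_T1WI = list(dim = c(32L, 32L, 32L), spacing = c(2, 2, 2)),
  d1         = list(dim = c(32L, 32L, 32L), spacing = c(2, 2, 2)),
  d2         = list(dim = c(32L, 32L, 32L), spacing = c(2, 2, 2)),
  d4         = list(dim = c(32L, 32L, 32L), spacing = c(2, 2, 2)),
  d6         = list(dim = c(32L, 32L, 32L), spacing = c(2, 2, 2))
)

#' Specification of one synthetic lesion phantom
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param base_radius Lesion radius in reference-grid voxels (2 mm voxels).
#' @param spiculation `c(spike_count, spike_length_mm)`; malignant masses
#'   grow radial spikes ("burrs"), benign masses none.
#' @param smoothness Gaussian blur sigma (mm) applied to the rendered
#'   intensity image (benign masses are smoother-edged). A named list in
#'   `smoothness_by` overrides it per modality, letting one modality carry
#'   an edge-sharpness cue the others lack.
#' @param smoothness_by Optional named list: modality -> blur sigma (mm).
#' @param modality_profiles Named list: modality -> `c(lesion_contrast,
#'   background_mean, noise_sd)` in arbitrary intensity units (lesion mean =
#'   background + contrast).
#' @param grids Named list: modality -> `list(dim, spacing)`.
#' @param center Physical lesion center (mm).
#' @param radii_scale Per-axis anisotropy factors of the ellipsoid.
#' @param spike_thickness Spike half-thickness (mm).
#' @param support_scale Scale of the main support ellipsoid (normalized
#'   coordinates; lobes and spikes add structure beyond it).
#' @param lobes `c(count, offset, radius)` in normalized ellipsoid
#'   coordinates: surface lobules ("lobes" of a lobulated margin), each a
#'   ball of the given radius centered `offset` along a random direction;
#'   `NULL` for none.
#' @param core_scale Scale of the smooth core rendered by
#'   `core_modalities`.
#' @param core_offset Physical offset (mm) of the enhancing core relative
#'   to the lesion center; a class-independent random offset prevents the
#'   crop centering from leaking shape class (lobulated supports shift the
#'   bounding cube slightly off the core).
#' @param core_modalities Modalities rendered from the smooth ellipsoid core
#'   only (no spikes, radius scaled by `core_scale`); `NULL` renders the
#'   full shape everywhere. Used by the complementary-information scenario,
#'   where the enhancing component must carry no shape information.
#' @param reference_modality Grid the ground-truth mask is drawn on.
#' @param case_id Identifier.
#' @param seed Integer; fixes the phantom bit-exactly.
#' @return A `PhantomSpec`.
#' @export
phantom_spec <- function(class_label = c("benign", "malignant"),
                         base_radius = 6, spiculation = c(0L, 0),
                         smoothness = 1.6, smoothness_by = NULL,
                         modality_profiles = NULL,
                         grids = .default_grids[c("T2WI", "nonfs_T1WI",
                                                  "d1", "d2")],
                         center = c(31, 31, 31), radii_scale = c(1, 1, 1),
                         spike_thickness = 1.5, support_scale = 1,
                         lobes = NULL,
                         core_scale = 1, core_offset = c(0, 0, 0),
                         core_modalities = NULL,
                         reference_modality = "d2", case_id = "case",
                         seed = 1L) {
  class_label <- match.arg(class_label)
  if (is.null(modality_profiles))
    modality_profiles <- setNames(
      lapply(names(grids), function(m) c(30, 50, 10)), names(grids))
  spec <- structure(list(class_label = class_label,
                         base_radius = base_radius,
                         spiculation = spiculation,
                         smoothness = smoothness,
                         smoothness_by = smoothness_by,
                         modality_profiles = modality_profiles,
                         grids = grids, center = center,
                         radii_scale = radii_scale,
                         spike_thickness = spike_thickness,
                         support_scale = support_scale,
                         lobes = lobes,
                         core_scale = core_scale,
                         core_offset = core_offset,
                         core_modalities = core_modalities,
                         reference_modality = reference_modality,
                         case_id = case_id, seed = as.integer(seed)),
                    class = "PhantomSpec")
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  for (m in names(spec$grids)) {
    g <- spec$grids[[m]]
    extent <- (g$dim - 1) * g$spacing
    reach <- 2 * spec$base_radius * max(spec$radii_scale) +
      spec$spiculation[2]
    if (any(spec$center - reach < 2 * g$spacing) ||
        any(spec$center + reach > extent - 2 * g$spacing))
      stop("lesion exceeds grid (margin < 2 voxels) in modality ", m)
    if (spec$modality_profiles[[m]][3] < 0) stop("noise sd must be >= 0")
  }
  invisible(spec)
}

# separable Gaussian blur, sigma in voxels per axis, edge replication
.gauss_smooth <- function(x, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2)); w <- w / sum(w)
    n <- dim(x)[axis]
    acc <- 0
    for (t in seq(-r, r)) {
      i <- pmin(pmax(seq_len(n) + t, 1L), n)
      shifted <- switch(axis, x[i, , , drop = FALSE],
                        x[, i, , drop = FALSE], x[, , i, drop = FALSE])
      acc <- acc + w[t + r + 1] * shifted
    }
    x <- acc
  }
  x
}

# analytic lesion indicator at physical points (matrix n x 3);
# `support_scale` shrinks the main ellipsoid in normalized coordinates,
# `lobes` (list: dirs, offset, radius, all in normalized coordinates) add
# surface lobulation, `spikes` add thin radial burrs in physical space
.lesion_indicator <- function(pts, center, radii, spikes, thickness,
                              support_scale = 1, lobes = NULL) {
  q <- sweep(pts, 2, center)
  qn <- sweep(q, 2, radii, "/")
  inside <- rowSums(qn^2) <= support_scale^2
  if (!is.null(lobes) && nrow(lobes$dirs) > 0) {
    for (k in seq_len(nrow(lobes$dirs))) {
      ctr <- lobes$offset * lobes$dirs[k, ]
      inside <- inside | rowSums(sweep(qn, 2, ctr)^2) <= lobes$radius^2
    }
  }
  if (!is.null(spikes) && nrow(spikes) > 0) {
    r_mean <- mean(radii) * support_scale
    len <- attr(spikes, "length")
    for (k in seq_len(nrow(spikes))) {
      u <- spikes[k, ]
      t <- q %*% u
      perp2 <- rowSums(q^2) - t^2
      inside <- inside | (t > 0 & t <= r_mean + len &
                            perp2 <= thickness^2)
    }
  }
  inside
}

#' Render one multi-modal phantom case
#'
#' The physical lesion -- an ellipsoid, plus radial spikes for malignant
#' specs -- is evaluated analytically at each modality's voxel centers
#' (grids share the physical origin), scaled to that modality's intensity
#' profile, Gaussian-blurred by the spec's smoothness, and corrupted with
#' additive Gaussian noise. The ground-truth mask is the unblurred
#' indicator on the reference grid.
#'
#' @param spec A `PhantomSpec`.
#' @return A `PhantomCase`: list with `volumes` (named `ModalityVolume`
#'   list), `mask` (`SegmentationMask`), `label`, `spec`.
#' @export
render_lesion <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  .validate_phantom_spec(spec)
  .with_seed(spec$seed, function() {
    radii <- spec$base_radius * 2 * spec$radii_scale   # reference vox -> mm
    n_spk <- spec$spiculation[1]
    spikes <- NULL
    if (n_spk > 0 && spec$spiculation[2] > 0) {
      v <- matrix(rnorm(3 * n_spk), n_spk, 3)
      spikes <- v / sqrt(rowSums(v^2))
      attr(spikes, "length") <- spec$spiculation[2]
    }
    lobes <- NULL
    if (!is.null(spec$lobes) && spec$lobes[1] > 0) {
      v <- matrix(rnorm(3 * spec$lobes[1]), spec$lobes[1], 3)
      lobes <- list(dirs = v / sqrt(rowSums(v^2)),
                    offset = spec$lobes[2], radius = spec$lobes[3])
    }
    shape_on <- function(grid, as_core) {
      axes <- lapply(1:3, function(a) (seq_len(grid$dim[a]) - 1) *
                       grid$spacing[a])
      pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
      ind <- if (as_core)
        .lesion_indicator(pts, spec$center + spec$core_offset,
                          radii * spec$core_scale,
                          NULL, spec$spike_thickness)
      else
        .lesion_indicator(pts, spec$center, radii,
                          spikes, spec$spike_thickness,
                          support_scale = spec$support_scale,
                          lobes = lobes)
      array(as.numeric(ind), dim = grid$dim)
    }
    volumes <- list()
    for (m in names(spec$grids)) {
      g <- spec$grids[[m]]
      as_core <- !is.null(spec$core_modalities) &&
        m %in% spec$core_modalities
      ind <- shape_on(g, as_core)
      prof <- spec$modality_profiles[[m]]
      img <- prof[2] + prof[1] * ind
      smo <- spec$smoothness_by[[m]] %||% spec$smoothness
      img <- .gauss_smooth(img, smo / g$spacing)
      if (prof[3] > 0)
        img <- img + array(rnorm(length(img), sd = prof[3]), dim = g$dim)
      volumes[[m]] <- modality_volume(img, g$spacing, m, spec$case_id)
    }
    ref <- spec$reference_modality
    ref_is_core <- !is.null(spec$core_modalities) &&
      ref %in% spec$core_modalities
    mask_arr <- shape_on(spec$grids[[ref]], ref_is_core)
    mask <- segmentation_mask(mask_arr, case_id = spec$case_id,
                              reference_modality = ref,
                              spacing = spec$grids[[ref]]$spacing)
    structure(list(volumes = volumes, mask = mask,
                   label = spec$class_label, spec = spec),
              class = "PhantomCase")
  })
}

# class-conditional spec draws for one scenario; all randomness must happen
# inside the caller's seeded block
.draw_spec <- function(label, difficulty, scenario, modalities,
                       reference_modality, case_id, render_seed) {
  sigma <- 5
  mal <- label == "malignant"
  jit <- function() rnorm(1, sd = sigma)
  b <- runif(1, 4.5, 6)   # base radius, reference voxels (2 mm)
  if (scenario == "standard") {
    prof <- list(
      T2WI = c(25 + (if (mal) 0.5 * difficulty * sigma else 0) + jit(),
               50, sigma),
      nonfs_T1WI = c(20 + (if (mal) 0.3 * difficulty * sigma else 0) + jit(),
                     50, sigma),
      d1 = c(15 + jit(), 50, sigma),
      d2 = c(25 + (if (mal) difficulty * sigma else 0) + jit(), 50, sigma),
      d4 = c(27 + (if (mal) 0.8 * difficulty * sigma else 0) + jit(),
             50, sigma),
      d6 = c(27 + (if (mal) 0.6 * difficulty * sigma else 0) + jit(),
             50, sigma))
    spic <- if (mal) c(12L, 1.2 * difficulty) else c(0L, 0)
    lob <- NULL
    smooth <- if (mal) max(0.5, 1.6 - 0.25 * difficulty) else 1.6
    support <- 1; core_scale <- 1; core <- NULL; thick <- 1.5
    core_off <- c(0, 0, 0)
  } else {
    # complementary: shape signal only in T2WI, intensity only in d2.
    # Both classes share one overall extent distribution (malignant =
    # shrunken ellipsoid + spikes reaching the benign radius) and every
    # non-T2 modality renders an identical-size smooth core, so neither
    # the bounding-cube size nor the enhancing channel leaks shape.
    prof <- list(
      T2WI = c(30 + jit(), 50, sigma),
      nonfs_T1WI = c(20 + jit(), 50, sigma),
      d1 = c(12 + jit(), 50, sigma),
      d2 = c(22 + (if (mal) difficulty * sigma else 0) + jit(), 50, sigma),
      d4 = c(22 + jit(), 50, sigma),
      d6 = c(22 + jit(), 50, sigma))
    # morphology cue: a lobulated margin, built in normalized ellipsoid
    # coordinates so lesion extent stays class-neutral (a smooth benign
    # envelope at scale 0.86 versus a 0.78 core carrying eight surface
    # lobules reaching ~0.9); spikes are not used here
    spic <- c(0L, 0)
    lob <- if (mal) c(8, 0.62, 0.28) else NULL
    smooth <- 1.2
    # edge-sharpness cue with within-class spread: class-mean blur gap
    # 0.45 mm over sd 0.4 bounds the cue's Bayes AUC near 0.79 regardless
    # of model capacity (a deterministic per-class blur is perfectly
    # separable and saturates any margin)
    smooth_by <- list(T2WI = min(3, max(0.6,
      (if (mal) 1.35 else 1.8) + rnorm(1, sd = 0.4))))
    support <- if (mal) 0.78 else 0.82
    core_scale <- 0.7
    core_off <- runif(3, -1.5, 1.5)
    core <- setdiff(modalities, "T2WI")
    thick <- 1.2
  }
  phantom_spec(class_label = label,
               base_radius = b,
               spiculation = spic, smoothness = smooth,
               smoothness_by = if (scenario == "complementary") smooth_by,
               modality_profiles = prof[modalities],
               grids = .default_grids[modalities],
               center = 31 + runif(3, -2, 2),
               radii_scale = runif(3, 0.85, 1.1),
               support_scale = support, lobes = lob,
               core_scale = core_scale, core_offset = core_off,
               spike_thickness = thick,
               core_modalities = core,
               reference_modality = reference_modality,
               case_id = case_id, seed = render_seed)
}

#' Generate a synthetic phantom cohort
#'
#' Draws class-conditional phantom specs whose class-mean intensity gap in
#' the informative channel equals `difficulty` times the noise sigma (so
#' the Bayes-optimal AUC of the intensity feature alone is
#' `pnorm(difficulty / sqrt(2))`), renders all cases, and (optionally)
#' writes NIfTI volumes, masks and a manifest CSV laid out exactly like
#' real-data input.
#'
#' @param n Number of lesions.
#' @param prevalence Fraction malignant, in (0, 1); class counts are the
#'   rounded split (`n = 207`, prevalence `106/207` gives 106 / 101).
#' @param difficulty Separation scale (class-mean gap in noise-sigma units);
#'   0 makes the class-conditional distributions identical.
#' @param seed Integer seed; fixes the cohort bit-exactly.
#' @param dir Output directory; when given, volumes/masks/manifest are
#'   written there.
#' @param modalities Modalities to render (fusion order).
#' @param scenario `"standard"` (morphology + intensity both scale with
#'   difficulty) or `"complementary"` (morphology signal only in T2WI,
#'   enhancement signal only in d2).
#' @param keep_cases Keep rendered cases in memory on the return value.
#' @param render Render voxel data at all; `FALSE` returns specs only
#'   (cheap parameter-distribution checks).
#' @return List with `manifest` (a `CohortManifest`; file columns filled
#'   when `dir` is given), `cases` (list of `PhantomCase` or `NULL`),
#'   `specs`.
#' @export
generate_cohort <- function(n, prevalence = 0.5, difficulty = 3, seed = 1L,
                            dir = NULL,
                            modalities = c("T2WI", "nonfs_T1WI", "d1", "d2"),
                            scenario = c("standard", "complementary"),
                            keep_cases = TRUE, render = TRUE) {
  scenario <- match.arg(scenario)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1")
  n_mal <- round(n * prevalence)
  n_ben <- n - n_mal
  if (n_mal < 1 || n_ben < 1) stop("n too small to hold both classes")
  stopifnot(all(modalities %in% MODALITY_TAGS))
  reference <- if (scenario == "complementary") "T2WI" else
    if ("d2" %in% modalities) "d2" else modalities[1]
  labels <- c(rep("benign", n_ben), rep("malignant", n_mal))
  specs <- .with_seed(seed, function() {
    ord <- sample(n)
    labs <- labels[ord]
    case_seeds <- sample.int(2^30, n)
    lapply(seq_len(n), function(i)
      .draw_spec(labs[i], difficulty, scenario, modalities, reference,
                 case_id = sprintf("case_%03d", i),
                 render_seed = case_seeds[i]))
  })
  if (!render && !is.null(dir))
    stop("writing a cohort to disk requires render = TRUE")
  cases <- if (render) lapply(specs, render_lesion)
  rows <- data.frame(case_id = vapply(specs, `[[`, "", "case_id"),
                     label = vapply(specs, `[[`, "", "class_label"),
                     stringsAsFactors = FALSE)
  for (col in c("t2wi", "nonfs_t1wi", "d1", "d2", "d4", "d6", "mask"))
    rows[[col]] <- NA_character_
  rows$reference_modality <- reference
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      case <- cases[[i]]
      for (m in modalities) {
        f <- file.path(dir, sprintf("%s_%s.nii", rows$case_id[i], m))
        write_nifti(case$volumes[[m]]$voxels, f,
                    spacing = case$volumes[[m]]$spacing)
        rows[[.manifest_col_for(m)]][i] <- f
      }
      fm <- file.path(dir, sprintf("%s_mask.nii", rows$case_id[i]))
      write_nifti(case$mask$voxels, fm, spacing = case$mask$spacing)
      rows$mask[i] <- fm
    }
  }
  manifest <- cohort_manifest(rows)
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, cases = if (keep_cases && render) cases,
       specs = specs)
}

#' Preprocess a phantom cohort into model input tensors
#'
#' Convenience binding of [preprocess_case()] over an in-memory cohort.
#'
#' @param cohort Return value of [generate_cohort()] (with `keep_cases`).
#' @param target_side Cube side after resampling.
#' @param include_sobel Append Sobel channels.
#' @param modalities Subset / order of modalities to fuse; default = all
#'   rendered.
#' @return List of `ModelInputTensor`s.
#' @export
cohort_tensors <- function(cohort, target_side = 64L, include_sobel = TRUE,
                           modalities = NULL) {
  stopifnot(!is.null(cohort$cases))
  lapply(cohort$cases, function(case) {
    vols <- case$volumes
    if (!is.null(modalities)) vols <- vols[modalities]
    preprocess_case(vols, case$mask, target_side = target_side,
                    include_sobel = include_sobel,
                    label = case$label)$tensor
  })
}
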