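test_that("phantoms are bit-deterministic and grid-consistent", {
  spec <- phantom_spec(class_label = "malignant", spiculation = c(8, 4),
                      seed = 31)
  c1 <- render_lesion(spec)
  c2 <- render_lesion(spec)
  for (m in names(c1$volumes))
    expect_identical(c1$volumes[[m]]$voxels, c2$volumes[[m]]$voxels)
  expect_identical(c1$mask$voxels, c2$mask$voxels)

  # modality grids deliberately differ (coarse-slice T2 vs fine DCE)
  expect_equal(dim(c1$volumes$T2WI$voxels), c(32, 32, 16))
  expect_equal(c1$volumes$T2WI$spacing, c(2, 2, 4))
  expect_equal(dim(c1$volumes$d2$voxels), c(32, 32, 32))
  # the mask lives on the reference grid and is non-empty
  expect_equal(dim(c1$mask$voxels),
               dim(c1$volumes[[c1$mask$reference_modality]]$voxels))
  expect_gt(sum(c1$mask$voxels), 0)
})

test_that("a spike-free noiseless phantom renders the exact ellipsoid", {
  prof <- list(d2 = c(40, 50, 0))
  spec <- phantom_spec(class_label = "benign", base_radius = 5,
                       spiculation = c(0, 0), smoothness = 0,
                       modality_profiles = prof,
                       grids = .default_grids["d2"],
                       center = c(30, 32, 31), radii_scale = c(1, 0.9, 1.05),
                       seed = 33)
  case <- render_lesion(spec)
  v <- case$volumes$d2$voxels
  # analytic oracle: evaluate the ellipsoid inequality at voxel centers
  g <- expand.grid(x = (0:31) * 2, y = (0:31) * 2, z = (0:31) * 2)
  radii <- 5 * 2 * c(1, 0.9, 1.05)
  inside <- ((g$x - 30) / radii[1])^2 + ((g$y - 32) / radii[2])^2 +
    ((g$z - 31) / radii[3])^2 <= 1
  expect_identical(v == 90, array(inside, c(32, 32, 32)))
  expect_identical(case$mask$voxels, array(as.numeric(inside), c(32, 32, 32)))
})

test_that("spiculation raises the surface-area-to-volume ratio", {
  base <- phantom_spec(class_label = "benign", base_radius = 5.5,
                       spiculation = c(0, 0), seed = 35)
  spiky <- phantom_spec(class_label = "malignant", base_radius = 5.5,
                        spiculation = c(12, 5), seed = 35)
  sv_base <- mask_surface_volume(render_lesion(base)$mask$voxels)
  sv_spiky <- mask_surface_volume(render_lesion(spiky)$mask$voxels)
  expect_gt(sv_spiky$area / sv_spiky$volume,
            sv_base$area / sv_base$volume)
})

test_that("cohort generation: class counts, determinism, validation", {
  # the study's prevalence: 207 lesions at 106/207 -> 106 / 101
  coh <- generate_cohort(207, 106 / 207, difficulty = 1, seed = 37,
                         modalities = "d2", keep_cases = FALSE,
                         render = FALSE)
  expect_equal(sum(coh$manifest$label == "malignant"), 106)
  expect_equal(sum(coh$manifest$label == "benign"), 101)
  expect_equal(manifest_counts(coh$manifest)$retained, 207)

  expect_error(generate_cohort(10, 1.0), "prevalence")
  expect_error(generate_cohort(10, 0), "prevalence")
  expect_error(generate_cohort(1, 0.5), "too small")

  c1 <- generate_cohort(4, 0.5, seed = 39, modalities = c("d1", "d2"))
  c2 <- generate_cohort(4, 0.5, seed = 39, modalities = c("d1", "d2"))
  expect_identical(c1$cases[[1]]$volumes$d2$voxels,
                   c2$cases[[1]]$volumes$d2$voxels)
})

test_that("difficulty 0 removes every class-conditional difference", {
  coh <- generate_cohort(40, 0.5, difficulty = 0, seed = 41,
                         keep_cases = FALSE, render = FALSE)
  by_class <- split(coh$specs,
                    vapply(coh$specs, `[[`, "", "class_label"))
  # malignant specs grow no spikes and share the benign smoothness
  expect_true(all(vapply(by_class$malignant,
                         function(s) s$spiculation[2] == 0, TRUE)))
  expect_equal(unique(vapply(by_class$malignant, `[[`, 0, "smoothness")),
               unique(vapply(by_class$benign, `[[`, 0, "smoothness")))
  # intensity contrasts share class-conditional means (gap scales with
  # difficulty, which is 0 here): compare d2 contrast means
  d2c <- function(ss) vapply(ss, function(s) s$modality_profiles$d2[1], 0)
  expect_lt(abs(mean(d2c(by_class$malignant)) - mean(d2c(by_class$benign))),
            3 * 5 / sqrt(10))
})

test_that("the difficulty scale sets the stated Bayes separation", {
  # class-mean gap in the enhancing channel = difficulty x noise sigma,
  # so the closed-form Bayes AUC of that feature is pnorm(d / sqrt(2))
  coh <- generate_cohort(300, 0.5, difficulty = 5, seed = 43,
                         modalities = c("d1", "d2"), keep_cases = FALSE,
                         render = FALSE)
  specs <- coh$specs
  lab <- vapply(specs, `[[`, "", "class_label")
  d2c <- vapply(specs, function(s) s$modality_profiles$d2[1], 0)
  gap <- mean(d2c[lab == "malignant"]) - mean(d2c[lab == "benign"])
  expect_equal(gap, 5 * 5, tolerance = 0.15)   # noise sigma is 5
  expect_gt(pnorm(5 / sqrt(2)), 0.99)
})

test_that("written cohorts are indistinguishable from real-data input", {
  dir <- file.path(tempdir(), "phantom_cohort")
  coh <- generate_cohort(4, 0.5, difficulty = 3, seed = 45, dir = dir,
                         modalities = c("T2WI", "d2"), keep_cases = TRUE)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  for (i in 1:4) {
    vol <- load_volume(man$d2[i], "d2", man$case_id[i])
    expect_identical(vol$voxels, coh$cases[[i]]$volumes$d2$voxels)
    ref <- load_volume(man[[if (man$reference_modality[i] == "T2WI")
      "t2wi" else "d2"]][i], man$reference_modality[i], man$case_id[i])
    msk <- load_mask(man$mask[i], ref)
    expect_identical(msk$voxels != 0, coh$cases[[i]]$mask$voxels != 0)
  }
  unlink(dir, recursive = TRUE)
})
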