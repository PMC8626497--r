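test_that("engulfed and lysosomal counts follow deterministic rounding", {
  p <- engulfment_sim_params(n_puncta = 200L, engulfed_fraction = 0.3,
                             seed = 7L)
  sim <- generate_engulfment_stack(p)
  # oracle: direct count of the truth flags emitted by the generator
  expect_identical(sum(sim$truth$puncta$is_engulfed), 60L)
  expect_identical(sim$truth$planted_scores$n_engulfed, 60L)
  expect_identical(sum(sim$truth$puncta$is_lysosomal),
                   as.integer(round(60 * 0.6)))
})

test_that("zero engulfment plants nothing inside glia", {
  p <- small_engulfment_params(engulfed_fraction = 0)
  sim <- generate_engulfment_stack(p)
  expect_identical(sim$truth$planted_scores$n_engulfed, 0L)
  expect_equal(sim$truth$planted_scores$inside_volume_um3, 0)
  expect_equal(sim$truth$planted_scores$lysosomal_volume_um3, 0)
})

test_that("full lysosomal fraction quenches GFP for every engulfed punctum", {
  p <- engulfment_sim_params(field_shape_voxels = c(16L, 64L, 64L),
                             voxel_size_um = c(1, 0.5, 0.5),
                             n_glia = 2L, glia_radius_um = 6,
                             n_puncta = 20L, engulfed_fraction = 0.4,
                             lysosomal_fraction_of_engulfed = 1,
                             snr = Inf, psf_sigma_um = 0, seed = 3L)
  sim <- generate_engulfment_stack(p)
  tr <- sim$truth
  expect_true(all(tr$puncta$is_lysosomal[tr$puncta$is_engulfed]))
  # pre-noise GFP emission is exactly zero on every engulfed punctum voxel
  gfp <- get_channel(sim$stack, "GFP")
  eng_ids <- tr$puncta$id[tr$puncta$is_engulfed]
  expect_equal(max(gfp[tr$puncta_labels %in% eng_ids]), 0)
})

test_that("ground truth respects the containment invariants", {
  sim <- generate_engulfment_stack(small_engulfment_params(seed = 5L))
  tr <- sim$truth
  # every lysosome voxel lies inside some glial label
  expect_true(all(tr$glia_labels[tr$lysosome_mask] > 0L))
  # every lysosomal punctum is engulfed
  expect_true(all(tr$puncta$is_engulfed[tr$puncta$is_lysosomal]))
  # engulfed centres carry the label of their host glia
  eng <- tr$puncta[tr$puncta$is_engulfed, ]
  v <- tr$voxel_size_um
  idx <- cbind(ceiling(eng$z_um / v[1]), ceiling(eng$y_um / v[2]),
               ceiling(eng$x_um / v[3]))
  expect_equal(tr$glia_labels[idx], eng$glia_label)
})

test_that("planted scores equal a brute-force recomputation from the masks", {
  sim <- generate_engulfment_stack(small_engulfment_params(seed = 9L))
  tr <- sim$truth
  vv <- prod(tr$voxel_size_um)
  fg <- tr$puncta_labels > 0L
  inside <- sum(fg & tr$glia_labels > 0L) * vv
  total <- sum(fg) * vv
  lys_vol <- sum(tr$puncta_labels %in% tr$puncta$id[tr$puncta$is_lysosomal]) * vv
  ps <- tr$planted_scores
  expect_equal(ps$inside_volume_um3, inside)
  expect_equal(ps$total_puncta_volume_um3, total)
  expect_equal(ps$lysosomal_volume_um3, lys_vol)
  expect_equal(ps$pct_inside, 100 * inside / total)
})

test_that("generation is bit-identical for identical params and seed", {
  p <- small_engulfment_params(seed = 21L)
  a <- generate_engulfment_stack(p)
  b <- generate_engulfment_stack(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$puncta, b$truth$puncta)
  s <- spine_sim_params(n_spines = 50L, seed = 8L)
  expect_identical(generate_spine_set(s), generate_spine_set(s))
  cp <- counts_sim_params(n_cells = 100L, n_genes = 200L, seed = 4L)
  expect_identical(generate_counts_table(cp), generate_counts_table(cp))
})

test_that("generator rejects infeasible or invalid geometry", {
  expect_error(engulfment_sim_params(field_shape_voxels = c(4L, 8L, 8L),
                                     glia_radius_um = 10),
               "too small")
  expect_error(engulfment_sim_params(engulfed_fraction = 1.2), "0, 1")
  expect_error(engulfment_sim_params(snr = 0), "snr")
  # feasible params but far too many puncta for the free volume
  p <- engulfment_sim_params(field_shape_voxels = c(12L, 32L, 32L),
                             voxel_size_um = c(1, 0.5, 0.5),
                             n_glia = 1L, glia_radius_um = 5,
                             n_puncta = 2000L, engulfed_fraction = 0,
                             seed = 1L)
  expect_error(generate_engulfment_stack(p), "placement error")
})

test_that("spine generator honours planted class structure", {
  # all filopodia: lengths above 2 um
  p <- spine_sim_params(n_spines = 10L,
                        class_proportions = c(1, 0, 0, 0, 0, 0), seed = 2L)
  s <- generate_spine_set(p)
  expect_true(all(s$length_um > 2))
  # all branched: two or more heads
  p <- spine_sim_params(n_spines = 5L,
                        class_proportions = c(0, 0, 0, 0, 0, 1), seed = 2L)
  s <- generate_spine_set(p)
  expect_true(all(s$heads >= 2))
  expect_identical(nrow(generate_spine_set(
    spine_sim_params(n_spines = 0L, seed = 1L))), 0L)
  expect_error(spine_sim_params(class_proportions = rep(0.2, 6)), "summing")
})

test_that("section-series generator matches closed-form volumes", {
  cone <- generate_section_series("cone", h = 1, base_area = 4, height = 2)
  expect_equal(cone$series$areas, c(4, 1, 0))
  expect_equal(cone$analytic_volume, 8 / 3)
  cyl <- generate_section_series("cylinder", h = 0.3, n_sections = 6L,
                                 base_area = 2.5)
  expect_equal(cyl$analytic_volume, 2.5 * 0.3 * 5)
  ell <- generate_section_series("ellipsoid", h = 0.1,
                                 semi_axes = c(1, 0.8, 0.6))
  expect_equal(ell$analytic_volume, 4 / 3 * pi * 1 * 0.8 * 0.6)
  expect_error(generate_section_series("cone", h = 3, base_area = 4,
                                       height = 2), "span")
  expect_error(generate_section_series("cylinder", h = 1, n_sections = 1L),
               "2 sections")
})

test_that("counts generator plants QC pathologies and DEGs exactly", {
  p <- counts_sim_params(n_cells = 500L, n_genes = 2000L,
                         outlier_fraction = 0.04, high_mito_fraction = 0.05,
                         n_true_degs = 50L, lfc_effect = 1.0, seed = 6L)
  g <- generate_counts_table(p)
  expect_identical(nrow(g$cell_qc), 500L)
  expect_identical(sum(g$truth$cells$planted_outlier != "none"), 20L)
  expect_identical(sum(g$truth$cells$planted_high_mito), 25L)
  expect_true(all(g$cell_qc$mito_fraction[g$truth$cells$planted_high_mito]
                  >= 0.30))
  # oracle: row-wise evaluation of the DEG rule on the emitted table
  pass <- g$deg_table$p_value < 0.05 & abs(g$deg_table$log2fc) > 0.58
  expect_identical(sum(pass), 50L)
  expect_identical(pass, g$truth$genes$is_deg)
  # clean params plant nothing
  p0 <- counts_sim_params(n_cells = 100L, n_genes = 100L,
                          outlier_fraction = 0, high_mito_fraction = 0,
                          n_true_degs = 0L, seed = 1L)
  g0 <- generate_counts_table(p0)
  expect_true(all(g0$truth$cells$planted_outlier == "none"))
  expect_false(any(g0$truth$cells$planted_high_mito))
  # empty tables
  ge <- generate_counts_table(counts_sim_params(n_cells = 0L, n_genes = 0L,
                                                n_true_degs = 0L, seed = 1L))
  expect_identical(nrow(ge$cell_qc), 0L)
  expect_identical(nrow(ge$deg_table), 0L)
})
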