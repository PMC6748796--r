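test_that("scene generation honors mixtures, determinism and infeasibility", {
  # all-tumor and all-default limits
  all_t <- generate_scene(scene_spec(class_mixture = c(tumor = 1),
                                     n_nonpredominant_regions = 0, seed = 1))
  expect_true(all(all_t$labels == 1L))
  all_d <- generate_scene(scene_spec(class_mixture = c(),
                                     n_nonpredominant_regions = 0, seed = 1))
  expect_true(all(all_d$labels == 2L))
  expect_error(scene_spec(class_mixture = c(tumor = 0.7, necrosis = 0.5)),
               "infeasible")

  # determinism
  s1 <- generate_scene(scene_spec(seed = 9))
  s2 <- generate_scene(scene_spec(seed = 9))
  expect_identical(s1$labels, s2$labels)

  # realized fractions near targets over seeds (pruning costs a little area)
  mix <- c(tumor = 0.5, necrosis = 0.2)
  fr <- sapply(1:10, function(s) {
    m <- generate_scene(scene_spec(class_mixture = mix,
                                   n_nonpredominant_regions = 0, seed = s))
    c(mean(m$labels == 1L), mean(m$labels == 4L))
  })
  expect_lt(abs(mean(fr[1, ]) - 0.5), 0.05)
  expect_lt(abs(mean(fr[2, ]) - 0.2), 0.05)
})

test_that("scene tracing yields polygons that re-render faithfully", {
  # single square region -> one polygon
  lab <- matrix(2L, 20, 20); lab[5:12, 5:12] <- 1L
  ann <- scene_to_truth_annotations(label_mask(lab, tax8))
  expect_length(ann$polygons, 1)
  expect_identical(ann$polygons[[1]]$class_name, "tumor")
  # empty non-default content -> empty set
  empty <- scene_to_truth_annotations(label_mask(matrix(2L, 8, 8), tax8))
  expect_length(empty$polygons, 0)
  # random scenes: >= 99% pixel agreement after re-render
  for (s in c(3, 14)) {
    sc <- generate_scene(scene_spec(seed = s))
    rr <- render_annotation_set(scene_to_truth_annotations(sc), tax8)
    expect_gt(mean(rr$labels == sc$labels), 0.99)
  }
})

test_that("annotator simulation: noise-free limit, misses, determinism", {
  sc <- generate_scene(scene_spec(seed = 5))
  truth <- scene_to_truth_annotations(sc)
  rendered_truth <- render_annotation_set(truth, tax8)

  clean <- annotator_error_model("SP", boundary_jitter_sigma = 0)
  sim <- simulate_annotator(truth, clean, tax8, seed = 2)
  expect_identical(render_annotation_set(sim, tax8)$labels,
                   rendered_truth$labels)

  # miss_prob 1 for non-predominant classes removes all their polygons
  misser <- annotator_error_model("NP", boundary_jitter_sigma = 0,
                                  miss_prob = c(predominant = 0,
                                                non_predominant = 1,
                                                challenging = 1))
  simm <- simulate_annotator(truth, misser, tax8, seed = 2)
  cls <- vapply(simm$polygons, `[[`, "", "class_name")
  expect_false(any(cls %in% tax8$class_name[tax8$tier != "predominant"]))

  # same seed, same output; different seeds differ under jitter
  noisy <- annotator_error_model("NP", boundary_jitter_sigma = 3)
  a <- simulate_annotator(truth, noisy, tax8, seed = 7)
  b <- simulate_annotator(truth, noisy, tax8, seed = 7)
  expect_identical(a$polygons, b$polygons)
  c_ <- simulate_annotator(truth, noisy, tax8, seed = 8)
  expect_false(identical(a$polygons, c_$polygons))
})

test_that("discordance to truth increases with boundary jitter", {
  sc <- generate_scene(scene_spec(seed = 6))
  truth <- scene_to_truth_annotations(sc)
  rt <- render_annotation_set(truth, tax8)
  sigmas <- c(0, 1, 2, 4, 8)
  mean_delta <- sapply(sigmas, function(sg) {
    mdl <- annotator_error_model("NP", boundary_jitter_sigma = sg)
    mean(sapply(1:6, function(s) {
      sim <- simulate_annotator(truth, mdl, tax8, seed = s)
      dice_discordance(rt, render_annotation_set(sim, tax8))
    }))
  })
  expect_true(all(diff(mean_delta) > 0))
})

test_that("simulated corrections move masks toward truth", {
  sc <- generate_scene(scene_spec(seed = 8))
  truth_ann <- scene_to_truth_annotations(sc)
  mdl <- annotator_error_model("NP", boundary_jitter_sigma = 4,
                               miss_prob = c(predominant = 0,
                                             non_predominant = 0.5,
                                             challenging = 0.5))
  noisy <- render_annotation_set(simulate_annotator(truth_ann, mdl, tax8,
                                                    seed = 3), tax8)
  # annotated == truth -> nothing to correct
  expect_length(simulate_correction(sc, sc), 0)
  # perfect reviewer restores truth exactly
  corr <- simulate_correction(noisy, sc, reviewer_miss = 0, seed = 4)
  expect_true(all(vapply(corr, `[[`, TRUE, "is_correction")))
  fixed <- apply_corrections(noisy, corr)
  expect_identical(fixed$labels, sc$labels)
  pre <- dice_discordance(noisy, sc)
  expect_gt(pre, 0)
  expect_equal(dice_discordance(fixed, sc), 0)
  # blind reviewer changes nothing
  none <- simulate_correction(noisy, sc, reviewer_miss = 1, seed = 4)
  expect_length(none, 0)
  # partial reviewer never increases discordance to truth
  some <- simulate_correction(noisy, sc, reviewer_miss = 0.5, seed = 4)
  part <- apply_corrections(noisy, some)
  expect_lte(dice_discordance(part, sc), pre)
})

test_that("cohort bundles implement the study design and are reproducible", {
  ros <- default_roster(n_sp = 1, n_jp = 1, n_np = 2)
  b <- simulate_cohort(roster = ros, n_eval_rois = 2, n_core_rois = 5,
                       seed = 13)
  # evaluation ROIs annotated by everyone: 4 participants x 2 ROIs
  ev <- b$assignment[grepl("^eval", b$assignment$roi_id), ]
  expect_identical(nrow(ev), 8L)
  # core ROIs partition: each covered exactly once
  core <- b$assignment[grepl("^core", b$assignment$roi_id), ]
  expect_identical(sort(core$roi_id), sort(b$rois$roi_id[b$rois$set_membership == "core"]))
  expect_false(anyDuplicated(core$roi_id) > 0)
  # corrections exist for core ROIs only
  expect_setequal(names(b$corrections), core$roi_id)
  # reproducibility
  b2 <- simulate_cohort(roster = ros, n_eval_rois = 2, n_core_rois = 5,
                        seed = 13)
  expect_identical(b$truth_masks[[1]]$labels, b2$truth_masks[[1]]$labels)
  expect_identical(b$annotations, b2$annotations)
})

test_that("a noise-free cohort has an identically zero discordance matrix", {
  clean <- annotator_error_model("SP", boundary_jitter_sigma = 0)
  ros <- data.frame(participant_id = c("a", "b", "c"),
                    tier = c("SP", "SP", "NP"),
                    model = I(replicate(3, clean, simplify = FALSE)),
                    stringsAsFactors = FALSE)
  b <- simulate_cohort(roster = ros, n_eval_rois = 2, seed = 17)
  dm <- pairwise_discordance(cohort_masks(b), participants = b$participants)
  expect_true(all(dm$values == 0))
})
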