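test_that("edge extraction recovers a rasterised circle radius", {
  # half-disc: every edge point sits 500 um from the sphere centre
  g <- gen_sessile_image(theta = 90, cap_base_radius = 500e-6,
                         calibration = 10e-6)
  img <- g$image
  cropped <- drop_image(img$pixels[seq_len(img$baseline_row - 1L), ,
                                   drop = FALSE], img$calibration)
  for (side in c("left", "right")) {
    e <- extract_drop_edge(cropped, side = side, min_size = 100L)
    centre_z <- 500e-6 # sphere centre sits one radius below the apex
    r <- sqrt(e$x^2 + (e$z - centre_z)^2)
    expect_lt(max(abs(r - 500e-6)), img$calibration) # within 1 px
  }
})

test_that("render/extract round trip reproduces a pendant profile", {
  g <- gen_pendant_image(gamma = 0.072, apex_radius = 1.5e-3, seed = 2)
  prof <- pendant_profile_from_image(g$image)
  truth <- make_pendant_truth(0.072, 1.5e-3)
  x_true <- approx(truth$z, truth$x, xout = prof$z, rule = 2)$y
  expect_lt(max(abs(prof$x - x_true)), g$image$calibration) # within 1 px
})

test_that("segmentation errors are raised for blank or multi-blob images", {
  blank <- drop_image(matrix(0.9, 100, 100), 1e-5)
  expect_error(extract_drop_edge(blank), class = "cf_segmentation_error")
  two <- matrix(0.9, 120, 120)
  two[10:40, 10:40] <- 0.1
  two[70:110, 70:110] <- 0.1
  expect_error(extract_drop_edge(drop_image(two, 1e-5), min_size = 400L),
               class = "cf_segmentation_error")
  speck <- matrix(0.9, 100, 100)
  speck[50:52, 50:52] <- 0.1
  expect_error(extract_drop_edge(drop_image(speck, 1e-5)),
               class = "cf_segmentation_error")
})

test_that("baseline detection finds the substrate row", {
  g <- gen_sessile_image(60, seed = 4)
  found <- detect_baseline(drop_image(g$image$pixels, g$image$calibration))
  expect_lte(abs(found - g$truth$truth$baseline_row), 1)
  # jittered edges do not move the full-width substrate edge
  gn <- gen_sessile_image(115, noise_sigma_px = 0.5, seed = 5)
  found_n <- detect_baseline(drop_image(gn$image$pixels, gn$image$calibration))
  expect_lte(abs(found_n - gn$truth$truth$baseline_row), 1)
})

test_that("baseline detection errors on featureless images and honours overrides", {
  flat <- drop_image(matrix(0.5, 100, 100), 1e-5)
  expect_error(detect_baseline(flat), class = "cf_baseline_not_found")
  withr <- drop_image(matrix(0.5, 100, 100), 1e-5, baseline_row = 77L)
  expect_identical(detect_baseline(withr), 77L)
})

test_that("contact angles are recovered within 2 degrees at two calibrations", {
  for (cal in c(4e-6, 8e-6)) {
    for (theta in c(30, 60, 90, 115, 150)) {
      g <- gen_sessile_image(theta, calibration = cal)
      m <- contact_angle_from_image(g$image)
      expect_lt(abs(m$theta_c - theta), 2)
    }
  }
})

test_that("half-disc symmetry gives 90 +/- 1 and |left - right| < 1", {
  for (theta in c(60, 90, 115)) {
    g <- gen_sessile_image(theta)
    m <- contact_angle_from_image(g$image)
    if (theta == 90) expect_lt(abs(m$theta_c - 90), 1)
    expect_lt(abs(m$left - m$right), 1)
  }
})

test_that("measured angle increases strictly with the true cap angle", {
  thetas <- c(30, 50, 70, 90, 110, 130, 150)
  measured <- vapply(thetas, function(th)
    contact_angle_from_image(gen_sessile_image(th)$image)$theta_c, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("no-contact and bad-window inputs are rejected", {
  g <- gen_sessile_image(60)
  img <- g$image
  cropped <- drop_image(img$pixels[seq_len(img$baseline_row - 1L), ,
                                   drop = FALSE], img$calibration)
  e <- extract_drop_edge(cropped, side = "left")
  # baseline far below the drop: the edge cannot reach it
  expect_error(measure_contact_angle(e, baseline_pos = max(e$z) * 3),
               class = "cf_no_contact")
  bp <- (img$baseline_row - 0.5 - attr(e, "apex_row")) * img$calibration
  expect_error(measure_contact_angle(e, bp, tangent_window = 3),
               class = "cf_invalid_parameter")
})
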