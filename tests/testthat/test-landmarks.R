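# silhouette width profile, the individual seed rules on phantoms, and full
# detection + segmentation on the rendered humanoid

test_that("width profile reports per-row intervals and totals", {
  mask <- matrix(FALSE, 200, 100)
  mask[50:150, 30:70] <- TRUE
  pr <- width_profile(mask_depth_map(mask))
  expect_equal(pr$width[100], 41)
  expect_equal(nrow(pr$intervals[[100]]), 1)
  expect_equal(pr$row_top, 50)
  expect_equal(pr$row_bottom, 150)

  bars <- matrix(FALSE, 120, 120)
  bars[10:110, 20:35] <- TRUE
  bars[10:110, 60:75] <- TRUE
  pr2 <- width_profile(mask_depth_map(bars))
  expect_equal(nrow(pr2$intervals[[50]]), 2)
  expect_equal(pr2$width[50], 32)
})

test_that("neck rule finds the narrowest row of an hourglass in the top 30%", {
  # widths: flat top, pinch at 20% of height, wide below
  half <- c(rep(30, 20), round(seq(30, 8, length.out = 20)),
            round(seq(8, 40, length.out = 30)), rep(40, 130))
  mask <- matrix(FALSE, length(half) + 2, 120)
  for (r in seq_along(half)) mask[r + 1, (60 - half[r]):(60 + half[r])] <- TRUE
  pr <- width_profile(mask_depth_map(mask))
  # brute-force oracle: narrowest row by construction is at index 41 (+1 pad)
  oracle <- which.min(c(rep(Inf, 20), half[-(1:20)])) + 1L
  neck <- anthromesh:::.find_neck_row(pr$smoothed, pr$row_top, pr$row_bottom)
  expect_lte(abs(neck - oracle), 1)
})

test_that("crotch rule scans upward from the toes to the leg merge row", {
  mask <- matrix(FALSE, 220, 150)
  mask[60:100, 30:120] <- TRUE    # pelvis block
  mask[100:200, 40:60] <- TRUE    # legs
  mask[100:200, 90:110] <- TRUE
  dm <- mask_depth_map(mask)
  pr <- width_profile(dm)
  res <- anthromesh:::.find_crotch(pr, dm$pixels > 0, mid_col = 75,
                                   from_row = 200)
  expect_equal(res$row, 100)      # brute force: lowest row covering col 75
})

test_that("armpit rule ignores single-pixel rasterization slivers", {
  mask <- matrix(FALSE, 160, 160)
  mask[20:150, 60:100] <- TRUE       # torso
  mask[40:150, 30:40] <- TRUE        # left arm, gap from row 40
  mask[30, 55] <- TRUE               # 1-px sliver must not fire the rule
  pr <- width_profile(mask_depth_map(mask))
  res <- anthromesh:::.find_armpit(pr, shoulder_row = 22, mid_col = 80, "left")
  expect_equal(res$row, 40)
  expect_equal(res$col, 60)          # torso-side gap boundary
})

test_that("the full detector returns 11 ordered landmarks on the humanoid", {
  fix <- default_humanoid()
  seeds <- fix$seeds
  expect_setequal(rownames(seeds$points), anthromesh:::SEED_POINT_NAMES)
  expect_equal(nrow(seeds$points), 11)
  p <- seeds$points
  expect_lt(p["head_top", "row"], p["neck", "row"])
  expect_lt(p["neck", "row"], p["left_shoulder", "row"])
  expect_lte(p["left_shoulder", "row"], p["left_armpit", "row"])
  expect_lt(p["left_armpit", "row"], p["crotch", "row"])
  expect_lt(p["crotch", "row"], p["left_toe", "row"])
  expect_lt(p["left_shoulder", "col"], p["right_shoulder", "col"])
  expect_lt(p["left_fingertip", "col"], p["right_fingertip", "col"])
  # determinism: identical maps give identical seeds
  seeds2 <- detect_seed_points(fix$dm)
  expect_identical(seeds2$points, seeds$points)
})

test_that("neck/armpit/crotch heights match the construction within 2% of stature", {
  fix <- default_humanoid()
  gt <- fix$body$truth$landmark_heights_mm
  H <- mesh_height(fix$body$mesh)
  wh <- fix$seeds$world_heights
  expect_lt(abs(wh[["neck"]] - gt[["neck"]]) / H, 0.02)
  expect_lt(abs(wh[["left_armpit"]] - gt[["armpit"]]) / H, 0.02)
  expect_lt(abs(wh[["right_armpit"]] - gt[["armpit"]]) / H, 0.02)
  expect_lt(abs(wh[["crotch"]] - gt[["crotch"]]) / H, 0.02)
})

test_that("mirroring the image mirrors every left/right landmark", {
  fix <- default_humanoid()
  dm <- fix$dm
  W <- dm$width
  mirrored <- depth_map(dm$pixels[, W:1], camera = dm$camera,
                        world_depth = dm$world_depth[, W:1],
                        cam_pos = dm$cam_pos)
  s1 <- fix$seeds$points
  s2 <- detect_seed_points(mirrored)$points
  swap <- c(left_shoulder = "right_shoulder", right_shoulder = "left_shoulder",
            left_armpit = "right_armpit", right_armpit = "left_armpit",
            left_fingertip = "right_fingertip",
            right_fingertip = "left_fingertip",
            left_toe = "right_toe", right_toe = "left_toe",
            head_top = "head_top", neck = "neck", crotch = "crotch")
  for (nm in names(swap)) {
    expect_equal(s2[nm, "row"], s1[swap[[nm]], "row"], info = nm)
    expect_lte(abs(s2[nm, "col"] - (W + 1L - s1[swap[[nm]], "col"])), 1,
               label = paste("col of", nm))
  }
})

test_that("segmentation partitions the silhouette into coherent parts", {
  fix <- default_humanoid()
  seg <- segment_body(fix$dm, fix$seeds)
  sil <- fix$dm$pixels > 0
  # exact partition: non-background labels cover the silhouette
  expect_true(all((seg$labels > 0) == sil))
  p <- fix$seeds$points
  lev <- function(nm) match(nm, seg$levels) - 1L
  expect_equal(seg$labels[p["left_fingertip", "row"], p["left_fingertip", "col"]],
               lev("left_arm"))
  expect_equal(seg$labels[p["left_toe", "row"], p["left_toe", "col"]],
               lev("left_leg"))
  expect_equal(seg$labels[p["head_top", "row"] + 1, p["head_top", "col"]],
               lev("head"))
  counts <- tabulate(seg$labels + 1L, nbins = 8)
  names(counts) <- seg$levels
  expect_equal(sum(counts[-1]), sum(sil))
  # bilateral symmetry of the build: paired parts agree within 5%
  expect_lt(abs(counts[["left_arm"]] - counts[["right_arm"]]) /
              counts[["left_arm"]], 0.05)
  expect_lt(abs(counts[["left_leg"]] - counts[["right_leg"]]) /
              counts[["left_leg"]], 0.05)
})

test_that("inconsistent seeds are rejected by segmentation", {
  fix <- default_humanoid()
  bad <- fix$seeds
  bad$points["neck", "row"] <- bad$points["head_top", "row"] - 1L
  expect_error(segment_body(fix$dm, bad), "inconsistent seeds")
})

test_that("detection errors name the failed landmark", {
  # arms fused to the torso: no armpit gap below the shoulder
  mask <- matrix(FALSE, 220, 160)
  mask[10:30, 60:100] <- TRUE     # head (wider than the neck)
  mask[30:40, 72:88] <- TRUE      # neck pinch
  mask[40:120, 40:120] <- TRUE    # torso + fused arms
  mask[120:210, 50:70] <- TRUE    # legs
  mask[120:210, 90:110] <- TRUE
  expect_error(detect_seed_points(mask_depth_map(mask)), "armpit")
})
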