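# perspective matrix, depth-map rendering, multi-view snapshots, back-projection

test_that("perspective matrix matches the closed-form symmetric frustum", {
  m90 <- perspective_matrix(camera_config(fovy = 90, aspect = 1))
  expect_equal(m90[2, 2], 1)                    # cot(45 deg) = 1
  expect_equal(m90[1, 1], 1)
  m60 <- perspective_matrix(camera_config(fovy = 60, aspect = 2))
  expect_equal(m60[2, 2], sqrt(3), tolerance = 1e-12)
  expect_equal(m60[1, 1], sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(m60[4, ], c(0, 0, -1, 0))
  # textbook oracle: glFrustum-style symmetric matrix from first principles
  cfg <- camera_config(fovy = 40, aspect = 1.5, near_n = 500, far_f = 4000)
  ct <- 1 / tan(20 * pi / 180)
  oracle <- matrix(0, 4, 4)
  oracle[1, 1] <- ct / 1.5
  oracle[2, 2] <- ct
  oracle[3, 3] <- -(4000 + 500) / 3500
  oracle[3, 4] <- -2 * 4000 * 500 / 3500
  oracle[4, 3] <- -1
  expect_equal(perspective_matrix(cfg), oracle, tolerance = 1e-12)
})

test_that("a point on the unit-distance projection plane maps to its NDC", {
  m <- perspective_matrix(camera_config(fovy = 90, aspect = 1))
  clip <- m %*% c(0.5, 0.5, -1, 1)
  ndc <- clip[1:2] / clip[4]
  expect_equal(ndc, c(0.5, 0.5))
})

test_that("a facing square rasterizes into the analytically predicted pixel block", {
  # 200 x 200 mm square, z = 0, y in [0, 200]; camera 1 m up, 3 m away
  v <- rbind(c(-100, 0, 0), c(100, 0, 0), c(100, 200, 0), c(-100, 200, 0))
  sq <- trimesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  cfg <- camera_config(fovy = 40, cam_height = 1, cam_distance = 3)
  dm <- render_depth_map(sq, cfg, 512, 512)
  nz <- which(dm$pixels > 0, arr.ind = TRUE)
  ct <- 1 / tan(20 * pi / 180)
  px_of <- function(x) (ct * x / 3000 + 1) / 2 * 512
  row_of <- function(y) (1 - ct * (y - 1000) / 3000) / 2 * 512
  expect_lte(abs(min(nz[, "col"]) - px_of(-100)), 1.5)
  expect_lte(abs(max(nz[, "col"]) - px_of(100)), 1.5)
  expect_lte(abs(min(nz[, "row"]) - row_of(200)), 1.5)
  expect_lte(abs(max(nz[, "row"]) - row_of(0)), 1.5)
})

test_that("nearer surfaces are strictly brighter and depth maps back-project", {
  near_sq <- trimesh(rbind(c(-400, 0, 0), c(-100, 0, 0), c(-100, 300, 0),
                           c(-400, 300, 0)), rbind(c(1, 2, 3), c(1, 3, 4)))
  far_sq <- trimesh(rbind(c(100, 0, -800), c(400, 0, -800), c(400, 300, -800),
                          c(100, 300, -800)), rbind(c(1, 2, 3), c(1, 3, 4)))
  both <- trimesh(rbind(near_sq$vertices, far_sq$vertices),
                  rbind(near_sq$faces, far_sq$faces + 4L))
  dm <- render_depth_map(both, camera_config(), 400, 400)
  left <- dm$pixels[, 1:200]
  right <- dm$pixels[, 201:400]
  expect_gt(min(left[left > 0]), max(right[right > 0]))
  # back-projection: every nonzero pixel of the near square lies near z = 0
  idx <- which(dm$world_depth > 0 & col(dm$world_depth) <= 200, arr.ind = TRUE)
  pick <- idx[seq(1, nrow(idx), length.out = 25), , drop = FALSE]
  pts <- t(apply(pick, 1, function(rc) back_project(dm, rc[1], rc[2])))
  expect_lt(max(abs(pts[, 3])), 5)
  # re-projecting a back-projected point lands in the same pixel (closed form)
  cfg <- dm$camera
  ct <- 1 / tan(cfg$fovy * pi / 360)
  for (k in seq_len(nrow(pick))) {
    p <- pts[k, ] - dm$cam_pos
    col_pred <- (ct * p[1] / -p[3] + 1) / 2 * dm$width + 0.5
    row_pred <- (1 - ct * p[2] / -p[3]) / 2 * dm$height + 0.5
    expect_lt(abs(col_pred - pick[k, 2]), 1)
    expect_lt(abs(row_pred - pick[k, 1]), 1)
  }
})

test_that("a mesh outside the frustum yields an all-zero map with a warning", {
  sq <- unit_triangle_mesh()
  cfg <- camera_config(cam_height = 50)   # camera 50 m up, looking level
  expect_warning(dm <- render_depth_map(sq, cfg, 64, 64), "frustum")
  expect_true(all(dm$pixels == 0))
  expect_true(dm$empty_frustum)
})

test_that("multi-view snapshots honour the step and symmetry", {
  cyl <- cylinder_fixture(r = 100, h = 800, sides = 48)$mesh
  views8 <- multi_view_snapshots(cyl, camera_config(), 45, 128, 128)
  expect_length(views8, 8)
  views4 <- multi_view_snapshots(cyl, camera_config(), 90, 64, 64)
  expect_length(views4, 4)
  expect_error(multi_view_snapshots(cyl, camera_config(), 70), "divide")
  # 180-degree yaw leaves a symmetric silhouette area unchanged (within 0.5%)
  a0 <- sum(views8[[1]]$pixels > 0)
  a4 <- sum(views8[[5]]$pixels > 0)
  expect_lt(abs(a0 - a4) / a0, 0.005)
})

test_that("intensity decreases linearly in depth over [near, far]", {
  cfg <- camera_config(near_n = 1000, far_f = 6000)
  plane_at <- function(z) trimesh(
    rbind(c(-200, 0, z), c(200, 0, z), c(200, 400, z), c(-200, 400, z)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  # single square: constant known depth -> predicted intensity
  dm <- render_depth_map(plane_at(0), cfg, 64, 64)
  d <- dm$world_depth[dm$world_depth > 0]
  g <- dm$pixels[dm$pixels > 0]
  pred <- round(255 - (d - 1000) / 5000 * 254)
  expect_equal(as.integer(g), as.integer(pmin(255, pmax(1, pred))))
})

test_that("depth maps survive a save/load round trip", {
  dm <- default_humanoid()$dm
  stem <- file.path(withr::local_tempdir(), "dm")
  save_depth_map(dm, stem)
  back <- load_depth_map(stem)
  expect_equal(back$pixels, dm$pixels)
  nz <- dm$world_depth > 0
  expect_lt(max(abs(back$world_depth[nz] - dm$world_depth[nz])), 0.2)
  expect_equal(back$camera$cam_distance, dm$camera$cam_distance)
})

test_that("back-projecting the head-top pixel recovers the mesh apex height", {
  fix <- default_humanoid()
  top <- fix$seeds$points["head_top", ]
  p <- back_project(fix$dm, top["row"], top["col"])
  expect_lt(abs(p[2] - max(fix$body$mesh$vertices[, 2])), 5)
  expect_error(back_project(fix$dm, 1, 1), "background")
})
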