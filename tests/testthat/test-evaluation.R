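# ratio-error pairs, camera-placement selection, accuracy aggregation

ref_report <- function(chest, waist, arm = 30, thigh = 50) {
  measurement_report(circumferences = c(chest = chest, waist = waist,
                                        left_arm = arm, left_thigh = thigh))
}

test_that("ratio errors are zero for identical reports and follow the formula", {
  r <- ref_report(100, 80)
  expect_equal(ratio_error_pair(r, r), list(A = 0, B = 0))
  m <- ref_report(110, 100)          # ratio 1.10
  ref <- ref_report(100, 100)        # ratio 1.00
  expect_equal(ratio_error_pair(m, ref)$A, 0.10, tolerance = 1e-12)
  # worked example from the published single-subject comparison:
  # reference 111.02/104.08, measured 107/100.2 -> A ~ 0.00111
  m2 <- ref_report(107, 100.2)
  r2 <- ref_report(111.02, 104.08)
  expect_equal(ratio_error_pair(m2, r2)$A,
               abs(107 / 100.2 - 111.02 / 104.08) / (111.02 / 104.08),
               tolerance = 1e-12)
  expect_lt(abs(ratio_error_pair(m2, r2)$A - 0.00111), 2e-5)
})

test_that("ratio errors are invariant to uniform scaling of either report", {
  m <- ref_report(107, 100.2, 28, 47)
  r <- ref_report(111, 104, 30, 50)
  scale_rep <- function(rep, s) {
    rep$circumferences <- rep$circumferences * s
    rep
  }
  e1 <- ratio_error_pair(m, r)
  e2 <- ratio_error_pair(scale_rep(m, 2.5), r)
  e3 <- ratio_error_pair(m, scale_rep(r, 0.4))
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_equal(e1, e3, tolerance = 1e-12)
  # absolute mode reports |dr| itself
  abs_mode <- ratio_error_pair(m, r, mode = "absolute")
  expect_equal(abs_mode$A, abs(107 / 100.2 - 111 / 104), tolerance = 1e-12)
})

test_that("the reference grid selects the 1 m / 3 m placement for both models", {
  grid <- camera_grid_reference()
  expect_s3_class(grid, "camera_grid")
  expect_equal(sum(grid$broken), 3)          # one model broken at 4 m
  sel <- select_camera(grid)
  expect_equal(sel$cam_height, 1)
  expect_equal(sel$cam_distance, 3)
  expect_true(sel$agreement)
  expect_equal(sel$per_model$height_m, c(1, 1))
  expect_equal(sel$per_model$distance_m, c(3, 3))
})

test_that("single-cell grids and broken-cell exclusion behave", {
  g1 <- camera_grid(data.frame(height_m = 1, distance_m = 2, model = "M",
                               A = 0.1, B = 0.2))
  sel <- select_camera(g1)
  expect_equal(c(sel$cam_height, sel$cam_distance), c(1, 2))
  # the globally smallest cell is broken and must not be selected
  g2 <- camera_grid(data.frame(height_m = c(1, 1), distance_m = c(2, 3),
                               model = "M", A = c(0.001, 0.1),
                               B = c(0.001, 0.1),
                               broken = c(TRUE, FALSE)))
  expect_equal(select_camera(g2)$cam_distance, 3)
  expect_error(camera_grid(data.frame(height_m = 1, distance_m = 2,
                                      model = "M", A = 0.1, B = 0.1,
                                      broken = TRUE)), "non-broken")
})

test_that("selection agrees with exhaustive enumeration on random grids", {
  set.seed(2024)
  for (rep in 1:20) {
    cells <- expand.grid(height_m = c(0.5, 1, 1.5),
                         distance_m = seq(1.5, 4, by = 0.5))
    df <- do.call(rbind, lapply(c("M1", "M2"), function(m) {
      transform(cells, model = m,
                A = round(stats::runif(nrow(cells), 0.01, 0.3), 3),
                B = round(stats::runif(nrow(cells), 0.01, 0.3), 3),
                broken = stats::runif(nrow(cells)) < 0.1)
    }))
    df$broken[1] <- FALSE            # keep at least one usable cell
    grid <- camera_grid(df)
    sel <- select_camera(grid)
    # oracle: brute-force minimizers per model, then the agreement rule
    usable <- df[!df$broken, ]
    mins <- lapply(split(usable, usable$model), function(g)
      g[which.min(g$A + g$B), c("height_m", "distance_m")])
    if (length(unique(vapply(mins, paste, character(1), collapse = "/"))) == 1) {
      expect_equal(c(sel$cam_height, sel$cam_distance),
                   unname(unlist(mins[[1]])))
      expect_true(sel$agreement)
    } else {
      expect_false(sel$agreement)
      key <- paste(usable$height_m, usable$distance_m)
      full <- names(which(table(key) == 2))
      pool <- usable[key %in% full, ]
      tot <- tapply(pool$A + pool$B, paste(pool$height_m, pool$distance_m), sum)
      expect_equal(paste(sel$cam_height, sel$cam_distance),
                   names(which.min(tot)))
    }
  }
})

test_that("error summaries average per-part percent errors into accuracy", {
  identical_rep <- c(chest = 107, waist = 100)
  s0 <- error_summary(identical_rep, identical_rep)
  expect_equal(s0$mean_error, 0)
  expect_equal(s0$accuracy, 100)
  s1 <- error_summary(c(a = 90, b = 100), c(a = 100, b = 100))
  expect_equal(s1$mean_error, 5)
  expect_equal(s1$accuracy, 95)
  expect_equal(s1$accuracy + s1$mean_error, 100, tolerance = 1e-9)
  # part reordering and joint scaling leave percent errors unchanged
  m <- c(chest = 107, waist = 100.2, hip = 96.5)
  r <- c(chest = 111.02, waist = 104.08, hip = 101.86)
  expect_equal(error_summary(m, r)$mean_error,
               error_summary(rev(m), rev(r))$mean_error)
  expect_equal(error_summary(m * 3, r * 3)$per_part,
               error_summary(m, r)$per_part)
  expect_warning(error_summary(c(a = 1, b = 2), c(a = 0, b = 2)), "zero")
})

test_that("the published per-part error column aggregates to 93% accuracy", {
  s <- aggregate_accuracy(c(chest = 7.5, chest_volume = 6.2, waist = 8.2,
                            hip = 5.4))
  expect_equal(s$mean_error, 6.825)
  expect_equal(s$accuracy, 93.175)
  expect_lt(abs(s$accuracy - 93), 0.5)   # consistent with the printed 93%
})
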