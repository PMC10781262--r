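# vertex normals, cross-sections, circumference modes, slab volumes, plane
# location and the full measurement report

test_that("vertex normals average incident face normals", {
  # flat +Y-facing square: every vertex normal is (0, 1, 0)
  sq <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, -1), c(0, 0, -1)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  n <- vertex_normals(sq)
  expect_equal(n, matrix(rep(c(0, 1, 0), each = 4), ncol = 3))
  # single triangle: all three equal the face normal
  tr <- unit_triangle_mesh()
  n1 <- vertex_normals(tr)
  expect_equal(n1, matrix(rep(c(0, 0, 1), each = 3), ncol = 3))
  expect_equal(sqrt(rowSums(n1^2)), rep(1, 3), tolerance = 1e-6)
})

test_that("sphere vertex normals are radial within 2 degrees", {
  sph <- make_primitive("ellipsoid", c(100, 100, 100), profile_sides = 64)$mesh
  n <- vertex_normals(sph)
  radial <- sweep(sph$vertices, 2, c(0, 100, 0))
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, rowSums(n * radial))) * 180 / pi
  expect_lt(max(ang), 2)
})

test_that("cylinder cross-section matches the inscribed-polygon closed form", {
  cyl <- cylinder_fixture(r = 100, h = 300, sides = 256)$mesh
  cs <- cross_section(cyl, 150)
  expect_length(cs$loops, 1)
  oracle <- 256 * 2 * 100 * sin(pi / 256)      # = 628.31 mm
  expect_equal(cs$perimeter, oracle, tolerance = 1e-9)
  expect_equal(cs$area, 0.5 * 256 * 100^2 * sin(2 * pi / 256),
               tolerance = 1e-9)
  # plane above the mesh: empty section
  expect_length(cross_section(cyl, 500)$loops, 0)
})

test_that("the humanoid chest plane sections into torso plus two arm loops", {
  fix <- default_humanoid()
  H <- mesh_height(fix$body$mesh)
  cs <- cross_section(fix$body$mesh, 0.70 * H)
  expect_length(cs$loops, 3)
  expect_equal(which.max(cs$area), which.max(cs$perimeter))
})

test_that("circumference selects loops and applies the tape modes", {
  # circle of r = 159.155 mm -> 100 cm
  circ <- cylinder_fixture(r = 1000 / (2 * pi), h = 100, sides = 256)$mesh
  cs <- cross_section(circ, 50)
  expect_equal(circumference(cs, "largest_area", "raw"), 100,
               tolerance = 1e-4)
  # square loop: raw == convex == 4a
  box <- make_primitive("box", c(100, 50, 100))$mesh
  bs <- cross_section(box, 25)
  expect_equal(circumference(bs, "largest_area", "raw"), 40)
  expect_equal(circumference(bs, "largest_area", "convex"), 40)
  # concave star: the convex tape is strictly shorter than the raw outline
  th <- 2 * pi * (0:19) / 20
  rad <- ifelse(seq_along(th) %% 2 == 0, 100, 50)
  ring <- function(y) cbind(rad * cos(th), y, rad * sin(th))
  star <- anthromesh:::.loft_rings(list(ring(0), ring(60)))
  ss <- cross_section(star, 30)
  expect_lt(circumference(ss, "largest_area", "convex"),
            circumference(ss, "largest_area", "raw"))
  expect_error(circumference(cross_section(box, 500)), "empty")
})

test_that("slab volume matches closed forms and converges at trapezoid order", {
  cyl <- cylinder_fixture(r = 100, h = 300, sides = 192)$mesh
  v <- slab_volume(cyl, 0, 300, n_slices = 64)
  expect_equal(v, pi * 100^2 * 300 / 1e6, tolerance = 0.005)
  expect_equal(slab_volume(cyl, 150, 150), 0)
  # spherical segment [-r/2, r/2] of r = 100 against the analytic formula
  sph <- make_primitive("ellipsoid", c(100, 100, 100), profile_sides = 128)$mesh
  seg <- slab_volume(sph, 50, 150, n_slices = 64)
  analytic <- pi * (100^2 * 100 - (50^3 + 50^3) / 3) / 1e6
  expect_equal(seg, analytic, tolerance = 0.01)
  # error halves (quadratic order) when slices double, against a fine reference
  ref <- slab_volume(sph, 50, 150, n_slices = 1024)
  e32 <- abs(slab_volume(sph, 50, 150, n_slices = 32) - ref)
  e64 <- abs(slab_volume(sph, 50, 150, n_slices = 64) - ref)
  expect_lt(e64, e32 / 1.8)
})

test_that("measurement planes land on the constructed extremum levels", {
  fix <- default_humanoid()
  H <- mesh_height(fix$body$mesh)
  planes <- locate_measurement_planes(fix$body$mesh, fix$seeds)
  expect_lt(abs(planes$chest - 0.72 * H) / H, 0.01)
  expect_lt(abs(planes$waist - 0.62 * H) / H, 0.01)
  expect_lt(abs(planes$hip - 0.53 * H) / H, 0.01)
  expect_lt(planes$thigh, fix$seeds$world_heights[["crotch"]])
})

test_that("a constant-girth cylinder reports chest = waist = hip = 2*pi*r", {
  cyl <- cylinder_fixture(r = 150, h = 1000, sides = 256)$mesh
  seeds <- synthetic_cylinder_seeds()
  rep <- suppressWarnings(measure_report(cyl, seeds))
  expected <- 2 * pi * 150 / 10
  for (g in c("chest", "waist", "hip"))
    expect_equal(rep$circumferences[[g]], expected, tolerance = 0.01)
  expect_equal(rep$height, 100, tolerance = 1e-6)
})

test_that("reported quantities obey the similarity laws under resizing", {
  cyl <- cylinder_fixture(r = 150, h = 1000, sides = 128)$mesh
  seeds <- synthetic_cylinder_seeds()
  r1 <- suppressWarnings(measure_report(cyl, seeds))
  s <- 1.5
  big <- resize_to_height(cyl, 150)            # 1000 mm -> 1500 mm
  seeds2 <- scale_seeds(seeds, s)
  r2 <- suppressWarnings(measure_report(big, seeds2))
  expect_equal(unname(r2$circumferences / r1$circumferences),
               rep(s, 7), tolerance = 1e-6)
  expect_equal(r2$chest_volume / r1$chest_volume, s^3, tolerance = 1e-6)
  expect_equal(r2$height / r1$height, s, tolerance = 1e-9)
})

test_that("obesity indices follow their formulas", {
  expect_equal(bmi(70, 175), 70 / 1.75^2, tolerance = 1e-12)
  expect_equal(round(bmi(70, 175), 3), 22.857)
  expect_equal(whtr(80, 160), 0.5)
  # BMI is invariant when mass and height^2 scale together
  expect_equal(bmi(140, 175 * sqrt(2)), bmi(70, 175))
  expect_error(bmi(-1, 170), "positive")
  expect_error(whtr(80, 0), "positive")
})
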