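# Three-step rigid registration: principal axis, RV-insertion rotation,
# ICP refinement, and their composition.

ellipsoidMesh <- function() scarDE:::lvShellMesh(20, 80)

test_that("principal axis points from base toward apex", {
  m <- ellipsoidMesh()  # apex at -z by construction
  expect_equal(as.numeric(principalAxis(m)), c(0, 0, -1), tolerance = 1e-6)
  # rotating the mesh rotates the axis with it
  R <- rotationAboutAxis(c(1, 1, 0), 0.7)
  mr <- applyTransform(m, RigidTransform(R))
  expect_equal(as.numeric(principalAxis(mr)), as.numeric(R %*% c(0, 0, -1)),
               tolerance = 1e-6)
})

test_that("principal axis rejects isotropic vertex clouds", {
  # cube corners have an exactly isotropic covariance
  cube <- SurfaceMesh(20 * as.matrix(expand.grid(c(-1, 1), c(-1, 1),
                                                 c(-1, 1))))
  expect_error(principalAxis(cube), "degenerate")
})

test_that("major-axis alignment recovers constructed rotations", {
  m <- ellipsoidMesh()
  expect_equal(alignMajorAxes(m, m)@rotation, diag(3), tolerance = 1e-9)
  t30 <- mkTransform(c(1, 0, 0), 30)
  moved <- applyTransform(m, t30)
  rec <- alignMajorAxes(moved, m)
  # recovered rotation must map the moved axis back onto the original
  axMoved <- principalAxis(moved); axFix <- principalAxis(m)
  expect_equal(as.numeric(rec@rotation %*% axMoved), as.numeric(axFix),
               tolerance = 1e-6)
  expect_equal(rotationAngle(rec@rotation) * 180 / pi, 30, tolerance = 1e-4)
  # anti-parallel axes: flipped mesh still maps axis onto axis
  flip <- applyTransform(m, mkTransform(c(1, 0, 0), 180))
  rec2 <- alignMajorAxes(flip, m)
  expect_equal(as.numeric(rec2@rotation %*% principalAxis(flip)),
               as.numeric(axFix), tolerance = 1e-6)
})

test_that("RV-insertion alignment is a pure rotation about the long axis", {
  p <- smallParams()
  case <- generateCase(p, 0, withVolumes = FALSE)
  m <- case@ctEndo
  expect_equal(alignRvInsertions(m, m, c(0, 0, -1))@rotation, diag(3),
               tolerance = 1e-9)
  t45 <- rotationAboutAxis(c(0, 0, -1), 45 * pi / 180)
  moved <- applyTransform(m, RigidTransform(t45))
  rec <- alignRvInsertions(moved, m, c(0, 0, -1))
  expect_equal(rotationAngle(rec@rotation) * 180 / pi, 45, tolerance = 1e-4)
  # applying the recovered rotation re-aligns the projected landmarks
  back <- applyTransform(moved, rec)
  for (nm in c("rv_insertion_anterior", "rv_insertion_inferior")) {
    d <- meshLandmarks(back)[[nm]] - meshLandmarks(m)[[nm]]
    expect_lt(sqrt(sum(d[1:2]^2)), 1e-6)  # in-plane residual
  }
  # missing landmark errors name the mesh side
  bare <- SurfaceMesh(meshVertices(m))
  expect_error(alignRvInsertions(bare, m, c(0, 0, -1)), "moving")
  # landmarks on the axis have zero projected radius
  onAxis <- m
  onAxis@landmarks$rv_insertion_anterior <- c(0, 0, -20)
  expect_error(alignRvInsertions(onAxis, m, c(0, 0, -1)), "zero projected")
})

test_that("ICP recovers a known small displacement and is monotone", {
  m <- ellipsoidMesh()
  idT <- icp(m, m, maxIter = 5L)
  expect_equal(rotationAngle(idT@rotation), 0, tolerance = 1e-9)
  expect_lt(attr(idT, "rms"), 1e-9)
  truth <- mkTransform(c(0, 0, 1), 1, c(2, 0, 0))
  moved <- applyTransform(m, truth)
  rec <- icp(moved, m)
  expect_lt(rotationErrDeg(rec, invertTransform(truth)), 0.1)
  expect_lt(translationErr(rec, invertTransform(truth)), 0.1)
  # RMS objective never increases across iterations
  h <- attr(rec, "history")
  expect_true(all(diff(h) <= 1e-9))
  # a single iteration already improves on the initial distance
  one <- icp(moved, m, maxIter = 1L)
  expect_lte(attr(one, "rms"),
             sqrt(mean(rowSums((meshVertices(moved) - meshVertices(m))^2))))
})

test_that("three-step registration is identity on identical meshes and
           equivariant under a common rigid motion", {
  p <- smallParams()
  case <- generateCase(p, 0, withVolumes = FALSE)
  m <- case@ctEndo
  tf <- registerLV(m, m)
  expect_lt(rotationAngle(tf@rotation) * 180 / pi, 1e-6)
  expect_lt(sqrt(sum(tf@translation^2)), 1e-6)
  # equivariance: registering g-moved copies conjugates the transform by g
  g <- mkTransform(c(1, 2, 0), 25, c(5, -2, 8))
  tf0 <- registerLV(case@mriEndo, case@ctEndo)
  tfg <- registerLV(applyTransform(case@mriEndo, g),
                    applyTransform(case@ctEndo, g))
  conj <- composeTransforms(g, composeTransforms(tf0, invertTransform(g)))
  expect_lt(rotationErrDeg(tfg, conj), 0.2)
  expect_lt(translationErr(tfg, conj), 0.3)
})

test_that("registration recovers the phantom's hidden misalignment", {
  p <- smallParams()
  for (i in 0:1) {
    case <- generateCase(p, i, withVolumes = FALSE)
    tf <- registerLV(case@mriEndo, case@ctEndo)
    expect_lt(rotationErrDeg(tf, case@trueMisalignment), 2)
    expect_lt(translationErr(tf, case@trueMisalignment), 1)
    reg <- applyTransform(case@mriEndo, tf)
    # symmetric surface distance after registration stays below 1 mm
    d1 <- mean(sqrt(rowSums((meshVertices(reg) -
                             meshVertices(case@ctEndo))^2)))
    expect_lt(d1, 1)
    expect_true(registrationQC(reg, case@ctEndo))
  }
})
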