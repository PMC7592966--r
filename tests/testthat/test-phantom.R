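test_that("phantoms are deterministic given their seed", {
  sp <- phantomSpec(dim = c(64L, 64L, 24L), seed = 9L)
  p1 <- generatePhantom(sp)
  p2 <- generatePhantom(sp)
  expect_identical(p1$volume@voxels, p2$volume@voxels)
  expect_identical(p1$liver@voxels, p2$liver@voxels)
  expect_identical(p1$tumor@voxels, p2$tumor@voxels)
  p3 <- generatePhantom(phantomSpec(dim = c(64L, 64L, 24L), seed = 10L))
  expect_false(identical(p1$volume@voxels, p3$volume@voxels))
})

test_that("phantom intensities follow the specified regime", {
  ph <- generatePhantom(phantomSpec(seed = 3L))
  v <- ph$volume@voxels
  lv <- ph$liver@voxels
  tm <- ph$tumor@voxels
  parenchyma <- lv == 1 & tm == 0
  n <- sum(parenchyma)
  # liver mean within 3 sd-of-mean of the specified 120 HU
  sdm <- sqrt(15^2 + 10^2) / sqrt(n)
  expect_lt(abs(mean(v[parenchyma]) - 120), 3 * sdm)
  expect_gt(sum(tm), 0)
  expect_lt(mean(v[tm == 1]), mean(v[parenchyma]))  # tumors darker
  # contrast exceeds 3x the noise level
  expect_gte(abs(mean(v[parenchyma]) - mean(v[tm == 1])), 3 * 10)
  # full HU range represented: air and bone
  expect_lt(min(v), -900)
  expect_gt(max(v), 400)
})

test_that("tumors stay strictly inside the liver with a 2 px margin", {
  for (s in c(3L, 5L, 8L)) {
    ph <- generatePhantom(phantomSpec(seed = s))
    lv <- ph$liver@voxels
    tm <- ph$tumor@voxels
    expect_true(all(lv[tm == 1] == 1))
    if (sum(tm) > 0) {
      d <- hepaseg:::cpp_edt(array(as.integer(lv == 0), dim(lv)),
                             c(1, 1, 2.5 / 1.5))
      expect_gte(min(d[tm == 1]), 2)
    }
  }
  expect_identical(sum(generatePhantom(phantomSpec(tumorCount = 0L,
                                                   seed = 2L))$tumor@voxels),
                   0L)
})

test_that("an infeasible tumor radius raises a spec error", {
  sp <- phantomSpec(dim = c(48L, 48L, 24L),
                    liverAxes = c(5, 5, 3), tumorRadius = c(10, 12),
                    tumorCount = 1L, seed = 1L)
  expect_error(generatePhantom(sp), class = "hepasegSpecError")
})

test_that("corpus generation writes a manifest and reproduces from seeds", {
  sp <- phantomSpec(dim = c(48L, 48L, 20L))
  td <- withr::local_tempdir()
  cp <- generateCorpus(4, sp, seed = 7L, outDir = td)
  expect_length(cp$cases, 4)
  expect_equal(nrow(cp$manifest), 4)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  expect_true(file.exists(file.path(td, "case_0003", "volume.nii.gz")))
  # files round-trip losslessly through the NIfTI reader
  rv <- readVolume(file.path(td, "case_0002", "volume.nii.gz"))
  expect_equal(rv@voxels, cp$cases[[2]]$volume@voxels, tolerance = 1e-6)
  # a case regenerated from its manifest seed is identical
  sp2 <- sp
  sp2@seed <- cp$manifest$seed[3]
  expect_identical(generatePhantom(sp2)$volume@voxels,
                   cp$cases[[3]]$volume@voxels)
  # disjoint corpus seeds give different corpora
  cp2 <- generateCorpus(4, sp, seed = 8L)
  expect_false(identical(cp2$cases[[1]]$volume@voxels,
                         cp$cases[[1]]$volume@voxels))
})
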