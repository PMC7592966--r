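test_that("Dice identities hold", {
  a <- array(0L, c(8, 8, 2))
  a[2:5, 2:5, 1] <- 1L
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(0L, c(8, 8, 2))
  b[6:8, 6:8, 2] <- 1L
  expect_equal(diceCoefficient(a, b), 0)
  # |A| = |B| = 4, overlap 2 -> 2*2/(4+4) = 0.5
  a2 <- array(0L, c(4, 4, 1)); a2[1, 1:4, 1] <- 1L
  b2 <- array(0L, c(4, 4, 1)); b2[1, 3:4, 1] <- 1L; b2[2, 1:2, 1] <- 1L
  expect_equal(diceCoefficient(a2, b2), 0.5)
  expect_equal(diceCoefficient(a * 0L, b * 0L), 1)   # empty vs empty
  expect_error(diceCoefficient(a, array(0L, c(4, 4, 4))),
               class = "hepasegContractError")
})

test_that("Dice is symmetric and agrees with the soft loss on binary masks", {
  set.seed(10)
  for (i in 1:10) {
    a <- array(rbinom(128, 1, 0.4), c(8, 8, 2))
    b <- array(rbinom(128, 1, 0.4), c(8, 8, 2))
    expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
    am <- matrix(a, 8, 16)  # one sample: soft loss complements global Dice
    bm <- matrix(b, 8, 16)
    expect_equal(diceCoefficient(a, b),
                 1 - softDiceLoss(am, bm, eps = 1e-9), tolerance = 1e-6)
  }
})

test_that("case evaluation averages per case and separates tumor-free cases", {
  mk <- function(fill) binaryMask(array(fill, c(6, 6, 2)))
  full <- mk(1L); empty <- mk(0L)
  half <- binaryMask(array(rep(c(1L, 0L), each = 36), c(6, 6, 2)))
  preds <- list(
    c1 = list(liver = full, liverUNet = half, tumor = half,
              tumorUNet = half),
    c2 = list(liver = full, liverUNet = full, tumor = empty,
              tumorUNet = full))
  truths <- list(c1 = list(liver = full, tumor = full),
                 c2 = list(liver = full, tumor = empty))
  ev <- evaluateCases(preds, truths)
  expect_equal(nrow(ev$scores), 2)
  expect_true(ev$scores$tumor_free[ev$scores$case_id == "c2"])
  # liver means: (2/3 + 1)/2 ; tumor means over tumor-bearing case c1 only
  expect_equal(unname(ev$means["liver_dice_unet"]), (2 / 3 + 1) / 2)
  expect_equal(unname(ev$means["tumor_dice_refined"]), 2 / 3)
  # empty prediction against nonempty truth records 0
  preds$c1$tumor <- empty
  expect_equal(evaluateCases(preds, truths)$scores$tumor_dice_refined[1], 0)
  expect_error(evaluateCases(preds, truths[1]),
               class = "hepasegContractError")
})
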