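make_flat_image <- function(rgb, h = 64, w = 64) {
  px <- array(rep(rgb / 255, each = h * w), c(h, w, 3))
  core_image(px, id = "flat")
}

test_that("grayscale conversion uses the documented luminance weights", {
  expect_equal(unique(as.vector(to_grayscale(make_flat_image(c(255, 255, 255))))), 1)
  expect_equal(unique(as.vector(to_grayscale(make_flat_image(c(0, 0, 0))))), 0)
  red <- to_grayscale(make_flat_image(c(255, 0, 0)))
  expect_equal(unique(as.vector(red)), 0.299)
  expect_error(to_grayscale(matrix(0, 64, 64)), "RGB")
})

test_that("Sobel gradient is zero on constants and peaks on a step edge", {
  expect_true(all(compute_gradient(matrix(0.5, 64, 64)) == 0))
  step <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  g <- compute_gradient(step)
  expect_true(all(g >= 0))
  # response confined to the two columns astride the edge
  inner <- g[5:60, ]
  expect_true(all(inner[, c(1:30, 35:64)] < 1e-10))
  expect_true(all(inner[, 32:33] > 1))
})

test_that("gradient response concentrates on ground-truth boundaries", {
  syn <- generate_core_image(small_image_spec(seed = 5, nucleus_density = 0))
  g <- compute_gradient(to_grayscale(syn$image))
  gn <- g / max(g)
  th <- EBImage::otsu(EBImage::Image(gn), range = c(0, 1))
  hot <- which(gn > th, arr.ind = TRUE)
  # distance of each super-threshold pixel to the nearest truth boundary
  bound <- syn$truth$tumor_mask != EBImage::erode(syn$truth$tumor_mask,
                                                  EBImage::makeBrush(3, "box"))
  bound <- bound | (syn$truth$core_mask !=
                      EBImage::erode(syn$truth$core_mask,
                                     EBImage::makeBrush(3, "box")))
  bidx <- which(bound, arr.ind = TRUE)
  if (nrow(hot) > 1500) hot <- hot[seq(1, nrow(hot), length.out = 1500), ]
  near <- vapply(seq_len(nrow(hot)), function(i) {
    min(abs(bidx[, 1] - hot[i, 1]) + abs(bidx[, 2] - hot[i, 2]))
  }, numeric(1))
  expect_gte(mean(near <= 3), 0.90)
})

test_that("tumor-object extraction recovers a clean nest and drops speckles", {
  expect_false(any(extract_tumor_objects(matrix(0, 128, 128), small_params())))

  # single synthetic nest on clean stroma background
  spec <- small_image_spec(seed = 21, true_stroma_frac = 0.91, n_nests = 1,
                           nest_radius_range = c(32, 34),
                           nucleus_density = 0, tol = 0.06)
  syn <- generate_core_image(spec)
  grad <- compute_gradient(to_grayscale(syn$image))
  mask <- extract_tumor_objects(grad, small_params())
  A <- sum(syn$truth$tumor_mask)
  got <- sum(mask & syn$truth$core_mask)
  expect_lt(abs(got - A) / A, 0.10)

  # nucleus speckles: removed at the default threshold, present at 0
  syn2 <- generate_core_image(small_image_spec(seed = 22,
                                               true_stroma_frac = 1,
                                               n_nests = 0,
                                               nucleus_density = 1.5))
  grad2 <- compute_gradient(to_grayscale(syn2$image))
  with_thr <- extract_tumor_objects(grad2,
                                    small_params(min_object_area = 200))
  without <- extract_tumor_objects(grad2, small_params(min_object_area = 0))
  expect_false(any(with_thr & syn2$truth$core_mask))
  expect_gt(sum(without & syn2$truth$core_mask), 0)
})

test_that("core segmentation recovers the tissue disc and rejects blanks", {
  # plain dark disc on white: an exact recovery case
  h <- w <- 256
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  disc <- (rr - 128)^2 + (cc - 128)^2 <= 90^2
  gray <- matrix(250 / 255, h, w); gray[disc] <- 100 / 255
  got <- segment_core(gray, small_params())
  expect_gte(sum(got & disc) / sum(got | disc), 0.98)

  expect_error(segment_core(matrix(1, 128, 128), small_params()),
               "no core detected")

  # full synthetic core with nests and speckles
  syn <- generate_core_image(small_image_spec(seed = 6))
  cm <- segment_core(to_grayscale(syn$image), small_params())
  jac <- sum(cm & syn$truth$core_mask) / sum(cm | syn$truth$core_mask)
  expect_gte(jac, 0.95)
})

test_that("assessment handles the all-tumor and all-stroma extremes", {
  all_tumor <- generate_core_image(
    small_image_spec(seed = 31, true_stroma_frac = 0, n_nests = 1,
                     nest_radius_range = c(200, 220), nucleus_density = 0))
  seg <- assess_core(all_tumor$image, small_params())
  expect_lte(seg$tsr, 0.02)

  no_tumor <- generate_core_image(
    small_image_spec(seed = 32, true_stroma_frac = 1, n_nests = 0,
                     nucleus_density = 0))
  seg2 <- assess_core(no_tumor$image, small_params())
  expect_identical(seg2$tsr, 1)
})

test_that("segmentation result satisfies the area identities and overlay colours", {
  syn <- generate_core_image(small_image_spec(seed = 8))
  seg <- assess_core(syn$image, small_params())
  expect_true(seg$tsr >= 0 && seg$tsr <= 1)
  expect_identical(seg$areas[["tumor"]] + seg$areas[["stroma"]],
                   seg$areas[["core"]])
  expect_identical(seg$tumor_mask | seg$stroma_mask, seg$core_mask)
  expect_false(any(seg$tumor_mask & seg$stroma_mask))
  # overlay: magenta tumor, cyan stroma, black outside
  i <- which(seg$tumor_mask)[1]
  expect_equal(c(seg$overlay[, , 1][i], seg$overlay[, , 2][i],
                 seg$overlay[, , 3][i]), c(1, 0, 1))
  j <- which(seg$stroma_mask)[1]
  expect_equal(c(seg$overlay[, , 1][j], seg$overlay[, , 2][j],
                 seg$overlay[, , 3][j]), c(0, 1, 1))
  k <- which(!seg$core_mask)[1]
  expect_equal(c(seg$overlay[, , 1][k], seg$overlay[, , 2][k],
                 seg$overlay[, , 3][k]), c(0, 0, 0))
})

test_that("raising the small-object threshold never grows the tumor area", {
  syn <- generate_core_image(small_image_spec(seed = 13,
                                              true_stroma_frac = 0.6,
                                              nucleus_density = 1.5))
  grad <- compute_gradient(to_grayscale(syn$image))
  areas <- vapply(c(0, 30, 60, 150, 400), function(a) {
    sum(extract_tumor_objects(grad, small_params(min_object_area = a)))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("TSR is approximately invariant under 90-degree rotation", {
  syn <- generate_core_image(small_image_spec(seed = 14))
  seg <- assess_core(syn$image, small_params())
  rot <- aperm(syn$image$pixels, c(2, 1, 3))[dim(syn$image$pixels)[2]:1, , ]
  seg_rot <- assess_core(core_image(rot, id = "rot"), small_params())
  expect_lte(abs(seg$tsr - seg_rot$tsr), 0.02)
})

test_that("specimen TSR is the field of highest stromal percentage", {
  expect_identical(assess_specimen(c(0.379, 0.781)), 0.781)
  expect_identical(assess_specimen(0.5), 0.5)
  expect_identical(assess_specimen(c(0.2, 0.2, 0.2)), 0.2)
  expect_error(assess_specimen(numeric(0)), "at least one")
})
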