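test_that("polygon rasterization matches the point-in-polygon oracle", {
  rect <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  m <- rasterize_polygon(rect, 64)
  expect_identical(sum(m), 100L) # 10 x 10 pixel centres inside
  expect_identical(m, brute_point_in_polygon(rect, 64))
  set.seed(21)
  for (rep in 1:5) {
    tri <- cbind(runif(3, 0, 32), runif(3, 0, 32))
    expect_identical(rasterize_polygon(tri, 32), brute_point_in_polygon(tri, 32))
    pent <- cbind(16 + 12 * cos(sort(runif(5, 0, 2 * pi))),
                  16 + 12 * sin(sort(runif(5, 0, 2 * pi))))
    expect_identical(rasterize_polygon(pent, 32),
                     brute_point_in_polygon(pent, 32))
  }
  whole <- rbind(c(-1, -1), c(33, -1), c(33, 33), c(-1, 33))
  expect_true(all(rasterize_polygon(whole, 32)))
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1)), 16), "degenerate")
})

test_that("label building partitions pixels into the four classes", {
  ann <- list(
    heart_polygon = rbind(c(12, 12), c(20, 12), c(20, 20), c(12, 20)),
    combined_polygon = rbind(c(4, 4), c(28, 4), c(28, 28), c(4, 28))
  )
  hu <- matrix(-800, 32, 32)
  lab <- build_labels(ann, hu)
  expect_identical(sum(lab == 255L), 0L) # all-air combined region: no unassigned
  expect_identical(sum(lab == 1L), 64L)
  hu0 <- matrix(0, 32, 32)
  lab0 <- build_labels(ann, hu0)
  expect_identical(sum(lab0 == 2L), 0L)
  expect_identical(sum(lab0 == 255L), 24L * 24L - 64L)
  # strict threshold: -401 becomes lung, -400 does not
  hu2 <- matrix(-400, 32, 32); hu2[, 1:16] <- -401
  lab2 <- build_labels(ann, hu2)
  in_comb <- rasterize_polygon(ann$combined_polygon, 32) &
    !rasterize_polygon(ann$heart_polygon, 32)
  expect_true(all(lab2[in_comb & col(hu2) <= 16] == 2L))
  expect_true(all(lab2[in_comb & col(hu2) > 16] == 255L))
  # partition property: counts sum to image size
  for (lab_i in list(lab, lab0, lab2)) {
    expect_identical(sum(lab_i == 0L) + sum(lab_i == 1L) + sum(lab_i == 2L) +
                       sum(lab_i == 255L), 32L * 32L)
  }
  ann_sz <- c(ann, list(image_size = c(32L, 32L)))
  expect_error(build_labels(ann_sz, matrix(0, 8, 8)), "do not match")
})

test_that("class assignment applies the 0.5/argmax rule with tie-breaks", {
  probs <- array(0, c(1, 3, 3, 1))
  probs[1, 1, , 1] <- c(0.2, 0.7, 0.1)   # heart
  probs[1, 2, , 1] <- c(0.4, 0.35, 0.25) # below threshold -> background
  probs[1, 3, , 1] <- c(0.5, 0.5, 0)     # tie -> lowest class index
  seg <- predict_classes(probs = probs)
  expect_identical(as.integer(seg$labels[1, , 1]), c(1L, 0L, 0L))
})

test_that("largest heart component cleanup matches a flood-fill oracle", {
  lab <- array(0L, c(8, 8, 6))
  lab[2:5, 2:5, 2:4] <- 1L          # 48-voxel blob
  lab[7:8, 7:8, 6] <- 1L            # 4-voxel blob
  stack <- new_segmentation_stack(lab)
  cleaned <- largest_heart_component(stack)
  expect_identical(sum(cleaned$labels == 1L), 48L)
  # idempotent
  expect_identical(largest_heart_component(cleaned)$labels, cleaned$labels)
  # sprinkle: oracle comparison
  set.seed(5)
  lab2 <- array(0L, c(10, 10, 8))
  lab2[3:7, 3:7, 3:6] <- 1L
  sprinkle <- sample(length(lab2), 30)
  lab2[sprinkle] <- 1L
  st2 <- largest_heart_component(new_segmentation_stack(lab2))
  comp <- bfs_components(array(lab2 == 1L, dim(lab2)))
  sizes <- tabulate(comp)
  keep <- which.max(sizes)
  expect_identical(st2$labels == 1L, comp == keep)
  # never increases non-background classes; heart shrinks or stays
  expect_lte(sum(st2$labels == 1L), sum(lab2 == 1L))
  # no heart voxels: unchanged with warning
  empty <- new_segmentation_stack(array(0L, c(4, 4, 2)))
  expect_warning(out <- largest_heart_component(empty), "no heart")
  expect_identical(out$labels, empty$labels)
})

test_that("dice coefficient follows its definition", {
  a <- array(FALSE, c(4, 4)); b <- a
  expect_equal(dice(a, b), 1) # both empty
  a[1:2, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b[3:4, 4] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A|=100, |B|=100, overlap 80
  A <- array(FALSE, c(20, 10)); B <- A
  A[1:100] <- TRUE; B[21:120] <- TRUE
  expect_equal(dice(A, B), 0.8)
  expect_error(dice(array(TRUE, c(2, 2)), array(TRUE, c(3, 3))), "differ")
})

test_that("masked pixels do not influence the dice loss", {
  ns <- asNamespace("ctpheno")
  set.seed(9)
  probs <- matrix(runif(30), 10, 3); probs <- probs / rowSums(probs)
  target <- matrix(0, 10, 3); target[cbind(1:10, sample(3, 10, TRUE))] <- 1
  mask <- rep(c(TRUE, FALSE), 5)
  l1 <- ns$soft_dice_loss(probs, target, mask)$loss
  target2 <- target
  target2[!mask, ] <- target2[!mask, c(3, 1, 2)] # flip masked labels
  l2 <- ns$soft_dice_loss(probs, target2, mask)$loss
  expect_identical(l1, l2)
})

test_that("u-net divisibility contract and masked training hold", {
  img <- array(0, c(48, 48, 4))
  lab <- array(0L, c(48, 48, 4)); lab[20:30, 20:30, ] <- 1L
  expect_error(train_unet(img, lab, depth = 5L, width = 2L, epochs = 1L),
               "divisible")
  expect_error(train_unet(img, array(0L, c(48, 48, 4)), depth = 2L,
                          width = 2L, epochs = 1L), "two classes")
  m <- train_unet(img, lab, depth = 2L, width = 2L, epochs = 2L, seed = 1)
  expect_true(all(is.finite(m$loss_history)))
  pr <- predict_unet_probs(m, img[, , 1])
  expect_equal(dim(pr), c(48, 48, 3, 1))
  expect_equal(apply(pr, c(1, 2, 4), sum), array(1, c(48, 48, 1)),
               tolerance = 1e-9)
  # inference determinism
  expect_identical(pr, predict_unet_probs(m, img[, , 1]))
})

test_that("the 80/20 image-level split reproduces the worked counts", {
  sp <- train_val_split(1121, 0.8, seed = 1)
  expect_identical(length(sp$train), 897L)
  expect_identical(length(sp$val), 224L)
  expect_identical(sort(c(sp$train, sp$val)), 1:1121)
})

test_that("2-D per-slice component mode matches a per-slice flood-fill oracle", {
  set.seed(17)
  lab <- array(0L, c(16, 16, 3))
  lab[2:6, 2:6, 1] <- 1L; lab[10:12, 10:14, 1] <- 1L
  lab[4:9, 8:12, 2] <- 1L; lab[14:15, 1:2, 2] <- 1L
  lab[sample(256, 20) + 2L * 256L] <- 1L
  st <- largest_heart_component(new_segmentation_stack(lab),
                                connectivity = "2d")
  # oracle: per-slice 4-connectivity labelling, global largest component
  comps <- list(); sizes <- c(); off <- 0L
  for (k in 1:3) {
    lb4 <- bfs_components(array(lab[, , k] == 1L, c(16, 16, 1)))
    comps[[k]] <- lb4[, , 1] + ifelse(lb4[, , 1] > 0, off, 0L)
    off <- off + max(lb4)
    sizes <- c(sizes, tabulate(lb4))
  }
  keep <- which.max(sizes)
  expected <- array(0L, dim(lab))
  for (k in 1:3) expected[, , k] <- ifelse(comps[[k]] == keep, 1L, 0L)
  expect_identical(st$labels == 1L, expected == 1L)
})
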