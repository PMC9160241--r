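# Small trained models shared across test files (trained once per session).

make_tiny_classifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- phantom_classification_dataset(60, phantom_spec(), seed = 42)
      cache <<- train_slice_classifier(ds$images, ds$chest,
                                       widths = c(4L, 8L, 8L),
                                       epochs = 4L, seed = 42)
    }
    cache
  }
})

# The reduced-depth segmentation run shared by the acceptance checks:
# 250 phantom slices, 200 train / 50 held out, depth 3 / width 8, up to
# 15 epochs. Trained once per session.
t9_segmentation_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- phantom_slice_dataset(250, phantom_spec(), seed = 42)
      m <- train_unet(ds$images[, , 1:200], ds$labels[, , 1:200],
                      depth = 3L, width = 8L, epochs = 15L,
                      batch_size = 4L, seed = 42)
      seg <- predict_classes(m, ds$images[, , 201:250])
      pred <- seg$labels
      # the method's output includes the largest-heart-component cleanup,
      # applied per phantom stack
      for (p in unique(ds$phantom[201:250])) {
        k <- which(ds$phantom[201:250] == p)
        st <- suppressWarnings(largest_heart_component(
          new_segmentation_stack(pred[, , k, drop = FALSE])))
        pred[, , k] <- st$labels
      }
      cache <<- list(model = m,
                     dice = dice_by_class(pred, ds$labels[, , 201:250]))
    }
    cache
  }
})

# Chest classifier at the documented desk-scale profile (200 slices,
# widths 8/16/32, 5 epochs); trained once per session.
make_chest_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- phantom_classification_dataset(240, phantom_spec(), seed = 42)
      m <- train_slice_classifier(ds$images[, , 1:200], ds$chest[1:200],
                                  widths = c(8L, 16L, 32L), epochs = 8L,
                                  seed = 42)
      cache <<- list(model = m, holdout = list(images = ds$images[, , 201:240],
                                               chest = ds$chest[201:240]))
    }
    cache
  }
})
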