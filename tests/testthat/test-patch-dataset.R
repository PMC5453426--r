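# Patch grids, dihedral augmentation, centering, and the record table.

test_that("patch grids reproduce the reference geometry", {
  g <- plan_patch_grid(1536, 2040, 512, 256, edge_anchor = TRUE)
  expect_equal(nrow(g$offsets), 35L)                 # 5 rows x 7 cols
  expect_equal(g$n_rows, 5L); expect_equal(g$n_cols, 7L)

  g12 <- plan_patch_grid(1536, 2040, 512, 512, edge_anchor = TRUE)
  expect_equal(nrow(g12$offsets), 12L)               # 3 rows x 4 cols
  expect_identical(g12$offsets, inference_grid(1536, 2040, 512)$offsets)

  g1 <- plan_patch_grid(512, 512, 512, 256, edge_anchor = TRUE)
  expect_equal(g1$offsets, data.frame(row = 0L, col = 0L))

  expect_error(plan_patch_grid(100, 100, 512, 256), "larger than image")
  expect_error(plan_patch_grid(512, 512, 512, 0), "stride")
})

test_that("grid offsets are in-bounds, strictly ordered, duplicate-free", {
  set.seed(31)
  for (i in 1:50) {
    dims <- sample(300:900, 2)
    patch <- sample(60:250, 1)
    stride <- sample(seq_len(patch), 1)
    g <- plan_patch_grid(dims[1], dims[2], patch, stride)
    off <- g$offsets
    expect_true(all(off$row >= 0 & off$row + patch <= dims[1]))
    expect_true(all(off$col >= 0 & off$col + patch <= dims[2]))
    key <- off$row * max(dims) * 2 + off$col
    expect_true(all(diff(key) > 0))                  # row-major, no dupes
  }
})

test_that("per-axis offset counts match brute force over random geometries", {
  brute_axis <- function(dim, patch, stride) {
    offs <- c()
    o <- 0
    while (o + patch <= dim) { offs <- c(offs, o); o <- o + stride }
    if (max(offs) != dim - patch) offs <- c(offs, dim - patch)
    offs
  }
  set.seed(77)
  for (i in 1:1000) {
    dim <- sample(64:3000, 1)
    patch <- sample(32:min(dim, 600), 1)
    stride <- patch %/% 2L
    if (stride < 1L) next
    got <- hepatch:::axis_offsets(dim, patch, stride, TRUE)
    expect_identical(got, as.integer(brute_axis(dim, patch, stride)))
    # closed form from the half-stride grid
    n_expected <- (dim - patch) %/% stride + 1L +
      as.integer((dim - patch) %% stride != 0L)
    expect_length(got, n_expected)
  }
})

test_that("grid planning is symmetric under transposing height and width", {
  set.seed(13)
  for (i in 1:20) {
    dims <- sample(300:900, 2); patch <- 128L; stride <- 64L
    a <- plan_patch_grid(dims[1], dims[2], patch, stride)
    b <- plan_patch_grid(dims[2], dims[1], patch, stride)
    expect_equal(sort(unique(a$offsets$row)), sort(unique(b$offsets$col)))
    expect_equal(sort(unique(a$offsets$col)), sort(unique(b$offsets$row)))
  }
})

test_that("dihedral augmentation yields 8 distinct patches that form a closed set", {
  p <- random_rgb(12, 12, seed = 5)                  # generic asymmetric patch
  aug <- augment_patch(p)
  expect_length(aug, 8L)
  sigs <- vapply(aug, function(a) paste(a, collapse = ","), "")
  expect_equal(length(unique(sigs)), 8L)             # pairwise distinct

  # group closure: augmenting any element regenerates the same set of 8
  for (pick in c(2, 5, 8)) {
    sigs2 <- unname(vapply(augment_patch(aug[[pick]]),
                           function(a) paste(a, collapse = ","), ""))
    expect_setequal(sigs2, unname(sigs))
  }

  # constant patch: all 8 equal in content
  const <- array(7L, c(6, 6, 3))
  expect_equal(length(unique(vapply(augment_patch(const),
                                    function(a) paste(a, collapse = ","), ""))), 1L)

  expect_error(augment_patch(random_rgb(6, 8)), "square")
})

test_that("center_channels zeroes per-channel means and is shift-invariant", {
  p <- random_rgb(16, 16, seed = 9)
  cp <- center_channels(p)
  expect_true(is.double(cp))
  for (ch in 1:3) expect_lt(abs(mean(cp[, , ch])), 1e-6)

  const <- array(0, c(8, 8, 3)); for (ch in 1:3) const[, , ch] <- ch * 10
  expect_true(all(center_channels(const) == 0))

  shift <- p; for (ch in 1:3) shift[, , ch] <- shift[, , ch] + ch * 3L
  expect_equal(center_channels(shift), cp)

  expect_error(center_channels(array(0, c(4, 4, 2))), "h, w, 3")
})

test_that("patch extraction and reassembly over a non-overlapping grid is exact", {
  img <- random_rgb(96, 128, seed = 21)
  g <- plan_patch_grid(96, 128, 32, 32, edge_anchor = FALSE)
  out <- array(NA_integer_, dim(img))
  for (i in seq_len(nrow(g$offsets))) {
    r <- g$offsets$row[i]; cc <- g$offsets$col[i]
    out[(r + 1):(r + 32), (cc + 1):(cc + 32), ] <- extract_patch(img, r, cc, 32)
  }
  expect_identical(out, img)
  expect_error(extract_patch(img, 90, 0, 32), "outside")
})

test_that("augmented record counts follow offsets x 8 and inherit labels", {
  dims <- list(c(1536L, 2040L))
  rec <- build_patch_records("img1", dims, "benign", 512L, 256L)
  expect_equal(nrow(rec), 280L)                      # 35 x 8
  expect_true(all(rec$label == "benign"))
  expect_equal(sort(unique(rec$augmentation_id)), 0:7)

  rec0 <- build_patch_records("img1", dims, "benign", 512L, 256L, augment = FALSE)
  expect_equal(nrow(rec0), 35L)

  # full-scale arithmetic: 250 reference-geometry images -> 70000 records
  n250 <- 250L
  rec250 <- build_patch_records(sprintf("im%03d", 1:n250),
                                rep(dims, n250),
                                rep(hepatch_classes(), length.out = n250),
                                512L, 256L)
  expect_equal(nrow(rec250), 70000L)
})

test_that("get_patch_pixels applies offset, augmentation and centering", {
  img <- random_rgb(64, 64, seed = 3)
  images <- list(a = img)
  rec <- data.frame(image_id = "a", row = 16L, col = 32L, augmentation_id = 6L,
                    label = "normal")
  got <- get_patch_pixels(images, rec, 16L, center = FALSE)
  manual <- apply_augmentation(extract_patch(img, 16L, 32L, 16L), 6L)
  expect_identical(got, manual)
  centered <- get_patch_pixels(images, rec, 16L, center = TRUE)
  expect_equal(centered, center_channels(manual))
  expect_error(get_patch_pixels(images, within(rec, image_id <- "b"), 16L),
               "no image")
})
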