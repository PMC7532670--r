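test_that("ImageScope XML parses, skips degenerate regions, round-trips", {
  tri <- rbind(c(10, 10), c(200, 40), c(60, 180))
  roi <- pathomsi:::new_roi_annotation("s1", list(tri), mpp = 0.5)
  path <- tempfile(fileext = ".xml")
  write_annotation_xml(roi, path)
  back <- parse_annotation_xml(path, "s1")
  expect_length(back$polygons, 1)
  expect_equal(back$polygons[[1]], tri)

  rect <- rbind(c(0, 0), c(100, 0), c(100, 50), c(0, 50))
  path2 <- tempfile(fileext = ".xml")
  write_annotation_xml(pathomsi:::new_roi_annotation("s2", list(rect)), path2)
  expect_equal(nrow(parse_annotation_xml(path2)$polygons[[1]]), 4)

  # hand-build an XML with a 2-vertex region and a triangle
  doc <- xml2::read_xml(paste0(
    "<Annotations><Annotation><Regions>",
    "<Region><Vertices><Vertex X='0' Y='0'/><Vertex X='5' Y='5'/></Vertices></Region>",
    "<Region><Vertices><Vertex X='0' Y='0'/><Vertex X='9' Y='0'/><Vertex X='0' Y='9'/></Vertices></Region>",
    "</Regions></Annotation></Annotations>"))
  path3 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, path3)
  expect_warning(r3 <- parse_annotation_xml(path3), "degenerate")
  expect_length(r3$polygons, 1)

  doc_empty <- xml2::read_xml("<Annotations><Annotation><Regions/></Annotation></Annotations>")
  path4 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc_empty, path4)
  expect_error(parse_annotation_xml(path4), "no usable region")
})

test_that("overlap fraction is exact on constructed cases", {
  full <- pathomsi:::new_roi_annotation("s", list(rbind(c(0, 0), c(512, 0),
                                                        c(512, 512), c(0, 512))))
  expect_equal(compute_overlap_fraction(0, 0, full, 512), 1)

  half <- pathomsi:::new_roi_annotation("s", list(rbind(c(-64, -64), c(256, -64),
                                                        c(256, 600), c(-64, 600))))
  expect_equal(compute_overlap_fraction(0, 0, half, 512), 0.5)

  # right triangle clipping one corner of a 64px patch: area 24*24/2
  tri <- pathomsi:::new_roi_annotation("s", list(rbind(c(40, 0), c(64, 0), c(64, 24))))
  expect_equal(compute_overlap_fraction(0, 0, tri, 64), (24 * 24 / 2) / (64 * 64),
               tolerance = 1e-9)
  expect_lt(abs(compute_overlap_fraction(0, 0, tri, 64) -
                  raster_overlap_oracle(tri$polygons[[1]], 64)), 1e-3)

  none <- pathomsi:::new_roi_annotation("s", list(rbind(c(600, 600), c(700, 600), c(650, 700))))
  expect_equal(compute_overlap_fraction(0, 0, none, 512), 0)
})

test_that("overlap fraction matches the 16x super-sampled oracle on random polygons", {
  set.seed(7)
  for (i in 1:200) {
    ring <- random_simple_polygon(sample(3:10, 1))
    roi <- pathomsi:::new_roi_annotation("s", list(ring))
    expect_lt(abs(compute_overlap_fraction(0, 0, roi, 64) -
                    raster_overlap_oracle(ring, 64)), 1e-3)
  }
})

test_that("tiling keeps only patches strictly above the overlap threshold", {
  aligned <- pathomsi:::new_roi_annotation("s", list(rbind(c(0, 0), c(1024, 0),
                                                           c(1024, 1024), c(0, 1024))))
  tiles <- tile_slide(aligned, c(2048, 2048))
  expect_equal(nrow(tiles), 4)
  expect_true(all(tiles$overlap == 1))
  expect_equal(tiles$origin_x, tiles$grid_x * 512L)

  offset <- pathomsi:::new_roi_annotation("s", list(rbind(c(256, 0), c(768, 0),
                                                          c(768, 512), c(256, 512))))
  expect_equal(nrow(tile_slide(offset, c(2048, 512))), 0)  # both candidates at 0.5

  outside <- pathomsi:::new_roi_annotation("s", list(rbind(c(-10, 0), c(100, 0), c(50, 90))))
  expect_error(tile_slide(outside, c(512, 512)), "outside")
})

test_that("tiling is vertex-order invariant and monotone in the threshold", {
  set.seed(21)
  ring <- random_simple_polygon(8, centre = c(140, 130), r_range = c(40, 120))
  roi <- pathomsi:::new_roi_annotation("s", list(ring))
  fwd <- tile_slide(roi, c(512, 512), patch_size = 64, min_overlap = 0.5)
  rev_roi <- pathomsi:::new_roi_annotation("s", list(ring[rev(seq_len(nrow(ring))), ]))
  expect_equal(tile_slide(rev_roi, c(512, 512), patch_size = 64, min_overlap = 0.5), fwd)

  thresholds <- c(0.2, 0.5, 0.8, 0.95)
  counts <- vapply(thresholds, function(t) {
    nrow(tile_slide(roi, c(512, 512), patch_size = 64, min_overlap = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("retained patch set equals the brute-force rasterised filter", {
  set.seed(33)
  for (i in 1:5) {
    ring <- random_simple_polygon(7, centre = c(130, 120), r_range = c(30, 110))
    roi <- pathomsi:::new_roi_annotation("s", list(ring))
    got <- tile_slide(roi, c(256, 256), patch_size = 64, min_overlap = 0.8)
    keys <- character(0)
    for (gx in 0:3) for (gy in 0:3) {
      shifted <- cbind(ring[, 1] - gx * 64, ring[, 2] - gy * 64)
      if (raster_overlap_oracle(shifted, 64) > 0.8) {
        keys <- c(keys, paste(gx, gy))
      }
    }
    expect_setequal(paste(got$grid_x, got$grid_y), keys)
  }
})

test_that("preprocessing crops from the centre and z-scores channels", {
  img <- array(0.5, c(512, 512, 3))
  cfg <- preprocess_config(crop_size = 224, channel_mean = c(0.5, 0.5, 0.5),
                           channel_std = c(1, 1, 1))
  out <- preprocess_patch(img, cfg)
  expect_equal(dim(out), c(224, 224, 3))
  expect_true(all(out == 0))

  # crop provenance: 0-based output pixel (0,0) = input pixel (144,144)
  img2 <- array(0, c(512, 512, 3))
  img2[145, 145, ] <- 1
  cfg2 <- preprocess_config(crop_size = 224, channel_mean = c(0, 0, 0),
                            channel_std = c(1, 1, 1))
  out2 <- preprocess_patch(img2, cfg2)
  expect_equal(out2[1, 1, 1], 1)
  expect_equal(sum(out2), 3)

  expect_error(preprocess_patch(array(0, c(512, 512)), cfg), "H x W x 3")
})

test_that("pure-flip augmentation is an involution about the vertical axis", {
  set.seed(4)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  cfg <- preprocess_config(crop_size = 64, channel_mean = c(0, 0, 0),
                           channel_std = c(1, 1, 1), augment = TRUE,
                           rotation_deg = 0, shear_deg = 0, scale_range = c(1, 1))
  plain <- preprocess_patch(img, preprocess_config(crop_size = 64,
                                                   channel_mean = c(0, 0, 0),
                                                   channel_std = c(1, 1, 1)))
  seen_flip <- FALSE; seen_id <- FALSE
  for (i in 1:20) {
    aug <- preprocess_patch(img, cfg)
    if (isTRUE(all.equal(aug, plain))) seen_id <- TRUE
    if (isTRUE(all.equal(aug, plain[, 64:1, ]))) seen_flip <- TRUE
  }
  expect_true(seen_flip && seen_id)
})

test_that("magnification downsampling block-averages before the crop", {
  img <- array(0, c(8, 8, 3))
  img[1:2, 1:2, ] <- c(1, 1, 0, 0)  # one 2x2 block half-on
  down <- pathomsi:::block_downsample(img, 2L)
  expect_equal(dim(down), c(4, 4, 3))
  expect_equal(down[1, 1, 1], 0.5)
  expect_equal(sum(down), sum(img) / 4)

  big <- array(runif(128 * 128 * 3), c(128, 128, 3))
  cfg <- preprocess_config(crop_size = 32, channel_mean = c(0, 0, 0),
                           channel_std = c(1, 1, 1), magnification_factor = 4L)
  expect_equal(dim(preprocess_patch(big, cfg)), c(32, 32, 3))
})
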