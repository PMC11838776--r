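test_that("frame schedules validate timing and derive mid-times", {
  fs <- FrameSchedule(duration = c(rep(0.25, 4), rep(1, 2)))
  expect_equal(frameStart(fs), c(0, 0.25, 0.5, 0.75, 1, 2))
  expect_equal(frameMid(fs), frameStart(fs) + frameDuration(fs) / 2)
  expect_equal(scanEnd(fs), 3)
  expect_error(FrameSchedule(start = c(0, 1), duration = c(2, 1)),
               "overlap")
  expect_error(FrameSchedule(start = c(0, 1), duration = c(0.5, -1)),
               "> 0")
  expect_error(FrameSchedule(start = c(1, 0), duration = c(0.5, 0.5)),
               "increasing")
  expect_equal(nFrames(pbr28Schedule()), 26L)
  expect_equal(scanEnd(pbr28Schedule()), 90)
  expect_equal(nFrames(pbr28ShortSchedule()), 23L)
  expect_equal(scanEnd(pbr28ShortSchedule()), 60)
})

test_that("schedule files round-trip through CSV and YAML", {
  fs <- pbr28ShortSchedule()
  for (ext in c("csv", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    writeSchedule(fs, f)
    fs2 <- readSchedule(f)
    expect_equal(frameStart(fs2), frameStart(fs))
    expect_equal(frameDuration(fs2), frameDuration(fs))
    unlink(f)
  }
})

test_that("TAC tables are read from long and wide layouts with row checks", {
  fs <- pbr28Schedule()
  set.seed(1)
  act <- matrix(runif(6 * 26, 0, 50), 6, 26)
  te <- TacExperiment(act, fs,
                      subjectId = rep(c("s1", "s2"), each = 3),
                      roiId = rep(c("roiA", "roiB", "roiC"), 2))
  f <- tempfile(fileext = ".csv")
  writeTacTable(te, f)
  te2 <- readTacTable(f, fs)
  expect_equal(nrow(te2), 6L)        # 2 subjects x 3 ROIs
  # round-trip is bit-exact
  key <- function(x) order(rowData(x)$subject_id, rowData(x)$roi_id)
  expect_identical(unname(activity(te2)[key(te2), ]),
                   unname(activity(te)[key(te), ]))

  # losing one frame row breaks the format
  d <- read.csv(f)
  write.csv(d[-1, ], f, row.names = FALSE)
  expect_error(readTacTable(f, fs), "format error")

  # wide layout
  w <- data.frame(subject_id = rep(c("s1", "s2"), each = 3),
                  roi_id = rep(c("roiA", "roiB", "roiC"), 2))
  w <- cbind(w, as.data.frame(act))
  names(w)[-(1:2)] <- paste0("frame", 1:26)
  write.csv(w, f, row.names = FALSE)
  te3 <- readTacTable(f, fs)
  expect_equal(dim(activity(te3)), c(6L, 26L))
  write.csv(w[, -3], f, row.names = FALSE)   # frame column missing
  expect_error(readTacTable(f, fs), "format error")
  unlink(f)
})

test_that("ROI extraction averages labelled voxels inside the mask", {
  fs <- tinySchedule(3)
  img <- array(0, c(4, 4, 2, 3))
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, 1, 1] <- 1L
  img[1:2, 1, 1, ] <- 5.0
  te <- extractRoiTacs(img, atlas, schedule = fs, subjectId = "p1")
  expect_equal(unname(activity(te)[1, ]), rep(5, 3))

  # mask away the value-2 half of a mixed ROI
  img[1, 1, 1, ] <- 2; img[2, 1, 1, ] <- 4
  mask <- array(0L, c(4, 4, 2)); mask[2, 1, 1] <- 1L
  te2 <- extractRoiTacs(img, atlas, mask, fs)
  expect_equal(unname(activity(te2)[1, ]), rep(4, 3))

  # empty ROI is excluded with a warning, not silently dropped
  atlas[4, 4, 2] <- 2L
  expect_warning(te3 <- extractRoiTacs(img, atlas, mask, fs),
                 "no voxels")
  expect_equal(metadata(te3)$excluded_rois, "roi2")

  expect_error(extractRoiTacs(img, array(0L, c(3, 3, 2)), NULL, fs),
               "dimension error")
})

test_that("ROI means equal the brute-force voxel average, any voxel order", {
  fs <- tinySchedule(4)
  set.seed(42)
  img <- array(rnorm(5 * 5 * 3 * 4, 10, 2), c(5, 5, 3, 4))
  atlas <- array(sample(0:2, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
  te <- extractRoiTacs(img, atlas, schedule = fs)
  for (lab in 1:2) {
    vox <- which(atlas == lab, arr.ind = TRUE)
    brute <- sapply(1:4, function(fr) {
      mean(apply(vox, 1, function(v) img[v[1], v[2], v[3], fr]))
    })
    expect_equal(unname(activity(te)[paste0("subject.roi", lab), ]),
                 brute, tolerance = 1e-12)
  }
  # voxel ordering cannot matter: permute via array index relabelling
  perm <- aperm(img, c(2, 1, 3, 4))
  atlasPerm <- aperm(atlas, c(2, 1, 3))
  teP <- extractRoiTacs(perm, atlasPerm, schedule = fs)
  expect_equal(activity(teP), activity(te), tolerance = 1e-12)
})

test_that("subject and expression tables validate their contracts", {
  f <- tempfile(fileext = ".csv")
  s <- demoSubjects(c("a", "b"))
  write.csv(s, f, row.names = FALSE)
  expect_silent(readSubjectTable(f))
  s2 <- s; s2$weight[1] <- -1
  write.csv(s2, f, row.names = FALSE)
  expect_error(readSubjectTable(f), "weight")
  em <- data.frame(roi_id = c("r1", "r2"), expression = c(0.1, 0.9),
                   class_label = c("low", "high"))
  writeExpressionMap(em, f)
  expect_equal(readExpressionMap(f), em)
  em$class_label[1] <- "wrong"
  writeExpressionMap(em, f)
  expect_error(readExpressionMap(f), "class_label")
  unlink(f)
})
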