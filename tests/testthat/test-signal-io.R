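# Record readers/writers and fixed-length segmentation.

test_that("CSV records round-trip and report duration correctly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1", "0.2"), f)
  rec <- read_csv_record(f, fs = 360)
  expect_s3_class(rec, "ecg_record")
  expect_length(rec$samples, 2)
  expect_equal(rec$fs, 360)

  # duration = n / fs by construction
  rec2 <- sine_record(n = 3600, fs = 360)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_csv_record(rec2, f2)
  back <- read_csv_record(f2, fs = 360)
  expect_equal(length(back$samples) / back$fs, 10)
  expect_equal(back$samples, rec2$samples, tolerance = 1e-9)

  # header and index column are auto-detected
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,mV", "0,0.5", "1,0.7"), f3)
  expect_equal(read_csv_record(f3, fs = 100)$samples, c(0.5, 0.7))
})

test_that("CSV reader errors name the condition and the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_csv_record(f, fs = 360), "empty record")
  writeLines(c("0.1", "abc", "0.3"), f)
  expect_error(read_csv_record(f, fs = 360), "row 2")
})

test_that("WFDB records round-trip through header, signal and annotations", {
  dir <- withr::local_tempdir()
  ann <- data.frame(sample = c(100L, 500L, 920L),
                    symbol = c("N", "N", "V"))
  rec <- sine_record(n = 1000, fs = 360, record_id = "fx1",
                     annotations = ann)
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, "fx1"))
  expect_length(back$samples, 1000)
  expect_equal(back$fs, 360)
  # gain 200 quantization
  expect_equal(back$samples, rec$samples, tolerance = 1 / 200)
  expect_equal(back$annotations$sample, ann$sample)
  expect_equal(back$annotations$symbol, ann$symbol)
})

test_that("WFDB annotations survive long inter-annotation gaps", {
  f <- withr::local_tempfile(fileext = ".atr")
  ann <- data.frame(sample = c(10L, 5000L, 70000L),
                    symbol = c("N", "A", "V"))
  write_wfdb_annotations(ann, f)
  back <- read_wfdb_annotations(f)
  expect_equal(back$sample, ann$sample)
  expect_equal(back$symbol, ann$symbol)
})

test_that("multi-channel WFDB records yield channel 1 and format 212 decodes", {
  dir <- withr::local_tempdir()
  rec <- sine_record(n = 400, fs = 250, record_id = "two")
  extra <- matrix(cos(2 * pi * 3 * (0:399) / 250), nrow = 1)
  write_wfdb_record(rec, dir, extra_channels = extra)
  back <- read_wfdb_record(file.path(dir, "two"))
  expect_equal(back$samples, rec$samples, tolerance = 1 / 200)
  ch2 <- read_wfdb_record(file.path(dir, "two"), channel = 2)
  expect_equal(ch2$samples, as.vector(extra), tolerance = 1 / 200)

  dir2 <- withr::local_tempdir()
  rec2 <- sine_record(n = 501, fs = 360, record_id = "pk")  # odd length
  write_wfdb_record(rec2, dir2, format = 212L)
  back2 <- read_wfdb_record(file.path(dir2, "pk"))
  expect_length(back2$samples, 501)
  expect_equal(back2$samples, rec2$samples, tolerance = 1 / 200)
})

test_that("WFDB reader errors on missing header and unknown format codes", {
  dir <- withr::local_tempdir()
  expect_error(read_wfdb_record(file.path(dir, "nope")), "header not found")
  writeLines(c("bad 1 360 100", "bad.dat 80 200 12 0 0 0 0 ch1"),
             file.path(dir, "bad.hea"))
  writeBin(raw(200), file.path(dir, "bad.dat"))
  expect_error(read_wfdb_record(file.path(dir, "bad")), "format code: 80")
})

test_that("segmentation start indices and counts follow the window formula", {
  rec <- sine_record(n = 6000)
  expect_length(segment_record(rec, 2000, 2000), 3)
  expect_length(segment_record(sine_record(n = 1999), 2000), 0)
  segs <- segment_record(sine_record(n = 5000), 2000, 1000)
  expect_length(segs, 4)
  expect_equal(vapply(segs, function(s) s$start_index, integer(1)),
               c(0L, 1000L, 2000L, 3000L))
})

test_that("segment counts match a brute-force enumerator and never overrun", {
  set.seed(42)
  for (k in 1:40) {
    len <- sample(2:10000, 1)
    window <- sample(2:10000, 1)
    stride <- sample(1:5000, 1)
    rec <- ecg_record(numeric(len) + 1, fs = 360, record_id = "r")
    segs <- segment_record(rec, window, stride)
    expect_length(segs, count_windows_bruteforce(len, window, stride))
    if (length(segs)) {
      last <- segs[[length(segs)]]
      expect_lte(last$start_index + length(last$values), len)
      expect_length(last$values, window)
    }
  }
})

test_that("segment labels follow the majority rule with documented tie-break", {
  rec <- sine_record(n = 1000)
  segs <- segment_record(rec, 500, 500)
  unanimous <- data.frame(sample = c(10L, 100L, 400L, 600L),
                          symbol = c("N", "N", "N", "N"))
  lab <- label_segments(segs, unanimous)
  expect_equal(lab[[1]]$label, "N")

  majority <- data.frame(sample = c(10L, 100L, 200L, 400L),
                         symbol = c("N", "N", "N", "V"))
  expect_equal(label_segments(segs[1], majority)[[1]]$label, "N")

  # 2 vs 2 tie: N precedes PVC in the canonical class order
  tie <- data.frame(sample = c(10L, 100L, 200L, 400L),
                    symbol = c("N", "N", "V", "V"))
  expect_equal(label_segments(segs[1], tie)[[1]]$label, "N")

  # unmapped symbols exclude the segment, with a reported count
  odd <- data.frame(sample = c(550L), symbol = c("Z"))
  expect_message(out <- label_segments(segs[2], odd), "1 segment")
  expect_length(out, 0)
})
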