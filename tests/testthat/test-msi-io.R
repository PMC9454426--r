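test_that("imzML writing and reading round-trips a synthetic dataset", {
  sim <- generate_tma(small_config(seed = 31L))
  d <- sim$dataset
  td <- withr::local_tempdir()
  path <- file.path(td, "tma.imzML")
  write_imzml(d, path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(td, "tma.ibd")))

  write_annotations(d, file.path(td, "cores.tsv"), file.path(td, "mask.tsv"))
  ann <- read_annotations(file.path(td, "cores.tsv"), file.path(td, "mask.tsv"))
  back <- read_imzml(path, annotations = ann)
  # intensities survive the 32-bit round trip; metadata exactly
  expect_identical(back$pixels[c("x", "y", "core_id", "tissue")],
                   d$pixels[c("x", "y", "core_id", "tissue")])
  expect_identical(back$cores, d$cores)
  expect_equal(back$mz, d$mz, tolerance = 1e-12)
  expect_equal(back$intensities, d$intensities, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("an imzML file with zero spectra loads as an empty dataset", {
  d <- msi_dataset(matrix(0, 0, 0),
                   data.frame(x = integer(0), y = integer(0),
                              core_id = character(0), tissue = integer(0)),
                   data.frame(core_id = character(0), label = character(0)),
                   mz = numeric(0))
  td <- withr::local_tempdir()
  path <- file.path(td, "empty.imzML")
  write_imzml(d, path)
  back <- read_imzml(path)
  expect_equal(nrow(back$intensities), 0)
})

test_that("a one-pixel four-bin dataset writes one spectrum of length four", {
  sc <- binning_scheme(100, 100.04, 0.01)
  d <- msi_dataset(matrix(c(1, 2, 3, 4), 1, 4),
                   data.frame(x = 0, y = 0, core_id = "c1"),
                   data.frame(core_id = "c1", label = "A"),
                   mz = bin_centers(sc), scheme = sc)
  td <- withr::local_tempdir()
  write_imzml(d, file.path(td, "one.imzML"))
  doc <- xml2::read_xml(file.path(td, "one.imzML"))
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  expect_length(specs, 1)
  lens <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//cvParam[@accession='IMS:1000103']"), "value")
  expect_true(all(lens == "4"))
  back <- read_imzml(file.path(td, "one.imzML"))
  expect_equal(as.numeric(back$intensities[1, ]), c(1, 2, 3, 4))
})

test_that("missing files and malformed axes raise I/O and format errors", {
  td <- withr::local_tempdir()
  expect_error(read_imzml(file.path(td, "absent.imzML")), "no such file")
  sim <- generate_tma(small_config(seed = 37L))
  path <- file.path(td, "x.imzML")
  write_imzml(sim$dataset, path)
  file.remove(file.path(td, "x.ibd"))
  expect_error(read_imzml(path), "missing binary")
})

test_that("imzML files interoperate with an independent parser (pyimzml)", {
  python <- Sys.which("python")
  expect_true(nzchar(python))
  td <- withr::local_tempdir()

  # our writer -> pyimzml reader
  sc <- binning_scheme(100, 110, 0.5)
  set.seed(3)
  d <- msi_dataset(matrix(round(runif(3 * 20), 4), 3, 20),
                   data.frame(x = c(0, 1, 0), y = c(0, 0, 1),
                              core_id = "c1"),
                   data.frame(core_id = "c1", label = "A"),
                   mz = bin_centers(sc), scheme = sc)
  write_imzml(d, file.path(td, "ours.imzML"))
  script <- file.path(td, "roundtrip.py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "out = []",
    "for i, (x, y, z) in enumerate(p.coordinates):",
    "    mz, ints = p.getspectrum(i)",
    "    out.append({'x': int(x), 'y': int(y),",
    "                'mz': [float(v) for v in mz],",
    "                'ints': [float(v) for v in ints]})",
    "print(json.dumps(out))"), script)
  res <- system2(python, c(script, file.path(td, "ours.imzML")),
                 stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""),
                               simplifyDataFrame = FALSE)
  expect_length(parsed, 3)
  for (i in 1:3) {
    # pyimzml reports 1-based imzML coordinates
    expect_equal(parsed[[i]]$x, d$pixels$x[i] + 1)
    expect_equal(parsed[[i]]$y, d$pixels$y[i] + 1)
    expect_equal(parsed[[i]]$mz, d$mz, tolerance = 1e-12)
    expect_equal(parsed[[i]]$ints, as.numeric(d$intensities[i, ]),
                 tolerance = 1e-6)
  }

  # pyimzml writer with known peak lists -> our reader
  writer <- file.path(td, "write.py")
  writeLines(c(
    "import sys",
    "from pyimzml.ImzMLWriter import ImzMLWriter",
    "import numpy as np",
    "mz = np.array([100.0, 100.5, 101.0, 102.25])",
    "with ImzMLWriter(sys.argv[1], mode='continuous') as w:",
    "    w.addSpectrum(mz, np.array([1.0, 2.0, 3.0, 4.0]), (1, 1, 1))",
    "    w.addSpectrum(mz, np.array([5.0, 6.0, 7.0, 8.0]), (2, 1, 1))"),
    writer)
  status <- system2(python, c(writer, file.path(td, "theirs.imzML")),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  theirs <- read_imzml(file.path(td, "theirs.imzML"))
  expect_equal(nrow(theirs$intensities), 2)
  expect_equal(theirs$mz, c(100.0, 100.5, 101.0, 102.25))
  expect_equal(theirs$pixels$x, c(0, 1))   # shifted to 0-based
  expect_equal(as.numeric(theirs$intensities[1, ]), c(1, 2, 3, 4),
               tolerance = 1e-6)
  expect_equal(as.numeric(theirs$intensities[2, ]), c(5, 6, 7, 8),
               tolerance = 1e-6)
})

test_that("annotation tables are validated on load", {
  td <- withr::local_tempdir()
  core_path <- file.path(td, "cores.tsv")

  writeLines(c("core_id\tlabel", "c1\tAdCy", "c2\tControl"), core_path)
  ann <- read_annotations(core_path)
  expect_equal(nrow(ann$cores), 2)
  expect_equal(ann$classes, c("AdCy", "Control"))

  # the eight study classes form a class set of size 8
  cls8 <- c("Acin", "AdCy", "Anos", "Control", "Matrix", "MuEp", "SaDu", "Sec")
  writeLines(c("core_id\tlabel",
               paste(sprintf("c%d", 1:8), cls8, sep = "\t")), core_path)
  ann8 <- read_annotations(core_path)
  expect_length(ann8$classes, 8)
  expect_equal(sort(ann8$classes), cls8)

  # conflicting duplicate labels rejected
  writeLines(c("core_id\tlabel", "c1\tAdCy", "c1\tControl"), core_path)
  expect_error(read_annotations(core_path), "conflicting")

  # unknown label against a configured class list
  writeLines(c("core_id\tlabel", "c1\tWeird"), core_path)
  expect_error(read_annotations(core_path, classes = cls8), "unknown label")

  # a pixel claimed by two cores
  writeLines(c("core_id\tlabel", "c1\tAdCy", "c2\tControl"), core_path)
  mask_path <- file.path(td, "mask.tsv")
  writeLines(c("x\ty\tcore_id\ttissue", "0\t0\tc1\t1", "0\t0\tc2\t1"),
             mask_path)
  expect_error(read_annotations(core_path, mask_path), "two cores")
})

test_that("the msid container round-trips exactly", {
  sim <- generate_tma(small_config(seed = 41L))
  td <- withr::local_tempdir()
  p <- file.path(td, "d.msid")
  write_msid(sim$dataset, p)
  back <- read_msid(p)
  expect_equal(back$intensities, sim$dataset$intensities)
  expect_identical(back$pixels, sim$dataset$pixels)
  expect_error(read_msid(system.file("python", "densmap_embed.py",
                                     package = "maldinet")))
})

test_that("model checkpoints and reports round-trip through their files", {
  td <- withr::local_tempdir()
  arch <- arch_config(n_conv_blocks = 2L, channels = c(3L, 5L),
                      kernel_size = 3L, pool_size = 2L, n_classes = 3L)
  m <- build_model(arch, 64L, c("a", "b", "c"), seed = 2L)
  p <- file.path(td, "model.cnn")
  save_model(m, p)
  m2 <- load_model(p)
  x <- runif(64)
  expect_identical(predict_scores(m2, x), predict_scores(m, x))
  expect_identical(m2$class_order, m$class_order)
  expect_error(suppressWarnings(load_model(file.path(td, "nothere"))))

  sim <- generate_tma(small_config(seed = 47L))
  flt <- matrix_filter(sim$dataset, n_filter = 5L)
  jp <- file.path(td, "report.json")
  write_filter_report(flt$report, jp)
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$reference_mz, flt$report$reference_mz)
  expect_equal(nrow(back$selected_peaks), 5)

  preds <- data.frame(x = 0:1, y = 0, core_id = "c1", true = "A",
                      pred = c("A", "B"), fold = 0L,
                      score_A = c(1, 0.2), score_B = c(0, 0.8))
  tp <- file.path(td, "preds.tsv")
  write_predictions(preds, tp)
  back2 <- utils::read.table(tp, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  expect_equal(back2$pred, c("A", "B"))
  expect_equal(back2$score_B, c(0, 0.8))
})
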