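# Domain types, readers/writers and validation

test_that("plate layout encodes the fixed control design and rejects bad wells", {
  lay <- plate_layout()
  r <- roles(lay)
  expect_equal(sum(r == "sample"), 90)
  expect_equal(sort(names(r)[r == "neg_control"]), c("A12", "B12", "G12", "H12"))
  expect_equal(sort(names(r)[r == "pos_control"]), c("G1", "H1"))
  expect_error(plate_layout(neg_control_wells = "Z99"),
               class = "kinscreen_validation_error")
  expect_error(plate_layout(neg_control_wells = "A1", pos_control_wells = "A1"),
               class = "kinscreen_validation_error")
  expect_error(parse_well("A01"), class = "kinscreen_validation_error")
})

test_that("layout and library tables round-trip through TSV", {
  sim <- small_screen(3)
  dir <- withr::local_tempdir()
  lp <- file.path(dir, "layout.tsv")
  write_layout(sim$layout, lp)
  lay2 <- read_layout(lp)
  expect_identical(roles(lay2), roles(sim$layout))

  bp <- file.path(dir, "library.tsv")
  write_sirna_library(sim$library, bp)
  lib2 <- read_sirna_library(bp)
  expect_equal(as.data.frame(lib2), as.data.frame(sim$library))
})

test_that("siRNA library invariants are enforced", {
  df <- data.frame(sirna_id = c("a1", "a2", "a3"), gene = "A",
                   plate = 1, well = c("A1", "A2", "A3"))
  expect_s3_class(sirna_library(df), "sirna_library")
  expect_error(sirna_library(df[1:2, ]), class = "kinscreen_validation_error")
  dup <- df; dup$well <- "A1"
  expect_error(sirna_library(dup), class = "kinscreen_validation_error")
  expect_silent(sirna_library(df[1:2, ], check = FALSE))
})

test_that("readouts round-trip bit-exactly and violations are caught", {
  sim <- small_screen(4)
  dir <- withr::local_tempdir()
  rp <- file.path(dir, "readouts.tsv")
  write_readouts(sim$screen, rp)
  back <- read_readouts(rp, sim$layout, sim$library)
  a <- sim$screen$values
  b <- back$values
  a <- a[order(a$replicate, a$plate, a$well, a$channel, method = "radix"), ]
  b <- b[order(b$replicate, b$plate, b$well, b$channel, method = "radix"), ]
  expect_identical(a$value, b$value)  # full float precision
  expect_identical(a$well, b$well)

  # 4-row file: one well, two channels, two replicates
  tiny <- file.path(dir, "tiny.tsv")
  writeLines(c("experiment\tplate\twell\tchannel\tvalue",
               "1\t1\tA1\tEROD\t10.5", "1\t1\tA1\tMB\t1.25",
               "2\t1\tA1\tEROD\t11.5", "2\t1\tA1\tMB\t1.5"), tiny)
  ds <- read_readouts(tiny, sim$layout, sim$library)
  expect_equal(ds$n_replicates, 2)
  v <- ds$values
  expect_equal(v$value[v$replicate == 2 & v$channel == "EROD"], 11.5)

  neg <- file.path(dir, "neg.tsv")
  writeLines(c("experiment\tplate\twell\tchannel\tvalue",
               "1\t1\tA1\tEROD\t-1"), neg)
  expect_error(read_readouts(neg, sim$layout, sim$library),
               class = "kinscreen_validation_error")

  nohdr <- file.path(dir, "nohdr.tsv")
  writeLines(c("experiment\tplate\twell\tchannel", "1\t1\tA1\tEROD"), nohdr)
  expect_error(read_readouts(nohdr, sim$layout, sim$library),
               class = "kinscreen_format_error")

  badwell <- file.path(dir, "badwell.tsv")
  writeLines(c("experiment\tplate\twell\tchannel\tvalue",
               "1\t1\tQ7\tEROD\t3"), badwell)
  expect_error(read_readouts(badwell, sim$layout, sim$library),
               class = "kinscreen_validation_error")
})

test_that("kinetic rows are grouped into traces and reduced to slopes", {
  dir <- withr::local_tempdir()
  kp <- file.path(dir, "kin.tsv")
  writeLines(c("experiment\tplate\twell\tchannel\ttime\tfluorescence\tvalue",
               "1\t1\tA1\tEROD\t0\t100\tNA",
               "1\t1\tA1\tEROD\t5\t150\tNA",
               "1\t1\tA1\tEROD\t10\t200\tNA",
               "1\t1\tA1\tEROD\t15\t250\tNA",
               "1\t1\tA1\tMB\tNA\tNA\t1.5"), kp)
  lay <- plate_layout()
  lib <- sirna_library(data.frame(sirna_id = c("a1", "a2", "a3"), gene = "A",
                                  plate = 1, well = c("A1", "A2", "A3")))
  ds <- read_readouts(kp, lay, lib)
  v <- ds$values
  expect_equal(v$value[v$channel == "EROD"], 10)
  expect_length(ds$traces, 1)
})

test_that("validation report is empty iff the screen is complete", {
  sim <- small_screen(5)
  rep0 <- validate_screen(sim$screen, sim$layout, sim$library)
  expect_true(rep0$complete)
  expect_equal(nrow(rep0$missing), 0)

  # delete one well-value
  scr <- sim$screen
  drop <- with(scr$values, which(replicate == 2 & plate == 1 &
                                   well == "B3" & channel == "EROD"))
  scr$values <- scr$values[-drop, ]
  scr <- screen_dataset(scr$values, scr$traces)
  rep1 <- validate_screen(scr, sim$layout, sim$library)
  expect_false(rep1$complete)
  expect_equal(rep1$missing$replicate, 2)
  expect_equal(rep1$missing$well, "B3")

  # gene with 2 siRNAs when r = 3
  lib <- sim$library[-1, ]
  lib2 <- sirna_library(as.data.frame(lib), check = FALSE)
  rep2 <- validate_screen(sim$screen, sim$layout, lib2)
  expect_true(sim$library$gene[1] %in% rep2$incomplete_genes$gene)
})

test_that("GMT parsing handles the standard, duplicate and empty cases", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.gmt")
  writeLines("T1\tdesc\tA\tB\tC", p)
  ann <- read_gmt(p)
  expect_equal(ann$term_map$T1, c("A", "B", "C"))
  expect_equal(ann$universe, c("A", "B", "C"))

  writeLines("T1 desc A B B C", p)  # whitespace + duplicate gene
  expect_equal(read_gmt(p)$term_map$T1, c("A", "B", "C"))

  writeLines("T1\tdesc", p)
  expect_error(read_gmt(p), class = "kinscreen_format_error")

  writeLines(character(), p)
  empty <- read_gmt(p)
  expect_length(empty$term_map, 0)
  expect_equal(nrow(enrich_hits(c("A"), empty)), 0)
})

test_that("screen config round-trips through YAML and checks invariants", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.yaml")
  cfg <- screen_config(top_k = 99, min_concordant = 3, mb_floor = 0.2)
  write_screen_config(cfg, cfgp)
  expect_equal(read_screen_config(cfgp), cfg)
  expect_error(screen_config(min_concordant = 4, sirnas_per_gene = 3),
               class = "kinscreen_argument_error")
  expect_error(screen_config(top_k = 1, min_concordant = 2),
               class = "kinscreen_argument_error")
  expect_error(screen_config(viability_z_threshold = 0),
               class = "kinscreen_argument_error")
})
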