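test_that("fpc dialect round-trips on randomized fixtures", {
  for (seed in c(3, 17, 42)) {
    map <- random_map(seed)
    path <- withr::local_tempfile(fileext = ".fpc")
    write_fpc(map, path)
    map2 <- read_fpc(path, quiet = TRUE)
    expect_equal(map2$clones, map$clones)
    expect_equal(clone_fingerprints(map2, map$clones$clone),
                 clone_fingerprints(map, map$clones$clone))
  }
})

test_that("sidecar band files are equivalent to inline bands", {
  map <- random_map(5)
  path <- withr::local_tempfile(fileext = ".fpc")
  write_fpc(map, path, bands = "sidecar")
  expect_true(file.exists(paste0(path, ".bands")))
  map2 <- read_fpc(path, bands_path = paste0(path, ".bands"), quiet = TRUE)
  expect_equal(clone_fingerprints(map2, map$clones$clone),
               clone_fingerprints(map, map$clones$clone))
})

test_that("fpc parser classifies clones and reports errors with line numbers", {
  path <- withr::local_tempfile(fileext = ".fpc")
  writeLines(c('BAC : "AA001A1"',
               'Map "ctg1" Ends Left 0 Right 10',
               'BAC : "AA001A2"',
               'Map "ctg1" Ends Left 5 Right 15',
               'BAC : "AA001A3"',          # no Map -> unassembled
               'BAC : "AA001A4"',
               'Map "ctg0" Ends Left 0 Right 9'), path)
  map <- read_fpc(path, quiet = TRUE)
  expect_equal(map$clones$status,
               c("contig", "contig", "unassembled", "singleton"))
  expect_equal(length(map$members), 1)

  writeLines(c('BAC : "AA001A1"', 'BAC : "AA001A1"'), path)
  expect_error(read_fpc(path, quiet = TRUE), "line 2.*duplicate",
               class = "pooldeconv_parse_error")
  writeLines(c('BAC : "AA001A1"', 'Bogus record'), path)
  expect_error(read_fpc(path, quiet = TRUE), "line 2.*unknown record")
  writeLines('Map "ctg1" Ends Left 0 Right 10', path)
  expect_error(read_fpc(path, quiet = TRUE), "before any BAC")
})

test_that("pool hit files parse, validate and round-trip", {
  d <- build_design(ae_tauschii_libraries(), matrix_shape = c(27, 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "marker\trsp\tcsp\trp\tcp",
               "BE442608\t2,5,9,11,20\t1,3,8,14,22,30\tHB/A,BB/N\tHB/7,BB/18",
               "EMPTY\t\t\t\t"), path)
  hits <- read_pool_hits(path, d)
  expect_length(hits, 2)
  expect_length(hits[[1]]$rsp, 5)
  expect_length(hits[[1]]$csp, 6)
  expect_equal(hits[[1]]$rp, c("BB/N", "HB/A"))
  expect_length(hits[[2]]$rsp, 0)
  expect_length(hits[[2]]$cp, 0)

  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_pool_hits(hits, p2)
  expect_equal(read_pool_hits(p2, d), hits)

  writeLines(c("marker\trsp\tcsp\trp\tcp",
               "M1\t99\t1\tHB/A\tHB/1"), path)
  expect_error(read_pool_hits(path, d), "M1.*RSP index outside matrix",
               class = "pooldeconv_parse_error")
  writeLines(c("marker\trsp\tcsp\trp\tcp",
               "M1\t1\t1\tZZ/A\tHB/1"), path)
  expect_error(read_pool_hits(path, d), "M1.*unknown sub-pool")
  writeLines(c("marker\trsp\tcsp\trp\tcp",
               "M1\t1\t1\tHB-A\tHB/1"), path)
  expect_error(read_pool_hits(path, d), "malformed RP")
})

test_that("matrix design files round-trip and rebuild the design", {
  d <- build_design(list(library_spec("AA", 3), library_spec("BB", 2)),
                    c(2, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_design(d, path)
  md <- read_matrix_design(path)
  expect_equal(unname(md), unname(d$matrix$cells))
  d2 <- design_from_matrix(md)
  expect_equal(d2$plates, d$plates)
  expect_equal(d2$matrix$cells, d$matrix$cells)
})

test_that("write_outputs emits summary, anchored and ACE files", {
  mk <- function(marker, status, solutions, assigned, cand) {
    structure(list(marker = marker, status = status, solutions = solutions,
                   assigned = assigned, candidates = cand,
                   diagnostics = list(n_plates = 1, n_candidates = length(cand),
                                      n_in_contigs = length(cand),
                                      n_singletons = 0, n_unassembled = 0,
                                      per_sub = c(AA = length(cand)),
                                      note = NA_character_)),
              class = "deconv_result")
  }
  five <- c("BB092N18", "BB070C1", "HB086J7", "HI137N13", "HB006B8")
  res <- list(
    mk("M1", "unique",
       list(list(contig = "ctg4985", clones = five, nc = 5, mc = 5, fn = 0,
                 score = 1)), five, five),
    mk("M2", "non_unique",
       list(list(contig = "ctg1", clones = c("AA001A1", "AA002B2"), nc = 2,
                 mc = 2, fn = 0, score = 1),
            list(contig = "ctg2", clones = c("AA003C3", "AA004D4"), nc = 2,
                 mc = 2, fn = 0, score = 1)),
       c("AA001A1", "AA002B2", "AA003C3", "AA004D4"),
       c("AA001A1", "AA002B2", "AA003C3", "AA004D4")),
    mk("M3", "no_solution", list(), character(0), character(0)))

  dir <- withr::local_tempdir()
  paths <- write_outputs(res, dir)
  expect_true(all(file.exists(paths)))

  smry <- read.delim(paths[["summary"]], comment.char = "#")
  expect_equal(nrow(smry), 3)
  expect_equal(smry$status, c("unique", "non_unique", "no_solution"))
  expect_equal(smry$contig[2], "ctg1;ctg2")

  anch <- read.delim(paths[["anchored"]], comment.char = "#")
  expect_equal(nrow(anch), 1)  # unique only
  expect_equal(anch$contig, "ctg4985")
  expect_equal(sort(strsplit(anch$clones, ",")[[1]]), sort(five))

  ace <- read.delim(paths[["ace"]], comment.char = "#", header = FALSE)
  expect_equal(nrow(ace), 5)
  expect_setequal(ace$V2, five)
  expect_true(all(ace$V3 == "ctg4985"))

  # zero markers: valid files with headers
  paths0 <- write_outputs(list(), withr::local_tempdir())
  smry0 <- read.delim(paths0[["summary"]], comment.char = "#")
  expect_equal(nrow(smry0), 0)
  expect_true("marker" %in% names(smry0))
})

test_that("simulated truth round-trips through TSV", {
  sim <- small_clean_sim(seed = 21, n_markers = 5)
  dir <- withr::local_tempdir()
  write_sim_truth(sim$truth, file.path(dir, "truth.tsv"),
                  hits_path = file.path(dir, "truth_hits.tsv"))
  tr <- read_sim_truth(file.path(dir, "truth.tsv"),
                       hits_path = file.path(dir, "truth_hits.tsv"))
  expect_equal(tr$tp_clones, sim$truth$tp_clones)
  expect_equal(tr$true_hits, sim$truth$true_hits)
})
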