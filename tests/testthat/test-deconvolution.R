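test_that("fingerprint relations follow set semantics", {
  expect_true(fp_contains(c(1, 2), c(1, 2, 3)))
  expect_false(fp_contains(c(1, 2, 3), c(1, 2)))
  expect_true(fp_spans(c(1, 2, 3), c(3, 4, 5), c(2, 3, 4)))
  expect_false(fp_spans(c(1, 2), c(5, 6), c(2, 3)))
  expect_false(fp_overlaps(c(1, 2), c(9, 10)))
  expect_true(fp_overlaps(c(1, 2, 3), c(3, 4), min_shared = 1))
  expect_false(fp_overlaps(c(1, 2, 3), c(3, 4), min_shared = 2))
  expect_false(fp_overlaps(integer(0), c(1, 2)))

  # band tolerance: greedy one-to-one matching in sorted order
  expect_equal(match_bands(c(10, 20, 30), c(11, 19, 31), tol = 1), 3)
  expect_equal(match_bands(c(10, 20, 30), c(11, 19, 31), tol = 0), 0)
  expect_equal(match_bands(c(10, 11), c(10), tol = 1), 1)  # one-to-one
  expect_true(fp_contains(c(10, 20), c(9, 21, 50), tol = 1))
})

test_that("plate_intersections excludes empty cells", {
  d <- build_design(ae_tauschii_libraries(), matrix_shape = c(27, 30))
  expect_length(plate_intersections(1:5, 1:6, d), 30)
  expect_length(plate_intersections(1, 1, d), 1)
  expect_length(plate_intersections(integer(0), 1:3, d), 0)

  # 2x2 block with one empty cell -> 3 plates (enumeration oracle)
  d3 <- build_design(list(library_spec("AA", 3)), c(2, 2))
  got <- plate_intersections(1:2, 1:2, d3)
  manual <- d3$matrix$cells[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))]
  expect_equal(got, sort(manual[!is.na(manual)]))
  expect_length(got, 3)
})

test_that("candidate counts reproduce the 256 / 64 / 60 arithmetic", {
  # 4x genome equivalents, one undivided pool stack: 16 plates x 4 RP x 4 CP
  d1 <- build_design(list(library_spec("ZZ", 16)), c(4, 4))
  cand1 <- candidate_clones(plate_intersections(1:4, 1:4, d1),
                            paste0("ZZ/", c("A", "B", "C", "D")),
                            paste0("ZZ/", 1:4), d1)
  expect_length(cand1$clones, 256)

  # same screen split into 4 sub-pools of 1x: (4 x 4 x 1 x 1) x 4 = 64
  d4 <- build_design(lapply(c("WA", "WB", "WC", "WD"), library_spec,
                            n_plates = 4), c(4, 4))
  tp <- c("WA001A1", "WB002B2", "WC003C3", "WD004D4")
  th <- lapply(tp, true_pool_hits, design = d4)
  rsp <- vapply(th, `[[`, 1L, "RSP"); csp <- vapply(th, `[[`, 1L, "CSP")
  rp <- vapply(th, `[[`, "", "RP"); cp <- vapply(th, `[[`, "", "CP")
  expect_length(unique(rsp), 4)  # distinct plates, rows, columns
  plates <- plate_intersections(rsp, csp, d4)
  expect_length(plates, 16)

  cand_off <- candidate_clones(plates, rp, cp, d4, library_filter = FALSE)
  expect_length(cand_off$clones, 64)
  expect_equal(unname(cand_off$per_sub), rep(16L, 4))
  expect_true(all(tp %in% cand_off$clones))
  expect_length(setdiff(cand_off$clones, tp), 60)

  # library filtering cuts each sub-pool to its own plates
  cand_on <- candidate_clones(plates, rp, cp, d4, library_filter = TRUE)
  expect_length(cand_on$clones, 16)
  expect_true(all(tp %in% cand_on$clones))

  expect_length(candidate_clones(plates, character(0), cp, d4)$clones, 0)
})

test_that("candidate sets equal brute-force well enumeration", {
  set.seed(99)
  designs <- list(
    build_design(list(library_spec("AA", 1)), c(1, 1)),
    build_design(list(library_spec("AA", 2), library_spec("BB", 2)), c(2, 2)),
    build_design(list(library_spec("AA", 3)), c(2, 2)))
  for (rep in 1:20) {
    d <- designs[[sample(length(designs), 1)]]
    rsp <- sample(d$matrix$n_rows, sample(0:d$matrix$n_rows, 1))
    csp <- sample(d$matrix$n_cols, sample(0:d$matrix$n_cols, 1))
    subs <- d$sub_pools
    rp <- paste0(sample(subs, 2, replace = TRUE), "/",
                 sample(LETTERS[1:16], 2))
    cp <- paste0(sample(subs, 2, replace = TRUE), "/", sample(1:24, 2))
    for (filt in c(TRUE, FALSE)) {
      got <- candidate_clones(plate_intersections(rsp, csp, d), rp, cp, d,
                              library_filter = filt)$clones
      expect_equal(got, oracle_candidates(d, rsp, csp, rp, cp, filt))
    }
  }
})

test_that("find_c2 returns relation-graph components of size >= 2", {
  fps <- list(a = c(1, 2), b = c(2, 3), c = c(3, 4), d = c(4, 5),
              e = c(5, 6))
  expect_equal(find_c2(letters[1:5], fps), list(letters[1:5]))

  fps2 <- list(a = c(1, 2), b = c(9, 10))
  expect_equal(find_c2(c("a", "b"), fps2), list())
  expect_equal(find_c2("a", fps2), list())

  fps3 <- list(a = c(1, 2), b = c(2, 3), c = c(10, 11), d = c(11, 12))
  got <- find_c2(c("a", "b", "c", "d"), fps3)
  expect_equal(length(got), 2)
  expect_setequal(got[[1]], c("a", "b"))
  expect_setequal(got[[2]], c("c", "d"))

  # inclusion links even without min_shared overlap
  fps4 <- list(a = c(5), b = c(4, 5, 6))
  expect_equal(find_c2(c("a", "b"), fps4, min_shared = 2),
               list(c("a", "b")))

  # spanning links a clone that shares < min_shared bands with each
  # neighbour individually
  fps5 <- list(a = c(1, 2), b = c(3, 4), c = c(2, 3))
  got5 <- find_c2(c("a", "b", "c"), fps5, min_shared = 2)
  expect_equal(length(got5), 1)
  expect_setequal(got5[[1]], c("a", "b", "c"))
})

test_that("count_fn counts interior non-candidate clones", {
  members <- data.frame(clone = paste0("c", 1:5),
                        left = c(0, 10, 20, 30, 40),
                        right = c(15, 25, 35, 45, 55))
  expect_equal(count_fn(c("c1", "c5"), members, c("c1", "c5")), 3)
  expect_equal(count_fn(c("c1", "c2"), members, c("c1", "c2")), 0)
  expect_equal(count_fn(c("c1", "c3"), members, c("c1", "c3", "c2")), 0)
  expect_error(count_fn(c("c1", "zz"), members, "c1"), "not in contig")
})

test_that("deconv_score evaluates the discrimination formula", {
  expect_equal(deconv_score(5, 5, 0), 1.0)
  expect_equal(deconv_score(2, 4, 1), 0.5)
  expect_equal(deconv_score(2, 2, 12), -0.2)
  expect_error(deconv_score(2, 0, 0), "MC")
  expect_error(deconv_score(2, 2, -1), "FN")
  # score bound: <= 1 over random valid inputs
  set.seed(4)
  for (i in 1:100) {
    mc <- sample(2:10, 1); nc <- sample(2:mc, 1); fn <- sample(0:20, 1)
    expect_lte(deconv_score(nc, mc, fn), 1 + 1e-12)
  }
})

test_that("deconvolute_marker recovers a planted clone set", {
  sc <- planted_scenario()
  res <- deconvolute_marker(sc$hits, sc$design, sc$map)
  expect_equal(res$status, "unique")
  expect_equal(res$assigned, sort(sc$tp))
  expect_equal(res$solutions[[1]]$contig, "ctg1")
  expect_equal(res$solutions[[1]]$fn, 1)  # AA001P24 interior, not candidate
  expect_lt(res$solutions[[1]]$score, 1)
  expect_equal(res$diagnostics$n_in_contigs, 3)
})

test_that("deconvolute_marker handles failure modes and ties", {
  sc <- planted_scenario()
  # empty screening results
  res0 <- deconvolute_marker(marker_hits("Mx"), sc$design, sc$map)
  expect_equal(res0$status, "no_solution")
  expect_equal(res0$diagnostics$note, "screening failure")

  # candidates exist but no contig holds two of them
  lone <- marker_hits("My", rsp = 1, csp = 1, rp = "AA/A", cp = "AA/1")
  res1 <- deconvolute_marker(lone, sc$design, sc$map)
  expect_equal(res1$status, "no_solution")
  expect_length(res1$solutions, 0)

  # two contigs with identical top scores -> non-unique
  d <- build_design(list(library_spec("AA", 4)), c(2, 2))
  fps <- list(AA001A1 = c(1, 2), AA002A2 = c(2, 3),
              AA003B1 = c(50, 51), AA004B2 = c(51, 52))
  map <- make_map(clone = names(fps), contig = c("ctg1", "ctg1", "ctg2", "ctg2"),
                  left = c(0, 5, 0, 5), right = c(10, 15, 10, 15), fps = fps)
  hits <- marker_hits("Mz", rsp = 1:2, csp = 1:2,
                      rp = c("AA/A", "AA/B"), cp = c("AA/1", "AA/2"))
  res2 <- deconvolute_marker(hits, d, map)
  expect_equal(res2$status, "non_unique")
  expect_length(res2$solutions, 2)
  expect_setequal(res2$assigned, names(fps))
})

test_that("clean simulated markers deconvolute to the planted TP set", {
  sim <- small_clean_sim(seed = 13, n_markers = 20)
  res <- deconvolute(sim$hits, sim$design, sim$map)
  for (r in res) {
    expect_true(r$status %in% c("unique", "non_unique"))
    expect_true(all(r$assigned %in% sim$truth$tp_clones[[r$marker]]))
  }
  df <- as.data.frame(res)
  expect_equal(nrow(df), 20)
  expect_true(all(df$n_candidates >= df$n_in_contigs))
})
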