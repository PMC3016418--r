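# Shared fixtures and independent oracles.

# Independent brute-force candidate enumeration over every well of the
# design (the oracle for candidate_clones). With library_filter = TRUE a
# clone is a candidate iff its plate lies at a positive RSP x CSP
# intersection and its own RP and CP pools are positive; with the filter
# off, iff any sub-pool has both its well row and well column positive.
oracle_candidates <- function(design, rsp, csp, rp, cp,
                              library_filter = TRUE) {
  hit_subs_rows <- strsplit(rp, "/", fixed = TRUE)
  hit_subs_cols <- strsplit(cp, "/", fixed = TRUE)
  out <- character(0)
  for (i in seq_len(nrow(design$plates))) {
    p <- design$plates[i, ]
    if (!(p$matrix_row %in% rsp) || !(p$matrix_col %in% csp)) next
    for (r in LETTERS[1:16]) {
      for (cc in 1:24) {
        ok <- if (library_filter) {
          (paste0(p$sub_pool, "/", r) %in% rp) &&
            (paste0(p$sub_pool, "/", cc) %in% cp)
        } else {
          any(vapply(design$sub_pools, function(s) {
            (paste0(s, "/", r) %in% rp) && (paste0(s, "/", cc) %in% cp)
          }, TRUE))
        }
        if (ok) {
          out <- c(out, sprintf("%s%03d%s%d", p$library, p$plate, r, cc))
        }
      }
    }
  }
  sort(unique(out))
}

# Enumeration oracle for expected_intersections: place g positive plates
# in distinct rows and columns of a large matrix and count row x column
# intersections directly.
oracle_intersections <- function(g, n = 10) {
  m <- matrix(FALSE, n, n)
  rows <- seq_len(g); cols <- seq_len(g)  # distinct by construction
  cells <- expand.grid(r = rows, c = cols)
  truth <- cells$r == cells$c  # plate k at (k, k)
  list(intersections = nrow(cells), false_positives = sum(!truth))
}

# A tiny contig map built from explicit clone tables.
make_map <- function(clone, contig, left, right, status = NULL, fps = NULL) {
  if (is.null(status)) {
    status <- ifelse(is.na(contig), "unassembled", "contig")
  }
  contig_map(data.frame(clone = clone, contig = contig, left = left,
                        right = right, status = status,
                        stringsAsFactors = FALSE),
             fingerprints = fps)
}

# Random small contig map for round-trip properties.
random_map <- function(seed) {
  set.seed(seed)
  n_ctg <- sample(1:3, 1)
  clone <- character(0); contig <- character(0)
  left <- numeric(0); right <- numeric(0); status <- character(0)
  fps <- list()
  k <- 0
  for (g in seq_len(n_ctg)) {
    sz <- sample(2:4, 1)
    pos <- 0
    for (j in seq_len(sz)) {
      k <- k + 1
      nm <- sprintf("AA%03d%s%d", k, sample(LETTERS[1:16], 1), sample(1:24, 1))
      clone <- c(clone, nm); contig <- c(contig, sprintf("ctg%d", g))
      left <- c(left, pos); right <- c(right, pos + sample(5:20, 1))
      pos <- pos + sample(1:10, 1)
      status <- c(status, "contig")
      fps[[nm]] <- sort(sample(1:500, sample(3:12, 1)))
    }
  }
  # a singleton and an unassembled clone
  clone <- c(clone, "AA900A1", "AA901B2")
  contig <- c(contig, NA, NA)
  left <- c(left, 100, NA); right <- c(right, 120, NA)
  status <- c(status, "singleton", "unassembled")
  fps[["AA900A1"]] <- sort(sample(1:500, 5))
  make_map(clone, contig, left, right, status, fps)
}

# Deterministic scenario with a planted marker: one library, clones
# chained in one contig, plus pool hits derived from the planted clones.
planted_scenario <- function() {
  design <- build_design(list(library_spec("AA", 4)), c(2, 2))
  tp <- c("AA001A1", "AA002B2", "AA003C3")
  # chained fingerprints; contig also holds a non-candidate interior clone
  fps <- list(AA001A1 = c(1, 2, 3), AA002B2 = c(3, 4, 5),
              AA003C3 = c(5, 6, 7), AA004D4 = c(100, 101),
              AA001P24 = c(2, 3, 4))
  map <- make_map(
    clone = c("AA001A1", "AA002B2", "AA001P24", "AA003C3", "AA004D4"),
    contig = c("ctg1", "ctg1", "ctg1", "ctg1", "ctg2"),
    left = c(0, 10, 15, 20, 0), right = c(15, 25, 30, 35, 10),
    fps = fps)
  th <- lapply(tp, true_pool_hits, design = design)
  hits <- marker_hits("Mk1",
                      rsp = vapply(th, `[[`, 1L, "RSP"),
                      csp = vapply(th, `[[`, 1L, "CSP"),
                      rp = vapply(th, `[[`, "", "RP"),
                      cp = vapply(th, `[[`, "", "CP"))
  list(design = design, map = map, hits = hits, tp = tp)
}

# Small clean simulation shared by several tests.
small_clean_sim <- function(seed = 11, n_markers = 25) {
  simulate_screening(sim_config(
    genome_length = 300, band_site_density = 100,
    libraries = list(list(code = "HB", coverage = 1),
                     list(code = "BB", coverage = 1)),
    n_markers = n_markers, min_tp = 2, seed = seed))
}
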