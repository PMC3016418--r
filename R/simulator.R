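# Seeded synthetic-data generator: interval clones on an abstract circular
# genome, band-site fingerprints, perfect contigs from interval overlaps,
# point markers, and pool screening with injectable per-pool-kind F+/F-
# rates. Everything downstream (design, I/O, deconvolution, evaluation) is
# testable against the generated truth without external data.

POOL_KINDS <- c("RSP", "CSP", "RP", "CP")

normalize_rates <- function(p, what) {
  if (length(p) == 1L && is.null(names(p))) {
    p <- stats::setNames(rep(as.numeric(p), 4L), POOL_KINDS)
  }
  p <- p[POOL_KINDS]
  names(p) <- POOL_KINDS
  p[is.na(p)] <- 0
  if (any(p < 0 | p > 1)) stop(what, " rates must be in [0, 1]")
  p
}

#' The five-library BAC collection used as the design-scale example
#'
#' A 302,976-clone, 789-plate, 8.5x genome-equivalent collection of five
#' BAC/BiBAC libraries of the wheat D-genome ancestor *Aegilops tauschii*
#' (codes RI, HB, BB, HI, HD; 1.6-1.9x coverage each), screened as a
#' 27 x 30 super-pool matrix with one row/column sub-pool per library.
#'
#' @return data.frame with columns `code`, `n_clones`, `n_plates`,
#'   `coverage`.
#' @export
ae_tauschii_libraries <- function() {
  data.frame(
    code = c("RI", "HB", "BB", "HI", "HD"),
    n_clones = c(54144L, 59904L, 76800L, 59904L, 52224L),
    n_plates = c(141L, 156L, 200L, 156L, 136L),
    coverage = c(1.6, 1.6, 1.9, 1.8, 1.6),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The defaults emulate the screening regime of a multi-library 8.5x
#' collection at desk scale: five libraries with 1.6-1.9x coverage each,
#' insert length 1 +- 0.15 abstract units, a dense lattice of fingerprint
#' band sites, and 55 markers. Error rates default to zero; realistic
#' screening error magnitudes are of order 0-0.3 per pool.
#'
#' @param genome_length Abstract genome length (units of one mean insert).
#' @param band_site_density Fingerprint band sites per genome unit (sites
#'   sit on a regular lattice; a clone's fingerprint is the set of site ids
#'   inside its interval, so interval overlap and shared bands coincide
#'   whenever the overlap holds at least one site).
#' @param libraries List of library descriptions: each a list with `code`
#'   and either `coverage` (genome equivalents) or `n_clones`, plus
#'   optional `insert_mean`, `insert_sd`.
#' @param insert_mean,insert_sd Default insert length distribution
#'   (normal, clamped to `[0.2, 2] * insert_mean`).
#' @param n_markers Number of point markers.
#' @param min_tp Resample marker positions until at least this many clones
#'   contain the marker (0 = unconstrained).
#' @param p_fp,p_fn Per-pool false-positive / false-negative probabilities;
#'   scalar or named vector with elements RSP, CSP, RP, CP.
#' @param p_unassembled Fraction of clones excluded from contig assembly
#'   (fingerprinting failures).
#' @param matrix_shape Optional super-pool matrix shape.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(genome_length = 2000,
                       band_site_density = 200,
                       libraries = list(
                         list(code = "RI", coverage = 1.6),
                         list(code = "HB", coverage = 1.6),
                         list(code = "BB", coverage = 1.9),
                         list(code = "HI", coverage = 1.8),
                         list(code = "HD", coverage = 1.6)),
                       insert_mean = 1.0, insert_sd = 0.15,
                       n_markers = 55, min_tp = 0,
                       p_fp = 0, p_fn = 0, p_unassembled = 0,
                       matrix_shape = NULL, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory in sim_config()")
  }
  if (genome_length <= 0) stop("genome_length must be positive")
  if (band_site_density <= 0) stop("band_site_density must be positive")
  if (n_markers < 1) stop("marker count must be >= 1")
  if (p_unassembled < 0 || p_unassembled >= 1) {
    stop("p_unassembled must be in [0, 1)")
  }
  structure(list(genome_length = genome_length,
                 band_site_density = band_site_density,
                 libraries = libraries,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 n_markers = as.integer(n_markers),
                 min_tp = as.integer(min_tp),
                 p_fp = normalize_rates(p_fp, "p_fp"),
                 p_fn = normalize_rates(p_fn, "p_fn"),
                 p_unassembled = p_unassembled,
                 matrix_shape = matrix_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a 5-D pool screening experiment
#'
#' Generates clone intervals uniformly on a circular genome, assigns
#' clones to 384-well plates/wells uniformly at random, derives lattice
#' band-site fingerprints, assembles perfect contigs as connected
#' components of the interval-overlap graph, places point markers, and
#' produces observed pool hits = true hits minus per-pool false negatives
#' plus per-pool false positives.
#'
#' @param config A [sim_config()].
#' @return A `sim_screen` list: `design` (`pooling_design`), `map`
#'   (`contig_map`), `hits` (list of [marker_hits()]), `truth`
#'   (`sim_truth` with clone intervals, marker positions, TP clones and
#'   pre-error true hits) and `config`.
#' @export
simulate_screening <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$genome_length
  d <- config$band_site_density
  n_sites <- floor(G * d)

  lib_code <- character(0); lib_nplates <- integer(0); lib_cov <- numeric(0)
  clone_lib <- character(0); clone_plate <- integer(0)
  clone_rowi <- integer(0); clone_coli <- integer(0)
  starts <- numeric(0); lens <- numeric(0)
  for (lb in config$libraries) {
    im <- lb$insert_mean %||% config$insert_mean
    isd <- lb$insert_sd %||% config$insert_sd
    n <- if (!is.null(lb$n_clones)) as.integer(lb$n_clones) else {
      as.integer(round((lb$coverage %||% 0) * G / im))
    }
    if (is.na(n) || n < 1L) {
      stop("library ", lb$code, " has zero coverage / no clones")
    }
    l <- pmin(pmax(stats::rnorm(n, im, isd), 0.2 * im), 2 * im)
    s <- stats::runif(n, 0, G)
    n_plates <- as.integer(ceiling(n / 384))
    w <- sample.int(n_plates * 384L, n)
    lib_code <- c(lib_code, lb$code)
    lib_nplates <- c(lib_nplates, n_plates)
    lib_cov <- c(lib_cov, sum(l) / G)
    clone_lib <- c(clone_lib, rep(lb$code, n))
    clone_plate <- c(clone_plate, (w - 1L) %/% 384L + 1L)
    wi <- (w - 1L) %% 384L
    clone_rowi <- c(clone_rowi, wi %/% 24L + 1L)
    clone_coli <- c(clone_coli, wi %% 24L + 1L)
    starts <- c(starts, s)
    lens <- c(lens, l)
  }
  n_all <- length(starts)
  ends <- starts + lens
  row_letter <- WELL_ROW_LABELS[clone_rowi]
  names_all <- make_clone_names(clone_lib, clone_plate, row_letter,
                                clone_coli)

  design <- build_design(
    data.frame(code = lib_code, n_plates = lib_nplates, coverage = lib_cov,
               stringsAsFactors = FALSE),
    matrix_shape = config$matrix_shape)

  # fingerprints: band-site lattice ids inside the clone interval
  fp_lo <- as.integer(floor(starts * d)) + 1L
  fp_hi <- as.integer(floor(pmin(ends, G) * d))
  wrapped <- ends > G
  fp_lo2 <- ifelse(wrapped, 1L, NA_integer_)
  fp_hi2 <- ifelse(wrapped, as.integer(floor((ends - G) * d)), NA_integer_)
  fp_hi2[wrapped & fp_hi2 < 1L] <- NA_integer_
  fp_lo2[wrapped & is.na(fp_hi2)] <- NA_integer_
  empty_fp <- fp_hi < fp_lo & is.na(fp_lo2)

  # assembly: exclude fingerprinting failures, then connected components
  # of the circular interval-overlap graph via a sweep over start order
  unasm <- stats::runif(n_all) < config$p_unassembled
  unasm <- unasm | empty_fp
  asm <- which(!unasm)
  contig <- rep(NA_character_, n_all)
  status <- rep("unassembled", n_all)
  shift <- numeric(n_all)
  if (length(asm)) {
    ord <- asm[order(starts[asm])]
    s_o <- starts[ord]; e_o <- ends[ord]
    cme <- cummax(e_o)
    n_o <- length(ord)
    new_comp <- c(TRUE, s_o[-1] >= cme[-n_o])
    comp <- cumsum(new_comp)
    # merge across the origin when the last component wraps past the
    # first component's start
    if (max(comp) > 1L && any(e_o > G)) {
      wrap_end <- max(e_o) - G
      if (wrap_end > s_o[1]) {
        swallowed <- unique(comp[s_o < wrap_end])
        last <- comp[n_o]
        shift[ord[comp %in% swallowed]] <- G
        comp[comp %in% c(swallowed, last)] <- last
      }
    }
    sizes <- table(comp)
    multi <- names(sizes)[sizes >= 2L]
    ctg_id <- stats::setNames(sprintf("ctg%d", seq_along(multi)), multi)
    cc <- as.character(comp)
    is_multi <- cc %in% multi
    contig[ord[is_multi]] <- ctg_id[cc[is_multi]]
    status[ord] <- ifelse(is_multi, "contig", "singleton")
  }

  clones_df <- data.frame(
    clone = names_all, contig = contig,
    left = as.integer(floor((starts + shift) * d)),
    right = as.integer(floor((ends + shift) * d)),
    status = status, stringsAsFactors = FALSE)
  clones_df$left[status == "unassembled"] <- NA_integer_
  clones_df$right[status == "unassembled"] <- NA_integer_
  map <- contig_map(clones_df,
                    fp_ranges = data.frame(lo = fp_lo, hi = fp_hi,
                                           lo2 = fp_lo2, hi2 = fp_hi2))

  # per-clone true pool ids (reverse lookup from the clone address)
  pid <- plate_id(clone_lib, clone_plate)
  pidx <- match(pid, design$plates$plate_id)
  clone_rsp <- design$plates$matrix_row[pidx]
  clone_csp <- design$plates$matrix_col[pidx]
  sub <- design$plates$sub_pool[pidx]
  clone_rp <- rp_id(sub, row_letter)
  clone_cp <- cp_id(sub, clone_coli)

  # marker placement with interval-stabbing index
  ord2 <- order(starts)
  ss <- starts[ord2]; ee <- ends[ord2]
  maxlen <- max(lens)
  wrapped_idx <- which(ends > G)
  stab <- function(p) {
    i1 <- findInterval(p - maxlen, ss) + 1L
    i2 <- findInterval(p, ss)
    hits <- integer(0)
    if (i2 >= i1) {
      rng <- seq.int(i1, i2)
      hits <- ord2[rng[ee[rng] > p]]
    }
    if (length(wrapped_idx)) {
      hits <- c(hits, wrapped_idx[ends[wrapped_idx] - G > p])
    }
    sort(unique(hits))
  }

  markers <- sprintf("M%04d", seq_len(config$n_markers))
  positions <- numeric(config$n_markers)
  tp <- vector("list", config$n_markers)
  for (j in seq_len(config$n_markers)) {
    for (try in seq_len(10000L)) {
      p <- stats::runif(1, 0, G)
      h <- stab(p)
      if (length(h) >= config$min_tp) break
      if (try == 10000L) stop("could not place a marker with >= ",
                              config$min_tp, " TP clones")
    }
    positions[j] <- p
    tp[[j]] <- h
  }

  true_hits <- lapply(seq_len(config$n_markers), function(j) {
    h <- tp[[j]]
    marker_hits(markers[j],
                rsp = unique(clone_rsp[h]), csp = unique(clone_csp[h]),
                rp = unique(clone_rp[h]), cp = unique(clone_cp[h]))
  })
  tp_names <- lapply(tp, function(h) sort(names_all[h]))

  observed <- inject_errors_impl(true_hits, design, config$p_fp, config$p_fn)

  truth <- structure(list(
    clone_intervals = data.frame(clone = names_all, start = starts,
                                 end = ends, stringsAsFactors = FALSE),
    marker_positions = stats::setNames(as.list(positions), markers),
    tp_clones = stats::setNames(tp_names, markers),
    true_hits = true_hits), class = "sim_truth")

  structure(list(design = design, map = map, hits = observed,
                 truth = truth, config = config),
            class = "sim_screen")
}

#' Inject per-pool screening errors into true pool hits
#'
#' Each true pool hit is dropped independently with probability
#' `p_fn[kind]`; each non-positive pool of the design becomes a spurious
#' hit independently with probability `p_fp[kind]`. The number of random
#' draws depends only on the truth, so runs with the same seed but
#' different rates are coupled: the hits dropped at a lower `p_fn` are a
#' subset of those dropped at a higher one.
#'
#' @param true_hits List of [marker_hits()] (pre-error truth).
#' @param design A `pooling_design`.
#' @param p_fp,p_fn Scalar or per-kind named rates (RSP, CSP, RP, CP).
#' @param seed Optional seed (set before drawing).
#' @return List of [marker_hits()] with errors applied.
#' @export
inject_errors <- function(true_hits, design, p_fp = 0, p_fn = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inject_errors_impl(true_hits, design,
                     normalize_rates(p_fp, "p_fp"),
                     normalize_rates(p_fn, "p_fn"))
}

pool_universe <- function(design, kind) {
  switch(kind,
    RSP = seq_len(design$matrix$n_rows),
    CSP = seq_len(design$matrix$n_cols),
    RP = as.vector(outer(design$sub_pools, WELL_ROW_LABELS, rp_id)),
    CP = as.vector(outer(design$sub_pools, seq_len(WELL_COLS), cp_id)))
}

inject_errors_impl <- function(true_hits, design, p_fp, p_fn) {
  universes <- stats::setNames(lapply(POOL_KINDS, pool_universe,
                                      design = design), POOL_KINDS)
  lapply(true_hits, function(h) {
    out <- list(marker = h$marker)
    for (kind in POOL_KINDS) {
      field <- tolower(kind)
      tr <- h[[field]]
      u_drop <- stats::runif(length(tr))
      keep <- tr[u_drop >= p_fn[[kind]]]
      nontrue <- setdiff(universes[[kind]], tr)
      u_add <- stats::runif(length(nontrue))
      add <- nontrue[u_add < p_fp[[kind]]]
      out[[field]] <- c(keep, add)
    }
    marker_hits(out$marker, out$rsp, out$csp, out$rp, out$cp)
  })
}

#' Randomly split contigs to mimic over-stringent assembly
#'
#' Each internal join (adjacency between consecutive clones in left-coordinate
#' order) is broken independently with probability `split_rate`, producing
#' sub-contigs named `<id>.1`, `<id>.2`, ... Clone coordinates are
#' preserved. `split_rate = 0` is the identity; `split_rate = 1` splits
#' every contig into size-1 contigs.
#'
#' @param map A `contig_map`.
#' @param split_rate Probability of breaking each join, in `[0, 1]`.
#' @param seed Optional seed.
#' @return A new `contig_map`.
#' @export
degrade_contigs <- function(map, split_rate, seed = NULL) {
  if (split_rate < 0 || split_rate > 1) stop("split_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  clones <- map$clones
  for (ctg in names(map$members)) {
    idx <- map$members[[ctg]]
    idx <- idx[order(clones$left[idx], clones$right[idx])]
    n <- length(idx)
    if (n < 2L) next
    breaks <- stats::runif(n - 1L) < split_rate
    if (!any(breaks)) next
    seg <- cumsum(c(1L, breaks))
    clones$contig[idx] <- sprintf("%s.%d", ctg, seg)
  }
  contig_map(clones, fingerprints = map$fingerprints,
             fp_ranges = map$fp_ranges)
}
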