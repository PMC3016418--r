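# Core deconvolution: candidate clones from pool-hit intersections, an
# exhaustive search over contigs for candidate subsets linked by
# fingerprint inclusion/spanning/overlap relations, and a discrimination
# score selecting the truly positive clone set per marker.

#' Count matched bands between two fingerprints
#'
#' With `tol = 0`, bands match exactly (set intersection). With `tol > 0`,
#' bands v and w match when `|v - w| <= tol`; matching is greedy one-to-one
#' over the sorted band lists.
#'
#' @param a,b Integer vectors of band values.
#' @param tol Band match tolerance (non-negative integer).
#' @return Number of matched bands.
#' @export
match_bands <- function(a, b, tol = 0) {
  a <- sort(unique(a)); b <- sort(unique(b))
  if (tol == 0) return(length(intersect(a, b)))
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[i] - b[j]) <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) i <- i + 1L else j <- j + 1L
  }
  m
}

#' Fingerprint relations between clones
#'
#' `fp_contains(a, b)`: clone a is contained in clone b iff f(a) belongs
#' to f(b). `fp_spans(a, b, c)`: clones a and b span clone c iff f(c) is
#' contained in the union of f(a) and f(b). `fp_overlaps(a, b)`: the
#' clones share at least `min_shared` matched bands.
#'
#' @param a,b,c Integer band vectors (fingerprints).
#' @param min_shared Minimum shared band count for an overlap.
#' @param tol Band match tolerance, see [match_bands()].
#' @return Logical.
#' @export
fp_contains <- function(a, b, tol = 0) {
  a <- unique(a)
  length(a) > 0 && match_bands(a, b, tol) == length(a)
}

#' @rdname fp_contains
#' @export
fp_spans <- function(a, b, c, tol = 0) {
  fp_contains(c, sort(unique(c(a, b))), tol)
}

#' @rdname fp_contains
#' @export
fp_overlaps <- function(a, b, min_shared = 1, tol = 0) {
  length(a) > 0 && length(b) > 0 && match_bands(a, b, tol) >= min_shared
}

#' Candidate plates from super-pool hits
#'
#' Positive plates sit at the intersections of positive RSP rows and CSP
#' columns of the 2-D super-pool matrix; empty matrix cells are excluded.
#'
#' @param rsp_hits,csp_hits Integer vectors of positive matrix rows/columns.
#' @param design A `pooling_design`.
#' @return Sorted character vector of candidate plate identifiers.
#' @export
plate_intersections <- function(rsp_hits, csp_hits, design) {
  rsp_hits <- unique(as.integer(rsp_hits))
  csp_hits <- unique(as.integer(csp_hits))
  if (length(rsp_hits) == 0L || length(csp_hits) == 0L) return(character(0))
  cells <- design$matrix$cells[rsp_hits, csp_hits, drop = FALSE]
  sort(cells[!is.na(cells)])
}

#' Candidate clones from plate, RP and CP hits
#'
#' For each sub-pool s, candidate clones lie at the intersections of the
#' candidate plates, the positive clone row pools of s, and the positive
#' clone column pools of s. With `library_filter = TRUE` (default) a
#' sub-pool's RP/CP hits combine only with candidate plates belonging to
#' that sub-pool; switching it off reproduces the unfiltered
#' plates x rows x columns arithmetic (e.g. (4x4x1x1) x 4 sub-pools = 64
#' candidates for a 4x genome-equivalent screen split into 4 sub-pools).
#'
#' @param plates Candidate plate identifiers (from [plate_intersections()]).
#' @param rp_hits,cp_hits Positive RP / CP pool ids
#'   (`"<sub_pool>/<row letter>"`, `"<sub_pool>/<column>"`).
#' @param design A `pooling_design`.
#' @param library_filter Restrict each sub-pool's hits to plates of its own
#'   sub-pool.
#' @param marker Optional marker name carried into the result.
#' @return A `candidate_set`: list with `marker`, `clones` (sorted clone
#'   names) and `per_sub` (candidate count per sub-pool, before
#'   de-duplication).
#' @export
candidate_clones <- function(plates, rp_hits, cp_hits, design,
                             library_filter = TRUE, marker = NA_character_) {
  subs <- design$sub_pools
  per_sub <- stats::setNames(integer(length(subs)), subs)
  clones <- character(0)
  if (length(plates) && length(rp_hits) && length(cp_hits)) {
    rp <- parse_subpool_hit(rp_hits, "RP", design)
    cp <- parse_subpool_hit(cp_hits, "CP", design)
    plate_sub <- design$plates[plates, "sub_pool"]
    plate_lib <- design$plates[plates, "library"]
    for (s in subs) {
      rows <- rp$index[rp$sub_pool == s]
      cols <- as.integer(cp$index[cp$sub_pool == s])
      if (length(rows) == 0L || length(cols) == 0L) next
      p_s <- if (library_filter) plates[plate_sub == s] else plates
      l_s <- if (library_filter) plate_lib[plate_sub == s] else plate_lib
      if (length(p_s) == 0L) next
      g <- expand.grid(plate = seq_along(p_s), row = rows, col = cols,
                       stringsAsFactors = FALSE)
      pn <- design$plates[p_s[g$plate], "plate"]
      nm <- make_clone_names(l_s[g$plate], pn, g$row, g$col)
      per_sub[s] <- per_sub[s] + length(nm)
      clones <- c(clones, nm)
    }
  }
  structure(list(marker = marker, clones = sort(unique(clones)),
                 per_sub = per_sub),
            class = "candidate_set")
}

#' Find linked candidate subsets (C2) within one contig
#'
#' Given the candidate clones of one contig (the set C1), returns the
#' connected components of the pairwise relation graph - edges are
#' inclusion or overlap relations; with `min_shared > 1` the ternary
#' spanning relation is also evaluated, since a spanned clone may then
#' share fewer than `min_shared` bands with either spanning clone alone.
#' Components of size >= 2 are the candidate C2 sets.
#'
#' @param c1 Character vector of candidate clone names in the contig.
#' @param fingerprints Named list of band vectors covering `c1`.
#' @param min_shared Minimum shared bands for an overlap edge.
#' @param tol Band match tolerance.
#' @return List of character vectors (each a C2 set, size >= 2).
#' @export
find_c2 <- function(c1, fingerprints, min_shared = 1, tol = 0) {
  n <- length(c1)
  if (n < 2L) return(list())
  fps <- fingerprints[c1]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (fp_overlaps(fps[[i]], fps[[j]], min_shared, tol) ||
          fp_contains(fps[[i]], fps[[j]], tol) ||
          fp_contains(fps[[j]], fps[[i]], tol)) {
        link(i, j)
      }
    }
  }
  if (min_shared > 1 && n >= 3L) {
    # spanning can link clone k to a pair (i, j) even when k shares fewer
    # than min_shared bands with each of i and j individually
    for (k in seq_len(n)) {
      for (i in seq_len(n - 1L)) {
        if (i == k) next
        for (j in seq.int(i + 1L, n)) {
          if (j == k) next
          if (find(k) == find(i) && find(k) == find(j)) next
          if (fp_spans(fps[[i]], fps[[j]], fps[[k]], tol)) {
            link(k, i); link(k, j)
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(c1, roots)
  unname(comps[lengths(comps) >= 2L])
}

#' Count false-negative clones under a C2 set
#'
#' F- clones are contig members located between the left-most and
#' right-most position of the C2 set (clone interval midpoint within the
#' closed span) that are not among the marker's candidate clones C.
#'
#' @param c2 Character vector, the C2 clone set.
#' @param members data.frame of the contig's clones (columns `clone`,
#'   `left`, `right`), e.g. from [contig_members()].
#' @param candidates Character vector, the candidate set C.
#' @return Integer count.
#' @export
count_fn <- function(c2, members, candidates) {
  i <- match(c2, members$clone)
  if (anyNA(i)) stop("C2 clone not in contig: ", c2[is.na(i)][1])
  lo <- min(members$left[i]); hi <- max(members$right[i])
  mid <- (members$left + members$right) / 2
  sum(mid >= lo & mid <= hi & !(members$clone %in% candidates))
}

#' Discrimination score of a C2 clone set
#'
#' `Score = 0.8 * NC/MC + 0.2 * (1 - FN/NC)` where NC is the number of
#' clones in the set, MC the maximum NC over all C2 sets found for the
#' marker, and FN the set's false-negative clone count. The maximum is 1
#' (NC = MC and FN = 0); a best score <= 0 means no solution.
#'
#' @param nc,mc,fn Integer counts (`mc >= nc >= 1`, `fn >= 0`).
#' @return Numeric score.
#' @export
deconv_score <- function(nc, mc, fn) {
  if (mc <= 0) stop("MC must be positive")
  if (nc < 1) stop("NC must be >= 1")
  if (fn < 0) stop("FN must be >= 0")
  0.8 * nc / mc + 0.2 * (1 - fn / nc)
}

#' Deconvolute one marker
#'
#' Runs the full per-marker pipeline: (1) candidate clones C at the
#' intersections of positive RSP x CSP plates with positive RP and CP
#' sub-pools; (2) per contig, the candidate subset C1; (3) for contigs with
#' |C1| >= 2, linked subsets C2 under the fingerprint relations; (4) false
#' negative counts; (5) discrimination scores (MC taken across all C2 sets
#' of the marker); (6) ranking. The top score decides the call: `unique`
#' (single best set with score > 0), `non_unique` (two or more sets tied at
#' the top score, rounded to `tie_digits` decimals), or `no_solution`
#' (no C2 of size >= 2, or best score <= 0, or empty screening results).
#'
#' @param hits A [marker_hits()] object.
#' @param design A `pooling_design`.
#' @param map A `contig_map`.
#' @param min_shared,tol Relation parameters, see [find_c2()].
#' @param library_filter See [candidate_clones()].
#' @param tie_digits Decimals used when comparing scores for ties.
#' @return A `deconv_result`: marker, status, ranked `solutions` (contig,
#'   clones, nc, mc, fn, score), `assigned` (union of top-tied solution
#'   clones), `candidates` and `diagnostics`.
#' @export
deconvolute_marker <- function(hits, design, map, min_shared = 1, tol = 0,
                               library_filter = TRUE, tie_digits = 6) {
  empty <- length(hits$rsp) == 0L && length(hits$csp) == 0L &&
    length(hits$rp) == 0L && length(hits$cp) == 0L
  plates <- plate_intersections(hits$rsp, hits$csp, design)
  cand <- candidate_clones(plates, hits$rp, hits$cp, design,
                           library_filter = library_filter,
                           marker = hits$marker)
  C <- cand$clones
  idx <- match(C, map$clones$clone)
  status_of <- ifelse(is.na(idx), "unassembled", map$clones$status[idx])
  diagnostics <- list(
    n_plates = length(plates),
    n_candidates = length(C),
    n_in_contigs = sum(status_of == "contig"),
    n_singletons = sum(status_of == "singleton"),
    n_unassembled = sum(status_of == "unassembled"),
    per_sub = cand$per_sub,
    note = if (empty) "screening failure" else NA_character_)

  in_ctg <- status_of == "contig"
  groups <- split(C[in_ctg], map$clones$contig[idx[in_ctg]])
  groups <- groups[lengths(groups) >= 2L]

  solutions <- list()
  for (ctg in names(groups)) {
    c1 <- groups[[ctg]]
    fps <- clone_fingerprints(map, c1)
    for (c2 in find_c2(c1, fps, min_shared = min_shared, tol = tol)) {
      solutions[[length(solutions) + 1L]] <-
        list(contig = ctg, clones = c2, nc = length(c2))
    }
  }

  if (length(solutions) == 0L) {
    return(structure(list(marker = hits$marker, status = "no_solution",
                          solutions = list(), assigned = character(0),
                          candidates = C, diagnostics = diagnostics),
                     class = "deconv_result"))
  }

  mc <- max(vapply(solutions, `[[`, 1L, "nc"))
  for (k in seq_along(solutions)) {
    s <- solutions[[k]]
    members <- contig_members(map, s$contig)
    s$mc <- mc
    s$fn <- count_fn(s$clones, members, C)
    s$score <- deconv_score(s$nc, mc, s$fn)
    solutions[[k]] <- s
  }
  scores <- vapply(solutions, `[[`, 1.0, "score")
  solutions <- solutions[order(-scores)]
  scores <- sort(scores, decreasing = TRUE)

  top <- round(scores[1], tie_digits)
  if (scores[1] <= 0) {
    status <- "no_solution"
    assigned <- character(0)
  } else {
    tied <- which(round(scores, tie_digits) == top)
    status <- if (length(tied) > 1L) "non_unique" else "unique"
    assigned <- sort(unique(unlist(lapply(solutions[tied], `[[`, "clones"))))
  }
  structure(list(marker = hits$marker, status = status,
                 solutions = solutions, assigned = assigned,
                 candidates = C, diagnostics = diagnostics),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("marker", x$marker, "->", x$status)
  if (length(x$solutions)) {
    s <- x$solutions[[1]]
    cat(sprintf(" | top: %s (NC=%d, FN=%d, score=%.3f)",
                s$contig, s$nc, s$fn, s$score))
  }
  cat(sprintf(" | %d candidates (%d in contigs)\n",
              x$diagnostics$n_candidates, x$diagnostics$n_in_contigs))
  invisible(x)
}

#' Deconvolute a set of markers
#'
#' @param hits_list List of [marker_hits()].
#' @param design A `pooling_design`.
#' @param map A `contig_map`.
#' @param ... Passed to [deconvolute_marker()].
#' @return A `deconv_results` list of `deconv_result` objects.
#' @export
deconvolute <- function(hits_list, design, map, ...) {
  structure(lapply(hits_list, deconvolute_marker, design = design,
                   map = map, ...),
            class = "deconv_results")
}

#' Summary table of deconvolution results
#'
#' @param x A `deconv_results` list (or plain list of `deconv_result`).
#' @param ... Unused.
#' @return data.frame with one row per marker.
#' @export
as.data.frame.deconv_results <- function(x, ...) {
  deconv_summary(x)
}

#' @rdname as.data.frame.deconv_results
#' @param results List of `deconv_result` objects.
#' @export
deconv_summary <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(marker = character(0), status = character(0),
                      n_candidates = integer(0), n_in_contigs = integer(0),
                      n_singletons = integer(0), n_unassembled = integer(0),
                      contig = character(0), n_clones = integer(0),
                      score = numeric(0), clones = character(0),
                      stringsAsFactors = FALSE))
  }
  row <- function(r) {
    d <- r$diagnostics
    has <- r$status %in% c("unique", "non_unique") && length(r$solutions) > 0
    top_score <- if (has) r$solutions[[1]]$score else NA_real_
    contigs <- if (has) {
      sc <- vapply(r$solutions, `[[`, 1.0, "score")
      tied <- round(sc, 6) == round(sc[1], 6)
      paste(unique(vapply(r$solutions[tied], `[[`, "", "contig")),
            collapse = ";")
    } else NA_character_
    data.frame(marker = r$marker, status = r$status,
               n_candidates = d$n_candidates,
               n_in_contigs = d$n_in_contigs,
               n_singletons = d$n_singletons,
               n_unassembled = d$n_unassembled,
               contig = contigs,
               n_clones = length(r$assigned),
               score = top_score,
               clones = paste(r$assigned, collapse = ","),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(lapply(results, row),
                   list(make.row.names = FALSE)))
}
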