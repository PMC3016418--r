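# I/O: minimal FPC-style contig map dialect (+ sidecar band file), pool-hit
# files, matrix design files, and the three result writers (summary,
# anchored-marker, ACE-style marker merge).
#
# The .fpc dialect is the textual clone-stanza subset:
#   BAC : "BB092N18"
#   Map "ctg4985" Ends Left 100 Right 150
#   Bands: 5 9 12
# Clones in "ctg0" are singletons; clones without a Map record are
# unassembled (not in the assembly). `Bands:` is an extension of the FPC
# text format; band sets may instead live in a sidecar TSV (clone <TAB>
# space-separated band values). All TSVs are tab-separated with a header
# line; lines starting with `#` (or `//` in .fpc) are comments.

#' Construct a contig map
#'
#' @param clones data.frame with columns `clone`, `contig` (contig id, or
#'   `NA` for singletons and unassembled clones), `left`, `right` (integer
#'   map coordinates in consensus-band units; `NA` when unplaced) and
#'   `status` (`"contig"`, `"singleton"` or `"unassembled"`).
#' @param fingerprints Named list mapping clone name to a sorted integer
#'   vector of band values. May be `NULL` when `fp_ranges` is given.
#' @param fp_ranges Optional compact fingerprint representation for
#'   simulated band-site fingerprints: a data.frame aligned with `clones`
#'   holding band-id ranges `lo`,`hi` (and `lo2`,`hi2` for clones wrapping
#'   the circular genome origin); the fingerprint is `lo:hi` (+
#'   `lo2:hi2`). Materialized on demand by [clone_fingerprints()].
#' @return A `contig_map` object.
#' @export
contig_map <- function(clones, fingerprints = NULL, fp_ranges = NULL) {
  stopifnot(is.data.frame(clones),
            all(c("clone", "contig", "left", "right", "status") %in%
                  names(clones)))
  if (anyDuplicated(clones$clone)) {
    parse_error("duplicate clone in contig map: ",
                clones$clone[duplicated(clones$clone)][1])
  }
  bad <- clones$status == "contig" &
    (is.na(clones$contig) | is.na(clones$left) | is.na(clones$right))
  if (any(bad)) stop("assembled clones must have contig id and coordinates")
  placed <- !is.na(clones$left) & !is.na(clones$right)
  if (any(clones$left[placed] > clones$right[placed])) {
    stop("clone with left coordinate > right coordinate")
  }
  rownames(clones) <- NULL
  map <- structure(list(clones = clones, fingerprints = fingerprints,
                        fp_ranges = fp_ranges),
                   class = "contig_map")
  idx <- which(clones$status == "contig")
  map$members <- split(idx, clones$contig[idx])
  map
}

#' @export
print.contig_map <- function(x, ...) {
  s <- table(factor(x$clones$status,
                    levels = c("contig", "singleton", "unassembled")))
  cat("contig map:", length(x$members), "contigs |",
      s[["contig"]], "placed clones |", s[["singleton"]], "singletons |",
      s[["unassembled"]], "unassembled\n")
  invisible(x)
}

#' Fingerprint band sets for clones
#'
#' @param map A `contig_map`.
#' @param clones Character vector of clone names.
#' @return Named list of sorted integer band vectors (empty integer vector
#'   for clones without fingerprint data).
#' @export
clone_fingerprints <- function(map, clones) {
  if (!is.null(map$fingerprints)) {
    out <- map$fingerprints[clones]
    out[vapply(out, is.null, TRUE)] <- list(integer(0))
    names(out) <- clones
    return(out)
  }
  if (is.null(map$fp_ranges)) {
    return(stats::setNames(rep(list(integer(0)), length(clones)), clones))
  }
  i <- match(clones, map$clones$clone)
  r <- map$fp_ranges
  out <- lapply(i, function(k) {
    if (is.na(k) || is.na(r$lo[k])) return(integer(0))
    v <- seq.int(r$lo[k], r$hi[k])
    if (!is.na(r$lo2[k])) v <- c(seq.int(r$lo2[k], r$hi2[k]), v)
    as.integer(v)
  })
  stats::setNames(out, clones)
}

#' Contig members with map coordinates
#'
#' @param map A `contig_map`.
#' @param contig Contig id.
#' @return data.frame of the contig's clones ordered by left coordinate.
#' @export
contig_members <- function(map, contig) {
  idx <- map$members[[contig]]
  if (is.null(idx)) stop("unknown contig: ", contig)
  m <- map$clones[idx, , drop = FALSE]
  m[order(m$left, m$right), , drop = FALSE]
}

#' Read a contig map in the minimal FPC dialect
#'
#' @param path Path to the `.fpc` file.
#' @param bands_path Optional sidecar band file (TSV: clone, space-separated
#'   band values); overrides inline `Bands:` records.
#' @param quiet Suppress the summary message.
#' @return A `contig_map`.
#' @export
read_fpc <- function(path, bands_path = NULL, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  clone <- character(0); contig <- character(0)
  left <- numeric(0); right <- numeric(0); status <- character(0)
  fps <- list()
  cur <- NA_character_
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "//")) next
    if (grepl("^BAC\\b", line)) {
      m <- regmatches(line, regexec("^BAC\\s*:\\s*\"([^\"]+)\"\\s*$", line))[[1]]
      if (length(m) == 0L) parse_error("line ", ln, ": malformed BAC record")
      cur <- m[2]
      if (cur %in% clone) parse_error("line ", ln, ": duplicate clone ",
                                      dQuote(cur))
      clone <- c(clone, cur)
      contig <- c(contig, NA_character_)
      left <- c(left, NA_real_); right <- c(right, NA_real_)
      status <- c(status, "unassembled")
    } else if (grepl("^Map\\b", line)) {
      if (is.na(cur)) parse_error("line ", ln, ": Map record before any BAC")
      m <- regmatches(line, regexec(
        "^Map\\s+\"([^\"]+)\"\\s+Ends\\s+Left\\s+(-?[0-9.]+)\\s+Right\\s+(-?[0-9.]+)\\s*$",
        line))[[1]]
      if (length(m) == 0L) parse_error("line ", ln, ": malformed Map record")
      k <- length(clone)
      left[k] <- as.numeric(m[3]); right[k] <- as.numeric(m[4])
      if (m[2] == "ctg0") {
        status[k] <- "singleton"
      } else {
        contig[k] <- m[2]; status[k] <- "contig"
      }
    } else if (grepl("^Bands\\s*:", line)) {
      if (is.na(cur)) parse_error("line ", ln, ": Bands record before any BAC")
      v <- suppressWarnings(as.integer(
        strsplit(trimws(sub("^Bands\\s*:", "", line)), "\\s+")[[1]]))
      if (anyNA(v)) parse_error("line ", ln, ": non-integer band value")
      fps[[cur]] <- sort(unique(v))
    } else {
      parse_error("line ", ln, ": unknown record type: ",
                  dQuote(substr(line, 1, 30)))
    }
  }
  if (!is.null(bands_path)) {
    side <- read_bands(bands_path)
    fps[names(side)] <- side
  }
  map <- contig_map(
    data.frame(clone = clone, contig = contig, left = left, right = right,
               status = status, stringsAsFactors = FALSE),
    fingerprints = if (length(fps)) fps else NULL)
  if (!quiet) {
    message("read_fpc: ", length(map$members), " contigs, ",
            sum(status == "contig"), " placed clones, ",
            sum(status == "singleton"), " singletons, ",
            sum(status == "unassembled"), " unassembled")
  }
  map
}

#' Write a contig map in the minimal FPC dialect
#'
#' @param map A `contig_map`.
#' @param path Output path.
#' @param bands `"inline"` (default) to emit `Bands:` records, `"sidecar"`
#'   to write a separate band file, `"none"` to omit band data.
#' @param bands_path Sidecar path (default: `path` with `.bands` extension).
#' @return Invisibly, `path`.
#' @export
write_fpc <- function(map, path, bands = c("inline", "sidecar", "none"),
                      bands_path = NULL) {
  bands <- match.arg(bands)
  cl <- map$clones
  fps <- if (bands != "none") clone_fingerprints(map, cl$clone) else NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("// pooldeconv minimal fpc dialect v1", con)
  for (i in seq_len(nrow(cl))) {
    out <- sprintf("BAC : \"%s\"", cl$clone[i])
    if (cl$status[i] != "unassembled" && !is.na(cl$left[i])) {
      ctg <- if (cl$status[i] == "singleton") "ctg0" else cl$contig[i]
      out <- c(out, sprintf("Map \"%s\" Ends Left %s Right %s", ctg,
                            format(cl$left[i], scientific = FALSE),
                            format(cl$right[i], scientific = FALSE)))
    }
    if (bands == "inline" && length(fps[[i]])) {
      out <- c(out, paste("Bands:", paste(fps[[i]], collapse = " ")))
    }
    writeLines(c(out, ""), con)
  }
  if (bands == "sidecar") {
    if (is.null(bands_path)) bands_path <- paste0(path, ".bands")
    write_bands(fps, bands_path)
  }
  invisible(path)
}

#' Read a sidecar band file
#'
#' @param path TSV with columns clone, bands (space-separated integers).
#' @return Named list of sorted integer band vectors.
#' @export
read_bands <- function(path) {
  lines <- read_tsv_lines(path)
  body <- lines$body
  if (length(body) == 0L) return(list())
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(parts) < 1L | !nzchar(vapply(parts, `[`, "", 1L))
  if (any(bad)) parse_error("malformed band file row: ",
                            dQuote(body[which(bad)[1]]))
  nm <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(trimws(p[2]))) return(integer(0))
    v <- suppressWarnings(as.integer(strsplit(trimws(p[2]), "\\s+")[[1]]))
    if (anyNA(v)) parse_error("non-integer band value for clone ", p[1])
    sort(unique(v))
  })
  stats::setNames(vals, nm)
}

write_bands <- function(fps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("clone\tbands", con)
  for (nm in names(fps)) {
    if (length(fps[[nm]]) == 0L) next
    writeLines(paste0(nm, "\t", paste(fps[[nm]], collapse = " ")), con)
  }
  invisible(path)
}

# Shared TSV plumbing: drop comments/blank lines, split off the header.
read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) parse_error("empty file: ", path)
  list(header = lines[1], body = lines[-1])
}

split_set <- function(s) {
  s <- trimws(s)
  if (!nzchar(s) || s == "-") return(character(0))
  trimws(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Marker pool hits
#'
#' @param marker Marker name.
#' @param rsp,csp Integer vectors of positive super-pool matrix row /
#'   column indices.
#' @param rp,cp Character vectors of positive clone row / column sub-pool
#'   ids (`"<sub_pool>/<row letter>"`, `"<sub_pool>/<column>"`).
#' @return A `marker_hits` object.
#' @export
marker_hits <- function(marker, rsp = integer(0), csp = integer(0),
                        rp = character(0), cp = character(0)) {
  structure(list(marker = as.character(marker),
                 rsp = sort(unique(as.integer(rsp))),
                 csp = sort(unique(as.integer(csp))),
                 rp = sort(unique(as.character(rp))),
                 cp = sort(unique(as.character(cp)))),
            class = "marker_hits")
}

#' Read a pool hit file
#'
#' TSV columns: marker, rsp, csp, rp, cp; each hit set comma-separated,
#' empty (or `-`) for no hits.
#'
#' @param path Input path.
#' @param design Optional `pooling_design`; when given, pool ids are
#'   validated against it.
#' @return List of [marker_hits()] objects.
#' @export
read_pool_hits <- function(path, design = NULL) {
  lines <- read_tsv_lines(path)
  hdr <- strsplit(lines$header, "\t", fixed = TRUE)[[1]]
  if (!identical(tolower(hdr[1:5]),
                 c("marker", "rsp", "csp", "rp", "cp"))) {
    parse_error("pool hit file header must be: marker rsp csp rp cp")
  }
  lapply(lines$body, function(row) {
    p <- strsplit(row, "\t", fixed = TRUE)[[1]]
    if (length(p) < 1L || !nzchar(p[1])) {
      parse_error("pool hit row without marker name: ", dQuote(row))
    }
    length(p) <- 5L
    p[is.na(p)] <- ""
    marker <- p[1]
    rsp <- suppressWarnings(as.integer(split_set(p[2])))
    csp <- suppressWarnings(as.integer(split_set(p[3])))
    if (anyNA(rsp) || anyNA(csp)) {
      parse_error("marker ", marker, ": non-integer RSP/CSP pool id")
    }
    rp <- split_set(p[4]); cp <- split_set(p[5])
    if (!is.null(design)) {
      if (any(rsp < 1L | rsp > design$matrix$n_rows)) {
        parse_error("marker ", marker, ": RSP index outside matrix")
      }
      if (any(csp < 1L | csp > design$matrix$n_cols)) {
        parse_error("marker ", marker, ": CSP index outside matrix")
      }
      if (length(rp)) {
        tryCatch(parse_subpool_hit(rp, "RP", design),
                 pooldeconv_parse_error = function(e)
                   parse_error("marker ", marker, ": ", conditionMessage(e)))
      }
      if (length(cp)) {
        tryCatch(parse_subpool_hit(cp, "CP", design),
                 pooldeconv_parse_error = function(e)
                   parse_error("marker ", marker, ": ", conditionMessage(e)))
      }
    }
    marker_hits(marker, rsp, csp, rp, cp)
  })
}

#' Write a pool hit file
#'
#' @param hits List of [marker_hits()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pool_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pooldeconv pool hit file v1", con)
  writeLines("marker\trsp\tcsp\trp\tcp", con)
  for (h in hits) {
    writeLines(paste(h$marker,
                     paste(h$rsp, collapse = ","),
                     paste(h$csp, collapse = ","),
                     paste(h$rp, collapse = ","),
                     paste(h$cp, collapse = ","), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a 2-D super-pool matrix design file
#'
#' TSV: header row of CSP column indices, first column RSP row indices,
#' cells plate identifiers (empty or `-` for unoccupied cells).
#'
#' @param path Input path.
#' @return Character matrix of plate identifiers (`NA` empty cells).
#' @export
read_matrix_design <- function(path) {
  lines <- read_tsv_lines(path)
  hdr <- strsplit(lines$header, "\t", fixed = TRUE)[[1]]
  n_cols <- length(hdr) - 1L
  if (n_cols < 1L) parse_error("matrix design file has no columns")
  rows <- strsplit(lines$body, "\t", fixed = TRUE)
  md <- matrix(NA_character_, length(rows), n_cols)
  for (i in seq_along(rows)) {
    p <- rows[[i]]
    length(p) <- n_cols + 1L
    cells <- p[-1]
    cells[is.na(cells) | !nzchar(trimws(cells)) | trimws(cells) == "-"] <-
      NA_character_
    md[i, ] <- trimws(cells)
  }
  dimnames(md) <- list(vapply(rows, `[[`, "", 1L), hdr[-1])
  md
}

#' Write the super-pool matrix design of a pooling design
#'
#' @param design A `pooling_design`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_design <- function(design, path) {
  cells <- design$matrix$cells
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pooldeconv 2-D super-pool matrix design v1", con)
  writeLines(paste(c("", seq_len(ncol(cells))), collapse = "\t"), con)
  for (r in seq_len(nrow(cells))) {
    row <- cells[r, ]
    row[is.na(row)] <- ""
    writeLines(paste(c(r, row), collapse = "\t"), con)
  }
  invisible(path)
}

#' Reconstruct a pooling design from a matrix design file
#'
#' Library codes and plate counts are inferred from the plate identifiers
#' in the matrix.
#'
#' @param matrix_design Character matrix from [read_matrix_design()].
#' @param sub_pool_plan Passed to [build_design()].
#' @return A `pooling_design`.
#' @export
design_from_matrix <- function(matrix_design, sub_pool_plan = NULL) {
  ids <- matrix_design[!is.na(matrix_design)]
  m <- regmatches(ids, regexec("^([A-Za-z]+)([0-9]+)$", ids))
  bad <- lengths(m) == 0L
  if (any(bad)) parse_error("unparseable plate identifier in matrix design: ",
                            ids[bad][1])
  lib <- vapply(m, `[[`, "", 2L)
  num <- as.integer(vapply(m, `[[`, "", 3L))
  libs <- data.frame(code = unique(lib), stringsAsFactors = FALSE)
  libs$n_plates <- vapply(libs$code, function(cd) max(num[lib == cd]), 1L)
  build_design(libs, matrix_shape = dim(matrix_design),
               sub_pool_plan = sub_pool_plan, matrix_design = matrix_design)
}

#' Write deconvolution outputs
#'
#' Writes the summary file (one row per marker), the anchored-marker file
#' (unique solutions: marker, contig, clone list) and an ACE-style
#' marker-merge file (one marker/clone/contig line per anchored clone;
#' FPC-ACE-compatible intent, format versioned in the header).
#'
#' @param results List of `deconv_result` objects (from [deconvolute()]).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, named character vector of the three paths.
#' @export
write_outputs <- function(results, dir, prefix = "deconv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, paste0(prefix, "_summary.tsv"))
  anchored_path <- file.path(dir, paste0(prefix, "_anchored.tsv"))
  ace_path <- file.path(dir, paste0(prefix, "_ace.txt"))

  df <- deconv_summary(results)
  con <- file(summary_path, "w")
  writeLines("# pooldeconv deconvolution summary v1", con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)

  con <- file(anchored_path, "w")
  writeLines("# pooldeconv anchored positive markers v1", con)
  writeLines("marker\tcontig\tn_clones\tclones", con)
  for (r in results) {
    if (r$status != "unique") next
    s <- r$solutions[[1]]
    writeLines(paste(r$marker, s$contig, length(s$clones),
                     paste(sort(s$clones), collapse = ","), sep = "\t"), con)
  }
  close(con)

  con <- file(ace_path, "w")
  writeLines(c("# pooldeconv ACE-style marker merge v1",
               "# marker\tclone\tcontig"), con)
  for (r in results) {
    if (r$status != "unique") next
    s <- r$solutions[[1]]
    for (cl in sort(s$clones)) {
      writeLines(paste(r$marker, cl, s$contig, sep = "\t"), con)
    }
  }
  close(con)

  invisible(c(summary = summary_path, anchored = anchored_path,
              ace = ace_path))
}

#' Write / read simulated truth
#'
#' Marker truth as TSV: marker, position, tp_clones (comma-separated).
#' True pool hits are stored alongside in pool-hit file format.
#'
#' @param truth A `sim_truth` object from [simulate_screening()].
#' @param path Output path for the marker truth TSV.
#' @param hits_path Optional path for the true pool hits.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path, hits_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pooldeconv simulated marker truth v1", con)
  writeLines("marker\tposition\ttp_clones", con)
  for (m in names(truth$marker_positions)) {
    writeLines(paste(m, format(truth$marker_positions[[m]],
                               scientific = FALSE),
                     paste(sort(truth$tp_clones[[m]]), collapse = ","),
                     sep = "\t"), con)
  }
  if (!is.null(hits_path)) write_pool_hits(truth$true_hits, hits_path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path, hits_path = NULL) {
  lines <- read_tsv_lines(path)
  rows <- strsplit(lines$body, "\t", fixed = TRUE)
  markers <- vapply(rows, `[[`, "", 1L)
  pos <- as.numeric(vapply(rows, `[[`, "", 2L))
  tp <- lapply(rows, function(p) if (length(p) >= 3L) split_set(p[3])
               else character(0))
  structure(list(marker_positions = stats::setNames(as.list(pos), markers),
                 tp_clones = stats::setNames(tp, markers),
                 true_hits = if (!is.null(hits_path))
                   read_pool_hits(hits_path) else NULL,
                 clone_intervals = NULL),
            class = "sim_truth")
}
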