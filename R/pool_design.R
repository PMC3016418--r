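# 5-D pool design: 384-well plate collections, the 2-D super-pool matrix of
# plate pools, and per-library clone row/column sub-pools.

WELL_ROWS <- 16L
WELL_COLS <- 24L
WELL_ROW_LABELS <- LETTERS[1:16]

#' Standard 384-well plate layout
#'
#' @return A list with `n_rows` (16), `n_cols` (24) and `row_labels`
#'   (`A`..`P`). Wells are addressed as row letter + 1-based column number.
#' @export
plate_layout <- function() {
  list(n_rows = WELL_ROWS, n_cols = WELL_COLS, row_labels = WELL_ROW_LABELS)
}

#' Describe one BAC library
#'
#' @param code Short unique library code, letters only (e.g. `"HB"`).
#' @param n_plates Number of 384-well plates in the library.
#' @param coverage Genome coverage of the library in genome equivalents
#'   (optional, informational).
#' @return A `library_spec` list.
#' @export
library_spec <- function(code, n_plates, coverage = NA_real_) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code) ||
      !grepl("^[A-Za-z]+$", code)) {
    stop("library code must be a non-empty string of letters, got: ",
         deparse(code))
  }
  n_plates <- as.integer(n_plates)
  if (is.na(n_plates) || n_plates < 1L) stop("n_plates must be >= 1")
  structure(list(code = code, n_plates = n_plates,
                 coverage = as.numeric(coverage)),
            class = "library_spec")
}

#' Canonical plate identifier, e.g. `"HB086"`
#'
#' @param library Library code.
#' @param plate 1-based plate number within the library.
#' @return Character vector of plate identifiers.
#' @export
plate_id <- function(library, plate) {
  sprintf("%s%03d", library, as.integer(plate))
}

#' Parse a BAC clone name into its address
#'
#' Clone names follow the convention library code + (zero padded) plate
#' number + well row letter + well column number, e.g. `"BB092N18"` is
#' library BB, plate 92, well N18. Unpadded plate numbers are accepted;
#' [format_clone_name()] canonicalizes to three plate digits.
#'
#' @param name Clone name string.
#' @param libraries Optional character vector of valid library codes (or a
#'   `pooling_design`); when given, unknown codes are an error.
#' @return A `clone_address` list with fields `library`, `plate`,
#'   `well_row`, `well_col`.
#' @export
parse_clone_name <- function(name, libraries = NULL) {
  if (!is.character(name) || length(name) != 1L) {
    stop("clone name must be a single string")
  }
  m <- regmatches(name, regexec("^([A-Za-z]+)([0-9]+)([A-P])([0-9]{1,2})$",
                                name))[[1]]
  if (length(m) == 0L) {
    parse_error("malformed clone name: ", dQuote(name),
                " (expected <library><plate><row letter A-P><column>)")
  }
  lib <- m[2]
  plate <- as.integer(m[3])
  row <- m[4]
  col <- as.integer(m[5])
  if (!is.null(libraries)) {
    codes <- if (inherits(libraries, "pooling_design")) {
      libraries$libraries$code
    } else {
      libraries
    }
    if (!(lib %in% codes)) {
      parse_error("unknown library code ", dQuote(lib), " in clone name ",
                  dQuote(name))
    }
  }
  if (plate < 1L) {
    parse_error("plate number must be >= 1 in clone name ", dQuote(name))
  }
  if (col < 1L || col > WELL_COLS) {
    parse_error("well column ", col, " out of range 1-24 in clone name ",
                dQuote(name))
  }
  structure(list(library = lib, plate = plate, well_row = row,
                 well_col = col),
            class = "clone_address")
}

#' Format a clone address as a canonical clone name
#'
#' @param address A `clone_address`, or a list with fields `library`,
#'   `plate`, `well_row`, `well_col`.
#' @return Canonical clone name, plate zero-padded to three digits.
#' @export
format_clone_name <- function(address) {
  sprintf("%s%03d%s%d", address$library, as.integer(address$plate),
          address$well_row, as.integer(address$well_col))
}

# Vectorised name construction used by the simulator.
make_clone_names <- function(library, plate, well_row, well_col) {
  sprintf("%s%03d%s%d", library, as.integer(plate), well_row,
          as.integer(well_col))
}

#' Construct a 5-D pooling design
#'
#' Builds the five pool dimensions for a multi-library collection of
#' 384-well plates: plate pools (PP), plate row/column super-pools
#' (RSP/CSP) from a 2-D matrix of plate pools, and clone row/column
#' sub-pools (RP/CP) obtained by splitting the plate stack per library
#' (optionally into several sub-pools per library, keeping each at roughly
#' 1-2x genome coverage).
#'
#' @param libraries A list of [library_spec()] objects, or a data.frame
#'   with columns `code`, `n_plates` and optionally `coverage`.
#' @param matrix_shape Integer vector `c(n_rows, n_cols)` for the
#'   super-pool matrix. Default: near-square matrix just large enough.
#' @param sub_pool_plan Optional named integer vector mapping library code
#'   to its number of sub-pools (default 1 per library). A split library
#'   gets sub-pool ids `CODE.1`, `CODE.2`, ... with plates divided into
#'   contiguous blocks.
#' @param matrix_design Optional character matrix of plate identifiers (as
#'   returned by [read_matrix_design()]) overriding the default row-major
#'   fill.
#' @return A `pooling_design` object.
#' @export
build_design <- function(libraries, matrix_shape = NULL,
                         sub_pool_plan = NULL, matrix_design = NULL) {
  if (inherits(libraries, "library_spec")) libraries <- list(libraries)
  if (is.data.frame(libraries)) {
    libs <- data.frame(code = as.character(libraries$code),
                       n_plates = as.integer(libraries$n_plates),
                       coverage = if ("coverage" %in% names(libraries)) {
                         as.numeric(libraries$coverage)
                       } else NA_real_,
                       stringsAsFactors = FALSE)
  } else {
    libs <- data.frame(code = vapply(libraries, `[[`, "", "code"),
                       n_plates = vapply(libraries, function(l)
                         as.integer(l$n_plates), 1L),
                       coverage = vapply(libraries, function(l)
                         as.numeric(l$coverage %||% NA_real_), 1.0),
                       stringsAsFactors = FALSE)
  }
  if (nrow(libs) == 0L) stop("at least one library is required")
  if (anyDuplicated(libs$code)) {
    stop("duplicate library codes: ",
         paste(unique(libs$code[duplicated(libs$code)]), collapse = ", "))
  }
  if (any(libs$n_plates < 1L)) stop("every library needs n_plates >= 1")

  total <- sum(libs$n_plates)
  if (is.null(matrix_shape)) {
    nc <- as.integer(ceiling(sqrt(total)))
    nr <- as.integer(ceiling(total / nc))
    matrix_shape <- c(nr, nc)
  }
  matrix_shape <- as.integer(matrix_shape)
  if (length(matrix_shape) != 2L || any(matrix_shape < 1L)) {
    stop("matrix_shape must be two positive integers")
  }
  n_rows <- matrix_shape[1]; n_cols <- matrix_shape[2]
  if (n_rows * n_cols < total) {
    stop("super-pool matrix capacity ", n_rows * n_cols,
         " exceeded by ", total, " plates")
  }

  plates <- data.frame(
    library = rep(libs$code, libs$n_plates),
    plate = unlist(lapply(libs$n_plates, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  plates$plate_id <- plate_id(plates$library, plates$plate)

  # sub-pool assignment: by default one sub-pool per library
  plates$sub_pool <- plates$library
  if (!is.null(sub_pool_plan)) {
    bad <- setdiff(names(sub_pool_plan), libs$code)
    if (length(bad)) stop("sub_pool_plan names unknown libraries: ",
                          paste(bad, collapse = ", "))
    for (code in names(sub_pool_plan)) {
      k <- as.integer(sub_pool_plan[[code]])
      if (k <= 1L) next
      sel <- which(plates$library == code)
      grp <- ceiling(seq_along(sel) / (length(sel) / k))
      grp <- pmin(grp, k)
      plates$sub_pool[sel] <- sprintf("%s.%d", code, grp)
    }
  }

  cells <- matrix(NA_character_, n_rows, n_cols)
  if (is.null(matrix_design)) {
    # deterministic row-major fill, libraries in declared order
    k <- seq_len(total)
    r <- ((k - 1L) %/% n_cols) + 1L
    cc <- ((k - 1L) %% n_cols) + 1L
    cells[cbind(r, cc)] <- plates$plate_id
    plates$matrix_row <- r
    plates$matrix_col <- cc
  } else {
    md <- matrix_design
    if (nrow(md) != n_rows || ncol(md) != n_cols) {
      stop("matrix_design is ", nrow(md), "x", ncol(md),
           " but matrix_shape is ", n_rows, "x", n_cols)
    }
    occ <- which(!is.na(md) & nzchar(md), arr.ind = TRUE)
    ids <- md[occ]
    if (anyDuplicated(ids)) {
      stop("matrix design assigns a plate to more than one cell: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    pos <- match(plates$plate_id, ids)
    if (anyNA(pos)) {
      stop("matrix design is missing plates: ",
           paste(utils::head(plates$plate_id[is.na(pos)], 5), collapse = ", "))
    }
    cells[occ] <- ids
    plates$matrix_row <- occ[pos, 1]
    plates$matrix_col <- occ[pos, 2]
  }
  rownames(plates) <- plates$plate_id

  structure(list(
    layout = plate_layout(),
    libraries = libs,
    plates = plates[, c("plate_id", "library", "plate", "sub_pool",
                        "matrix_row", "matrix_col")],
    matrix = list(n_rows = n_rows, n_cols = n_cols, cells = cells),
    sub_pools = unique(plates$sub_pool)
  ), class = "pooling_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pooling_design <- function(x, ...) {
  cat("5-D pooling design\n")
  cat("  libraries:", paste(x$libraries$code, collapse = ", "), "\n")
  cat("  plates:", nrow(x$plates), " (384-well)\n")
  cat("  super-pool matrix:", x$matrix$n_rows, "x", x$matrix$n_cols,
      sprintf("(%d empty cells)\n",
              x$matrix$n_rows * x$matrix$n_cols - nrow(x$plates)))
  pc <- pool_counts(x)
  cat("  pools: PP", pc[["PP"]], "| RSP", pc[["RSP"]], "| CSP", pc[["CSP"]],
      "| RP", pc[["RP"]], "| CP", pc[["CP"]], "\n")
  invisible(x)
}

#' Number of pools of each kind in a design
#'
#' RP pools number 16 x N and CP pools 24 x N for N sub-pools.
#'
#' @param design A `pooling_design`.
#' @return Named integer vector with elements `PP`, `RSP`, `CSP`, `RP`, `CP`.
#' @export
pool_counts <- function(design) {
  n_sub <- length(design$sub_pools)
  c(PP = nrow(design$plates),
    RSP = design$matrix$n_rows,
    CSP = design$matrix$n_cols,
    RP = WELL_ROWS * n_sub,
    CP = WELL_COLS * n_sub)
}

# RP/CP pool identifiers are strings "<sub_pool>/<well row letter>" and
# "<sub_pool>/<well column>".
rp_id <- function(sub_pool, well_row) paste0(sub_pool, "/", well_row)
cp_id <- function(sub_pool, well_col) paste0(sub_pool, "/", well_col)

parse_subpool_hit <- function(id, kind, design = NULL) {
  parts <- strsplit(id, "/", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (any(!ok)) {
    parse_error("malformed ", kind, " pool id: ",
                paste(id[!ok], collapse = ", "),
                " (expected <sub_pool>/<",
                if (kind == "RP") "row letter A-P" else "column 1-24", ">)")
  }
  sub <- vapply(parts, `[[`, "", 1L)
  idx <- vapply(parts, `[[`, "", 2L)
  if (!is.null(design)) {
    bad <- !(sub %in% design$sub_pools)
    if (any(bad)) {
      parse_error("unknown sub-pool in ", kind, " hit: ",
                  paste(unique(sub[bad]), collapse = ", "))
    }
  }
  if (kind == "RP") {
    bad <- !(idx %in% WELL_ROW_LABELS)
    if (any(bad)) parse_error("invalid well row in RP hit: ",
                              paste(id[bad], collapse = ", "))
  } else {
    v <- suppressWarnings(as.integer(idx))
    bad <- is.na(v) | v < 1L | v > WELL_COLS
    if (any(bad)) parse_error("invalid well column in CP hit: ",
                              paste(id[bad], collapse = ", "))
  }
  data.frame(sub_pool = sub, index = idx, stringsAsFactors = FALSE)
}

#' Size (clone count) of one pool in a design
#'
#' Plates are counted as full 384-well plates: an RSP holds 384 clones per
#' occupied plate in its matrix row, a CSP per occupied plate in its
#' column; an RP sub-pool holds 24 clones per plate of its sub-pool, a CP
#' sub-pool 16 per plate.
#'
#' @param design A `pooling_design`.
#' @param kind One of `"PP"`, `"RSP"`, `"CSP"`, `"RP"`, `"CP"`.
#' @param index Pool index: plate id for PP, matrix row/column number for
#'   RSP/CSP, `"<sub_pool>/<row letter>"` for RP, `"<sub_pool>/<col>"` for CP.
#' @return Integer clone count.
#' @export
pool_size <- function(design, kind, index) {
  kind <- match.arg(kind, c("PP", "RSP", "CSP", "RP", "CP"))
  switch(kind,
    PP = {
      if (!index %in% design$plates$plate_id) stop("unknown plate: ", index)
      WELL_ROWS * WELL_COLS
    },
    RSP = {
      r <- as.integer(index)
      if (is.na(r) || r < 1L || r > design$matrix$n_rows) {
        stop("unknown RSP index: ", index)
      }
      sum(design$plates$matrix_row == r) * WELL_ROWS * WELL_COLS
    },
    CSP = {
      cc <- as.integer(index)
      if (is.na(cc) || cc < 1L || cc > design$matrix$n_cols) {
        stop("unknown CSP index: ", index)
      }
      sum(design$plates$matrix_col == cc) * WELL_ROWS * WELL_COLS
    },
    RP = {
      p <- parse_subpool_hit(index, "RP", design)
      sum(design$plates$sub_pool == p$sub_pool) * WELL_COLS
    },
    CP = {
      p <- parse_subpool_hit(index, "CP", design)
      sum(design$plates$sub_pool == p$sub_pool) * WELL_ROWS
    })
}

#' True pool membership of a clone
#'
#' Every clone belongs to exactly one pool of each of the five kinds; all
#' five are recoverable from the clone name and the design (the reverse
#' lookup used both to build true pool hits in simulation and to audit
#' screening results).
#'
#' @param clone Clone name or `clone_address`.
#' @param design A `pooling_design`.
#' @return Named list with elements `PP`, `RSP`, `CSP`, `RP`, `CP`.
#' @export
true_pool_hits <- function(clone, design) {
  addr <- if (is.character(clone)) {
    parse_clone_name(clone, design$libraries$code)
  } else clone
  pid <- plate_id(addr$library, addr$plate)
  i <- match(pid, design$plates$plate_id)
  if (is.na(i)) stop("clone ", format_clone_name(addr), " not in design: ",
                     "no plate ", pid)
  sub <- design$plates$sub_pool[i]
  list(PP = pid,
       RSP = design$plates$matrix_row[i],
       CSP = design$plates$matrix_col[i],
       RP = rp_id(sub, addr$well_row),
       CP = cp_id(sub, addr$well_col))
}

#' Expected plate intersections when screening g genome equivalents
#'
#' Under the idealized assumption that each of the `g` positive plates
#' lands in a distinct super-pool matrix row and column, `g` positive RSPs
#' and `g` positive CSPs intersect in `g^2` cells, of which `g^2 - g` are
#' false positives. This is the arithmetic motivating sub-pooling to 1-2x
#' coverage.
#'
#' @param genome_equivalents Positive integer `g`.
#' @return Named list `intersections` (`g^2`) and `false_positives`
#'   (`g^2 - g`).
#' @export
expected_intersections <- function(genome_equivalents) {
  g <- as.integer(genome_equivalents)
  if (is.na(g) || g < 1L) stop("genome_equivalents must be an integer >= 1")
  list(intersections = g^2, false_positives = g^2 - g)
}
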