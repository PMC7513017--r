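# Readers and writers for the plain-text exchange formats: dense CSV/TSV
# weight matrices (optional single header row of node labels), 3-column
# weighted edge lists, the per-node TSV table and the JSON report.

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a connectivity matrix from a text file
#'
#' Supports two formats: a dense `n x n` matrix (CSV or TSV, optional single
#' header row of node labels, blank cells read as 0) and a 3-column weighted
#' edge list (`node_a`, `node_b`, `weight`; undirected, each pair listed
#' once). With `format = "auto"` a 3-column non-square table is read as an
#' edge list and anything else as a matrix (a 3-node matrix is necessarily
#' 3 x 3 and is read as a matrix; pass `format = "edgelist"` to override).
#'
#' @param path file to read.
#' @param format `"auto"`, `"matrix"` or `"edgelist"`.
#' @param symmetrize copy upper-triangle entries below the diagonal instead
#'   of requiring symmetry (matrix format only).
#' @param clip_negative zero out negative weights instead of erroring.
#' @return a `"connectivity"` matrix.
#' @seealso [write_connectivity()], [as_connectivity()]
#' @export
read_connectivity <- function(path, format = c("auto", "matrix", "edgelist"),
                              symmetrize = FALSE, clip_negative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  sep <- detect_sep(lines[[1]])
  split_fields <- function(x) {
    if (sep == "") return(strsplit(trimws(x), "[[:space:]]+"))
    parts <- lapply(strsplit(x, sep, fixed = TRUE), trimws)
    # strsplit drops trailing empty fields; restore them from the sep count
    widths <- vapply(gregexpr(sep, x, fixed = TRUE), function(g) {
      if (g[1] == -1) 1L else length(g) + 1L
    }, 1L)
    Map(function(p, w) c(p, rep("", w - length(p))), parts, widths)
  }
  fields <- split_fields(lines)
  widths <- lengths(fields)
  if (format == "auto") {
    format <- if (all(widths == 3) && length(lines) != 3) "edgelist"
              else "matrix"
  }
  if (format == "edgelist") {
    read_edgelist_fields(fields, path, clip_negative)
  } else {
    read_matrix_fields(fields, path, symmetrize, clip_negative)
  }
}

read_matrix_fields <- function(fields, path, symmetrize, clip_negative) {
  labels <- NULL
  probe <- fields[[1]]
  probe[probe == ""] <- "0"    # blank cells are zeros, not labels
  first <- suppressWarnings(as.numeric(probe))
  if (anyNA(first)) {
    labels <- fields[[1]]
    fields <- fields[-1]
  }
  n <- length(fields)
  widths <- lengths(fields)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged rows in %s: row %d has %d cells, expected %d",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  if (widths[1] != n) {
    stop(sprintf("matrix in %s is not square: %d rows x %d columns",
                 path, n, widths[1]), call. = FALSE)
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- fields[[i]]
    row[row == ""] <- "0"        # missing/blank cells are absent edges
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                   row[j], i, j, path), call. = FALSE)
    }
    M[i, ] <- v
  }
  as_connectivity(M, labels = labels, symmetrize = symmetrize,
                  clip_negative = clip_negative)
}

read_edgelist_fields <- function(fields, path, clip_negative) {
  if (any(lengths(fields) != 3)) {
    bad <- which(lengths(fields) != 3)[1]
    stop(sprintf("edge list %s: row %d has %d columns, expected 3",
                 path, bad, lengths(fields)[bad]), call. = FALSE)
  }
  tab <- do.call(rbind, fields)
  # optional header row: non-numeric weight column
  if (is.na(suppressWarnings(as.numeric(tab[1, 3])))) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0) stop(sprintf("no edges in %s", path), call. = FALSE)
  w <- suppressWarnings(as.numeric(tab[, 3]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop(sprintf("non-numeric weight '%s' at edge-list row %d of %s",
                 tab[bad, 3], bad, path), call. = FALSE)
  }
  ids <- c(tab[, 1], tab[, 2])
  ints <- suppressWarnings(as.integer(ids))
  if (!anyNA(ints) && all(ints > 0) && all(ints == as.numeric(ids))) {
    labels <- as.character(seq_len(max(ints)))    # 1-based integer node ids
    a <- as.integer(tab[, 1]); b <- as.integer(tab[, 2])
  } else {
    labels <- unique(ids)
    a <- match(tab[, 1], labels); b <- match(tab[, 2], labels)
  }
  if (any(a == b)) {
    stop(sprintf("self-loop at edge-list row %d of %s",
                 which(a == b)[1], path), call. = FALSE)
  }
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated edge at edge-list row %d of %s (each pair once)",
                 which(duplicated(key))[1], path), call. = FALSE)
  }
  n <- length(labels)
  M <- matrix(0, n, n)
  M[cbind(pmin(a, b), pmax(a, b))] <- w
  as_connectivity(M, labels = labels, symmetrize = TRUE,
                  clip_negative = clip_negative)
}

#' Write a connectivity matrix as a dense CSV/TSV file
#'
#' @param C connectivity matrix.
#' @param path output file; extension `.tsv` selects tab separation,
#'   anything else commas.
#' @param header write the node labels as a single header row; by default
#'   only when they are not the plain 1..n indices (a purely numeric header
#'   row could not be told apart from a data row when read back).
#' @return invisibly, `path`.
#' @export
write_connectivity <- function(C, path, header = NULL) {
  C <- as_connectivity(C)
  if (is.null(header)) {
    header <- !identical(rownames(C), as.character(seq_len(nrow(C))))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lines <- apply(unclass(C), 1, function(r) {
    paste(sprintf("%.12g", r), collapse = sep)
  })
  if (header) lines <- c(paste(rownames(C), collapse = sep), lines)
  write_atomically(lines, path)
  invisible(path)
}

# write via a temp file in the same directory so errors never leave a
# partial output behind
write_atomically <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir),
                             call. = FALSE)
  tmp <- tempfile(tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop(sprintf("cannot write %s", path),
                                    call. = FALSE)
  invisible(path)
}

#' Build an analysis report for a fitted model
#'
#' @param model a [random_walk_model()] fit.
#' @param input description of the input (path or generator spec) recorded in
#'   the metadata.
#' @param reference include reference-measure columns and fits.
#' @param seed seed recorded in the metadata.
#' @return an object of class `"analysis_report"`: a list with `metadata`,
#'   `global` (global measures in bits), `nodes` (per-node table) and
#'   `extremes` (all nodes attaining the max/min of each local measure,
#'   ties included).
#' @export
analysis_report <- function(model, input = NULL, reference = TRUE,
                            seed = NULL) {
  stopifnot(inherits(model, "random_walk_model"))
  nodes <- local_measures(model)
  if (reference) {
    ref <- reference_measures(model$C)
    nodes <- cbind(nodes, ref[, c("eccentricity", "clustering")])
  }
  extremes <- lapply(c(E = "E", I1 = "I1", I2 = "I2", I1e = "I1e"),
                     function(mname) extreme_nodes(nodes[[mname]], nodes$node))
  structure(list(
    metadata = list(
      input = if (is.null(input)) "<matrix>" else input,
      n = model$n, m = model$m,
      density = round(model$density, 4),
      seed = seed,
      tool = paste0("connectropy ",
                    as.character(utils::packageVersion("connectropy"))),
      units = "bits"
    ),
    global = as.list(as.data.frame(global_measures(model))),
    nodes = nodes,
    extremes = extremes
  ), class = "analysis_report")
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (metadata, global measures and per-measure extreme
#' nodes) and `nodes.tsv` (per-node table, 12 significant digits,
#' not-applicable entries as `NA`) into `out_dir`.
#'
#' @param report an [analysis_report()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (nrow(report$nodes) == 0) stop("empty per-node table: nothing computed",
                                    call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  tsv_path <- file.path(out_dir, "nodes.tsv")
  payload <- list(metadata = report$metadata, global = report$global,
                  extremes = report$extremes)
  write_atomically(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
    json_path)
  write_atomically(format_node_table(report$nodes), tsv_path)
  invisible(c(json = json_path, nodes = tsv_path))
}

format_node_table <- function(nodes) {
  num <- vapply(nodes, is.numeric, logical(1))
  body <- nodes
  body[num] <- lapply(nodes[num], function(v) {
    ifelse(is.na(v), "NA", sprintf("%.12g", v))
  })
  c(paste(names(nodes), collapse = "\t"),
    apply(as.matrix(body), 1, paste, collapse = "\t"))
}

#' Read back a per-node table written by [write_report()]
#'
#' @param path the `nodes.tsv` file.
#' @return a data frame matching the written table.
#' @export
read_node_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(node = "character"))
}
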