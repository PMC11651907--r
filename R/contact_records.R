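#' Temporal contact record sets
#'
#' A `contact_records` object holds timestamped pairwise contact records at a
#' fixed recording resolution, as produced by proximity sensors (RFID badges,
#' mobile devices). Records are kept sorted by time, with times normalised to
#' seconds from study start; the original time origin is retained as metadata.
#'
#' @param records data frame with columns `time` (seconds, non-negative
#'   multiples of `resolution`), `i` and `j` (node identifiers, character).
#' @param directed logical; if `FALSE`, pairs are stored in canonical
#'   (unordered) orientation and mirrored duplicates are collapsed.
#' @param resolution recording interval in seconds (e.g. 20 for SocioPatterns
#'   badges, 15 for the cruise sensors, 300 for mobile-device data).
#' @param node_attributes optional data frame of node metadata with a `node`
#'   column (see [read_node_attributes()]).
#' @param origin numeric; raw timestamp corresponding to normalised time 0.
#'
#' @return An object of class `contact_records`: a list with elements
#'   `records`, `directed`, `resolution`, `node_attributes`, `origin` and
#'   `n_duplicates` (count of collapsed duplicate records, so silent
#'   de-duplication stays observable).
#' @seealso [read_tij()], [build_episodes()], [build_snapshots()]
#' @export
contact_records <- function(records, directed = FALSE, resolution,
                            node_attributes = NULL, origin = 0) {
  if (!is.data.frame(records) || !all(c("time", "i", "j") %in% names(records)))
    stop_("`records` must be a data frame with columns time, i, j")
  if (!is_count(resolution, min = 1)) stop_("`resolution` must be a positive integer")
  rec <- data.frame(time = as.numeric(records$time),
                    i = as.character(records$i),
                    j = as.character(records$j),
                    stringsAsFactors = FALSE)
  if (nrow(rec)) {
    if (any(!is.finite(rec$time)) || any(rec$time < 0))
      stop_("record times must be non-negative numbers")
    off <- rec$time %% resolution
    if (any(off != 0))
      stop_("record times must be multiples of the resolution (", resolution,
            " s); first offender at time ", rec$time[which(off != 0)[1]])
    if (any(rec$i == rec$j))
      stop_("self-contact found (node '", rec$i[which(rec$i == rec$j)[1]], "')")
    if (!directed) {
      o <- orient_pairs(rec$i, rec$j)
      rec$i <- o$i; rec$j <- o$j
    }
    key <- paste(rec$time, pair_key(rec$i, rec$j))
    dup <- duplicated(key)
    n_dup <- sum(dup)
    rec <- rec[!dup, , drop = FALSE]
    rec <- rec[order(rec$time, rec$i, rec$j), , drop = FALSE]
    rownames(rec) <- NULL
  } else n_dup <- 0L
  if (!is.null(node_attributes)) {
    if (!is.data.frame(node_attributes) || !"node" %in% names(node_attributes))
      stop_("`node_attributes` must be a data frame with a `node` column")
    obs <- unique(c(rec$i, rec$j))
    missing_nodes <- setdiff(obs, node_attributes$node)
    if (length(missing_nodes))
      stop_("node(s) without attributes: ",
            paste(utils::head(missing_nodes, 5), collapse = ", "))
  }
  structure(list(records = rec, directed = isTRUE(directed),
                 resolution = as.integer(resolution),
                 node_attributes = node_attributes,
                 origin = origin, n_duplicates = as.integer(n_dup)),
            class = "contact_records")
}

#' Read a tij-format temporal edge list
#'
#' Parses the plain-text contact format used by proximity-sensor studies:
#' one record per line, `t i j`, whitespace- or comma-separated, where `t` is
#' the timestamp in seconds and `i`, `j` are node identifiers. Extra columns
#' are ignored. Duplicate records (and, for undirected data, mirrored
#' `(t,j,i)` records) are collapsed to one; the number collapsed is recorded
#' in the returned object's `n_duplicates`.
#'
#' Timestamps are validated as multiples of `resolution`, then normalised to
#' seconds from study start (the minimum observed time becomes 0); the
#' original origin is kept in the `origin` field.
#'
#' @param path path to the text file.
#' @param directed logical; whether records are directed (face-to-face
#'   sensors record directed contacts, omnidirectional sensors undirected).
#' @param resolution recording interval in seconds.
#' @param node_attributes optional node-attribute data frame, as returned by
#'   [read_node_attributes()].
#' @param normalize_time logical; shift times so the first record is at 0.
#' @return A [contact_records] object.
#' @examples
#' f <- tempfile()
#' writeLines(c("20 a b", "20 b a", "40 a c"), f)
#' x <- read_tij(f, directed = FALSE, resolution = 20)
#' nrow(x$records)  # 2: the mirrored record collapses
#' @export
read_tij <- function(path, directed = FALSE, resolution,
                     node_attributes = NULL, normalize_time = TRUE) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx)) {
    return(contact_records(data.frame(time = numeric(), i = character(),
                                      j = character()),
                           directed = directed, resolution = resolution,
                           node_attributes = node_attributes))
  }
  fields <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_("malformed line ", idx[which(nf < 3)[1]], ": expected `t i j`")
  t_raw <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  if (any(is.na(t_raw)))
    stop_("malformed line ", idx[which(is.na(t_raw))[1]], ": non-numeric timestamp")
  i <- vapply(fields, `[[`, "", 2L)
  j <- vapply(fields, `[[`, "", 3L)
  if (any(t_raw %% resolution != 0))
    stop_("line ", idx[which(t_raw %% resolution != 0)[1]],
          ": timestamp not a multiple of the resolution (", resolution, " s)")
  if (any(i == j))
    stop_("line ", idx[which(i == j)[1]], ": self-contact")
  origin <- if (normalize_time) min(t_raw) else 0
  contact_records(data.frame(time = t_raw - origin, i = i, j = j,
                             stringsAsFactors = FALSE),
                  directed = directed, resolution = resolution,
                  node_attributes = node_attributes, origin = origin)
}

#' Read a node-attribute table
#'
#' Reads a CSV with a header whose first column identifies the node and whose
#' remaining columns are categorical attributes (department, class, cabin,
#' ...). Empty cells become the explicit label `"unknown"`.
#'
#' @param path path to the CSV file.
#' @return data frame with a character `node` column and one character column
#'   per attribute.
#' @export
read_node_attributes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (ncol(df) < 2) stop_("attribute file needs a node column plus >=1 attribute")
  names(df)[1] <- "node"
  if (anyDuplicated(df$node))
    stop_("duplicate node row(s): ",
          paste(unique(df$node[duplicated(df$node)]), collapse = ", "))
  for (col in names(df)[-1]) {
    v <- df[[col]]
    v[is.na(v) | !nzchar(trimws(v))] <- "unknown"
    df[[col]] <- v
  }
  rownames(df) <- NULL
  df
}

#' Convert a directed record set to undirected
#'
#' Collapses each directed record to its unordered pair; simultaneous
#' `i -> j` and `j -> i` records in the same interval merge into one contact.
#' Used for the sensitivity analysis that treats face-to-face networks as
#' undirected. Idempotent on undirected input.
#'
#' @param x a [contact_records] object.
#' @return An undirected [contact_records] object.
#' @export
to_undirected <- function(x) {
  stopifnot(inherits(x, "contact_records"))
  if (!x$directed) return(x)
  out <- contact_records(x$records, directed = FALSE,
                         resolution = x$resolution,
                         node_attributes = x$node_attributes,
                         origin = x$origin)
  out$n_duplicates <- out$n_duplicates + x$n_duplicates
  out
}

#' Write a record set as canonical tij
#'
#' Writes tab-separated `t i j` lines sorted by time (then node ids), with no
#' header. `read_tij(write_tij(x))` round-trips exactly for record sets whose
#' times start at 0.
#'
#' @param x a [contact_records] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tij <- function(x, path) {
  stopifnot(inherits(x, "contact_records"))
  rec <- x$records
  lines <- if (nrow(rec)) paste(format(rec$time, scientific = FALSE, trim = TRUE),
                                rec$i, rec$j, sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.contact_records <- function(x, ...) {
  cat("<contact_records> ", nrow(x$records), " records, ",
      length(unique(c(x$records$i, x$records$j))), " nodes, ",
      if (x$directed) "directed" else "undirected",
      ", resolution ", x$resolution, " s\n", sep = "")
  if (x$n_duplicates)
    cat("  (", x$n_duplicates, " duplicate record(s) collapsed)\n", sep = "")
  if (nrow(x$records))
    cat("  time span: ", min(x$records$time), "-",
        max(x$records$time) + x$resolution, " s\n", sep = "")
  invisible(x)
}
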