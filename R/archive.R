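# Molecule archive: a UUID-keyed store of per-molecule trajectories,
# parameters, tags, change-point segment tables and an append-only log.
# Archives persist as a single UTF-8 JSON document ("fmtkit-archive/1")
# written one record per physical line, with a uid -> byte-offset index so
# that any single record can be retrieved without parsing the whole file.

ARCHIVE_SCHEMA <- "fmtkit-archive/1"

#' Create a molecule record
#'
#' One tethered molecule: its trajectory, derived parameters, tags,
#' change-point segment tables, and a log of operations applied to it.
#'
#' @param uid UUID string (see [fmt_uuid()]).
#' @param trajectory Data frame with columns `t_s` (strictly increasing),
#'   `frame` (non-negative integers), `x_um`, `y_um`.
#' @param parameters Named list of numeric (or string) scalars.
#' @param tags Character vector of tags.
#' @param segments List of segment tables (data frames with columns
#'   `t_start`, `t_end`, `slope`, `intercept`, `resid_sd`), optionally named.
#' @param log Character vector of operation descriptions.
#' @return Object of class `mol_record`.
#' @export
mol_record <- function(uid, trajectory, parameters = list(),
                       tags = character(), segments = list(),
                       log = character()) {
  rec <- structure(list(uid = uid,
                        trajectory = trajectory,
                        parameters = parameters,
                        tags = unique(as.character(tags)),
                        segments = segments,
                        log = as.character(log)),
                   class = "mol_record")
  validate_record(rec)
  rec
}

validate_record <- function(rec) {
  if (!is.character(rec$uid) || length(rec$uid) != 1 || !nzchar(rec$uid)) {
    stop("mol_record: uid must be a non-empty string")
  }
  tr <- rec$trajectory
  need <- c("t_s", "frame", "x_um", "y_um")
  if (!is.data.frame(tr) || !all(need %in% names(tr))) {
    stop("mol_record: trajectory needs columns t_s, frame, x_um, y_um")
  }
  if (nrow(tr) > 1 && any(diff(tr$t_s) <= 0)) {
    stop(sprintf("mol_record %s: trajectory time must be strictly increasing",
                 rec$uid))
  }
  if (any(tr$frame < 0) || any(tr$frame != round(tr$frame))) {
    stop(sprintf("mol_record %s: frame indices must be non-negative integers",
                 rec$uid))
  }
  invisible(rec)
}

#' Append a log entry to a record
#' @param rec A `mol_record`.
#' @param entry Description of the operation.
#' @return The record with the entry appended.
#' @export
record_log <- function(rec, entry) {
  rec$log <- c(rec$log, entry)
  rec
}

#' Read a parameter off a record, `NA` if absent
#' @param rec A `mol_record`.
#' @param name Parameter name.
#' @export
rec_param <- function(rec, name) {
  v <- rec$parameters[[name]]
  if (is.null(v)) NA_real_ else v
}

#' Test whether a record carries a tag
#' @param rec A `mol_record`.
#' @param tag Tag string.
#' @export
has_tag <- function(rec, tag) tag %in% rec$tags

#' Create an empty molecule archive
#'
#' @param metadata Named list of experiment properties; a `timeline` entry
#'   (see [protocol_timeline()]) is consulted by the classification
#'   pipeline.
#' @return Object of class `mol_archive`.
#' @export
new_archive <- function(metadata = list()) {
  structure(list(records = structure(list(), names = character()),
                 metadata = metadata),
            class = "mol_archive")
}

#' @export
length.mol_archive <- function(x) length(x$records)

#' List the uids stored in an archive (insertion order)
#' @param archive A `mol_archive`.
#' @export
archive_uids <- function(archive) names(archive$records)

#' Add a record to an archive
#'
#' @param archive A `mol_archive`.
#' @param rec A `mol_record`; its uid must not already be present.
#' @return The archive with the record appended.
#' @export
add_record <- function(archive, rec) {
  validate_record(rec)
  if (rec$uid %in% names(archive$records)) {
    stop(sprintf("add_record: duplicate uid %s", rec$uid))
  }
  archive$records[[rec$uid]] <- rec
  archive
}

#' Retrieve a record by uid
#' @param archive A `mol_archive`.
#' @param uid UUID string.
#' @export
get_record <- function(archive, uid) {
  rec <- archive$records[[uid]]
  if (is.null(rec)) stop(sprintf("get_record: no record with uid %s", uid))
  rec
}

#' Replace a stored record (uid must exist), appending a log entry
#' @param archive A `mol_archive`.
#' @param rec The updated record.
#' @param entry Log entry describing the mutation.
#' @export
update_record <- function(archive, rec, entry = NULL) {
  if (!rec$uid %in% names(archive$records)) {
    stop(sprintf("update_record: no record with uid %s", rec$uid))
  }
  if (!is.null(entry)) rec <- record_log(rec, entry)
  archive$records[[rec$uid]] <- rec
  archive
}

#' Merge two archives with disjoint uid sets
#'
#' Record logs are retained untouched; metadata of both inputs is kept under
#' `metadata$sources`, and `metadata$record_source` maps every uid to the
#' archive it came from, so merged datasets can be partitioned exactly.
#'
#' @param a,b `mol_archive` objects.
#' @param names_ab Length-2 character vector naming the two sources.
#' @return Merged `mol_archive`.
#' @export
merge_archives <- function(a, b, names_ab = c("a", "b")) {
  clash <- intersect(names(a$records), names(b$records))
  if (length(clash) > 0) {
    stop(sprintf("merge_archives: uid collision: %s",
                 paste(clash, collapse = ", ")))
  }
  src_a <- a$metadata$record_source
  if (is.null(src_a)) {
    src_a <- stats::setNames(rep(names_ab[1], length(a$records)),
                             names(a$records))
  }
  src_b <- b$metadata$record_source
  if (is.null(src_b)) {
    src_b <- stats::setNames(rep(names_ab[2], length(b$records)),
                             names(b$records))
  }
  sources <- c(
    if (is.null(a$metadata$sources)) stats::setNames(list(a$metadata), names_ab[1])
    else a$metadata$sources,
    if (is.null(b$metadata$sources)) stats::setNames(list(b$metadata), names_ab[2])
    else b$metadata$sources
  )
  out <- new_archive(metadata = list(sources = sources,
                                     record_source = c(src_a, src_b)))
  out$records <- c(a$records, b$records)
  out
}

#' Query an archive, returning matching uids in stable (insertion) order
#'
#' @param archive A `mol_archive`.
#' @param predicate Function of one `mol_record` returning TRUE/FALSE; use
#'   [rec_param()] and [has_tag()] so that missing values compare false.
#' @return Character vector of uids for which the predicate is `TRUE`
#'   (anything non-`TRUE`, including `NA`, is treated as no match).
#' @export
query_uids <- function(archive, predicate) {
  keep <- vapply(archive$records, function(r) isTRUE(predicate(r)), logical(1))
  names(archive$records)[keep]
}

# ---- JSON persistence -------------------------------------------------

record_to_list <- function(rec) {
  tr <- rec$trajectory
  segs <- lapply(seq_along(rec$segments), function(i) {
    s <- rec$segments[[i]]
    nm <- names(rec$segments)[i]
    list(name = if (is.null(nm) || !nzchar(nm)) paste0("segments_", i) else nm,
         t_start = as.numeric(s$t_start), t_end = as.numeric(s$t_end),
         slope = as.numeric(s$slope), intercept = as.numeric(s$intercept),
         resid_sd = as.numeric(s$resid_sd))
  })
  list(uid = rec$uid,
       tags = as.character(rec$tags),
       parameters = rec$parameters,
       trajectory = list(t_s = as.numeric(tr$t_s),
                         frame = as.integer(tr$frame),
                         x_um = as.numeric(tr$x_um),
                         y_um = as.numeric(tr$y_um)),
       segments = segs,
       log = as.character(rec$log))
}

record_to_json <- function(rec) {
  x <- record_to_list(rec)
  # tags/log/trajectory columns stay arrays even at length 1; parameters are
  # scalars; numbers serialized at full (17 s.f.) precision.
  x$tags <- I(x$tags)
  x$log <- I(x$log)
  x$trajectory <- lapply(x$trajectory, I)
  x$segments <- lapply(x$segments, function(s) {
    s[-1] <- lapply(s[-1], I)
    s
  })
  # I(17) = 17 *significant* digits, enough to round-trip IEEE doubles
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                                null = "null", na = "null"))
}

as_num <- function(v) {
  if (is.null(v) || length(v) == 0) return(numeric(0))
  vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
}

record_from_list <- function(x) {
  tr <- x$trajectory
  trajectory <- data.frame(t_s = as_num(tr$t_s),
                           frame = as.integer(as_num(tr$frame)),
                           x_um = as_num(tr$x_um),
                           y_um = as_num(tr$y_um))
  segs <- list()
  for (s in x$segments) {
    segs[[s$name]] <- data.frame(t_start = as_num(s$t_start),
                                 t_end = as_num(s$t_end),
                                 slope = as_num(s$slope),
                                 intercept = as_num(s$intercept),
                                 resid_sd = as_num(s$resid_sd))
  }
  params <- x$parameters
  if (is.null(params)) params <- list()
  params <- lapply(params, function(v) if (is.null(v)) NA_real_ else v)
  mol_record(uid = x$uid, trajectory = trajectory, parameters = params,
             tags = unlist(x$tags) %||% character(),
             segments = segs, log = unlist(x$log) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an archive to a JSON file
#'
#' Layout: one JSON document with top-level keys `schema`, `metadata`,
#' `records` and `index`. Every record occupies exactly one line; `index`
#' maps each uid to the byte offset of its line, enabling O(1) single-record
#' reads via [read_record()].
#'
#' @param archive A `mol_archive`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  meta <- archive$metadata
  meta_json <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = I(17), null = "null",
                                             na = "null"))
  rec_json <- vapply(archive$records, record_to_json, character(1),
                     USE.NAMES = FALSE)
  n <- length(rec_json)
  head_lines <- c("{",
                  sprintf('"schema": "%s",', ARCHIVE_SCHEMA),
                  sprintf('"metadata": %s,', meta_json),
                  '"records": [')
  rec_lines <- if (n > 0) paste0(rec_json, c(rep(",", n - 1), "")) else character()
  # byte offset of each record line: bytes of all preceding lines + newlines
  pre <- c(head_lines, rec_lines)
  lens <- nchar(pre, type = "bytes") + 1L
  offsets <- cumsum(c(0L, lens))[length(head_lines) + seq_len(n)]
  idx <- structure(as.list(offsets), names = names(archive$records))
  idx_json <- as.character(jsonlite::toJSON(idx, auto_unbox = TRUE))
  if (n == 0) idx_json <- "{}"
  lines <- c(pre, "],", sprintf('"index": %s', idx_json), "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a whole archive from a JSON file
#'
#' @param path Archive path written by [write_archive()].
#' @return A `mol_archive`.
#' @export
read_archive <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop(sprintf(
                  "read_archive: malformed archive file %s (%s)",
                  path, conditionMessage(e))))
  if (!identical(x$schema, ARCHIVE_SCHEMA)) {
    stop(sprintf("read_archive: unsupported schema '%s'", x$schema))
  }
  meta <- x$metadata %||% list()
  if (!is.null(meta$record_source)) meta$record_source <- unlist(meta$record_source)
  arch <- new_archive(metadata = meta)
  for (r in x$records) {
    rec <- tryCatch(record_from_list(r), error = function(e) stop(sprintf(
      "read_archive: bad record %s: %s",
      if (is.null(r$uid)) "<missing uid>" else r$uid, conditionMessage(e))))
    arch <- add_record(arch, rec)
  }
  arch
}

# Read the uid -> offset index from the file tail without parsing records.
# Returns list(index = named offsets, bytes_read).
read_archive_index <- function(path) {
  size <- file.info(path)$size
  chunk <- 65536L
  repeat {
    take <- min(chunk, size)
    con <- file(path, open = "rb")
    seek(con, where = size - take, origin = "start")
    tail_raw <- readBin(con, what = "raw", n = take)
    close(con)
    txt <- rawToChar(tail_raw)
    m <- regexpr('\n"index": ', txt, fixed = TRUE)
    if (m > 0 || take == size) break
    chunk <- chunk * 4L
  }
  if (m < 0) stop(sprintf("read_archive_index: no index found in %s", path))
  rest <- substr(txt, m + attr(m, "match.length"), nchar(txt))
  idx_line <- sub("\n\\}\\s*$", "", rest)
  idx <- jsonlite::fromJSON(idx_line, simplifyVector = FALSE)
  list(index = idx, bytes_read = take)
}

#' Read a single record from an archive file by uid
#'
#' Uses the byte-offset index in the file tail, so only the index and one
#' record line are read -- not the whole file ("virtual storage"). The
#' number of bytes actually read is attached as attribute `bytes_read`.
#'
#' @param path Archive path written by [write_archive()].
#' @param uid UUID of the record to fetch.
#' @return The `mol_record`, with attribute `bytes_read`.
#' @export
read_record <- function(path, uid) {
  ix <- read_archive_index(path)
  off <- ix$index[[uid]]
  if (is.null(off)) stop(sprintf("read_record: uid %s not in archive index", uid))
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = off, origin = "start")
  line <- readLines(con, n = 1L, warn = FALSE)
  line <- sub(",\\s*$", "", line)
  rec <- tryCatch(record_from_list(jsonlite::fromJSON(line, simplifyVector = FALSE)),
                  error = function(e) stop(sprintf(
                    "read_record: malformed record %s: %s", uid,
                    conditionMessage(e))))
  attr(rec, "bytes_read") <- ix$bytes_read + nchar(line, type = "bytes") + 1L
  rec
}

# ---- trajectory CSV interchange ---------------------------------------

#' Export trajectories to CSV (`uid,frame,t_s,x_um,y_um`)
#' @param archive A `mol_archive`.
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(archive, path) {
  tabs <- lapply(archive$records, function(r) {
    cbind(uid = r$uid, r$trajectory[, c("frame", "t_s", "x_um", "y_um")])
  })
  df <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import trajectories from CSV (`uid,frame,t_s,x_um,y_um`)
#' @param path CSV path.
#' @param metadata Metadata for the new archive.
#' @return A `mol_archive` with one record per uid.
#' @export
read_trajectory_csv <- function(path, metadata = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("uid", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("read_trajectory_csv: header must be uid,frame,t_s,x_um,y_um")
  }
  arch <- new_archive(metadata = metadata)
  for (u in unique(df$uid)) {
    sub <- df[df$uid == u, ]
    sub <- sub[order(sub$t_s), ]
    arch <- add_record(arch, mol_record(
      uid = as.character(u),
      trajectory = data.frame(t_s = sub$t_s, frame = sub$frame,
                              x_um = sub$x_um, y_um = sub$y_um),
      log = "imported from CSV"))
  }
  arch
}

#' @export
print.mol_archive <- function(x, ...) {
  cat(sprintf("<mol_archive> %d records\n", length(x$records)))
  invisible(x)
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record> %s: %d points, tags [%s]\n", x$uid,
              nrow(x$trajectory), paste(x$tags, collapse = ", ")))
  invisible(x)
}
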