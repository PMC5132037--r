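#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig text dialect: blocks starting `LM=k`, followed by
#' `k` lines of two reals, then optional `ID=`, `IMAGE=`, `SCALE=`
#' lines.  When `SCALE=` is present every coordinate of the block is
#' multiplied by it (so stored coordinates are in physical units).
#' `CURVES=`/`POINTS=` outline sections are ignored with a warning:
#' outline curves are expected to arrive already resampled into
#' semilandmarks.  LF and CRLF line endings are both accepted.
#'
#' @param path path to a TPS file.
#' @param roles optional per-landmark role vector passed to
#'   [landmark_set()].
#' @param scale_units unit tag for the stored coordinates.
#' @return a [landmark_set()], one specimen per block.
#' @export
read_tps <- function(path, roles = NULL, scale_units = "unknown") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= blocks found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  saw_curves <- FALSE
  configs <- list(); ids <- character(0)
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    k <- suppressWarnings(as.integer(sub("^LM=", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("block ", b, ": unparseable landmark count '", block[1L], "'")
    body <- block[-1L]
    is_kw <- grepl("^[A-Za-z]+=", body)
    if (any(grepl("^(CURVES|POINTS)=", body, ignore.case = TRUE)))
      saw_curves <- TRUE
    # coordinate lines: the leading run of non-keyword lines
    first_kw <- if (any(is_kw)) which(is_kw)[1L] else length(body) + 1L
    coord_lines <- body[seq_len(first_kw - 1L)]
    if (length(coord_lines) != k)
      stop("block ", b, ": expected ", k, " coordinate lines, found ",
           length(coord_lines))
    xy <- t(vapply(strsplit(coord_lines, "[[:space:],]+"), function(f) {
      v <- suppressWarnings(as.numeric(f))
      if (length(v) != 2L || anyNA(v))
        stop("block ", b, ": bad coordinate line '",
             paste(f, collapse = " "), "'")
      v
    }, numeric(2L)))
    kw <- body[is_kw]
    getkw <- function(name) {
      hit <- grep(paste0("^", name, "="), kw, ignore.case = TRUE)
      if (length(hit)) sub("^[A-Za-z]+=", "", kw[hit[1L]]) else NA_character_
    }
    id <- getkw("ID")
    scale <- suppressWarnings(as.numeric(getkw("SCALE")))
    if (!is.na(scale)) xy <- xy * scale
    configs[[b]] <- xy
    ids[b] <- if (!is.na(id)) id else paste0("spec", b)
  }
  if (saw_curves)
    warning("CURVES/POINTS outline sections ignored; ",
            "semilandmarks must be pre-digitized")
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across blocks: ",
         paste(unique(ks), collapse = ", "))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  landmark_set(configs,
               records = data.frame(specimen_id = ids,
                                    stringsAsFactors = FALSE),
               roles = roles, scale_units = scale_units)
}

#' Write a landmark set to a TPS file
#'
#' Inverse of [read_tps()]: writes one `LM=` block per specimen with an
#' `ID=` line.  Coordinates are written at full double precision so a
#' read/write round trip reproduces the data to numerical identity.
#'
#' @param data a [landmark_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path) {
  stopifnot(inherits(data, "landmark_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(n_specimens(data))) {
    xy <- data$coords[i, , ]
    writeLines(sprintf("LM=%d", nrow(xy)), con)
    writeLines(sprintf("%.17g %.17g", xy[, 1L], xy[, 2L]), con)
    writeLines(sprintf("ID=%s", data$records$specimen_id[i]), con)
  }
  invisible(path)
}
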