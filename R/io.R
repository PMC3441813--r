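io_header <- function(kind) {
  c(sprintf("# rhmap %s file", kind),
    "# tab-delimited, UTF-8; lines starting with '#' are comments")
}

read_body <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Write an RH call matrix as a vector file
#'
#' The vector-file dialect: comment header, a clone-id header line, then one
#' line per marker holding the marker id, a tab, and a `{0,1,2}` string of
#' length `n_clones`.
#'
#' @param calls an [rh_call_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(calls, path) {
  stopifnot(inherits(calls, "rh_calls"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(io_header("vector"), con)
  writeLines(paste(c("clones", rownames(calls)), collapse = "\t"), con)
  vecs <- apply(calls, 2, paste, collapse = "")
  writeLines(paste(colnames(calls), vecs, sep = "\t"), con)
  invisible(path)
}

#' Read a vector file into an RH call matrix
#'
#' @param path vector file written by [write_vectors()].
#' @return an [rh_call_matrix()].
#' @export
read_vectors <- function(path) {
  b <- read_body(path)
  if (!length(b$lines)) stop_rhmap("empty vector file", "rhmap_parse_error")
  head_parts <- strsplit(b$lines[1], "\t", fixed = TRUE)[[1]]
  if (head_parts[1] != "clones" || length(head_parts) < 2L)
    stop_rhmap(sprintf("line %d: expected a 'clones' header line",
                       b$lineno[1]), "rhmap_parse_error")
  clones <- head_parts[-1]
  body <- b$lines[-1]; lns <- b$lineno[-1]
  calls <- matrix(0L, length(clones), length(body))
  markers <- character(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop_rhmap(sprintf("line %d: expected 'marker<TAB>vector'", lns[i]),
                 "rhmap_parse_error")
    if (nchar(parts[2]) != length(clones))
      stop_rhmap(sprintf(
        "line %d: vector length %d does not match %d clones", lns[i],
        nchar(parts[2]), length(clones)), "rhmap_parse_error")
    v <- strtoi(strsplit(parts[2], "")[[1]])
    if (any(is.na(v)) || any(!v %in% 0:2))
      stop_rhmap(sprintf("line %d: calls must be 0, 1 or 2", lns[i]),
                 "rhmap_parse_error")
    markers[i] <- parts[1]
    calls[, i] <- v
  }
  dimnames(calls) <- list(clones, markers)
  rh_call_matrix(calls)
}

#' Write ordered RH group maps as a map TSV
#'
#' Columns: `group`, `position`, `cr`, `markers` (comma-joined when
#' co-localized).
#'
#' @param maps list of `rh_map` objects (with or without [colocalize()]
#'   positions).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rh_maps <- function(maps, path) {
  rows <- lapply(maps, function(mp) {
    if (!is.null(mp$positions)) {
      data.frame(group = mp$group, position = mp$positions$position,
                 cr = mp$positions$cr, markers = mp$positions$markers,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = mp$group, position = seq_along(mp$markers),
                 cr = mp$cr, markers = mp$markers, stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(io_header("map"), con)
  writeLines("group\tposition\tcr\tmarkers", con)
  writeLines(sprintf("%s\t%d\t%.1f\t%s", df$group, df$position, df$cr,
                     df$markers), con)
  invisible(path)
}

#' Read a map TSV written by [write_rh_maps()]
#'
#' @param path map file.
#' @return list of `rh_map`-like objects (`group`, `markers`, `cr`,
#'   `positions`); likelihood fields are not stored in the file.
#' @export
read_rh_maps <- function(path) {
  df <- read_tsv_checked(path, c("group", "position", "cr", "markers"),
                         c("character", "integer", "numeric", "character"))
  out <- lapply(split(df, df$group), function(sub) {
    sub <- sub[order(sub$position), ]
    members <- strsplit(sub$markers, ",", fixed = TRUE)
    structure(list(group = sub$group[1],
                   markers = unlist(members),
                   cr = rep(sub$cr, lengths(members)),
                   length_cr = max(sub$cr),
                   positions = data.frame(
                     position = sub$position, cr = sub$cr,
                     n_markers = lengths(members), markers = sub$markers,
                     stringsAsFactors = FALSE)),
              class = "rh_map")
  })
  out[order(names(out))]
}

read_tsv_checked <- function(path, cols, types) {
  b <- read_body(path)
  if (!length(b$lines)) stop_rhmap("empty file", "rhmap_parse_error")
  header <- strsplit(b$lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, cols))
    stop_rhmap(sprintf("line %d: expected header '%s'", b$lineno[1],
                       paste(cols, collapse = "\t")), "rhmap_parse_error")
  body <- b$lines[-1]; lns <- b$lineno[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad))
    stop_rhmap(sprintf("line %d: expected %d fields, found %d", lns[bad[1]],
                       length(cols), lengths(parts)[bad[1]]),
               "rhmap_parse_error")
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- cols
  for (k in seq_along(cols)) {
    if (types[k] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[k]]))
      if (any(is.na(v) & nzchar(df[[k]])))
        stop_rhmap(sprintf("line %d: '%s' is not numeric",
                           lns[which(is.na(v))[1]], cols[k]),
                   "rhmap_parse_error")
      df[[k]] <- v
    } else if (types[k] == "integer") {
      v <- suppressWarnings(as.integer(df[[k]]))
      if (any(is.na(v)))
        stop_rhmap(sprintf("line %d: '%s' is not an integer",
                           lns[which(is.na(v))[1]], cols[k]),
                   "rhmap_parse_error")
      df[[k]] <- v
    }
  }
  df
}

#' Write / read a genetic map TSV (`lg`, `marker`, `cm`)
#'
#' @param gmap genetic map data frame.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_genetic_map <- function(gmap, path) {
  stopifnot(all(c("lg", "marker", "cm") %in% names(gmap)))
  gmap <- gmap[order(gmap$lg, gmap$cm, gmap$marker), , drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(io_header("genetic map"), con)
  writeLines("lg\tmarker\tcm", con)
  writeLines(sprintf("%s\t%s\t%s", gmap$lg, gmap$marker,
                     format(gmap$cm, trim = TRUE, digits = 15)), con)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv_checked(path, c("lg", "marker", "cm"),
                         c("character", "character", "numeric"))
  if (any(df$cm < 0)) stop_rhmap("cM positions must be >= 0",
                                 "rhmap_parse_error")
  if (anyDuplicated(df[, c("lg", "marker")]))
    stop_rhmap("(lg, marker) pairs must be unique", "rhmap_parse_error")
  df
}

#' Write / read an anchor TSV (`marker`, `species`, `chrom`, `start`, `end`,
#' `pos`)
#'
#' @param anchors anchor data frame.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_anchors <- function(anchors, path) {
  need <- c("marker", "species", "chrom", "start", "end", "pos")
  stopifnot(all(need %in% names(anchors)))
  anchors <- anchors[order(anchors$species, anchors$chrom, anchors$pos,
                           anchors$marker), need, drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(io_header("anchor"), con)
  writeLines(paste(need, collapse = "\t"), con)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%s", anchors$marker,
                     anchors$species, anchors$chrom,
                     format(anchors$start, trim = TRUE, digits = 15),
                     format(anchors$end, trim = TRUE, digits = 15),
                     format(anchors$pos, trim = TRUE, digits = 15)), con)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  read_tsv_checked(path,
                   c("marker", "species", "chrom", "start", "end", "pos"),
                   c("character", "character", "character", "numeric",
                     "numeric", "numeric"))
}

#' Export RH maps in the GMOD CMap tab-delimited layout
#'
#' Writes one feature row per marker position with the standard CMap columns
#' (`map_acc`, `map_name`, `map_start`, `map_stop`, `feature_acc`,
#' `feature_name`, `feature_start`, `feature_stop`, `feature_type_acc`) in cR
#' coordinates, and optionally a correspondence file connecting markers
#' shared with a genetic map by name.
#'
#' @param maps list of `rh_map` objects.
#' @param path CMap feature file path.
#' @param gmap optional genetic map; when given, `corr_path` receives
#'   `feature_acc1`/`feature_acc2`/`evidence` rows for shared markers.
#' @param corr_path correspondence file path (required with `gmap`).
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path, gmap = NULL, corr_path = NULL) {
  cols <- c("map_acc", "map_name", "map_start", "map_stop", "feature_acc",
            "feature_name", "feature_start", "feature_stop",
            "feature_type_acc")
  rows <- list()
  for (mp in maps) {
    rows[[length(rows) + 1L]] <- data.frame(
      map_acc = mp$group, map_name = mp$group, map_start = 0,
      map_stop = mp$length_cr, feature_acc = mp$markers,
      feature_name = mp$markers, feature_start = mp$cr,
      feature_stop = mp$cr, feature_type_acc = "marker",
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(sprintf,
                     c(list("%s\t%s\t%.1f\t%.1f\t%s\t%s\t%.1f\t%.1f\t%s"),
                       unname(df[cols]))), con)
  if (!is.null(gmap)) {
    if (is.null(corr_path))
      stop_rhmap("corr_path is required when exporting correspondences")
    shared <- intersect(df$feature_acc, gmap$marker)
    con2 <- file(corr_path, "w", encoding = "UTF-8")
    on.exit(close(con2), add = TRUE)
    writeLines("feature_acc1\tfeature_acc2\tevidence", con2)
    if (length(shared))
      writeLines(sprintf("%s\t%s\tANB", sort(shared), sort(shared)), con2)
  }
  invisible(path)
}
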