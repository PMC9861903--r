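#' Write label maps to a CMAP v0.1 file
#'
#' Label maps sharing a `map_id` are written as one multi-channel CMAP record
#' (sites of all channels interleaved by position); channel codes are assigned
#' in order of first appearance and the enzyme names recorded in the header.
#' Positions are written 1-based with one decimal, plus the conventional
#' end-of-map sentinel row with `LabelChannel` 0.
#'
#' @param maps list of [label_map] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path) {
  stopifnot(length(maps) > 0)
  channels <- unique(vapply(maps, function(m) m$channel, ""))
  ids <- unique(vapply(maps, function(m) m$map_id, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# CMAP File Version:\t0.1",
    sprintf("# Label Channels:\t%d", length(channels)),
    sprintf("# Nickase Recognition Site %d:\t%s", seq_along(channels), channels),
    "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition\tStdDev\tCoverage\tOccurrence",
    "#f int\tfloat\tint\tint\tint\tfloat\tfloat\tfloat\tfloat"
  ), con)
  for (k in seq_along(ids)) {
    sub <- Filter(function(m) m$map_id == ids[k], maps)
    len <- max(vapply(sub, function(m) m$length, 0))
    pos <- unlist(lapply(sub, function(m) m$positions))
    chan <- unlist(lapply(sub, function(m)
      rep(match(m$channel, channels), length(m$positions))))
    o <- order(pos)
    pos <- pos[o]; chan <- chan[o]
    n <- length(pos)
    rows <- sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f",
                    k, len, n, seq_len(n), chan, pos + 1, 1, 1, 1)
    sentinel <- sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f",
                        k, len, n, n + 1L, 0L, len, 0, 1, 0)
    writeLines(c(rows, sentinel), con)
  }
  invisible(path)
}

#' Read a CMAP v0.1 file
#'
#' Multi-channel records are split into one [label_map] per channel. Channel
#' names are taken from `# Nickase Recognition Site` header lines when
#' present, otherwise `"channel<code>"`. The `LabelChannel` 0 end-of-map
#' sentinel is validated and dropped.
#'
#' @param path CMAP file path.
#' @return list of [label_map] objects named `"<map_id>|<channel>"`; map ids
#'   are the CMapId values as characters.
#' @export
read_cmap <- function(path) {
  lines <- readLines(path)
  is_head <- startsWith(lines, "#")
  chan_names <- character(0)
  for (h in lines[is_head]) {
    m <- regmatches(h, regexec("^# Nickase Recognition Site ([0-9]+):\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) chan_names[as.integer(m[2])] <- m[3]
  }
  body_idx <- which(!is_head & nzchar(lines))
  if (!length(body_idx)) return(list())
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("CMAP format error: fewer than 6 columns at line ", body_idx[which(nf < 6)[1]],
         call. = FALSE)
  tab <- data.frame(
    line = body_idx,
    CMapId = vapply(fields, function(f) f[1], ""),
    ContigLength = as.numeric(vapply(fields, function(f) f[2], "")),
    NumSites = as.integer(vapply(fields, function(f) f[3], "")),
    SiteID = as.integer(vapply(fields, function(f) f[4], "")),
    LabelChannel = as.integer(vapply(fields, function(f) f[5], "")),
    Position = as.numeric(vapply(fields, function(f) f[6], "")),
    stringsAsFactors = FALSE
  )
  maps <- list()
  for (id in unique(tab$CMapId)) {
    sub <- tab[tab$CMapId == id, , drop = FALSE]
    if (!identical(sub$SiteID, seq_len(nrow(sub))))
      stop("CMAP format error: SiteID gap for map ", id, " at line ",
           sub$line[which(sub$SiteID != seq_len(nrow(sub)))[1]], call. = FALSE)
    bad <- which(diff(sub$Position) < 0)
    if (length(bad))
      stop("CMAP format error: non-monotone positions at line ", sub$line[bad[1] + 1],
           call. = FALSE)
    len <- sub$ContigLength[1]
    if (sub$LabelChannel[nrow(sub)] != 0)
      stop("CMAP format error: missing end-of-map sentinel for map ", id,
           " at line ", sub$line[nrow(sub)], call. = FALSE)
    sites <- sub[sub$LabelChannel != 0, , drop = FALSE]
    for (code in unique(sites$LabelChannel)) {
      nm <- if (!is.na(chan_names[code])) chan_names[code] else paste0("channel", code)
      pos <- sites$Position[sites$LabelChannel == code] - 1
      maps[[paste0(id, "|", nm)]] <- label_map(id, len, nm, pos)
    }
  }
  maps
}
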