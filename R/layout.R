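#' Scaffold layout (AGP-shaped)
#'
#' Ordered, oriented contig placements interleaved with gap records per
#' scaffold, plus the list of unplaced contigs. Coordinates are 0-based
#' half-open internally; AGP I/O converts to/from the 1-based inclusive
#' convention of AGP v2.1.
#'
#' @param components tibble with columns `scaffold`, `part` (integer),
#'   `start`, `end` (0-based half-open scaffold coordinates), `type` (`"W"`
#'   for contigs, `"N"`/`"U"` for gaps), `comp_id`, `comp_beg`, `comp_end`
#'   (0-based half-open contig coordinates, `NA` for gaps), `orientation`
#'   (`"+"`/`"-"`, `NA` for gaps), `gap_length` and `gap_source` (`NA` for
#'   contig rows).
#' @param unplaced tibble with columns `comp_id`, `length` for contigs not
#'   placed in any scaffold.
#' @return an object of class `scaffold_layout`.
#' @export
scaffold_layout <- function(components, unplaced = NULL) {
  components <- tibble::as_tibble(components)
  if (is.null(unplaced))
    unplaced <- tibble::tibble(comp_id = character(0), length = numeric(0))
  unplaced <- tibble::as_tibble(unplaced)
  for (sc in unique(components$scaffold)) {
    sub <- components[components$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$part), , drop = FALSE]
    if (sub$start[1] != 0 || any(sub$start[-1] != sub$end[-nrow(sub)]))
      stop("components must tile scaffold ", sc, " without overlap", call. = FALSE)
  }
  structure(list(components = components, unplaced = unplaced),
            class = "scaffold_layout")
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat(sprintf("<scaffold_layout> %d scaffolds, %d placed contigs, %d gaps, %d unplaced contigs\n",
              length(unique(x$components$scaffold)),
              sum(x$components$type == "W"),
              sum(x$components$type != "W"),
              nrow(x$unplaced)))
  invisible(x)
}

#' Scaffold lengths of a layout
#' @param layout a [scaffold_layout].
#' @return named numeric vector of scaffold lengths (bp).
#' @export
scaffold_lengths <- function(layout) {
  comp <- layout$components
  tapply(comp$end, comp$scaffold, max)[unique(comp$scaffold)]
}

#' Gap records of a layout
#'
#' @param layout a [scaffold_layout].
#' @param source restrict to gaps with this source tag (e.g. `"HIC"`);
#'   `NULL` keeps all.
#' @return tibble with `scaffold`, `gap_index` (1-based per scaffold),
#'   `start`, `end`, `declared_length`, `source`.
#' @export
gap_records <- function(layout, source = NULL) {
  comp <- layout$components
  g <- comp[comp$type != "W", , drop = FALSE]
  if (!is.null(source)) g <- g[!is.na(g$gap_source) & g$gap_source == source, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(g)), g$scaffold, FUN = seq_along)
  tibble::tibble(scaffold = g$scaffold, gap_index = as.integer(idx),
                 start = g$start, end = g$end,
                 declared_length = g$gap_length, source = g$gap_source)
}

#' Total contig bases in a layout (placed components only)
#' @param layout a [scaffold_layout].
#' @return total bp of placed contig components.
#' @export
placed_contig_bases <- function(layout) {
  comp <- layout$components
  sum(comp$end[comp$type == "W"] - comp$start[comp$type == "W"])
}

#' Build scaffold sequences from a layout
#'
#' Concatenates oriented contig sequences with `N` runs of the declared gap
#' lengths.
#'
#' @param layout a [scaffold_layout].
#' @param contigs a named [Biostrings::DNAStringSet] of contig sequences.
#' @return a [Biostrings::DNAStringSet], one sequence per scaffold.
#' @export
build_scaffold_seqs <- function(layout, contigs) {
  comp <- layout$components
  out <- character(0)
  for (sc in unique(comp$scaffold)) {
    sub <- comp[comp$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$part), , drop = FALSE]
    pieces <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      if (sub$type[i] == "W") {
        s <- Biostrings::subseq(contigs[[sub$comp_id[i]]],
                                start = sub$comp_beg[i] + 1, end = sub$comp_end[i])
        if (sub$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
        pieces[i] <- as.character(s)
      } else {
        pieces[i] <- strrep("N", sub$gap_length[i])
      }
    }
    out[sc] <- paste(pieces, collapse = "")
  }
  Biostrings::DNAStringSet(out)
}

#' Write a layout as AGP v2.1
#'
#' Gap lines carry the declared length, `gap_type` "scaffold", linkage "yes"
#' and the gap source tag in column 9. Unplaced contigs are written as
#' single-component objects named after the contig.
#'
#' @param layout a [scaffold_layout].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path) {
  comp <- layout$components
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (sc in unique(comp$scaffold)) {
    sub <- comp[comp$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$part), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (sub$type[i] == "W") {
        writeLines(paste(sc, sub$start[i] + 1, sub$end[i], sub$part[i], "W",
                         sub$comp_id[i], sub$comp_beg[i] + 1, sub$comp_end[i],
                         sub$orientation[i], sep = "\t"), con)
      } else {
        writeLines(paste(sc, sub$start[i] + 1, sub$end[i], sub$part[i], sub$type[i],
                         sub$gap_length[i], "scaffold", "yes",
                         sub$gap_source[i], sep = "\t"), con)
      }
    }
  }
  up <- layout$unplaced
  for (i in seq_len(nrow(up))) {
    writeLines(paste(up$comp_id[i], 1, up$length[i], 1, "W",
                     up$comp_id[i], 1, up$length[i], "+", sep = "\t"), con)
  }
  invisible(path)
}

#' Read an AGP v2.1 file into a scaffold layout
#'
#' Component lines `W` become placements, `N`/`U` lines become gaps (unknown
#' size `U` gaps keep their declared 100 bp). Objects consisting of a single
#' component named after themselves are treated as unplaced contigs.
#'
#' @param path AGP file path.
#' @return a [scaffold_layout].
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  obj <- vapply(f, `[`, "", 1)
  typ <- vapply(f, `[`, "", 5)
  col <- function(k) vapply(f, `[`, "", k)
  num_if <- function(x, keep) {
    out <- rep(NA_real_, length(x))
    out[keep] <- as.numeric(x[keep])
    out
  }
  is_w <- typ == "W"
  comp <- tibble::tibble(
    scaffold = obj,
    part = as.integer(col(4)),
    start = as.numeric(col(2)) - 1,
    end = as.numeric(col(3)),
    type = typ,
    comp_id = ifelse(is_w, col(6), NA_character_),
    comp_beg = num_if(col(7), is_w) - 1,
    comp_end = num_if(col(8), is_w),
    orientation = ifelse(is_w, col(9), NA_character_),
    gap_length = num_if(col(6), !is_w),
    gap_source = ifelse(is_w, NA_character_, col(9))
  )
  single <- tapply(seq_len(nrow(comp)), comp$scaffold, length) == 1
  is_unplaced <- comp$scaffold %in% names(single)[single] &
    comp$type == "W" & comp$scaffold == comp$comp_id
  up <- comp[is_unplaced, , drop = FALSE]
  scaffold_layout(
    comp[!is_unplaced, , drop = FALSE],
    tibble::tibble(comp_id = up$comp_id, length = up$end - up$start)
  )
}
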