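#' Label map object
#'
#' An ordered list of label positions (bp, 0-based from sequence start) on a
#' sequence or consensus map, for one enzyme channel. The shape mirrors one
#' channel of a CMAP record.
#'
#' @param map_id map identifier.
#' @param length map length in bp.
#' @param channel enzyme (channel) name.
#' @param positions strictly increasing numeric label positions in
#'   `[0, length)`.
#' @return an object of class `label_map`.
#' @export
label_map <- function(map_id, length, channel, positions) {
  positions <- as.numeric(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("label positions must be strictly increasing", call. = FALSE)
  if (length(positions) && (positions[1] < 0 || positions[length(positions)] >= length))
    stop("label positions must lie in [0, length)", call. = FALSE)
  structure(list(map_id = as.character(map_id), length = as.numeric(length),
                 channel = as.character(channel), positions = positions),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s channel=%s length=%.0f labels=%d\n",
              x$map_id, x$channel, x$length, length(x$positions)))
  invisible(x)
}

#' Find nicking-enzyme recognition sites
#'
#' Exact matches of the motif and of its reverse complement on the forward
#' strand, merged and sorted. Ambiguity codes in the sequence (e.g. runs of N
#' in gap fillers) never match.
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param motif recognition motif over A/C/G/T, length >= 4.
#' @return sorted 0-based start positions of all matches.
#' @export
find_recognition_sites <- function(sequence, motif) {
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) == 0)
    stop("motif must be a non-empty character scalar", call. = FALSE)
  if (grepl("[^ACGT]", motif))
    stop("motif must contain only A/C/G/T", call. = FALSE)
  if (nchar(motif) < 4)
    stop("motif must be at least 4 bp", call. = FALSE)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(motif), sequence, fixed = TRUE)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(motif))
  rev <- Biostrings::matchPattern(rc, sequence, fixed = TRUE)
  sort(unique(c(Biostrings::start(fwd), Biostrings::start(rev)))) - 1
}

#' Condense close label sites
#'
#' Sites closer than `min_dist` are merged left-to-right into their midpoint
#' (rounded down), emulating the resolution limit of optical instruments:
#' two labels closer than ~1 kb are imaged as one.
#'
#' @param positions sorted site positions (bp).
#' @param min_dist minimum separation (bp); 0 returns the input unchanged.
#' @return condensed, strictly increasing positions.
#' @export
condense_sites <- function(positions, min_dist) {
  stopifnot(min_dist >= 0)
  n <- length(positions)
  if (min_dist == 0 || n < 2) return(positions)
  out <- numeric(n)
  k <- 1L
  cur <- positions[1]
  for (i in 2:n) {
    if (positions[i] - cur < min_dist) {
      cur <- floor((cur + positions[i]) / 2)
    } else {
      out[k] <- cur
      k <- k + 1L
      cur <- positions[i]
    }
  }
  out[k] <- cur
  out[seq_len(k)]
}

#' In-silico digestion of sequences
#'
#' Computes a [label_map] per (sequence, enzyme) pair: recognition sites on
#' both strands, condensed at `min_label_distance`.
#'
#' @param sequences a [Biostrings::DNAStringSet] (named) or named character
#'   vector.
#' @param enzymes list of `list(name=, motif=)` entries.
#' @param min_label_distance condensation distance in bp (default 1000).
#' @return a list of [label_map] objects, named `"<seq>|<enzyme>"`.
#' @export
in_silico_digest <- function(sequences, enzymes, min_label_distance = 1000) {
  stopifnot(min_label_distance >= 0)
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  nms <- names(sequences)
  if (is.null(nms)) nms <- paste0("seq", seq_along(sequences))
  maps <- list()
  for (i in seq_along(sequences)) {
    seq_i <- sequences[[i]]
    for (e in enzymes) {
      sites <- find_recognition_sites(seq_i, e$motif)
      lab <- condense_sites(sites, min_label_distance)
      maps[[paste0(nms[i], "|", e$name)]] <-
        label_map(nms[i], length(seq_i), e$name, lab)
    }
  }
  maps
}
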