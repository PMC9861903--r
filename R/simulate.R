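#' Generate a random genome
#'
#' Uniform-composition chromosomes totalling `genome_length` (chromosome
#' sizes jittered around equal shares). Deterministic for a fixed seed.
#'
#' @param config a [sim_config].
#' @param seed seed to use; defaults to `config$seed`. Pass `NULL` to draw
#'   from the current RNG state.
#' @return a named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_chromosomes
  w <- stats::runif(n, 0.9, 1.1)
  lens <- floor(config$genome_length * w / sum(w))
  lens[n] <- config$genome_length - sum(lens[-n])
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(n))
  out
}

## -- misjoin editing machinery -------------------------------------------
## Scaffolds are held as ordered data.frames of (comp_id, orientation).
## Each edit records the ordered pair of contigs flanking one disrupted
## junction; those contigs are then locked so later edits cannot separate
## them, keeping recorded junctions intact and distinct.

mj_state_new <- function(plc) list(plc = plc, locked = character(0), records = list())

mj_interior_slots <- function(plc) {
  out <- NULL
  for (s in names(plc)) {
    n <- nrow(plc[[s]])
    if (n >= 3) out <- rbind(out, data.frame(scaffold = s, idx = 2:(n - 1)))
  }
  out
}

mj_apply_translocation <- function(st) {
  slots <- mj_interior_slots(st$plc)
  if (is.null(slots)) return(NULL)
  free <- slots[!mapply(function(s, i) st$plc[[s]]$comp_id[i] %in% st$locked,
                        slots$scaffold, slots$idx), , drop = FALSE]
  if (nrow(free) < 2) return(NULL)
  for (attempt in seq_len(50)) {
    pick <- free[sample(nrow(free), 2), , drop = FALSE]
    same <- pick$scaffold[1] == pick$scaffold[2]
    if (same && abs(pick$idx[1] - pick$idx[2]) < 2) next
    s1 <- pick$scaffold[1]; i1 <- pick$idx[1]
    s2 <- pick$scaffold[2]; i2 <- pick$idx[2]
    x <- st$plc[[s1]][i1, ]; y <- st$plc[[s2]][i2, ]
    st$plc[[s1]][i1, ] <- y
    st$plc[[s2]][i2, ] <- x
    p <- st$plc[[s1]]$comp_id[i1 - 1]
    st$records <- c(st$records, list(list(type = "TRANSLOCATION",
                                          left = p, right = y$comp_id)))
    st$locked <- union(st$locked, c(p, y$comp_id, x$comp_id))
    return(st)
  }
  NULL
}

mj_apply_inversion <- function(st) {
  slots <- mj_interior_slots(st$plc)
  if (is.null(slots)) return(NULL)
  free <- slots[!mapply(function(s, i) st$plc[[s]]$comp_id[i] %in% st$locked,
                        slots$scaffold, slots$idx), , drop = FALSE]
  if (!nrow(free)) return(NULL)
  pick <- free[sample(nrow(free), 1), , drop = FALSE]
  s <- pick$scaffold; i <- pick$idx
  o <- st$plc[[s]]$orientation[i]
  st$plc[[s]]$orientation[i] <- if (o == "+") "-" else "+"
  k <- st$plc[[s]]$comp_id[i]
  p <- st$plc[[s]]$comp_id[i - 1]
  st$records <- c(st$records, list(list(type = "INVERSION", left = p, right = k)))
  st$locked <- union(st$locked, c(p, k))
  st
}

mj_apply_fusion <- function(st) {
  scs <- names(st$plc)[vapply(st$plc, nrow, 0L) >= 2]
  if (length(scs) < 2) return(NULL)
  cuts <- NULL
  for (s in scs) {
    n <- nrow(st$plc[[s]])
    for (i in seq_len(n - 1)) {
      a <- st$plc[[s]]$comp_id[i]; b <- st$plc[[s]]$comp_id[i + 1]
      if (!(a %in% st$locked) && !(b %in% st$locked))
        cuts <- rbind(cuts, data.frame(scaffold = s, idx = i))
    }
  }
  if (is.null(cuts)) return(NULL)
  for (attempt in seq_len(50)) {
    pick <- cuts[sample(nrow(cuts), 2), , drop = FALSE]
    if (pick$scaffold[1] == pick$scaffold[2]) next
    s1 <- pick$scaffold[1]; i1 <- pick$idx[1]
    s2 <- pick$scaffold[2]; i2 <- pick$idx[2]
    p1 <- st$plc[[s1]]; p2 <- st$plc[[s2]]
    a <- p1$comp_id[i1]; b <- p1$comp_id[i1 + 1]
    cc <- p2$comp_id[i2]; d <- p2$comp_id[i2 + 1]
    st$plc[[s1]] <- rbind(p1[seq_len(i1), ], p2[(i2 + 1):nrow(p2), ])
    st$plc[[s2]] <- rbind(p2[seq_len(i2), ], p1[(i1 + 1):nrow(p1), ])
    st$records <- c(st$records, list(list(type = "FUSION", left = a, right = d)))
    st$locked <- union(st$locked, c(a, b, cc, d))
    return(st)
  }
  NULL
}

## Build a component tibble for scaffolds given per-junction gap lengths.
## gap_len(left_comp, right_comp) -> bp; gap_source tag applied to all gaps.
build_components <- function(plc, contig_len, gap_len, gap_source) {
  rows <- list()
  for (s in names(plc)) {
    df <- plc[[s]]
    pos <- 0; part <- 1L
    for (i in seq_len(nrow(df))) {
      cid <- df$comp_id[i]
      L <- contig_len[[cid]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        scaffold = s, part = part, start = pos, end = pos + L, type = "W",
        comp_id = cid, comp_beg = 0, comp_end = L,
        orientation = df$orientation[i],
        gap_length = NA_real_, gap_source = NA_character_)
      pos <- pos + L; part <- part + 1L
      if (i < nrow(df)) {
        g <- gap_len(cid, df$comp_id[i + 1])
        rows[[length(rows) + 1]] <- tibble::tibble(
          scaffold = s, part = part, start = pos, end = pos + g, type = "N",
          comp_id = NA_character_, comp_beg = NA_real_, comp_end = NA_real_,
          orientation = NA_character_,
          gap_length = g, gap_source = gap_source)
        pos <- pos + g; part <- part + 1L
      }
    }
  }
  do.call(rbind, rows)
}

#' Fragment a genome into contigs and build true and misjoined layouts
#'
#' Contigs tile each chromosome, separated by true physical gaps (normal,
#' truncated at 100 bp). The true layout records contigs with their true gap
#' sizes. The observed layout emulates a Hi-C scaffolder: identical contig
#' order/orientation except for the requested misjoin edits, with every gap
#' replaced by a fixed `hic_gap_fill` filler tagged `"HIC"`. Each edit
#' disrupts at least one junction; the record stores the disrupted junction's
#' coordinate in the observed layout (first base of the gap filler).
#'
#' @param genome a named [Biostrings::DNAStringSet] from [generate_genome()].
#' @param config a [sim_config].
#' @param seed seed (default `config$seed + 1`); `NULL` uses current RNG.
#' @return a list of class `ground_truth` with elements `contigs`
#'   ([Biostrings::DNAStringSet]), `true_layout`, `observed_layout`
#'   ([scaffold_layout]), `misjoin_records` (tibble: `type`, `scaffold`,
#'   `junction_index`, `position`, `left_comp`, `right_comp`),
#'   `true_gap_sizes` (tibble keyed by the left contig of each junction).
#' @export
fragment_and_scaffold <- function(genome, config, seed = config$seed + 1) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  chr_len <- Biostrings::width(genome)
  n_chr <- length(genome)
  ## contigs per chromosome, proportional to length
  ni <- pmax(1L, round(config$n_contigs * chr_len / sum(chr_len)))
  while (sum(ni) != config$n_contigs) {
    k <- which.max(chr_len / ni)
    ni[k] <- ni[k] + sign(config$n_contigs - sum(ni))
  }
  contig_seqs <- character(0)
  contig_len <- numeric(0)
  true_plc <- list()
  true_gaps <- list()   # per junction: left comp -> gap bp
  cid <- 0L
  for (ci in seq_len(n_chr)) {
    n <- ni[ci]
    L <- chr_len[ci]
    g <- if (n > 1) pmax(100, round(stats::rnorm(n - 1, config$true_gap_mean,
                                                 config$true_gap_sd))) else numeric(0)
    avail <- L - sum(g)
    if (avail < n * config$min_contig_length)
      stop("chromosome too small for requested contigs and gaps", call. = FALSE)
    extra <- avail - n * config$min_contig_length
    parts <- config$min_contig_length +
      as.vector(stats::rmultinom(1, extra, prob = stats::runif(n)))
    ids <- sprintf("ctg%04d", cid + seq_len(n))
    cid <- cid + n
    pos <- 0
    for (i in seq_len(n)) {
      contig_seqs[ids[i]] <- as.character(
        Biostrings::subseq(genome[[ci]], pos + 1, pos + parts[i]))
      contig_len[ids[i]] <- parts[i]
      pos <- pos + parts[i]
      if (i < n) {
        true_gaps[[ids[i]]] <- g[i]
        pos <- pos + g[i]
      }
    }
    true_plc[[names(genome)[ci]]] <-
      data.frame(comp_id = ids, orientation = "+", stringsAsFactors = FALSE)
  }
  ## true layout: chromosome-coordinate tiling with true gap sizes
  true_comp <- build_components(true_plc, contig_len,
                                function(l, r) true_gaps[[l]], "TRUE")
  true_layout <- scaffold_layout(true_comp)

  ## observed layout: same order, HIC gaps, then misjoin edits
  obs_plc <- true_plc
  names(obs_plc) <- paste0("scaffold_", seq_len(n_chr))
  st <- mj_state_new(obs_plc)
  mj <- config$misjoins
  for (type in c("FUSION", "TRANSLOCATION", "INVERSION")) {
    k <- if (type %in% names(mj)) mj[[type]] else 0L
    for (i in seq_len(k)) {
      st2 <- switch(type,
                    FUSION = mj_apply_fusion(st),
                    TRANSLOCATION = mj_apply_translocation(st),
                    INVERSION = mj_apply_inversion(st))
      if (is.null(st2))
        stop("requested misjoins exceed available junctions", call. = FALSE)
      st <- st2
    }
  }
  obs_comp <- build_components(st$plc, contig_len,
                               function(l, r) config$hic_gap_fill, "HIC")
  observed_layout <- scaffold_layout(obs_comp)

  ## resolve recorded junctions to observed coordinates
  recs <- st$records
  mj_tbl <- tibble::tibble(type = character(0), scaffold = character(0),
                           junction_index = integer(0), position = numeric(0),
                           left_comp = character(0), right_comp = character(0))
  if (length(recs)) {
    gaps <- gap_records(observed_layout, source = "HIC")
    rows <- lapply(recs, function(r) {
      hit <- NULL
      for (s in names(st$plc)) {
        ids <- st$plc[[s]]$comp_id
        i <- which(ids == r$left)
        if (length(i) && i < length(ids) && ids[i + 1] == r$right) {
          g <- gaps[gaps$scaffold == s, , drop = FALSE][i, ]
          hit <- tibble::tibble(type = r$type, scaffold = s,
                                junction_index = i, position = g$start,
                                left_comp = r$left, right_comp = r$right)
          break
        }
      }
      if (is.null(hit)) stop("internal error: recorded junction lost", call. = FALSE)
      hit
    })
    mj_tbl <- do.call(rbind, rows)
  }
  structure(list(
    contigs = Biostrings::DNAStringSet(contig_seqs),
    true_layout = true_layout,
    observed_layout = observed_layout,
    misjoin_records = mj_tbl,
    true_gap_sizes = tibble::tibble(left_comp = names(true_gaps),
                                    gap = unlist(true_gaps, use.names = FALSE))
  ), class = "ground_truth")
}

#' Ground-truth status of every Hi-C junction
#'
#' A junction is intact when its flanking contigs are truly adjacent in the
#' same relative order and orientation; otherwise it is misjoined.
#'
#' @param truth a `ground_truth` from [fragment_and_scaffold()].
#' @return tibble, one row per HIC gap of the observed layout: `scaffold`,
#'   `gap_index`, `start`, `end`, `left_comp`, `right_comp`, `intact`,
#'   `true_gap` (bp, `NA` for misjoined junctions).
#' @export
junction_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tc <- truth$true_layout$components
  tw <- tc[tc$type == "W", , drop = FALSE]
  true_next <- character(0)
  for (s in unique(tw$scaffold)) {
    ids <- tw$comp_id[tw$scaffold == s]
    if (length(ids) > 1) true_next[ids[-length(ids)]] <- ids[-1]
  }
  gap_after <- stats::setNames(truth$true_gap_sizes$gap, truth$true_gap_sizes$left_comp)
  oc <- truth$observed_layout$components
  rows <- list()
  for (s in unique(oc$scaffold)) {
    sub <- oc[oc$scaffold == s, , drop = FALSE]
    sub <- sub[order(sub$part), , drop = FALSE]
    gidx <- 0L
    for (i in seq_len(nrow(sub))) {
      if (sub$type[i] == "W") next
      gidx <- gidx + 1L
      L <- sub[i - 1, ]; R <- sub[i + 1, ]
      intact <- FALSE; tg <- NA_real_
      if (L$orientation == "+" && R$orientation == "+" &&
          !is.na(true_next[L$comp_id]) && isTRUE(true_next[[L$comp_id]] == R$comp_id)) {
        intact <- TRUE; tg <- gap_after[[L$comp_id]]
      } else if (L$orientation == "-" && R$orientation == "-" &&
                 !is.na(true_next[R$comp_id]) && isTRUE(true_next[[R$comp_id]] == L$comp_id)) {
        intact <- TRUE; tg <- gap_after[[R$comp_id]]
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        scaffold = s, gap_index = gidx, start = sub$start[i], end = sub$end[i],
        left_comp = L$comp_id, right_comp = R$comp_id, intact = intact,
        true_gap = tg)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a noisy optical label map of a sequence
#'
#' Starts from the exact in-silico site list, then applies the optical noise
#' model: each inter-label interval of true length L gets additive Gaussian
#' noise with SD `sizing_sd_coeff * sqrt(L/1000)`; each label is dropped
#' independently with probability `label_miss_rate`; false labels are added
#' as a homogeneous Poisson process at `false_label_rate` per 100 kb.
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param enzyme a `list(name=, motif=)` entry.
#' @param config a [sim_config] supplying the noise parameters.
#' @param map_id identifier for the resulting map.
#' @param seed optional seed; `NULL` (default) uses the current RNG state.
#' @param min_label_distance condensation distance applied to the true site
#'   list before noise (match the value used for reference digests).
#' @return a [label_map].
#' @export
simulate_label_map <- function(sequence, enzyme, config, map_id = "map",
                               seed = NULL, min_label_distance = 1000) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  len <- length(sequence)
  pos <- condense_sites(find_recognition_sites(sequence, enzyme$motif),
                        min_label_distance)
  n <- length(pos)
  if (n > 0 && config$sizing_sd_coeff > 0) {
    d <- diff(c(0, pos))
    noise <- stats::rnorm(n, 0, config$sizing_sd_coeff * sqrt(d / 1000))
    pos <- cumsum(pmax(1, d + noise))
  }
  if (n > 0 && config$label_miss_rate > 0) {
    pos <- pos[stats::runif(n) >= config$label_miss_rate]
  }
  if (config$false_label_rate > 0) {
    m <- stats::rpois(1, config$false_label_rate * len / 1e5)
    if (m > 0) pos <- c(pos, stats::runif(m, 0, len))
  }
  pos <- sort(unique(pos))
  len_out <- max(len, if (length(pos)) max(pos) + 1 else 0)
  label_map(map_id, len_out, enzyme$name, pos)
}

#' Simulate long-read alignments in observed-scaffold coordinates
#'
#' Reads are drawn from the true genome (lognormal lengths, uniform starts,
#' to the requested coverage) and emitted as PAF-shaped records against the
#' observed layout. A read is split wherever its true locus is discontiguous
#' in the observed layout; consequently an intact Hi-C junction acquires
#' single-record spanning reads and a misjoined junction acquires none, with
#' the split fragments mapped to their true contigs' observed positions.
#' Read bases falling into true gap regions are not part of any record.
#'
#' @param truth a `ground_truth` from [fragment_and_scaffold()].
#' @param config a [sim_config].
#' @param seed seed (default `config$seed + 2`); `NULL` uses current RNG.
#' @return tibble of PAF records: `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#' @export
simulate_read_alignments <- function(truth, config, seed = config$seed + 2) {
  validate_sim_config(config)
  if (config$read_coverage <= 0)
    stop("invalid simulation config: read_coverage must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tc <- truth$true_layout$components
  oc <- truth$observed_layout$components
  ow <- oc[oc$type == "W", , drop = FALSE]
  ## per-contig observed placement as named vectors (fast lookups)
  obs_scaf <- stats::setNames(ow$scaffold, ow$comp_id)
  obs_start <- stats::setNames(ow$start, ow$comp_id)
  obs_end <- stats::setNames(ow$end, ow$comp_id)
  obs_orient <- stats::setNames(ow$orientation, ow$comp_id)
  ord_idx <- stats::setNames(integer(nrow(ow)), ow$comp_id)
  for (s in unique(ow$scaffold)) {
    ids <- ow$comp_id[ow$scaffold == s][order(ow$part[ow$scaffold == s])]
    ord_idx[ids] <- seq_along(ids)
  }
  merge_ok <- function(c1, c2) {
    if (obs_scaf[[c1]] != obs_scaf[[c2]]) return(FALSE)
    i <- ord_idx[[c1]]; j <- ord_idx[[c2]]
    (j == i + 1 && obs_orient[[c1]] == "+" && obs_orient[[c2]] == "+") ||
      (i == j + 1 && obs_orient[[c1]] == "-" && obs_orient[[c2]] == "-")
  }
  chroms <- unique(tc$scaffold)
  chr_len <- scaffold_lengths(truth$true_layout)
  scaf_len <- scaffold_lengths(truth$observed_layout)
  mean_len <- config$read_length_median * exp(config$read_length_sigma^2 / 2)
  n_reads <- ceiling(config$read_coverage * sum(chr_len) / mean_len)
  read_chr <- sample(chroms, n_reads, replace = TRUE, prob = chr_len[chroms])
  read_len <- round(stats::rlnorm(n_reads, log(config$read_length_median),
                                  config$read_length_sigma))
  read_start <- floor(stats::runif(n_reads) * (chr_len[read_chr] - 1))
  comp_by_chr <- lapply(chroms, function(s) {
    w <- tc[tc$scaffold == s & tc$type == "W", , drop = FALSE]
    w <- w[order(w$part), , drop = FALSE]
    list(start = w$start, end = w$end, comp_id = w$comp_id)
  })
  names(comp_by_chr) <- chroms
  ## vector accumulators: one slot per emitted PAF record
  cap <- n_reads * 2L
  o_ri <- integer(cap); o_qlen <- numeric(cap)
  o_qs <- numeric(cap); o_qe <- numeric(cap); o_strand <- character(cap)
  o_t <- character(cap); o_ts <- numeric(cap); o_te <- numeric(cap)
  o_nm <- numeric(cap)
  nout <- 0L
  push <- function(ri, qlen, qs, qe, strand, tname, ts, te, nm) {
    nout <<- nout + 1L
    if (nout > length(o_ri)) {   # grow
      grow <- function(v) c(v, vector(mode = mode(v), length = length(v)))
      o_ri <<- grow(o_ri); o_qlen <<- grow(o_qlen); o_qs <<- grow(o_qs)
      o_qe <<- grow(o_qe); o_strand <<- grow(o_strand); o_t <<- grow(o_t)
      o_ts <<- grow(o_ts); o_te <<- grow(o_te); o_nm <<- grow(o_nm)
    }
    o_ri[nout] <<- ri; o_qlen[nout] <<- qlen; o_qs[nout] <<- qs
    o_qe[nout] <<- qe; o_strand[nout] <<- strand; o_t[nout] <<- tname
    o_ts[nout] <<- ts; o_te[nout] <<- te; o_nm[nout] <<- nm
  }
  for (ri in seq_len(n_reads)) {
    chr <- read_chr[ri]
    w <- comp_by_chr[[chr]]
    s <- read_start[ri]
    e <- min(s + read_len[ri], chr_len[[chr]])
    qlen <- e - s
    idx <- which(w$end > s & w$start < e)
    if (!length(idx)) next
    ## current (possibly merged) fragment
    cur <- NULL
    for (i in idx) {
      a <- max(s, w$start[i]); b <- min(e, w$end[i])
      cid <- w$comp_id[i]
      if (obs_orient[[cid]] == "+") {
        ts <- obs_start[[cid]] + (a - w$start[i])
        te <- obs_start[[cid]] + (b - w$start[i])
        strand <- "+"
      } else {
        ts <- obs_start[[cid]] + (w$end[i] - b)
        te <- obs_start[[cid]] + (w$end[i] - a)
        strand <- "-"
      }
      if (!is.null(cur) && cur$strand == strand && merge_ok(cur$cid, cid)) {
        cur$qe <- b - s
        cur$ts <- min(cur$ts, ts); cur$te <- max(cur$te, te)
        cur$bases <- cur$bases + (b - a)
        cur$cid <- cid
      } else {
        if (!is.null(cur))
          push(ri, qlen, cur$qs, cur$qe, cur$strand, cur$tname,
               cur$ts, cur$te, cur$bases)
        cur <- list(cid = cid, qs = a - s, qe = b - s, strand = strand,
                    tname = obs_scaf[[cid]], ts = ts, te = te, bases = b - a)
      }
    }
    push(ri, qlen, cur$qs, cur$qe, cur$strand, cur$tname, cur$ts, cur$te, cur$bases)
  }
  keep <- seq_len(nout)
  tibble::tibble(
    qname = sprintf("read%06d", o_ri[keep]), qlen = o_qlen[keep],
    qstart = o_qs[keep], qend = o_qe[keep], strand = o_strand[keep],
    tname = o_t[keep], tlen = unname(scaf_len[o_t[keep]]),
    tstart = o_ts[keep], tend = o_te[keep], nmatch = o_nm[keep],
    alen = o_qe[keep] - o_qs[keep], mapq = 60L)
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs the whole generator under one seed: genome, contigs, true and
#' misjoined layouts, one noisy label map per (chromosome, enzyme), and
#' read alignments. This is the fixture generator used by the package's
#' synthetic experiments.
#'
#' @param config a [sim_config].
#' @param reads simulate read alignments too (default `TRUE`; skip for
#'   map-only experiments).
#' @return list of class `sim_dataset`: `config`, `genome`, `truth`
#'   (`ground_truth`), `query_maps` (list of [label_map], one per
#'   chromosome/enzyme), `reads` (PAF tibble or `NULL`).
#' @export
simulate_dataset <- function(config, reads = TRUE) {
  validate_sim_config(config)
  genome <- generate_genome(config, seed = config$seed)
  truth <- fragment_and_scaffold(genome, config, seed = config$seed + 1)
  query_maps <- list()
  for (ci in seq_along(genome)) {
    for (ei in seq_along(config$enzymes)) {
      e <- config$enzymes[[ei]]
      id <- names(genome)[ci]
      query_maps[[paste0(id, "|", e$name)]] <-
        simulate_label_map(genome[[ci]], e, config, map_id = id,
                           seed = config$seed + 1000 + 17 * ci + ei)
    }
  }
  paf <- if (reads) simulate_read_alignments(truth, config, seed = config$seed + 2)
         else NULL
  structure(list(config = config, genome = genome, truth = truth,
                 query_maps = query_maps, reads = paf),
            class = "sim_dataset")
}
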