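# Novel-miRNA candidate evaluation: flank extraction around genome
# hits, MFE folding, MFE/AMFE/MFEI metrics and the filter battery
# (genome hits, mature length, MFE, stem residence, MFEI, single
# stem-loop). The machine-learned pseudo-precursor classifier used in
# published screens is replaced here by this deterministic battery
# and flagged in reports as "mipred_surrogate".

#' Extract precursor windows around genome hits
#'
#' For each hit, the window `[start - flank, end + flank)` on its
#' chromosome, clipped to the sequence ends; minus-strand hits return
#' the reverse complement of the plus-strand window. Coordinates are
#' 0-based, half-open.
#'
#' @param hits data frame with columns `locus`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`).
#' @param genome data frame with columns `id`, `seq` (e.g. from
#'   [read_fasta()]).
#' @param flank bases added on each side (default 150).
#' @return the hits tibble with `window_start`, `window_end` (plus
#'   strand coordinates) and `window` (oriented sequence) added.
#' @export
extract_flanks <- function(hits, genome, flank = 150L) {
  check_that(all(c("locus", "chrom", "start", "end", "strand") %in% names(hits)),
             "`hits` needs columns locus, chrom, start, end, strand")
  check_that(all(c("id", "seq") %in% names(genome)),
             "`genome` needs columns id, seq")
  glen <- setNames(nchar(genome$seq), genome$id)
  gseq <- setNames(genome$seq, genome$id)
  check_that(all(hits$chrom %in% genome$id), "hit chromosome not in genome")
  check_that(all(hits$start >= 0 & hits$end <= glen[hits$chrom] &
                   hits$start < hits$end),
             "hit coordinates out of genome bounds")
  ws <- pmax(0L, hits$start - flank)
  we <- pmin(unname(glen[hits$chrom]), hits$end + flank)
  check_that(all(we > ws), "empty extraction window")
  win <- substr(gseq[hits$chrom], ws + 1L, we)
  minus <- hits$strand == "-"
  win[minus] <- revcomp(win[minus])
  dplyr::mutate(as_tibble(hits), window_start = ws, window_end = we,
                window = unname(win))
}

#' Fold sequences to their minimum-free-energy structure
#'
#' Pseudoknot-free secondary structure minimizing the package's
#' nearest-neighbour energy model (see [energy_params()]): stacking
#' energies for Watson-Crick and G.U pairs, hairpin loops of at least
#' 3 unpaired bases, bulge and internal loop penalties, no multibranch
#' loops. A sequence with no possible pairs folds to all-unpaired at
#' exactly 0 kcal/mol. Deterministic: ties are broken by a fixed
#' traceback preference (pairing over unpaired; innermost pairs at the
#' smallest 5' position, then the largest 3' position).
#'
#' @param seq character vector of sequences over `{A,C,G,U/T}`.
#' @param params energy parameter set from [energy_params()].
#' @return a tibble with columns `seq`, `structure` (dot-bracket) and
#'   `mfe` (kcal/mol, `<= 0`).
#' @export
#' @examples
#' fold_mfe("GGGGCAAAACCCC")
fold_mfe <- function(seq, params = energy_params()) {
  seq <- normalize_seq(seq)
  check_that(all(nchar(seq) >= 1), "sequences must be non-empty")
  res <- lapply(seq, function(s) {
    codes <- encode_seq(s)
    tabs <- loop_tables(nchar(s), params)
    c_fold_mfe(codes, params$stack, tabs$hairpin, tabs$bulge, tabs$internal,
               params$min_hairpin, params$max_loop)
  })
  tibble(seq = seq,
         structure = vapply(res, `[[`, character(1), "structure"),
         mfe = vapply(res, `[[`, numeric(1), "mfe"))
}

#' Parse a dot-bracket string into a partner map
#'
#' @param structure dot-bracket string.
#' @return integer vector: `partner[i]` is the 1-based position paired
#'   with `i`, `NA` if unpaired.
#' @export
parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  partner <- rep(NA_integer_, length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      check_that(length(open) > 0, "unbalanced dot-bracket string",
                 class = "caprimir_format_error")
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  check_that(length(open) == 0, "unbalanced dot-bracket string",
             class = "caprimir_format_error")
  partner
}

# top-level closed-pair spans (depth-0 helices) of a structure:
# tibble of 1-based from/to
toplevel_spans <- function(partner) {
  spans <- list()
  i <- 1L
  n <- length(partner)
  while (i <= n) {
    if (!is.na(partner[i]) && partner[i] > i) {
      spans[[length(spans) + 1]] <- c(i, partner[i])
      i <- partner[i] + 1L
    } else {
      i <- i + 1L
    }
  }
  spans
}

# terminal loop spans: list of c(from, to) of unpaired runs enclosed
# by an innermost pair
terminal_loops <- function(structure) {
  m <- gregexpr("\\((\\.*)\\)", structure)[[1]]
  if (m[1] == -1) return(list())
  lapply(seq_along(m), function(k) {
    c(m[k] + 1L, m[k] + attr(m, "match.length")[k] - 2L)
  })
}

#' Precursor folding metrics: AMFE and MFEI
#'
#' `AMFE = 100 * MFE / length` (kcal/mol per 100 nt) and
#' `MFEI = |AMFE| / GC%`, the minimal folding free energy index whose
#' values above 0.85 characterize miRNA precursors. A GC content of
#' zero leaves MFEI undefined (`NA`; such candidates fail the screen).
#'
#' @param mfe minimum free energy, kcal/mol (`<= 0`).
#' @param seq precursor sequence(s).
#' @return tibble with columns `amfe`, `gc_percent`, `mfei`.
#' @export
mfei_metrics <- function(mfe, seq) {
  seq <- normalize_seq(seq)
  len <- nchar(seq)
  check_that(all(len > 0), "sequences must be non-empty")
  check_that(all(mfe <= 0), "`mfe` must be <= 0")
  gc <- 100 * (nchar(gsub("[^GC]", "", seq))) / len
  amfe <- 100 * mfe / len
  tibble(amfe = amfe, gc_percent = gc,
         mfei = ifelse(gc == 0, NA_real_, abs(amfe) / gc))
}

#' Evaluate novel-miRNA hairpin candidates
#'
#' Folds each window, trims it to the stem-loop harboring the mature
#' read (the top-level helix of the window's minimum-energy structure
#' with maximal overlap with the mature read; flanking sequence folds
#' independently and is discarded), refolds the trimmed precursor and
#' applies the filter battery, one flag per criterion: (1) at most
#' `genome_hits_max` genome hits; (2) mature length within
#' `mature_len`; (3) `MFE < mfe_max`; (4) mature read resides in a
#' stem arm (at most `loop_bases_max` mature bases inside terminal
#' loops or outside the precursor); (5) `MFEI > mfei_min`; (6) a
#' single terminal loop in the precursor's minimum-energy structure.
#' The verdict is the conjunction of all flags. The battery stands in
#' for a machine-learned precursor classifier and is labelled
#' `mipred_surrogate` in the output.
#'
#' @param candidates data frame with columns `locus`, `window`
#'   (precursor sequence containing the mature read), `mature`
#'   (mature read sequence) and `genome_hits`.
#' @param mfe_max MFE threshold, kcal/mol (default -18; filter is
#'   `mfe < mfe_max`).
#' @param mfei_min MFEI threshold (default 0.85; filter is strict
#'   `>`).
#' @param mature_len inclusive mature length range (default 16-30).
#' @param genome_hits_max maximum genome hits (default 10).
#' @param loop_bases_max mature bases allowed inside terminal loops
#'   (default 4).
#' @param params energy parameter set from [energy_params()].
#' @return a `mir_hairpins` tibble with the trimmed `precursor` (and
#'   its `precursor_start`/`precursor_end` within the window), the
#'   folding fields (`structure`, `mfe`, `amfe`, `gc_percent`,
#'   `mfei`), mature placement (`mature_start`, `mature_end`, 0-based
#'   half-open on the precursor, and `arm`), per-filter flags `flag_hits`, `flag_len`, `flag_mfe`,
#'   `flag_stem`, `flag_mfei`, `flag_single_loop`, the `verdict`, and
#'   a `screen` label column.
#' @export
evaluate_candidates <- function(candidates, mfe_max = -18, mfei_min = 0.85,
                                mature_len = c(16L, 30L), genome_hits_max = 10L,
                                loop_bases_max = 4L, params = energy_params()) {
  check_that(all(c("locus", "window", "mature", "genome_hits") %in%
                   names(candidates)),
             "`candidates` needs columns locus, window, mature, genome_hits")
  candidates <- as_tibble(candidates)
  win <- normalize_seq(candidates$window)
  mat <- normalize_seq(candidates$mature)

  pos <- vapply(seq_along(win), function(i) {
    regexpr(mat[i], win[i], fixed = TRUE)[[1]]
  }, integer(1))
  if (any(pos < 0)) {
    abort(sprintf("mature read not found in window for locus '%s'",
                  candidates$locus[which(pos < 0)[1]]),
          class = "caprimir_domain_error")
  }

  window_fold <- fold_mfe(win, params)

  placement <- lapply(seq_along(win), function(i) {
    s <- pos[i]                        # 1-based start of mature in window
    e <- s + nchar(mat[i]) - 1L
    wpartner <- parse_dotbracket(window_fold$structure[i])
    spans <- toplevel_spans(wpartner)
    overlap <- vapply(spans, function(sp) {
      max(0L, min(sp[2], e) - max(sp[1], s) + 1L)
    }, integer(1))
    if (length(spans) > 0 && max(overlap) > 0) {
      sp <- spans[[which.max(overlap)]]
    } else {
      sp <- c(1L, nchar(win[i]))       # no harboring helix: keep window
    }
    prec <- substr(win[i], sp[1], sp[2])
    pf <- fold_mfe(prec, params)
    partner <- parse_dotbracket(pf$structure)
    loops <- terminal_loops(pf$structure)
    in_loop <- rep(FALSE, nchar(prec))
    for (lp in loops) if (lp[2] >= lp[1]) in_loop[lp[1]:lp[2]] <- TRUE
    # mature coordinates within the precursor; bases falling outside
    # the precursor count against stem residence
    ps <- s - sp[1] + 1L
    pe <- e - sp[1] + 1L
    inside <- max(ps, 1L):min(pe, nchar(prec))
    outside <- length(ps:pe) - length(inside)
    loop_bases <- sum(in_loop[inside]) + outside
    partners <- partner[inside]
    paired <- !is.na(partners)
    arm <- if (!any(paired)) {
      "loop"
    } else if (mean(partners[paired] > inside[paired]) >= 0.5) "5p" else "3p"
    list(precursor = prec, structure = pf$structure, mfe = pf$mfe,
         prec_start0 = sp[1] - 1L, prec_end0 = sp[2],
         start0 = max(ps, 1L) - 1L, end0 = min(pe, nchar(prec)),
         arm = arm, loop_bases = loop_bases, n_loops = length(loops))
  })

  prec <- vapply(placement, `[[`, character(1), "precursor")
  prec_mfe <- vapply(placement, `[[`, numeric(1), "mfe")
  metrics <- mfei_metrics(prec_mfe, prec)

  out <- dplyr::mutate(
    candidates,
    precursor = prec,
    precursor_start = vapply(placement, `[[`, integer(1), "prec_start0"),
    precursor_end = vapply(placement, `[[`, integer(1), "prec_end0"),
    structure = vapply(placement, `[[`, character(1), "structure"),
    mfe = prec_mfe,
    amfe = metrics$amfe,
    gc_percent = metrics$gc_percent,
    mfei = metrics$mfei,
    mature_start = vapply(placement, `[[`, integer(1), "start0"),
    mature_end = vapply(placement, `[[`, integer(1), "end0"),
    arm = vapply(placement, `[[`, character(1), "arm"),
    loop_bases = vapply(placement, function(p) as.integer(p$loop_bases),
                        integer(1)),
    n_terminal_loops = vapply(placement, function(p) as.integer(p$n_loops),
                              integer(1)),
    flag_hits = .data$genome_hits <= genome_hits_max,
    flag_len = nchar(mat) >= mature_len[1] & nchar(mat) <= mature_len[2],
    flag_mfe = .data$mfe < mfe_max,
    flag_stem = .data$loop_bases <= loop_bases_max,
    flag_mfei = !is.na(.data$mfei) & .data$mfei > mfei_min,
    flag_single_loop = .data$n_terminal_loops == 1L,
    verdict = .data$flag_hits & .data$flag_len & .data$flag_mfe &
      .data$flag_stem & .data$flag_mfei & .data$flag_single_loop,
    screen = "mipred_surrogate")
  structure(out, class = c("mir_hairpins", class(tibble())))
}

#' Write dot-bracket structures in Vienna-style text
#' @param hairpins a `mir_hairpins` tibble (or any frame with `locus`,
#'   `precursor`, `structure`, `mfe`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(hairpins, path) {
  writeLines(paste0(">", hairpins$locus, "\n", hairpins$precursor, "\n",
                    hairpins$structure,
                    sprintf(" (%.2f)", hairpins$mfe)), path)
  invisible(path)
}
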