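# Rule-based miRNA -> 3'UTR target prediction with penalty scoring
# after the plant-rule convention (Allen 2005 / Schwab 2005): the
# miRNA is aligned 5'->3' against the reverse-complement sense of a
# UTR window; each mismatch costs 1.0, each G.U wobble 0.5 and each
# 1-nt bulge 2.0, all doubled at miRNA positions 2-13. Sites pass at
# penalty <= 4.0, with no more than 2 consecutive mismatches and no
# mismatch at positions 10-11. A nearest-neighbour stacking sum over
# the paired run gives a duplex energy for ranking.
#
# Alignment strings run along the miRNA 5'->3' plus bulged bases:
# "|" Watson-Crick match, "o" G.U wobble, "x" mismatch, "-" bulge.

COST_MISMATCH <- 1.0
COST_GU <- 0.5
COST_BULGE <- 2.0
DOUBLED_POSITIONS <- 2:13

rule_weights <- function(m) ifelse(seq_len(m) %in% DOUBLED_POSITIONS, 2, 1)

# score one gapless alignment of miRNA chars vs aligned site chars
# (site chars already ordered along the miRNA)
score_gapless <- function(mi_chars, site_chars) {
  comp <- chartr("ACGT", "TGCA", mi_chars)
  match <- site_chars == comp
  gu <- !match & ((mi_chars == "G" & site_chars == "T") |
                    (mi_chars == "T" & site_chars == "G"))
  mism <- !match & !gu
  w <- rule_weights(length(mi_chars))
  list(penalty = sum(w * (COST_MISMATCH * mism + COST_GU * gu)),
       states = ifelse(match, "|", ifelse(gu, "o", "x")))
}

#' Score a miRNA against one candidate site
#'
#' Aligns the miRNA 5'->3' against the reverse-complement sense of the
#' site (given in UTR plus-strand orientation) and returns the
#' penalty under the rule table, allowing at most one 1-nt bulge on
#' either strand (site length within miRNA length +/- 1). Among
#' alternative bulge placements the smallest penalty wins (the
#' 5'-most placement on ties).
#'
#' @param mirna mature miRNA sequence (5'->3').
#' @param site UTR site sequence, plus strand.
#' @return a list with `penalty`, `alignment` (string along the miRNA
#'   plus bulges: `|` match, `o` G.U, `x` mismatch, `-` bulge) and
#'   `site` (the input site).
#' @export
#' @examples
#' duplex_score("TGGAATGTAAAGAAGTATGTAT", revcomp("TGGAATGTAAAGAAGTATGTAT"))
duplex_score <- function(mirna, site) {
  mirna <- normalize_seq(mirna)
  site <- normalize_seq(site)
  m <- nchar(mirna)
  L <- nchar(site)
  check_that(abs(L - m) <= 1,
             "site length must be within 1 nt of the miRNA length (one 1-nt bulge)")
  check_that(m >= 3, "miRNA too short to score")
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  sc <- strsplit(site, "", fixed = TRUE)[[1]]

  cands <- list()
  if (L == m) {
    g <- score_gapless(mi, sc[m + 1 - seq_len(m)])
    cands[[1]] <- list(penalty = g$penalty, aln = paste(g$states, collapse = ""))
  } else if (L == m + 1) {
    # extra site base bulged out between miRNA positions g and g+1
    for (g in seq_len(m - 1)) {
      sp <- (m + 1) - seq_len(m) + ifelse(seq_len(m) <= g, 1L, 0L)
      gg <- score_gapless(mi, sc[sp])
      bw <- if ((g + 1) %in% DOUBLED_POSITIONS) 2 else 1
      states <- append(gg$states, "-", after = g)
      cands[[length(cands) + 1]] <- list(
        penalty = gg$penalty + COST_BULGE * bw,
        aln = paste(states, collapse = ""))
    }
  } else {
    # miRNA base b bulged out (unpaired), interior positions only
    for (b in 2:(m - 1)) {
      idx <- setdiff(seq_len(m), b)
      gg <- score_gapless(mi[idx], sc[L + 1 - seq_along(idx)])
      bw <- if (b %in% DOUBLED_POSITIONS) 2 else 1
      states <- append(gg$states, "-", after = b - 1L)
      cands[[length(cands) + 1]] <- list(
        penalty = gg$penalty + COST_BULGE * bw,
        aln = paste(states, collapse = ""))
    }
  }
  best <- which.min(vapply(cands, `[[`, numeric(1), "penalty"))
  list(penalty = cands[[best]]$penalty, alignment = cands[[best]]$aln,
       site = site)
}

# alignment-string filters: no mismatch at miRNA positions 10-11, no
# run of 3+ consecutive mismatches (runs counted along the alignment)
alignment_passes <- function(aln) {
  states <- strsplit(aln, "", fixed = TRUE)[[1]]
  mi_pos <- cumsum(states != "-")
  mm <- states == "x"
  if (any(mm & mi_pos %in% c(10L, 11L))) return(FALSE)
  r <- rle(mm)
  !any(r$values & r$lengths > 2)
}

#' Intermolecular duplex energy of an alignment
#'
#' Sum of nearest-neighbour stacking energies over consecutive paired
#' positions (Watson-Crick or G.U) of a [duplex_score()] alignment;
#' 0 for a fully unpaired alignment. A reporting/ranking field, not a
#' filter.
#'
#' @param mirna mature miRNA sequence.
#' @param site aligned site sequence (plus strand, as scored).
#' @param alignment alignment string from [duplex_score()].
#' @param params energy parameter set from [energy_params()].
#' @return duplex energy in kcal/mol (`<= 0`).
#' @export
duplex_energy <- function(mirna, site, alignment, params = energy_params()) {
  mirna <- normalize_seq(mirna)
  site <- normalize_seq(site)
  states <- strsplit(alignment, "", fixed = TRUE)[[1]]
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  sc <- strsplit(site, "", fixed = TRUE)[[1]]
  m <- length(mi)
  L <- length(sc)
  mi_pos <- cumsum(states != "-")
  # site is consumed 3'->5' along the alignment; a bulge column
  # consumes a site base only when the bulge is on the site strand
  consumed <- if (L > m) rep(TRUE, length(states)) else states != "-"
  site_idx <- L + 1L - cumsum(consumed)
  paired <- states %in% c("|", "o")
  energy <- 0
  for (k in seq_len(max(length(states) - 1, 0))) {
    if (paired[k] && paired[k + 1]) {
      p1 <- pair_type(mi[mi_pos[k]], sc[site_idx[k]])
      p2 <- pair_type(mi[mi_pos[k + 1]], sc[site_idx[k + 1]])
      if (!is.na(p1) && !is.na(p2)) energy <- energy + params$stack[p1, p2]
    }
  }
  min(energy, 0)
}

# One vectorized scan pass over all windows of one UTR for one miRNA.
# `gap`: NA for gapless; list(type = "site", g) for an extra site base
# bulged after miRNA position g; list(type = "mirna", b) for miRNA
# base b bulged. Mismatch-run and 10-11 rules are evaluated along the
# miRNA positions (conservative across a bulge).
scan_pass <- function(mi, uc, gap = NULL) {
  m <- length(mi)
  n <- length(uc)
  L <- if (is.null(gap)) m else if (gap$type == "site") m + 1L else m - 1L
  if (n < L) return(NULL)
  starts <- seq_len(n - L + 1L)               # 1-based window starts
  offs <- if (is.null(gap)) {
    m - seq_len(m)                            # partner = w + m - i
  } else if (gap$type == "site") {
    m - seq_len(m) + ifelse(seq_len(m) <= gap$g, 1L, 0L)
  } else {
    ifelse(seq_len(m) < gap$b, m - 1L - seq_len(m), m - seq_len(m))
  }
  active <- if (is.null(gap) || gap$type == "site") rep(TRUE, m) else
    seq_len(m) != gap$b
  w <- rule_weights(m)
  penalty <- numeric(length(starts))
  mismL <- matrix(FALSE, nrow = length(starts), ncol = m)
  comp <- chartr("ACGT", "TGCA", mi)
  for (i in which(active)) {
    P <- uc[starts + offs[i]]
    mt <- P == comp[i]
    gu <- !mt & ((mi[i] == "G" & P == "T") | (mi[i] == "T" & P == "G"))
    mm <- !mt & !gu
    mismL[, i] <- mm
    penalty <- penalty + w[i] * (COST_MISMATCH * mm + COST_GU * gu)
  }
  if (!is.null(gap)) {
    bp <- if (gap$type == "site") gap$g + 1L else gap$b
    penalty <- penalty + COST_BULGE * (if (bp %in% DOUBLED_POSITIONS) 2 else 1)
  }
  ok1011 <- !(mismL[, 10L] | mismL[, 11L])
  run3 <- rep(FALSE, length(starts))
  for (i in seq_len(m - 2L)) {
    run3 <- run3 | (mismL[, i] & mismL[, i + 1L] & mismL[, i + 2L])
  }
  tibble(start0 = starts - 1L, end0 = starts - 1L + L,
         penalty = penalty, pass_rules = ok1011 & !run3,
         bulged = !is.null(gap))
}

#' Scan 3'UTRs for miRNA target sites
#'
#' Scores every UTR window against every miRNA under the rule table
#' and keeps sites with penalty at most `max_penalty` that satisfy the
#' mismatch rules (none at miRNA positions 10-11; no more than 2
#' consecutive). Overlapping hits of the same miRNA on the same UTR
#' are collapsed to the best-scoring window. Retained sites get an
#' alignment and duplex energy and are sorted by
#' `(penalty, duplex_mfe)`.
#'
#' @param mirnas data frame with columns `id`, `seq` (mature miRNAs,
#'   at least 12 nt).
#' @param utrs data frame with columns `id`, `seq` (3'UTRs).
#' @param max_penalty penalty cutoff (default 4.0).
#' @param with_bulges also consider alignments with one 1-nt bulge
#'   (default TRUE).
#' @param params energy parameter set for the duplex energies.
#' @return a `mir_sites` tibble: `mirna`, `transcript`, `start`,
#'   `end` (0-based half-open on the UTR), `penalty`, `duplex_mfe`,
#'   `alignment`, `site`.
#' @export
scan_targets <- function(mirnas, utrs, max_penalty = 4.0, with_bulges = TRUE,
                         params = energy_params()) {
  check_that(all(c("id", "seq") %in% names(mirnas)) &&
               all(c("id", "seq") %in% names(utrs)),
             "`mirnas` and `utrs` need columns id, seq")
  mirnas <- dplyr::mutate(as_tibble(mirnas), seq = normalize_seq(.data$seq))
  utrs <- dplyr::mutate(as_tibble(utrs), seq = normalize_seq(.data$seq))
  check_that(all(nchar(mirnas$seq) >= 12), "miRNAs must be at least 12 nt")

  empty <- tibble(mirna = character(), transcript = character(),
                  start = integer(), end = integer(), penalty = numeric(),
                  duplex_mfe = numeric(), alignment = character(),
                  site = character())
  rows <- list()
  for (im in seq_len(nrow(mirnas))) {
    mi <- strsplit(mirnas$seq[im], "", fixed = TRUE)[[1]]
    m <- length(mi)
    gaps <- list(NULL)
    if (with_bulges) {
      gaps <- c(gaps,
                lapply(seq_len(m - 1L), function(g) list(type = "site", g = g)),
                lapply(2:(m - 1L), function(b) list(type = "mirna", b = b)))
    }
    for (iu in seq_len(nrow(utrs))) {
      uc <- strsplit(utrs$seq[iu], "", fixed = TRUE)[[1]]
      cand <- dplyr::bind_rows(lapply(gaps, function(g) scan_pass(mi, uc, g)))
      if (is.null(cand) || nrow(cand) == 0) next
      cand <- cand[cand$penalty <= max_penalty & cand$pass_rules, , drop = FALSE]
      if (nrow(cand) == 0) next
      # collapse overlapping windows, best penalty first (gapless wins ties)
      cand <- cand[order(cand$penalty, cand$bulged, cand$start0), , drop = FALSE]
      occupied <- rep(FALSE, length(uc))
      sel <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        span <- (cand$start0[k] + 1L):cand$end0[k]
        if (!any(occupied[span])) {
          sel[k] <- TRUE
          occupied[span] <- TRUE
        }
      }
      cand <- cand[sel, , drop = FALSE]
      cand$mirna <- mirnas$id[im]
      cand$transcript <- utrs$id[iu]
      rows[[length(rows) + 1]] <- cand
    }
  }
  if (length(rows) == 0) {
    return(structure(empty, class = c("mir_sites", class(tibble()))))
  }
  allhits <- dplyr::bind_rows(rows)
  useq <- setNames(utrs$seq, utrs$id)
  mseq <- setNames(mirnas$seq, mirnas$id)
  detail <- lapply(seq_len(nrow(allhits)), function(k) {
    site <- substr(useq[[allhits$transcript[k]]],
                   allhits$start0[k] + 1L, allhits$end0[k])
    ds <- duplex_score(mseq[[allhits$mirna[k]]], site)
    en <- duplex_energy(mseq[[allhits$mirna[k]]], site, ds$alignment, params)
    tibble(alignment = ds$alignment, site = site, duplex_mfe = en)
  })
  detail <- dplyr::bind_rows(detail)
  out <- tibble(mirna = allhits$mirna, transcript = allhits$transcript,
                start = allhits$start0, end = allhits$end0,
                penalty = allhits$penalty, duplex_mfe = detail$duplex_mfe,
                alignment = detail$alignment, site = detail$site)
  out <- out[order(out$penalty, out$duplex_mfe, out$mirna, out$transcript,
                   out$start), ]
  structure(out, class = c("mir_sites", class(tibble())))
}

#' Write a target-site table
#' @param sites a `mir_sites` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
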