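# Seeded generators for every input the pipeline consumes, with known
# ground truth. They emulate the two-stage muscle study design at desk
# scale: two pooled libraries, log-normal baseline miRNA abundances
# with a planted differentially expressed subset, Poisson count
# sampling, stem-loop precursors, 3'UTRs with planted target sites and
# random pathway memberships. All generators are reproducible given
# (seed, parameters); seeds are scoped so callers' RNG state is
# untouched.

#' Simulate a two-library miRNA count table with planted DE
#'
#' Baseline abundances are log-normal across features, normalized so
#' miRNA reads make up `mirna_fraction` of each library (miRNA
#' dominance of a muscle small RNA library). A planted subset carries
#' a log2 effect of `effect_log2` (random sign, half each way, split
#' symmetrically across the two libraries); counts are Poisson at the
#' given depths. Defaults are the study conditions at desk scale:
#' 464 features, depths 1e6, effect 3.
#'
#' @param n_features number of miRNA features (default 464).
#' @param depth1,depth2 library clean-read totals (default 1e6).
#' @param de_fraction fraction of features planted as DE (default
#'   0.25).
#' @param effect_log2 absolute planted log2 effect (default 3).
#' @param sdlog log-normal spread of baselines (default 1.5).
#' @param mirna_fraction fraction of the library totals attributed to
#'   the simulated features (default 0.815).
#' @param seed integer seed.
#' @return list with `counts` (a `mir_counts` table) and `truth`
#'   (tibble `feature`, `baseline_pm`, `effect_log2` signed, `de`).
#' @export
simulate_libraries <- function(n_features = 464L, depth1 = 1e6, depth2 = 1e6,
                               de_fraction = 0.25, effect_log2 = 3,
                               sdlog = 1.5, mirna_fraction = 0.815,
                               seed = 1L) {
  check_that(depth1 > 0 && depth2 > 0, "depths must be positive")
  check_that(de_fraction >= 0 && de_fraction <= 1,
             "`de_fraction` must lie in [0, 1]")
  check_that(n_features >= 1, "`n_features` must be positive")
  with_seed(seed, {
    base <- rlnorm(n_features, meanlog = 0, sdlog = sdlog)
    base_pm <- base / sum(base) * mirna_fraction * 1e6
    n_de <- round(de_fraction * n_features)
    de <- seq_len(n_features) %in% sample.int(n_features, n_de)
    sign <- ifelse(runif(n_features) < 0.5, 1, -1)
    eff <- ifelse(de, sign * effect_log2, 0)
    lam1 <- base_pm * depth1 / 1e6 * 2^(eff / 2)
    lam2 <- base_pm * depth2 / 1e6 * 2^(-eff / 2)
    x <- rpois(n_features, lam1)
    y <- rpois(n_features, lam2)
    feats <- sprintf("mir-%04d", seq_len(n_features))
    counts <- count_table(feats, x, y,
                          c(max(depth1, sum(x)), max(depth2, sum(y))))
    list(counts = counts,
         truth = tibble(feature = feats, baseline_pm = base_pm,
                        effect_log2 = eff, de = de))
  })
}

# weighted random sequence of one length
random_seq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate mature-miRNA-like reads
#'
#' Unique read sequences with log-normal multiplicities, a length
#' distribution peaked at 22 nt (the Dicer product mode) and a strong
#' U bias at the first position, for profiling demonstrations.
#'
#' @param n_unique number of unique sequences (default 200).
#' @param first_u probability the first base is U (default 0.87).
#' @param seed integer seed.
#' @return tibble with columns `seq`, `count`.
#' @export
simulate_mirna_reads <- function(n_unique = 200L, first_u = 0.87, seed = 1L) {
  with_seed(seed, {
    lens <- sample(18:25, n_unique, replace = TRUE,
                   prob = c(0.02, 0.03, 0.05, 0.15, 0.55, 0.12, 0.05, 0.03))
    seqs <- vapply(lens, function(L) {
      first <- if (runif(1) < first_u) "T" else sample(c("A", "C", "G"), 1)
      paste0(first, random_seq(L - 1L, gc = 0.4))
    }, character(1))
    tibble(seq = seqs,
           count = pmax(1, round(rlnorm(n_unique, meanlog = 3, sdlog = 1.5))))
  })
}

#' Simulate stem-loop miRNA precursors
#'
#' Each precursor is a left arm, a loop, and the reverse complement of
#' the left arm with point mismatches at `mismatch_rate`; a 22-nt
#' mature read is cut from the left (5') arm. The truth records the
#' arm and loop boundaries (0-based half-open on the precursor).
#'
#' @param n number of precursors.
#' @param stem_len paired stem length in bp (default 35; precursor
#'   length is `2 * stem_len + loop_len`).
#' @param loop_len terminal loop length (default 10).
#' @param gc stem GC fraction (default 0.5).
#' @param mismatch_rate per-base probability of a stem mismatch
#'   (default 0.05).
#' @param mature_len mature read length (default 22).
#' @param seed integer seed.
#' @return tibble: `locus`, `precursor`, `mature`, `mature_start`,
#'   `mature_end`, `arm5_end`, `loop_end` (boundaries: 5' arm is
#'   `[0, arm5_end)`, loop `[arm5_end, loop_end)`, 3' arm to the end).
#' @export
simulate_hairpins <- function(n = 1L, stem_len = 35L, loop_len = 10L,
                              gc = 0.5, mismatch_rate = 0.05,
                              mature_len = 22L, seed = 1L) {
  check_that(stem_len >= 16, "`stem_len` must be at least 16")
  check_that(loop_len >= 3, "`loop_len` must be at least 3")
  check_that(mature_len <= stem_len, "mature read must fit in the stem arm")
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      left <- random_seq(stem_len, gc)
      loop <- random_seq(loop_len, gc = 0.3)
      right <- strsplit(revcomp(left), "", fixed = TRUE)[[1]]
      flip <- runif(stem_len) < mismatch_rate
      if (any(flip)) {
        right[flip] <- vapply(right[flip], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      prec <- paste0(left, loop, paste(right, collapse = ""))
      ms <- sample.int(stem_len - mature_len + 1L, 1L) - 1L  # 0-based
      tibble(locus = sprintf("hp-%03d", i), precursor = prec,
             mature = substr(prec, ms + 1L, ms + mature_len),
             mature_start = ms, mature_end = ms + mature_len,
             arm5_end = stem_len, loop_end = stem_len + loop_len)
    })
    dplyr::bind_rows(rows)
  })
}

#' Dinucleotide-free shuffle of sequences
#'
#' Composition-matched controls: each sequence's bases are permuted
#' uniformly at random.
#'
#' @param seqs character vector of sequences.
#' @param seed integer seed.
#' @return character vector of shuffled sequences.
#' @export
shuffle_seqs <- function(seqs, seed = 1L) {
  with_seed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Simulate 3'UTRs with planted miRNA target sites
#'
#' Random-background UTRs carrying reverse-complement sites of the
#' given miRNAs with exactly `mutation_count` mismatches at recorded
#' miRNA positions (mutations are set to a base that can neither pair
#' nor wobble). Planted sites do not overlap.
#'
#' @param mirnas data frame with columns `id`, `seq`.
#' @param n_utrs number of UTRs (default 20).
#' @param sites_per_utr planted sites per UTR (default 1; 0 gives
#'   pure background).
#' @param mutation_count mismatches per planted site (default 0).
#' @param utr_len UTR length in nt (default 300).
#' @param seed integer seed.
#' @return list with `utrs` (tibble `id`, `seq`) and `truth` (tibble
#'   `transcript`, `mirna`, `start`, `end` 0-based half-open,
#'   `mutated_positions` list-column of 1-based miRNA positions).
#' @export
simulate_utrs <- function(mirnas, n_utrs = 20L, sites_per_utr = 1L,
                          mutation_count = 0L, utr_len = 300L, seed = 1L) {
  check_that(all(c("id", "seq") %in% names(mirnas)),
             "`mirnas` needs columns id, seq")
  mir_seq <- normalize_seq(mirnas$seq)
  m_max <- max(nchar(mir_seq))
  check_that(utr_len >= m_max + 20L, "UTRs too short for the miRNAs")
  # a base that neither Watson-Crick pairs nor wobbles with `b`
  non_pairing <- c(A = "C", C = "A", G = "G", T = "T")
  with_seed(seed, {
    utrs <- list()
    truth <- list()
    for (u in seq_len(n_utrs)) {
      uid <- sprintf("utr-%03d", u)
      uc <- strsplit(random_seq(utr_len, gc = 0.45), "", fixed = TRUE)[[1]]
      placed <- rep(FALSE, utr_len)
      for (s in seq_len(sites_per_utr)) {
        im <- sample.int(nrow(mirnas), 1)
        site <- strsplit(revcomp(mir_seq[im]), "", fixed = TRUE)[[1]]
        m <- length(site)
        for (attempt in seq_len(50)) {
          st <- sample.int(utr_len - m + 1L, 1L) - 1L   # 0-based
          if (!any(placed[(st + 1):(st + m)])) break
          st <- NA_integer_
        }
        if (is.na(st)) next
        mut_pos <- integer(0)
        if (mutation_count > 0) {
          mut_pos <- sort(sample.int(m, mutation_count))
          for (p in mut_pos) {
            # miRNA position p pairs site column m + 1 - p
            mb <- substr(mir_seq[im], p, p)
            site[m + 1 - p] <- non_pairing[[mb]]
          }
        }
        uc[(st + 1):(st + m)] <- site
        placed[(st + 1):(st + m)] <- TRUE
        truth[[length(truth) + 1]] <-
          tibble(transcript = uid, mirna = mirnas$id[im],
                 start = st, end = st + m,
                 mutated_positions = list(mut_pos))
      }
      utrs[[u]] <- tibble(id = uid, seq = paste(uc, collapse = ""))
    }
    list(utrs = dplyr::bind_rows(utrs),
         truth = if (length(truth)) dplyr::bind_rows(truth) else
           tibble(transcript = character(), mirna = character(),
                  start = integer(), end = integer(),
                  mutated_positions = list()))
  })
}

#' Simulate a pathway collection with planted enrichment
#'
#' Random gene-set memberships; designated enriched pathways
#' oversample DE-target genes at the given odds.
#'
#' @param genes character vector of background gene ids.
#' @param n_pathways number of pathways (default 50).
#' @param size_range inclusive pathway size range (default 10-40).
#' @param n_enriched number of planted enriched pathways (default 0).
#' @param de_genes DE-target genes oversampled in enriched pathways.
#' @param odds sampling odds of a DE-target gene in an enriched
#'   pathway relative to background (default 10).
#' @param seed integer seed.
#' @return list with `pathways` (tibble as [read_gmt()]) and `truth`
#'   (tibble `pathway`, `enriched`).
#' @export
simulate_pathways <- function(genes, n_pathways = 50L,
                              size_range = c(10L, 40L), n_enriched = 0L,
                              de_genes = character(), odds = 10,
                              seed = 1L) {
  check_that(size_range[1] >= 2, "pathway sizes must be at least 2")
  check_that(length(genes) >= size_range[2], "too few genes for the sizes")
  if (n_pathways == 0L) {
    return(list(pathways = tibble(pathway = character(),
                                  description = character(), genes = list()),
                truth = tibble(pathway = character(), enriched = logical())))
  }
  with_seed(seed, {
    enriched <- seq_len(n_pathways) <= n_enriched
    rows <- lapply(seq_len(n_pathways), function(i) {
      size <- sample(size_range[1]:size_range[2], 1)
      wt <- rep(1, length(genes))
      if (enriched[i]) wt[genes %in% de_genes] <- odds
      tibble(pathway = sprintf("pw-%03d", i),
             description = if (enriched[i]) "planted enriched" else "background",
             genes = list(sample(genes, size, prob = wt)))
    })
    list(pathways = dplyr::bind_rows(rows),
         truth = tibble(pathway = sprintf("pw-%03d", seq_len(n_pathways)),
                        enriched = enriched))
  })
}

#' Embed precursors in a synthetic genome
#'
#' Places each precursor at a random non-overlapping locus on a random
#' chromosome sequence (plus or minus strand) and emits the genome
#' plus a hit table of the mature reads' genomic coordinates, the
#' input expected by [extract_flanks()].
#'
#' @param hairpins tibble from [simulate_hairpins()].
#' @param chrom_len chromosome length (default 20000).
#' @param minus_fraction fraction of loci on the minus strand
#'   (default 0.5).
#' @param seed integer seed.
#' @return list with `genome` (tibble `id`, `seq`) and `hits` (tibble
#'   `locus`, `chrom`, `start`, `end`, `strand`, `mature`,
#'   `genome_hits`), coordinates of the mature read, 0-based
#'   half-open.
#' @export
simulate_genome <- function(hairpins, chrom_len = 20000L,
                            minus_fraction = 0.5, seed = 1L) {
  n <- nrow(hairpins)
  plen <- nchar(hairpins$precursor)
  check_that(chrom_len > (max(plen) + 400L) * n,
             "chromosome too short for the precursors")
  with_seed(seed, {
    gseq <- strsplit(random_seq(chrom_len, gc = 0.42), "", fixed = TRUE)[[1]]
    # non-overlapping slots with >= 200 nt spacing
    slot <- floor(chrom_len / n)
    starts <- (seq_len(n) - 1L) * slot +
      vapply(seq_len(n), function(i) sample.int(slot - plen[i] - 200L, 1L),
             integer(1))
    strand <- ifelse(runif(n) < minus_fraction, "-", "+")
    hits <- lapply(seq_len(n), function(i) {
      p <- hairpins$precursor[i]
      emb <- if (strand[i] == "-") revcomp(p) else p
      gseq[(starts[i] + 1):(starts[i] + plen[i])] <<-
        strsplit(emb, "", fixed = TRUE)[[1]]
      # mature coordinates on the plus strand
      if (strand[i] == "+") {
        ms <- starts[i] + hairpins$mature_start[i]
        me <- starts[i] + hairpins$mature_end[i]
      } else {
        ms <- starts[i] + plen[i] - hairpins$mature_end[i]
        me <- starts[i] + plen[i] - hairpins$mature_start[i]
      }
      tibble(locus = hairpins$locus[i], chrom = "chr1", start = ms, end = me,
             strand = strand[i], mature = hairpins$mature[i],
             genome_hits = 1L)
    })
    list(genome = tibble(id = "chr1", seq = paste(gseq, collapse = "")),
         hits = dplyr::bind_rows(hits))
  })
}
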