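test_that("flank extraction windows are clipped and strand-aware", {
  genome <- tibble::tibble(id = "chr1",
                           seq = paste(rep("ACGT", 250), collapse = ""))
  hits <- tibble::tibble(locus = c("h1", "h2"), chrom = "chr1",
                         start = c(200L, 0L), end = c(222L, 22L),
                         strand = "+")
  w <- extract_flanks(hits, genome, 150)
  expect_equal(w$window_start, c(50L, 0L))
  expect_equal(w$window_end, c(372L, 172L))
  expect_equal(nchar(w$window), c(322L, 172L))
  expect_equal(w$window[1], substr(genome$seq, 51, 372))
  # minus strand: reverse complement of the plus-strand window;
  # double reverse-complement is the identity
  hits_m <- dplyr::mutate(hits[1, ], strand = "-")
  wm <- extract_flanks(hits_m, genome, 150)
  expect_equal(wm$window, revcomp(w$window[1]))
  expect_equal(revcomp(wm$window), w$window[1])
  # out-of-bounds hit
  bad <- tibble::tibble(locus = "x", chrom = "chr1", start = 990L,
                        end = 1010L, strand = "+")
  expect_error(extract_flanks(bad, genome), class = "caprimir_domain_error")
})

test_that("folding a pair-free sequence gives the empty structure at 0", {
  f <- fold_mfe("AAAAAAAA")
  expect_equal(f$structure, "........")
  expect_equal(f$mfe, 0)
})

test_that("DP folding equals exhaustive enumeration on small sequences", {
  f <- fold_mfe("GGGGCAAAACCCC")
  o <- oracle_fold("GGGGCAAAACCCC")
  expect_equal(f$mfe, o$mfe, tolerance = 1e-9)
  expect_equal(score_db("GGGGCAAAACCCC", f$structure), f$mfe,
               tolerance = 1e-9)
  set.seed(202)
  for (i in 1:25) {
    n <- sample(8:13, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    f <- fold_mfe(s)
    o <- oracle_fold(s)
    expect_equal(f$mfe, o$mfe, tolerance = 1e-9, label = s)
    # the returned structure attains the optimum under the
    # independent scorer
    expect_equal(score_db(s, f$structure), f$mfe, tolerance = 1e-9,
                 label = s)
  }
})

test_that("folding is deterministic and invariant to T/U spelling", {
  s <- "GGGAGCUUCGGCUCCC"
  f1 <- fold_mfe(s)
  f2 <- fold_mfe(chartr("U", "T", s))
  f3 <- fold_mfe(s)
  expect_equal(f1$structure, f2$structure)
  expect_equal(f1$mfe, f2$mfe)
  expect_identical(f1, f3)
  expect_error(fold_mfe("ACGX"), class = "caprimir_alphabet_error")
})

test_that("MFEI metrics follow the defining arithmetic", {
  m <- mfei_metrics(-40, paste0(strrep("G", 20), strrep("C", 20),
                                strrep("A", 40)))
  expect_equal(m$amfe, -50)
  expect_equal(m$gc_percent, 50)
  expect_equal(m$mfei, 1.0)
  m0 <- mfei_metrics(0, strrep("ACGC", 25))
  expect_equal(m0$mfei, 0)
  m18 <- mfei_metrics(-18, paste0(strrep("GC", 20), strrep("AT", 30)))
  expect_equal(m18$amfe, -18)
  expect_equal(m18$mfei, 0.45)
  # zero GC leaves MFEI undefined
  mna <- mfei_metrics(-1, strrep("AT", 10))
  expect_true(is.na(mna$mfei))
})

test_that("constructed stem-loops pass the screen; weak ones fail", {
  hp <- simulate_hairpins(n = 1, stem_len = 28L, loop_len = 6L, gc = 0.6,
                          mismatch_rate = 0, seed = 4)
  ev <- evaluate_candidates(
    tibble::tibble(locus = "hp", window = hp$precursor, mature = hp$mature,
                   genome_hits = 1L))
  expect_true(ev$verdict)
  expect_equal(ev$arm, "5p")
  expect_equal(ev$n_terminal_loops, 1L)
  expect_true(ev$mfe < -18)
  expect_true(ev$mfei > 0.85)
  # weak stem: MFE above the -18 kcal/mol cutoff fails flag 3
  weak <- paste0("GCGCAT", strrep("A", 10), "ATGCGC", strrep("A", 16))
  evw <- evaluate_candidates(
    tibble::tibble(locus = "w", window = weak,
                   mature = substr(weak, 1, 16), genome_hits = 1L))
  expect_false(evw$flag_mfe)
  expect_false(evw$verdict)
})

test_that("per-filter flags catch each published criterion", {
  hp <- simulate_hairpins(n = 1, stem_len = 34L, loop_len = 8L, gc = 0.6,
                          mismatch_rate = 0, mature_len = 22L, seed = 9)
  base <- tibble::tibble(locus = "hp", window = hp$precursor,
                         mature = hp$mature, genome_hits = 1L)
  # mature length out of 16-30 fails flag 2 (use a 31-mer from the window)
  long <- dplyr::mutate(base, mature = substr(window, 1, 31))
  expect_false(evaluate_candidates(long)$flag_len)
  # more than 10 genome hits fails flag 1
  multi <- dplyr::mutate(base, genome_hits = 11L)
  ev <- evaluate_candidates(multi)
  expect_false(ev$flag_hits)
  expect_false(ev$verdict)
  # mature spanning the loop accumulates loop bases and fails flag 4
  loopy <- dplyr::mutate(base, mature = substr(window, 26, 50))
  evl <- evaluate_candidates(loopy)
  expect_false(evl$flag_stem)
  # mature not in window is a domain error
  expect_error(evaluate_candidates(dplyr::mutate(base, mature = strrep("A", 22))),
               "not found", class = "caprimir_domain_error")
})

test_that("true hairpins pass and shuffled controls fail at rate", {
  hp <- simulate_hairpins(n = 30, seed = 11)
  ev <- evaluate_candidates(
    tibble::tibble(locus = hp$locus, window = hp$precursor,
                   mature = hp$mature, genome_hits = 1L))
  expect_gte(mean(ev$verdict), 0.95)
  sh <- shuffle_seqs(hp$precursor, seed = 12)
  ev2 <- evaluate_candidates(
    tibble::tibble(locus = hp$locus, window = sh,
                   mature = substr(sh, hp$mature_start + 1, hp$mature_end),
                   genome_hits = 1L))
  expect_lte(mean(ev2$verdict), 0.05)
})

test_that("structures written in Vienna style parse back", {
  hp <- simulate_hairpins(n = 2, seed = 3)
  ev <- evaluate_candidates(
    tibble::tibble(locus = hp$locus, window = hp$precursor,
                   mature = hp$mature, genome_hits = 1L))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_structures(ev, tf)
  lines <- readLines(tf)
  expect_equal(length(lines), 6)
  expect_true(all(startsWith(lines[c(1, 4)], ">")))
  # dot-bracket lines are balanced
  expect_silent(parse_dotbracket(sub(" \\(.*\\)$", "", lines[3])))
})
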