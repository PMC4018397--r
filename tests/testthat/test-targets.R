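LET7F <- "TGAGGTAGTAGGTTGTATAGTT"  # 22 nt; position 5 is G, position 20 is G

# plant a specific state at miRNA position p of a perfect site:
# miRNA position p pairs site position m + 1 - p (plus strand)
mutate_site <- function(mirna, p, base) {
  site <- strsplit(revcomp(mirna), "", fixed = TRUE)[[1]]
  site[nchar(mirna) + 1 - p] <- base
  paste(site, collapse = "")
}

test_that("duplex penalty follows the rule table position by position", {
  perfect <- revcomp(LET7F)
  ds <- duplex_score(LET7F, perfect)
  expect_equal(ds$penalty, 0)
  expect_equal(ds$alignment, strrep("|", 22))
  # G.U wobble at position 5: 0.5 doubled inside positions 2-13
  gu5 <- duplex_score(LET7F, mutate_site(LET7F, 5, "T"))
  expect_equal(gu5$penalty, 1.0)
  expect_equal(substr(gu5$alignment, 5, 5), "o")
  # mismatch at position 20: cost 1.0, outside the doubling window
  mm20 <- duplex_score(LET7F, mutate_site(LET7F, 20, "G"))
  expect_equal(mm20$penalty, 1.0)
  expect_equal(substr(mm20$alignment, 20, 20), "x")
  # mismatch at position 5: doubled
  mm5 <- duplex_score(LET7F, mutate_site(LET7F, 5, "G"))
  expect_equal(mm5$penalty, 2.0)
  # 1-nt site bulge after position 15: cost 2.0, outside doubling
  site_chars <- strsplit(revcomp(LET7F), "", fixed = TRUE)[[1]]
  m <- nchar(LET7F)
  bulged <- paste(append(site_chars, "A", after = m - 15), collapse = "")
  bs <- duplex_score(LET7F, bulged)
  expect_equal(bs$penalty, 2.0)
  expect_equal(nchar(bs$alignment), m + 1)
  expect_equal(sum(strsplit(bs$alignment, "")[[1]] == "-"), 1)
})

test_that("penalty is monotone in the number of mismatches", {
  site <- strsplit(revcomp(LET7F), "", fixed = TRUE)[[1]]
  m <- nchar(LET7F)
  prev <- -1
  for (nmut in 0:3) {
    s <- site
    if (nmut > 0) {
      for (p in seq(14, 14 + nmut - 1)) s[m + 1 - p] <- "G"
    }
    pen <- duplex_score(LET7F, paste(s, collapse = ""))$penalty
    expect_gte(pen, prev)
    prev <- pen
  }
})

test_that("perfect duplexes stay perfect under joint reverse-complement", {
  set.seed(8)
  for (i in 1:5) {
    mir <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
    site <- revcomp(mir)
    expect_equal(duplex_score(mir, site)$penalty, 0)
    expect_equal(duplex_score(revcomp(site), revcomp(mir))$penalty, 0)
  }
})

test_that("duplex energy sums stacks and tracks GC content", {
  perfect_gc <- strrep("GC", 11)
  perfect_at <- strrep("AT", 11)
  e_gc <- duplex_energy(perfect_gc, revcomp(perfect_gc), strrep("|", 22))
  e_at <- duplex_energy(perfect_at, revcomp(perfect_at), strrep("|", 22))
  expect_lt(e_gc, e_at)
  # fully unpaired alignment scores 0
  expect_equal(duplex_energy(LET7F, revcomp(LET7F), strrep("x", 22)), 0)
  # independent summation oracle over the stack table
  params <- energy_params()
  set.seed(77)
  for (i in 1:10) {
    mir <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE),
                 collapse = "")
    site <- revcomp(mir)
    en <- duplex_energy(mir, site, strrep("|", 18), params)
    mi <- strsplit(mir, "", fixed = TRUE)[[1]]
    sc <- strsplit(site, "", fixed = TRUE)[[1]]
    expected <- 0
    for (k in 1:17) {
      p1 <- paste0(chartr("T", "U", mi[k]), chartr("T", "U", sc[18 + 1 - k]))
      p2 <- paste0(chartr("T", "U", mi[k + 1]), chartr("T", "U", sc[18 - k]))
      expected <- expected + params$stack[p1, p2]
    }
    expect_equal(en, min(expected, 0))
  }
})

test_that("planted perfect sites are recovered at exact coordinates", {
  mirnas <- tibble::tibble(id = c("m1", "m2"),
                           seq = c(LET7F, MIR1_SEQ))
  sim <- simulate_utrs(mirnas, n_utrs = 8, sites_per_utr = 1,
                       mutation_count = 0, utr_len = 250, seed = 21)
  sites <- scan_targets(mirnas, sim$utrs)
  hits0 <- sites[sites$penalty == 0, ]
  found <- merge(sim$truth, hits0,
                 by.x = c("transcript", "mirna", "start", "end"),
                 by.y = c("transcript", "mirna", "start", "end"))
  expect_equal(nrow(found), nrow(sim$truth))
})

test_that("mutated planted sites score exactly per the rule table", {
  mirnas <- tibble::tibble(id = "m1", seq = LET7F)
  sim <- simulate_utrs(mirnas, n_utrs = 6, sites_per_utr = 1,
                       mutation_count = 1, utr_len = 250, seed = 33)
  sites <- scan_targets(mirnas, sim$utrs)
  wt <- function(p) ifelse(p %in% 2:13, 2, 1)
  for (i in seq_len(nrow(sim$truth))) {
    p <- sim$truth$mutated_positions[[i]]
    expected <- 1.0 * wt(p)
    hit <- sites[sites$transcript == sim$truth$transcript[i] &
                   sites$start == sim$truth$start[i], ]
    if (p %in% c(10, 11)) {
      # the seed-adjacent mismatch rule rejects the site
      expect_equal(nrow(hit), 0)
    } else {
      expect_equal(nrow(hit), 1)
      expect_equal(hit$penalty, expected)
    }
  }
})

test_that("a mutation at miRNA position 10 always rejects the site", {
  mirnas <- tibble::tibble(id = "m1", seq = LET7F)
  utr <- tibble::tibble(id = "u1",
                        seq = paste0(strrep("A", 40),
                                     mutate_site(LET7F, 10, "G"),
                                     strrep("A", 40)))
  sites <- scan_targets(mirnas, utr)
  expect_false(any(sites$start == 40 & sites$end == 62))
})

test_that("degenerate inputs give empty site lists", {
  mirnas <- tibble::tibble(id = "m1", seq = LET7F)
  short <- tibble::tibble(id = "u", seq = "ACGTACGTAA")
  expect_equal(nrow(scan_targets(mirnas, short)), 0)
  # stringent cutoff on random background is almost always empty
  set.seed(5)
  n_hit <- 0
  for (i in 1:5) {
    utr <- tibble::tibble(id = "u", seq = paste(
      sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""))
    n_hit <- n_hit + nrow(scan_targets(mirnas, utr, max_penalty = 0))
  }
  expect_equal(n_hit, 0)
})
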