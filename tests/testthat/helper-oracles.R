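# Independent oracles, deliberately implemented apart from the
# package's own code paths: brute-force tail summation for the exact
# two-library test, exhaustive structure enumeration with an
# independent energy scorer for folding, and combinatorial summation
# for the hypergeometric enrichment p.

# --- exact-test oracle: direct log-space summation of the conditional
# law p(k | x) = (N2/N1)^k (x+k)! / (x! k! (1+N2/N1)^(x+k+1))
ac_log_pmf <- function(k, x, n1, n2) {
  lr <- log(n2 / n1)
  lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) + k * lr -
    (x + k + 1) * log1p(n2 / n1)
}

ac_p_oracle <- function(x, y, n1, n2) {
  if (x == 0 && y == 0) return(1)  # no-information convention, shared
  kmax <- max(y, x) + 2000L  # geometric tail, ample truncation
  pmf <- exp(ac_log_pmf(0:kmax, x, n1, n2))
  lower <- sum(pmf[seq_len(y + 1)])
  upper <- sum(pmf[(y + 1):(kmax + 1)])
  min(1, 2 * min(lower, upper))
}

# --- folding oracle: enumerate every pseudoknot-free pairing with
# hairpin loops of >= 3 unpaired bases, score each under the model
# grammar (multibranch loops are outside the grammar and score Inf),
# and minimize. Usable to n ~ 13.
enumerate_pairings <- function(n, pairable, min_hairpin = 3L) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1, j), identity)           # i unpaired
    ks <- if (i + min_hairpin + 1 <= j) (i + min_hairpin + 1):j else integer(0)
    for (k in ks) {
      if (!pairable[i, k]) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1]] <- c(list(c(i, k)), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# independent scorer for a pairing (list of c(i, j)); Inf if the
# structure is outside the model grammar
score_pairing <- function(pairs, chars, params) {
  n <- length(chars)
  if (length(pairs) == 0) return(0)
  ptab <- params$stack
  pair_name <- function(i, j) {
    key <- paste0(chartr("T", "U", chars[i]), chartr("T", "U", chars[j]))
    if (key %in% rownames(ptab)) key else NA_character_
  }
  opens <- vapply(pairs, function(p) as.integer(p[1]), integer(1))
  closes <- vapply(pairs, function(p) as.integer(p[2]), integer(1))
  total <- 0
  for (idx in seq_along(pairs)) {
    i <- opens[idx]; j <- closes[idx]
    if (is.na(pair_name(i, j))) return(Inf)
    # immediate children: pairs nested in (i, j) not nested in a
    # deeper pair within it
    inside <- which(opens > i & closes < j)
    if (length(inside) > 0) {
      nested_depth <- vapply(inside, function(a) {
        sum(opens[inside] < opens[a] & closes[inside] > closes[a])
      }, integer(1))
      inside <- inside[nested_depth == 0]
    }
    if (length(inside) == 0) {
      L <- j - i - 1
      if (L < 3) return(Inf)
      total <- total + params$hairpin(L)
    } else if (length(inside) == 1) {
      p <- opens[inside]; q <- closes[inside]
      l1 <- p - i - 1; l2 <- j - q - 1
      if (is.na(pair_name(p, q))) return(Inf)
      e <- if (l1 == 0 && l2 == 0) {
        ptab[pair_name(i, j), pair_name(p, q)]
      } else if (l1 == 0 || l2 == 0) {
        params$bulge(l1 + l2)
      } else {
        params$internal(l1 + l2)
      }
      total <- total + e
    } else {
      return(Inf)  # multibranch: outside the model grammar
    }
  }
  total
}

oracle_fold <- function(seq, params = energy_params()) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]]
  n <- length(chars)
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  pairable <- outer(chars, chars, Vectorize(ok))
  pairings <- enumerate_pairings(n, pairable)
  scores <- vapply(pairings, score_pairing, numeric(1), chars = chars,
                   params = params)
  best <- min(scores, 0)  # empty structure scores 0
  list(mfe = best,
       optimal = pairings[which(abs(scores - best) < 1e-9)])
}

# score a dot-bracket string with the independent scorer
score_db <- function(seq, db, params = energy_params()) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]]
  st <- strsplit(db, "", fixed = TRUE)[[1]]
  open <- integer(0)
  pairs <- list()
  for (i in seq_along(st)) {
    if (st[i] == "(") open <- c(open, i)
    if (st[i] == ")") {
      pairs[[length(pairs) + 1]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  score_pairing(pairs, chars, params)
}

# --- hypergeometric oracle: direct combinatorial summation of
# P(X >= k) drawing n from N with K successes
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  if (length(js) == 0 || k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}
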