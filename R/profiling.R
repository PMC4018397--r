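# Library accounting and sequence-composition profiling: QC discard
# percentages, genome-mapped category breakdowns, read-length
# distribution and first-base / per-position nucleotide bias.
#
# All printed percentages use half-up rounding to 2 decimals, matching
# the published report tables.

QC_CATEGORIES <- c("total_reads", "high_quality", "3'adapter_null",
                   "insert_null", "5'adapter_contaminants",
                   "smaller_than_18nt", "polyA", "clean_reads")

#' QC percentages of high-quality reads
#'
#' Library accounting for a small RNA library: each category (discard
#' classes plus `clean_reads`) as a percentage of `high_quality` reads,
#' which reports 100%. `total_reads` rows, if present, pass through
#' with no percentage. The invariant `clean_reads + discards =
#' high_quality` is enforced.
#'
#' @param qc a data frame with columns `category` and `count`; must
#'   contain a `high_quality` row with positive count.
#' @param check enforce the clean+discards accounting invariant
#'   (default TRUE).
#' @return the input tibble with a `percent` column (2 decimals,
#'   half-up; `NA` for `total_reads`).
#' @export
#' @examples
#' qc <- tibble::tibble(
#'   category = c("high_quality", "smaller_than_18nt", "clean_reads"),
#'   count = c(100, 1, 99))
#' qc_percentages(qc)
qc_percentages <- function(qc, check = TRUE) {
  check_that(all(c("category", "count") %in% names(qc)),
             "`qc` needs columns `category` and `count`")
  hq <- qc$count[qc$category == "high_quality"]
  check_that(length(hq) == 1 && hq > 0,
             "`qc` must contain one `high_quality` row with positive count")
  check_that(all(qc$count >= 0), "counts must be non-negative")
  if (check) {
    parts <- qc$count[!qc$category %in% c("total_reads", "high_quality")]
    if (length(parts) > 0 && sum(parts) != hq) {
      abort("clean_reads + discard categories must sum to high_quality",
            class = "caprimir_domain_error")
    }
    tot <- qc$count[qc$category == "total_reads"]
    check_that(length(tot) == 0 || hq <= tot,
               "high_quality cannot exceed total_reads")
  }
  dplyr::mutate(as_tibble(qc),
                percent = ifelse(.data$category == "total_reads", NA_real_,
                                 round_half_up(100 * .data$count / hq, 2)))
}

#' Category percentages of genome-mapped reads
#'
#' Distribution of genome-mapped small RNA sequences over annotation
#' classes (miRNA, exon/intron sense and antisense, rRNA, scRNA,
#' snRNA, snoRNA, tRNA, unannotated), as unique-sequence and read
#' percentages of the library totals.
#'
#' @param cs a data frame with columns `category`, `unique_count`,
#'   `read_count`. Totals are the column sums unless a `Total` row is
#'   present, in which case it must equal them.
#' @return tibble with `unique_percent` and `read_percent` columns
#'   added (2 decimals, half-up).
#' @export
category_percentages <- function(cs) {
  check_that(all(c("category", "unique_count", "read_count") %in% names(cs)),
             "`cs` needs columns `category`, `unique_count`, `read_count`")
  cs <- as_tibble(cs)
  is_total <- tolower(cs$category) == "total"
  body <- cs[!is_total, ]
  tot_u <- sum(body$unique_count)
  tot_r <- sum(body$read_count)
  if (any(is_total)) {
    check_that(cs$unique_count[is_total] == tot_u &&
                 cs$read_count[is_total] == tot_r,
               "`Total` row must equal the column sums")
  }
  check_that(tot_u > 0 && tot_r > 0, "category totals must be positive")
  dplyr::mutate(cs,
                unique_percent = round_half_up(100 * .data$unique_count / tot_u, 2),
                read_percent = round_half_up(100 * .data$read_count / tot_r, 2))
}

# reads argument -> tibble(seq, count); bare data frames without a
# count column get multiplicity 1.
as_reads <- function(reads) {
  check_that(is.data.frame(reads) && "seq" %in% names(reads),
             "`reads` must be a data frame with a `seq` column")
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1
  check_that(all(reads$count >= 0), "read counts must be non-negative")
  reads$seq <- normalize_seq(reads$seq)
  reads
}

#' Read-length distribution
#'
#' Fraction of reads at each length in the small RNA size range
#' (18-30 nt); out-of-range lengths are binned as `"other"`. Fractions
#' sum to 1 over observed bins.
#'
#' @param reads data frame with columns `seq` and (optionally) `count`
#'   for read multiplicity.
#' @param range inclusive length range kept as individual bins.
#' @return tibble with columns `length` (character; `"other"` for
#'   out-of-range), `reads`, `fraction`.
#' @export
length_distribution <- function(reads, range = c(18L, 30L)) {
  reads <- as_reads(reads)
  if (nrow(reads) == 0L || sum(reads$count) == 0) {
    return(tibble(length = character(), reads = numeric(), fraction = numeric()))
  }
  len <- nchar(reads$seq)
  bin <- ifelse(len >= range[1] & len <= range[2], as.character(len), "other")
  out <- dplyr::summarise(dplyr::group_by(tibble(length = bin, n = reads$count),
                                          .data$length),
                          reads = sum(.data$n), .groups = "drop")
  out <- out[order(suppressWarnings(as.integer(out$length)), na.last = TRUE), ]
  dplyr::mutate(out, fraction = .data$reads / sum(.data$reads))
}

BASES_RNA <- c("A", "C", "G", "U")

#' First-nucleotide bias by read length
#'
#' For each read length 18-25 nt, the fraction of reads starting with
#' each base. Rows for a length sum to 1. Bases are reported in RNA
#' spelling (U).
#'
#' @param reads data frame with columns `seq` and optional `count`.
#' @param lengths lengths to profile (default 18:25).
#' @return tibble with columns `length`, `base`, `fraction`.
#' @export
first_nucleotide_bias <- function(reads, lengths = 18:25) {
  reads <- as_reads(reads)
  len <- nchar(reads$seq)
  keep <- len %in% lengths & reads$count > 0
  reads <- reads[keep, ]
  if (nrow(reads) == 0L) {
    return(tibble(length = integer(), base = character(), fraction = numeric()))
  }
  df <- tibble(length = nchar(reads$seq),
               base = chartr("T", "U", substr(reads$seq, 1, 1)),
               n = reads$count)
  df <- df[df$base %in% BASES_RNA, ]
  out <- dplyr::summarise(dplyr::group_by(df, .data$length, .data$base),
                          n = sum(.data$n), .groups = "drop_last")
  out <- dplyr::mutate(out, fraction = .data$n / sum(.data$n))
  tidyr::complete(dplyr::ungroup(out), length = sort(unique(df$length)),
                  base = BASES_RNA, fill = list(n = 0, fraction = 0))[
                    , c("length", "base", "fraction")]
}

#' Positional nucleotide bias
#'
#' Base composition at each position 1..`max_pos` along the reads
#' (reads shorter than a position are skipped for it), plus the G+C
#' percentage per position. Each position's base fractions sum to 1.
#'
#' @param reads data frame with columns `seq` and optional `count`.
#' @param max_pos last position profiled (default 24).
#' @return tibble with columns `position`, `a`, `c`, `g`, `u`
#'   (fractions) and `gc_percent`.
#' @export
positional_nucleotide_bias <- function(reads, max_pos = 24L) {
  reads <- as_reads(reads)
  reads <- reads[reads$count > 0, ]
  if (nrow(reads) == 0L) {
    return(tibble(position = integer(), a = numeric(), c = numeric(),
                  g = numeric(), u = numeric(), gc_percent = numeric()))
  }
  res <- lapply(seq_len(max_pos), function(p) {
    long_enough <- nchar(reads$seq) >= p
    if (!any(long_enough)) return(NULL)
    base <- substr(reads$seq[long_enough], p, p)
    n <- reads$count[long_enough]
    tot <- sum(n)
    frac <- vapply(c("A", "C", "G", "T"),
                   function(b) sum(n[base == b]) / tot, numeric(1))
    tibble(position = p, a = frac[["A"]], c = frac[["C"]], g = frac[["G"]],
           u = frac[["T"]],
           gc_percent = 100 * (frac[["C"]] + frac[["G"]]))
  })
  dplyr::bind_rows(res)
}
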