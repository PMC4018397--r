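# Readers/writers for every file the pipeline touches, with strict
# validation. Dialects: single-line-written FASTA (wrapped accepted on
# read), tab-separated count tables with header
# "feature\tcount_lib1\tcount_lib2", GMT gene sets, tab-separated edge
# lists. All errors are classed conditions naming the offending line.

#' Read a FASTA file of nucleotide sequences
#'
#' Accepts wrapped or single-line records. Sequences are uppercased and
#' U is normalized to the internal DNA alphabet (T). Record ids must be
#' unique and sequences non-empty; violations raise a format error that
#' names the line involved.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` and `seq`, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chi-miR-1", "TGGAATGTAAAGAAGTATGTAT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "caprimir_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) return(tibble(id = character(), seq = character()))

  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    abort(sprintf("line %d: expected FASTA header starting with '>'", lineno[1L]),
          class = "caprimir_format_error")
  }
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  hdr_line <- lineno[is_hdr]
  empty_id <- !nzchar(ids)
  if (any(empty_id)) {
    abort(sprintf("line %d: empty FASTA header", hdr_line[which(empty_id)[1L]]),
          class = "caprimir_format_error")
  }
  rec <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(ids))),
                 paste, character(1), collapse = "")
  empty_seq <- !nzchar(seqs)
  if (any(empty_seq)) {
    abort(sprintf("line %d: record '%s' has an empty sequence",
                  hdr_line[which(empty_seq)[1L]], ids[which(empty_seq)[1L]]),
          class = "caprimir_format_error")
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    abort(sprintf("line %d: duplicate record id '%s'",
                  hdr_line[which(dup)[1L]], ids[which(dup)[1L]]),
          class = "caprimir_format_error")
  }
  tibble(id = ids, seq = unname(normalize_seq(seqs)))
}

#' Write sequences as single-line FASTA
#'
#' @param seqs a data frame with columns `id` and `seq` (or a named
#'   character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs) && !is.null(names(seqs))) {
    seqs <- tibble(id = names(seqs), seq = unname(seqs))
  }
  check_that(all(c("id", "seq") %in% names(seqs)),
             "`seqs` needs columns `id` and `seq`", class = "caprimir_io_error")
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path)
  invisible(path)
}

#' Construct a two-library count table
#'
#' Library totals are whole-library clean-read counts and are carried
#' separately from the per-feature counts: libraries contain non-miRNA
#' reads, so totals must be at least the column sums.
#'
#' @param features character vector of unique feature ids.
#' @param count1,count2 non-negative integer counts per feature in
#'   library 1 (fetal, FC) and library 2 (six-month, SMC).
#' @param totals length-2 numeric, total clean reads `(N1, N2)`.
#' @return a `mir_counts` tibble with columns `feature`, `count_lib1`,
#'   `count_lib2` and attribute `totals`.
#' @export
count_table <- function(features, count1, count2, totals) {
  check_that(length(totals) == 2 && all(totals > 0),
             "`totals` must be two positive library sizes")
  check_that(!anyDuplicated(features), "feature ids must be unique",
             class = "caprimir_format_error")
  cnt <- cbind(count1, count2)
  check_that(all(is.finite(cnt)) && all(cnt >= 0) && all(cnt == round(cnt)),
             "counts must be non-negative integers",
             class = "caprimir_format_error")
  check_that(totals[1] >= sum(count1) && totals[2] >= sum(count2),
             "library totals are smaller than the column sums")
  out <- tibble(feature = as.character(features),
                count_lib1 = as.numeric(count1),
                count_lib2 = as.numeric(count2))
  structure(out, totals = as.numeric(totals),
            class = c("mir_counts", class(out)))
}

#' Library totals of a count table
#' @param x a `mir_counts` table.
#' @return numeric length-2 `(N1, N2)`.
#' @export
library_totals <- function(x) attr(x, "totals")

#' Read a two-library count table
#'
#' Tab-separated, three columns (feature id, count in library 1, count
#' in library 2), with an optional header line.
#'
#' @param path path to the table.
#' @param totals length-2 numeric of library clean-read totals.
#' @return a `mir_counts` tibble (see [count_table()]).
#' @export
read_count_table <- function(path, totals) {
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "caprimir_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L) {
    first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[2L])))) {
      lines <- lines[-1L]  # header
    }
  }
  if (length(lines) == 0L) {
    return(count_table(character(), numeric(), numeric(), totals))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("line %d: expected 3 tab-separated fields, found %d",
                  which(nf < 3)[1L], nf[which(nf < 3)[1L]]),
          class = "caprimir_format_error")
  }
  feat <- vapply(parts, `[[`, character(1), 1L)
  c1 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  c2 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- is.na(c1) | is.na(c2) | c1 < 0 | c2 < 0 | c1 != round(c1) | c2 != round(c2)
  if (any(bad)) {
    abort(sprintf("line %d: counts must be non-negative integers", which(bad)[1L]),
          class = "caprimir_format_error")
  }
  count_table(feat, c1, c2, totals)
}

#' Write a two-library count table
#' @param counts a `mir_counts` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(feature = counts$feature,
                   count_lib1 = format(counts$count_lib1, scientific = FALSE, trim = TRUE),
                   count_lib2 = format(counts$count_lib2, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway collection
#'
#' GMT dialect: pathway id, description, then member gene ids, all
#' tab-separated. Genes are deduplicated within a line; duplicate
#' pathway ids and lines with fewer than 3 fields are format errors.
#'
#' @param path path to a GMT file.
#' @return a tibble with columns `pathway`, `description` and a
#'   list-column `genes`.
#' @export
read_gmt <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "caprimir_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(pathway = character(), description = character(),
                  genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("line %d: GMT line needs at least 3 fields", which(nf < 3)[1L]),
          class = "caprimir_format_error")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  dup <- duplicated(ids)
  if (any(dup)) {
    abort(sprintf("line %d: duplicate pathway id '%s'",
                  which(dup)[1L], ids[which(dup)[1L]]),
          class = "caprimir_format_error")
  }
  tibble(pathway = ids,
         description = vapply(parts, `[[`, character(1), 2L),
         genes = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Write a GMT pathway collection
#' @param pathways tibble as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  writeLines(vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway[i], pathways$description[i],
            pathways$genes[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Pathway collection as a named list of gene sets
#' @param pathways tibble as returned by [read_gmt()].
#' @return named list mapping pathway id to character vector of genes.
#' @export
pathway_sets <- function(pathways) setNames(pathways$genes, pathways$pathway)

#' Write a tab-separated edge list
#'
#' Serialization for the bipartite miRNA-gene networks. The first two
#' columns are `source` and `target`; any further columns are edge
#' attributes and must be consistent across edges.
#'
#' @param edges data frame whose first two columns are source and
#'   target node ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  check_that(ncol(edges) >= 2, "edge list needs source and target columns",
             class = "caprimir_format_error")
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated edge list written by [write_edge_list()]
#' @param path path to the edge list.
#' @return a tibble; round-trips with [write_edge_list()].
#' @export
read_edge_list <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "caprimir_io_error")
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE,
                              colClasses = "character"))
}
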