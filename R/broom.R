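# broom-style accessors: tidy() returns the per-feature table as a
# plain tibble, glance() a one-row summary of each fitted result.

#' @rdname de_table
#' @param x a `mir_de` table.
#' @param ... unused.
#' @method tidy mir_de
#' @export
tidy.mir_de <- function(x, ...) as_tibble(unclass(x))

#' @rdname de_table
#' @method glance mir_de
#' @export
glance.mir_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(n_features = nrow(x),
         n_tested = sum(!(x$x == 0 & x$y == 0)),
         n_up = sum(x$de_class == "up"),
         n_down = sum(x$de_class == "down"),
         fdr_max = unname(th["fdr_max"]),
         log2_min = unname(th["log2_min"]))
}

#' @rdname evaluate_candidates
#' @param x a `mir_hairpins` table.
#' @param ... unused.
#' @method tidy mir_hairpins
#' @export
tidy.mir_hairpins <- function(x, ...) as_tibble(unclass(x))

#' @rdname evaluate_candidates
#' @method glance mir_hairpins
#' @export
glance.mir_hairpins <- function(x, ...) {
  tibble(n_candidates = nrow(x), n_pass = sum(x$verdict),
         mfe_range_low = if (nrow(x)) min(x$mfe) else NA_real_,
         mfe_range_high = if (nrow(x)) max(x$mfe) else NA_real_,
         median_mfei = if (nrow(x)) stats::median(x$mfei, na.rm = TRUE)
         else NA_real_)
}

#' @rdname scan_targets
#' @param x a `mir_sites` table.
#' @param ... unused.
#' @method tidy mir_sites
#' @export
tidy.mir_sites <- function(x, ...) as_tibble(unclass(x))

#' @rdname scan_targets
#' @method glance mir_sites
#' @export
glance.mir_sites <- function(x, ...) {
  tibble(n_sites = nrow(x), n_mirnas = length(unique(x$mirna)),
         n_transcripts = length(unique(x$transcript)),
         n_perfect = sum(x$penalty == 0))
}

#' @rdname enrich_pathways
#' @param x a `mir_enrich` table.
#' @param ... unused.
#' @method tidy mir_enrich
#' @export
tidy.mir_enrich <- function(x, ...) as_tibble(unclass(x))

#' @rdname enrich_pathways
#' @method glance mir_enrich
#' @export
glance.mir_enrich <- function(x, ...) {
  tibble(n_pathways = nrow(x),
         n_p05 = sum(x$p < 0.05),
         n_fdr05 = sum(x$fdr <= 0.05),
         top_pathway = if (nrow(x)) x$pathway[1] else NA_character_)
}

#' @rdname build_network
#' @param x a `mir_network`.
#' @param ... unused.
#' @method tidy mir_network
#' @export
tidy.mir_network <- function(x, ...) as_tibble(x$edges)

#' @rdname build_network
#' @method glance mir_network
#' @export
glance.mir_network <- function(x, ...) {
  tibble(n_mirnas = sum(x$nodes$type == "mirna"),
         n_genes = sum(x$nodes$type == "gene"),
         n_edges = nrow(x$edges),
         hub = if (length(x$hubs)) x$hubs[1] else NA_character_,
         hub_degree = if (length(x$hubs))
           x$nodes$degree[match(x$hubs[1], x$nodes$id)] else NA_integer_)
}

#' @method print mir_network
#' @export
print.mir_network <- function(x, ...) {
  cat(sprintf("Bipartite miRNA-gene network: %d miRNAs, %d genes, %d edges\n",
              sum(x$nodes$type == "mirna"), sum(x$nodes$type == "gene"),
              nrow(x$edges)))
  if (length(x$hubs)) {
    cat("hub miRNA(s):", paste(x$hubs, collapse = ", "), "\n")
  }
  invisible(x)
}
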