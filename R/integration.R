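# miRNA-mRNA integration: selection of strongly differential miRNAs
# (|log2 ratio| >= 3), intersection of their predicted targets with
# the DEG set ("DE targets"), hypergeometric pathway enrichment with
# BH FDR, and per-pathway bipartite regulatory networks.

#' Select strongly differential miRNAs for integration
#'
#' miRNA ids with `|log2fc| >= abs_log2_min` and a significant DE
#' call. The published selection is written "-3 >= log2 ratio >= 3",
#' which is unsatisfiable as printed; it is read here as
#' `|log2 ratio| >= 3` and reported as such.
#'
#' @param de a `mir_de` table from [de_table()].
#' @param abs_log2_min absolute log2 ratio cutoff (default 3).
#' @return character vector of selected miRNA ids.
#' @export
select_de_mirnas <- function(de, abs_log2_min = 3) {
  check_that(all(c("feature", "log2fc", "de_class") %in% names(de)),
             "`de` must be a DE table")
  keep <- !is.na(de$log2fc) & abs(de$log2fc) >= abs_log2_min &
    de$de_class != "not_de"
  de$feature[keep]
}

#' Intersect predicted targets with the DEG set
#'
#' DE targets: genes that are both predicted targets of a selected
#' differentially expressed miRNA and themselves differentially
#' expressed. One edge per (miRNA, gene) pair, with both directions
#' attached. Genes present in the site table but missing a DEG
#' direction are dropped with a warning.
#'
#' @param sites a `mir_sites` table from [scan_targets()] (transcript
#'   ids are gene ids).
#' @param de_mirnas data frame with columns `feature`, `de_class`
#'   (e.g. a filtered [de_table()]) or a character vector of miRNA
#'   ids (directions then default to `NA`).
#' @param degs data frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`).
#' @return a `mir_de_targets` tibble: `mirna`, `gene`, `mirna_dir`,
#'   `gene_dir`, one row per unique pair.
#' @export
intersect_de_targets <- function(sites, de_mirnas, degs) {
  check_that(all(c("gene", "direction") %in% names(degs)),
             "`degs` needs columns gene, direction")
  if (is.character(de_mirnas)) {
    de_mirnas <- tibble(feature = de_mirnas, de_class = NA_character_)
  }
  edges <- dplyr::distinct(tibble(mirna = sites$mirna, gene = sites$transcript))
  edges <- edges[edges$mirna %in% de_mirnas$feature, , drop = FALSE]
  in_deg <- edges$gene %in% degs$gene
  miss_dir <- edges$gene %in% degs$gene[is.na(degs$direction)]
  if (any(miss_dir)) {
    warn(sprintf("%d edge(s) dropped: target gene has no DEG direction",
                 sum(miss_dir)))
  }
  edges <- edges[in_deg & !miss_dir, , drop = FALSE]
  out <- dplyr::mutate(
    edges,
    mirna_dir = as.character(de_mirnas$de_class)[match(.data$mirna,
                                                       de_mirnas$feature)],
    gene_dir = as.character(degs$direction)[match(.data$gene, degs$gene)])
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  structure(out, class = c("mir_de_targets", class(tibble())))
}

#' Hypergeometric pathway enrichment of DE targets
#'
#' Upper-tail hypergeometric test per pathway (probability of `k` or
#' more DE targets in the pathway, drawing `n` genes from a background
#' of `N` with `K` pathway members), BH FDR across tested pathways,
#' sorted by p. Pathways with no background member are skipped.
#'
#' @param de_target_genes character vector of DE-target gene ids
#'   (must be a subset of `background`).
#' @param pathways pathway tibble from [read_gmt()] /
#'   [simulate_pathways()].
#' @param background character vector of background gene ids (all
#'   expressed genes with pathway annotation context).
#' @return a `mir_enrich` tibble: `pathway`, `description`, `k`, `K`,
#'   `n`, `N`, `p`, `fdr`.
#' @export
enrich_pathways <- function(de_target_genes, pathways, background) {
  background <- unique(background)
  check_that(length(background) > 0, "background gene set is empty")
  de_target_genes <- unique(de_target_genes)
  check_that(all(de_target_genes %in% background),
             "`de_target_genes` must be a subset of `background`")
  n <- length(de_target_genes)
  N <- length(background)
  rows <- lapply(seq_len(nrow(pathways)), function(i) {
    members <- intersect(pathways$genes[[i]], background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, de_target_genes))
    # P(X >= k); k = 0 gives p = 1
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(pathway = pathways$pathway[i],
           description = pathways$description[i],
           k = k, K = K, n = n, N = N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(pathway = character(), description = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p = numeric(), fdr = numeric())
  } else {
    out$fdr <- bh_fdr(out$p)
    out <- out[order(out$p, out$pathway), ]
  }
  structure(out, class = c("mir_enrich", class(tibble())))
}

#' Build the bipartite miRNA-gene network of one pathway
#'
#' Restricts the DE-target edge set to genes of one pathway and
#' assembles a bipartite network: miRNA and gene nodes with direction
#' attributes, per-node degrees, and the hub (maximum-degree) miRNA
#' with ties listed.
#'
#' @param de_targets a `mir_de_targets` table from
#'   [intersect_de_targets()].
#' @param pathway_genes character vector of the pathway's gene ids.
#' @return a `mir_network` list: `nodes` (tibble `id`, `type`,
#'   `direction`, `degree`), `edges` (tibble `mirna`, `gene`,
#'   `mirna_dir`, `gene_dir`), `graph` (igraph, bipartite), `hubs`
#'   (character vector of maximum-degree miRNAs).
#' @export
build_network <- function(de_targets, pathway_genes) {
  edges <- de_targets[de_targets$gene %in% pathway_genes, , drop = FALSE]
  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    out <- list(nodes = tibble(id = character(), type = character(),
                               direction = character(), degree = integer()),
                edges = edges, graph = g, hubs = character())
    return(structure(out, class = "mir_network"))
  }
  mir_nodes <- dplyr::distinct(tibble(id = edges$mirna, type = "mirna",
                                      direction = edges$mirna_dir))
  gene_nodes <- dplyr::distinct(tibble(id = edges$gene, type = "gene",
                                       direction = edges$gene_dir))
  check_that(!any(mir_nodes$id %in% gene_nodes$id),
             "node appears as both miRNA and gene; network would not be bipartite",
             class = "caprimir_domain_error")
  nodes <- dplyr::bind_rows(mir_nodes, gene_nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$mirna, to = edges$gene),
    directed = FALSE, vertices = as.data.frame(nodes))
  igraph::V(g)$type <- igraph::V(g)$type == "mirna"  # igraph bipartite flag
  check_that(igraph::is_bipartite(g), "network is not bipartite")
  deg <- igraph::degree(g)
  nodes$degree <- as.integer(deg[nodes$id])
  mdeg <- nodes[nodes$type == "mirna", ]
  hubs <- sort(mdeg$id[mdeg$degree == max(mdeg$degree)])
  structure(list(nodes = nodes, edges = edges, graph = g, hubs = hubs),
            class = "mir_network")
}

#' Top pathways report with their networks
#'
#' The published integration report: the pathways with the smallest
#' enrichment p-values, each with its miRNA and DE-target counts in
#' the restricted network.
#'
#' @param enrich a `mir_enrich` table.
#' @param de_targets a `mir_de_targets` table.
#' @param pathways pathway tibble from [read_gmt()].
#' @param top number of pathways (default 10), taken strictly by
#'   ascending p.
#' @return tibble: `pathway`, `n_mirnas`, `n_targets`, `p`, `fdr`,
#'   with one `mir_network` per pathway in the `network` list-column.
#' @export
top_pathway_networks <- function(enrich, de_targets, pathways, top = 10L) {
  sel <- head(enrich, top)
  sets <- pathway_sets(pathways)
  nets <- lapply(sel$pathway, function(pw) {
    build_network(de_targets, sets[[pw]])
  })
  tibble(pathway = sel$pathway,
         n_mirnas = vapply(nets, function(nw) sum(nw$nodes$type == "mirna"),
                           integer(1)),
         n_targets = vapply(nets, function(nw) sum(nw$nodes$type == "gene"),
                            integer(1)),
         p = sel$p, fdr = sel$fdr, network = nets)
}

#' Write an enrichment table
#' @param enrich a `mir_enrich` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrich, path) {
  utils::write.table(as.data.frame(enrich), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
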