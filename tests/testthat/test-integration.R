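make_de_fixture <- function(features, log2fc, de_class) {
  structure(tibble::tibble(feature = features, log2fc = log2fc,
                           de_class = de_class),
            class = c("mir_de", class(tibble::tibble())))
}

test_that("strong-miRNA selection applies the |log2| >= 3 reading", {
  de <- make_de_fixture(c("a", "b", "c", "d"),
                        c(3.2, 2.9, -3.5, 8),
                        c("up", "up", "down", "not_de"))
  expect_equal(select_de_mirnas(de), c("a", "c"))
  expect_equal(select_de_mirnas(de[0, ]), character(0))
  # a strong fold change without a significant call is not selected
  expect_false("d" %in% select_de_mirnas(de))
})

fixture_sites <- function() {
  structure(tibble::tibble(
    mirna = c("m1", "m1", "m1", "m2", "m2", "m2"),
    transcript = c("g1", "g2", "g5", "g1", "g2", "g6"),
    start = 0L, end = 22L, penalty = 0, duplex_mfe = -20,
    alignment = strrep("|", 22), site = strrep("A", 22)),
    class = c("mir_sites", class(tibble::tibble())))
}

test_that("DE-target intersection is exact set arithmetic", {
  sites <- fixture_sites()
  de_mirnas <- make_de_fixture(c("m1", "m2"), c(4, -5), c("up", "down"))
  degs <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         direction = c("up", "down", "up"))
  det <- intersect_de_targets(sites, de_mirnas, degs)
  # 2 miRNAs x 3 sites each, 2 target genes in the DEG set -> 4 edges
  expect_equal(nrow(det), 4)
  expect_setequal(paste(det$mirna, det$gene),
                  c("m1 g1", "m1 g2", "m2 g1", "m2 g2"))
  expect_equal(det$mirna_dir[det$mirna == "m1"][1], "up")
  expect_equal(det$gene_dir[det$gene == "g2"][1], "down")
  # same gene targeted by both miRNAs: degree 2
  expect_equal(sum(det$gene == "g1"), 2)
  # disjoint gene sets give an empty intersection
  none <- intersect_de_targets(sites, de_mirnas,
                               tibble::tibble(gene = "zz", direction = "up"))
  expect_equal(nrow(none), 0)
  # invariant to input ordering
  det2 <- intersect_de_targets(sites[sample.int(6), ], de_mirnas,
                               degs[3:1, ])
  expect_equal(det, det2)
  # missing direction drops the edge with a warning
  degs_na <- tibble::tibble(gene = c("g1", "g2"),
                            direction = c("up", NA))
  expect_warning(det3 <- intersect_de_targets(sites, de_mirnas, degs_na),
                 "no DEG direction")
  expect_false("g2" %in% det3$gene)
})

test_that("enrichment p equals the combinatorial summation", {
  pw <- tibble::tibble(pathway = "pwA", description = "d",
                       genes = list(sprintf("g%02d", 1:10)))
  bg <- sprintf("g%02d", 1:100)
  det <- sprintf("g%02d", c(1:5, 50:54))        # k = 5, K = 10, n = 10
  enr <- enrich_pathways(det, pw, bg)
  expect_equal(enr$k, 5)
  expect_equal(enr$p, hyper_tail_oracle(5, 10, 10, 100), tolerance = 1e-12)
  # pathway equal to the whole background: p = 1
  pw_all <- tibble::tibble(pathway = "all", description = "d",
                           genes = list(bg))
  expect_equal(enrich_pathways(det, pw_all, bg)$p, 1)
  # empty DE-target set: all p = 1
  expect_equal(enrich_pathways(character(0), pw, bg)$p, 1)
  # spot grid against the oracle
  set.seed(12)
  for (i in 1:20) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    bgx <- sprintf("x%03d", 1:N)
    pwx <- tibble::tibble(pathway = "p", description = "d",
                          genes = list(bgx[1:K]))
    detx <- sample(bgx, n)
    k <- length(intersect(detx, bgx[1:K]))
    expect_equal(enrich_pathways(detx, pwx, bgx)$p,
                 hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(enrich_pathways("g1", pw, character(0)),
               class = "caprimir_domain_error")
})

test_that("a planted enriched pathway ranks first by p", {
  genes <- sprintf("g%03d", 1:300)
  de_genes <- sample(genes, 40)
  ranks_first <- 0
  for (s in 1:10) {
    pw <- simulate_pathways(genes, n_pathways = 30, n_enriched = 1,
                            de_genes = de_genes, odds = 20,
                            size_range = c(25L, 35L), seed = s)
    enr <- enrich_pathways(de_genes, pw$pathways, genes)
    ranks_first <- ranks_first +
      (enr$pathway[1] == pw$truth$pathway[pw$truth$enriched])
  }
  expect_gte(ranks_first / 10, 0.9)
})

test_that("bipartite networks carry degrees, directions and hubs", {
  # one miRNA targeting 16 pathway genes: hub degree 16
  genes16 <- sprintf("g%02d", 1:16)
  det <- structure(tibble::tibble(
    mirna = c(rep("miR-424-5p", 16), "miR-29a"),
    gene = c(genes16, "g01"),
    mirna_dir = "down", gene_dir = "up"),
    class = c("mir_de_targets", class(tibble::tibble())))
  nw <- build_network(det, genes16)
  expect_equal(nw$hubs, "miR-424-5p")
  expect_equal(nw$nodes$degree[nw$nodes$id == "miR-424-5p"], 16L)
  expect_equal(glance(nw)$hub_degree, 16L)
  expect_true(igraph::is_bipartite(nw$graph))
  expect_equal(sum(nw$nodes$type == "gene"), 16)
  # every edge traces back to the DE-target set (provenance join)
  expect_true(all(paste(nw$edges$mirna, nw$edges$gene) %in%
                    paste(det$mirna, det$gene)))
  # empty pathway intersection
  empty <- build_network(det, "unrelated-gene")
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$hubs, character(0))
  # a node on both sides violates bipartiteness
  bad <- structure(tibble::tibble(mirna = "x", gene = "x",
                                  mirna_dir = "up", gene_dir = "up"),
                   class = c("mir_de_targets", class(tibble::tibble())))
  expect_error(build_network(bad, "x"), class = "caprimir_domain_error")
})

test_that("top-pathway report restricts networks per pathway", {
  sites <- fixture_sites()
  de_mirnas <- make_de_fixture(c("m1", "m2"), c(4, -5), c("up", "down"))
  degs <- tibble::tibble(gene = c("g1", "g2", "g5", "g6"),
                         direction = c("up", "down", "up", "down"))
  det <- intersect_de_targets(sites, de_mirnas, degs)
  pw <- tibble::tibble(pathway = c("pwA", "pwB"), description = "d",
                       genes = list(c("g1", "g2"), c("g5", "g6", "g9")))
  bg <- c(degs$gene, sprintf("bg%02d", 1:20))
  enr <- enrich_pathways(unique(det$gene), pw, bg)
  top <- top_pathway_networks(enr, det, pw, top = 2)
  expect_equal(nrow(top), 2)
  i_a <- which(top$pathway == "pwA")
  expect_equal(top$n_mirnas[i_a], 2)
  expect_equal(top$n_targets[i_a], 2)
  expect_s3_class(top$network[[i_a]]$edges, "tbl_df")
})
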