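# build a genome with genes at chosen midpoints so clustering can be tested
# against the pairwise rule directly
.mid_genome <- function(mids, L = 200000, circular = FALSE, width = 101L) {
  n <- length(mids)
  half <- (width - 1L) %/% 2L
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                      contig_id = "c1",
                      start = as.integer(mids - half),
                      end = as.integer(mids + half),
                      strand = "+", stringsAsFactors = FALSE)
  ann <- genome_annotation("m", data.frame(contig_id = "c1", length = L,
                                           circular = circular), genes)
  hits <- data.frame(family_id = sprintf("f%02d", seq_len(n)),
                     gene_id = sprintf("g%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  list(ann = ann, hits = hits)
}

test_that("co-localization clustering applies the strict 5 kb midpoint rule", {
  g <- .mid_genome(c(1000, 5500))
  expect_length(cluster_colocalized(g$hits, g$ann), 1L) # 4500 < 5000
  g <- .mid_genome(c(1000, 7000))
  expect_length(cluster_colocalized(g$hits, g$ann), 2L)
  g <- .mid_genome(c(1000, 6000))
  expect_length(cluster_colocalized(g$hits, g$ann), 2L) # exactly 5000: split
  g <- .mid_genome(c(1000, 5000, 9000))
  cl <- cluster_colocalized(g$hits, g$ann)
  expect_length(cl, 1L) # single-linkage chaining
  expect_length(cluster_colocalized(g$hits, g$ann, linkage = "complete"), 2L)
})

test_that("clustering respects circular distances and is a maximal partition", {
  # two genes 400 bp apart across the origin of a 100 kb circle
  g <- .mid_genome(c(200, 99800), L = 100000, circular = TRUE)
  expect_length(cluster_colocalized(g$hits, g$ann), 1L)

  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    mids <- sort(sample(seq(500, 150000, by = 50), n))
    g <- .mid_genome(mids)
    cl <- cluster_colocalized(g$hits, g$ann)
    ids <- unlist(lapply(cl, function(x) x$gene_id))
    expect_setequal(ids, g$hits$gene_id) # partition: every hit exactly once
    expect_equal(anyDuplicated(ids), 0L)
    # maximality under single linkage: no cross-cluster pair within 5 kb
    assign_of <- rep(seq_along(cl), vapply(cl, nrow, integer(1)))
    names(assign_of) <- ids
    mm <- setNames(unlist(lapply(cl, function(x) x$midpoint)), ids)
    for (i in names(mm)) for (j in names(mm)) {
      if (assign_of[i] != assign_of[j])
        expect_gte(abs(mm[i] - mm[j]), 5000)
    }
  }
})

test_that("raising max_gap never splits an existing cluster", {
  set.seed(17)
  for (rep in 1:10) {
    mids <- sort(sample(seq(500, 80000, by = 100), 10))
    g <- .mid_genome(mids)
    cl1 <- cluster_colocalized(g$hits, g$ann, max_gap = 3000)
    cl2 <- cluster_colocalized(g$hits, g$ann, max_gap = 8000)
    # every small-gap cluster is contained in one large-gap cluster
    for (c1 in cl1) {
      holders <- vapply(cl2, function(c2) all(c1$gene_id %in% c2$gene_id),
                        logical(1))
      expect_equal(sum(holders), 1L)
    }
  }
})

test_that("variant classification depends only on the family set", {
  expect_equal(classify_variant(yih_families()), "LONG")
  expect_equal(classify_variant(sample(yih_families())), "LONG")
  expect_equal(classify_variant(c("yihT", "yihU", "yihV", "yihW")), "SHORT")
  expect_equal(classify_variant(c("yihW", "yihU", "yihT", "yihV")), "SHORT")
  expect_equal(classify_variant(c("yihT", "yihU")), "PARTIAL")
  expect_equal(classify_variant(c(yih_families(), "extra")), "PARTIAL")
  expect_equal(classify_variant(character(0)), "NONE")
  expect_warning(v <- classify_variant(c("yihT", "yihT", "yihU", "yihV",
                                         "yihW")), "duplicate family")
  expect_equal(v, "SHORT")
})

test_that("cassette_span takes first start to last end, flags origin wrap", {
  g <- .mid_genome(c(250, 750))
  cl <- data.frame(gene_id = c("a", "b"), contig_id = "c1",
                   start = c(100, 600), end = c(400, 900),
                   midpoint = c(250, 750), stringsAsFactors = FALSE)
  sp <- cassette_span(cl, g$ann)
  expect_equal(sp$start, 100)
  expect_equal(sp$end, 900)
  expect_false(sp$origin_spanning)

  single <- cl[1, ]; single$start <- 50; single$end <- 80
  sp1 <- cassette_span(single, g$ann)
  expect_equal(c(sp1$start, sp1$end), c(50, 80))

  # origin-spanning cluster on a 10 kb circle: genes at 9500-9800 and 100-400
  circ <- genome_annotation("c", data.frame(contig_id = "c1", length = 10000,
                                            circular = TRUE),
                            data.frame(gene_id = c("a", "b"),
                                       contig_id = "c1",
                                       start = c(9500, 100),
                                       end = c(9800, 400), strand = "+"))
  clw <- data.frame(gene_id = c("a", "b"), contig_id = "c1",
                    start = c(9500, 100), end = c(9800, 400),
                    midpoint = c(9650, 250), stringsAsFactors = FALSE)
  spw <- cassette_span(clw, circ)
  expect_true(spw$origin_spanning)
  expect_equal(spw$start, 9500)
  expect_equal(spw$end, 10400) # unwrapped coordinate

  cl$contig_id <- c("c1", "c2")
  expect_error(cassette_span(cl, g$ann), "multiple contigs")
})

test_that("flanking UOGs follow the nearest-neighbor rule", {
  ann <- genome_annotation("s",
    data.frame(contig_id = "c1", length = 20000, circular = FALSE),
    data.frame(gene_id = c("u1", "cas", "u2"), contig_id = "c1",
               start = c(1, 2000, 10000), end = c(500, 8000, 10400),
               strand = "+"))
  uogs <- uog_table(data.frame(strain_id = "s", gene_id = c("u1", "u2"),
                               uog_id = c("UOG217", "UOG236")))
  cas <- list(strain_id = "s", contig_id = "c1",
              span = list(start = 2000, end = 8000))
  ctx <- flanking_uogs(cas, uogs, ann)
  expect_equal(ctx$upstream_uog$uog_id, "UOG217")
  expect_equal(ctx$upstream_uog$distance, 1499)
  expect_equal(ctx$downstream_uog$uog_id, "UOG236")
  expect_equal(ctx$downstream_uog$distance, 1999)

  # no downstream UOG on a linear contig
  uogs1 <- uog_table(data.frame(strain_id = "s", gene_id = "u1",
                                uog_id = "UOG217"))
  ctx1 <- flanking_uogs(cas, uogs1, ann)
  expect_null(ctx1$downstream_uog)

  expect_warning(
    ctx0 <- flanking_uogs(cas, uog_table(
      data.frame(strain_id = character(), gene_id = character(),
                 uog_id = character())), ann), "empty UOG table")
  expect_null(ctx0$upstream_uog)
})

test_that("orientation and inversion calls follow the reference order", {
  fwd <- data.frame(family_id = c("yihT", "yihU", "yihV", "yihW"),
                    gene_id = paste0("g", 1:4), contig_id = "c1",
                    start = c(100, 600, 1100, 1600),
                    end = c(400, 900, 1400, 1900),
                    strand = "+", midpoint = c(250, 750, 1250, 1750),
                    stringsAsFactors = FALSE)
  o <- call_orientation(fwd)
  expect_equal(o$orientation, "forward")
  expect_false(o$inverted)

  rev_cl <- fwd
  rev_cl$family_id <- rev(fwd$family_id)
  rev_cl$strand <- "-"
  o2 <- call_orientation(rev_cl)
  expect_equal(o2$orientation, "reverse")
  expect_true(o2$inverted)

  mixed <- fwd
  mixed$family_id <- c("yihU", "yihT", "yihV", "yihW")
  expect_equal(call_orientation(mixed)$orientation, "mixed")

  # flank pair itself swapped relative to the reference: call flips
  ctx <- structure(list(upstream_uog = list(uog_id = "UOG236"),
                        downstream_uog = list(uog_id = "UOG217"),
                        inverted = NA), class = "synteny_context")
  o3 <- call_orientation(rev_cl, ctx, reference_upstream = "UOG217")
  expect_false(o3$inverted)
})

test_that("detection recovers planted short cassettes with inversion", {
  g <- toy_genome(fams = yih_short_families(), strand = "-", reverse = TRUE)
  call <- detect_cassettes(g, yih_query_proteins(), toy_uogs())
  expect_equal(call$variant, "SHORT")
  expect_equal(call$best$orientation, "reverse")
  expect_true(call$best$inverted)
  expect_equal(call$best$context$upstream_uog$uog_id, "UOG217")
  expect_equal(call$best$context$downstream_uog$uog_id, "UOG236")

  tab <- cassette_table(list(call))
  expect_equal(tab$variant, "SHORT")
  expect_equal(tab$families, "yihW,yihV,yihU,yihT")
})

test_that("multi-locus strains report the best-supported cluster", {
  q <- yih_query_proteins()
  # short set at one locus, a lone distant yihQ at another
  base <- toy_genome(fams = yih_short_families())
  extra <- data.frame(gene_id = "far_q", contig_id = "c1",
                      start = 50000L, end = 50000L + 3L * 150L + 2L,
                      strand = "+", protein_seq = q[["yihQ"]],
                      product = "yihQ", stringsAsFactors = FALSE)
  genes <- rbind(base$genes, extra)
  ann <- genome_annotation("two", transform(base$contigs, length = 60000),
                           genes)
  expect_warning(call <- detect_cassettes(ann, q, toy_uogs("two")),
                 "cassette-like loci")
  expect_equal(call$variant, "SHORT")
  expect_equal(call$n_loci, 2L)
})

test_that("alternative-cluster scan distinguishes adjacent from distant", {
  q <- yih_query_proteins()
  enz <- query_family_set(q[c("yihQ", "yihS")])
  # two planted homologs 50 kb apart: no multi-member cluster
  far <- genome_annotation("far",
    data.frame(contig_id = "c1", length = 100000, circular = FALSE),
    data.frame(gene_id = c("e1", "e2"), contig_id = "c1",
               start = c(1000, 51000),
               end = c(1000, 51000) + 3 * nchar(q[c("yihQ", "yihS")]) + 2,
               strand = "+", protein_seq = unname(q[c("yihQ", "yihS")])))
  rep_far <- scan_alternative_clusters(far, enz)
  expect_length(rep_far$multi_clusters, 0L)
  expect_equal(nrow(rep_far$singletons), 2L)
  expect_equal(rep_far$max_identity, 100)

  near <- genome_annotation("near",
    data.frame(contig_id = "c1", length = 100000, circular = FALSE),
    data.frame(gene_id = c("e1", "e2"), contig_id = "c1",
               start = c(1000, 3000),
               end = c(1000, 3000) + 3 * nchar(q[c("yihQ", "yihS")]) + 2,
               strand = "+", protein_seq = unname(q[c("yihQ", "yihS")])))
  rep_near <- scan_alternative_clusters(near, enz)
  expect_length(rep_near$multi_clusters, 1L)
  expect_equal(nrow(rep_near$multi_clusters[[1]]), 2L)
})
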