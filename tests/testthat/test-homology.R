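test_that("align_proteins handles the identity case and rejects bad input", {
  r <- align_proteins("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(r$identity, 100)
  expect_equal(r$coverage, 100)
  expect_error(align_proteins("MKTJ", "MKTA"), "non-amino-acid")
  expect_error(align_proteins("", "MKTA"))
})

test_that("worked 6-mer case matches the frozen DP-oracle fixture", {
  # oracle_align("MKTAYI", "MKTGYI"): six substitution columns,
  # M+K+T+(A:G)+Y+I = 5+5+5+0+7+4 = 26, 5/6 identical
  r <- align_proteins("MKTAYI", "MKTGYI")
  expect_equal(r$score, 26L)
  expect_equal(r$matches, 5L)
  expect_equal(r$aln_cols, 6L)
  expect_equal(r$identity, 100 * 5 / 6)
  o <- oracle_align("MKTAYI", "MKTGYI")
  expect_equal(r$score, o$score)
  expect_equal(r$identity, o$identity)
})

test_that("aligner equals the brute-force DP oracle on short random pairs", {
  set.seed(2024)
  for (i in 1:40) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    r <- align_proteins(a, b)
    o <- oracle_align(a, b)
    expect_equal(r$score, o$score, info = paste(a, b))
    expect_equal(r$matches, o$matches, info = paste(a, b))
    expect_equal(r$aln_cols, o$aln_cols, info = paste(a, b))
    expect_equal(r$coverage, o$coverage, info = paste(a, b))
  }
})

test_that("score/identity are swap-invariant; coverage follows the query", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_protein(sample(10:40, 1))
    b <- random_protein(sample(10:40, 1))
    r1 <- align_proteins(a, b)
    r2 <- align_proteins(b, a)
    expect_equal(r1$score, r2$score)
    expect_equal(r1$identity, r2$identity)
    expect_equal(r1$matches, r2$matches)
  }
})

test_that("find_family_hits reports thresholded best-family hits", {
  q <- yih_query_proteins()
  g <- toy_genome(fams = c("yihT", "yihU"))
  hits <- find_family_hits(q, g)
  expect_equal(sort(hits$family_id), c("yihT", "yihU"))
  expect_equal(hits$identity, c(100, 100))
  expect_equal(hits$gene_id[hits$family_id == "yihT"], "g_yihT")

  # a genome with unrelated sequences yields nothing
  set.seed(5)
  rand <- genome_annotation("r",
    data.frame(contig_id = "c1", length = 10000, circular = FALSE),
    data.frame(gene_id = c("x1", "x2"), contig_id = "c1",
               start = c(100, 2000), end = c(400, 2300), strand = "+",
               protein_seq = c(random_protein(90), random_protein(90))))
  expect_equal(nrow(find_family_hits(q, rand)), 0L)
  expect_error(find_family_hits(query_family_set(character(0)), g))
})

test_that("a diverged planted copy is recovered with oracle-checked identity", {
  q <- yih_query_proteins()
  set.seed(99)
  ref <- q[["yihU"]]
  ch <- strsplit(ref, "")[[1]]
  idx <- sample(length(ch), round(0.2 * length(ch)))
  aa <- setdiff(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V"), "")
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  mut <- paste(ch, collapse = "")
  g <- genome_annotation("m",
    data.frame(contig_id = "c1", length = 10000, circular = FALSE),
    data.frame(gene_id = "gm", contig_id = "c1", start = 100,
               end = 100 + 3 * nchar(mut) + 2, strand = "+",
               protein_seq = mut))
  hits <- find_family_hits(q, g)
  expect_equal(hits$family_id, "yihU")
  expect_gt(hits$identity, 70) # ~80% expected at 20% substitution
  o <- oracle_align(ref, mut)
  expect_equal(hits$identity, o$identity)
  expect_equal(hits$score, o$score)
})

test_that("find_family_hits is monotone in thresholds", {
  p <- simulate_panel(synthetic_panel_config(n_strains = 2, seed = 21,
                                             n_uogs = 6, divergence = 0.15))
  q <- yih_query_proteins()
  g <- p$genomes[[1]]
  loose <- find_family_hits(q, g, min_identity = 30, min_coverage = 50)
  tight <- find_family_hits(q, g, min_identity = 60, min_coverage = 80)
  expect_true(all(tight$gene_id %in% loose$gene_id))
})

test_that("reciprocal best hits: exact copies, missing genes, ties", {
  mk <- function(id, seqs) {
    n <- length(seqs)
    genome_annotation(id,
      data.frame(contig_id = "c1", length = 100000, circular = FALSE),
      data.frame(gene_id = names(seqs), contig_id = "c1",
                 start = seq(100, by = 1000, length.out = n),
                 end = seq(100, by = 1000, length.out = n) +
                   3 * nchar(seqs) + 2,
                 strand = "+", protein_seq = unname(seqs)))
  }
  set.seed(31)
  s3 <- setNames(vapply(1:3, function(i) random_protein(60), character(1)),
                 c("a1", "a2", "a3"))
  ga <- mk("A", s3)
  gb <- mk("B", setNames(s3, c("b1", "b2", "b3")))
  rb <- reciprocal_best_hits(ga, gb)
  expect_equal(nrow(rb), 3L)
  expect_equal(rb$identity, rep(100, 3))
  expect_equal(rb$gene_b[rb$gene_a == "a2"], "b2")

  # symmetric under genome swap
  rb2 <- reciprocal_best_hits(gb, ga)
  expect_equal(rb$gene_a, rb2$gene_b[match(rb$gene_b, rb2$gene_a)])

  # missing gene -> unpaired
  gb_miss <- mk("B", setNames(s3[1:2], c("b1", "b2")))
  rb3 <- reciprocal_best_hits(ga, gb_miss)
  expect_false("a3" %in% rb3$gene_a)

  # duplicated target (two equal-score best hits) -> query excluded
  gb_dup <- mk("B", setNames(s3[c(1, 1, 2, 3)], c("b1", "b1x", "b2", "b3")))
  rb4 <- reciprocal_best_hits(ga, gb_dup)
  expect_false("a1" %in% rb4$gene_a)
  expect_true(all(c("a2", "a3") %in% rb4$gene_a))
})

test_that("max_identity_to_known_enzymes finds exact and null cases", {
  q <- yih_query_proteins()
  g <- toy_genome(fams = "yihQ")
  tab <- max_identity_to_known_enzymes(g, q)
  expect_equal(tab$best_identity[tab$gene_id == "g_yihQ"], 100)
  empty <- genome_annotation("e",
    data.frame(contig_id = "c1", length = 100, circular = FALSE),
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character()))
  expect_equal(nrow(max_identity_to_known_enzymes(empty, q)), 0L)

  # random 50-mer: value equals the oracle maximum over the set
  set.seed(123)
  r50 <- random_protein(50)
  gr <- genome_annotation("r",
    data.frame(contig_id = "c1", length = 10000, circular = FALSE),
    data.frame(gene_id = "r1", contig_id = "c1", start = 100, end = 252,
               strand = "+", protein_seq = r50))
  got <- max_identity_to_known_enzymes(gr, q)$best_identity
  oracle_max <- max(vapply(names(q), function(f) {
    o <- oracle_align(q[[f]], r50)
    if (o$score <= 0) 0 else o$identity
  }, numeric(1)))
  expect_equal(got, oracle_max)
})

test_that("BLAST tabular import/export bypasses the aligner consistently", {
  q <- yih_query_proteins()
  g <- toy_genome(fams = c("yihT", "yihU", "yihV", "yihW"))
  hits <- find_family_hits(q, g)
  f <- tempfile(fileext = ".tsv")
  write_blast_tab(hits, f)
  expect_equal(ncol(read.delim(f, header = FALSE)), 12L)

  # import an externally produced table with explicit spans
  ext <- data.frame(q = "yihT", s = "g_yihT", pid = 95, len = 110, mm = 5,
                    go = 0, qs = 1, qe = 110, ss = 1, se = 110,
                    ev = NA, bs = 500)
  f2 <- tempfile(fileext = ".tsv")
  write.table(ext, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  imp <- read_blast_tab(f2, q, "toy")
  expect_equal(imp$family_id, "yihT")
  expect_equal(imp$coverage, 100)
  # and it can drive detection in place of the aligner
  call <- detect_cassettes(g, q, toy_uogs(), hits = imp)
  expect_equal(call$variant, "PARTIAL")
})
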