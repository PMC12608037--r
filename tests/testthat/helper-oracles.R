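# Independent oracles used by the unit and acceptance tests. Each mirrors the
# published definition of the quantity it checks with the plainest possible
# code (naive loops, direct products, exhaustive enumeration) and never calls
# the implementation path it validates.

.oracle_aa <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V","X")

.oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[.oracle_aa, .oracle_aa]
    }
    cache
  }
})

# Naive R dynamic program for local affine-gap alignment, optimizing
# (score desc, matches desc, columns asc) lexicographically, with gap states
# opening from the match state only and extending from themselves, restart
# at lowest priority, endpoint = first best substitution cell in row-major
# order. Cell value: c(score, matches, cols, qstart, tstart).
oracle_align <- function(a, b, gap_open = 11, gap_ext = 1) {
  sub <- .oracle_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  strictly_better <- function(u, v) {
    # is u strictly better than v?
    if (is.null(v)) return(!is.null(u))
    if (is.null(u)) return(FALSE)
    if (u[1] != v[1]) return(u[1] > v[1])
    if (u[2] != v[2]) return(u[2] > v[2])
    u[3] < v[3]
  }
  M <- X <- Y <- array(list(NULL), dim = c(la + 1, lb + 1))
  best <- c(0, 0, 0, 0, 0); bq <- 0; bt <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- sub[av[i], bv[j]]
      eq <- as.integer(av[i] == bv[j])
      # M: candidates in priority order M > X > Y > restart
      m <- NULL
      for (pred in list(M[[i, j]], X[[i, j]], Y[[i, j]])) {
        if (is.null(pred)) next
        cand <- c(pred[1] + s, pred[2] + eq, pred[3] + 1, pred[4], pred[5])
        if (strictly_better(cand, m)) m <- cand
      }
      restart <- c(s, eq, 1, i, j)
      if (strictly_better(restart, m)) m <- restart
      M[i + 1, j + 1] <- list(m)
      # X: consume a[i]; open from M above, extend from X above
      x <- NULL
      if (!is.null(M[[i, j + 1]])) {
        p <- M[[i, j + 1]]
        x <- c(p[1] - gap_open - gap_ext, p[2], p[3] + 1, p[4], p[5])
      }
      if (!is.null(X[[i, j + 1]])) {
        p <- X[[i, j + 1]]
        cand <- c(p[1] - gap_ext, p[2], p[3] + 1, p[4], p[5])
        if (strictly_better(cand, x)) x <- cand
      }
      X[i + 1, j + 1] <- list(x)
      # Y: consume b[j]; open from M left, extend from Y left
      y <- NULL
      if (!is.null(M[[i + 1, j]])) {
        p <- M[[i + 1, j]]
        y <- c(p[1] - gap_open - gap_ext, p[2], p[3] + 1, p[4], p[5])
      }
      if (!is.null(Y[[i + 1, j]])) {
        p <- Y[[i + 1, j]]
        cand <- c(p[1] - gap_ext, p[2], p[3] + 1, p[4], p[5])
        if (strictly_better(cand, y)) y <- cand
      }
      Y[i + 1, j + 1] <- list(y)
      if (strictly_better(m, best)) { best <- m; bq <- i; bt <- j }
    }
  }
  if (best[1] <= 0)
    return(list(score = 0, identity = 0, coverage = 0, matches = 0,
                aln_cols = 0, qstart = 0, qend = 0))
  list(score = best[1], identity = 100 * best[2] / best[3],
       coverage = 100 * (bq - best[4] + 1) / la,
       matches = best[2], aln_cols = best[3],
       qstart = best[4], qend = bq, tstart = best[5], tend = bt)
}

# Binomial coefficient by direct product of ratios (no logarithms).
oracle_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  if (k == 0) return(1)
  prod((n - k + seq_len(k)) / seq_len(k))
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, point probabilities as direct products.
oracle_fisher <- function(a, b, c, d, rel_tol = 1e-7) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1.0)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  denom <- oracle_choose(n, c1)
  probs <- vapply(supp, function(k)
    oracle_choose(r1, k) * oracle_choose(n - r1, c1 - k) / denom,
    numeric(1))
  p_obs <- probs[match(a, supp)]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Minimum state-transition count by brute force over all internal-node
# labelings (states drawn from the tip alphabet).
oracle_fitch <- function(tree, states, alphabet = c("LONG", "SHORT")) {
  keep <- tree$tip.label[tree$tip.label %in% names(states) &
                           states[tree$tip.label] %in% alphabet]
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  st <- states[tree$tip.label]
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  best <- Inf
  combos <- expand.grid(rep(list(alphabet), nint), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    lab <- c(st, unlist(combos[r, ], use.names = FALSE))
    cost <- sum(lab[edges[, 1]] != lab[edges[, 2]])
    best <- min(best, cost)
  }
  as.integer(best)
}

random_protein <- function(len) {
  paste(sample(setdiff(.oracle_aa, "X"), len, replace = TRUE),
        collapse = "")
}

# Tiny deterministic genome used across the genome_io / cassette tests:
# UOG anchors at both ends, a configurable set of cassette-family genes in
# between (in the supplied order/strand), all on one contig.
toy_genome <- function(strain_id = "toy",
                       fams = yih_short_families(),
                       strand = "+", reverse = FALSE,
                       gap = 300L, circular = FALSE,
                       length_bp = NULL) {
  q <- yih_query_proteins()
  if (reverse) fams <- rev(fams)
  pos <- 1000L
  rows <- list()
  add <- function(id, plen, strd, prod) {
    glen <- 3L * plen + 3L
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = id, contig_id = "c1", start = pos, end = pos + glen - 1L,
      strand = strd, protein_seq = NA_character_, product = prod,
      stringsAsFactors = FALSE)
    pos <<- pos + glen + gap
  }
  add("uogA", 90L, "+", "UOG217")
  for (f in fams) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = paste0("g_", f), contig_id = "c1", start = pos,
      end = pos + 3L * nchar(q[[f]]) + 2L, strand = strand,
      protein_seq = q[[f]], product = f, stringsAsFactors = FALSE)
    pos <- pos + 3L * nchar(q[[f]]) + 3L + gap
  }
  add("uogB", 90L, "+", "UOG236")
  genes <- do.call(rbind, rows)
  L <- if (is.null(length_bp)) max(genes$end) + 2000L else length_bp
  genome_annotation(strain_id,
                    data.frame(contig_id = "c1", length = L,
                               circular = circular),
                    genes)
}

toy_uogs <- function(strain_id = "toy") {
  uog_table(data.frame(strain_id = strain_id,
                       gene_id = c("uogA", "uogB"),
                       uog_id = c("UOG217", "UOG236"),
                       stringsAsFactors = FALSE))
}
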