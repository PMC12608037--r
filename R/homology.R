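#' @title Protein homology search and reciprocal best hits
#' @name homology
#' @description
#' Genome genes are assigned to query gene families by local protein
#' alignment (Smith-Waterman with affine gaps, BLOSUM62, gap open 11 /
#' extend 1 — the community default; published MMseqs2 screens are not
#' reproduced bit-for-bit and external hit tables can be imported instead).
#' Identity is percent identical pairs over alignment columns; coverage is
#' percent of the query length spanned by the alignment. Among co-optimal
#' alignments the aligner maximizes matches, then minimizes columns, so
#' identity is deterministic and swap-symmetric.
NULL

.aligner_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.aligner_env$sub)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    storage.mode(m) <- "integer"
    .aligner_env$sub <- m
  }
  .aligner_env$sub
}

.aa_encode <- function(seq, what = "sequence") {
  ch <- strsplit(seq, "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx))
    stop(sprintf("%s contains non-amino-acid characters: %s", what,
                 paste(unique(ch[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  idx - 1L
}

#' Align two protein sequences (local, affine gaps)
#'
#' @param a Query protein sequence (coverage is computed over `a`).
#' @param b Target protein sequence.
#' @param gap_open,gap_ext Affine gap parameters; a gap of length L costs
#'   `gap_open + L * gap_ext`.
#' @return List with `identity` (percent over alignment columns), `coverage`
#'   (percent of `a` aligned), `score`, `matches`, `aln_cols`, and the
#'   1-based aligned spans `qstart`, `qend`, `tstart`, `tend`. A best local
#'   score of 0 means no alignment: identity and coverage are 0.
#' @export
align_proteins <- function(a, b, gap_open = 11L, gap_ext = 1L) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  r <- .cpp_align(.aa_encode(a, "a"), .aa_encode(b, "b"), .blosum62(),
                  as.integer(gap_open), as.integer(gap_ext))
  .align_result(r, nchar(a))
}

.align_result <- function(r, qlen) {
  cols <- r$cols
  list(identity = if (cols > 0) 100 * r$matches / cols else 0,
       coverage = if (cols > 0) 100 * (r$qend - r$qstart + 1) / qlen else 0,
       score = r$score, matches = r$matches, aln_cols = cols,
       qstart = r$qstart, qend = r$qend, tstart = r$tstart, tend = r$tend)
}

#' Construct a query family set
#'
#' @param x Named character vector of protein sequences (names are family
#'   ids), a named `AAStringSet`, or a protein FASTA path.
#' @return Named character vector classed `query_family_set`.
#' @export
query_family_set <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) && is.null(names(x)))
    x <- Biostrings::readAAStringSet(x)
  if (methods::is(x, "AAStringSet"))
    x <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  if (!is.character(x) || is.null(names(x)))
    stop("query family set must be a named character vector of sequences")
  if (anyDuplicated(names(x))) stop("family ids must be unique")
  if (any(!nzchar(x))) stop("family sequences must be non-empty")
  .check_protein(x, "family sequence")
  structure(x, class = c("query_family_set", class(unclass(x))))
}

# score/identity/coverage of one family (query) against all proteins in
# `enc` (list of encoded targets); returns the raw batch matrix.
.batch_vs <- function(query_seq, enc, gap_open = 11L, gap_ext = 1L) {
  .cpp_align_batch(.aa_encode(query_seq, "family sequence"), enc,
                   .blosum62(), as.integer(gap_open), as.integer(gap_ext))
}

.encode_genome_proteins <- function(genome) {
  g <- genome$genes
  ok <- !is.na(g$protein_seq) & nzchar(g$protein_seq)
  list(gene_id = g$gene_id[ok],
       enc = lapply(g$protein_seq[ok], .aa_encode))
}

#' Find homologs of the query families in one genome
#'
#' Every genome gene meeting both thresholds against at least one family is
#' reported once, assigned to its best family (highest score; ties broken by
#' higher identity, then lexicographic family id). Output is sorted by
#' (`family_id`, decreasing `score`).
#'
#' @param families A [query_family_set()] (or coercible).
#' @param genome A `genome_annotation` whose genes carry protein sequences.
#' @param min_identity,min_coverage Acceptance thresholds in percent
#'   (defaults 40 and 70: the observed identity ceiling for non-homologous
#'   SQ-enzyme candidates is 37%, so the cutoff sits just above it).
#' @return data.frame: `family_id`, `strain_id`, `gene_id`, `identity`,
#'   `coverage`, `score`.
#' @export
find_family_hits <- function(families, genome, min_identity = 40,
                             min_coverage = 70) {
  if (!inherits(families, "query_family_set"))
    families <- query_family_set(families)
  if (length(families) == 0) stop("empty family set")
  prot <- .encode_genome_proteins(genome)
  empty <- data.frame(family_id = character(), strain_id = character(),
                      gene_id = character(), identity = numeric(),
                      coverage = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(prot$enc) == 0) return(empty)

  per_fam <- lapply(names(families), function(fam) {
    m <- .batch_vs(families[[fam]], prot$enc)
    qlen <- nchar(families[[fam]])
    cols <- m[, "cols"]
    data.frame(family_id = fam, strain_id = genome$strain_id,
               gene_id = prot$gene_id,
               identity = ifelse(cols > 0, 100 * m[, "matches"] / cols, 0),
               coverage = ifelse(cols > 0,
                                 100 * (m[, "qend"] - m[, "qstart"] + 1) / qlen,
                                 0),
               score = m[, "score"], stringsAsFactors = FALSE)
  })
  all_hits <- do.call(rbind, per_fam)
  all_hits <- all_hits[all_hits$identity >= min_identity &
                         all_hits$coverage >= min_coverage, , drop = FALSE]
  if (nrow(all_hits) == 0) return(empty)
  # one family per gene: highest score, then identity, then family id
  all_hits <- all_hits[order(all_hits$gene_id, -all_hits$score,
                             -all_hits$identity, all_hits$family_id), ,
                       drop = FALSE]
  all_hits <- all_hits[!duplicated(all_hits$gene_id), , drop = FALSE]
  all_hits <- all_hits[order(all_hits$family_id, -all_hits$score,
                             all_hits$gene_id), , drop = FALSE]
  rownames(all_hits) <- NULL
  all_hits
}

# Per-query best hit of genome_a proteins against genome_b proteins.
# Exact (score, identity) ties across distinct targets disqualify the query.
.best_hits <- function(genome_a, genome_b, min_identity, min_coverage) {
  pa <- genome_a$genes[!is.na(genome_a$genes$protein_seq), , drop = FALSE]
  pb <- .encode_genome_proteins(genome_b)
  out <- vector("list", nrow(pa))
  for (k in seq_len(nrow(pa))) {
    m <- .batch_vs(pa$protein_seq[k], pb$enc)
    cols <- m[, "cols"]
    ident <- ifelse(cols > 0, 100 * m[, "matches"] / cols, 0)
    cover <- ifelse(cols > 0,
                    100 * (m[, "qend"] - m[, "qstart"] + 1) /
                      nchar(pa$protein_seq[k]), 0)
    keep <- which(ident >= min_identity & cover >= min_coverage &
                    m[, "score"] > 0)
    if (length(keep) == 0) next
    sc <- m[keep, "score"]; id <- ident[keep]
    best <- keep[order(-sc, -id, pb$gene_id[keep])][1]
    tied <- sum(m[keep, "score"] == m[best, "score"] &
                  abs(ident[keep] - ident[best]) < 1e-12)
    if (tied > 1) next
    out[[k]] <- data.frame(query = pa$gene_id[k],
                           target = pb$gene_id[best],
                           identity = ident[best],
                           score = m[best, "score"],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reciprocal best-hit ortholog pairs between two genomes
#'
#' A pair (x, y) is reported iff y is x's unique best hit in `genome_b` and
#' x is y's unique best hit in `genome_a`. Exact (score, identity) ties for
#' best hit disqualify the gene from pairing.
#'
#' @param genome_a,genome_b `genome_annotation` objects with protein
#'   sequences.
#' @param min_identity,min_coverage Thresholds in percent.
#' @return data.frame: `strain_a`, `gene_a`, `strain_b`, `gene_b`,
#'   `identity`.
#' @export
reciprocal_best_hits <- function(genome_a, genome_b, min_identity = 40,
                                 min_coverage = 70) {
  ab <- .best_hits(genome_a, genome_b, min_identity, min_coverage)
  ba <- .best_hits(genome_b, genome_a, min_identity, min_coverage)
  empty <- data.frame(strain_a = character(), gene_a = character(),
                      strain_b = character(), gene_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (is.null(ab) || is.null(ba) || nrow(ab) == 0 || nrow(ba) == 0)
    return(empty)
  back <- setNames(ba$target, ba$query)
  keep <- !is.na(back[ab$target]) & back[ab$target] == ab$query
  ab <- ab[keep, , drop = FALSE]
  if (nrow(ab) == 0) return(empty)
  out <- data.frame(strain_a = genome_a$strain_id, gene_a = ab$query,
                    strain_b = genome_b$strain_id, gene_b = ab$target,
                    identity = ab$identity, stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum identity of each genome gene to a set of known enzymes
#'
#' For each gene carrying a protein sequence, the maximum percent identity
#' over the enzyme set (0 when no alignment has positive score). Used to
#' screen for candidate SQ-catabolism enzymes outside the cassette.
#'
#' @param genome A `genome_annotation`.
#' @param enzyme_set A [query_family_set()] of known enzyme sequences.
#' @return data.frame: `gene_id`, `best_identity`, `best_enzyme` (NA when
#'   nothing aligns).
#' @export
max_identity_to_known_enzymes <- function(genome, enzyme_set) {
  if (!inherits(enzyme_set, "query_family_set"))
    enzyme_set <- query_family_set(enzyme_set)
  prot <- .encode_genome_proteins(genome)
  if (length(prot$enc) == 0)
    return(data.frame(gene_id = character(), best_identity = numeric(),
                      best_enzyme = character(), stringsAsFactors = FALSE))
  best_id <- rep(0, length(prot$enc))
  best_enz <- rep(NA_character_, length(prot$enc))
  for (enz in names(enzyme_set)) {
    m <- .batch_vs(enzyme_set[[enz]], prot$enc)
    ident <- ifelse(m[, "cols"] > 0, 100 * m[, "matches"] / m[, "cols"], 0)
    ident[m[, "score"] <= 0] <- 0
    upd <- ident > best_id
    best_id[upd] <- ident[upd]
    best_enz[upd] <- enz
  }
  data.frame(gene_id = prot$gene_id, best_identity = best_id,
             best_enzyme = best_enz, stringsAsFactors = FALSE)
}

# ---- BLAST tabular interchange ---------------------------------------------

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Export homology hits as 12-column BLAST tabular TSV
#'
#' The evalue column is not computed internally and is written as NA; the
#' internal alignment score stands in for the bitscore column.
#'
#' @param hits data.frame from [find_family_hits()] (alignment spans are not
#'   retained there, so qstart/qend/sstart/send are written as NA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  df <- data.frame(qseqid = hits$family_id, sseqid = hits$gene_id,
                   pident = hits$identity, length = NA, mismatch = NA,
                   gapopen = NA, qstart = NA, qend = NA, sstart = NA,
                   send = NA, evalue = NA, bitscore = hits$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Import an external hit table in BLAST tabular (outfmt 6) layout
#'
#' Bypasses the internal aligner: rows are filtered by the same identity /
#' query-coverage thresholds (coverage from qstart/qend over the query
#' length) and reduced to one best family per gene by bitscore.
#'
#' @param path 12-column TSV without header (qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore).
#' @param families A [query_family_set()] giving query lengths.
#' @param strain_id Strain the target genes belong to.
#' @param min_identity,min_coverage Thresholds in percent.
#' @return data.frame in the [find_family_hits()] layout.
#' @export
read_blast_tab <- function(path, families, strain_id, min_identity = 40,
                           min_coverage = 70) {
  if (!inherits(families, "query_family_set"))
    families <- query_family_set(families)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    stop("expected 12 columns in BLAST tabular file, got ", ncol(df))
  names(df) <- .blast_cols
  unknown <- setdiff(unique(df$qseqid), names(families))
  if (length(unknown) > 0)
    stop("hit table references unknown families: ",
         paste(unknown, collapse = ", "))
  qlen <- nchar(families)[df$qseqid]
  hits <- data.frame(family_id = df$qseqid, strain_id = strain_id,
                     gene_id = df$sseqid, identity = df$pident,
                     coverage = 100 * (df$qend - df$qstart + 1) / qlen,
                     score = df$bitscore, stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= min_identity &
                 hits$coverage >= min_coverage, , drop = FALSE]
  hits <- hits[order(hits$gene_id, -hits$score, -hits$identity,
                     hits$family_id), , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  hits <- hits[order(hits$family_id, -hits$score, hits$gene_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
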