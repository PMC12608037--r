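#' @title Genome annotation containers and coordinate arithmetic
#' @name genome_io
#' @description
#' A `genome_annotation` holds one strain's gene models: a contig table
#' (`contig_id`, `length`, `circular`) and a gene table (`gene_id`,
#' `contig_id`, `start`, `end`, `strand`, `protein_seq`, `product`), with
#' 1-based inclusive coordinates (GFF3 convention). Origin-spanning genes on
#' circular contigs are represented with `end < start` and unwrapped
#' internally; any BED export converts to 0-based half-open at the boundary.
NULL

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","X")

.check_protein <- function(seq, what = "protein_seq") {
  bad <- setdiff(unique(strsplit(paste(seq, collapse = ""), "")[[1]]),
                 AA_ALPHABET)
  if (length(bad) > 0)
    stop(sprintf("%s contains non-amino-acid characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Construct a genome annotation
#'
#' @param strain_id Strain identifier.
#' @param contigs data.frame with columns `contig_id`, `length` (bp),
#'   `circular` (logical).
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` and optionally `protein_seq`, `product`. Coordinates are
#'   1-based inclusive; `end < start` is only legal for origin-spanning genes
#'   on circular contigs.
#' @return An object of class `genome_annotation`, genes sorted by
#'   (`contig_id`, `start`).
#' @export
genome_annotation <- function(strain_id, contigs, genes) {
  stopifnot(is.character(strain_id), length(strain_id) == 1)
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("contig_id", "length", "circular")
  if (!all(need %in% names(contigs)))
    stop("contigs must have columns: ", paste(need, collapse = ", "))
  needg <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(needg %in% names(genes)))
    stop("genes must have columns: ", paste(needg, collapse = ", "))
  if (!"protein_seq" %in% names(genes))
    genes$protein_seq <- rep(NA_character_, nrow(genes))
  if (!"product" %in% names(genes))
    genes$product <- rep(NA_character_, nrow(genes))
  genes$protein_seq <- as.character(genes$protein_seq)
  genes$product <- as.character(genes$product)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id within strain '", strain_id, "': ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (any(genes$start < 1))
    stop("gene(s) with start < 1: ",
         paste(genes$gene_id[genes$start < 1], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand symbol for gene(s): ",
         paste(genes$gene_id[!genes$strand %in% c("+", "-")],
               collapse = ", "))
  miss <- setdiff(genes$contig_id, contigs$contig_id)
  if (length(miss) > 0)
    stop("genes reference unknown contig(s): ", paste(miss, collapse = ", "))

  idx <- match(genes$contig_id, contigs$contig_id)
  circ <- contigs$circular[idx]
  len <- contigs$length[idx]
  rev <- genes$end < genes$start
  if (any(rev & !circ))
    stop("end < start on linear contig for gene(s): ",
         paste(genes$gene_id[rev & !circ], collapse = ", "))
  if (any(!rev & genes$end > len))
    stop("gene end beyond contig length for gene(s): ",
         paste(genes$gene_id[!rev & genes$end > len], collapse = ", "))
  ok <- !is.na(genes$protein_seq)
  if (any(ok)) .check_protein(genes$protein_seq[ok])

  genes <- genes[order(genes$contig_id, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(strain_id = strain_id, contigs = contigs, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> strain %s: %d contig(s), %d gene(s)\n",
              x$strain_id, nrow(x$contigs), nrow(x$genes)))
  invisible(x)
}

.contig_of <- function(ann, contig_id) {
  i <- match(contig_id, ann$contigs$contig_id)
  if (is.na(i)) stop("unknown contig: ", contig_id)
  ann$contigs[i, , drop = FALSE]
}

#' Validate a UOG membership table
#'
#' Checks the single-copy invariant (each `uog_id` at most once per strain)
#' and, when annotations are supplied, that every `gene_id` exists in its
#' strain's annotation.
#'
#' @param uogs data.frame with columns `strain_id`, `gene_id`, `uog_id`.
#' @param annotations Optional named list of `genome_annotation` objects.
#' @return The validated data.frame, invisibly classed `uog_table`.
#' @export
uog_table <- function(uogs, annotations = NULL) {
  uogs <- as.data.frame(uogs, stringsAsFactors = FALSE)
  need <- c("strain_id", "gene_id", "uog_id")
  if (!all(need %in% names(uogs)))
    stop("UOG table must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(uogs[, c("strain_id", "uog_id")])
  if (any(dup))
    stop("UOG table violates single-copy invariant for: ",
         paste(unique(paste(uogs$strain_id[dup], uogs$uog_id[dup], sep = "/")),
               collapse = ", "))
  if (!is.null(annotations)) {
    for (s in unique(uogs$strain_id)) {
      if (is.null(annotations[[s]])) next
      miss <- setdiff(uogs$gene_id[uogs$strain_id == s],
                      annotations[[s]]$genes$gene_id)
      if (length(miss) > 0)
        stop("UOG table references unknown gene(s) in strain ", s, ": ",
             paste(miss, collapse = ", "))
    }
  }
  class(uogs) <- c("uog_table", "data.frame")
  uogs
}

#' Midpoint genomic position of a gene
#'
#' Linear contigs: `(start + end) / 2`. Origin-spanning genes on circular
#' contigs (`end < start`) are unwrapped to `end + length` and the midpoint
#' reduced modulo the contig length into `(0, length]`.
#'
#' @param gene One gene: a list or one-row data.frame with `start`, `end`
#'   and `contig_id`.
#' @param contig Contig descriptor: list/row with `contig_id`, `length`,
#'   `circular`.
#' @return Midpoint position in bp (possibly half-integral).
#' @export
gene_midpoint <- function(gene, contig) {
  if (!is.null(gene$contig_id) && !is.null(contig$contig_id) &&
      gene$contig_id != contig$contig_id)
    stop("gene lies on contig '", gene$contig_id,
         "', not '", contig$contig_id, "'")
  s <- as.numeric(gene$start); e <- as.numeric(gene$end)
  if (e >= s) return((s + e) / 2)
  if (!isTRUE(as.logical(contig$circular)))
    stop("end < start on a linear contig")
  L <- as.numeric(contig$length)
  m <- ((s + e + L) / 2) %% L
  if (m == 0) L else m
}

#' Distance between two positions on a contig
#'
#' Linear contigs: `|a - b|`; circular contigs: the shorter way around,
#' `min(|a - b|, length - |a - b|)`.
#'
#' @param a,b Positions in bp.
#' @param contig Contig descriptor with `length` and `circular`.
#' @return Distance in bp.
#' @export
circular_distance <- function(a, b, contig) {
  d <- abs(as.numeric(a) - as.numeric(b))
  if (isTRUE(as.logical(contig$circular))) {
    L <- as.numeric(contig$length)
    d <- pmin(d, L - d)
  }
  d
}

# ---- readers ----------------------------------------------------------------

#' Read a genome annotation
#'
#' Formats: `"gff3"` (CDS/gene features via rtracklayer, contig lengths and
#' circularity from `region` features or `##sequence-region` pragmas, protein
#' sequences joined from a FASTA keyed by gene id), `"tsv"` (plain dialect
#' with columns gene_id, contig, start, end, strand, protein_seq and optional
#' product), or `"genbank"` (minimal flat-file subset: LOCUS line plus CDS
#' features with location, `/locus_tag`, `/product`, `/translation`; compound
#' `join()` locations are not supported).
#'
#' @param path File path (GFF3, TSV or GenBank).
#' @param format One of `"gff3"`, `"tsv"`, `"genbank"`.
#' @param protein_fasta Optional protein FASTA path (gff3 format only).
#' @param strain_id Strain identifier; defaults to the file base name.
#' @param contigs Optional contig table for the TSV dialect; inferred as a
#'   single linear contig per `contig` value otherwise.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, format = c("gff3", "tsv", "genbank"),
                            protein_fasta = NULL, strain_id = NULL,
                            contigs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(strain_id))
    strain_id <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         gff3 = .read_gff3(path, protein_fasta, strain_id),
         tsv = .read_tsv(path, strain_id, contigs),
         genbank = .read_genbank(path, strain_id))
}

.read_gff3 <- function(path, protein_fasta, strain_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  is_region <- df$type %in% c("region", "chromosome", "contig")
  reg <- df[is_region, , drop = FALSE]
  feat <- df[df$type %in% c("CDS", "gene"), , drop = FALSE]
  if (nrow(feat) == 0) stop("no CDS/gene features in ", path)
  # prefer CDS when both are present
  if (any(feat$type == "CDS")) feat <- feat[feat$type == "CDS", , drop = FALSE]

  gid <- feat$ID
  if (is.null(gid) || anyNA(gid)) {
    lt <- feat$locus_tag
    if (!is.null(lt)) gid <- ifelse(is.na(gid), lt, gid)
  }
  if (is.null(gid) || anyNA(gid))
    stop("GFF3 features without ID/locus_tag in ", path)

  seqn <- as.character(feat$seqnames)
  sl <- GenomeInfoDb::seqlengths(gr)
  contig_ids <- unique(c(as.character(df$seqnames)))
  len <- rep(NA_real_, length(contig_ids))
  names(len) <- contig_ids
  known <- intersect(names(sl)[!is.na(sl)], contig_ids)
  len[known] <- sl[known]
  circ <- setNames(rep(FALSE, length(contig_ids)), contig_ids)
  if (nrow(reg) > 0) {
    rlen <- setNames(reg$end, as.character(reg$seqnames))
    len[names(rlen)] <- ifelse(is.na(len[names(rlen)]), rlen, len[names(rlen)])
    if (!is.null(reg$Is_circular))
      circ[as.character(reg$seqnames)] <- tolower(
        as.character(reg$Is_circular)) %in% "true"
  }
  for (cid in contig_ids) if (is.na(len[cid]))
    len[cid] <- max(feat$end[seqn == cid], 1)

  genes <- data.frame(
    gene_id = gid, contig_id = seqn,
    start = feat$start, end = feat$end,
    strand = as.character(feat$strand),
    protein_seq = NA_character_,
    product = if (!is.null(feat$product)) as.character(feat$product)
              else NA_character_,
    stringsAsFactors = FALSE)
  if (any(genes$strand == "*"))
    stop("unknown strand symbol for gene(s): ",
         paste(genes$gene_id[genes$strand == "*"], collapse = ", "))
  if (!is.null(protein_fasta)) {
    aa <- Biostrings::readAAStringSet(protein_fasta)
    nm <- sub("\\s.*$", "", names(aa))
    hit <- match(genes$gene_id, nm)
    genes$protein_seq[!is.na(hit)] <- as.character(aa[hit[!is.na(hit)]])
  }
  ctg <- data.frame(contig_id = contig_ids, length = as.numeric(len),
                    circular = unname(circ), stringsAsFactors = FALSE)
  genome_annotation(strain_id, ctg, genes)
}

.read_tsv <- function(path, strain_id, contigs) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("contig" %in% names(df)) names(df)[names(df) == "contig"] <- "contig_id"
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("TSV dialect requires columns: gene_id, contig, start, end, strand")
  if (is.null(contigs)) {
    contigs <- do.call(rbind, lapply(unique(df$contig_id), function(cid) {
      data.frame(contig_id = cid,
                 length = max(df$end[df$contig_id == cid],
                              df$start[df$contig_id == cid]),
                 circular = FALSE, stringsAsFactors = FALSE)
    }))
  }
  genome_annotation(strain_id, contigs, df)
}

.read_genbank <- function(path, strain_id) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1)
    stop("expected exactly one LOCUS record in ", path)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  contig_id <- toks[2]
  clen <- as.numeric(toks[3])
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  feat_start <- grep("^FEATURES", lines)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- feat_end[feat_end > feat_start][1]
  if (is.na(feat_end)) feat_end <- length(lines) + 1
  fl <- lines[(feat_start + 1):(feat_end - 1)]

  is_key <- grepl("^ {5}\\S", fl)
  starts <- which(is_key & grepl("^ {5}CDS\\s", fl))
  nexts <- c(which(is_key), length(fl) + 1)
  recs <- lapply(starts, function(i) {
    j <- nexts[nexts > i][1]
    fl[i:(j - 1)]
  })

  parse_rec <- function(block) {
    loc <- sub("^ {5}CDS\\s+", "", block[1])
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order", loc))
      stop("compound GenBank locations are not supported: ", loc)
    m <- regmatches(loc, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", loc))[[1]]
    if (length(m) != 3) stop("malformed GenBank location: ", loc)
    qual_text <- paste(trimws(block[-1]), collapse = "\n")
    getq <- function(name, collapse_ws = TRUE) {
      pat <- sprintf("/%s=\"([^\"]*)\"", name)
      mm <- regmatches(qual_text, regexec(pat, qual_text))[[1]]
      if (length(mm) < 2) return(NA_character_)
      v <- gsub("\n", if (collapse_ws) " " else "", mm[2])
      v
    }
    translation <- getq("translation", collapse_ws = FALSE)
    if (!is.na(translation)) translation <- gsub("\\s", "", translation)
    data.frame(
      gene_id = getq("locus_tag"), contig_id = contig_id,
      start = as.integer(m[2]), end = as.integer(m[3]),
      strand = strand, protein_seq = translation,
      product = getq("product"), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(recs, parse_rec))
  if (is.null(genes) || nrow(genes) == 0)
    stop("no CDS features found in ", path)
  if (anyNA(genes$gene_id))
    stop("CDS feature without /locus_tag in ", path)
  ctg <- data.frame(contig_id = contig_id, length = clen,
                    circular = circular, stringsAsFactors = FALSE)
  genome_annotation(strain_id, ctg, genes)
}

# ---- writers ----------------------------------------------------------------

#' Write a genome annotation as GFF3 (+ optional protein FASTA)
#'
#' Emits one `region` feature per contig (carrying `Is_circular`) and one CDS
#' feature per gene. Origin-spanning genes cannot be represented in GFF3 and
#' raise an error; use the TSV dialect for those.
#'
#' @param ann A `genome_annotation`.
#' @param gff_path Output GFF3 path.
#' @param faa_path Optional output protein FASTA path.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(ann, gff_path, faa_path = NULL) {
  g <- ann$genes
  if (any(g$end < g$start))
    stop("origin-spanning genes cannot be written as GFF3; use TSV")
  ctg <- ann$contigs
  reg <- GenomicRanges::GRanges(
    seqnames = ctg$contig_id,
    ranges = IRanges::IRanges(start = 1, end = ctg$length))
  S4Vectors::mcols(reg)$type <- "region"
  S4Vectors::mcols(reg)$ID <- paste0("region-", ctg$contig_id)
  S4Vectors::mcols(reg)$Is_circular <-
    ifelse(ctg$circular, "true", NA_character_)
  cds <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  S4Vectors::mcols(cds)$type <- "CDS"
  S4Vectors::mcols(cds)$ID <- g$gene_id
  S4Vectors::mcols(cds)$product <- g$product
  S4Vectors::mcols(cds)$phase <- 0L
  gr <- suppressWarnings(c(reg, cds))
  sl <- setNames(as.integer(ctg$length), ctg$contig_id)
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- sl[
    GenomeInfoDb::seqlevels(gr)])
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(faa_path)) {
    ok <- !is.na(g$protein_seq)
    aa <- Biostrings::AAStringSet(setNames(g$protein_seq[ok], g$gene_id[ok]))
    Biostrings::writeXStringSet(aa, faa_path)
  }
  invisible(gff_path)
}

#' Write result tables
#'
#' @param objects For `cassette_table`/`synteny_table`: a data.frame. For
#'   `association`: a list (written as JSON). For `itol`: character lines of
#'   an iTOL dataset. For `bed`: a cassette table (converted to 0-based
#'   half-open BED of cassette spans).
#' @param kind One of `"cassette_table"`, `"synteny_table"`, `"association"`,
#'   `"itol"`, `"bed"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(objects,
                          kind = c("cassette_table", "synteny_table",
                                   "association", "itol", "bed"),
                          path) {
  kind <- match.arg(kind)
  if (kind %in% c("cassette_table", "synteny_table")) {
    stopifnot(is.data.frame(objects))
    write.table(objects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (kind == "association") {
    jsonlite::write_json(objects, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else if (kind == "itol") {
    writeLines(objects, path)
  } else { # bed: 0-based half-open conversion at the boundary
    stopifnot(is.data.frame(objects),
              all(c("strain_id", "contig_id", "span_start", "span_end")
                  %in% names(objects)))
    bed <- data.frame(chrom = objects$contig_id,
                      chromStart = objects$span_start - 1L,
                      chromEnd = objects$span_end,
                      name = paste(objects$strain_id, objects$variant,
                                   sep = "|"))
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a cassette table written by [write_results()]
#' @param path TSV path.
#' @return data.frame with the cassette-table columns.
#' @export
read_cassette_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("inverted", "origin_spanning"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}
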