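#' @title Cassette architecture: co-localization, variant, synteny, inversion
#' @name cassette_arch
#' @description
#' Family hits are clustered into cassettes per contig when their gene
#' midpoints lie within `max_gap` (strictly less than 5000 bp by default) of
#' each other under single-linkage closure; the cluster is classified LONG
#' (all ten families), SHORT (exactly yihT/U/V/W), or PARTIAL; its span runs
#' from the first member's start to the last member's end; the nearest
#' universal single-copy orthologous group (UOG) genes up- and downstream
#' anchor the locus; and orientation is called against the reference
#' (long-variant) family order, yielding an inversion flag.
NULL

.hit_coords <- function(hits, genome) {
  g <- genome$genes
  idx <- match(hits$gene_id, g$gene_id)
  if (anyNA(idx))
    stop("hit references unknown gene(s): ",
         paste(hits$gene_id[is.na(idx)], collapse = ", "))
  mid <- vapply(idx, function(i)
    gene_midpoint(g[i, ], .contig_of(genome, g$contig_id[i])), numeric(1))
  data.frame(family_id = hits$family_id, gene_id = hits$gene_id,
             contig_id = g$contig_id[idx], start = g$start[idx],
             end = g$end[idx], strand = g$strand[idx], midpoint = mid,
             identity = if ("identity" %in% names(hits)) hits$identity else NA,
             stringsAsFactors = FALSE)
}

#' Cluster co-localized family hits
#'
#' Two hits on the same contig join a cluster iff the distance between their
#' gene midpoints is strictly less than `max_gap` under the chosen linkage
#' closure (single linkage by default: the weakest consistent closure of the
#' pairwise rule, matching contiguous operon structure; complete linkage is
#' available for sensitivity analysis). Distances respect circular contigs.
#'
#' @param hits data.frame from [find_family_hits()] (or any table with
#'   `family_id`, `gene_id`).
#' @param genome The `genome_annotation` the hits refer to.
#' @param max_gap Midpoint distance threshold in bp (strict; default 5000).
#' @param linkage `"single"` or `"complete"`.
#' @return List of member clusters (data.frames with columns `family_id`,
#'   `gene_id`, `contig_id`, `start`, `end`, `strand`, `midpoint`,
#'   `identity`), ordered by contig then leftmost midpoint; members within a
#'   cluster are ordered by midpoint.
#' @export
cluster_colocalized <- function(hits, genome, max_gap = 5000,
                                linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(hits) == 0) return(list())
  mem <- .hit_coords(hits, genome)
  out <- list()
  for (cid in unique(mem$contig_id)) {
    sub <- mem[mem$contig_id == cid, , drop = FALSE]
    sub <- sub[order(sub$midpoint, sub$gene_id), , drop = FALSE]
    ctg <- .contig_of(genome, cid)
    if (nrow(sub) == 1) {
      grp <- 1L
    } else {
      d <- outer(sub$midpoint, sub$midpoint,
                 function(x, y) circular_distance(x, y, ctg))
      h <- stats::hclust(stats::as.dist(d), method = linkage)
      # strict "< max_gap": cut just below the threshold (midpoint distances
      # are multiples of 0.5, so 1e-6 cannot cross a real merge height)
      grp <- stats::cutree(h, h = max_gap - 1e-6)
    }
    for (k in unique(grp)) out[[length(out) + 1L]] <-
        sub[grp == k, , drop = FALSE]
  }
  lefts <- vapply(out, function(cl) min(cl$midpoint), numeric(1))
  ctgs <- vapply(out, function(cl) cl$contig_id[1], character(1))
  out <- out[order(ctgs, lefts)]
  lapply(out, function(cl) { rownames(cl) <- NULL; cl })
}

#' Classify the structural variant of a member cluster
#'
#' LONG iff all ten cassette families are present; SHORT iff the family set
#' is exactly yihT, yihU, yihV, yihW; PARTIAL for any other non-empty set;
#' NONE for an empty cluster. Classification depends only on the family set;
#' duplicated families within a cluster are flagged with a warning and
#' classification proceeds on the set.
#'
#' @param cluster A member cluster data.frame (or a character vector of
#'   family ids).
#' @return One of `"LONG"`, `"SHORT"`, `"PARTIAL"`, `"NONE"`.
#' @export
classify_variant <- function(cluster) {
  fams <- if (is.data.frame(cluster)) cluster$family_id else cluster
  if (length(fams) == 0) return("NONE")
  if (anyDuplicated(fams))
    warning("duplicate family within one cluster: ",
            paste(unique(fams[duplicated(fams)]), collapse = ", "),
            "; classifying on the family set")
  fs <- unique(fams)
  if (setequal(fs, yih_families())) return("LONG")
  if (setequal(fs, yih_short_families())) return("SHORT")
  "PARTIAL"
}

#' Span of a cassette cluster
#'
#' The start coordinate of the first member gene and the end coordinate of
#' the last. On circular contigs a cluster whose locus crosses the origin
#' (detected as the complement of the largest inter-member gap on the
#' circle) is reported on the unwrapped coordinate (end may exceed the
#' contig length) with `origin_spanning = TRUE`.
#'
#' @param cluster Member cluster data.frame.
#' @param genome The `genome_annotation`.
#' @return List with `start`, `end`, `origin_spanning`.
#' @export
cassette_span <- function(cluster, genome) {
  if (length(unique(cluster$contig_id)) != 1)
    stop("cluster members lie on multiple contigs")
  ctg <- .contig_of(genome, cluster$contig_id[1])
  L <- ctg$length
  starts <- cluster$start; ends <- cluster$end
  wrapped_genes <- ends < starts
  wrap <- FALSE
  if (isTRUE(ctg$circular) && nrow(cluster) > 1) {
    mp <- sort(cluster$midpoint)
    gaps <- diff(c(mp, mp[1] + L))
    if (which.max(gaps) != length(mp)) wrap <- TRUE
  }
  wrap <- wrap || any(wrapped_genes)
  if (!wrap) return(list(start = min(starts), end = max(ends),
                         origin_spanning = FALSE))
  if (!isTRUE(ctg$circular))
    stop("wrapped cluster on a linear contig")
  # unwrap: shift members left of the largest gap boundary by +L
  mp <- cluster$midpoint
  ord <- order(mp)
  gaps <- diff(c(sort(mp), sort(mp)[1] + L))
  cutpos <- which.max(gaps) # locus starts after the largest gap
  first_mp <- sort(mp)[(cutpos %% length(mp)) + 1]
  shift <- mp < first_mp
  starts2 <- ifelse(shift, starts + L, starts)
  ends2 <- ifelse(wrapped_genes, ends + L, ifelse(shift, ends + L, ends))
  list(start = min(starts2), end = max(ends2), origin_spanning = TRUE)
}

#' Nearest flanking UOG genes of a cassette
#'
#' Upstream: the UOG gene on the cassette's contig with the largest end
#' strictly below the span start; downstream: the smallest start strictly
#' above the span end (ascending-coordinate convention). On circular contigs
#' the search wraps around the origin. Distances are non-negative gap sizes.
#'
#' @param cassette A cassette object from [detect_cassettes()] or a list
#'   with `strain_id`, `contig_id` and `span` (list with start/end).
#' @param uogs A [uog_table()] data.frame.
#' @param genome The `genome_annotation`.
#' @return List (`synteny_context`): `upstream_uog`, `downstream_uog` (each
#'   `NULL` or list(uog_id, gene_id, distance)), `inverted` (NA here; set by
#'   [call_orientation()]).
#' @export
flanking_uogs <- function(cassette, uogs, genome) {
  ctx <- list(upstream_uog = NULL, downstream_uog = NULL, inverted = NA)
  class(ctx) <- "synteny_context"
  u <- uogs[uogs$strain_id == genome$strain_id, , drop = FALSE]
  if (nrow(u) == 0) {
    warning("empty UOG table for strain ", genome$strain_id,
            "; no flanks assigned")
    return(ctx)
  }
  g <- genome$genes
  idx <- match(u$gene_id, g$gene_id)
  keep <- !is.na(idx) & g$contig_id[idx] == cassette$contig_id
  u <- u[keep, , drop = FALSE]; idx <- idx[keep]
  if (nrow(u) == 0) return(ctx)
  ctg <- .contig_of(genome, cassette$contig_id)
  L <- ctg$length
  us <- g$start[idx]; ue <- g$end[idx]
  s <- cassette$span$start; e <- cassette$span$end

  up <- which(ue < s)
  if (length(up) > 0) {
    i <- up[which.max(ue[up])]
    ctx$upstream_uog <- list(uog_id = u$uog_id[i], gene_id = u$gene_id[i],
                             distance = max(0, s - ue[i] - 1))
  } else if (isTRUE(ctg$circular)) {
    i <- which.max(ue)
    ctx$upstream_uog <- list(uog_id = u$uog_id[i], gene_id = u$gene_id[i],
                             distance = max(0, (s - ue[i] - 1) %% L))
  }
  e_lin <- if (e > L && isTRUE(ctg$circular)) e - L else e
  down <- which(us > e)
  if (length(down) > 0) {
    i <- down[which.min(us[down])]
    ctx$downstream_uog <- list(uog_id = u$uog_id[i], gene_id = u$gene_id[i],
                               distance = max(0, us[i] - e - 1))
  } else if (isTRUE(ctg$circular)) {
    down2 <- which(us > e_lin & us <= L)
    i <- if (length(down2) > 0) down2[which.min(us[down2])] else which.min(us)
    ctx$downstream_uog <- list(uog_id = u$uog_id[i], gene_id = u$gene_id[i],
                               distance = max(0, (us[i] - e_lin - 1) %% L))
  }
  ctx
}

#' Call cassette orientation and inversion
#'
#' Members are read along ascending coordinates. Orientation is `forward`
#' when the family order equals the reference order restricted to the
#' present families and the majority strand is `+`; `reverse` when it equals
#' the reversed restriction with majority strand `-`; `mixed` otherwise.
#' The long configuration anchored by its upstream flank defines "forward",
#' so `inverted` is TRUE iff the orientation is `reverse` (when a synteny
#' context and `reference_upstream` are supplied and the flank pair itself
#' is swapped relative to the reference, the call is flipped accordingly).
#'
#' @param cluster Member cluster data.frame (ordered or not).
#' @param context Optional `synteny_context` from [flanking_uogs()].
#' @param reference_order Family order of the reference long configuration.
#' @param reference_upstream Optional UOG id expected upstream in the
#'   reference configuration (e.g. "UOG217").
#' @return List: `orientation` ("forward"/"reverse"/"mixed"), `inverted`
#'   (logical; NA when orientation is mixed).
#' @export
call_orientation <- function(cluster, context = NULL,
                             reference_order = yih_families(),
                             reference_upstream = NULL) {
  if (nrow(cluster) == 0) stop("empty cluster")
  cl <- cluster[order(cluster$midpoint), , drop = FALSE]
  fams <- cl$family_id
  ref <- reference_order[reference_order %in% fams]
  n_plus <- sum(cl$strand == "+")
  maj_plus <- n_plus > nrow(cl) / 2
  maj_minus <- (nrow(cl) - n_plus) > nrow(cl) / 2
  orientation <-
    if (identical(fams, ref) &&
        (maj_plus || nrow(cl) == 1 && cl$strand[1] == "+")) "forward"
    else if (identical(fams, rev(ref)) &&
             (maj_minus || nrow(cl) == 1 && cl$strand[1] == "-")) "reverse"
    else "mixed"
  inverted <- switch(orientation, forward = FALSE, reverse = TRUE, NA)
  if (!is.na(inverted) && !is.null(context) && !is.null(reference_upstream) &&
      !is.null(context$upstream_uog) && !is.null(context$downstream_uog) &&
      context$downstream_uog$uog_id == reference_upstream) {
    # the whole locus (flanks included) is flipped: orientation relative to
    # the flank pair is unchanged
    inverted <- !inverted
  }
  list(orientation = orientation, inverted = inverted)
}

#' Detect yih cassettes in one genome
#'
#' Full per-strain pipeline: family hits, co-localization clustering,
#' variant classification, span, UOG anchoring and orientation. All clusters
#' are reported; the strain-level call is the best-supported cluster (most
#' distinct families, ties broken by leftmost position), with a warning when
#' several clusters exist.
#'
#' @param genome A `genome_annotation` with protein sequences.
#' @param queries A [query_family_set()] of the ten cassette gene families.
#' @param uogs A [uog_table()] data.frame (may be empty).
#' @param max_gap,min_identity,min_coverage,linkage Passed through.
#' @param hits Optional precomputed hit table (e.g. from
#'   [read_blast_tab()]); when supplied the internal aligner is skipped.
#' @return Object of class `cassette_call`: list with `strain_id`,
#'   `variant` (strain-level), `cassettes` (list, each with members, span,
#'   variant, orientation, inverted, synteny context), `n_loci`.
#' @export
detect_cassettes <- function(genome, queries, uogs = NULL, max_gap = 5000,
                             min_identity = 40, min_coverage = 70,
                             linkage = "single", hits = NULL) {
  if (is.null(hits))
    hits <- find_family_hits(queries, genome, min_identity, min_coverage)
  clusters <- cluster_colocalized(hits, genome, max_gap, linkage)
  cassettes <- lapply(clusters, function(cl) {
    span <- cassette_span(cl, genome)
    cas <- list(strain_id = genome$strain_id, contig_id = cl$contig_id[1],
                members = cl[order(cl$midpoint), , drop = FALSE],
                span = span, variant = classify_variant(cl))
    ctx <- if (!is.null(uogs)) flanking_uogs(cas, uogs, genome)
           else structure(list(upstream_uog = NULL, downstream_uog = NULL,
                               inverted = NA), class = "synteny_context")
    ori <- call_orientation(cl, ctx)
    cas$orientation <- ori$orientation
    cas$inverted <- ori$inverted
    cas$context <- ctx
    class(cas) <- "cassette"
    cas
  })
  if (length(cassettes) > 1)
    warning("strain ", genome$strain_id, " has ", length(cassettes),
            " cassette-like loci; reporting the best-supported one at ",
            "strain level")
  best <- NULL
  if (length(cassettes) > 0) {
    nfam <- vapply(cassettes, function(c) length(unique(c$members$family_id)),
                   integer(1))
    left <- vapply(cassettes, function(c) min(c$members$midpoint), numeric(1))
    best <- cassettes[[order(-nfam, left)[1]]]
  }
  structure(list(strain_id = genome$strain_id,
                 variant = if (is.null(best)) "NONE" else best$variant,
                 best = best, cassettes = cassettes,
                 n_loci = length(cassettes)),
            class = "cassette_call")
}

#' @export
print.cassette_call <- function(x, ...) {
  cat(sprintf("<cassette_call> %s: %s (%d locus/loci)\n",
              x$strain_id, x$variant, x$n_loci))
  invisible(x)
}

#' Tabulate cassette calls
#'
#' @param calls A list of `cassette_call` objects (one per strain).
#' @return data.frame with one row per strain: strain_id, contig, variant,
#'   span_start, span_end, origin_spanning, orientation, inverted, families
#'   (comma list), upstream_uog, upstream_gap, downstream_uog,
#'   downstream_gap, n_loci.
#' @export
cassette_table <- function(calls) {
  rows <- lapply(calls, function(cc) {
    b <- cc$best
    if (is.null(b))
      return(data.frame(strain_id = cc$strain_id, contig_id = NA, variant =
               "NONE", span_start = NA, span_end = NA, origin_spanning = NA,
               orientation = NA, inverted = NA, families = "",
               upstream_uog = NA, upstream_gap = NA, downstream_uog = NA,
               downstream_gap = NA, n_loci = 0L, stringsAsFactors = FALSE))
    up <- b$context$upstream_uog; dn <- b$context$downstream_uog
    data.frame(strain_id = cc$strain_id, contig_id = b$contig_id,
               variant = b$variant, span_start = b$span$start,
               span_end = b$span$end,
               origin_spanning = b$span$origin_spanning,
               orientation = b$orientation, inverted = b$inverted,
               families = paste(b$members$family_id, collapse = ","),
               upstream_uog = if (is.null(up)) NA else up$uog_id,
               upstream_gap = if (is.null(up)) NA else up$distance,
               downstream_uog = if (is.null(dn)) NA else dn$uog_id,
               downstream_gap = if (is.null(dn)) NA else dn$distance,
               n_loci = cc$n_loci, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a genome for alternative co-localized enzyme clusters
#'
#' Applies [find_family_hits()] with permissive thresholds followed by
#' [cluster_colocalized()], reporting any multi-member cluster and the
#' genome-wide maximum identity to the enzyme set. Used to ask whether SQ
#' catabolism could be encoded outside the canonical cassette locus.
#'
#' @param genome A `genome_annotation`.
#' @param enzyme_set A [query_family_set()] of known enzymes.
#' @param max_gap Midpoint threshold in bp.
#' @param min_identity,min_coverage Permissive thresholds (defaults 20/50).
#' @return List: `multi_clusters` (list of clusters with >= 2 members),
#'   `singletons` (data.frame of lone candidates), `max_identity`
#'   (genome-wide maximum identity to the set).
#' @export
scan_alternative_clusters <- function(genome, enzyme_set, max_gap = 5000,
                                      min_identity = 20, min_coverage = 50) {
  hits <- find_family_hits(enzyme_set, genome, min_identity, min_coverage)
  clusters <- cluster_colocalized(hits, genome, max_gap)
  sizes <- vapply(clusters, nrow, integer(1))
  idtab <- max_identity_to_known_enzymes(genome, enzyme_set)
  list(multi_clusters = clusters[sizes >= 2],
       singletons = if (any(sizes == 1))
         do.call(rbind, clusters[sizes == 1]) else NULL,
       max_identity = if (nrow(idtab) > 0) max(idtab$best_identity) else 0)
}
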